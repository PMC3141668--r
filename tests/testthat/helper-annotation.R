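# Hand-built two-(plus-)transcript gene model on an all-A contig, shared
# by the annotation tests and the acceptance suite. Every plus-strand
# codon is AAA (Lys) and every minus-strand codon TTT (Phe), so amino-acid
# expectations are manual genetic-code derivations.

annotFixture <- function() {
  ref <- refFromStrings(strrep("A", 700))
  models <- list(
    # plus strand: exons 101-160 / 201-280 / 351-420,
    # CDS 121-160 / 201-280 / 351-380 (150 nt = 50 codons)
    T1 = geneModel("T1", "G1", "c1", "+",
                   exons = IRanges::IRanges(c(101, 201, 351),
                                            c(160, 280, 420)),
                   cds = IRanges::IRanges(c(121, 201, 351),
                                          c(160, 280, 380))),
    # overlapping alternative transcript whose exon reaches into T1's
    # intron; its CDS starts later so early positions are 5'UTR
    T3 = geneModel("T3", "G1", "c1", "+",
                   exons = IRanges::IRanges(151, 230),
                   cds = IRanges::IRanges(171, 230)),
    # minus strand single-exon CDS 501-560 (60 nt = 20 codons of TTT)
    T2 = geneModel("T2", "G2", "c1", "-",
                   exons = IRanges::IRanges(501, 560),
                   cds = IRanges::IRanges(501, 560)),
    # incomplete model: CDS length 40, not divisible by 3
    T4 = geneModel("T4", "G3", "c1", "+",
                   exons = IRanges::IRanges(601, 640),
                   cds = IRanges::IRanges(601, 640)))
  list(ref = ref, models = models)
}
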