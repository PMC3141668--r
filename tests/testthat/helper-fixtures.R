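# Small fixture builders shared across test files. Everything is built in
# code; no fixture files.

refFromStrings <- function(...) {
  seqs <- c(...)
  ref <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(ref) <- paste0("c", seq_along(seqs))
  ref
}

randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  vapply(s, function(x)
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(x, "")[[1]]), collapse = "")), "",
    USE.NAMES = FALSE)
}

# one calls-data.frame row per SNP; pair is (ref, alt1) unless alt2 given
makeCalls <- function(chrom, pos, ref, alt1, alt2 = NA_character_,
                      readsRef = 5L, readsAlt1 = 5L, readsAlt2 = NA_integer_,
                      qualRef = 30L, qualAlt1 = 30L, qualAlt2 = NA_integer_,
                      zygosity = "het", triallelic = FALSE) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
             alt1 = alt1, alt2 = alt2,
             readsRef = as.integer(readsRef),
             readsAlt1 = as.integer(readsAlt1),
             readsAlt2 = as.integer(readsAlt2),
             qualRef = as.integer(qualRef),
             qualAlt1 = as.integer(qualAlt1),
             qualAlt2 = as.integer(qualAlt2),
             zygosity = zygosity, triallelic = triallelic,
             stringsAsFactors = FALSE)
}

# a base-space ReadSet from plain vectors, defaulting quals to Phred 40
makeReads <- function(sequences, chrom, pos, strand = NULL, quals = NULL,
                      id = "rs", animal = "a1", chemistry = "sanger") {
  n <- length(sequences)
  if (is.null(strand)) strand <- rep("+", n)
  if (is.null(quals))
    quals <- vapply(nchar(sequences), function(w)
      paste(rep("I", w), collapse = ""), "")
  ReadSet(id = id, sequences = sequences, quals = quals,
          chrom = chrom, pos = as.integer(pos), strand = strand,
          animal = animal, chemistry = chemistry, space = "base")
}

# random SnpDataset of n het SNPs on one contig (distinct positions)
randomDataset <- function(id, n, L = 10000L, animal = "a1",
                          chemistry = "sanger", posPool = NULL) {
  pos <- if (is.null(posPool)) sample.int(L, n) else sample(posPool, n)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), "", USE.NAMES = FALSE)
  SnpDataset(id, animal, chemistry, "test",
             makeCalls("c1", sort(pos), ref, alt))
}
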