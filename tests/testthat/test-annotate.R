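# The shared hand-built gene model (annotFixture) lives in
# helper-annotation.R; expected amino-acid changes in these tests are
# manual genetic-code derivations.

test_that("placements match manual genetic-code derivations", {
  fx <- annotFixture()
  ann <- function(pos, alt) annotateSnp("c1", pos, "A", alt, fx$models,
                                        fx$ref)
  # codon 1 third position AAA->AAG: Lys->Lys, synonymous
  r <- ann(123, "G")
  expect_identical(r$category, "synonymous")
  expect_identical(c(r$refAA, r$altAA), c("K", "K"))
  expect_identical(r$proteinPos, 1L)
  # codon 2 first position AAA->GAA: Lys->Glu
  r <- ann(124, "G")
  expect_identical(r$category, "nonsynonymous")
  expect_identical(c(r$refAA, r$altAA), c("K", "E"))
  expect_identical(r$proteinPos, 2L)
  # first base of the second CDS chunk: coding position 41, codon 14
  # second position, AAA->AGA: Lys->Arg
  r <- ann(201, "G")
  expect_identical(r$category, "nonsynonymous")
  expect_identical(c(r$refAA, r$altAA, r$proteinPos), c("K", "R", "14"))
  # minus strand: genomic A>G at 558 is coding T>C at position 3,
  # TTT->TTC: Phe->Phe synonymous
  r <- ann(558, "G")
  expect_identical(r$category, "synonymous")
  expect_identical(c(r$refAA, r$altAA), c("F", "F"))
  # minus strand first codon base (genomic 560, A>C is coding T>G),
  # TTT->GTT: Phe->Val
  r <- ann(560, "C")
  expect_identical(r$category, "nonsynonymous")
  expect_identical(c(r$refAA, r$altAA), c("F", "V"))
})

test_that("non-coding placements follow the interval logic", {
  fx <- annotFixture()
  ann <- function(pos, alt = "G") annotateSnp("c1", pos, "A", alt,
                                              fx$models, fx$ref)
  expect_identical(ann(50)$category, "intergenic")
  expect_identical(ann(110)$category, "utr5")     # exon before CDS, + strand
  expect_identical(ann(400)$category, "utr3")     # exon after CDS, + strand
  expect_identical(ann(161)$category, "splice_site")  # intron base 1
  expect_identical(ann(200)$category, "splice_site")  # intron last base
  expect_identical(ann(300)$category, "intronic")     # mid-intron (T1 only)
  expect_identical(ann(285)$category, "intronic")     # beyond 2 bp window
  # widened splice window captures deeper intronic bases
  wide <- annotateSnp("c1", 285, "A", "G", fx$models, fx$ref,
                      spliceWindow = 5L)
  expect_identical(wide$category, "splice_site")
  # incomplete CDS downgrades to coding_unresolved
  expect_identical(ann(610)$category, "coding_unresolved")
  # reference allele disagreement is an error
  expect_error(annotateSnp("c1", 50, "C", "G", fx$models, fx$ref),
               "mismatch")
})

test_that("per-transcript placements can vary and consolidate by priority", {
  fx <- annotFixture()
  # 155: coding in T1, 5'UTR in T3 -> consolidated coding, flagged varying
  r <- annotateSnp("c1", 155, "A", "G", fx$models, fx$ref)
  expect_true(r$placementVaries)
  expect_true(r$category %in% c("synonymous", "nonsynonymous"))
  expect_match(r$placements, "T3:utr5")
  # 210: coding in both T1 and T3 -> no variation flag
  r2 <- annotateSnp("c1", 210, "A", "G", fx$models, fx$ref)
  expect_false(r2$placementVaries)
})

test_that("minus-strand annotation equals plus-strand on the mirrored locus", {
  fx <- annotFixture()
  L <- 700L
  mirrorRef <- Biostrings::DNAStringSet(
    Biostrings::reverseComplement(fx$ref[[1]]))
  names(mirrorRef) <- "c1"
  # T2 (minus, exon/CDS 501-560) mirrors to a plus-strand model
  mT2 <- geneModel("mT2", "G2", "c1", "+",
                   exons = IRanges::IRanges(L - 560 + 1L, L - 501 + 1L),
                   cds = IRanges::IRanges(L - 560 + 1L, L - 501 + 1L))
  for (case in list(c(558L, "G"), c(560L, "C"), c(530L, "T"))) {
    pos <- as.integer(case[1]); alt <- case[2]
    orig <- annotateSnp("c1", pos, "A", alt, fx$models["T2"], fx$ref)
    mirPos <- L - pos + 1L
    mirAlt <- chartr("ACGT", "TGCA", alt)
    mir <- annotateSnp("c1", mirPos, "T", mirAlt, list(mT2 = mT2),
                       mirrorRef)
    expect_identical(mir$category, orig$category)
    expect_identical(mir$refAA, orig$refAA)
    expect_identical(mir$altAA, orig$altAA)
    expect_identical(mir$proteinPos, orig$proteinPos)
  }
})

test_that("every SNP gets exactly one category and summaries normalise", {
  fx <- annotFixture()
  set.seed(90)
  pos <- sample(1:700, 120)
  snps <- data.frame(chrom = "c1", pos = pos, ref = "A",
                     alt = sample(c("C", "G", "T"), 120, replace = TRUE),
                     stringsAsFactors = FALSE)
  recs <- annotateSnps(snps, fx$models, fx$ref)
  expect_identical(nrow(recs), 120L)
  expect_false(any(is.na(recs$category)))
  expect_true(all(recs$category %in% c(
    "intergenic", "intronic", "splice_site", "synonymous",
    "nonsynonymous", "utr5", "utr3", "coding_unresolved")))
  sm <- summarizeAnnotation(recs)
  expect_equal(sum(sm$fractions), 1, tolerance = 1e-12)
  expect_identical(sm$nPlacementVaries, sum(recs$placementVaries))
  expect_identical(as.integer(sum(sm$counts)), 120L)

  allInter <- recs[recs$category == "intergenic", ]
  smI <- summarizeAnnotation(allInter)
  expect_identical(as.numeric(smI$fractions[["intergenic"]]), 1)
})

test_that("variant translation differs exactly at the reported protein position", {
  fx <- annotFixture()
  r <- annotateSnp("c1", 124, "A", "G", fx$models, fx$ref)
  cds <- strrep("AAA", 50)
  varCds <- cds
  substr(varCds, 4, 4) <- "G"
  p1 <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  p2 <- as.character(Biostrings::translate(Biostrings::DNAString(varCds)))
  d <- which(strsplit(p1, "")[[1]] != strsplit(p2, "")[[1]])
  expect_identical(d, r$proteinPos)
})

test_that("gene models round-trip through GFF3", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\ttest\tgene\t101\t420\t.\t+\t.\tID=G1",
    "c1\ttest\tmRNA\t101\t420\t.\t+\t.\tID=T1;Parent=G1",
    "c1\ttest\texon\t101\t160\t.\t+\t.\tID=e1;Parent=T1",
    "c1\ttest\texon\t201\t280\t.\t+\t.\tID=e2;Parent=T1",
    "c1\ttest\texon\t351\t420\t.\t+\t.\tID=e3;Parent=T1",
    "c1\ttest\tCDS\t121\t160\t.\t+\t0\tID=c1a;Parent=T1",
    "c1\ttest\tCDS\t201\t280\t.\t+\t2\tID=c1b;Parent=T1",
    "c1\ttest\tCDS\t351\t380\t.\t+\t0\tID=c1c;Parent=T1",
    "c1\ttest\tmRNA\t501\t560\t.\t-\t.\tID=T2;Parent=G2",
    "c1\ttest\texon\t501\t560\t.\t-\t.\tID=e4;Parent=T2",
    "c1\ttest\tCDS\t501\t560\t.\t-\t0\tID=c2a;Parent=T2"), f)
  models <- readGeneModels(f)
  expect_setequal(names(models), c("T1", "T2"))
  expect_identical(models$T1$strand, "+")
  expect_identical(length(models$T1$exons), 3L)
  expect_identical(sum(IRanges::width(models$T1$cds)), 150L)
  expect_identical(models$T2$strand, "-")

  # classifications agree with the hand-built model
  fx <- annotFixture()
  r <- annotateSnp("c1", 124, "A", "G", models, fx$ref)
  expect_identical(r$category, "nonsynonymous")
  expect_identical(c(r$refAA, r$altAA), c("K", "E"))
})
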