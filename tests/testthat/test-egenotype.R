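test_that("probes carry 15 bp flanks and differ only at the centre", {
  ref <- refFromStrings(paste0(strrep("A", 15), "A", strrep("G", 15)))
  snps <- makeCalls("c1", 16, "A", "G")
  p <- buildProbes(ref, snps)
  expect_identical(nrow(p), 2L)
  expect_setequal(p$allele, c("A", "G"))
  expect_true(all(nchar(p$sequence) == 31L))
  expect_identical(p$centerIndex, c(16L, 16L))
  s <- p$sequence
  diffs <- which(strsplit(s[1], "")[[1]] != strsplit(s[2], "")[[1]])
  expect_identical(diffs, 16L)
  expect_identical(substr(s[p$allele == "G"], 16, 16), "G")
})

test_that("SNPs near contig ends or gaps yield no probes", {
  ref <- refFromStrings(paste0(strrep("C", 40)))
  p <- buildProbes(ref, makeCalls("c1", 10, "C", "T"))
  expect_identical(nrow(p), 0L)
  expect_match(attr(p, "skipped")$reason, "contig end")

  withN <- Biostrings::DNAStringSet(paste0(strrep("C", 14), "N",
                                           strrep("C", 25)))
  names(withN) <- "c1"
  p2 <- buildProbes(withN, makeCalls("c1", 20, "C", "T"))
  expect_identical(nrow(p2), 0L)
  expect_match(attr(p2, "skipped")$reason, "ambiguous")

  # a non-reference allele pair yields three probes (ref + both alts)
  ref3 <- refFromStrings(randomSeq(60))
  call3 <- makeCalls("c1", 30, substr(as.character(ref3[[1]]), 30, 30),
                     alt1 = "A", alt2 = "C", readsRef = 0)
  call3$alt1 <- setdiff(c("A", "C", "G", "T"), call3$ref)[1]
  call3$alt2 <- setdiff(c("A", "C", "G", "T"), call3$ref)[2]
  p3 <- buildProbes(ref3, call3)
  expect_identical(nrow(p3), 3L)
})

test_that("uniqueness counts probe-window occurrences on both strands", {
  set.seed(50)
  core <- randomSeq(31)
  filler1 <- randomSeq(40); filler2 <- randomSeq(40)
  # planted twice -> not unique
  refDup <- refFromStrings(paste0(filler1, core, filler2, core, filler1))
  # planted once forward and once reverse-complemented -> not unique
  refRc <- refFromStrings(paste0(filler1, core, filler2, revcomp(core),
                                 filler1))
  # single occurrence -> unique
  refOne <- refFromStrings(paste0(filler1, core, filler2))
  snp <- makeCalls("c1", 41 + 15, substr(core, 16, 16),
                   setdiff(c("A", "C", "G", "T"), substr(core, 16, 16))[1])
  for (cfg in list(list(ref = refDup, want = FALSE),
                   list(ref = refRc, want = FALSE),
                   list(ref = refOne, want = TRUE))) {
    p <- screenProbeUniqueness(buildProbes(cfg$ref, snp), cfg$ref)
    expect_identical(unique(p$unique), cfg$want)
    # agreement with the naive window-occurrence oracle
    occ <- naiveWindowOccurrences(p$sequence[1], 16L, cfg$ref)
    expect_identical(unique(p$unique), occ == 1L)
  }
})

test_that("exact matching counts reads in base space, both strands", {
  set.seed(51)
  ref <- refFromStrings(randomSeq(200))
  snp <- makeCalls("c1", 100, substr(as.character(ref[[1]]), 100, 100),
                   setdiff(c("A", "C", "G", "T"),
                           substr(as.character(ref[[1]]), 100, 100))[1])
  probes <- screenProbeUniqueness(buildProbes(ref, snp), ref)
  refProbe <- probes$sequence[probes$allele == snp$ref]
  altProbe <- probes$sequence[probes$allele == snp$alt1]

  reads <- c(refProbe,                       # read == probe: counts 1
             revcomp(altProbe),              # reverse complement counts
             paste0("AC", refProbe, "GT"),   # embedded occurrence
             substr(refProbe, 1, 25),        # shorter than probe: never
             randomSeq(40))
  rs <- makeReads(reads, rep("c1", 5), rep(1, 5))
  res <- scanReadset(probes, rs, StringencyProfile())
  counts <- c(res$n1, res$n2, res$nRef)
  counts <- counts[!is.na(counts)]
  nref <- if (res$a1 == snp$ref) res$n1 else res$n2
  nalt <- if (res$a1 == snp$ref) res$n2 else res$n1
  expect_identical(nref, 2L)
  expect_identical(nalt, 1L)
  expect_identical(res$status, "positive")
})

test_that("scan counts equal the naive all-offsets/both-strands oracle", {
  set.seed(52)
  ref <- simulateReference(1, 4000, seed = 53)
  tt <- simulateIndividual(ref, 5e-3, seed = 54)
  rsBase <- simulateReads(ref, tt, ChemistryProfile("b", 60L, 4, 5e-3,
                                                    "base"), seed = 55)
  rsColor <- simulateReads(ref, tt, ChemistryProfile("cc", 60L, 4, 5e-3,
                                                     "color"), seed = 56)
  g <- genotypes(tt)
  snps <- makeCalls(g$chrom, g$pos, g$ref, g$a2)
  probes <- screenProbeUniqueness(buildProbes(ref, snps), ref)
  probes <- probes[probes$unique, ][seq_len(min(20, sum(probes$unique))), ]

  res <- scanReadset(probes, rsBase, StringencyProfile())
  naive <- naiveScanBase(probes, rsBase)
  for (i in seq_len(nrow(probes))) {
    r <- res[res$key == probes$key[i], ]
    got <- if (r$a1 == probes$allele[i]) r$n1
           else if (r$a2 == probes$allele[i]) r$n2 else r$nRef
    expect_identical(got, naive[i])
  }

  resC <- scanReadset(probes, rsColor, StringencyProfile())
  naiveC <- naiveScanColor(probes, rsColor)
  for (i in seq_len(nrow(probes))) {
    r <- resC[resC$key == probes$key[i], ]
    got <- if (r$a1 == probes$allele[i]) r$n1
           else if (r$a2 == probes$allele[i]) r$n2 else r$nRef
    expect_identical(got, naiveC[i])
  }
})

test_that("reverse-complementing every read leaves counts unchanged", {
  set.seed(57)
  ref <- simulateReference(1, 3000, seed = 58)
  tt <- simulateIndividual(ref, 4e-3, seed = 59)
  rs <- simulateReads(ref, tt, ChemistryProfile("b", 50L, 6, 0, "base"),
                      seed = 60)
  g <- genotypes(tt)
  probes <- screenProbeUniqueness(
    buildProbes(ref, makeCalls(g$chrom, g$pos, g$ref, g$a2)), ref)
  res1 <- scanReadset(probes, rs, StringencyProfile())
  flipped <- makeReads(revcomp(sequences(rs)), rs@chrom, rs@pos)
  res2 <- scanReadset(probes, flipped, StringencyProfile())
  expect_identical(res1[, c("key", "n1", "n2", "nRef")],
                   res2[, c("key", "n1", "n2", "nRef")])
})

test_that("mate-pair length reads (25 bp) can never match a 31 bp probe", {
  ref <- simulateReference(1, 5000, seed = 61)
  tt <- simulateIndividual(ref, 5e-3, seed = 62)
  rs <- simulateReads(ref, tt, chemistryPreset("solid_matepair"), seed = 63)
  g <- genotypes(tt)
  probes <- screenProbeUniqueness(
    buildProbes(ref, makeCalls(g$chrom, g$pos, g$ref, g$a2)), ref)
  res <- scanReadset(probes, rs, StringencyProfile())
  expect_true(all(res$n1 == 0L & res$n2 == 0L))
  expect_true(all(res$status == "negative"))
})

test_that("clustered SNPs within the probe window reduce detection", {
  set.seed(64)
  ref <- simulateReference(1, 60000, seed = 65)
  L <- 60000L
  # isolated het sites at every 100th position; clustered pairs 8 bp apart
  isoPos <- seq(2000L, 30000L, by = 100L)
  cluPos <- seq(32000L, 59000L, by = 100L)
  refc <- as.character(ref[[1]])
  baseAt <- function(p) substr(refc, p, p)
  altOf <- function(b) chartr("ACGT", "CGTA", b)
  g <- rbind(
    data.frame(individual = "ind1", chrom = "c1", pos = c(isoPos, cluPos),
               stringsAsFactors = FALSE),
    data.frame(individual = "ind1", chrom = "c1", pos = cluPos + 8L,
               stringsAsFactors = FALSE))
  g$ref <- baseAt(g$pos); g$a1 <- g$ref; g$a2 <- altOf(g$ref)
  tt <- TruthTable(genotypes = g,
                   contigs = c(c1 = L))
  rs <- simulateReads(ref, tt, ChemistryProfile("b", 50L, 8, 0, "base"),
                      seed = 66)
  snps <- makeCalls("c1", c(isoPos, cluPos), baseAt(c(isoPos, cluPos)),
                    altOf(baseAt(c(isoPos, cluPos))))
  res <- egenotypeSnps(ref, snps, rs)
  posRate <- function(p) {
    r <- res[res$pos %in% p & res$status != "no_probe", ]
    mean(r$status == "positive")
  }
  expect_gt(posRate(isoPos), posRate(cluPos))
})

test_that("genotype calls follow the per-allele positivity rule", {
  res <- data.frame(key = c("c1:1:A/G", "c1:2:A/G", "c1:3:A/C"),
                    chrom = "c1", pos = 1:3,
                    a1 = c("A", "A", "A"), a2 = c("G", "G", "C"),
                    n1 = c(3L, 4L, 250L), n2 = c(2L, 0L, 0L),
                    nRef = NA_integer_,
                    status = c("positive", "negative", "overflow"),
                    stringsAsFactors = FALSE)
  gc <- callGenotypes(res, StringencyProfile())
  expect_identical(gc$call, c("het", "hom", "no_call"))
  expect_identical(gc$g1[2], "A")
  expect_true(is.na(gc$g1[3]))
})
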