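test_that("reference simulation is deterministic and honours GC and lengths", {
  r1 <- simulateReference(1, 1000, 0.5, seed = 1)
  r2 <- simulateReference(1, 1000, 0.5, seed = 1)
  expect_identical(as.character(r1), as.character(r2))

  gcOnly <- simulateReference(1, 500, 1.0, seed = 2)
  expect_true(grepl("^[GC]+$", as.character(gcOnly[[1]])))

  r3 <- simulateReference(2, c(100, 200), seed = 3)
  expect_identical(names(r3), c("c1", "c2"))
  expect_identical(Biostrings::width(r3), c(100L, 200L))

  # base composition near requested GC for a long contig
  r4 <- simulateReference(1, 50000, 0.42, seed = 4)
  gc <- sum(Biostrings::letterFrequency(r4[[1]], c("G", "C"))) / 50000
  expect_lt(abs(gc - 0.42), 3 * sqrt(0.42 * 0.58 / 50000) + 1e-9)
})

test_that("individual simulation draws het sites at the requested rate", {
  ref <- simulateReference(1, 1e6, seed = 5)
  tt <- simulateIndividual(ref, 1.5e-3, seed = 6)
  n <- nrow(genotypes(tt))
  expected <- 1e6 * 1.5e-3
  sdv <- sqrt(1e6 * 1.5e-3 * (1 - 1.5e-3))
  expect_lt(abs(n - expected), 4 * sdv)
  g <- genotypes(tt)
  expect_true(all(g$a1 == g$ref & g$a2 != g$ref))

  expect_identical(genotypes(simulateIndividual(ref, 1.5e-3, seed = 6)),
                   genotypes(tt))
  expect_identical(nrow(genotypes(simulateIndividual(ref, 0, seed = 7))), 0L)
  expect_error(simulateIndividual(ref, 0.5), "hetRate")
})

test_that("population simulation shares sites and hits the target heterozygosity", {
  ref <- simulateReference(1, 5e5, seed = 8)
  tt <- simulatePopulation(ref, 3, 1.5e-3, seed = 9)
  g <- genotypes(tt)
  hets <- g[g$a1 != g$a2, ]
  perInd <- table(hets$individual)
  expect_length(perInd, 3L)
  # each individual's het count within 5 SD of the calibration target
  for (n in perInd)
    expect_lt(abs(n - 750), 5 * sqrt(750))
  # sites are shared: some position het in >= 2 individuals
  shared <- table(hets$pos)
  expect_gt(sum(shared >= 2), 0)
  # alt allele consistent across individuals at a shared site
  byPos <- split(g$a2, g$pos)
  expect_true(all(vapply(byPos, function(x) length(unique(x)) == 1L,
                         logical(1))))
})

test_that("read counts, coverage and placements are as requested", {
  ref <- simulateReference(1, 10000, seed = 10)
  tt <- simulateIndividual(ref, 0, seed = 11)
  prof <- ChemistryProfile("frag", 50L, 5.0, 0, "base")
  rs <- simulateReads(ref, tt, prof, seed = 12)
  expect_identical(length(rs), 1000L)        # L * cov / len
  expect_lt(abs(realizedCoverage(rs, ref) - 5.0), 0.01)

  # error-free homozygous-reference reads match the reference verbatim
  seqs <- sequences(rs)
  for (i in sample(length(rs), 50)) {
    win <- as.character(Biostrings::extractAt(
      ref[[1]], IRanges::IRanges(rs@pos[i], width = 50))[[1]])
    expect_identical(seqs[i],
                     if (rs@strand[i] == "+") win else revcomp(win))
  }

  r2 <- simulateReads(ref, tt, prof, seed = 12)
  expect_identical(sequences(r2), seqs)      # determinism

  # realized coverage within 2% at >= 100 kb
  bigRef <- simulateReference(1, 1e5, seed = 13)
  bigTT <- simulateIndividual(bigRef, 0, seed = 13)
  bigRs <- simulateReads(bigRef, bigTT, prof, seed = 14)
  expect_lt(abs(realizedCoverage(bigRs, bigRef) / 5.0 - 1), 0.02)
})

test_that("both alleles of a het site appear among overlapping error-free reads", {
  ref <- simulateReference(1, 2000, seed = 15)
  tt <- simulateIndividual(ref, 5e-3, seed = 16)
  g <- genotypes(tt)
  expect_gt(nrow(g), 0)
  prof <- ChemistryProfile("deep", 50L, 30, 0, "base")
  rs <- simulateReads(ref, tt, prof, seed = 17)
  pu <- pileupReads(rs, ref)
  cols <- pileupColumns(pu)
  for (i in seq_len(nrow(g))) {
    col <- cols[cols$pos == g$pos[i], ]
    n <- c(A = col$nA, C = col$nC, G = col$nG, T = col$nT)
    expect_gt(n[[g$a1[i]]], 0)
    expect_gt(n[[g$a2[i]]], 0)
  }
})

test_that("colour-space chemistries emit decodable colour reads", {
  ref <- simulateReference(1, 3000, seed = 18)
  tt <- simulateIndividual(ref, 0, seed = 18)
  prof <- ChemistryProfile("cf", 40L, 4, 0, "color")
  rs <- simulateReads(ref, tt, prof, seed = 19)
  expect_identical(readSpace(rs), "color")
  expect_true(all(grepl("^T[0-3]+$", sequences(rs))))
  # decoding recovers the reference sequence at the placement
  dec <- decodeColorspace(substring(sequences(rs), 2), "T")
  i <- which(rs@strand == "+")[1]
  win <- as.character(Biostrings::extractAt(
    ref[[1]], IRanges::IRanges(rs@pos[i], width = 40))[[1]])
  expect_identical(dec[i], win)
})

test_that("mate-pair chemistry emits paired 25 bp reads at the insert", {
  ref <- simulateReference(1, 50000, seed = 20)
  tt <- simulateIndividual(ref, 0, seed = 20)
  rs <- simulateReads(ref, tt, chemistryPreset("solid_matepair"),
                      seed = 21)
  expect_true(all(nchar(sequences(rs)) == 26L))  # primer + 25 colours
  expect_lt(abs(realizedCoverage(rs, ref) / 8 - 1), 0.03)
})

test_that("collapsed duplication doubles coverage and fakes heterozygotes everywhere", {
  ref <- simulateReference(1, 20000, seed = 22)
  tt <- simulatePopulation(ref, 2, 1e-3, seed = 23)
  tt <- injectCollapsedDuplication(tt, ref, "c1", 5001, 12000, 2e-3,
                                   seed = 24)
  div <- divergentSites(tt)
  expect_gt(nrow(div), 0)
  expect_true(all(div$pos >= 5001 & div$pos <= 12000))
  expect_error(injectCollapsedDuplication(tt, ref, "c1", 11000, 13000,
                                          1e-3), "overlaps")
  expect_error(injectCollapsedDuplication(tt, ref, "c1", 100, 200, 0.5),
               "divergence")

  prof <- ChemistryProfile("frag", 50L, 15, 1e-3, "base")
  profile <- StringencyProfile()
  for (ind in c("ind1", "ind2")) {
    rs <- simulateReads(ref, tt, prof, individual = ind, seed = 25)
    pu <- pileupReads(rs, ref)
    inside <- mean(pileupCoverage(pu, rep("c1", 200), 7001:7200))
    outside <- mean(pileupCoverage(pu, rep("c1", 200), 15001:15200))
    expect_gt(inside / outside, 1.6)
    expect_lt(inside / outside, 2.4)
    # divergent positions are called heterozygous in every individual
    ds <- callHeterozygotes(pu, profile, ref)
    hetPos <- snpCalls(ds)$pos
    expect_gt(mean(div$pos %in% hetPos), 0.85)
  }
})
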