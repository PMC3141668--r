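test_that("positional validation needs identical unordered allele pairs", {
  a <- SnpDataset("a", "x", "sanger", "t", makeCalls("c1", 10, "A", "G"))
  b <- SnpDataset("b", "y", "sanger", "t", makeCalls("c1", 10, "A", "G"))
  expect_identical(comparePositional(a, b), snpKey("c1", 10, "A", "G"))

  # allele order within the pair is irrelevant: A/G vs pair stored G-first
  b2 <- SnpDataset("b2", "y", "sanger", "t",
                   makeCalls("c1", 10, "G", "A"))
  expect_length(comparePositional(a, b2), 1L)

  # same position, different pair -> no validation
  c <- SnpDataset("c", "y", "sanger", "t", makeCalls("c1", 10, "A", "C"))
  expect_length(comparePositional(a, c), 0L)

  # an allele with > 200 reads disqualifies the site
  d <- SnpDataset("d", "y", "sanger", "t",
                  makeCalls("c1", 10, "A", "G", readsAlt1 = 201))
  expect_length(comparePositional(a, d), 0L)

  # an allele below the Phred floor disqualifies the site
  e <- SnpDataset("e", "y", "sanger", "t",
                  makeCalls("c1", 10, "A", "G", qualAlt1 = 15))
  expect_length(comparePositional(a, e), 0L)
})

test_that("positional validation is symmetric on random datasets", {
  set.seed(70)
  for (i in 1:5) {
    a <- randomDataset("a", 40, posPool = 1:200)
    b <- randomDataset("b", 40, posPool = 1:200)
    expect_setequal(comparePositional(a, b), comparePositional(b, a))
  }
})

test_that("validation matrix equals brute-force pairwise intersections", {
  set.seed(71)
  reg <- list(randomDataset("d1", 100, posPool = 1:400),
              randomDataset("d2", 100, posPool = 1:400),
              randomDataset("d3", 100, posPool = 1:400))
  vm <- buildValidationMatrix(reg)
  cm <- pairCounts(vm)
  for (i in 2:3) for (j in 1:(i - 1)) {
    want <- oracleValidate(reg[[i]], reg[[j]])
    expect_identical(cm[i, j], length(want))
    expect_setequal(validatedKeys(vm)[[pairName(
      datasetId(reg[[i]]), datasetId(reg[[j]]))]], want)
  }
})

test_that("matrix handles disjoint and identical registries", {
  d1 <- SnpDataset("d1", "x", "sanger", "t", makeCalls("c1", 1:5 * 10, "A", "G"))
  d2 <- SnpDataset("d2", "y", "sanger", "t", makeCalls("c1", 1:5 * 10 + 1, "A", "G"))
  d3 <- SnpDataset("d3", "z", "sanger", "t", makeCalls("c1", 1:5 * 10 + 2, "A", "G"))
  vm <- buildValidationMatrix(list(d1, d2, d3))
  expect_true(all(pairCounts(vm)[lower.tri(pairCounts(vm))] == 0L))

  same <- lapply(c("s1", "s2", "s3"), function(id)
    SnpDataset(id, id, "sanger", "t", makeCalls("c1", 1:7 * 10, "A", "G")))
  vm2 <- buildValidationMatrix(same)
  expect_true(all(pairCounts(vm2)[lower.tri(pairCounts(vm2))] == 7L))
})

test_that("e-genotyping validation guards against self-comparison", {
  src <- SnpDataset("src", "a1", "sanger", "t", makeCalls("c1", 10, "A", "G"))
  res <- data.frame(key = snpKey("c1", 10, "A", "G"), chrom = "c1",
                    pos = 10L, a1 = "A", a2 = "G", n1 = 2L, n2 = 1L,
                    nRef = NA_integer_, status = "positive",
                    stringsAsFactors = FALSE)
  expect_identical(compareEgeno(src, res, "a1", "solid_frag"), res$key)
  expect_identical(compareEgeno(src, res, "a2", "sanger"), res$key)
  expect_error(compareEgeno(src, res, "a1", "sanger"), "self-comparison")
  res$status <- "negative"
  expect_length(compareEgeno(src, res, "a1", "solid_frag"), 0L)
})

test_that("merging deduplicates by position and unions alleles", {
  k1 <- snpKey("c1", 10, "A", "G")
  pairs <- list("a|b" = k1, "a|c" = k1, "b|c" = k1,
                "a|d" = snpKey("c1", 20, "A", "G"),
                "b|d" = snpKey("c1", 20, "A", "T"))
  m <- mergeValidated(pairs)
  expect_identical(nrow(m), 2L)
  r1 <- m[m$pos == 10, ]
  expect_identical(r1$nPairs, 3L)
  expect_identical(r1$alleles, "A/G")
  expect_false(r1$multiAllelic)
  r2 <- m[m$pos == 20, ]
  expect_identical(r2$alleles, "A/G/T")
  expect_true(r2$multiAllelic)

  expect_identical(nrow(mergeValidated(list())), 0L)

  # more than three distinct alleles at one site is inconsistent
  bad <- list("a|b" = snpKey("c1", 5, "A", "G"),
              "c|d" = snpKey("c1", 5, "C", "T"))
  expect_warning(mb <- mergeValidated(bad), "inconsistent")
  expect_identical(nrow(mb), 0L)
})

test_that("merge annotates per-site dataset and animal het counts", {
  mk <- function(id, an, pos) SnpDataset(id, an, "sanger", "t",
                                         makeCalls("c1", pos, "A", "G"))
  reg <- list(mk("a_s", "a", c(10, 20)), mk("a_f", "a", c(10, 20)),
              mk("b_s", "b", 10))
  vm <- buildValidationMatrix(reg)
  m <- mergeValidated(vm, registry = reg)
  r10 <- m[m$pos == 10, ]
  expect_identical(r10$nDatasetsHet, 3L)
  expect_identical(r10$nAnimalsHet, 2L)
  r20 <- m[m$pos == 20, ]
  expect_identical(r20$nDatasetsHet, 2L)
  expect_identical(r20$nAnimalsHet, 1L)
})

test_that("validated and unvalidated calls partition each dataset", {
  set.seed(72)
  reg <- list(randomDataset("d1", 60, posPool = 1:300),
              randomDataset("d2", 60, posPool = 1:300),
              randomDataset("d3", 60, posPool = 1:300))
  merged <- mergeValidated(buildValidationMatrix(reg), registry = reg)
  unval <- partitionUnvalidated(reg, merged)
  mergedSites <- paste(merged$chrom, merged$pos)
  for (ds in reg) {
    calls <- snpCalls(ds)
    nIn <- sum(paste(calls$chrom, calls$pos) %in% mergedSites)
    expect_identical(nIn + nrow(unval[[datasetId(ds)]]), nrow(calls))
  }
  # fully validated dataset -> empty unvalidated list
  twin <- list(SnpDataset("t1", "x", "sanger", "t", makeCalls("c1", 10, "A", "G")),
               SnpDataset("t2", "y", "sanger", "t", makeCalls("c1", 10, "A", "G")))
  m2 <- mergeValidated(buildValidationMatrix(twin))
  u2 <- partitionUnvalidated(twin, m2)
  expect_identical(vapply(u2, nrow, 0L), c(t1 = 0L, t2 = 0L))
  # nothing validated -> unvalidated == original
  solo <- list(SnpDataset("u1", "x", "sanger", "t", makeCalls("c1", 10, "A", "G")),
               SnpDataset("u2", "y", "sanger", "t", makeCalls("c1", 99, "A", "G")))
  m3 <- mergeValidated(buildValidationMatrix(solo))
  u3 <- partitionUnvalidated(solo, m3)
  expect_identical(nrow(u3$u1), 1L)
})

test_that("no merged SNP is supported by fewer than two sources", {
  set.seed(73)
  reg <- list(randomDataset("d1", 50, posPool = 1:200),
              randomDataset("d2", 50, posPool = 1:200))
  merged <- mergeValidated(buildValidationMatrix(reg))
  keysBoth <- intersect(callKeys(reg[[1]]), callKeys(reg[[2]]))
  sitesBoth <- sub(":[ACGT]/[ACGT]$", "", keysBoth)
  expect_setequal(paste0(merged$chrom, ":", merged$pos), sitesBoth)
})
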