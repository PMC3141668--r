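## End-to-end orchestration: the full discovery-validation pipeline on a
## registry of datasets and raw readsets, and a study-scale simulation
## harness exercising it with known truth.

#' Run the full cross-validation pipeline
#'
#' (1) pairwise positional-allele comparison of all datasets; (2) retained
#' unvalidated calls from each dataset are turned into uniquely-mapping
#' e-genotyping probes and scanned against every readset of a different
#' chemistry or animal; (3) positive e-genotyping results are appended as
#' additional validating pairs; (4) everything is merged and deduplicated
#' by chromosome/basepair.
#'
#' @param registry list of \code{SnpDataset}s.
#' @param readsets named list of \code{ReadSet}s (names = the dataset id
#'   each readset underlies); may be NULL to skip e-genotyping.
#' @param reference the reference \code{DNAStringSet}.
#' @param profile a \code{\link{StringencyProfile}}.
#' @param egeno run the e-genotyping rescue stage.
#' @param flank probe flank length.
#' @return list with elements \code{matrix} (ValidationMatrix),
#'   \code{merged} (final merged validated set, with per-site het-count
#'   annotations), \code{unvalidated} (per-dataset retained calls),
#'   \code{egenoPairs} (named list of e-genotyping validated key sets).
#' @export
runCrossValidation <- function(registry, readsets = NULL, reference,
                               profile = StringencyProfile(),
                               egeno = !is.null(readsets),
                               flank = 15L) {
  vm <- buildValidationMatrix(registry, profile)
  egenoPairs <- list()
  if (egeno && length(readsets)) {
    merged0 <- mergeValidated(vm)
    unval <- partitionUnvalidated(registry, merged0)
    byId <- stats::setNames(registry, vapply(registry, datasetId, ""))
    for (srcId in names(unval)) {
      calls <- unval[[srcId]]
      calls <- calls[calls$zygosity == "het", , drop = FALSE]
      if (!nrow(calls)) next
      src <- byId[[srcId]]
      probes <- screenProbeUniqueness(
        buildProbes(reference, calls, flank), reference)
      if (!any(probes$unique)) next
      for (tgtId in names(readsets)) {
        rs <- readsets[[tgtId]]
        if (identical(animal(src), animal(rs)) &&
            identical(chemistry(src), chemistry(rs))) next
        res <- scanReadset(probes, rs, profile)
        keys <- compareEgeno(src, res, animal(rs), chemistry(rs))
        if (length(keys)) {
          pn <- pairName(srcId, tgtId)
          egenoPairs[[pn]] <- unique(c(egenoPairs[[pn]], keys))
        }
      }
    }
  }
  merged <- mergeValidated(vm, registry = registry, extraPairs = egenoPairs)
  list(matrix = vm,
       merged = merged,
       unvalidated = partitionUnvalidated(registry, merged),
       egenoPairs = egenoPairs)
}

#' Simulate a complete multi-animal, multi-chemistry study
#'
#' Generates the study conditions the pipeline is evaluated under: a
#' random reference genome, a population of diploid individuals sharing
#' segregating sites, per-individual read sets for each chemistry, an
#' optional injected collapsed duplication, and an unplaced contig
#' (assembled sequence not assigned to any chromosome) simulated
#' independently of the main genome.
#'
#' @param genomeLength main contig length in bp.
#' @param nAnimals number of individuals.
#' @param hetRate per-individual per-bp heterozygosity.
#' @param chemistries chemistry preset names; every animal is sequenced
#'   with every chemistry.
#' @param dupLength,dupDivergence collapsed-duplication interval length
#'   and per-bp copy divergence (set \code{dupLength = 0} for none).
#' @param unplacedLength length of the simulated unplaced contig.
#' @param seed master seed; all stages derive their own sub-seeds from it.
#' @return list(reference, unplaced, truth, readsets, animals).
#' @export
simulateStudy <- function(genomeLength = 2e6, nAnimals = 3,
                          hetRate = 1.5e-3,
                          chemistries = c("sanger", "solid_frag",
                                          "solid_matepair"),
                          dupLength = 5e4, dupDivergence = 1e-3,
                          unplacedLength = 1e5, seed = 1L) {
  seeds <- subSeeds(seed, 4L + nAnimals * length(chemistries))
  reference <- simulateReference(1L, genomeLength, gc = 0.42, seed = seeds[1])
  unplaced <- simulateReference(1L, unplacedLength, gc = 0.42, seed = seeds[2])
  names(unplaced) <- "chrUn"
  truth <- simulatePopulation(reference, nAnimals, hetRate, seed = seeds[3])
  if (dupLength > 0) {
    set.seed(seeds[4])
    start <- sample.int(genomeLength - dupLength - 1000L, 1L) + 500L
    truth <- injectCollapsedDuplication(truth, reference, "c1",
                                        start, start + dupLength - 1L,
                                        dupDivergence, seed = seeds[4])
  }
  animals <- paste0("ind", seq_len(nAnimals))
  readsets <- list()
  k <- 4L
  for (ind in animals) {
    for (chem in chemistries) {
      k <- k + 1L
      rs <- simulateReads(reference, truth, chemistryPreset(chem),
                          individual = ind, seed = seeds[k])
      readsets[[datasetId(rs)]] <- rs
    }
  }
  list(reference = reference, unplaced = unplaced, truth = truth,
       readsets = readsets, animals = animals)
}

#' Run discovery and validation on a simulated study
#'
#' Pileups each readset, calls heterozygotes under the profile, runs the
#' full cross-validation pipeline (including the e-genotyping rescue
#' stage), and records per-dataset read depth at every true segregating
#' site. Pileups named in \code{keepPileups} are retained in the result
#' (by default the first animal's Sanger and mate-pair pileups, used by
#' the coverage screen and the stringency contrast).
#'
#' @param sim output of \code{\link{simulateStudy}}.
#' @param profile a \code{\link{StringencyProfile}}.
#' @param keepPileups readset ids whose pileups to retain.
#' @return list(registry, pipeline, covAtSites, siteIndex, keptPileups).
#' @export
runStudy <- function(sim, profile = StringencyProfile(),
                     keepPileups = c("ind1_sanger", "ind1_solid_matepair")) {
  gt <- genotypes(sim$truth)
  sites <- unique(data.frame(chrom = gt$chrom, pos = gt$pos,
                             stringsAsFactors = FALSE))
  div <- divergentSites(sim$truth)
  if (nrow(div))
    sites <- unique(rbind(sites, div[, c("chrom", "pos")]))
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL

  registry <- list()
  covAtSites <- matrix(0L, nrow(sites), length(sim$readsets),
                       dimnames = list(NULL, names(sim$readsets)))
  keptPileups <- list()
  for (id in names(sim$readsets)) {
    rs <- sim$readsets[[id]]
    pu <- pileupReads(rs, sim$reference)
    covAtSites[, id] <- pileupCoverage(pu, sites$chrom, sites$pos,
                                       minPhred = profile@minPhred)
    ds <- callHeterozygotes(pu, profile, sim$reference, id = id,
                            animal = animal(rs), chemistry = chemistry(rs))
    registry[[id]] <- ds
    if (id %in% keepPileups) keptPileups[[id]] <- pu
    rm(pu); gc(verbose = FALSE)
  }
  pipe <- runCrossValidation(registry, sim$readsets, sim$reference, profile)
  list(registry = registry, pipeline = pipe, covAtSites = covAtSites,
       siteIndex = sites, keptPileups = keptPileups)
}

#' Recovery and false-validation statistics of a simulated study
#'
#' A true heterozygous site is counted as recoverable when at least two of
#' the datasets belonging to animals that actually carry the heterozygote
#' cover it with at least \code{minCov} qualifying reads -- the condition
#' under which two independent observations of the het are possible at
#' all. The recovery rate is the fraction of recoverable sites present in
#' the merged validated set. The false-validation rate is the fraction of
#' positions that are neither truly segregating nor inside an injected
#' duplication interval, yet appear in the merged set.
#'
#' @param study output of \code{\link{runStudy}}.
#' @param sim the \code{\link{simulateStudy}} output it was run on.
#' @param minCov per-dataset depth for a site to count as covered.
#' @return list(nRecoverable, nRecovered, recoveryRate, nFalse,
#'   nNonVariantSites, falseRate).
#' @export
studyRecovery <- function(study, sim, minCov = 5L) {
  gt <- genotypes(sim$truth)
  hets <- gt[gt$a1 != gt$a2, , drop = FALSE]
  sites <- study$siteIndex
  key <- siteId(sites$chrom, sites$pos)
  dsAnimal <- vapply(study$registry, animal, "")

  ## per site, which animals are het there
  hetKey <- siteId(hets$chrom, hets$pos)
  bySite <- split(hets$individual, hetKey)
  m <- match(key, names(bySite))

  dup <- duplications(sim$truth)
  inDup <- rep(FALSE, length(key))
  for (k in seq_len(nrow(dup)))
    inDup <- inDup | (sites$chrom == dup$chrom[k] &
                        sites$pos >= dup$start[k] & sites$pos <= dup$end[k])

  eligible <- logical(length(key))
  for (i in seq_along(key)) {
    if (is.na(m[i]) || inDup[i]) next
    ans <- bySite[[m[i]]]
    dsOk <- names(dsAnimal)[dsAnimal %in% ans]
    eligible[i] <- sum(study$covAtSites[i, dsOk] >= minCov) >= 2L
  }

  merged <- study$pipeline$merged
  mergedSites <- siteId(merged$chrom, merged$pos)
  recovered <- eligible & (key %in% mergedSites)

  ## false validations: merged sites at non-segregating, non-duplicated
  ## positions
  truthSites <- unique(siteId(gt$chrom, gt$pos))
  dupSpan <- sum(pmax(0L, dup$end - dup$start + 1L))
  inDupMerged <- rep(FALSE, nrow(merged))
  for (k in seq_len(nrow(dup)))
    inDupMerged <- inDupMerged | (merged$chrom == dup$chrom[k] &
                                    merged$pos >= dup$start[k] &
                                    merged$pos <= dup$end[k])
  false <- !(mergedSites %in% truthSites) & !inDupMerged
  genomeLength <- sum(as.numeric(sim$truth@contigs))
  nNonVariant <- genomeLength - length(truthSites) - dupSpan
  list(nRecoverable = sum(eligible), nRecovered = sum(recovered),
       recoveryRate = if (sum(eligible)) sum(recovered) / sum(eligible) else NA,
       nFalse = sum(false), nNonVariantSites = nNonVariant,
       falseRate = sum(false) / nNonVariant)
}
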