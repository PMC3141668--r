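## Evaluation statistics: genotype concordance, validation efficiency,
## SNP density per chromosome, cross-species positional overlap.

.CONCORDANCE_CATS <- c("good_hom", "good_het", "het_as_hom",
                       "hom_as_wrong_hom", "erroneous_het")

#' Classify genotype calls against simulated truth
#'
#' Each call is placed in exactly one concordance category: good
#' homozygous call, good heterozygote call, heterozygote called as a
#' homozygote, homozygote called as the wrong homozygote, or erroneously
#' called heterozygote. The miscall rate is the fraction of calls in the
#' three error categories. With per-site coverage supplied, the rate is
#' also reported after excluding sites outside the coverage bounds
#' (defaults [3, 2 x mean]): very high coverage sites are typically
#' repetitive/non-specific and very low coverage sites drop alleles.
#'
#' @param truth a \code{\link{TruthTable}}.
#' @param individual which individual's truth to compare against.
#' @param calls genotype calls (\code{\link{callGenotypes}} output);
#'   \code{no_call} rows are ignored.
#' @param reference the reference \code{DNAStringSet} (supplies implicit
#'   homozygous-reference truth genotypes).
#' @param coverage optional per-call read depth (parallel to calls).
#' @param bounds optional c(lo, hi) coverage bounds; defaults to
#'   c(3, 2 * mean(coverage)).
#' @return list of class \code{"concordanceReport"}: counts, total,
#'   miscallRate, and (with coverage) boundedMiscallRate, bounds,
#'   byCoverage.
#' @export
classifyConcordance <- function(truth, individual, calls, reference,
                                coverage = NULL, bounds = NULL) {
  keep <- calls$call != "no_call"
  calls <- calls[keep, , drop = FALSE]
  if (!is.null(coverage)) coverage <- coverage[keep]
  gt <- genotypes(truth)
  gt <- gt[gt$individual == individual, , drop = FALSE]

  ctg <- truth@contigs
  if (length(ctg)) {
    bad <- !(calls$chrom %in% names(ctg)) | calls$pos < 1L |
      calls$pos > ctg[calls$chrom]
    if (any(bad))
      stop("call at position absent from truth: ",
           paste(siteId(calls$chrom[bad], calls$pos[bad])[1], "..."))
  }

  m <- match(siteId(calls$chrom, calls$pos), siteId(gt$chrom, gt$pos))
  refBase <- referenceBases(reference, calls$chrom, calls$pos)
  t1 <- ifelse(is.na(m), refBase, gt$a1[m])
  t2 <- ifelse(is.na(m), refBase, gt$a2[m])
  truthHet <- t1 != t2
  callHet <- calls$g1 != calls$g2
  samePair <- snpKey(calls$chrom, calls$pos, t1, t2) ==
    snpKey(calls$chrom, calls$pos, calls$g1, calls$g2)

  cat <- ifelse(truthHet,
                ifelse(!callHet, "het_as_hom",
                       ifelse(samePair, "good_het", "erroneous_het")),
                ifelse(callHet, "erroneous_het",
                       ifelse(calls$g1 == t1, "good_hom", "hom_as_wrong_hom")))
  counts <- table(factor(cat, levels = .CONCORDANCE_CATS))
  total <- length(cat)
  miscall <- sum(counts[c("het_as_hom", "hom_as_wrong_hom",
                          "erroneous_het")]) / total
  out <- list(counts = counts, total = total, miscallRate = miscall,
              categories = cat)
  if (!is.null(coverage)) {
    if (is.null(bounds)) bounds <- c(3, 2 * mean(coverage))
    inside <- coverage >= bounds[1] & coverage <= bounds[2]
    out$bounds <- bounds
    out$boundedMiscallRate <- if (any(inside))
      mean(cat[inside] %in% c("het_as_hom", "hom_as_wrong_hom",
                              "erroneous_het"))
    else NA_real_
    out$byCoverage <- table(coverage, factor(cat, levels = .CONCORDANCE_CATS))
  }
  class(out) <- "concordanceReport"
  out
}

#' @export
print.concordanceReport <- function(x, ...) {
  cat("Genotype concordance over", x$total, "calls\n")
  print(x$counts)
  cat(sprintf("miscall rate: %.3f%%\n", 100 * x$miscallRate))
  if (!is.null(x$boundedMiscallRate))
    cat(sprintf("miscall rate within coverage [%g, %g]: %.3f%%\n",
                x$bounds[1], x$bounds[2], 100 * x$boundedMiscallRate))
  invisible(x)
}

#' Per-dataset validation efficiency
#'
#' The fraction of each dataset's potential SNPs whose position made it
#' into the merged validated set. Empty datasets report NA.
#'
#' @param registry list of \code{SnpDataset}s.
#' @param merged merged validated SNPs.
#' @return data.frame(id, nCalls, nValidated, fraction).
#' @export
validationEfficiency <- function(registry, merged) {
  validatedSites <- siteId(merged$chrom, merged$pos)
  rows <- lapply(registry, function(ds) {
    calls <- snpCalls(ds)
    n <- nrow(calls)
    v <- sum(siteId(calls$chrom, calls$pos) %in% validatedSites)
    data.frame(id = datasetId(ds), nCalls = n, nValidated = v,
               fraction = if (n) v / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' SNP density per chromosome
#'
#' Counts and SNPs/Mb per chromosome, with mean and standard deviation
#' across the non-excluded chromosomes and outlier flags for chromosomes
#' deviating by more than one standard deviation from the mean. Excluded
#' chromosomes (e.g. the X when a male animal depresses X discovery) are
#' still reported but do not enter the mean/SD.
#'
#' @param merged merged validated SNPs.
#' @param lengths named vector of chromosome lengths (bp).
#' @param exclude chromosomes to leave out of the mean/SD.
#' @return list(table = data.frame(chrom, count, mb, density, excluded,
#'   outlier), mean, sd).
#' @export
densityByChromosome <- function(merged, lengths, exclude = character()) {
  stopifnot(all(lengths > 0))
  counts <- table(factor(merged$chrom, levels = names(lengths)))
  df <- data.frame(chrom = names(lengths),
                   count = as.integer(counts),
                   mb = as.numeric(lengths) / 1e6,
                   stringsAsFactors = FALSE)
  df$density <- df$count / df$mb
  df$excluded <- df$chrom %in% exclude
  mu <- mean(df$density[!df$excluded])
  sdv <- stats::sd(df$density[!df$excluded])
  if (is.na(sdv)) sdv <- 0
  df$outlier <- abs(df$density - mu) > sdv
  list(table = df, mean = mu, sd = sdv)
}

#' Positional overlap between two SNP sets
#'
#' Exact (chrom, pos) intersection, the overlap percentage relative to set
#' A, the overlap expected if positions were entirely uncorrelated
#' (|A| x |B-universe| / genome length), and the enrichment ratio
#' observed/expected.
#'
#' @param setA,setB data.frames with columns chrom, pos on a common
#'   coordinate system.
#' @param genomeLength total basepairs of the common genome.
#' @param bUniverse size of the universe set B is drawn from (defaults to
#'   |B|).
#' @return list(nA, nB, nIntersect, overlapPercent, expected,
#'   expectedPercent, enrichment).
#' @export
positionOverlap <- function(setA, setB, genomeLength,
                            bUniverse = nrow(setB)) {
  if (genomeLength <= 0) stop("genomeLength must be positive")
  inter <- sum(siteId(setA$chrom, setA$pos) %in%
                 siteId(setB$chrom, setB$pos))
  overlapReport(nrow(setA), inter, bUniverse, genomeLength, nB = nrow(setB))
}

#' Overlap arithmetic from counts
#'
#' The count-level form of \code{\link{positionOverlap}}, for use when
#' only the set sizes and intersection count are available (e.g. from a
#' published comparison).
#'
#' @param nA size of set A.
#' @param nIntersect exact position matches between A and B.
#' @param bUniverse size of the universe B is drawn from.
#' @param genomeLength total basepairs of the common genome.
#' @param nB size of set B (defaults to \code{bUniverse}).
#' @return list(nA, nB, nIntersect, overlapPercent, expected,
#'   expectedPercent, enrichment).
#' @export
overlapReport <- function(nA, nIntersect, bUniverse, genomeLength,
                          nB = bUniverse) {
  if (genomeLength <= 0) stop("genomeLength must be positive")
  expected <- nA * (bUniverse / genomeLength)
  list(nA = nA, nB = nB, nIntersect = nIntersect,
       overlapPercent = 100 * nIntersect / nA,
       expected = expected,
       expectedPercent = 100 * expected / nA,
       enrichment = nIntersect / expected)
}
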