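## Artifact screens for collapsed segmental duplications.

#' Coverage-distribution screen for collapsed-duplication artifacts
#'
#' Collapsed near-identical duplications make every individual appear
#' heterozygous at the divergent positions, and double local read depth.
#' The screen compares read coverage for the suspect group A -- validated
#' SNPs scored heterozygous in all animals -- against an equal-size,
#' seeded random control sample of SNPs heterozygous in exactly two
#' animals (group B). It reports group means, coverage histograms, the
#' fraction of each group at or above \code{ceiling(2 * mean coverage)}
#' (twice the genome-wide average), and a two-proportion test of the
#' high-coverage fractions.
#'
#' @param merged merged validated SNPs with \code{nAnimalsHet} (see
#'   \code{\link{mergeValidated}} with a registry).
#' @param pileup coverage source \code{Pileup} (e.g. the reference
#'   animal's Sanger pileup).
#' @param nAnimals total number of animals in the study.
#' @param meanCoverage genome-wide mean fold coverage; computed from the
#'   pileup when NULL.
#' @param seed seed for the control-group sample.
#' @param intervals optional data.frame(chrom, start, end) of suspect
#'   intervals (e.g. the known injected duplications); when given, the
#'   mean coverage of group-A sites inside the intervals relative to the
#'   genome-wide mean is reported as \code{intervalCoverageRatio}.
#' @return list of class \code{"coverageScreen"}: group sizes, means,
#'   \code{threshold}, high-coverage fractions, histograms, the
#'   \code{prop.test} result (\code{pValue}, \code{enriched}), and
#'   optionally \code{intervalCoverageRatio}.
#' @export
coverageScreen <- function(merged, pileup, nAnimals,
                           meanCoverage = NULL, seed = 1L,
                           intervals = NULL) {
  if (!"nAnimalsHet" %in% names(merged))
    stop("merged set lacks nAnimalsHet; run mergeValidated with a registry")
  if (is.null(meanCoverage)) meanCoverage <- pileupMeanCoverage(pileup)
  threshold <- as.integer(ceiling(2 * meanCoverage))

  groupA <- merged[merged$nAnimalsHet == nAnimals, , drop = FALSE]
  if (!nrow(groupA))
    stop("no sites heterozygous in all ", nAnimals, " animals")
  poolB <- merged[merged$nAnimalsHet == 2L & merged$nAnimalsHet < nAnimals, ,
                  drop = FALSE]
  if (!nrow(poolB))
    stop("no control sites heterozygous in exactly two animals")
  set.seed(seed)
  nB <- min(nrow(groupA), nrow(poolB))
  if (nB < nrow(groupA))
    warning("control pool smaller than group A; using ", nB, " control sites")
  groupB <- poolB[sample.int(nrow(poolB), nB), , drop = FALSE]

  covA <- pileupCoverage(pileup, groupA$chrom, groupA$pos)
  covB <- pileupCoverage(pileup, groupB$chrom, groupB$pos)
  fracA <- mean(covA >= threshold)
  fracB <- mean(covB >= threshold)
  pt <- suppressWarnings(stats::prop.test(
    c(sum(covA >= threshold), sum(covB >= threshold)),
    c(length(covA), length(covB))))

  out <- list(
    nA = length(covA), nB = length(covB),
    meanCovA = mean(covA), meanCovB = mean(covB),
    meanCoverage = meanCoverage, threshold = threshold,
    fracHighA = fracA, fracHighB = fracB,
    histA = table(covA), histB = table(covB),
    pValue = pt$p.value,
    enriched = fracA > fracB && pt$p.value < 0.01)
  if (!is.null(intervals) && nrow(intervals)) {
    inIv <- rep(FALSE, nrow(groupA))
    for (k in seq_len(nrow(intervals)))
      inIv <- inIv | (groupA$chrom == intervals$chrom[k] &
                        groupA$pos >= intervals$start[k] &
                        groupA$pos <= intervals$end[k])
    out$intervalCoverageRatio <-
      if (any(inIv)) mean(covA[inIv]) / meanCoverage else NA_real_
  }
  class(out) <- "coverageScreen"
  out
}

#' @export
print.coverageScreen <- function(x, ...) {
  cat(sprintf("Coverage screen: %d all-animal-het sites vs %d controls\n",
              x$nA, x$nB))
  cat(sprintf("  mean coverage %.2f vs %.2f (genome-wide %.2f, threshold >= %d)\n",
              x$meanCovA, x$meanCovB, x$meanCoverage, x$threshold))
  cat(sprintf("  high-coverage fraction %.3f vs %.3f, p = %.3g (%s)\n",
              x$fracHighA, x$fracHighB, x$pValue,
              if (x$enriched) "ENRICHED" else "no enrichment"))
  if (!is.null(x$intervalCoverageRatio))
    cat(sprintf("  interval coverage ratio: %.2fx\n", x$intervalCoverageRatio))
  invisible(x)
}

#' Split a sequence into consecutive pseudo-reads
#'
#' Chunks the input into consecutive non-overlapping windows of
#' \code{readLength} bases; the final short chunk is kept, so the
#' concatenation of the chunks reproduces the input exactly.
#'
#' @param sequence a single string or \code{DNAString}.
#' @param readLength chunk length in bp.
#' @return character vector of chunks.
#' @export
chunkSequence <- function(sequence, readLength = 150L) {
  s <- as.character(sequence)
  L <- nchar(s)
  if (!L) return(character())
  starts <- seq.int(1L, L, by = readLength)
  substring(s, starts, pmin(starts + readLength - 1L, L))
}

#' Probe scan of unplaced assembly sequence
#'
#' Duplicated sequence that was excluded from the chromosome scaffolds
#' tends to end up in the unplaced ("chromosome unknown") bin. This
#' screen splits the unplaced sequence into consecutive pseudo-reads
#' (150 bp by default) and scans them with e-genotyping probes built from
#' the validated SNPs: any probe hit indicates a validated SNP with an
#' unrecognised near-identical copy in unplaced sequence. Note that a
#' probe occurrence straddling a chunk boundary is invisible to the scan,
#' a property inherited from the chunked design.
#'
#' @param unplaced unplaced contig sequence (string, \code{DNAString}, or
#'   single-element \code{DNAStringSet}).
#' @param probes screened probe data.frame.
#' @param readLength pseudo-read length.
#' @param profile a \code{\link{StringencyProfile}}.
#' @return list(totalHits, nProbesHit, hits = per-probe hit data.frame,
#'   nPseudoReads).
#' @export
scanUnplaced <- function(unplaced, probes, readLength = 150L,
                         profile = StringencyProfile()) {
  if (is(unplaced, "DNAStringSet")) unplaced <- unplaced[[1]]
  chunks <- chunkSequence(unplaced, readLength)
  rs <- ReadSet(id = "unplaced_pseudoreads",
                sequences = chunks,
                quals = vapply(nchar(chunks), function(w)
                  paste(rep("I", w), collapse = ""), ""),
                chrom = rep("chrUn", length(chunks)),
                pos = as.integer(seq.int(1L, by = readLength,
                                         length.out = length(chunks))),
                strand = rep("+", length(chunks)),
                space = "base")
  res <- scanReadset(probes, rs, profile)
  hits <- res[res$n1 > 0L | res$n2 > 0L |
                (!is.na(res$nRef) & res$nRef > 0L), , drop = FALSE]
  totalHits <- sum(res$n1, res$n2, res$nRef[!is.na(res$nRef)])
  list(totalHits = totalHits, nProbesHit = nrow(hits), hits = hits,
       nPseudoReads = length(chunks))
}
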