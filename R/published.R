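## Published validated-SNP counts shipped with the package, and the
## bookkeeping that reduces them to study totals.

#' Load the published pairwise validated-SNP counts
#'
#' The package ships, as plain TSV under \code{extdata}, the pairwise
#' validated-SNP counts of the rhesus macaque discovery study this
#' toolkit's methodology derives from: one row per (source, target,
#' method) cell, where method is positional-allele comparison or
#' e-genotyping (source = the probe-building dataset), plus a companion
#' table tagging each dataset with its animal and whether it is a
#' resequencing or previously-published source.
#'
#' @return list(cells, datasets) of data.frames.
#' @export
publishedValidationCounts <- function() {
  dir <- system.file("extdata", package = "snpXval", mustWork = TRUE)
  list(
    cells = utils::read.delim(file.path(dir, "published_validation_counts.tsv"),
                              stringsAsFactors = FALSE),
    datasets = utils::read.delim(file.path(dir, "published_datasets.tsv"),
                                 stringsAsFactors = FALSE))
}

#' Load the published cross-species overlap counts
#' @return named numeric vector of the count inputs to
#'   \code{\link{overlapReport}}.
#' @export
publishedOverlapCounts <- function() {
  dir <- system.file("extdata", package = "snpXval", mustWork = TRUE)
  df <- utils::read.delim(file.path(dir, "published_overlap_counts.tsv"),
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$value), df$quantity)
}

#' Reduce pairwise validated counts to study totals
#'
#' Buckets every pairwise cell by the nature of its two endpoints --
#' within-animal multi-chemistry, cross-animal resequencing,
#' e-genotyping with resequencing targets (split by Sanger- vs
#' SOLiD-derived probes), comparisons involving previously published
#' data, and published-vs-published -- and sums each bucket. The grand
#' total is the sum of all cells (each validated SNP is already
#' deduplicated across pairs in the source bookkeeping).
#'
#' @param counts list(cells, datasets) as returned by
#'   \code{\link{publishedValidationCounts}}.
#' @return list of totals: withinAnimal, crossAnimal, egenoSangerProbes,
#'   egenoSolidProbes, egeno, publishedLinked, publishedOnly, total.
#' @export
validationTotals <- function(counts = publishedValidationCounts()) {
  cells <- counts$cells
  ds <- counts$datasets
  srcAnimal <- ds$animal[match(cells$source, ds$name)]
  tgtAnimal <- ds$animal[match(cells$target, ds$name)]
  srcType <- ds$type[match(cells$source, ds$name)]
  tgtType <- ds$type[match(cells$target, ds$name)]
  if (anyNA(srcType) || anyNA(tgtType))
    stop("count cell references an unknown dataset")
  bothReseq <- srcType == "reseq" & tgtType == "reseq"
  positional <- cells$method == "positional"
  egeno <- cells$method == "egeno"

  withinAnimal <- sum(cells$count[positional & bothReseq &
                                    srcAnimal == tgtAnimal])
  crossAnimal <- sum(cells$count[positional & bothReseq &
                                   srcAnimal != tgtAnimal])
  sangerProbe <- egeno & bothReseq & cells$source == "17573_sanger"
  solidProbe <- egeno & bothReseq & cells$source != "17573_sanger"
  egenoSanger <- sum(cells$count[sangerProbe])
  egenoSolid <- sum(cells$count[solidProbe])
  publishedOnly <- sum(cells$count[positional & srcType == "published" &
                                     tgtType == "published"])
  publishedLinked <- sum(cells$count) - withinAnimal - crossAnimal -
    egenoSanger - egenoSolid - publishedOnly
  list(withinAnimal = withinAnimal,
       crossAnimal = crossAnimal,
       egenoSangerProbes = egenoSanger,
       egenoSolidProbes = egenoSolid,
       egeno = egenoSanger + egenoSolid,
       publishedLinked = publishedLinked,
       publishedOnly = publishedOnly,
       total = sum(cells$count))
}
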