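## Pairwise positional-allele validation, e-genotyping integration,
## validation matrix, merged deduplicated output and unvalidated retention.

## keys of a dataset's het calls that are eligible for validation under a
## profile: every allele of the pair has >=1 read at >= minPhred, and no
## recorded allele exceeds maxAlleleReads
eligibleKeys <- function(dataset, profile) {
  calls <- snpCalls(dataset)
  calls <- calls[calls$zygosity == "het", , drop = FALSE]
  if (!nrow(calls)) return(character())
  useRef <- is.na(calls$alt2)
  r1 <- ifelse(useRef, calls$readsRef, calls$readsAlt1)
  q1 <- ifelse(useRef, calls$qualRef, calls$qualAlt1)
  r2 <- ifelse(useRef, calls$readsAlt1, calls$readsAlt2)
  q2 <- ifelse(useRef, calls$qualAlt1, calls$qualAlt2)
  maxReads <- pmax(calls$readsRef, calls$readsAlt1,
                   ifelse(is.na(calls$readsAlt2), 0L, calls$readsAlt2))
  ok <- r1 >= 1L & r2 >= 1L &
    q1 >= profile@minPhred & q2 >= profile@minPhred &
    maxReads <= profile@maxAlleleReads
  p <- callPair(calls)
  snpKey(calls$chrom, calls$pos, p$a1, p$a2)[ok]
}

#' Pairwise positional-allele comparison of two datasets
#'
#' The validation rule: a SNP validates iff the same chromosome/basepair
#' position is called heterozygous with the identical unordered allele
#' pair in both datasets, each dataset shows at least one qualifying read
#' (Phred >= \code{minPhred}) for each allele, and no allele exceeds
#' \code{maxAlleleReads} reads in either dataset.
#'
#' @param a,b \code{SnpDataset}s on the same reference coordinates.
#' @param profile a \code{\link{StringencyProfile}}.
#' @return character vector of validated SNP keys (see \code{\link{snpKey}}).
#' @export
comparePositional <- function(a, b, profile = StringencyProfile()) {
  intersect(eligibleKeys(a, profile), eligibleKeys(b, profile))
}

#' Validate SNPs from e-genotyping positives
#'
#' Positive e-genotyping results confirm the probe-source SNPs against an
#' independent read set. Validation requires the source dataset and the
#' target readset to differ in chemistry or in animal -- a dataset can
#' never validate against its own reads.
#'
#' @param source the \code{SnpDataset} the probes were built from.
#' @param results e-genotyping scan results (\code{\link{scanReadset}} on
#'   the target readset).
#' @param targetAnimal,targetChemistry identity of the scanned readset.
#' @return character vector of validated SNP keys.
#' @export
compareEgeno <- function(source, results, targetAnimal, targetChemistry) {
  if (identical(animal(source), targetAnimal) &&
      identical(chemistry(source), targetChemistry))
    stop("self-comparison: e-genotyping requires a cross-chemistry or ",
         "cross-animal source/target pair")
  results$key[results$status == "positive"]
}

#' Build the pairwise validation matrix
#'
#' Runs \code{\link{comparePositional}} over every unordered pair of
#' datasets, retaining both the counts (lower triangle) and the per-pair
#' validated key sets.
#'
#' @param registry list of \code{SnpDataset}s.
#' @param profile a \code{\link{StringencyProfile}}.
#' @return A \code{\link[=ValidationMatrix-class]{ValidationMatrix}}.
#' @export
buildValidationMatrix <- function(registry, profile = StringencyProfile()) {
  stopifnot(length(registry) >= 2L)
  ids <- vapply(registry, datasetId, "")
  if (anyDuplicated(ids)) stop("dataset ids must be unique")
  n <- length(ids)
  counts <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  pairs <- list()
  elig <- lapply(registry, eligibleKeys, profile = profile)
  for (j in seq_len(n - 1L)) {
    for (i in seq((j + 1L), n)) {
      keys <- intersect(elig[[i]], elig[[j]])
      counts[i, j] <- length(keys)
      pairs[[pairName(ids[i], ids[j])]] <- keys
    }
  }
  new("ValidationMatrix", ids = ids, counts = counts, pairs = pairs)
}

#' Merge validated SNPs across all pairs, removing duplicates
#'
#' All per-pair validated sets (positional pairs from the matrix, plus any
#' e-genotyping pair sets) are appended and deduplicated by
#' chromosome/basepair. The validated alleles of a site are the union over
#' pairs; sites whose pairs validated different allele pairs are flagged
#' \code{multiAllelic} (up to 3 total alleles; sites exceeding that are
#' dropped as inconsistent, with a warning). When the dataset registry is
#' supplied, each merged site is annotated with the number of datasets and
#' distinct animals in which it was called heterozygous.
#'
#' @param matrix a \code{ValidationMatrix}, or a named list of per-pair
#'   validated key vectors (names "idA|idB").
#' @param registry optional list of \code{SnpDataset}s for the per-site
#'   het-count annotations.
#' @param extraPairs optional named list of additional per-pair key sets
#'   (e.g. e-genotyping validations, named "src|tgt").
#' @return data.frame with one row per validated site: \code{chrom},
#'   \code{pos}, \code{alleles} ("X/Y" or "X/Y/Z"), \code{nPairs},
#'   \code{supportingPairs}, \code{multiAllelic}, and (with a registry)
#'   \code{nDatasetsHet}, \code{nAnimalsHet}.
#' @export
mergeValidated <- function(matrix, registry = NULL, extraPairs = NULL) {
  pairSets <- if (is(matrix, "ValidationMatrix")) matrix@pairs else matrix
  if (!is.null(extraPairs)) pairSets <- c(pairSets, extraPairs)
  empty <- data.frame(chrom = character(), pos = integer(),
                      alleles = character(), nPairs = integer(),
                      supportingPairs = character(), multiAllelic = logical(),
                      stringsAsFactors = FALSE)
  keys <- unlist(pairSets, use.names = FALSE)
  if (!length(keys)) {
    if (!is.null(registry)) {
      empty$nDatasetsHet <- integer()
      empty$nAnimalsHet <- integer()
    }
    return(empty)
  }
  pairOf <- rep(names(pairSets), lengths(pairSets))
  parsed <- parseSnpKey(keys)
  site <- siteId(parsed$chrom, parsed$pos)

  usite <- unique(site)
  first <- match(usite, site)
  splitIdx <- split(seq_along(site), factor(site, levels = usite))
  alleles <- vapply(splitIdx, function(ix)
    paste(sort(unique(c(parsed$a1[ix], parsed$a2[ix]))), collapse = "/"), "")
  support <- vapply(splitIdx, function(ix)
    paste(sort(unique(pairOf[ix])), collapse = ","), "")
  nPairs <- vapply(splitIdx, function(ix) length(unique(pairOf[ix])), 0L)
  nAl <- lengths(strsplit(alleles, "/", fixed = TRUE))

  out <- data.frame(chrom = parsed$chrom[first], pos = parsed$pos[first],
                    alleles = alleles, nPairs = nPairs,
                    supportingPairs = support,
                    multiAllelic = nAl > 2L,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (any(nAl > 3L)) {
    warning(sum(nAl > 3L), " site(s) with >3 validated alleles dropped as inconsistent")
    out <- out[nAl <= 3L, , drop = FALSE]
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL

  if (!is.null(registry)) {
    sites <- siteId(out$chrom, out$pos)
    nDatasets <- integer(nrow(out))
    animalHet <- vector("list", nrow(out))
    hetByAnimal <- list()
    for (ds in registry) {
      calls <- snpCalls(ds)
      calls <- calls[calls$zygosity == "het", , drop = FALSE]
      here <- sites %in% siteId(calls$chrom, calls$pos)
      nDatasets <- nDatasets + here
      an <- animal(ds)
      hetByAnimal[[an]] <- unique(c(hetByAnimal[[an]],
                                    sites[here]))
    }
    nAnimals <- integer(nrow(out))
    for (an in names(hetByAnimal))
      nAnimals <- nAnimals + (sites %in% hetByAnimal[[an]])
    out$nDatasetsHet <- nDatasets
    out$nAnimalsHet <- nAnimals
  }
  out
}

#' Retained unvalidated SNPs, per dataset
#'
#' For each dataset, the calls whose (chrom, pos) is absent from the
#' merged validated set. These are kept (and exportable as BED via
#' \code{\link{writeBed}}) to support future discovery in sparsely
#' covered regions.
#'
#' @param registry list of \code{SnpDataset}s.
#' @param merged merged validated SNPs (\code{\link{mergeValidated}}).
#' @return named list of calls data.frames.
#' @export
partitionUnvalidated <- function(registry, merged) {
  validatedSites <- siteId(merged$chrom, merged$pos)
  out <- lapply(registry, function(ds) {
    calls <- snpCalls(ds)
    calls[!(siteId(calls$chrom, calls$pos) %in% validatedSites), ,
          drop = FALSE]
  })
  stats::setNames(out, vapply(registry, datasetId, ""))
}

#' Convert merged validated sites back into a calls table
#'
#' Reconstructs a calls data.frame (one row per site, reference allele
#' from the reference genome) from a merged validated set, e.g. to build
#' e-genotyping probes from all validated SNPs or to feed the annotator.
#' Read counts and qualities are nominal (the merged set no longer
#' carries per-dataset support).
#'
#' @param merged merged validated SNPs (\code{\link{mergeValidated}}).
#' @param reference the reference \code{DNAStringSet}.
#' @return a calls data.frame as used by \code{\link{SnpDataset}}.
#' @export
mergedToCalls <- function(merged, reference) {
  if (!nrow(merged)) return(emptyCalls())
  refBase <- referenceBases(reference, merged$chrom, merged$pos)
  alleleList <- strsplit(merged$alleles, "/", fixed = TRUE)
  alts <- mapply(function(als, rb) {
    out <- setdiff(als, rb)
    c(out, NA_character_)[1:2]
  }, alleleList, refBase)
  refIn <- mapply(function(als, rb) rb %in% als, alleleList, refBase)
  alt2 <- ifelse(refIn, NA_character_, alts[2, ])
  data.frame(chrom = merged$chrom, pos = merged$pos, ref = refBase,
             alt1 = alts[1, ], alt2 = alt2,
             readsRef = ifelse(refIn, 1L, 0L),
             readsAlt1 = 1L,
             readsAlt2 = ifelse(is.na(alt2), NA_integer_, 1L),
             qualRef = 40L, qualAlt1 = 40L,
             qualAlt2 = ifelse(is.na(alt2), NA_integer_, 40L),
             zygosity = "het", triallelic = FALSE,
             stringsAsFactors = FALSE)
}
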