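## Minimal pileup-based heterozygote caller. Stands in for the external
## SNP callers used per chemistry in the original workflow; parameterised
## by a StringencyProfile so low- vs high-stringency call sets can be
## produced from the same pileup.

#' Pile reads up on the reference
#'
#' Uses the true placement metadata carried by simulated reads (no aligner
#' is involved). Colour-space readsets are decoded to base space first --
#' the colour code is lossless given the primer base. Minus-strand reads
#' are reverse-complemented back into reference orientation. The result is
#' a compact store of (position, base, Phred) observations; columns at any
#' quality threshold come from \code{\link{pileupColumns}}.
#'
#' @param readset a \code{ReadSet} with placement metadata.
#' @param reference the reference \code{DNAStringSet}.
#' @return A \code{\link[=Pileup-class]{Pileup}}.
#' @export
pileupReads <- function(readset, reference) {
  contigs <- names(reference)
  lens <- stats::setNames(as.integer(Biostrings::width(reference)), contigs)
  n <- length(readset)
  if (!n)
    return(new("Pileup", id = readset@id, contigs = contigs,
               contigLengths = lens, chromIdx = integer(), pos = integer(),
               base = integer(), phred = integer()))
  if (anyNA(readset@pos) || anyNA(readset@chrom))
    stop("pileup requires placement metadata on every read")

  if (readSpace(readset) == "color") {
    ## drop the primer base/qual, decode colours to bases
    seqs <- decodeColorspace(substring(sequences(readset), 2L),
                             readset@primer)
    quals <- substring(readset@quals, 2L)
  } else {
    seqs <- sequences(readset)
    quals <- readset@quals
  }

  ## restore reference orientation for minus-strand reads
  minus <- readset@strand == "-"
  if (any(minus)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))
    seqs[minus] <- rc
    quals[minus] <- reverseStrings(quals[minus])
  }

  widths <- nchar(seqs)
  cidx <- match(readset@chrom, contigs)
  if (anyNA(cidx))
    stop("read placed on unknown contig: ",
         paste(unique(readset@chrom[is.na(cidx)]), collapse = ", "))
  if (any(readset@pos < 1L) || any(readset@pos + widths - 1L > lens[cidx]))
    stop("read placement outside reference bounds")

  base <- .baseLookup[utf8ToInt(paste(seqs, collapse = ""))]
  phred <- utf8ToInt(paste(quals, collapse = "")) - 33L
  pos <- rep(readset@pos, widths) + sequence(widths) - 1L
  chromIdx <- rep(cidx, widths)

  keep <- base > 0L  # drop N observations
  new("Pileup", id = readset@id, contigs = contigs, contigLengths = lens,
      chromIdx = chromIdx[keep], pos = pos[keep], base = base[keep],
      phred = phred[keep])
}

## global 0-based offset of each contig for flat indexing
.contigOffsets <- function(pileup) {
  c(0, cumsum(as.numeric(pileup@contigLengths)))[seq_along(pileup@contigs)]
}

#' Materialise pileup columns at a quality threshold
#'
#' One row per covered position; bases below \code{minPhred} are excluded
#' from the counts. Columns carry per-allele read counts (\code{nA..nT})
#' and per-allele best Phred (\code{qA..qT}).
#'
#' @param pileup a \code{Pileup}.
#' @param minPhred minimum per-base Phred for a base to be counted.
#' @return data.frame(chrom, pos, nA, nC, nG, nT, qA, qC, qG, qT).
#' @export
pileupColumns <- function(pileup, minPhred = 0L) {
  keep <- pileup@phred >= minPhred
  if (!any(keep)) {
    return(data.frame(chrom = character(), pos = integer(),
                      nA = integer(), nC = integer(), nG = integer(),
                      nT = integer(), qA = integer(), qC = integer(),
                      qG = integer(), qT = integer(),
                      stringsAsFactors = FALSE))
  }
  off <- .contigOffsets(pileup)
  gpos <- off[pileup@chromIdx[keep]] + pileup@pos[keep]
  base <- pileup@base[keep]
  ph <- pileup@phred[keep]

  upos <- sort(unique(gpos))
  m <- match(gpos, upos)
  nU <- length(upos)
  counts <- matrix(0L, nU, 4L)
  bestq <- matrix(0L, nU, 4L)
  o <- order(ph)  # later (higher-phred) writes win -> max per cell
  for (b in 1:4) {
    sel <- base == b
    counts[, b] <- tabulate(m[sel], nbins = nU)
    ob <- o[base[o] == b]
    if (length(ob))
      bestq[cbind(m[ob], rep.int(b, length(ob)))] <- ph[ob]
  }
  ci <- findInterval(upos - 0.5, c(off, sum(as.numeric(pileup@contigLengths))))
  data.frame(chrom = pileup@contigs[ci],
             pos = as.integer(upos - off[ci]),
             nA = counts[, 1], nC = counts[, 2], nG = counts[, 3],
             nT = counts[, 4],
             qA = bestq[, 1], qC = bestq[, 2], qG = bestq[, 3],
             qT = bestq[, 4],
             stringsAsFactors = FALSE)
}

#' Read depth at specific sites
#'
#' @param pileup a \code{Pileup}.
#' @param chrom,pos site vectors.
#' @param minPhred count only bases at or above this quality.
#' @return integer vector of depths.
#' @export
pileupCoverage <- function(pileup, chrom, pos, minPhred = 0L) {
  off <- .contigOffsets(pileup)
  keep <- pileup@phred >= minPhred
  gpos <- off[pileup@chromIdx[keep]] + pileup@pos[keep]
  q <- off[match(chrom, pileup@contigs)] + pos
  uq <- unique(q)
  m <- match(gpos, uq)
  cnt <- tabulate(m[!is.na(m)], nbins = length(uq))
  cnt[match(q, uq)]
}

#' Mean genome-wide fold coverage of a pileup
#' @param pileup a \code{Pileup}.
#' @param minPhred count only bases at or above this quality.
#' @export
pileupMeanCoverage <- function(pileup, minPhred = 0L) {
  sum(pileup@phred >= minPhred) / sum(as.numeric(pileup@contigLengths))
}

#' Call heterozygous positions from a pileup
#'
#' The three threshold rules, applied literally: (1) only bases at or
#' above \code{minPhred} count; (2) a position is called heterozygous when
#' at least two alleles each have at least \code{minVariantReads}
#' qualifying reads; (3) positions where any allele carries more than
#' \code{maxAlleleReads} reads are suppressed outright (presumed collapsed
#' repeats or mis-mapping). At columns where three alleles pass the read
#' threshold, the two best-supported alleles are called and the site is
#' flagged \code{triallelic}.
#'
#' @param pileup a \code{Pileup}.
#' @param profile a \code{\link{StringencyProfile}}.
#' @param reference the reference \code{DNAStringSet} (supplies the
#'   reference allele of each call).
#' @param id,animal,chemistry,caller tags for the resulting dataset
#'   (defaulted from the pileup where possible).
#' @return A \code{\link{SnpDataset}} of heterozygote calls.
#' @export
callHeterozygotes <- function(pileup, profile, reference,
                              id = NULL, animal = "unknown",
                              chemistry = "unknown", caller = "snpXval") {
  if (is.null(id)) id <- pileup@id
  cols <- pileupColumns(pileup, profile@minPhred)
  if (!nrow(cols))
    return(SnpDataset(id, animal, chemistry, caller))
  counts <- as.matrix(cols[, c("nA", "nC", "nG", "nT")])
  quals <- as.matrix(cols[, c("qA", "qC", "qG", "qT")])
  nr <- nrow(counts)

  c1 <- max.col(counts, ties.method = "first")
  v1 <- counts[cbind(seq_len(nr), c1)]
  tmp <- counts
  tmp[cbind(seq_len(nr), c1)] <- -1L
  c2 <- max.col(tmp, ties.method = "first")
  v2 <- tmp[cbind(seq_len(nr), c2)]
  tmp[cbind(seq_len(nr), c2)] <- -1L
  v3 <- tmp[cbind(seq_len(nr), max.col(tmp, ties.method = "first"))]

  het <- v2 >= profile@minVariantReads &
    pmax(counts[, 1], counts[, 2], counts[, 3], counts[, 4]) <=
      profile@maxAlleleReads
  ## (v1 >= v2 by construction, so rule (2) reduces to v2)
  if (!any(het))
    return(SnpDataset(id, animal, chemistry, caller))

  hi <- which(het)
  a1 <- .BASES[c1[hi]]; a2 <- .BASES[c2[hi]]
  refBase <- referenceBases(reference, cols$chrom[hi], cols$pos[hi])
  refIdx <- match(refBase, .BASES)
  readsRef <- counts[cbind(hi, refIdx)]
  qualRef <- quals[cbind(hi, refIdx)]

  refIsA1 <- a1 == refBase
  refIsA2 <- a2 == refBase
  refInPair <- refIsA1 | refIsA2
  alt1 <- ifelse(refIsA1, a2, a1)
  alt2 <- ifelse(refInPair, NA_character_, a2)
  altIdx1 <- match(alt1, .BASES)
  altIdx2 <- match(alt2, .BASES)
  df <- data.frame(
    chrom = cols$chrom[hi], pos = cols$pos[hi], ref = refBase,
    alt1 = alt1, alt2 = alt2,
    readsRef = readsRef,
    readsAlt1 = counts[cbind(hi, altIdx1)],
    readsAlt2 = ifelse(is.na(altIdx2), NA_integer_,
                       counts[cbind(hi, ifelse(is.na(altIdx2), 1L, altIdx2))]),
    qualRef = qualRef,
    qualAlt1 = quals[cbind(hi, altIdx1)],
    qualAlt2 = ifelse(is.na(altIdx2), NA_integer_,
                      quals[cbind(hi, ifelse(is.na(altIdx2), 1L, altIdx2))]),
    zygosity = "het",
    triallelic = v3[hi] >= profile@minVariantReads,
    stringsAsFactors = FALSE)
  SnpDataset(id, animal, chemistry, caller, df)
}

#' Call heterozygotes under several stringency profiles at once
#'
#' All profiles are applied to the same pileup, which is how the low- vs
#' high-stringency contrast is produced: when one profile's thresholds
#' dominate another's, its call set is a subset.
#'
#' @param pileup a \code{Pileup}.
#' @param profiles list of \code{StringencyProfile}s (named or not).
#' @param reference the reference \code{DNAStringSet}.
#' @param ... forwarded to \code{\link{callHeterozygotes}}.
#' @return named list of \code{SnpDataset}s, one per profile.
#' @export
stringencySweep <- function(pileup, profiles, reference, ...) {
  stopifnot(length(profiles) >= 1L)
  if (is.null(names(profiles)))
    names(profiles) <- paste0("profile", seq_along(profiles))
  out <- lapply(names(profiles), function(nm)
    callHeterozygotes(pileup, profiles[[nm]], reference,
                      id = paste0(pileup@id, ".", nm), ...))
  stats::setNames(out, names(profiles))
}
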