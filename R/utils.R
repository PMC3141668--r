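## Shared low-level helpers.

.BASES <- c("A", "C", "G", "T")

## byte-indexed lookup: ASCII code -> base index 1..4 (0 for anything else)
.baseLookup <- local({
  lk <- integer(256)
  lk[utf8ToInt("A")] <- 1L; lk[utf8ToInt("a")] <- 1L
  lk[utf8ToInt("C")] <- 2L; lk[utf8ToInt("c")] <- 2L
  lk[utf8ToInt("G")] <- 3L; lk[utf8ToInt("g")] <- 3L
  lk[utf8ToInt("T")] <- 4L; lk[utf8ToInt("t")] <- 4L
  lk
})

## complement on base indices 1..4 (A<->T, C<->G); 0 stays 0
.compIdx <- c(4L, 3L, 2L, 1L)

## string of one contig -> integer codes 1..4 (0 = N or other)
seqToCodes <- function(s) .baseLookup[utf8ToInt(s)]

codesToSeq <- function(codes) {
  intToUtf8(utf8ToInt("ACGTN")[ifelse(codes == 0L, 5L, codes)])
}

#' Canonical SNP key
#'
#' Builds the order-insensitive match unit used throughout validation:
#' chromosome, 1-based position, and the unordered allele pair, rendered as
#' \code{"chrom:pos:X/Y"} with the alleles sorted. Two calls with the same
#' position and the same allele pair produce identical keys regardless of
#' allele order.
#'
#' @param chrom,pos,a1,a2 vectors describing one SNP per element.
#' @return character vector of keys.
#' @examples
#' snpKey("c1", 10, "G", "A") == snpKey("c1", 10, "A", "G")
#' @export
snpKey <- function(chrom, pos, a1, a2) {
  lo <- ifelse(a1 <= a2, a1, a2)
  hi <- ifelse(a1 <= a2, a2, a1)
  paste0(chrom, ":", pos, ":", lo, "/", hi)
}

## parse keys back into a data.frame
parseSnpKey <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  al <- strsplit(vapply(parts, `[`, "", 3L), "/", fixed = TRUE)
  data.frame(chrom = vapply(parts, `[`, "", 1L),
             pos = as.integer(vapply(parts, `[`, "", 2L)),
             a1 = vapply(al, `[`, "", 1L),
             a2 = vapply(al, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Canonical unordered pair name
#'
#' Dataset pairs are identified as \code{"a|b"} with the two ids in
#' lexicographic order, so the same unordered pair always maps to the
#' same name.
#' @param a,b dataset ids.
#' @export
pairName <- function(a, b) {
  lo <- ifelse(a <= b, a, b)
  hi <- ifelse(a <= b, b, a)
  paste0(lo, "|", hi)
}

## position-only site id
siteId <- function(chrom, pos) paste0(chrom, ":", pos)

#' Extract single reference bases
#'
#' @param reference a \code{DNAStringSet}.
#' @param chrom,pos parallel vectors of contig names and 1-based positions.
#' @return character vector of bases.
#' @export
referenceBases <- function(reference, chrom, pos) {
  out <- character(length(chrom))
  for (ct in unique(chrom)) {
    if (!ct %in% names(reference))
      stop("contig not in reference: ", ct)
    sel <- chrom == ct
    p <- pos[sel]
    len <- Biostrings::width(reference[ct])
    if (any(p < 1L | p > len))
      stop("position outside contig ", ct)
    v <- Biostrings::extractAt(reference[[ct]], IRanges::IRanges(p, width = 1L))
    out[sel] <- as.character(v)
  }
  out
}

## derive k reproducible sub-seeds (< 2^31) from one master seed
subSeeds <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

## per-read heterozygous allele pair of a calls data.frame
callPair <- function(calls) {
  useRef <- is.na(calls$alt2)
  a1 <- ifelse(useRef, calls$ref, calls$alt1)
  a2 <- ifelse(useRef, calls$alt1, calls$alt2)
  list(a1 = a1, a2 = a2)
}

#' SNP keys of a dataset's heterozygote calls
#'
#' @param x a \code{SnpDataset} or calls data.frame.
#' @return character vector of \code{\link{snpKey}} keys, one per het call.
#' @export
callKeys <- function(x) {
  calls <- if (is(x, "SnpDataset")) snpCalls(x) else x
  calls <- calls[calls$zygosity == "het", , drop = FALSE]
  if (!nrow(calls)) return(character())
  p <- callPair(calls)
  snpKey(calls$chrom, calls$pos, p$a1, p$a2)
}

## Phred+33 quality string helpers
.qualChars <- vapply(0:93, function(q) intToUtf8(q + 33L), "")

#' Convert Phred scores to FASTQ (Phred+33) quality characters
#' @param ph integer Phred scores.
#' @export
phredToChars <- function(ph) .qualChars[pmax(0L, pmin(93L, ph)) + 1L]

#' Convert a FASTQ (Phred+33) quality string to Phred scores
#' @param s a quality string.
#' @export
qualStringToPhred <- function(s) utf8ToInt(s) - 33L
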