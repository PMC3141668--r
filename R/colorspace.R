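## SOLiD di-base colour-space encoding and decoding.
##
## Each colour encodes the transition between two adjacent bases:
##   identical pair -> 0;  A<->C, G<->T -> 1;  A<->G, C<->T -> 2;
##   A<->T, C<->G -> 3.
## With the 2-bit encoding A=00, C=01, G=10, T=11 this is exactly the
## bitwise XOR of the two base codes, which is what the implementation
## uses. Two properties follow directly: decode(encode(s)) == s given the
## primer base, and the colour string of a reverse-complemented sequence is
## the reverse of the colour string (complementation flips both bits of
## each base, leaving every XOR unchanged).

## split equal/unequal-width strings into an integer code matrix and back
.withWidthGroups <- function(x, f) {
  w <- nchar(x)
  out <- character(length(x))
  for (wi in unique(w)) {
    sel <- w == wi
    out[sel] <- f(x[sel], wi)
  }
  out
}

## vector of strings (equal width) -> integer matrix n x width
.strsToMat <- function(x, width) {
  matrix(utf8ToInt(paste(x, collapse = "")), ncol = width, byrow = TRUE)
}

## integer code matrix (values used to index `alphabet`) -> strings
.matToStrs <- function(m, alphabet) {
  cols <- lapply(seq_len(ncol(m)), function(j) alphabet[m[, j]])
  do.call(paste0, cols)
}

.base2bit <- local({
  lk <- rep(NA_integer_, 256)
  lk[utf8ToInt("A")] <- 0L; lk[utf8ToInt("C")] <- 1L
  lk[utf8ToInt("G")] <- 2L; lk[utf8ToInt("T")] <- 3L
  lk
})

.digit2int <- local({
  lk <- rep(NA_integer_, 256)
  lk[utf8ToInt("0")] <- 0L; lk[utf8ToInt("1")] <- 1L
  lk[utf8ToInt("2")] <- 2L; lk[utf8ToInt("3")] <- 3L
  lk
})

#' Encode nucleotide sequence(s) into SOLiD colour space
#'
#' Returns one colour digit per input base; the first colour encodes the
#' transition from the primer base to the first sequence base, so the
#' output has the same length as the input.
#'
#' @param sequence character vector of A/C/G/T strings.
#' @param primer single primer base.
#' @return character vector of digit strings over 0-3.
#' @examples
#' encodeColorspace("AAAA", "A")  # "0000"
#' encodeColorspace("ACGT", "A")  # "0131"
#' @export
encodeColorspace <- function(sequence, primer) {
  stopifnot(length(primer) == 1L, primer %in% .BASES)
  p2 <- .base2bit[utf8ToInt(primer)]
  .withWidthGroups(sequence, function(x, w) {
    m <- .strsToMat(x, w)
    b <- .base2bit[m]
    if (anyNA(b))
      stop("sequence contains characters outside ACGT (N not encodable)")
    dim(b) <- dim(m)
    prev <- cbind(rep.int(p2, nrow(b)),
                  b[, -ncol(b), drop = FALSE])
    col <- bitwXor(prev, b) + 1L
    dim(col) <- dim(b)
    .matToStrs(col, c("0", "1", "2", "3"))
  })
}

#' Decode SOLiD colour string(s) back to nucleotide space
#'
#' Exact inverse of \code{\link{encodeColorspace}} given the same primer.
#'
#' @param colors character vector of digit strings over 0-3 (primer
#'   transition included as the first digit).
#' @param primer single primer base.
#' @return character vector of A/C/G/T strings.
#' @export
decodeColorspace <- function(colors, primer) {
  stopifnot(length(primer) == 1L, primer %in% .BASES)
  p2 <- .base2bit[utf8ToInt(primer)]
  .withWidthGroups(colors, function(x, w) {
    m <- .strsToMat(x, w)
    d <- .digit2int[m]
    if (anyNA(d))
      stop("colour string contains characters outside 0-3")
    dim(d) <- dim(m)
    acc <- rep.int(p2, nrow(d))
    out <- matrix(0L, nrow(d), ncol(d))
    for (j in seq_len(ncol(d))) {
      acc <- bitwXor(acc, d[, j])
      out[, j] <- acc
    }
    .matToStrs(out + 1L, .BASES)
  })
}

## colour digits <-> letter proxy (0123 -> ACGT) so that exact colour
## matching can ride on the same Biostrings machinery as base space
colorDigitsToLetters <- function(x) chartr("0123", "ACGT", x)

## genomic colour portion of a colour read: strip the primer base and the
## primer-transition colour (the first digit), which encodes the adapter
## junction rather than genomic sequence
readColorLetters <- function(readset) {
  colorDigitsToLetters(substring(sequences(readset), 3L))
}

## reverse each string in a character vector
reverseStrings <- function(x) {
  .withWidthGroups(x, function(v, w) {
    m <- .strsToMat(v, w)[, rev(seq_len(w)), drop = FALSE]
    vapply(seq_len(nrow(m)), function(i) intToUtf8(m[i, ]), "")
  })
}
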