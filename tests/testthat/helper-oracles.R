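# Independent brute-force oracles. These deliberately use naive string
# scans and literal rule application, sharing no machinery with the
# implementation paths they check.

# number of reads containing pattern (or its reverse complement when
# rcPatterns given) as an exact substring, one count per read per pattern
naiveReadHitCounts <- function(patterns, reads, rcPatterns = NULL) {
  vapply(seq_along(patterns), function(i) {
    hit <- grepl(patterns[i], reads, fixed = TRUE)
    if (!is.null(rcPatterns))
      hit <- hit | grepl(rcPatterns[i], reads, fixed = TRUE)
    sum(hit)
  }, integer(1))
}

# per-probe naive scan of a base-space readset
naiveScanBase <- function(probes, readset) {
  naiveReadHitCounts(probes$sequence, sequences(readset),
                     revcomp(probes$sequence))
}

# per-probe naive scan of a colour-space readset: match the probe's
# internal colour string (or its reverse) in the read's genomic colours
naiveScanColor <- function(probes, readset) {
  readCols <- substring(sequences(readset), 3L)
  revstr <- function(s) vapply(s, function(x)
    paste(rev(strsplit(x, "")[[1]]), collapse = ""), "", USE.NAMES = FALSE)
  naiveReadHitCounts(probes$colorSequence, readCols,
                     revstr(probes$colorSequence))
}

# literal application of the three calling rules to pileup columns
oracleHetCalls <- function(cols, minPhred, minVariantReads, maxAlleleReads) {
  out <- list()
  for (i in seq_len(nrow(cols))) {
    counts <- c(A = cols$nA[i], C = cols$nC[i], G = cols$nG[i],
                T = cols$nT[i])
    if (max(counts) > maxAlleleReads) next          # rule 3: suppress
    passing <- names(counts)[counts >= minVariantReads]
    if (length(passing) < 2L) next                  # rule 2
    top2 <- names(counts)[order(-counts, seq_along(counts))][1:2]
    # ties broken by base order (A < C < G < T), matching the caller
    out[[length(out) + 1L]] <- data.frame(
      chrom = cols$chrom[i], pos = cols$pos[i],
      key = snpKey(cols$chrom[i], cols$pos[i], top2[1], top2[2]),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), pos = integer(),
                      key = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# brute-force pairwise intersection of het call lists by (chrom,pos,pair)
oracleValidate <- function(dsA, dsB) {
  keyOf <- function(ds) {
    calls <- snpCalls(ds)
    calls <- calls[calls$zygosity == "het", , drop = FALSE]
    keys <- character(nrow(calls))
    for (i in seq_len(nrow(calls))) {
      pair <- if (is.na(calls$alt2[i])) c(calls$ref[i], calls$alt1[i])
              else c(calls$alt1[i], calls$alt2[i])
      pair <- sort(pair)
      keys[i] <- paste0(calls$chrom[i], ":", calls$pos[i], ":",
                        pair[1], "/", pair[2])
    }
    keys
  }
  intersect(keyOf(dsA), keyOf(dsB))
}

# hand encoding via the di-base transition matrix (no XOR shortcut)
.colorMatrix <- local({
  m <- matrix(0L, 4, 4, dimnames = list(c("A","C","G","T"),
                                        c("A","C","G","T")))
  m["A","C"] <- m["C","A"] <- m["G","T"] <- m["T","G"] <- 1L
  m["A","G"] <- m["G","A"] <- m["C","T"] <- m["T","C"] <- 2L
  m["A","T"] <- m["T","A"] <- m["C","G"] <- m["G","C"] <- 3L
  m
})

handEncodeColors <- function(sequence, primer) {
  chars <- strsplit(sequence, "")[[1]]
  prev <- primer
  out <- integer(length(chars))
  for (i in seq_along(chars)) {
    out[i] <- .colorMatrix[prev, chars[i]]
    prev <- chars[i]
  }
  paste(out, collapse = "")
}

# count occurrences of the probe window (flanks + any centre base) in a
# reference, both strands, by regex with overlap-tolerant lookahead
naiveWindowOccurrences <- function(probeSeq, centerIndex, reference) {
  left <- substr(probeSeq, 1L, centerIndex - 1L)
  right <- substr(probeSeq, centerIndex + 1L, nchar(probeSeq))
  pat <- paste0("(?=", left, "[ACGT]", right, ")")
  n <- 0L
  for (i in seq_along(reference)) {
    for (s in c(as.character(reference[[i]]),
                revcomp(as.character(reference[[i]])))) {
      hits <- gregexpr(pat, s, perl = TRUE)[[1]]
      n <- n + sum(hits > 0L)
    }
  }
  n
}
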