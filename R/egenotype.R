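## In-silico probe genotyping ("e-genotyping"): 31 bp allele-specific
## probes, uniqueness screening against the reference, and exact matching
## against raw reads in base or colour space.

.PROBE_FLANK <- 15L

#' Build allele-specific probes for potential SNPs
#'
#' For each SNP, one probe per allele is constructed: the reference allele
#' plus each alternate of the heterozygous pair. A probe is the reference
#' window of \code{flank} bases either side of the SNP with the centre
#' base replaced by the probe allele (31 bp at the default flank of 15).
#' SNPs within \code{flank} bp of a contig end, or whose window contains
#' an ambiguous base (assembly gap), yield no probes and are reported as
#' skipped -- such SNPs are invisible to this method by construction.
#'
#' @param reference a \code{DNAStringSet}.
#' @param snps a \code{SnpDataset} or calls data.frame.
#' @param flank flank length in bp (probe length is \code{2*flank+1}).
#' @return data.frame with one row per probe: \code{key}, \code{chrom},
#'   \code{pos}, \code{allele}, \code{sequence}, \code{centerIndex},
#'   \code{unique} (NA until screened), \code{colorSequence} (internal
#'   transition colours of the probe). Skipped SNPs are attached as
#'   attribute \code{"skipped"} (data.frame key, reason).
#' @export
buildProbes <- function(reference, snps, flank = .PROBE_FLANK) {
  calls <- if (is(snps, "SnpDataset")) snpCalls(snps) else snps
  calls <- calls[calls$zygosity == "het", , drop = FALSE]
  emptyP <- data.frame(key = character(), chrom = character(),
                       pos = integer(), allele = character(),
                       sequence = character(), centerIndex = integer(),
                       unique = logical(), colorSequence = character(),
                       stringsAsFactors = FALSE)
  skipped <- data.frame(key = character(), reason = character(),
                        stringsAsFactors = FALSE)
  if (!nrow(calls)) {
    attr(emptyP, "skipped") <- skipped
    return(emptyP)
  }
  pr <- callPair(calls)
  keys <- snpKey(calls$chrom, calls$pos, pr$a1, pr$a2)

  probeRows <- vector("list", length(unique(calls$chrom)))
  names(probeRows) <- unique(calls$chrom)
  for (ct in unique(calls$chrom)) {
    sel <- which(calls$chrom == ct)
    if (!ct %in% names(reference))
      stop("SNP on unknown contig: ", ct)
    L <- Biostrings::width(reference[ct])
    codes <- seqToCodes(as.character(reference[[ct]]))
    pos <- calls$pos[sel]

    atEdge <- pos - flank < 1L | pos + flank > L
    winOK <- !atEdge
    win <- matrix(NA_integer_, length(sel), 2L * flank + 1L)
    if (any(winOK)) {
      idx <- rep(pos[winOK] - flank, each = 2L * flank + 1L) +
        rep.int(0:(2L * flank), sum(winOK))
      win[winOK, ] <- matrix(codes[idx], ncol = 2L * flank + 1L, byrow = TRUE)
    }
    hasN <- winOK & (rowSums(win == 0L) > 0L)
    hasN[is.na(hasN)] <- FALSE
    good <- winOK & !hasN

    if (any(atEdge))
      skipped <- rbind(skipped, data.frame(
        key = keys[sel][atEdge], reason = "within flank of contig end",
        stringsAsFactors = FALSE))
    if (any(hasN))
      skipped <- rbind(skipped, data.frame(
        key = keys[sel][hasN], reason = "ambiguous base in probe window",
        stringsAsFactors = FALSE))
    if (!any(good)) next

    gi <- which(good)
    ii <- sel[gi]
    ## probe alleles: reference base plus the (1-2) non-reference alleles
    ## of the heterozygous pair (long form, one row per probe)
    winStr <- .matToStrs(win[gi, , drop = FALSE], .BASES)
    left <- substr(winStr, 1L, flank)
    right <- substr(winStr, flank + 2L, 2L * flank + 1L)
    long <- data.frame(
      key = rep(keys[ii], 3L),
      chrom = ct,
      pos = rep(calls$pos[ii], 3L),
      allele = c(calls$ref[ii], pr$a1[ii], pr$a2[ii]),
      left = rep(left, 3L), right = rep(right, 3L),
      stringsAsFactors = FALSE)
    long <- long[!duplicated(paste(long$key, long$allele)), , drop = FALSE]
    long$sequence <- paste0(long$left, long$allele, long$right)
    long$centerIndex <- flank + 1L
    long$unique <- NA
    probeRows[[ct]] <- long[, c("key", "chrom", "pos", "allele",
                                "sequence", "centerIndex", "unique")]
  }
  probes <- do.call(rbind, c(list(emptyP[, setdiff(names(emptyP), "colorSequence")]),
                             unname(probeRows)))
  rownames(probes) <- NULL
  probes$colorSequence <- character(nrow(probes))
  ## internal transitions: encode positions 2..end with the probe's own
  ## first base as primer, giving 2*flank colours independent of any primer
  if (nrow(probes)) {
    first <- substr(probes$sequence, 1L, 1L)
    cs <- character(nrow(probes))
    for (b in .BASES) {
      selb <- first == b
      if (any(selb))
        cs[selb] <- encodeColorspace(substring(probes$sequence[selb], 2L), b)
    }
    probes$colorSequence <- cs
  }
  attr(probes, "skipped") <- skipped
  probes
}

#' Screen probes for unique mapping in the reference
#'
#' A probe site maps uniquely when its probe window -- the two 15 bp
#' flanks with any base at the centre -- occurs exactly once in the
#' reference genome counting both strands (an occurrence of the reverse
#' complement counts). All allele-specific probes of a SNP share the
#' site's flag: an alternate-allele probe never occurs verbatim in the
#' reference, so uniqueness is a property of where the window maps, not
#' of the substituted centre base. Non-unique probes are excluded from
#' scanning by \code{\link{scanReadset}}. Exact k-mer occurrence counting
#' (over the four centre-base variants) is used, matching the exact-match
#' semantics of the scan itself.
#'
#' @param probes probe data.frame from \code{\link{buildProbes}}.
#' @param reference a \code{DNAStringSet}.
#' @return the probe data.frame with the \code{unique} column filled.
#' @export
screenProbeUniqueness <- function(probes, reference) {
  if (!nrow(probes)) return(probes)
  site <- paste0(probes$chrom, ":", probes$pos)
  uFirst <- !duplicated(site)
  tmpl <- probes$sequence[uFirst]
  ctr <- probes$centerIndex[uFirst]
  nSite <- length(tmpl)
  ## all four centre-base variants of each unique site window
  pats <- unlist(lapply(.BASES, function(b) {
    s <- tmpl
    substr(s, ctr, ctr) <- b
    s
  }))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats))
  occ <- rowSums(Biostrings::vcountPDict(pd, reference)) +
    rowSums(Biostrings::vcountPDict(
      pd, Biostrings::reverseComplement(reference)))
  total <- rowSums(matrix(occ, nrow = nSite))
  probes$unique <- (total == 1L)[match(site, site[uFirst])]
  probes
}

## count, per probe, the number of reads containing an exact occurrence of
## `patterns[i]` or `revPatterns[i]`; each read counts once per probe
.countReadHits <- function(patterns, revPatterns, subjects) {
  nP <- length(patterns)
  if (!length(subjects) || !nP) return(integer(nP))
  w <- unique(nchar(patterns))
  stopifnot(length(w) == 1L)
  long <- Biostrings::width(subjects) >= w
  if (!any(long)) return(integer(nP))
  subj <- subjects[long]
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(patterns))
  hitF <- Biostrings::vwhichPDict(pd, subj)
  pdR <- Biostrings::PDict(Biostrings::DNAStringSet(revPatterns))
  hitR <- Biostrings::vwhichPDict(pdR, subj)
  readIdx <- c(rep(seq_along(hitF), lengths(hitF)),
               rep(seq_along(hitR), lengths(hitR)))
  probeIdx <- c(unlist(hitF, use.names = FALSE),
                unlist(hitR, use.names = FALSE))
  if (!length(probeIdx)) return(integer(nP))
  dedup <- !duplicated(readIdx * (nP + 1) + probeIdx)
  tabulate(probeIdx[dedup], nbins = nP)
}

#' Scan a readset for exact probe matches
#'
#' A read supports a probe allele iff the full probe sequence -- or its
#' reverse complement in base space; its reversed colour sequence in
#' colour space -- is an exact substring of the read. Reads shorter than
#' the probe can never match. In colour space the primer-transition colour
#' (the first colour of every read) is excluded from matching since it
#' encodes the adapter junction, not genomic sequence; a probe of
#' \code{2f+1} bases matches as its \code{2f} internal transition colours.
#'
#' Counts are aggregated per SNP allele across the probe set; each read
#' counts at most once per probe. Only probes flagged \code{unique} are
#' scanned.
#'
#' @param probes screened probe data.frame (see
#'   \code{\link{screenProbeUniqueness}}).
#' @param readset a \code{ReadSet}; its space decides the matching mode.
#' @param profile a \code{\link{StringencyProfile}} (supplies
#'   \code{maxAlleleReads} for overflow and \code{positiveMinReads} for
#'   positivity).
#' @return data.frame with one row per scanned SNP: \code{key},
#'   \code{chrom}, \code{pos}, alleles \code{a1}/\code{a2} (the
#'   heterozygous pair), counts \code{n1}/\code{n2}, reference-allele
#'   count \code{nRef}, and \code{status} in \{positive, negative,
#'   overflow\}.
#' @export
scanReadset <- function(probes, readset, profile = StringencyProfile()) {
  if (any(is.na(probes$unique)))
    stop("probes must be screened for uniqueness before scanning")
  probes <- probes[probes$unique, , drop = FALSE]
  if (!nrow(probes)) {
    return(data.frame(key = character(), chrom = character(),
                      pos = integer(), a1 = character(), a2 = character(),
                      n1 = integer(), n2 = integer(), nRef = integer(),
                      status = character(), stringsAsFactors = FALSE))
  }
  if (readSpace(readset) == "base") {
    subj <- Biostrings::DNAStringSet(sequences(readset))
    counts <- .countReadHits(
      probes$sequence,
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(probes$sequence))),
      subj)
  } else {
    subj <- Biostrings::DNAStringSet(readColorLetters(readset))
    pat <- colorDigitsToLetters(probes$colorSequence)
    counts <- .countReadHits(pat, reverseStrings(pat), subj)
  }
  probes$count <- counts

  ## aggregate probes back to SNPs (vectorised: match on key+allele)
  keys <- unique(probes$key)
  snp <- parseSnpKey(keys)
  pk <- paste(probes$key, probes$allele)
  lookup <- function(al) {
    cnt <- probes$count[match(paste(keys, al), pk)]
    ifelse(is.na(cnt), 0L, cnt)
  }
  res <- data.frame(key = keys, chrom = snp$chrom, pos = snp$pos,
                    a1 = snp$a1, a2 = snp$a2,
                    n1 = lookup(snp$a1), n2 = lookup(snp$a2),
                    stringsAsFactors = FALSE)
  ## reference-allele probe count, when the pair excludes the reference
  res$nRef <- NA_integer_
  extra <- probes[!(pk %in% c(paste(keys, snp$a1), paste(keys, snp$a2))), ,
                  drop = FALSE]
  if (nrow(extra)) {
    m <- match(res$key, extra$key)
    res$nRef <- ifelse(is.na(m), NA_integer_, extra$count[m])
  }
  over <- pmax(res$n1, res$n2, ifelse(is.na(res$nRef), 0L, res$nRef)) >
    profile@maxAlleleReads
  pos <- res$n1 >= profile@positiveMinReads & res$n2 >= profile@positiveMinReads
  res$status <- ifelse(over, "overflow", ifelse(pos, "positive", "negative"))
  res
}

#' Call genotypes from e-genotyping scan results
#'
#' A SNP is called heterozygous when both alleles of its pair have at
#' least \code{positiveMinReads} exact-match reads; homozygous for the
#' single observed allele when only one has support; and \code{no_call}
#' when neither allele has support or the site overflowed the
#' \code{maxAlleleReads} bound.
#'
#' @param results scan results from \code{\link{scanReadset}}.
#' @param profile a \code{\link{StringencyProfile}}.
#' @return data.frame(key, chrom, pos, call, g1, g2) where \code{call} is
#'   "het", "hom" or "no_call" and g1/g2 the called genotype alleles (NA
#'   for no_call).
#' @export
callGenotypes <- function(results, profile = StringencyProfile()) {
  t1 <- results$n1 >= profile@positiveMinReads
  t2 <- results$n2 >= profile@positiveMinReads
  over <- results$status == "overflow"
  call <- ifelse(over, "no_call",
          ifelse(t1 & t2, "het",
          ifelse(t1 | t2, "hom", "no_call")))
  g1 <- ifelse(call == "het", results$a1,
        ifelse(call == "hom", ifelse(t1, results$a1, results$a2),
               NA_character_))
  g2 <- ifelse(call == "het", results$a2,
        ifelse(call == "hom", g1, NA_character_))
  data.frame(key = results$key, chrom = results$chrom, pos = results$pos,
             call = call, g1 = g1, g2 = g2, stringsAsFactors = FALSE)
}

#' One-step e-genotyping of a SNP list against a readset
#'
#' Convenience wrapper: build probes, screen them for uniqueness, scan the
#' readset and return the results, with SNPs that produced no usable probe
#' reported with status \code{no_probe}.
#'
#' @param reference a \code{DNAStringSet}.
#' @param snps a \code{SnpDataset} or calls data.frame.
#' @param readset a \code{ReadSet}.
#' @param profile a \code{\link{StringencyProfile}}.
#' @param flank probe flank length.
#' @param probes optional pre-screened probe data.frame (skips rebuild).
#' @return as \code{\link{scanReadset}}, plus \code{no_probe} rows.
#' @export
egenotypeSnps <- function(reference, snps, readset,
                          profile = StringencyProfile(),
                          flank = .PROBE_FLANK, probes = NULL) {
  if (is.null(probes)) {
    probes <- buildProbes(reference, snps, flank)
    probes <- screenProbeUniqueness(probes, reference)
  }
  res <- scanReadset(probes, readset, profile)
  skipped <- attr(probes, "skipped")
  noProbe <- unique(c(
    if (!is.null(skipped)) skipped$key else character(),
    setdiff(unique(probes$key[!probes$unique]), res$key)))
  noProbe <- setdiff(noProbe, res$key)
  if (length(noProbe)) {
    snp <- parseSnpKey(noProbe)
    res <- rbind(res, data.frame(
      key = noProbe, chrom = snp$chrom, pos = snp$pos,
      a1 = snp$a1, a2 = snp$a2, n1 = 0L, n2 = 0L, nRef = NA_integer_,
      status = "no_probe", stringsAsFactors = FALSE))
  }
  res
}
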