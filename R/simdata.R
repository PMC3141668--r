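## Synthetic references, diploid individuals, multi-chemistry read sets and
## collapsed-duplication artifacts with known truth.

#' Simulate a reference genome
#'
#' Contigs are named \code{c1..cN} and drawn i.i.d. per base at the
#' requested GC fraction.
#'
#' @param nContigs number of contigs.
#' @param lengths contig lengths (recycled to \code{nContigs}).
#' @param gc GC fraction in [0, 1].
#' @param seed optional RNG seed; fixed seed gives identical output.
#' @return A named \code{DNAStringSet}.
#' @export
simulateReference <- function(nContigs, lengths, gc = 0.5, seed = NULL) {
  stopifnot(nContigs >= 1L, all(lengths >= 1L), gc >= 0, gc <= 1)
  if (!is.null(seed)) set.seed(seed)
  lengths <- rep_len(as.integer(lengths), nContigs)
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  codes <- utf8ToInt("ACGT")
  seqs <- vapply(lengths, function(L)
    intToUtf8(sample(codes, L, replace = TRUE, prob = prob)), "")
  ref <- Biostrings::DNAStringSet(seqs)
  names(ref) <- paste0("c", seq_len(nContigs))
  ref
}

#' Simulate one diploid individual
#'
#' Heterozygous sites are drawn independently per basepair at rate
#' \code{hetRate}; the alternate allele is uniform over the three
#' non-reference bases. The default rate corresponds to roughly 4.3 million
#' heterozygous positions in a ~2.9 Gb genome, the discovery scale the
#' pipeline is designed around.
#'
#' @param reference a \code{DNAStringSet}.
#' @param hetRate per-bp heterozygosity in [0, 0.1].
#' @param seed optional RNG seed.
#' @param individual individual identifier.
#' @return A \code{\link{TruthTable}}.
#' @export
simulateIndividual <- function(reference, hetRate = 1.5e-3, seed = NULL,
                               individual = "ind1") {
  if (hetRate < 0 || hetRate > 0.1)
    stop("hetRate must lie in [0, 0.1]")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(names(reference), function(ct) {
    L <- Biostrings::width(reference[ct])
    pos <- which(stats::runif(L) < hetRate)
    if (!length(pos)) return(NULL)
    refc <- seqToCodes(as.character(reference[[ct]]))[pos]
    altc <- ((refc - 1L + sample.int(3L, length(pos), replace = TRUE)) %% 4L) + 1L
    data.frame(individual = individual, chrom = ct, pos = pos,
               ref = .BASES[refc], a1 = .BASES[refc], a2 = .BASES[altc],
               stringsAsFactors = FALSE)
  })
  g <- do.call(rbind, c(list(emptyGenotypes()), rows))
  TruthTable(genotypes = g,
             contigs = stats::setNames(Biostrings::width(reference),
                                       names(reference)))
}

#' Simulate a population of diploid individuals with shared polymorphism
#'
#' Unlike \code{\link{simulateIndividual}}, which draws heterozygous sites
#' independently per individual, this generator first draws a set of
#' segregating sites with per-site minor allele frequencies and then
#' genotypes every individual at those sites under Hardy-Weinberg
#' proportions. Individuals therefore share polymorphic positions, which
#' is what makes cross-animal validation (and "heterozygous in two of
#' three animals" control groups) possible. The site density is calibrated
#' so the expected per-individual heterozygosity equals \code{hetRate}.
#'
#' @param reference a \code{DNAStringSet}.
#' @param individuals individual ids (or a count).
#' @param hetRate target per-bp per-individual heterozygosity.
#' @param mafRange range of the uniform per-site minor allele frequency.
#' @param seed optional RNG seed.
#' @return A \code{\link{TruthTable}} covering all individuals.
#' @export
simulatePopulation <- function(reference, individuals = 3L,
                               hetRate = 1.5e-3, mafRange = c(0.05, 0.5),
                               seed = NULL) {
  if (hetRate < 0 || hetRate > 0.1)
    stop("hetRate must lie in [0, 0.1]")
  if (is.numeric(individuals) && length(individuals) == 1L)
    individuals <- paste0("ind", seq_len(individuals))
  if (!is.null(seed)) set.seed(seed)
  a <- mafRange[1]; b <- mafRange[2]
  meanHet <- 2 * ((a + b) / 2 - (a^2 + a * b + b^2) / 3)  # E[2p(1-p)], p~U(a,b)
  density <- hetRate / meanHet

  rows <- lapply(names(reference), function(ct) {
    L <- Biostrings::width(reference[ct])
    pos <- which(stats::runif(L) < density)
    if (!length(pos)) return(NULL)
    n <- length(pos)
    refc <- seqToCodes(as.character(reference[[ct]]))[pos]
    altc <- ((refc - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L
    maf <- stats::runif(n, a, b)
    perInd <- lapply(individuals, function(ind) {
      gcount <- stats::rbinom(n, 2L, maf)
      keep <- gcount > 0L
      if (!any(keep)) return(NULL)
      data.frame(individual = ind, chrom = ct, pos = pos[keep],
                 ref = .BASES[refc[keep]],
                 a1 = ifelse(gcount[keep] == 2L, .BASES[altc[keep]],
                             .BASES[refc[keep]]),
                 a2 = .BASES[altc[keep]],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, perInd)
  })
  g <- do.call(rbind, c(list(emptyGenotypes()), rows))
  g <- g[order(g$individual, g$chrom, g$pos), , drop = FALSE]
  TruthTable(genotypes = g,
             contigs = stats::setNames(Biostrings::width(reference),
                                       names(reference)))
}

#' Register a collapsed duplication
#'
#' Emulates a near-identical segmental duplication that was mistakenly
#' collapsed into a single locus during genome assembly: reads are
#' thereafter generated from both the original interval and a divergent
#' copy, but all carry placements onto the single reference copy. Local
#' read coverage doubles and every simulated individual appears
#' heterozygous at each divergent position -- the artifact signature the
#' duplication screens are built to detect.
#'
#' @param truth a \code{\link{TruthTable}}.
#' @param reference the reference \code{DNAStringSet}.
#' @param chrom,start,end the collapsed interval (1-based inclusive).
#' @param divergence per-bp divergence between the two copies, in (0, 0.1).
#' @param seed optional RNG seed.
#' @param id duplication identifier.
#' @return The updated \code{TruthTable}.
#' @export
injectCollapsedDuplication <- function(truth, reference, chrom, start, end,
                                       divergence, seed = NULL,
                                       id = NULL) {
  if (divergence < 0 || divergence >= 0.1)
    stop("divergence must lie in [0, 0.1); 0 injects an identical copy")
  if (!chrom %in% names(reference)) stop("unknown contig: ", chrom)
  L <- Biostrings::width(reference[chrom])
  if (start < 1L || end > L || start > end)
    stop("interval outside contig ", chrom)
  dup <- duplications(truth)
  clash <- dup$chrom == chrom & dup$start <= end & dup$end >= start
  if (any(clash))
    stop("interval overlaps an existing injected duplication")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(id)) id <- paste0("dup", nrow(dup) + 1L)

  len <- end - start + 1L
  off <- which(stats::runif(len) < divergence)
  refc <- seqToCodes(as.character(
    Biostrings::extractAt(reference[[chrom]],
                          IRanges::IRanges(start, end))[[1]]))[off]
  altc <- ((refc - 1L + sample.int(3L, length(off), replace = TRUE)) %% 4L) + 1L
  newDup <- data.frame(id = id, chrom = chrom, start = as.integer(start),
                       end = as.integer(end), divergence = divergence,
                       stringsAsFactors = FALSE)
  newDiv <- if (length(off))
    data.frame(dupId = id, chrom = chrom, pos = as.integer(start - 1L + off),
               ref = .BASES[refc], alt = .BASES[altc],
               stringsAsFactors = FALSE)
  else emptyDivergences()
  TruthTable(genotypes = genotypes(truth),
             duplications = rbind(dup, newDup),
             divergences = rbind(divergentSites(truth), newDiv),
             contigs = truth@contigs)
}

## draw per-base Phred scores consistent with a target mean error rate:
## each base gets phred ~ round(N(-10log10(rate), 4)) clamped to [2, 40]
## and then errs with probability 10^(-phred/10)
.drawPhred <- function(n, errorRate) {
  if (errorRate == 0) return(rep.int(40L, n))
  p0 <- -10 * log10(errorRate)
  pmin(40L, pmax(2L, as.integer(round(stats::rnorm(n, p0, 4)))))
}

## apply haplotype genotypes onto reference codes
.haplotypeCodes <- function(refCodes, gt) {
  hap1 <- refCodes
  hap2 <- refCodes
  if (nrow(gt)) {
    c1 <- .baseLookup[utf8ToInt(paste(gt$a1, collapse = ""))]
    c2 <- .baseLookup[utf8ToInt(paste(gt$a2, collapse = ""))]
    flip <- stats::runif(nrow(gt)) < 0.5
    hap1[gt$pos] <- ifelse(flip, c2, c1)
    hap2[gt$pos] <- ifelse(flip, c1, c2)
  }
  list(hap1, hap2)
}

## extract reads from one source code vector; returns list(codes=matrix)
.pullReads <- function(codes, starts, len) {
  idx <- rep(starts, each = len) + rep.int(seq_len(len) - 1L, length(starts))
  matrix(codes[idx], ncol = len, byrow = TRUE)
}

#' Simulate a read set for one individual and chemistry
#'
#' Reads are sampled uniformly along each contig, each read drawn from one
#' of the two haplotypes chosen fairly. Per-base Phred qualities are drawn
#' around the quality equivalent of the profile's error rate and each base
#' errs with the probability its own quality implies, so qualities and
#' errors are mutually consistent. True placements (contig, leftmost
#' reference position, strand) are recorded. Colour-space chemistries emit
#' colour reads via \code{\link{encodeColorspace}}; mate-pair chemistries
#' emit two reads per sampled fragment at a fixed insert.
#'
#' If the truth table registers collapsed duplications, additional reads
#' are generated from the divergent copy of each interval at the same
#' local coverage and placed onto the single reference copy, doubling
#' coverage there.
#'
#' @param reference a \code{DNAStringSet}.
#' @param truth a \code{\link{TruthTable}}.
#' @param profile a \code{\link{ChemistryProfile}}.
#' @param individual which individual's genotypes to sequence.
#' @param seed optional RNG seed.
#' @param id readset id (default "<individual>_<chemistry>").
#' @param primer colour-space primer base.
#' @return A \code{\link{ReadSet}}.
#' @export
simulateReads <- function(reference, truth, profile, individual = NULL,
                          seed = NULL, id = NULL, primer = "T") {
  stopifnot(is(profile, "ChemistryProfile"))
  len <- profile@readLength
  if (len > min(Biostrings::width(reference)))
    stop("read length exceeds the shortest contig")
  if (!is.null(seed)) set.seed(seed)
  gt <- genotypes(truth)
  if (is.null(individual))
    individual <- if (nrow(gt)) gt$individual[1] else "ind1"
  if (is.null(id)) id <- paste0(individual, "_", profile@name)
  gt <- gt[gt$individual == individual, , drop = FALSE]
  dup <- duplications(truth)
  div <- divergentSites(truth)

  allCodes <- NULL; allStart <- integer(); allChrom <- character()
  for (ct in names(reference)) {
    L <- Biostrings::width(reference[ct])
    refCodes <- seqToCodes(as.character(reference[[ct]]))
    haps <- .haplotypeCodes(refCodes, gt[gt$chrom == ct, , drop = FALSE])

    ## primary reads (whole contig, both haplotypes)
    if (profile@matePair) {
      insert <- min(profile@insertSize, max(0L, L - 2L * len))
      nFrag <- round(L * profile@coverage / (2 * len))
      fs <- sample.int(max(1L, L - insert - len + 1L), nFrag, replace = TRUE)
      starts <- c(fs, fs + insert)
    } else {
      n <- round(L * profile@coverage / len)
      starts <- sample.int(L - len + 1L, n, replace = TRUE)
    }
    hapIdx <- sample.int(2L, length(starts), replace = TRUE)
    m <- rbind(.pullReads(haps[[1]], starts[hapIdx == 1L], len),
               .pullReads(haps[[2]], starts[hapIdx == 2L], len))
    st <- c(starts[hapIdx == 1L], starts[hapIdx == 2L])

    ## duplication-copy reads: same local coverage again, placed onto the
    ## single reference copy
    dct <- dup[dup$chrom == ct, , drop = FALSE]
    for (k in seq_len(nrow(dct))) {
      ds <- dct$start[k]; de <- dct$end[k]
      dlen <- de - ds + 1L
      if (dlen < len) next
      copy <- refCodes[ds:de]
      dv <- div[div$dupId == dct$id[k], , drop = FALSE]
      if (nrow(dv))
        copy[dv$pos - ds + 1L] <- .baseLookup[utf8ToInt(paste(dv$alt, collapse = ""))]
      ## reads from the copy lie fully inside the interval, so scale by
      ## the start window to hit the target coverage over the interior
      ## (coverage tapers within one read length of the interval ends)
      nd <- round((dlen - len + 1L) * profile@coverage / len)
      dst <- sample.int(dlen - len + 1L, nd, replace = TRUE)
      m <- rbind(m, .pullReads(copy, dst, len))
      st <- c(st, ds - 1L + dst)
    }

    allCodes <- if (is.null(allCodes)) m else rbind(allCodes, m)
    allStart <- c(allStart, st)
    allChrom <- c(allChrom, rep.int(ct, length(st)))
  }

  nReads <- nrow(allCodes)
  ## strand: half the reads are sequenced from the minus strand
  minus <- stats::runif(nReads) < 0.5
  if (any(minus)) {
    sub <- allCodes[minus, , drop = FALSE]
    sub <- .compIdx[sub]
    dim(sub) <- c(sum(minus), len)
    allCodes[minus, ] <- sub[, rev(seq_len(len)), drop = FALSE]
  }

  ## qualities and substitution errors
  ph <- .drawPhred(nReads * len, profile@errorRate)
  if (profile@errorRate > 0) {
    err <- which(stats::runif(length(ph)) < 10^(-ph / 10))
    if (length(err)) {
      v <- as.vector(t(allCodes))
      v[err] <- ((v[err] - 1L + sample.int(3L, length(err), replace = TRUE)) %% 4L) + 1L
      allCodes <- matrix(v, nrow = nReads, byrow = TRUE)
    }
  }
  phm <- matrix(ph, nrow = nReads, byrow = TRUE)

  seqs <- .matToStrs(allCodes, .BASES)
  quals <- .matToStrs(phm + 1L, .qualChars)
  strand <- ifelse(minus, "-", "+")

  if (profile@space == "color") {
    seqs <- paste0(primer, encodeColorspace(seqs, primer))
    quals <- paste0("!", quals)
  }
  ReadSet(id = id, sequences = seqs, quals = quals,
          chrom = allChrom, pos = allStart, strand = strand,
          animal = individual, chemistry = profile@name,
          space = profile@space, primer = if (profile@space == "color") primer else "")
}

#' Realized fold-coverage of a readset
#' @param readset a \code{ReadSet}.
#' @param reference the reference it was simulated from.
#' @return total sequenced bases divided by genome length.
#' @export
realizedCoverage <- function(readset, reference) {
  n <- sum(nchar(sequences(readset)))
  if (readSpace(readset) == "color")
    n <- n - length(readset)  # primer base is not a genomic base
  n / sum(as.numeric(Biostrings::width(reference)))
}
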