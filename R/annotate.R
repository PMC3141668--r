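## Genomic-context classification of SNPs against gene models.

.PLACEMENT_PRIORITY <- c("splice_site", "nonsynonymous", "synonymous",
                         "coding_unresolved", "utr5", "utr3",
                         "intronic", "intergenic")

#' Construct a gene model
#'
#' A minimal transcript model: exon intervals, CDS intervals and strand on
#' one contig. Coordinates are 1-based inclusive. Exons must not overlap
#' within the transcript and every CDS interval must lie within an exon.
#'
#' @param txId,geneId transcript / gene identifiers.
#' @param chrom contig.
#' @param strand "+" or "-".
#' @param exons,cds \code{IRanges} (cds may be empty for non-coding
#'   transcripts).
#' @return a \code{"GeneModel"} list.
#' @export
geneModel <- function(txId, geneId, chrom, strand, exons,
                      cds = IRanges::IRanges()) {
  stopifnot(strand %in% c("+", "-"))
  exons <- exons[order(IRanges::start(exons))]
  cds <- cds[order(IRanges::start(cds))]
  if (length(exons) > 1L &&
      any(IRanges::start(exons)[-1] <= IRanges::end(exons)[-length(exons)]))
    stop("exons overlap within transcript ", txId)
  if (length(cds)) {
    ov <- IRanges::countOverlaps(cds, exons, type = "within")
    if (any(ov == 0L))
      stop("CDS intervals must lie within exons (", txId, ")")
  }
  structure(list(txId = txId, geneId = geneId, chrom = chrom,
                 strand = strand, exons = exons, cds = cds),
            class = "GeneModel")
}

#' Read gene models from GFF3
#'
#' Builds one \code{\link{geneModel}} per mRNA/transcript feature, from
#' its child exon and CDS features (linked by \code{Parent}).
#'
#' @param path GFF3 file.
#' @return list of \code{GeneModel}s, named by transcript id.
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  firstParent <- function(x) vapply(as.list(x), function(p)
    if (length(p)) p[[1]] else NA_character_, "")
  tx <- gr[type %in% c("mRNA", "transcript")]
  models <- lapply(seq_along(tx), function(i) {
    id <- tx$ID[i]
    kids <- gr[!is.na(firstParent(gr$Parent)) & firstParent(gr$Parent) == id]
    ktype <- as.character(kids$type)
    exons <- IRanges::ranges(kids[ktype == "exon"])
    cds <- IRanges::ranges(kids[ktype == "CDS"])
    if (!length(exons)) exons <- IRanges::ranges(tx[i])
    geneModel(txId = id,
              geneId = firstParent(tx$Parent)[i],
              chrom = as.character(GenomicRanges::seqnames(tx[i])),
              strand = as.character(GenomicRanges::strand(tx[i])),
              exons = exons, cds = cds)
  })
  stats::setNames(models, vapply(models, `[[`, "", "txId"))
}

## coding sequence of a model: string plus the genomic position of each
## coding base in transcription order
.cdsSeq <- function(model, reference) {
  cds <- model$cds
  pos <- unlist(lapply(seq_along(cds), function(i)
    seq.int(IRanges::start(cds)[i], IRanges::end(cds)[i])))
  chars <- referenceWindow(reference, model$chrom, min(pos), max(pos))
  bases <- substring(chars, pos - min(pos) + 1L, pos - min(pos) + 1L)
  if (model$strand == "-") {
    pos <- rev(pos)
    bases <- chartr("ACGT", "TGCA", rev(bases))
  }
  list(seq = paste(bases, collapse = ""), pos = pos)
}

## one contiguous reference window as a plain string
referenceWindow <- function(reference, chrom, start, end) {
  as.character(Biostrings::extractAt(
    reference[[chrom]], IRanges::IRanges(start, end))[[1]])
}

.translate1 <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

## placement of one SNP relative to one transcript; NULL when the SNP does
## not overlap the transcript span
.placeInTranscript <- function(model, pos, ref, alt, reference, spliceWindow,
                               cache) {
  if (pos < min(IRanges::start(model$exons)) ||
      pos > max(IRanges::end(model$exons))) return(NULL)
  inExon <- any(pos >= IRanges::start(model$exons) &
                  pos <= IRanges::end(model$exons))
  if (!inExon) {
    ## intronic; splice site if within spliceWindow of an intron end
    ends <- IRanges::end(model$exons)[-length(model$exons)]
    starts <- IRanges::start(model$exons)[-1]
    splice <- any((pos - ends >= 1L & pos - ends <= spliceWindow) |
                    (starts - pos >= 1L & starts - pos <= spliceWindow))
    return(list(placement = if (splice) "splice_site" else "intronic"))
  }
  if (!length(model$cds))
    return(list(placement = "intronic"))
  inCds <- any(pos >= IRanges::start(model$cds) &
                 pos <= IRanges::end(model$cds))
  if (!inCds) {
    cdsLo <- min(IRanges::start(model$cds))
    cdsHi <- max(IRanges::end(model$cds))
    before <- pos < cdsLo
    utr5 <- (model$strand == "+" && before) ||
      (model$strand == "-" && !before && pos > cdsHi)
    return(list(placement = if (utr5) "utr5" else "utr3"))
  }
  ## coding: derive codon
  key <- model$txId
  cs <- cache[[key]]
  if (is.null(cs)) {
    cs <- .cdsSeq(model, reference)
    cache[[key]] <- cs
  }
  if (nchar(cs$seq) %% 3L != 0L)
    return(list(placement = "coding_unresolved"))
  cpos <- match(pos, cs$pos)
  codonIdx <- (cpos - 1L) %/% 3L
  within <- (cpos - 1L) %% 3L
  codon <- substr(cs$seq, codonIdx * 3L + 1L, codonIdx * 3L + 3L)
  altC <- if (model$strand == "-") chartr("ACGT", "TGCA", alt) else alt
  altCodon <- codon
  substr(altCodon, within + 1L, within + 1L) <- altC
  refAA <- .translate1(codon)
  altAA <- .translate1(altCodon)
  list(placement = if (identical(refAA, altAA)) "synonymous" else "nonsynonymous",
       codon = codon, altCodon = altCodon, refAA = refAA, altAA = altAA,
       proteinPos = codonIdx + 1L)
}

#' Annotate one SNP against a set of gene models
#'
#' Computes the genomic placement (intergenic, intronic, splice site,
#' synonymous, non-synonymous, 5'UTR, 3'UTR) for every transcript the SNP
#' overlaps, and consolidates them into a single category by priority
#' (splice_site > nonsynonymous > synonymous > utr5 > utr3 > intronic >
#' intergenic). A SNP overlapping no transcript is intergenic. Coding
#' placements in transcripts whose CDS length is not divisible by 3 are
#' downgraded to \code{coding_unresolved} and excluded from the
#' synonymous/non-synonymous tallies. When placements differ between
#' transcripts the record is flagged \code{placementVaries}.
#'
#' @param chrom,pos,ref,alt the SNP (single alternate allele).
#' @param models list of \code{GeneModel}s.
#' @param reference a \code{DNAStringSet}.
#' @param spliceWindow intronic bases at each intron end treated as splice
#'   site (canonical donor/acceptor = 2).
#' @param cache internal per-transcript CDS cache (an environment).
#' @return one-row data.frame: chrom, pos, ref, alt, category,
#'   placementVaries, placements (comma-joined per-transcript, as
#'   "tx:placement"), codon, altCodon, refAA, altAA, proteinPos.
#' @export
annotateSnp <- function(chrom, pos, ref, alt, models, reference,
                        spliceWindow = 2L, cache = new.env()) {
  rb <- referenceBases(reference, chrom, pos)
  if (rb != ref)
    stop(sprintf("reference allele mismatch at %s:%d (got %s, reference %s)",
                 chrom, pos, ref, rb))
  placements <- list()
  for (model in models) {
    if (model$chrom != chrom) next
    p <- .placeInTranscript(model, pos, ref, alt, reference, spliceWindow,
                            cache)
    if (!is.null(p)) placements[[model$txId]] <- p
  }
  if (!length(placements)) {
    cats <- "intergenic"
    perTx <- character()
  } else {
    cats <- vapply(placements, `[[`, "", "placement")
    perTx <- paste0(names(placements), ":", cats)
  }
  best <- cats[which.min(match(cats, .PLACEMENT_PRIORITY))]
  coding <- Filter(function(p)
    p$placement %in% c("synonymous", "nonsynonymous"), placements)
  ## codon details from the highest-priority coding transcript
  cd <- if (length(coding)) {
    ord <- order(match(vapply(coding, `[[`, "", "placement"),
                       .PLACEMENT_PRIORITY))
    coding[[ord[1]]]
  } else NULL
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             category = best,
             placementVaries = length(unique(cats)) > 1L,
             placements = paste(perTx, collapse = ","),
             codon = if (is.null(cd)) NA_character_ else cd$codon,
             altCodon = if (is.null(cd)) NA_character_ else cd$altCodon,
             refAA = if (is.null(cd)) NA_character_ else cd$refAA,
             altAA = if (is.null(cd)) NA_character_ else cd$altAA,
             proteinPos = if (is.null(cd)) NA_integer_ else cd$proteinPos,
             stringsAsFactors = FALSE)
}

#' Annotate a table of SNPs
#'
#' @param snps data.frame with columns chrom, pos, ref, alt.
#' @param models,reference,spliceWindow see \code{\link{annotateSnp}}.
#' @return data.frame of annotation records, one per input row.
#' @export
annotateSnps <- function(snps, models, reference, spliceWindow = 2L) {
  cache <- new.env()
  rows <- lapply(seq_len(nrow(snps)), function(i)
    annotateSnp(snps$chrom[i], snps$pos[i], snps$ref[i], snps$alt[i],
                models, reference, spliceWindow, cache))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise annotation categories
#'
#' @param records annotation records from \code{\link{annotateSnps}}.
#' @return list(counts, fractions, nPlacementVaries, total); fractions sum
#'   to 1 over the consolidated categories.
#' @export
summarizeAnnotation <- function(records) {
  counts <- table(factor(records$category, levels = .PLACEMENT_PRIORITY))
  total <- nrow(records)
  list(counts = counts,
       fractions = if (total) counts / total else counts,
       nPlacementVaries = sum(records$placementVaries),
       total = total)
}
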