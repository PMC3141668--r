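## Readers and writers for the standard formats the pipeline touches.

#' Load a reference genome from FASTA
#'
#' Reads a (multi-)FASTA reference into a \code{DNAStringSet}, normalising
#' lowercase bases to uppercase. Contig names are the first whitespace-
#' delimited token of each header.
#'
#' @param path FASTA file.
#' @return A named \code{DNAStringSet}.
#' @export
loadReference <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ref <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  names(ref) <- sub("\\s.*$", "", names(ref))
  if (anyDuplicated(names(ref)))
    stop("duplicate contig name(s) in ", path, ": ",
         paste(unique(names(ref)[duplicated(names(ref))]), collapse = ", "))
  ## (lowercase bases are normalised to uppercase by the DNA alphabet)
  ref
}

#' Write a reference genome to FASTA
#' @param reference a \code{DNAStringSet}.
#' @param path output file.
#' @export
writeReference <- function(reference, path) {
  Biostrings::writeXStringSet(reference, path)
  invisible(path)
}

#' Load a potential-SNP list from TSV
#'
#' Expects a tab-separated file with a header row and columns \code{chrom},
#' \code{pos}, \code{ref}, \code{alt}, \code{reads_ref}, \code{reads_alt},
#' \code{qual_ref}, \code{qual_alt}. The \code{alt} column carries one
#' allele, or two comma-joined alleles for heterozygous pairs that exclude
#' the reference base; \code{reads_alt}/\code{qual_alt} are comma-joined in
#' parallel. Duplicate (chrom, pos) rows resolve last-wins with a warning.
#'
#' @param path TSV file.
#' @param id dataset identifier.
#' @param animal,chemistry,caller dataset tags.
#' @return A \code{\link{SnpDataset}}.
#' @export
loadSnpList <- function(path, id, animal = "unknown", chemistry = "unknown",
                        caller = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, colClasses = "character")
  need <- c("chrom", "pos", "ref", "alt", "reads_ref", "reads_alt",
            "qual_ref", "qual_alt")
  if (!all(need %in% names(raw)))
    stop("SNP list ", path, " must have columns: ",
         paste(need, collapse = ", "))
  if (!nrow(raw))
    return(SnpDataset(id, animal, chemistry, caller))

  pos <- suppressWarnings(as.integer(raw$pos))
  if (anyNA(pos))
    stop("non-integer pos in ", path, " at data row(s): ",
         paste(which(is.na(pos)), collapse = ", "))

  altSplit <- strsplit(raw$alt, ",", fixed = TRUE)
  nAlt <- lengths(altSplit)
  if (any(nAlt < 1L | nAlt > 2L))
    stop("alt must carry 1-2 alleles; offending row(s): ",
         paste(which(nAlt < 1L | nAlt > 2L), collapse = ", "))
  alt1 <- vapply(altSplit, `[`, "", 1L)
  alt2 <- vapply(altSplit, function(x) if (length(x) > 1L) x[2L] else NA_character_, "")
  bad <- !(raw$ref %in% .BASES) | !(alt1 %in% .BASES) |
    (!is.na(alt2) & !(alt2 %in% .BASES))
  if (any(bad))
    stop("allele outside ACGT in ", path, " at data row(s): ",
         paste(which(bad), collapse = ", "))

  splitInt <- function(col, n) {
    s <- strsplit(col, ",", fixed = TRUE)
    v1 <- suppressWarnings(as.integer(vapply(s, `[`, "", 1L)))
    v2 <- suppressWarnings(as.integer(
      vapply(s, function(x) if (length(x) > 1L) x[2L] else NA_character_, "")))
    if (anyNA(v1)) stop("non-integer ", n, " in ", path)
    list(v1 = v1, v2 = v2)
  }
  ra <- splitInt(raw$reads_alt, "reads_alt")
  qa <- splitInt(raw$qual_alt, "qual_alt")
  readsRef <- suppressWarnings(as.integer(raw$reads_ref))
  qualRef <- suppressWarnings(as.integer(raw$qual_ref))
  if (anyNA(readsRef) || anyNA(qualRef))
    stop("non-integer reads_ref/qual_ref in ", path)

  het <- !is.na(alt2) | (readsRef > 0L & ra$v1 > 0L)
  zyg <- ifelse(het, "het", ifelse(ra$v1 > 0L, "hom_alt", "hom_ref"))
  df <- data.frame(chrom = raw$chrom, pos = pos, ref = raw$ref,
                   alt1 = alt1, alt2 = alt2,
                   readsRef = readsRef, readsAlt1 = ra$v1, readsAlt2 = ra$v2,
                   qualRef = qualRef, qualAlt1 = qa$v1, qualAlt2 = qa$v2,
                   zygosity = zyg,
                   triallelic = if ("triallelic" %in% names(raw))
                     as.logical(raw$triallelic) else FALSE,
                   stringsAsFactors = FALSE)

  key <- paste(df$chrom, df$pos)
  if (anyDuplicated(key)) {
    warning("duplicate (chrom, pos) rows in ", path, "; keeping last occurrence")
    df <- df[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  SnpDataset(id, animal, chemistry, caller, df)
}

#' Write a SNP list to TSV
#'
#' Inverse of \code{\link{loadSnpList}}: a write-then-load round trip
#' reproduces chrom, pos, alleles, read counts and qualities exactly.
#'
#' @param dataset a \code{SnpDataset}.
#' @param path output TSV.
#' @export
writeSnpList <- function(dataset, path) {
  df <- snpCalls(dataset)
  join2 <- function(v1, v2) ifelse(is.na(v2), as.character(v1),
                                   paste0(v1, ",", v2))
  out <- data.frame(
    chrom = df$chrom, pos = df$pos, ref = df$ref,
    alt = join2(df$alt1, df$alt2),
    reads_ref = df$readsRef,
    reads_alt = join2(df$readsAlt1, ifelse(is.na(df$alt2), NA, df$readsAlt2)),
    qual_ref = df$qualRef,
    qual_alt = join2(df$qualAlt1, ifelse(is.na(df$alt2), NA, df$qualAlt2)),
    triallelic = df$triallelic,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write merged validated SNPs as VCF 4.x
#'
#' One record per (chrom, pos), sorted by reference contig order then
#' position. Multi-allelic sites emit comma-joined ALT alleles. The INFO
#' field carries the supporting dataset pairs (\code{DP2}) and the number
#' of validating pairs (\code{NV}). Sites where the reference base is not
#' among the validated alleles are flagged \code{REF_MISMATCH} in FILTER
#' (rather than silently dropped): these surface either reference-call
#' errors or genuinely tri-allelic SNPs.
#'
#' @param merged merged validated SNPs, as returned by
#'   \code{\link{mergeValidated}}.
#' @param reference the reference \code{DNAStringSet}.
#' @param path output VCF path.
#' @return the path, invisibly.
#' @export
writeValidatedVcf <- function(merged, reference, path) {
  if (nrow(merged)) {
    if (!all(merged$chrom %in% names(reference)))
      stop("merged SNPs reference unknown contig(s): ",
           paste(setdiff(unique(merged$chrom), names(reference)), collapse = ", "))
    ord <- order(match(merged$chrom, names(reference)), merged$pos)
    merged <- merged[ord, , drop = FALSE]
    refBase <- referenceBases(reference, merged$chrom, merged$pos)
    alleleList <- strsplit(merged$alleles, "/", fixed = TRUE)
    mismatch <- !mapply(function(als, rb) rb %in% als, alleleList, refBase)
    altList <- mapply(function(als, rb) setdiff(als, rb), alleleList, refBase,
                      SIMPLIFY = FALSE)
  } else {
    refBase <- character()
    altList <- list()
    mismatch <- logical()
  }

  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(merged)) merged$chrom else character(),
    ranges = IRanges::IRanges(start = if (nrow(merged)) merged$pos else integer(),
                              width = 1L))
  GenomeInfoDb::seqlevels(gr) <- names(reference)
  fixed <- S4Vectors::DataFrame(
    REF = Biostrings::DNAStringSet(refBase),
    ALT = Biostrings::DNAStringSetList(altList),
    QUAL = rep(NA_real_, nrow(merged)),
    FILTER = ifelse(mismatch, "REF_MISMATCH", "PASS"))
  info <- S4Vectors::DataFrame(
    NV = if (nrow(merged)) merged$nPairs else integer(),
    DP2 = if (nrow(merged)) merged$supportingPairs else character())
  hdr <- VariantAnnotation::VCFHeader(
    samples = character(),
    header = IRanges::DataFrameList(
      fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                        row.names = "fileformat"),
      FILTER = S4Vectors::DataFrame(
        Description = c("All filters passed",
                        "Reference base absent from the validated allele pair"),
        row.names = c("PASS", "REF_MISMATCH")),
      INFO = S4Vectors::DataFrame(
        Number = c("1", "1"), Type = c("Integer", "String"),
        Description = c("Number of validating dataset pairs",
                        "Supporting dataset pairs"),
        row.names = c("NV", "DP2"))))
  vcf <- VariantAnnotation::VCF(rowRanges = gr, fixed = fixed, info = info,
                                collapsed = TRUE)
  VariantAnnotation::header(vcf) <- hdr
  names(vcf) <- if (nrow(merged)) siteId(merged$chrom, merged$pos) else character()
  VariantAnnotation::writeVcf(vcf, path)
  invisible(path)
}

#' Write SNP positions as a BED track
#'
#' Used for the retained per-dataset unvalidated-SNP tracks. Scores and
#' strand are omitted; names are the SNP site ids.
#'
#' @param calls a calls data.frame (or \code{SnpDataset}).
#' @param path output BED path.
#' @export
writeBed <- function(calls, path) {
  if (is(calls, "SnpDataset")) calls <- snpCalls(calls)
  gr <- GenomicRanges::GRanges(
    seqnames = calls$chrom,
    ranges = IRanges::IRanges(start = calls$pos, width = 1L),
    name = siteId(calls$chrom, calls$pos))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a readset to disk
#'
#' Base-space readsets are written as FASTQ (Phred+33). Colour-space
#' readsets are written as a TSV with columns \code{id}, \code{sequence}
#' (primer base + colour digits), \code{qual}, \code{chrom}, \code{pos},
#' \code{strand}.
#'
#' @param readset a \code{ReadSet}.
#' @param path output file.
#' @export
writeReads <- function(readset, path) {
  n <- length(readset)
  ids <- sprintf("%s_%06d", readset@id, seq_len(n))
  if (readSpace(readset) == "base") {
    seqs <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(sequences(readset)),
      Biostrings::PhredQuality(readset@quals))
    names(seqs) <- ids
    Biostrings::writeQualityScaledXStringSet(seqs, path)
  } else {
    utils::write.table(
      data.frame(id = ids, sequence = readset@sequences, qual = readset@quals,
                 chrom = readset@chrom, pos = readset@pos,
                 strand = readset@strand, stringsAsFactors = FALSE),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Load a base-space readset from FASTQ
#'
#' Placement metadata is parsed from read names of the form
#' \code{id chrom:pos:strand} when present (the simulator writes it);
#' otherwise placements are NA.
#'
#' @param path FASTQ file.
#' @param id,animal,chemistry readset tags.
#' @return A \code{ReadSet}.
#' @export
loadReadsFastq <- function(path, id, animal = "unknown", chemistry = "unknown") {
  ## (the reader warns that it drops mcols it never uses; silence that)
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  ReadSet(id = id, sequences = as.character(x),
          quals = as.character(Biostrings::quality(x)),
          chrom = rep(NA_character_, length(x)),
          pos = rep(NA_integer_, length(x)),
          strand = rep(NA_character_, length(x)),
          animal = animal, chemistry = chemistry, space = "base")
}

#' Load a colour-space readset from TSV
#' @param path TSV written by \code{\link{writeReads}}.
#' @param id,animal,chemistry readset tags.
#' @export
loadReadsColor <- function(path, id, animal = "unknown", chemistry = "unknown") {
  df <- utils::read.delim(path, colClasses = "character")
  ReadSet(id = id, sequences = df$sequence, quals = df$qual,
          chrom = df$chrom, pos = as.integer(df$pos), strand = df$strand,
          animal = animal, chemistry = chemistry, space = "color",
          primer = substr(df$sequence[1], 1L, 1L))
}
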