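## Central S4 classes shared by all modules.

#' @include AllGenerics.R
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Stringency profile for heterozygote calling and validation
#'
#' Bundles the quality/coverage thresholds that govern both the pileup
#' heterozygote caller and the pairwise validation rules: the minimum
#' per-base Phred score, the minimum number of reads required per variant
#' allele for a heterozygote call, the maximum number of reads an allele may
#' carry before the site is discarded as presumed mis-mapping, and the
#' minimum per-allele read count for an e-genotyping result to be scored
#' positive.
#'
#' The low-stringency defaults (Phred >= 20, >= 2 reads per variant allele,
#' <= 200 reads per allele, >= 1 read per allele for e-genotyping positives)
#' deliberately favour sensitivity: the downstream cross-chemistry /
#' cross-animal validation step is what controls the false-positive rate.
#'
#' @slot minPhred minimum per-base Phred quality for a base to count.
#' @slot minVariantReads minimum reads supporting each variant allele.
#' @slot maxAlleleReads sites where any allele exceeds this read count are
#'   suppressed (presumed collapsed repeats / mis-mapping).
#' @slot positiveMinReads minimum exact-match reads per allele for an
#'   e-genotyping call to be positive.
#' @export
setClass("StringencyProfile",
  representation(
    minPhred = "integer",
    minVariantReads = "integer",
    maxAlleleReads = "integer",
    positiveMinReads = "integer"
  )
)

setValidity("StringencyProfile", function(object) {
  vals <- c(object@minPhred, object@minVariantReads,
            object@maxAlleleReads, object@positiveMinReads)
  if (any(is.na(vals)) || any(vals < 0L))
    return("all thresholds must be non-negative integers")
  TRUE
})

#' @param minPhred,minVariantReads,maxAlleleReads,positiveMinReads see slots.
#' @return A \code{StringencyProfile} object.
#' @rdname StringencyProfile-class
#' @examples
#' StringencyProfile()            # the low-stringency defaults
#' StringencyProfile(30, 4)       # a high-stringency variant
#' @export
StringencyProfile <- function(minPhred = 20L, minVariantReads = 2L,
                              maxAlleleReads = 200L, positiveMinReads = 1L) {
  new("StringencyProfile",
      minPhred = as.integer(minPhred),
      minVariantReads = as.integer(minVariantReads),
      maxAlleleReads = as.integer(maxAlleleReads),
      positiveMinReads = as.integer(positiveMinReads))
}

#' @export
#' @rdname StringencyProfile-class
lowStringency <- function() StringencyProfile(20L, 2L)

#' High-stringency counterpart used for the stringency-contrast analysis.
#' @export
#' @rdname StringencyProfile-class
highStringency <- function() StringencyProfile(30L, 4L)

setMethod("show", "StringencyProfile", function(object) {
  cat(sprintf(
    "StringencyProfile: minPhred=%d minVariantReads=%d maxAlleleReads=%d positiveMinReads=%d\n",
    object@minPhred, object@minVariantReads, object@maxAlleleReads,
    object@positiveMinReads))
})

#' Sequencing chemistry profile
#'
#' Describes one sequencing technology for the read simulator: read length,
#' target fold-coverage, per-base error rate and the read space (nucleotide
#' "base" space or SOLiD di-base "color" space). Mate-pair chemistries emit
#' two reads per sampled fragment separated by a fixed insert.
#'
#' @slot name chemistry name.
#' @slot readLength read length in bp (per mate for mate-pair libraries).
#' @slot coverage target fold-coverage.
#' @slot errorRate mean per-base substitution error rate.
#' @slot space "base" or "color".
#' @slot matePair whether two reads are emitted per fragment.
#' @slot insertSize mate-pair insert (outer distance between mate starts).
#' @export
setClass("ChemistryProfile",
  representation(
    name = "character",
    readLength = "integer",
    coverage = "numeric",
    errorRate = "numeric",
    space = "character",
    matePair = "logical",
    insertSize = "integer"
  )
)

setValidity("ChemistryProfile", function(object) {
  if (object@coverage <= 0) return("coverage must be > 0")
  if (object@errorRate < 0 || object@errorRate >= 0.25)
    return("error rate must lie in [0, 0.25)")
  if (object@readLength < 1L) return("read length must be >= 1")
  if (!object@space %in% c("base", "color"))
    return("space must be 'base' or 'color'")
  TRUE
})

#' @param name,readLength,coverage,errorRate,space,matePair,insertSize see slots.
#' @rdname ChemistryProfile-class
#' @export
ChemistryProfile <- function(name, readLength, coverage, errorRate,
                             space = c("base", "color"), matePair = FALSE,
                             insertSize = 1000L) {
  space <- match.arg(space)
  new("ChemistryProfile", name = name, readLength = as.integer(readLength),
      coverage = coverage, errorRate = errorRate, space = space,
      matePair = matePair, insertSize = as.integer(insertSize))
}

#' Preset chemistry profiles at the study coverages
#'
#' Presets mirror the coverages and read lengths of the study design:
#' Sanger whole-genome shotgun at 5.2X (700 bp reads), SOLiD fragment
#' libraries at 5X (50 bp, colour space), SOLiD mate-pair at 8X
#' (25 x 25 bp, colour space) and 454 at 0.5X (250 bp). The per-base error
#' rates are simulator defaults chosen to be representative of each
#' technology and are freely configurable.
#'
#' @param name one of "sanger", "solid_frag", "solid_matepair", "roche454".
#' @param coverage optional override of the preset fold-coverage.
#' @return A \code{ChemistryProfile}.
#' @examples
#' chemistryPreset("solid_frag")
#' chemistryPreset("sanger", coverage = 2)
#' @export
chemistryPreset <- function(name = c("sanger", "solid_frag",
                                     "solid_matepair", "roche454"),
                            coverage = NULL) {
  name <- match.arg(name)
  p <- switch(name,
    sanger         = ChemistryProfile("sanger", 700L, 5.2, 1e-3, "base"),
    solid_frag     = ChemistryProfile("solid_frag", 50L, 5.0, 5e-3, "color"),
    solid_matepair = ChemistryProfile("solid_matepair", 25L, 8.0, 5e-3,
                                      "color", matePair = TRUE),
    roche454       = ChemistryProfile("roche454", 250L, 0.5, 2e-3, "base"))
  if (!is.null(coverage)) p@coverage <- coverage
  validObject(p)
  p
}

setMethod("show", "ChemistryProfile", function(object) {
  cat(sprintf("ChemistryProfile '%s': %dbp%s %.2gX err=%.2g space=%s\n",
              object@name, object@readLength,
              if (object@matePair) " mate-pair" else "",
              object@coverage, object@errorRate, object@space))
})

#' A tagged collection of SNP calls from one dataset
#'
#' A dataset is one (animal, chemistry, caller) combination together with
#' its potential-SNP calls. Calls are held in a data.frame with one row per
#' (chrom, pos): columns \code{chrom}, \code{pos} (1-based), \code{ref},
#' \code{alt1}, \code{alt2} (NA unless the heterozygous allele pair excludes
#' the reference base), per-allele read counts (\code{readsRef},
#' \code{readsAlt1}, \code{readsAlt2}), per-allele best Phred qualities
#' (\code{qualRef}, \code{qualAlt1}, \code{qualAlt2}), \code{zygosity}
#' ("het", "hom_ref" or "hom_alt") and a \code{triallelic} flag for columns
#' where a third allele also met the read threshold.
#'
#' The heterozygous allele pair of a call is (ref, alt1) when \code{alt2}
#' is NA, and (alt1, alt2) otherwise.
#'
#' @export
setClass("SnpDataset",
  representation(
    id = "character",
    animal = "character",
    chemistry = "character",
    caller = "character",
    calls = "data.frame"
  )
)

.CALL_COLS <- c("chrom", "pos", "ref", "alt1", "alt2",
                "readsRef", "readsAlt1", "readsAlt2",
                "qualRef", "qualAlt1", "qualAlt2",
                "zygosity", "triallelic")

emptyCalls <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt1 = character(), alt2 = character(),
             readsRef = integer(), readsAlt1 = integer(),
             readsAlt2 = integer(),
             qualRef = integer(), qualAlt1 = integer(),
             qualAlt2 = integer(),
             zygosity = character(), triallelic = logical(),
             stringsAsFactors = FALSE)
}

setValidity("SnpDataset", function(object) {
  df <- object@calls
  if (!all(.CALL_COLS %in% names(df)))
    return(paste("calls must have columns:", paste(.CALL_COLS, collapse = ", ")))
  if (nrow(df)) {
    if (anyDuplicated(paste(df$chrom, df$pos)))
      return("(chrom, pos) must be unique within a dataset")
    if (any(df$pos < 1L)) return("positions must be >= 1")
    ok <- c("A", "C", "G", "T")
    if (!all(df$ref %in% ok) || !all(df$alt1 %in% ok) ||
        !all(df$alt2 %in% c(ok, NA_character_)))
      return("alleles must be A/C/G/T")
    if (any(df$ref == df$alt1, na.rm = TRUE) ||
        any(df$ref == df$alt2, na.rm = TRUE))
      return("reference allele must not appear among alternate alleles")
  }
  TRUE
})

#' @param id,animal,chemistry,caller dataset tags.
#' @param calls calls data.frame (see class description).
#' @rdname SnpDataset-class
#' @export
SnpDataset <- function(id, animal = "unknown",
                       chemistry = c("sanger", "solid_frag", "solid_matepair",
                                     "roche454", "unknown"),
                       caller = "internal", calls = emptyCalls()) {
  chemistry <- match.arg(chemistry)
  rownames(calls) <- NULL
  new("SnpDataset", id = id, animal = animal, chemistry = chemistry,
      caller = caller, calls = calls)
}

#' @rdname SnpDataset-class
#' @export
setMethod("datasetId", "SnpDataset", function(x) x@id)
#' @rdname SnpDataset-class
#' @export
setMethod("animal", "SnpDataset", function(x) x@animal)
#' @rdname SnpDataset-class
#' @export
setMethod("chemistry", "SnpDataset", function(x) x@chemistry)
#' @rdname SnpDataset-class
#' @export
setMethod("snpCalls", "SnpDataset", function(x) x@calls)

#' @export
setMethod("length", "SnpDataset", function(x) nrow(x@calls))

setMethod("show", "SnpDataset", function(object) {
  cat(sprintf("SnpDataset '%s' (animal=%s, chemistry=%s, caller=%s): %d calls\n",
              object@id, object@animal, object@chemistry, object@caller,
              nrow(object@calls)))
})

#' A tagged collection of sequencing reads
#'
#' Reads are stored columnar: one sequence string, one Phred+33 quality
#' string and the true placement (contig, 1-based start of the leftmost
#' reference base, strand) per read. Colour-space reads are stored as a
#' primer base followed by digits 0-3 (one colour per base, the first
#' colour encoding the primer-to-first-base transition); their quality
#' strings carry a placeholder "!" for the primer position.
#'
#' @slot id readset identifier.
#' @slot animal source individual.
#' @slot chemistry chemistry name.
#' @slot space "base" or "color".
#' @slot sequences per-read sequence strings.
#' @slot quals per-read Phred+33 quality strings.
#' @slot chrom,pos,strand true placement metadata (simulation provenance).
#' @slot primer colour-space primer base ("" for base space).
#' @export
setClass("ReadSet",
  representation(
    id = "character",
    animal = "character",
    chemistry = "character",
    space = "character",
    sequences = "character",
    quals = "character",
    chrom = "character",
    pos = "integer",
    strand = "character",
    primer = "character"
  )
)

setValidity("ReadSet", function(object) {
  n <- length(object@sequences)
  if (length(object@quals) != n || length(object@chrom) != n ||
      length(object@pos) != n || length(object@strand) != n)
    return("sequences, quals and placement vectors must have equal length")
  if (!object@space %in% c("base", "color"))
    return("space must be 'base' or 'color'")
  if (n && any(nchar(object@quals) != nchar(object@sequences)))
    return("each quality string must match its sequence length")
  if (object@space == "color" && n) {
    if (!grepl("^[ACGT]$", object@primer))
      return("colour-space readsets need a single-base primer")
    bad <- !grepl("^[ACGT][0123]*$", object@sequences)
    if (any(bad))
      return("colour reads must be a primer base followed by digits 0-3")
  }
  TRUE
})

#' @param id,animal,chemistry,space,sequences,quals,chrom,pos,strand,primer
#'   see slots.
#' @rdname ReadSet-class
#' @export
ReadSet <- function(id, sequences, quals, chrom, pos, strand,
                    animal = "unknown", chemistry = "unknown",
                    space = c("base", "color"), primer = "") {
  space <- match.arg(space)
  new("ReadSet", id = id, animal = animal, chemistry = chemistry,
      space = space, sequences = as.character(sequences),
      quals = as.character(quals), chrom = as.character(chrom),
      pos = as.integer(pos), strand = as.character(strand), primer = primer)
}

#' @rdname ReadSet-class
#' @export
setMethod("datasetId", "ReadSet", function(x) x@id)
#' @rdname ReadSet-class
#' @export
setMethod("animal", "ReadSet", function(x) x@animal)
#' @rdname ReadSet-class
#' @export
setMethod("chemistry", "ReadSet", function(x) x@chemistry)
#' @rdname ReadSet-class
#' @export
setMethod("readSpace", "ReadSet", function(x) x@space)
#' @rdname ReadSet-class
#' @export
setMethod("sequences", "ReadSet", function(x) x@sequences)

#' @export
setMethod("length", "ReadSet", function(x) length(x@sequences))

setMethod("show", "ReadSet", function(object) {
  cat(sprintf("ReadSet '%s' (animal=%s, chemistry=%s, %s space): %d reads\n",
              object@id, object@animal, object@chemistry, object@space,
              length(object@sequences)))
})

#' Simulated ground truth: per-individual genotypes and duplication registry
#'
#' Holds, for each simulated individual, the genotype at every segregating
#' site (heterozygous and homozygous-alternate sites; homozygous-reference
#' genotypes are implicit), plus the registry of injected collapsed
#' duplications: their intervals and the divergent positions between the
#' two collapsed copies. Divergent-duplication sites appear heterozygous in
#' every simulated individual, the artifact signature the duplication
#' screens look for.
#'
#' @slot genotypes data.frame(individual, chrom, pos, ref, a1, a2).
#' @slot duplications data.frame(id, chrom, start, end, divergence).
#' @slot divergences data.frame(dupId, chrom, pos, ref, alt).
#' @slot contigs named integer vector of contig lengths.
#' @export
setClass("TruthTable",
  representation(
    genotypes = "data.frame",
    duplications = "data.frame",
    divergences = "data.frame",
    contigs = "integer"
  )
)

setValidity("TruthTable", function(object) {
  g <- object@genotypes
  need <- c("individual", "chrom", "pos", "ref", "a1", "a2")
  if (!all(need %in% names(g)))
    return(paste("genotypes must have columns:", paste(need, collapse = ", ")))
  ok <- c("A", "C", "G", "T")
  if (nrow(g) && (!all(g$a1 %in% ok) || !all(g$a2 %in% ok)))
    return("genotype alleles must be A/C/G/T")
  d <- object@divergences
  if (nrow(d)) {
    dup <- object@duplications
    m <- match(d$dupId, dup$id)
    if (anyNA(m)) return("divergence rows must reference a registered duplication")
    if (any(d$pos < dup$start[m] | d$pos > dup$end[m]))
      return("divergent positions must lie inside their source interval")
  }
  TRUE
})

emptyGenotypes <- function() {
  data.frame(individual = character(), chrom = character(), pos = integer(),
             ref = character(), a1 = character(), a2 = character(),
             stringsAsFactors = FALSE)
}

emptyDuplications <- function() {
  data.frame(id = character(), chrom = character(), start = integer(),
             end = integer(), divergence = numeric(), stringsAsFactors = FALSE)
}

emptyDivergences <- function() {
  data.frame(dupId = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), stringsAsFactors = FALSE)
}

#' @param genotypes,duplications,divergences,contigs see slots.
#' @rdname TruthTable-class
#' @export
TruthTable <- function(genotypes = emptyGenotypes(),
                       duplications = emptyDuplications(),
                       divergences = emptyDivergences(),
                       contigs = integer()) {
  rownames(genotypes) <- NULL
  new("TruthTable", genotypes = genotypes, duplications = duplications,
      divergences = divergences, contigs = contigs)
}

#' @rdname TruthTable-class
#' @export
setMethod("genotypes", "TruthTable", function(x) x@genotypes)
#' @rdname TruthTable-class
#' @export
setMethod("duplications", "TruthTable", function(x) x@duplications)
#' @rdname TruthTable-class
#' @export
setMethod("divergentSites", "TruthTable", function(x) x@divergences)

setMethod("show", "TruthTable", function(object) {
  cat(sprintf("TruthTable: %d genotype records, %d individuals, %d duplications (%d divergent sites)\n",
              nrow(object@genotypes),
              length(unique(object@genotypes$individual)),
              nrow(object@duplications), nrow(object@divergences)))
})

#' Pileup of reads on a reference
#'
#' Compact triple store of every qualifying base observation: contig index,
#' 1-based position, base (1..4 for A/C/G/T) and Phred quality. Columns at
#' any quality cutoff are materialised on demand with
#' \code{\link{pileupColumns}}, so one pileup supports stringency sweeps
#' over different Phred thresholds without recomputation.
#'
#' @export
setClass("Pileup",
  representation(
    id = "character",
    contigs = "character",
    contigLengths = "integer",
    chromIdx = "integer",
    pos = "integer",
    base = "integer",
    phred = "integer"
  )
)

setMethod("show", "Pileup", function(object) {
  cat(sprintf("Pileup '%s': %d base observations on %d contig(s) (%.2fX mean depth)\n",
              object@id, length(object@pos), length(object@contigs),
              length(object@pos) / sum(as.numeric(object@contigLengths))))
})

#' @export
setMethod("length", "Pileup", function(x) length(x@pos))

#' Pairwise dataset-by-dataset validation matrix
#'
#' Lower-triangular matrix of validated-SNP counts for all unordered
#' dataset pairs, together with the per-pair sets of validated SNP keys.
#' Pair sets are named "idA|idB".
#'
#' @export
setClass("ValidationMatrix",
  representation(
    ids = "character",
    counts = "matrix",
    pairs = "list"
  )
)

setValidity("ValidationMatrix", function(object) {
  n <- length(object@ids)
  if (!all(dim(object@counts) == c(n, n)))
    return("counts must be a square matrix over the dataset ids")
  lens <- vapply(object@pairs, length, integer(1))
  idx <- which(lower.tri(object@counts), arr.ind = TRUE)
  for (nm in names(object@pairs)) {
    ij <- strsplit(nm, "|", fixed = TRUE)[[1]]
    cnt <- object@counts[ij[2], ij[1]]
    if (!is.na(cnt) && cnt != length(object@pairs[[nm]]))
      return(sprintf("count for pair %s disagrees with its key set", nm))
  }
  TRUE
})

#' @rdname ValidationMatrix-class
#' @export
setMethod("pairCounts", "ValidationMatrix", function(x) x@counts)

#' @param x a ValidationMatrix.
#' @param pair optional "idA|idB" pair name; when omitted all pair sets are
#'   returned as a named list.
#' @rdname ValidationMatrix-class
#' @export
setMethod("validatedKeys", "ValidationMatrix", function(x, pair = NULL) {
  if (is.null(pair)) x@pairs else x@pairs[[pairName(pair[1], pair[2])]]
})

setMethod("show", "ValidationMatrix", function(object) {
  cat(sprintf("ValidationMatrix over %d datasets (%d validated SNP-pair entries)\n",
              length(object@ids), sum(object@counts[lower.tri(object@counts)],
                                      na.rm = TRUE)))
  print(object@counts)
})
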