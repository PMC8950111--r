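#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAString
#' @importClassesFrom S4Vectors DataFrame
NULL

setClassUnion("DNAString_OR_NULL", c("DNAString", "NULL"))

#' GenomeModel: coordinate model of an M13KE-like phage genome
#'
#' Holds the genome length, named features as a [GenomicRanges::GRanges]
#' (1-based inclusive coordinates throughout, matching standard phage genome
#' numbering), the signature positions whose bases distinguish the library
#' vector WT-M13KE from environmental WT-M13, and optionally the nucleotide
#' sequence itself. The sequence is optional so that coordinate-only logic
#' (deletion annotation, coordinate offsets) works without any licensed
#' vendor sequence; the synthetic generator supplies a random sequence with
#' the true coordinates.
#'
#' @slot genomeLength single integer, genome length in nucleotides.
#' @slot features [GenomicRanges::GRanges] of named features.
#' @slot signatures [S4Vectors::DataFrame] with columns `position`
#'   (1-based M13KE coordinate), `m13keBase` (one of A/C/G/T) and `m13Base`
#'   (the wild-type M13 base where known, otherwise `NA`).
#' @slot sequence optional [Biostrings::DNAString] of exactly
#'   `genomeLength` letters over A/C/G/T/N, or `NULL`.
#'
#' @seealso [m13keGenomeModel()], [featureDistance()], [annotateDeletion()]
#' @export
setClass("GenomeModel",
    slots = c(
        genomeLength = "integer",
        features = "GRanges",
        signatures = "DataFrame",
        sequence = "DNAString_OR_NULL"
    )
)

setValidity("GenomeModel", function(object) {
    msg <- character()
    len <- object@genomeLength
    if (length(len) != 1L || is.na(len) || len < 1L)
        msg <- c(msg, "genomeLength must be a single positive integer")
    ft <- object@features
    if (length(ft)) {
        if (is.null(names(ft)) || anyNA(names(ft)) || any(names(ft) == ""))
            msg <- c(msg, "all features must be named")
        if (any(GenomicRanges::start(ft) < 1L) ||
            any(GenomicRanges::end(ft) > len))
            msg <- c(msg, "features must lie within [1, genomeLength]")
    }
    sg <- object@signatures
    if (nrow(sg)) {
        if (!all(c("position", "m13keBase") %in% colnames(sg)))
            msg <- c(msg, "signatures need columns 'position' and 'm13keBase'")
        else {
            if (any(sg$position < 1L) || any(sg$position > len))
                msg <- c(msg, "signature positions must lie in [1, genomeLength]")
            if (!all(sg$m13keBase %in% c("A", "C", "G", "T")))
                msg <- c(msg, "m13keBase must be one of A, C, G, T")
        }
    }
    if (!is.null(object@sequence) && length(object@sequence) != len)
        msg <- c(msg, "sequence length must equal genomeLength")
    if (length(msg)) msg else TRUE
})

#' ReadLayout: positional contract of the displayed-peptide amplicon read
#'
#' Locates the 21-nt displayed-peptide region and the following 12-nt
#' Gly-Gly-Gly-Ser linker within a single-end amplicon read. The linker can
#' be validated at the amino-acid level (any synonymous codons accepted,
#' the default, since the filtering rule is stated on translated output) or
#' against one exact nucleotide sequence (`linkerMode = "nucleotide"`).
#'
#' @slot peptideOffset 0-based offset of the first peptide nucleotide.
#' @slot peptideLenNt peptide length in nucleotides (21 for a 7-mer).
#' @slot linkerLenNt linker length in nucleotides (12).
#' @slot expectedLinkerAa expected linker translation ("GGGS").
#' @slot linkerMode "aa" (synonymous codons accepted) or "nucleotide".
#' @slot linkerNt exact linker nucleotides required in nucleotide mode.
#' @export
setClass("ReadLayout",
    slots = c(
        peptideOffset = "integer",
        peptideLenNt = "integer",
        linkerLenNt = "integer",
        expectedLinkerAa = "character",
        linkerMode = "character",
        linkerNt = "character"
    )
)

setValidity("ReadLayout", function(object) {
    msg <- character()
    if (object@peptideOffset < 0L)
        msg <- c(msg, "peptideOffset must be >= 0")
    if (object@peptideLenNt %% 3L != 0L || object@linkerLenNt %% 3L != 0L)
        msg <- c(msg, "peptide and linker lengths must be codon multiples")
    if (nchar(object@expectedLinkerAa) != object@linkerLenNt / 3L)
        msg <- c(msg, "expectedLinkerAa length must match linkerLenNt/3")
    if (!object@linkerMode %in% c("aa", "nucleotide"))
        msg <- c(msg, "linkerMode must be 'aa' or 'nucleotide'")
    if (object@linkerMode == "nucleotide" &&
        nchar(object@linkerNt) != object@linkerLenNt)
        msg <- c(msg, "linkerNt length must equal linkerLenNt")
    if (length(msg)) msg else TRUE
})

#' FilterReport: read-filtering bookkeeping for one FASTQ sample
#'
#' @slot totalReads,cleanReads,removedReads read counts; clean + removed =
#'   total.
#' @slot removedPercent percent of reads removed, half-up to 1 decimal.
#' @slot removalReasons named integer vector of counts per rejection reason
#'   (`stop_in_peptide`, `invalid_aa_in_peptide`, `bad_linker`, `too_short`).
#' @export
setClass("FilterReport",
    slots = c(
        totalReads = "integer",
        cleanReads = "integer",
        removedReads = "integer",
        removedPercent = "numeric",
        removalReasons = "integer"
    )
)

setValidity("FilterReport", function(object) {
    msg <- character()
    if (object@cleanReads + object@removedReads != object@totalReads)
        msg <- c(msg, "cleanReads + removedReads must equal totalReads")
    if (sum(object@removalReasons) != object@removedReads)
        msg <- c(msg, "removalReasons must sum to removedReads")
    if (length(msg)) msg else TRUE
})

#' FrequencyTable: peptide read counts for one sample
#'
#' Counts of clean (filter-passing) 7-mer peptides for one sample or time
#' point, stored in descending count order with ties broken lexicographically
#' by peptide.
#'
#' @slot sampleId sample label.
#' @slot counts named integer vector, peptide -> clean read count.
#' @slot cleanTotal total clean reads (equals `sum(counts)`).
#' @export
setClass("FrequencyTable",
    slots = c(
        sampleId = "character",
        counts = "integer",
        cleanTotal = "integer"
    )
)

setValidity("FrequencyTable", function(object) {
    msg <- character()
    cnt <- object@counts
    if (length(cnt)) {
        if (is.null(names(cnt)))
            msg <- c(msg, "counts must be named by peptide")
        else {
            aa <- "ACDEFGHIKLMNPQRSTVWY"
            bad <- !grepl(sprintf("^[%s]+$", aa), names(cnt))
            if (any(bad))
                msg <- c(msg, "peptides must use the 20-amino-acid alphabet")
        }
        if (any(cnt < 0L)) msg <- c(msg, "counts must be non-negative")
    }
    if (sum(cnt) != object@cleanTotal)
        msg <- c(msg, "sum(counts) must equal cleanTotal")
    if (length(msg)) msg else TRUE
})

#' CPATimeCourse: focal-clone abundance across competitive propagation
#'
#' Per-time-point percentage of the focal clone (plaque-count or NGS based)
#' in a competitive propagation assay. Times are minutes since inoculation
#' and must be strictly increasing.
#'
#' @slot timeMin numeric, minutes since inoculation.
#' @slot focalPercent numeric in [0, 100], focal-clone percentage.
#' @slot focalPeptide focal peptide label (may be NA for plaque-based data).
#' @export
setClass("CPATimeCourse",
    slots = c(
        timeMin = "numeric",
        focalPercent = "numeric",
        focalPeptide = "character"
    )
)

setValidity("CPATimeCourse", function(object) {
    msg <- character()
    if (length(object@timeMin) != length(object@focalPercent))
        msg <- c(msg, "timeMin and focalPercent must have equal length")
    if (length(object@timeMin) && any(diff(object@timeMin) <= 0))
        msg <- c(msg, "time points must be strictly increasing")
    if (any(object@focalPercent < 0 | object@focalPercent > 100, na.rm = TRUE))
        msg <- c(msg, "focalPercent must lie in [0, 100]")
    if (length(msg)) msg else TRUE
})

#' DeletionCall: a single contiguous deletion between two assembled genomes
#'
#' @slot start 1-based first deleted reference position (left-aligned).
#' @slot end 1-based last deleted reference position.
#' @slot length deletion length in nucleotides (`end - start + 1`).
#' @slot homologyLen length of breakpoint micro-homology (0 when the
#'   placement is unique).
#' @slot leftAligned TRUE; calls are normalized to the smallest start.
#' @export
setClass("DeletionCall",
    slots = c(
        start = "integer",
        end = "integer",
        length = "integer",
        homologyLen = "integer",
        leftAligned = "logical"
    )
)

setValidity("DeletionCall", function(object) {
    msg <- character()
    if (object@length != object@end - object@start + 1L)
        msg <- c(msg, "length must equal end - start + 1")
    if (object@length < 1L) msg <- c(msg, "length must be >= 1")
    if (length(msg)) msg else TRUE
})

#' DeletionAnnotation: a deletion call placed on a genome model
#'
#' @slot call the [DeletionCall-class].
#' @slot affectedFeatures data.frame with columns `feature`, `relation`
#'   (`upstream_of`, `downstream_of`, `overlaps`, `contains`,
#'   `contained_in`) and `distance` (nucleotides strictly between call and
#'   feature; 0 when they touch).
#' @slot genomeFractionPercent percent of the genome removed, half-up to
#'   1 decimal.
#' @export
setClass("DeletionAnnotation",
    slots = c(
        call = "DeletionCall",
        affectedFeatures = "data.frame",
        genomeFractionPercent = "numeric"
    )
)

#' ProvenanceCall: library vs environmental origin of a plaque sequence
#'
#' Verdicts follow the signature-nucleotide rule: `library` when every
#' covered signature position carries the M13KE base and at least three
#' positions are covered; `non_library` when two or more covered positions
#' mismatch; `ambiguous` otherwise (including no coverage).
#'
#' @slot verdict one of `library`, `non_library`, `ambiguous`.
#' @slot matches number of covered signature positions matching M13KE.
#' @slot covered number of signature positions covered by the query.
#' @slot perPosition named character vector, observed base per covered
#'   signature position.
#' @export
setClass("ProvenanceCall",
    slots = c(
        verdict = "character",
        matches = "integer",
        covered = "integer",
        perPosition = "character"
    )
)

setValidity("ProvenanceCall", function(object) {
    msg <- character()
    if (!object@verdict %in% c("library", "non_library", "ambiguous"))
        msg <- c(msg, "verdict must be library, non_library or ambiguous")
    if (object@matches > object@covered)
        msg <- c(msg, "matches cannot exceed covered")
    if (length(msg)) msg else TRUE
})

#' QPCRStandard: fitted qPCR standard curve
#'
#' Ordinary least-squares line of Ct on log10 genome copies; inverted by
#' [ctToCopies()] for absolute quantification.
#'
#' @slot points data.frame with columns `log10_copies` and `ct`.
#' @slot slope,intercept fitted line coefficients (slope < 0 for valid
#'   amplification).
#' @export
setClass("QPCRStandard",
    slots = c(
        points = "data.frame",
        slope = "numeric",
        intercept = "numeric"
    )
)
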