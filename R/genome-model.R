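#' Construct a GenomeModel
#'
#' @param genomeLength genome length in nucleotides.
#' @param features [GenomicRanges::GRanges] of named features (1-based
#'   inclusive), or a data.frame with columns `name`, `start`, `end`,
#'   `strand`.
#' @param signatures data.frame/DataFrame with columns `position`,
#'   `m13keBase` and optionally `m13Base`.
#' @param sequence optional [Biostrings::DNAString] (or character scalar)
#'   of exactly `genomeLength` letters.
#' @return a [GenomeModel-class] object.
#' @export
#' @examples
#' gm <- GenomeModel(100,
#'     features = data.frame(name = "f", start = 10, end = 20, strand = "+"))
GenomeModel <- function(genomeLength, features = NULL, signatures = NULL,
                        sequence = NULL) {
    if (is.data.frame(features)) {
        gr <- GenomicRanges::GRanges(
            seqnames = "genome",
            ranges = IRanges::IRanges(as.integer(features$start),
                                      as.integer(features$end)),
            strand = if ("strand" %in% names(features)) features$strand
                     else "+"
        )
        names(gr) <- features$name
        features <- gr
    } else if (is.null(features)) {
        features <- GenomicRanges::GRanges()
    }
    if (is.null(signatures)) {
        signatures <- DataFrame(position = integer(),
                                m13keBase = character(),
                                m13Base = character())
    } else {
        signatures <- DataFrame(as.data.frame(signatures))
        if (!"m13Base" %in% colnames(signatures))
            signatures$m13Base <- NA_character_
        signatures$position <- as.integer(signatures$position)
    }
    if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
    new("GenomeModel",
        genomeLength = as.integer(genomeLength),
        features = features,
        signatures = signatures,
        sequence = sequence)
}

#' M13KE genome model fixture
#'
#' A coordinate model of the 7222-nt M13KE cloning vector used by the
#' Ph.D.-7 library, carrying the features relevant to white-plaque
#' characterization: the origin of replication (`Ori`, 5487-5867), the
#' lacZ-alpha gene whose loss turns plaques white (`lacZalpha`, 6216-6695),
#' the intergenic region between them, and gII modeled from its documented
#' spacing downstream of the recurrent deletion (start 6821, extended to the
#' genome end). The five signature positions distinguishing WT-M13KE from
#' environmental WT-M13 are 1610:G, 1613:A, 1631:G, 1634:C, 1662:T; the
#' WT-M13 bases at those positions are left `NA` (not established at base
#' level here).
#'
#' @param sequence optional genome sequence ([Biostrings::DNAString] or
#'   character) of exactly 7222 nt.
#' @return a [GenomeModel-class].
#' @export
#' @examples
#' gm <- m13keGenomeModel()
#' genomeFeatures(gm)
m13keGenomeModel <- function(sequence = NULL) {
    GenomeModel(
        genomeLength = 7222L,
        features = data.frame(
            name = c("Ori", "intergenic_Ori_lacZalpha", "lacZalpha", "gII"),
            start = c(5487L, 5868L, 6216L, 6821L),
            end = c(5867L, 6215L, 6695L, 7222L),
            strand = "+"
        ),
        signatures = data.frame(
            position = c(1610L, 1613L, 1631L, 1634L, 1662L),
            m13keBase = c("G", "A", "G", "C", "T"),
            m13Base = NA_character_
        ),
        sequence = sequence
    )
}

#' Accessors for GenomeModel
#'
#' @param x a [GenomeModel-class].
#' @return `genomeLength`: integer length; `genomeFeatures`: a
#'   [GenomicRanges::GRanges]; `signaturePositions`: a
#'   [S4Vectors::DataFrame]; `genomeSequence`: a [Biostrings::DNAString]
#'   or `NULL`.
#' @name GenomeModel-accessors
NULL

#' @rdname GenomeModel-accessors
#' @export
genomeLength <- function(x) x@genomeLength

#' @rdname GenomeModel-accessors
#' @export
genomeFeatures <- function(x) x@features

#' @rdname GenomeModel-accessors
#' @export
signaturePositions <- function(x) x@signatures

#' @rdname GenomeModel-accessors
#' @export
genomeSequence <- function(x) x@sequence

#' Map a WT-M13 coordinate onto WT-M13KE
#'
#' The M13KE vector lacks the T that wild-type M13 carries at position 1565,
#' so downstream coordinates shift by one: positions up to 1564 map to
#' themselves, position 1565 has no M13KE image (returns `NA`), and
#' positions from 1566 map to `pos - 1`.
#'
#' @param pos integer vector of 1-based WT-M13 positions (all >= 1).
#' @return integer vector of 1-based M13KE positions, `NA` where the M13
#'   base was deleted.
#' @export
#' @examples
#' m13ToM13keCoord(c(1000, 1565, 1611))  # 1000, NA, 1610
m13ToM13keCoord <- function(pos) {
    if (!is.numeric(pos) || anyNA(pos) || any(pos < 1))
        stopDomain("positions must be integers >= 1")
    pos <- as.integer(pos)
    out <- ifelse(pos <= 1564L, pos,
           ifelse(pos == 1565L, NA_integer_, pos - 1L))
    as.integer(out)
}

#' Signed gap and relation between an interval and a genome feature
#'
#' Computes the number of nucleotides strictly between a 1-based inclusive
#' interval (for example a deletion call) and a feature, plus a relation
#' tag describing the interval's position relative to the feature on the
#' forward strand: `upstream_of` / `downstream_of` when disjoint,
#' `contains` when the interval covers the whole feature and extends beyond
#' it, `contained_in` when the feature strictly covers the interval, and
#' `overlaps` for any other intersection (including identical intervals).
#' The gap is computed with [IRanges::distance()] and is 0 whenever the two
#' touch or overlap.
#'
#' @param interval length-2 numeric `c(start, end)`, 1-based inclusive.
#' @param featureStart,featureEnd feature interval, 1-based inclusive.
#' @return list with elements `distance` (integer >= 0) and `relation`.
#' @export
#' @examples
#' featureDistance(c(5879, 6705), 5487, 5867)  # 11 nt downstream of Ori
#' featureDistance(c(5879, 6705), 6216, 6695)  # contains lacZalpha
featureDistance <- function(interval, featureStart, featureEnd) {
    if (length(interval) != 2L || anyNA(interval) ||
        interval[1] > interval[2] || interval[1] < 1)
        stopDomain("interval must be c(start, end) with 1 <= start <= end")
    if (featureStart > featureEnd || featureStart < 1)
        stopDomain("malformed feature interval")
    qi <- IRanges::IRanges(as.integer(interval[1]), as.integer(interval[2]))
    fi <- IRanges::IRanges(as.integer(featureStart), as.integer(featureEnd))
    gap <- as.integer(IRanges::distance(qi, fi))
    s <- interval[1]; e <- interval[2]
    if (e < featureStart) {
        rel <- "upstream_of"
    } else if (s > featureEnd) {
        rel <- "downstream_of"
    } else if (s <= featureStart && e >= featureEnd &&
               (s < featureStart || e > featureEnd)) {
        rel <- "contains"
    } else if (s > featureStart && e < featureEnd) {
        rel <- "contained_in"
    } else {
        rel <- "overlaps"
    }
    list(distance = gap, relation = rel)
}

#' Read / write genome-model configuration
#'
#' Genome models round-trip through a small declarative YAML config
#' (genome length, feature table, signature positions) plus an optional
#' single-record FASTA carrying the sequence.
#'
#' @param path config file path (YAML).
#' @param fasta optional FASTA path for the genome sequence.
#' @param x a [GenomeModel-class] to write.
#' @return `readGenomeModel` returns a [GenomeModel-class];
#'   `writeGenomeModel` returns `path` invisibly.
#' @export
readGenomeModel <- function(path, fasta = NULL) {
    cfg <- yaml::read_yaml(path)
    feats <- if (length(cfg$features)) {
        do.call(rbind, lapply(cfg$features, function(f)
            data.frame(name = f$name, start = f$start, end = f$end,
                       strand = if (is.null(f$strand)) "+" else f$strand)))
    } else NULL
    sigs <- if (length(cfg$signatures)) {
        do.call(rbind, lapply(cfg$signatures, function(s)
            data.frame(position = s$position, m13keBase = s$m13keBase,
                       m13Base = if (is.null(s$m13Base)) NA_character_
                                 else s$m13Base)))
    } else NULL
    seq <- NULL
    if (!is.null(fasta)) {
        ss <- Biostrings::readDNAStringSet(fasta)
        if (length(ss) != 1L)
            stopDomain("genome FASTA must contain exactly one record")
        seq <- ss[[1L]]
    }
    GenomeModel(cfg$genome_length, features = feats, signatures = sigs,
                sequence = seq)
}

#' @rdname readGenomeModel
#' @export
writeGenomeModel <- function(x, path, fasta = NULL) {
    ft <- genomeFeatures(x)
    cfg <- list(
        genome_length = genomeLength(x),
        features = lapply(seq_along(ft), function(i) list(
            name = names(ft)[i],
            start = GenomicRanges::start(ft)[i],
            end = GenomicRanges::end(ft)[i],
            strand = as.character(GenomicRanges::strand(ft))[i]
        )),
        signatures = lapply(seq_len(nrow(x@signatures)), function(i) list(
            position = x@signatures$position[i],
            m13keBase = x@signatures$m13keBase[i]
        ))
    )
    yaml::write_yaml(cfg, path)
    if (!is.null(fasta) && !is.null(genomeSequence(x))) {
        ss <- Biostrings::DNAStringSet(genomeSequence(x))
        names(ss) <- "genome"
        Biostrings::writeXStringSet(ss, fasta)
    }
    invisible(path)
}

setMethod("show", "GenomeModel", function(object) {
    cat(sprintf("GenomeModel of %d nt, %d feature(s), %d signature position(s)%s\n",
        genomeLength(object), length(object@features),
        nrow(object@signatures),
        if (is.null(object@sequence)) " (coordinates only)"
        else " (with sequence)"))
    if (length(object@features)) {
        ft <- object@features
        for (i in seq_along(ft))
            cat(sprintf("  %-26s %5d-%5d (%s)\n", names(ft)[i],
                GenomicRanges::start(ft)[i], GenomicRanges::end(ft)[i],
                as.character(GenomicRanges::strand(ft))[i]))
    }
})
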