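#' Call a single contiguous deletion from a reference/mutant genome pair
#'
#' Compares two assembled sequences by their longest common prefix P and
#' longest common suffix S. A single contiguous deletion of the reference
#' exists iff `P + S >= length(mutant)`; the call is then left-aligned
#' (VCF-style: the smallest valid start), with breakpoint micro-homology of
#' length `P + S - length(mutant)` when positive. The call is verified by
#' reconstruction: excising `[start, end]` from the reference must
#' reproduce the mutant exactly.
#'
#' @param reference,mutant nucleotide strings (character or
#'   [Biostrings::DNAString]) over A/C/G/T with
#'   `nchar(mutant) < nchar(reference)`.
#' @return a [DeletionCall-class].
#' @export
#' @examples
#' callSingleDeletion("AAATTTCCC", "AAACCC")   # start 4, end 6, length 3
#' callSingleDeletion("AAAAA", "AAA")          # start 1, end 2, homology 3
callSingleDeletion <- function(reference, mutant) {
    if (is(reference, "DNAString")) reference <- as.character(reference)
    if (is(mutant, "DNAString")) mutant <- as.character(mutant)
    if (grepl("[^ACGT]", reference) || grepl("[^ACGT]", mutant))
        stopDomain("sequences must be over A, C, G, T")
    nr <- nchar(reference)
    nm <- nchar(mutant)
    if (nm == nr)
        stopDomain("sequences have equal length; no indel to call",
                   class = "no_indel")
    if (nm > nr)
        stopDomain("mutant is longer than reference; not a deletion")

    r <- charToRaw(reference)
    m <- charToRaw(mutant)
    neq <- which(r[seq_len(nm)] != m)
    P <- if (length(neq)) neq[1L] - 1L else nm
    neqS <- which(rev(r)[seq_len(nm)] != rev(m))
    S <- if (length(neqS)) neqS[1L] - 1L else nm
    if (P + S < nm)
        stopDomain("sequences differ by more than one contiguous deletion",
                   class = "complex_variant")

    start <- min(P, nm - S) + 1L
    len <- nr - nm
    end <- start + len - 1L
    reconstructed <- paste0(substr(reference, 1L, start - 1L),
                            substr(reference, end + 1L, nr))
    if (reconstructed != mutant)
        stopDomain("excision does not reproduce the mutant",
                   class = "complex_variant")
    new("DeletionCall",
        start = as.integer(start),
        end = as.integer(end),
        length = as.integer(len),
        homologyLen = as.integer(max(0L, P + S - nm)),
        leftAligned = TRUE)
}

#' Accessors for DeletionCall
#'
#' @param x a [DeletionCall-class].
#' @return integers: first / last deleted reference position (1-based),
#'   deletion length, breakpoint micro-homology length.
#' @name DeletionCall-accessors
NULL

#' @rdname DeletionCall-accessors
#' @export
deletionStart <- function(x) x@start

#' @rdname DeletionCall-accessors
#' @export
deletionEnd <- function(x) x@end

#' @rdname DeletionCall-accessors
#' @export
deletionLength <- function(x) x@length

#' @rdname DeletionCall-accessors
#' @export
homologyLength <- function(x) x@homologyLen

#' Annotate a deletion call against a genome model
#'
#' Reports, for every feature of the model, the relation of the deleted
#' interval to the feature ([featureDistance()]) and the percent of the
#' genome removed.
#'
#' @param call a [DeletionCall-class] lying within the genome.
#' @param genome a [GenomeModel-class].
#' @return a [DeletionAnnotation-class].
#' @export
#' @examples
#' gm <- m13keGenomeModel()
#' call <- new("DeletionCall", start = 5879L, end = 6705L, length = 827L,
#'     homologyLen = 0L, leftAligned = TRUE)
#' annotateDeletion(call, gm)
annotateDeletion <- function(call, genome) {
    if (deletionStart(call) < 1L || deletionEnd(call) > genomeLength(genome))
        stopDomain("deletion call lies outside the genome")
    ft <- genomeFeatures(genome)
    rows <- lapply(seq_along(ft), function(i) {
        fd <- featureDistance(c(deletionStart(call), deletionEnd(call)),
                              GenomicRanges::start(ft)[i],
                              GenomicRanges::end(ft)[i])
        data.frame(feature = names(ft)[i], relation = fd$relation,
                   distance = fd$distance)
    })
    aff <- if (length(rows)) do.call(rbind, rows)
           else data.frame(feature = character(), relation = character(),
                           distance = integer())
    frac <- roundHalfUp(100 * deletionLength(call) / genomeLength(genome), 1)
    new("DeletionAnnotation", call = call, affectedFeatures = aff,
        genomeFractionPercent = frac)
}

#' Accessors for DeletionAnnotation
#'
#' @param x a [DeletionAnnotation-class].
#' @return `affectedFeatures`: data.frame of feature relations;
#'   `genomeFraction`: numeric percent of the genome removed.
#' @name DeletionAnnotation-accessors
NULL

#' @rdname DeletionAnnotation-accessors
#' @export
affectedFeatures <- function(x) x@affectedFeatures

#' @rdname DeletionAnnotation-accessors
#' @export
genomeFraction <- function(x) x@genomeFractionPercent

#' Write a deletion call as TSV and minimal VCF
#'
#' The VCF record follows the 1-based anchor-base convention: POS is the
#' base before the deletion, REF is anchor + deleted bases, ALT is the
#' anchor alone. A deletion starting at reference position 1 has no left
#' anchor and uses the base after the deletion instead (POS 1).
#'
#' @param call a [DeletionCall-class].
#' @param reference the reference sequence the call was made on.
#' @param path output path (TSV) or VCF path.
#' @param contig contig name used in the VCF.
#' @return the path, invisibly.
#' @export
writeDeletionTsv <- function(call, path) {
    df <- data.frame(start = deletionStart(call), end = deletionEnd(call),
                     length = deletionLength(call),
                     homology_len = homologyLength(call))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeDeletionTsv
#' @export
writeDeletionVcf <- function(call, reference, path, contig = "genome") {
    if (is(reference, "DNAString")) reference <- as.character(reference)
    s <- deletionStart(call); e <- deletionEnd(call)
    if (s > 1L) {
        pos <- s - 1L
        ref <- substr(reference, s - 1L, e)
        alt <- substr(reference, s - 1L, s - 1L)
    } else {
        pos <- 1L
        ref <- substr(reference, 1L, e + 1L)
        alt <- substr(reference, e + 1L, e + 1L)
    }
    lines <- c(
        "##fileformat=VCFv4.2",
        sprintf("##contig=<ID=%s,length=%d>", contig, nchar(reference)),
        "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Variant type\">",
        "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Deletion length\">",
        "##INFO=<ID=HOMLEN,Number=1,Type=Integer,Description=\"Breakpoint micro-homology length\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
        sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tSVTYPE=DEL;SVLEN=-%d;HOMLEN=%d",
                contig, pos, ref, alt, deletionLength(call),
                homologyLength(call))
    )
    writeLines(lines, path)
    invisible(path)
}

setMethod("show", "DeletionCall", function(object) {
    cat(sprintf(
        "DeletionCall: %d-%d (%d nt), micro-homology %d nt, left-aligned\n",
        object@start, object@end, object@length, object@homologyLen))
})

setMethod("show", "DeletionAnnotation", function(object) {
    show(object@call)
    cat(sprintf("  removes %.1f%% of the genome\n",
        object@genomeFractionPercent))
    af <- object@affectedFeatures
    for (i in seq_len(nrow(af)))
        cat(sprintf("  %-26s %-13s %d nt\n", af$feature[i], af$relation[i],
            af$distance[i]))
})
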