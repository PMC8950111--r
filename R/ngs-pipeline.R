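#' Construct a ReadLayout
#'
#' @param peptideOffset 0-based offset of the first peptide nucleotide in
#'   the read. The default (12) matches the synthetic amplicon produced by
#'   [generateFastq()]; real runs set it from their amplicon design.
#' @param peptideLenNt peptide length in nucleotides (default 21, a 7-mer).
#' @param linkerLenNt linker length in nucleotides (default 12).
#' @param expectedLinkerAa expected linker translation (default "GGGS").
#' @param linkerMode `"aa"` accepts any synonymous linker codons (the
#'   filtering rule is stated on translated output); `"nucleotide"`
#'   requires the exact nucleotides in `linkerNt`.
#' @param linkerNt exact linker nucleotide sequence for nucleotide mode.
#' @return a [ReadLayout-class].
#' @export
#' @examples
#' ReadLayout()
ReadLayout <- function(peptideOffset = 12L, peptideLenNt = 21L,
                       linkerLenNt = 12L, expectedLinkerAa = "GGGS",
                       linkerMode = c("aa", "nucleotide"),
                       linkerNt = "GGTGGAGGTTCG") {
    new("ReadLayout",
        peptideOffset = as.integer(peptideOffset),
        peptideLenNt = as.integer(peptideLenNt),
        linkerLenNt = as.integer(linkerLenNt),
        expectedLinkerAa = expectedLinkerAa,
        linkerMode = match.arg(linkerMode),
        linkerNt = linkerNt)
}

#' Translate nucleotides codon-by-codon
#'
#' Standard genetic code; stop codons become `*` and any codon containing
#' an ambiguous base (N) becomes `X`, a marker distinct from the 20 amino
#' acids. Vectorized over input sequences.
#'
#' @param nt character vector or [Biostrings::DNAStringSet]; every element's
#'   length must be divisible by 3.
#' @return character vector of amino-acid strings.
#' @export
#' @examples
#' translateCodons("TGGTCTCTGGGTTATACTGGT")  # "WSLGYTG"
#' translateCodons("TAGGGTGGTGGTGGTGGTGGT")  # "*GGGGGG"
translateCodons <- function(nt) {
    if (is.character(nt)) nt <- Biostrings::DNAStringSet(nt)
    if (any(Biostrings::width(nt) %% 3L != 0L))
        stopDomain("sequence length must be divisible by 3")
    aa <- Biostrings::translate(nt, if.fuzzy.codon = "X",
                                no.init.codon = TRUE)
    as.character(aa)
}

#' Filter many reads at once
#'
#' Vectorized form of [processRead()]: classifies each read as clean
#' (returning its peptide) or rejected with the first failing reason, in
#' the order `too_short`, `stop_in_peptide`, `invalid_aa_in_peptide`,
#' `bad_linker`.
#'
#' @param seqs character vector or [Biostrings::DNAStringSet] of reads.
#' @param layout a [ReadLayout-class].
#' @return list with character vectors `peptide` and `reason`, parallel to
#'   `seqs` (`reason` is `NA` for clean reads).
#' @export
processReads <- function(seqs, layout = ReadLayout()) {
    stopifnot(is(layout, "ReadLayout"))
    if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
    n <- length(seqs)
    off <- layout@peptideOffset
    need <- off + layout@peptideLenNt + layout@linkerLenNt
    reason <- rep(NA_character_, n)
    peptide <- rep(NA_character_, n)

    tooShort <- Biostrings::width(seqs) < need
    reason[tooShort] <- "too_short"

    idx <- which(!tooShort)
    if (length(idx)) {
        sub <- seqs[idx]
        pepNt <- Biostrings::subseq(sub, start = off + 1L,
                                    width = layout@peptideLenNt)
        linkNt <- Biostrings::subseq(sub,
                                     start = off + layout@peptideLenNt + 1L,
                                     width = layout@linkerLenNt)
        pepAa <- translateCodons(pepNt)
        hasStop <- grepl("*", pepAa, fixed = TRUE)
        hasInvalid <- !hasStop & grepl("X", pepAa, fixed = TRUE)
        linkBad <- if (layout@linkerMode == "aa") {
            translateCodons(linkNt) != layout@expectedLinkerAa
        } else {
            as.character(linkNt) != layout@linkerNt
        }
        r <- rep(NA_character_, length(idx))
        r[linkBad] <- "bad_linker"
        r[hasInvalid] <- "invalid_aa_in_peptide"
        r[hasStop] <- "stop_in_peptide"
        reason[idx] <- r
        ok <- is.na(r)
        peptide[idx[ok]] <- pepAa[ok]
    }
    list(peptide = peptide, reason = reason)
}

#' Filter one read and extract its displayed peptide
#'
#' Applies the clean-read rule: the 21-nt peptide region must translate to
#' seven canonical amino acids (no stop, no ambiguity) and the following
#' 12-nt linker must translate exactly to GGGS. Checks run in the order
#' `too_short`, `stop_in_peptide`, `invalid_aa_in_peptide`, `bad_linker`
#' and the first failure is reported.
#'
#' @param read a single read (character or [Biostrings::DNAString]).
#' @param layout a [ReadLayout-class].
#' @return list with `peptide` (7-mer or `NA`) and `reason` (`NA` for a
#'   clean read).
#' @export
#' @examples
#' processRead(paste0(strrep("A", 12),
#'     "TGGTCTCTGGGTTATACTGGT", "GGTGGAGGTTCG"), ReadLayout())
processRead <- function(read, layout = ReadLayout()) {
    if (is(read, "DNAString")) read <- as.character(read)
    res <- processReads(read, layout)
    list(peptide = res$peptide[1L], reason = res$reason[1L])
}

#' Build a peptide frequency table and filter report from FASTQ reads
#'
#' Streams the reads through the clean-read filter and tallies clean
#' peptides. The table iterates in descending count order with ties broken
#' lexicographically by peptide. Quality scores are parsed but unused: the
#' filter acts only on translation validity.
#'
#' @param reads a FASTQ file path (plain or gzip), a
#'   [Biostrings::DNAStringSet], or a character vector of read sequences.
#' @param layout a [ReadLayout-class].
#' @param sampleId label stored on the [FrequencyTable-class].
#' @return list with elements `table` ([FrequencyTable-class]) and
#'   `report` ([FilterReport-class]).
#' @export
buildFrequencyTable <- function(reads, layout = ReadLayout(),
                                sampleId = "sample") {
    if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
        reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
    }
    if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
    if (length(reads) == 0L)
        stopDomain("empty read stream", class = "empty_input")

    cls <- processReads(reads, layout)
    clean <- is.na(cls$reason)
    reasons <- table(factor(cls$reason[!clean],
        levels = c("stop_in_peptide", "invalid_aa_in_peptide",
                   "bad_linker", "too_short")))
    reasons <- structure(as.integer(reasons), names = names(reasons))
    reasons <- reasons[reasons > 0L]

    cnt <- table(cls$peptide[clean])
    cnt <- structure(as.integer(cnt), names = names(cnt))
    if (length(cnt))
        cnt <- cnt[order(-cnt, names(cnt), method = "radix")]

    total <- length(reads)
    nClean <- sum(clean)
    report <- new("FilterReport",
        totalReads = total,
        cleanReads = as.integer(nClean),
        removedReads = as.integer(total - nClean),
        removedPercent = roundHalfUp(100 * (total - nClean) / total, 1),
        removalReasons = if (length(reasons)) reasons
                         else structure(integer(), names = character()))
    tab <- new("FrequencyTable",
        sampleId = sampleId,
        counts = cnt,
        cleanTotal = as.integer(nClean))
    list(table = tab, report = report)
}

#' Accessors for FrequencyTable and FilterReport
#'
#' @param x a [FrequencyTable-class] or [FilterReport-class].
#' @return `peptideCounts`: named integer vector in descending count order;
#'   `cleanTotal`: integer; `removedPercent`: numeric; `removalReasons`:
#'   named integer vector.
#' @name frequency-accessors
NULL

#' @rdname frequency-accessors
#' @export
peptideCounts <- function(x) x@counts

#' @rdname frequency-accessors
#' @export
cleanTotal <- function(x) x@cleanTotal

#' @rdname frequency-accessors
#' @export
removedPercent <- function(x) x@removedPercent

#' @rdname frequency-accessors
#' @export
removalReasons <- function(x) x@removalReasons

#' Relative abundance of a peptide among clean reads
#'
#' @param table a [FrequencyTable-class] with `cleanTotal > 0`.
#' @param peptide 7-mer peptide to query (absent peptides count 0).
#' @return percent of clean reads, half-up to 1 decimal.
#' @export
#' @examples
#' tab <- new("FrequencyTable", sampleId = "s",
#'     counts = c(WSLGYTG = 541L, AAAAAAA = 459L), cleanTotal = 1000L)
#' relativeAbundance(tab, "WSLGYTG")  # 54.1
relativeAbundance <- function(table, peptide) {
    if (cleanTotal(table) == 0L)
        stopDomain("clean_total is zero; relative abundance undefined")
    cnt <- peptideCounts(table)[peptide]
    cnt <- ifelse(is.na(cnt), 0L, cnt)
    unname(roundHalfUp(100 * cnt / cleanTotal(table), 1))
}

#' Write / read frequency tables and filter reports as TSV
#'
#' @param x object to write.
#' @param path TSV path.
#' @return the path, invisibly (writers); a data.frame (readers).
#' @export
writeFrequencyTable <- function(x, path) {
    df <- data.frame(peptide = names(peptideCounts(x)),
                     count = unname(peptideCounts(x)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeFrequencyTable
#' @param sampleId sample label for the rebuilt table.
#' @export
readFrequencyTable <- function(path, sampleId = "sample") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    cnt <- structure(as.integer(df$count), names = df$peptide)
    cnt <- cnt[order(-cnt, names(cnt), method = "radix")]
    new("FrequencyTable", sampleId = sampleId, counts = cnt,
        cleanTotal = as.integer(sum(cnt)))
}

#' @rdname writeFrequencyTable
#' @export
writeFilterReport <- function(x, path) {
    rs <- removalReasons(x)
    df <- data.frame(
        metric = c("total_reads", "clean_reads", "removed_reads",
                   "removed_percent", names(rs)),
        value = c(x@totalReads, x@cleanReads, x@removedReads,
                  x@removedPercent, unname(rs)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

setMethod("show", "FilterReport", function(object) {
    cat(sprintf(
        "FilterReport: %d reads, %d clean, %d removed (%.1f%%)\n",
        object@totalReads, object@cleanReads, object@removedReads,
        object@removedPercent))
    rs <- object@removalReasons
    for (nm in names(rs)) cat(sprintf("  %-22s %d\n", nm, rs[[nm]]))
})

setMethod("show", "FrequencyTable", function(object) {
    cat(sprintf("FrequencyTable '%s': %d distinct peptide(s), %d clean reads\n",
        object@sampleId, length(object@counts), object@cleanTotal))
    head <- utils::head(object@counts, 5L)
    for (i in seq_along(head))
        cat(sprintf("  %s %8d (%.1f%%)\n", names(head)[i], head[[i]],
            100 * head[[i]] / max(1L, object@cleanTotal)))
    if (length(object@counts) > 5L) cat("  ...\n")
})
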