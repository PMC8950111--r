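#' Classify a plaque sequence as library-derived or environmental
#'
#' WT-M13KE (the Ph.D. library vector) differs from environmental WT-M13 at
#' a set of signature nucleotides; observing the M13KE bases in a sequenced
#' white plaque shows the plaque derives from the library rather than from
#' contamination. The verdict is `library` when every covered signature
#' position carries the M13KE base and at least 3 positions are covered;
#' `non_library` when 2 or more covered positions mismatch; `ambiguous`
#' otherwise (including zero coverage). These thresholds tolerate a single
#' Sanger miscall without flipping the verdict.
#'
#' @param query nucleotide string over A/C/G/T/N (character or
#'   [Biostrings::DNAString]); for `strand = "-"` the query is the reverse
#'   complement of the plus-strand region starting at `queryStart`.
#' @param queryStart 1-based M13KE coordinate of the query's first
#'   plus-strand base.
#' @param signatures [S4Vectors::DataFrame]/data.frame with columns
#'   `position` and `m13keBase`, e.g. from [signaturePositions()].
#' @param strand `"+"` (default) or `"-"`.
#' @return a [ProvenanceCall-class].
#' @export
#' @examples
#' gm <- m13keGenomeModel()
#' q <- strrep("A", 551)   # span 1130..1680
#' sig <- signaturePositions(gm)
#' for (i in seq_len(nrow(sig)))
#'     substr(q, sig$position[i] - 1129, sig$position[i] - 1129) <-
#'         sig$m13keBase[i]
#' classifyOrigin(q, 1130, sig)
classifyOrigin <- function(query, queryStart, signatures, strand = "+") {
    if (is(query, "DNAString")) query <- as.character(query)
    if (!is.character(query) || length(query) != 1L || nchar(query) == 0L)
        stopDomain("query must be a single non-empty nucleotide string")
    if (grepl("[^ACGTN]", query))
        stopDomain("query must be over A, C, G, T, N")
    if (queryStart < 1) stopDomain("queryStart must be >= 1")
    if (!strand %in% c("+", "-")) stopDomain("strand must be '+' or '-'")
    if (strand == "-")
        query <- as.character(
            Biostrings::reverseComplement(Biostrings::DNAString(query)))
    signatures <- as.data.frame(signatures)
    qEnd <- queryStart + nchar(query) - 1L
    cov <- signatures$position >= queryStart & signatures$position <= qEnd
    pos <- signatures$position[cov]
    expected <- signatures$m13keBase[cov]
    observed <- if (length(pos))
        substring(query, pos - queryStart + 1L, pos - queryStart + 1L)
    else character(0)
    match <- observed == expected
    nCov <- length(pos)
    nMatch <- sum(match)
    verdict <- if (nCov >= 3L && nMatch == nCov) "library"
               else if (nCov - nMatch >= 2L) "non_library"
               else "ambiguous"
    new("ProvenanceCall",
        verdict = verdict,
        matches = as.integer(nMatch),
        covered = as.integer(nCov),
        perPosition = structure(observed, names = as.character(pos)))
}

#' Extract the displayed peptide from a Sanger read
#'
#' Finds the unique exact occurrence of an upstream anchor sequence
#' (searching both strands), translates the following 21 nucleotides as the
#' displayed 7-mer and the next 12 as the linker, and returns the peptide
#' only when the linker translates to GGGS.
#'
#' @param read nucleotide string (character or [Biostrings::DNAString]).
#' @param upstreamAnchor anchor sequence immediately 5' of the peptide
#'   cassette; at least 12 nt.
#' @param linkerAa expected linker translation (default "GGGS").
#' @return list with `found` (logical), `peptide` (7-mer or `NA`) and
#'   `reason` (`NA`, `anchor_absent`, `anchor_ambiguous`, `truncated` or
#'   `bad_linker`).
#' @export
extractSangerPeptide <- function(read, upstreamAnchor, linkerAa = "GGGS") {
    if (nchar(upstreamAnchor) < 12L)
        stopDomain("anchor must be at least 12 nt")
    if (is.character(read)) read <- Biostrings::DNAString(read)
    notFound <- function(reason)
        list(found = FALSE, peptide = NA_character_, reason = reason)

    anchor <- Biostrings::DNAString(upstreamAnchor)
    fwd <- Biostrings::matchPattern(anchor, read)
    rev <- Biostrings::matchPattern(anchor,
        Biostrings::reverseComplement(read))
    nHits <- length(fwd) + length(rev)
    if (nHits == 0L) return(notFound("anchor_absent"))
    if (nHits > 1L) return(notFound("anchor_ambiguous"))

    strandRead <- if (length(fwd)) read
                  else Biostrings::reverseComplement(read)
    hit <- if (length(fwd)) fwd else rev
    from <- IRanges::end(hit)[1L] + 1L
    if (from + 32L > length(strandRead))
        return(notFound("truncated"))
    pepNt <- Biostrings::subseq(strandRead, from, from + 20L)
    linkNt <- Biostrings::subseq(strandRead, from + 21L, from + 32L)
    if (translateCodons(as.character(linkNt)) != linkerAa)
        return(notFound("bad_linker"))
    pep <- translateCodons(as.character(pepNt))
    list(found = TRUE, peptide = pep, reason = NA_character_)
}

setMethod("show", "ProvenanceCall", function(object) {
    cat(sprintf("ProvenanceCall: %s (%d/%d signature positions match)\n",
        object@verdict, object@matches, object@covered))
    if (length(object@perPosition))
        cat("  observed:",
            paste(sprintf("%s:%s", names(object@perPosition),
                object@perPosition), collapse = " "), "\n")
})
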