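# Independent brute-force oracle for single-deletion calling: enumerate
# every start whose excision of (nchar(ref) - nchar(mut)) bases reproduces
# the mutant; report the leftmost and the number of valid placements.
bruteForceDeletion <- function(ref, mut) {
    d <- nchar(ref) - nchar(mut)
    stopifnot(d > 0)
    starts <- integer()
    for (s in seq_len(nchar(mut) + 1L)) {
        ex <- paste0(substr(ref, 1L, s - 1L), substr(ref, s + d, nchar(ref)))
        if (ex == mut) starts <- c(starts, s)
    }
    if (!length(starts)) return(NULL)
    list(start = min(starts), nPlacements = length(starts))
}

randomDna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Assemble a single synthetic amplicon read around given peptide/linker
# nucleotides at the default layout (offset 12, 53 nt).
makeRead <- function(peptideNt = "TGGTCTCTGGGTTATACTGGT",
                     linkerNt = "GGTGGAGGTTCG",
                     offset = 12L, readLength = 53L) {
    prefix <- strrep("A", offset)
    body <- paste0(prefix, peptideNt, linkerNt)
    pad <- readLength - nchar(body)
    if (pad > 0) body <- paste0(body, strrep("C", pad))
    body
}

# Plus-strand query over the signature region with the M13KE bases planted,
# optionally substituting the given signature indices.
makeSignatureQuery <- function(from = 1130L, to = 1680L,
                               mismatchAt = integer()) {
    sig <- as.data.frame(signaturePositions(m13keGenomeModel()))
    q <- strsplit(randomDna(to - from + 1L), "")[[1]]
    for (i in seq_len(nrow(sig))) {
        p <- sig$position[i] - from + 1L
        if (p >= 1L && p <= length(q)) {
            if (i %in% mismatchAt) {
                q[p] <- setdiff(c("A", "C", "G", "T"), sig$m13keBase[i])[1]
            } else {
                q[p] <- sig$m13keBase[i]
            }
        }
    }
    paste(q, collapse = "")
}
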