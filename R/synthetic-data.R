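## Fixed codon choices used when a peptide has to be reverse-translated
## (focal inserts, Sanger cassettes). One codon per amino acid.
.AA_CODON <- c(
    A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
    H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
    P = "CCG", Q = "CAG", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
    W = "TGG", Y = "TAT")

.GLY_CODONS <- c("GGT", "GGC", "GGA", "GGG")
.SER_CODONS <- c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC")
.STOP_CODONS <- c("TAA", "TAG", "TGA")

## Constant amplicon context flanking the peptide cassette in synthetic
## reads: 12 nt before the peptide, padding after the linker.
.READ_PREFIX <- "TCTCACTCTGCA"
.READ_PAD <- "GACTGAGTCTAGACTGAGTCTAGA"

#' Reverse-translate a peptide with fixed codons
#'
#' @param peptide amino-acid string over the 20-letter alphabet.
#' @return nucleotide string, 3 nt per residue.
#' @export
#' @examples
#' reverseTranslate("WSLGYTG")  # "TGGTCTCTGGGTTATACTGGT"
reverseTranslate <- function(peptide) {
    aa <- strsplit(peptide, "")[[1L]]
    if (!all(aa %in% names(.AA_CODON)))
        stopDomain("peptide must use the 20-amino-acid alphabet")
    paste(.AA_CODON[aa], collapse = "")
}

#' Simulation configuration for the competitive propagation assay
#'
#' Defaults emulate the published assay conditions: three time points (0,
#' 150, 270 min) at which the focal WSLGYTG clone comprises 54.1%, 75.9%
#' and 91.6% of the pool, 53-nt single-end reads with the peptide cassette
#' at offset 12, and a total read-corruption rate around the observed ~5%
#' removal at t = 0, split between in-peptide stop codons and linker
#' corruption (the split is not observable in the published totals; see the
#' package vignette).
#'
#' @param seed integer RNG seed; fixed seed gives byte-identical output.
#' @param nReads reads per time point (default 1e4).
#' @param focalPeptide focal displayed 7-mer (default "WSLGYTG").
#' @param focalFractions per-time-point probability that a read comes from
#'   the focal clone.
#' @param timesMin time points in minutes, strictly increasing.
#' @param stopRate probability that a read carries an in-peptide stop codon.
#' @param linkerErrorRate probability that a read carries a corrupted
#'   (non-GGGS) linker.
#' @param readLength read length in nt (default 53).
#' @param peptideOffset 0-based offset of the peptide in the read.
#' @return a list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L, nReads = 1e4L, focalPeptide = "WSLGYTG",
                      focalFractions = c(0.541, 0.759, 0.916),
                      timesMin = c(0, 150, 270),
                      stopRate = 0.01, linkerErrorRate = 0.038,
                      readLength = 53L, peptideOffset = 12L) {
    if (length(focalFractions) != length(timesMin))
        stopDomain("focalFractions and timesMin must have equal length")
    if (any(focalFractions < 0 | focalFractions > 1))
        stopDomain("focalFractions must lie in [0, 1]")
    if (stopRate < 0 || stopRate > 1 || linkerErrorRate < 0 ||
        linkerErrorRate > 1 || stopRate + linkerErrorRate > 1)
        stopDomain("corruption rates must be probabilities summing to <= 1")
    if (readLength < peptideOffset + 33L)
        stopDomain("readLength must cover peptideOffset + 33 nt")
    structure(list(seed = as.integer(seed), nReads = as.integer(nReads),
                   focalPeptide = focalPeptide,
                   focalFractions = focalFractions, timesMin = timesMin,
                   stopRate = stopRate, linkerErrorRate = linkerErrorRate,
                   readLength = as.integer(readLength),
                   peptideOffset = as.integer(peptideOffset)),
              class = "SimConfig")
}

#' Layout matching the synthetic amplicon of a SimConfig
#'
#' @param cfg a [simConfig()] list.
#' @return a [ReadLayout-class].
#' @export
simReadLayout <- function(cfg) {
    ReadLayout(peptideOffset = cfg$peptideOffset)
}

#' Sample NNK codons and NNK-encoded library inserts
#'
#' NNK degenerate codons (N = any base, K = G or T) cover all 20 amino
#' acids among 32 codons, with TAG the only reachable stop. Library inserts
#' are 7 consecutive NNK codons; inserts containing TAG are emitted and can
#' be identified by translation.
#'
#' @param n number of codons / inserts to draw.
#' @return `sampleNnkCodon`: character vector of 3-nt codons;
#'   `sampleLibraryPeptide`: character vector of 21-nt inserts.
#' @export
#' @examples
#' set.seed(7)
#' sampleNnkCodon(3)
sampleNnkCodon <- function(n) {
    b <- c("A", "C", "G", "T")
    paste0(sample(b, n, replace = TRUE), sample(b, n, replace = TRUE),
           sample(c("G", "T"), n, replace = TRUE))
}

#' @rdname sampleNnkCodon
#' @export
sampleLibraryPeptide <- function(n) {
    m <- matrix(sampleNnkCodon(7L * n), nrow = n)
    do.call(paste0, as.data.frame(m))
}

#' @noRd
#' NNK inserts rejection-sampled to be stop-free (the displayed peptides a
#' functional library clone can carry).
sampleStopFreeInsert <- function(n) {
    out <- character(n)
    todo <- seq_len(n)
    while (length(todo)) {
        draw <- sampleLibraryPeptide(length(todo))
        ok <- !grepl("*", translateCodons(draw), fixed = TRUE)
        out[todo[ok]] <- draw[ok]
        todo <- todo[!ok]
    }
    out
}

#' @noRd
#' Random synonymous GGGS linkers, n at a time.
sampleLinker <- function(n) {
    paste0(sample(.GLY_CODONS, n, replace = TRUE),
           sample(.GLY_CODONS, n, replace = TRUE),
           sample(.GLY_CODONS, n, replace = TRUE),
           sample(.SER_CODONS, n, replace = TRUE))
}

#' Simulate one time point of amplicon reads
#'
#' Each read carries the constant prefix, a 21-nt insert (the focal peptide
#' with probability `focalFraction`, otherwise a stop-free NNK library
#' insert), a synonymous GGGS linker, and constant padding to
#' `readLength`. Corruption: with probability `stopRate` a random peptide
#' codon is replaced by a stop codon; with probability `linkerErrorRate`
#' the second base of a random linker codon is substituted (always
#' non-synonymous, so the linker no longer translates to GGGS). With
#' `exact = TRUE` the corruption counts are `round(rate * n)` exactly
#' rather than binomial, which pins the removal percentage of the
#' downstream filter.
#'
#' @param n number of reads.
#' @param focalFraction probability a read is focal.
#' @param focalPeptide focal 7-mer.
#' @param stopRate,linkerErrorRate per-read corruption probabilities.
#' @param readLength,peptideOffset amplicon geometry.
#' @param exact use exact corruption counts instead of binomial draws.
#' @return list with `seqs` (character vector of reads) and `truth`
#'   (data.frame with columns `label` in clean/stop_in_peptide/bad_linker,
#'   `is_focal`, `peptide` — `NA` for corrupted reads).
#' @export
simulateReads <- function(n, focalFraction, focalPeptide = "WSLGYTG",
                          stopRate = 0, linkerErrorRate = 0,
                          readLength = 53L, peptideOffset = 12L,
                          exact = FALSE) {
    n <- as.integer(n)
    if (n < 1L) stopDomain("n must be >= 1")
    if (readLength < peptideOffset + 33L)
        stopDomain("readLength must cover peptideOffset + 33 nt")

    if (exact) {
        nStop <- round(stopRate * n)
        nBad <- round(linkerErrorRate * n)
        lab <- sample(c(rep("stop_in_peptide", nStop),
                        rep("bad_linker", nBad),
                        rep("clean", n - nStop - nBad)))
    } else {
        lab <- sample(c("stop_in_peptide", "bad_linker", "clean"), n,
                      replace = TRUE,
                      prob = c(stopRate, linkerErrorRate,
                               1 - stopRate - linkerErrorRate))
    }
    isFocal <- stats::runif(n) < focalFraction

    inserts <- character(n)
    inserts[isFocal] <- reverseTranslate(focalPeptide)
    if (any(!isFocal))
        inserts[!isFocal] <- sampleStopFreeInsert(sum(!isFocal))

    iStop <- which(lab == "stop_in_peptide")
    if (length(iStop)) {
        codonIdx <- sample(7L, length(iStop), replace = TRUE)
        stopCodon <- sample(.STOP_CODONS, length(iStop), replace = TRUE)
        substr(inserts[iStop], (codonIdx - 1L) * 3L + 1L,
               codonIdx * 3L) <- stopCodon
    }

    linkers <- sampleLinker(n)
    iBad <- which(lab == "bad_linker")
    if (length(iBad)) {
        codonIdx <- sample(4L, length(iBad), replace = TRUE)
        pos <- (codonIdx - 1L) * 3L + 2L
        old <- substr(linkers[iBad], pos, pos)
        repl <- vapply(old, function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
        substr(linkers[iBad], pos, pos) <- repl
    }

    prefix <- substr(strrep(.READ_PREFIX,
                            ceiling(peptideOffset / nchar(.READ_PREFIX))),
                     1L, peptideOffset)
    padLen <- readLength - peptideOffset - 33L
    pad <- substr(strrep(.READ_PAD, ceiling(max(1L, padLen) /
                                            nchar(.READ_PAD))), 1L, padLen)
    seqs <- paste0(prefix, inserts, linkers, pad)

    pep <- rep(NA_character_, n)
    clean <- lab == "clean"
    pep[clean & isFocal] <- focalPeptide
    if (any(clean & !isFocal))
        pep[clean & !isFocal] <- translateCodons(inserts[clean & !isFocal])

    list(seqs = seqs,
         truth = data.frame(label = lab, is_focal = isFocal, peptide = pep,
                            stringsAsFactors = FALSE))
}

#' Generate the full synthetic competitive propagation FASTQ series
#'
#' Produces one FASTQ per time point (when `outDir` is given) or in-memory
#' [Biostrings::DNAStringSet]s, plus the ground truth for every read. All
#' randomness is driven by `cfg$seed`: a fixed seed gives byte-identical
#' files across runs.
#'
#' @param cfg a [simConfig()].
#' @param outDir optional output directory; FASTQ files `cpa_t<min>.fastq`
#'   and `sim_truth.tsv` are written there.
#' @return list with `reads` (named list of DNAStringSet per time point),
#'   `truth` (data.frame: `time_min`, `read_id`, `label`, `is_focal`,
#'   `peptide`), `layout` (the matching [ReadLayout-class]), and `files`
#'   (paths, or `NULL`).
#' @export
generateFastq <- function(cfg = simConfig(), outDir = NULL) {
    set.seed(cfg$seed)
    reads <- list()
    truths <- list()
    files <- NULL
    for (i in seq_along(cfg$timesMin)) {
        t <- cfg$timesMin[i]
        sim <- simulateReads(cfg$nReads, cfg$focalFractions[i],
                             focalPeptide = cfg$focalPeptide,
                             stopRate = cfg$stopRate,
                             linkerErrorRate = cfg$linkerErrorRate,
                             readLength = cfg$readLength,
                             peptideOffset = cfg$peptideOffset)
        ids <- sprintf("t%g_read%06d", t, seq_len(cfg$nReads))
        ss <- Biostrings::DNAStringSet(sim$seqs)
        names(ss) <- ids
        reads[[sprintf("t%g", t)]] <- ss
        tr <- sim$truth
        tr$read_id <- ids
        tr$time_min <- t
        truths[[i]] <- tr[, c("time_min", "read_id", "label", "is_focal",
                              "peptide")]
    }
    truth <- do.call(rbind, truths)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        files <- character()
        for (nm in names(reads)) {
            fp <- file.path(outDir, sprintf("cpa_%s.fastq", nm))
            qual <- Biostrings::BStringSet(
                rep(strrep("I", cfg$readLength), length(reads[[nm]])))
            Biostrings::writeXStringSet(reads[[nm]], fp, format = "fastq",
                                        qualities = qual)
            files <- c(files, fp)
        }
        truthFp <- file.path(outDir, "sim_truth.tsv")
        utils::write.table(truth, truthFp, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        files <- c(files, truthFp)
    }
    list(reads = reads, truth = truth, layout = simReadLayout(cfg),
         files = files)
}

#' Generate a synthetic M13KE-like reference/mutant genome pair
#'
#' Emits a random 7222-nt reference carrying the fixture feature
#' coordinates and the five signature bases, and a 6395-nt mutant equal to
#' the reference with positions 5879-6705 excised. The sequence content is
#' synthetic (random); only the coordinates are real, which is all the
#' coordinate-level results depend on. By default the breakpoint flanks are
#' forced to differ so the deletion placement is unique; with
#' `withHomology = TRUE` a 3-nt micro-homology is planted at the right
#' flank (the left-aligned call is still 5879).
#'
#' @param seed integer RNG seed.
#' @param withHomology plant breakpoint micro-homology (default FALSE).
#' @param outDir optional directory to write `reference_synthetic.fasta`,
#'   `mutant_synthetic.fasta` and `m13ke_model.yaml`.
#' @return list with `reference`, `mutant` ([Biostrings::DNAString]),
#'   `model` ([GenomeModel-class] carrying the reference sequence),
#'   `deletion` (`c(5879, 6705)`) and `files`.
#' @export
generateGenomes <- function(seed = 1L, withHomology = FALSE,
                            outDir = NULL) {
    set.seed(seed)
    b <- c("A", "C", "G", "T")
    delStart <- 5879L; delEnd <- 6705L
    len <- 7222L
    ref <- sample(b, len, replace = TRUE)

    gm0 <- m13keGenomeModel()
    sig <- signaturePositions(gm0)
    ref[sig$position] <- sig$m13keBase

    ## unique left flank: base before the deletion must differ from the
    ## last deleted base, otherwise the excision could shift left
    if (ref[delStart - 1L] == ref[delEnd])
        ref[delEnd] <- sample(setdiff(b, ref[delStart - 1L]), 1L)
    if (withHomology) {
        ref[(delEnd + 1L):(delEnd + 3L)] <- ref[delStart:(delStart + 2L)]
        if (ref[delEnd + 4L] == ref[delStart + 3L])
            ref[delEnd + 4L] <- sample(setdiff(b, ref[delStart + 3L]), 1L)
    } else {
        if (ref[delEnd + 1L] == ref[delStart])
            ref[delEnd + 1L] <- sample(setdiff(b, ref[delStart]), 1L)
    }

    refStr <- paste(ref, collapse = "")
    mutStr <- paste0(substr(refStr, 1L, delStart - 1L),
                     substr(refStr, delEnd + 1L, len))
    reference <- Biostrings::DNAString(refStr)
    mutant <- Biostrings::DNAString(mutStr)
    model <- m13keGenomeModel(sequence = reference)

    files <- NULL
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        refFp <- file.path(outDir, "reference_synthetic.fasta")
        mutFp <- file.path(outDir, "mutant_synthetic.fasta")
        cfgFp <- file.path(outDir, "m13ke_model.yaml")
        rs <- Biostrings::DNAStringSet(reference)
        names(rs) <- "M13KE_synthetic_reference"
        Biostrings::writeXStringSet(rs, refFp)
        ms <- Biostrings::DNAStringSet(mutant)
        names(ms) <- "M13KE_synthetic_deletion_mutant"
        Biostrings::writeXStringSet(ms, mutFp)
        writeGenomeModel(model, cfgFp)
        files <- c(reference = refFp, mutant = mutFp, config = cfgFp)
    }
    list(reference = reference, mutant = mutant, model = model,
         deletion = c(delStart, delEnd), files = files)
}

#' Default anchor sequence used in synthetic Sanger reads
#'
#' @return an 18-nt anchor string placed immediately 5' of the peptide
#'   cassette by [generateSanger()].
#' @export
defaultSangerAnchor <- function() "GCTTCCGGTCTGGTTCGC"

#' Generate synthetic Sanger reads of white plaques
#'
#' Emulates plus-strand Sanger reads spanning the signature region
#' (M13KE coordinates 1130-1680) followed by an anchored displayed-peptide
#' cassette. Library-origin reads carry the five M13KE signature bases;
#' environmental reads carry random substitutions at 2 or more signature
#' positions.
#'
#' @param seed integer RNG seed.
#' @param origin `"library"` or `"environmental"`.
#' @param peptide displayed 7-mer embedded behind the anchor.
#' @param n number of reads (default 8).
#' @param anchor upstream anchor sequence (default
#'   [defaultSangerAnchor()]).
#' @return list with `reads` ([Biostrings::DNAStringSet]), `truth`
#'   (data.frame: `read_id`, `origin`, `n_signature_mismatch`),
#'   `queryStart` (1130), `anchor` and `peptide`.
#' @export
generateSanger <- function(seed = 1L, origin = c("library", "environmental"),
                           peptide = "WSLGYTG", n = 8L,
                           anchor = defaultSangerAnchor()) {
    origin <- match.arg(origin)
    set.seed(seed)
    b <- c("A", "C", "G", "T")
    regionStart <- 1130L; regionEnd <- 1680L
    sig <- signaturePositions(m13keGenomeModel())

    region <- sample(b, regionEnd - regionStart + 1L, replace = TRUE)
    region[sig$position - regionStart + 1L] <- sig$m13keBase
    cassette <- paste0(anchor, reverseTranslate(peptide), "GGTGGAGGTTCG")

    seqs <- character(n)
    nMis <- integer(n)
    for (i in seq_len(n)) {
        reg <- region
        if (origin == "environmental") {
            k <- sample(2:5, 1L)
            at <- sample(seq_len(nrow(sig)), k)
            for (j in at) {
                p <- sig$position[j] - regionStart + 1L
                reg[p] <- sample(setdiff(b, sig$m13keBase[j]), 1L)
            }
            nMis[i] <- k
        }
        tail <- paste(sample(b, 10L, replace = TRUE), collapse = "")
        seqs[i] <- paste0(paste(reg, collapse = ""), cassette, tail)
    }
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- sprintf("%s_plaque_%02d", origin, seq_len(n))
    list(reads = reads,
         truth = data.frame(read_id = names(reads), origin = origin,
                            n_signature_mismatch = nMis),
         queryStart = regionStart, anchor = anchor, peptide = peptide)
}
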