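test_that("codon translation follows the standard genetic code", {
    expect_identical(translateCodons("TGGTCTCTGGGTTATACTGGT"), "WSLGYTG")
    expect_identical(translateCodons("TAGGGTGGTGGTGGTGGTGGT"), "*GGGGGG")
    expect_identical(translateCodons("GGTGGAGGTTCG"), "GGGS")
    # any codon containing N is marked X, distinct from the 20 amino acids
    expect_identical(translateCodons("GGNTGG"), "XW")
    expect_error(translateCodons("GGTA"), class = "domain_error")
})

test_that("processRead returns the peptide or the first failing reason", {
    layout <- ReadLayout()
    ok <- processRead(makeRead(), layout)
    expect_identical(ok$peptide, "WSLGYTG")
    expect_true(is.na(ok$reason))

    stopRead <- makeRead(peptideNt = "TGGTCTTAAGGTTATACTGGT")
    expect_identical(processRead(stopRead, layout)$reason, "stop_in_peptide")

    # GGGR linker: last codon CGG = Arg
    badLinker <- makeRead(linkerNt = "GGTGGAGGTCGG")
    expect_identical(processRead(badLinker, layout)$reason, "bad_linker")

    nRead <- makeRead(peptideNt = "TGGTCTNTGGGTTATACTGGT")
    expect_identical(processRead(nRead, layout)$reason,
                     "invalid_aa_in_peptide")

    expect_identical(processRead("ACGT", layout)$reason, "too_short")

    # a stop in the peptide outranks a corrupted linker
    both <- makeRead(peptideNt = "TGGTCTTAAGGTTATACTGGT",
                     linkerNt = "GGTGGAGGTCGG")
    expect_identical(processRead(both, layout)$reason, "stop_in_peptide")
})

test_that("synonymous linkers pass in aa mode and fail in nucleotide mode", {
    synon <- makeRead(linkerNt = "GGAGGCGGGAGC")  # GGGS, different codons
    expect_identical(processRead(synon, ReadLayout())$peptide, "WSLGYTG")
    strict <- ReadLayout(linkerMode = "nucleotide")
    expect_identical(processRead(synon, strict)$reason, "bad_linker")
    expect_identical(processRead(makeRead(), strict)$peptide, "WSLGYTG")
})

test_that("frequency table reconciles totals and orders counts", {
    reads <- c(rep(makeRead(), 5),
               rep(makeRead(peptideNt = reverseTranslate("AAAAAAA")), 3),
               rep(makeRead(peptideNt = reverseTranslate("CCCCCCC")), 3),
               makeRead(peptideNt = "TGGTCTTAAGGTTATACTGGT"))
    res <- buildFrequencyTable(reads, sampleId = "s1")
    rep <- res$report
    expect_identical(rep@totalReads, 12L)
    expect_identical(rep@cleanReads, 11L)
    expect_identical(removalReasons(rep), c(stop_in_peptide = 1L))
    expect_identical(rep@cleanReads + rep@removedReads, rep@totalReads)
    # descending counts, ties broken lexicographically
    expect_identical(names(peptideCounts(res$table)),
                     c("WSLGYTG", "AAAAAAA", "CCCCCCC"))
    expect_identical(unname(peptideCounts(res$table)), c(5L, 3L, 3L))
    expect_identical(cleanTotal(res$table), 11L)

    expect_error(buildFrequencyTable(character(0)), class = "empty_input")
})

test_that("clean percentages: error-free and exactly-corrupted streams", {
    res <- buildFrequencyTable(rep(makeRead(), 100))
    expect_identical(removedPercent(res$report), 0)

    set.seed(11)
    sim <- simulateReads(1000, 0.5, stopRate = 0, linkerErrorRate = 0.1,
                         exact = TRUE)
    res <- buildFrequencyTable(sim$seqs)
    expect_identical(removedPercent(res$report), 10)
    expect_identical(removalReasons(res$report), c(bad_linker = 100L))
})

test_that("filter report reasons equal generator truth exactly", {
    set.seed(23)
    sim <- simulateReads(5000, 0.4, stopRate = 0.03, linkerErrorRate = 0.05)
    res <- buildFrequencyTable(sim$seqs)
    truthTab <- table(sim$truth$label)
    expect_identical(res$report@cleanReads,
                     as.integer(truthTab[["clean"]]))
    rs <- removalReasons(res$report)
    expect_identical(unname(rs["stop_in_peptide"]),
                     as.integer(truthTab[["stop_in_peptide"]]))
    expect_identical(unname(rs["bad_linker"]),
                     as.integer(truthTab[["bad_linker"]]))
    # clean peptides agree read by read
    clean <- sim$truth$label == "clean"
    expected <- sort(table(sim$truth$peptide[clean]))
    got <- peptideCounts(res$table)
    expect_identical(sum(got), sum(clean))
    expect_identical(unname(got[names(expected)]),
                     unname(as.integer(expected)))
})

test_that("conservation holds and removal grows with corruption rate", {
    set.seed(31)
    rates <- c(0, 0.02, 0.05, 0.1, 0.25)
    removed <- vapply(rates, function(r) {
        sim <- simulateReads(4000, 0.5, stopRate = r / 2,
                             linkerErrorRate = r / 2, exact = TRUE)
        rp <- buildFrequencyTable(sim$seqs)$report
        expect_identical(rp@cleanReads + rp@removedReads, rp@totalReads)
        removedPercent(rp)
    }, numeric(1))
    expect_true(all(diff(removed) >= 0))
})

test_that("relative abundance is a rounded clean-read percentage", {
    tab <- new("FrequencyTable", sampleId = "s",
               counts = c(WSLGYTG = 541L, AAAAAAA = 459L),
               cleanTotal = 1000L)
    expect_identical(relativeAbundance(tab, "WSLGYTG"), 54.1)
    expect_identical(relativeAbundance(tab, "NOTHERE"), 0)
    solo <- new("FrequencyTable", sampleId = "s", counts = c(MMMMMMM = 1L),
                cleanTotal = 1L)
    expect_identical(relativeAbundance(solo, "MMMMMMM"), 100)
    empty <- new("FrequencyTable", sampleId = "s",
                 counts = structure(integer(), names = character()),
                 cleanTotal = 0L)
    expect_error(relativeAbundance(empty, "WSLGYTG"),
                 class = "domain_error")
})

test_that("frequency tables and reports round-trip FASTQ and TSV", {
    dir <- withr::local_tempdir()
    cfg <- simConfig(seed = 5, nReads = 500, stopRate = 0.02,
                     linkerErrorRate = 0.03)
    out <- generateFastq(cfg, outDir = dir)
    fq <- file.path(dir, "cpa_t0.fastq")
    expect_true(file.exists(fq))
    res <- buildFrequencyTable(fq, out$layout, sampleId = "t0")
    truth0 <- out$truth[out$truth$time_min == 0, ]
    expect_identical(res$report@cleanReads,
                     sum(truth0$label == "clean"))
    tsv <- file.path(dir, "freq.tsv")
    writeFrequencyTable(res$table, tsv)
    back <- readFrequencyTable(tsv, sampleId = "t0")
    expect_identical(peptideCounts(back), peptideCounts(res$table))
})
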