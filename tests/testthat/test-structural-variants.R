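test_that("single-deletion calls are left-aligned and verified", {
    call <- callSingleDeletion("AAATTTCCC", "AAACCC")
    expect_identical(deletionStart(call), 4L)
    expect_identical(deletionEnd(call), 6L)
    expect_identical(deletionLength(call), 3L)
    expect_identical(homologyLength(call), 0L)

    # fully ambiguous placement in a homopolymer left-aligns to 1
    call <- callSingleDeletion("AAAAA", "AAA")
    expect_identical(deletionStart(call), 1L)
    expect_identical(deletionEnd(call), 2L)
    expect_identical(homologyLength(call), 3L)

    expect_error(callSingleDeletion("ACGT", "ACGT"), class = "no_indel")
    expect_error(callSingleDeletion("ACGT", "ACGTAA"),
                 class = "domain_error")
    # two separated differences are not a single contiguous deletion
    expect_error(callSingleDeletion("AACCGGTTAA", "ACCGGTA"),
                 class = "complex_variant")
    expect_error(callSingleDeletion("ACGTN", "ACG"), class = "domain_error")
})

test_that("caller matches the brute-force leftmost-excision oracle", {
    set.seed(71)
    for (i in 1:300) {
        n <- sample(20:200, 1)
        ref <- randomDna(n)
        len <- sample(1:(n - 5), 1)
        s <- sample(1:(n - len + 1), 1)
        mut <- paste0(substr(ref, 1, s - 1), substr(ref, s + len, n))
        oracle <- bruteForceDeletion(ref, mut)
        call <- callSingleDeletion(ref, mut)
        expect_identical(deletionStart(call), as.integer(oracle$start))
        expect_identical(deletionLength(call), len)
        expect_identical(homologyLength(call),
                         as.integer(oracle$nPlacements - 1L))
        # reconstruction invariant
        rec <- paste0(substr(ref, 1, deletionStart(call) - 1),
                      substr(ref, deletionEnd(call) + 1, n))
        expect_identical(rec, mut)
        # left-alignment: no valid placement with smaller start
        if (oracle$start > 1) {
            d <- nchar(ref) - nchar(mut)
            sm <- oracle$start - 1L
            expect_false(paste0(substr(ref, 1, sm - 1),
                                substr(ref, sm + d, n)) == mut)
        }
    }
})

test_that("the synthetic genome pair yields the recurrent 827-nt deletion", {
    g <- generateGenomes(seed = 3)
    call <- callSingleDeletion(g$reference, g$mutant)
    expect_identical(deletionStart(call), 5879L)
    expect_identical(deletionEnd(call), 6705L)
    expect_identical(deletionLength(call), 827L)

    # with planted breakpoint micro-homology the left-aligned call is stable
    gh <- generateGenomes(seed = 3, withHomology = TRUE)
    ch <- callSingleDeletion(gh$reference, gh$mutant)
    expect_identical(deletionStart(ch), 5879L)
    expect_identical(homologyLength(ch), 3L)
    oracle <- bruteForceDeletion(as.character(gh$reference),
                                 as.character(gh$mutant))
    expect_identical(as.integer(oracle$start), 5879L)
})

test_that("deletion annotation reports feature relations and genome fraction", {
    gm <- m13keGenomeModel()
    call <- new("DeletionCall", start = 5879L, end = 6705L, length = 827L,
                homologyLen = 0L, leftAligned = TRUE)
    ann <- annotateDeletion(call, gm)
    af <- affectedFeatures(ann)
    expect_identical(af$relation[af$feature == "lacZalpha"], "contains")
    expect_identical(af$distance[af$feature == "lacZalpha"], 0L)
    expect_identical(af$relation[af$feature == "Ori"], "downstream_of")
    expect_identical(af$distance[af$feature == "Ori"], 11L)
    expect_identical(af$relation[af$feature == "gII"], "upstream_of")
    expect_identical(af$distance[af$feature == "gII"], 115L)
    expect_identical(genomeFraction(ann), 11.5)

    tiny <- new("DeletionCall", start = 1L, end = 1L, length = 1L,
                homologyLen = 0L, leftAligned = TRUE)
    expect_identical(genomeFraction(annotateDeletion(tiny, gm)), 0)

    exact <- new("DeletionCall", start = 6216L, end = 6695L, length = 480L,
                 homologyLen = 0L, leftAligned = TRUE)
    afx <- affectedFeatures(annotateDeletion(exact, gm))
    expect_identical(afx$relation[afx$feature == "lacZalpha"], "overlaps")
    expect_identical(afx$distance[afx$feature == "lacZalpha"], 0L)

    out <- new("DeletionCall", start = 7000L, end = 7300L, length = 301L,
               homologyLen = 0L, leftAligned = TRUE)
    expect_error(annotateDeletion(out, gm), class = "domain_error")
})

test_that("deletion calls export as TSV and anchored VCF records", {
    dir <- withr::local_tempdir()
    g <- generateGenomes(seed = 9)
    call <- callSingleDeletion(g$reference, g$mutant)
    tsv <- file.path(dir, "del.tsv")
    writeDeletionTsv(call, tsv)
    df <- read.delim(tsv)
    expect_identical(df$start, 5879L)
    expect_identical(df$length, 827L)

    vcf <- file.path(dir, "del.vcf")
    writeDeletionVcf(call, g$reference, vcf, contig = "m13ke")
    rec <- strsplit(grep("^m13ke", readLines(vcf), value = TRUE), "\t")[[1]]
    expect_identical(as.integer(rec[2]), 5878L)
    expect_identical(nchar(rec[4]), 828L)  # anchor + deleted bases
    expect_identical(substr(rec[4], 1, 1), rec[5])
    expect_true(grepl("SVLEN=-827", rec[8]))
    # anchored REF really is the reference slice
    expect_identical(rec[4],
        as.character(Biostrings::subseq(g$reference, 5878, 6705)))
})
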