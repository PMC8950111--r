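test_that("plaque CPA rows reproduce the white/blue titration arithmetic", {
    r0 <- plaqueCpaRow(0, 4.9e7, 4.1e7)
    expect_identical(r0$white_blue_ratio, 1.2)
    expect_identical(r0$white_percent, 54.4)

    r150 <- plaqueCpaRow(150, 5.3e8, 8.0e7)
    expect_identical(r150$white_blue_ratio, 6.6)
    expect_identical(r150$white_percent, 86.9)

    # the t = 270 ratio is computed from the titers themselves
    r270 <- plaqueCpaRow(270, 2.7e10, 1.9e8)
    expect_identical(r270$white_percent, 99.3)
    expect_identical(r270$white_blue_ratio,
                     roundHalfUp(2.7e10 / 1.9e8, 1))

    none <- plaqueCpaRow(0, 0, 1e8)
    expect_identical(none$white_blue_ratio, 0)
    expect_identical(none$white_percent, 0)

    noBlue <- plaqueCpaRow(0, 1e8, 0)
    expect_true(is.na(noBlue$white_blue_ratio))
    expect_identical(noBlue$white_percent, 100)

    expect_error(plaqueCpaRow(0, 0, 0), class = "domain_error")
})

test_that("percent and ratio columns are mutually consistent", {
    set.seed(41)
    for (i in 1:50) {
        w <- 10^stats::runif(1, 6.5, 8.5)
        b <- 10^stats::runif(1, 6.5, 8.5)
        row <- plaqueCpaRow(0, w, b)
        # the printed ratio is within half a rounding unit of the titer ratio
        expect_lt(abs(row$white_blue_ratio - w / b), 0.05 + 1e-9)
        # the odds implied by the rounded percent bracket the titer ratio
        p <- row$white_percent
        lo <- (p - 0.05) / (100 - (p - 0.05))
        hi <- (p + 0.05) / (100 - (p + 0.05))
        expect_gte(w / b, lo)
        expect_lte(w / b, hi)
    }
})

test_that("Sanger pick frequencies cover the pick list", {
    picks <- c(rep("WSLGYTG", 4),
               replicate(41, paste(sample(LETTERS[1:20], 7, TRUE),
                                   collapse = "")))
    df <- sangerPickFrequency(picks)
    expect_identical(sum(df$count), 45L)
    top <- df[df$peptide == "WSLGYTG", ]
    expect_identical(top$count, 4L)
    expect_identical(top$percent, 8.9)

    mono <- sangerPickFrequency(rep("AAAAAAA", 10))
    expect_identical(mono$count, 10L)
    expect_identical(mono$percent, 100)

    tri <- sangerPickFrequency(c("AAAAAAA", "CCCCCCC", "DDDDDDD"))
    expect_identical(tri$count, rep(1L, 3))
    expect_identical(tri$percent, rep(33.3, 3))

    expect_error(sangerPickFrequency(character(0)), class = "empty_input")
})

test_that("NGS time course recovers generator mixture fractions", {
    set.seed(53)
    fr <- c(0.5, 0.75, 0.9)
    n <- 2e4
    tabs <- lapply(fr, function(f) {
        sim <- simulateReads(n, f)
        buildFrequencyTable(sim$seqs)$table
    })
    tc <- ngsCpaTimecourse(tabs, c(0, 150, 270), "WSLGYTG")
    rows <- cpaRows(tc)
    se <- 100 * sqrt(fr * (1 - fr) / n)
    expect_true(all(abs(rows$focal_percent - 100 * fr) <= 3 * se + 0.05))
    expect_true(all(relativeFitness(tc) > 0))
})

test_that("NGS time course degenerate pools and input validation", {
    mk <- function(cnt) new("FrequencyTable", sampleId = "s",
                            counts = cnt, cleanTotal = sum(cnt))
    absent <- lapply(1:3, function(i) mk(c(AAAAAAA = 10L)))
    tc <- ngsCpaTimecourse(absent, c(0, 10, 20), "WSLGYTG")
    expect_identical(cpaRows(tc)$focal_percent, rep(0, 3))

    solo <- lapply(1:2, function(i) mk(c(WSLGYTG = 5L)))
    tc <- ngsCpaTimecourse(solo, c(0, 10), "WSLGYTG")
    expect_identical(cpaRows(tc)$focal_percent, rep(100, 2))

    expect_error(ngsCpaTimecourse(solo, c(10, 10), "WSLGYTG"),
                 class = "domain_error")
    expect_error(ngsCpaTimecourse(solo[1], 0, "WSLGYTG"),
                 class = "domain_error")
})

test_that("relative fitness is the per-minute log-odds slope", {
    tc <- new("CPATimeCourse", timeMin = c(0, 100, 200),
              focalPercent = c(50, 50, 50), focalPeptide = "X")
    expect_equal(relativeFitness(tc), c(0, 0))

    tc <- new("CPATimeCourse", timeMin = c(0, 150),
              focalPercent = c(50, 75), focalPeptide = "X")
    expect_equal(relativeFitness(tc), log(3) / 150)

    # antisymmetry under swapping focal and background
    up <- new("CPATimeCourse", timeMin = c(0, 60),
              focalPercent = c(20, 70), focalPeptide = "X")
    down <- new("CPATimeCourse", timeMin = c(0, 60),
                focalPercent = 100 - c(20, 70), focalPeptide = "X")
    expect_equal(relativeFitness(up), -relativeFitness(down))
    expect_true(relativeFitness(down) < 0)

    edge <- new("CPATimeCourse", timeMin = c(0, 60),
                focalPercent = c(0, 50), focalPeptide = "X")
    expect_true(is.na(relativeFitness(edge)))
})

test_that("plaque time course wraps the summary rows", {
    obs <- data.frame(time_min = c(0, 150, 270),
                      white_titer = c(4.9e7, 5.3e8, 2.7e10),
                      blue_titer = c(4.1e7, 8.0e7, 1.9e8))
    tc <- plaqueCpaTimecourse(obs)
    expect_identical(cpaRows(tc)$focal_percent, c(54.4, 86.9, 99.3))
    expect_true(all(relativeFitness(tc) > 0))
})
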