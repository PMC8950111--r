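#' Summarize one plaque-count observation of a competitive propagation assay
#'
#' From the white (focal, deletion-bearing) and blue (library) plaque titers
#' at one time point, computes the white/blue titer ratio and the percent of
#' white plaques in the pool, `100 * white / (white + blue)`, both half-up
#' to 1 decimal. When no blue plaques are observed the ratio is undefined
#' (`NA`) while the percent is still 100.
#'
#' @param timeMin minutes since inoculation.
#' @param whiteTiter,blueTiter plaque titers (pfu/mL), both >= 0 and not
#'   both zero.
#' @return one-row data.frame with columns `time_min`, `white_blue_ratio`,
#'   `white_percent`.
#' @export
#' @examples
#' plaqueCpaRow(0, 4.9e7, 4.1e7)     # ratio 1.2, percent 54.4
#' plaqueCpaRow(150, 5.3e8, 8.0e7)   # ratio 6.6, percent 86.9
plaqueCpaRow <- function(timeMin, whiteTiter, blueTiter) {
    if (timeMin < 0) stopDomain("time must be >= 0")
    if (whiteTiter < 0 || blueTiter < 0)
        stopDomain("titers must be >= 0")
    if (whiteTiter + blueTiter == 0)
        stopDomain("both titers are zero; no plaques to summarize")
    ratio <- if (blueTiter == 0) NA_real_
             else roundHalfUp(whiteTiter / blueTiter, 1)
    pct <- roundHalfUp(100 * whiteTiter / (whiteTiter + blueTiter), 1)
    data.frame(time_min = timeMin, white_blue_ratio = ratio,
               white_percent = pct)
}

#' Summarize a table of plaque-count observations
#'
#' @param obs data.frame with columns `time_min`, `white_titer`,
#'   `blue_titer`.
#' @return data.frame of [plaqueCpaRow()] results, one row per time point.
#' @export
plaqueCpaTable <- function(obs) {
    need <- c("time_min", "white_titer", "blue_titer")
    if (!all(need %in% names(obs)))
        stopDomain("obs needs columns time_min, white_titer, blue_titer")
    do.call(rbind, lapply(seq_len(nrow(obs)), function(i)
        plaqueCpaRow(obs$time_min[i], obs$white_titer[i], obs$blue_titer[i])))
}

#' Clone frequencies among Sanger-sequenced plaque picks
#'
#' @param picks non-empty character vector of peptide labels, one per
#'   sequenced plaque.
#' @return data.frame with columns `peptide`, `count`, `percent` (half-up
#'   to 1 decimal), sorted by descending count then peptide.
#' @export
#' @examples
#' picks <- c(rep("WSLGYTG", 4), paste0("PEPTID", LETTERS[1:41]))
#' sangerPickFrequency(picks)[1, ]  # WSLGYTG: 4 picks, 8.9%
sangerPickFrequency <- function(picks) {
    if (length(picks) == 0L)
        stopDomain("empty pick list", class = "empty_input")
    tab <- table(picks)
    df <- data.frame(peptide = names(tab), count = as.integer(tab))
    df$percent <- roundHalfUp(100 * df$count / length(picks), 1)
    df <- df[order(-df$count, df$peptide), , drop = FALSE]
    rownames(df) <- NULL
    df
}

#' NGS-based competitive propagation time course
#'
#' Builds a [CPATimeCourse-class] from per-time-point peptide frequency
#' tables: the focal clone's percentage at each time point is its relative
#' abundance among clean reads.
#'
#' @param tables list of [FrequencyTable-class], one per time point.
#' @param timesMin numeric vector of minutes since inoculation, strictly
#'   increasing, same length as `tables` (>= 2 time points).
#' @param focal focal 7-mer peptide (for example "WSLGYTG").
#' @return a [CPATimeCourse-class].
#' @export
ngsCpaTimecourse <- function(tables, timesMin, focal) {
    if (length(tables) != length(timesMin))
        stopDomain("tables and timesMin must have equal length")
    if (length(tables) < 2L)
        stopDomain("need at least 2 time points")
    if (anyDuplicated(timesMin))
        stopDomain("duplicate time points")
    if (any(diff(timesMin) <= 0))
        stopDomain("time points must be strictly increasing")
    pct <- vapply(tables, relativeAbundance, numeric(1), peptide = focal)
    new("CPATimeCourse", timeMin = as.numeric(timesMin),
        focalPercent = unname(pct), focalPeptide = focal)
}

#' Plaque-based competitive propagation time course
#'
#' @param obs data.frame as in [plaqueCpaTable()].
#' @return a [CPATimeCourse-class] carrying the white-plaque percentages.
#' @export
plaqueCpaTimecourse <- function(obs) {
    rows <- plaqueCpaTable(obs)
    rows <- rows[order(rows$time_min), , drop = FALSE]
    new("CPATimeCourse", timeMin = rows$time_min,
        focalPercent = rows$white_percent, focalPeptide = NA_character_)
}

#' Accessors for CPATimeCourse
#'
#' @param x a [CPATimeCourse-class].
#' @return data.frame with columns `time_min` and `focal_percent`.
#' @export
cpaRows <- function(x) {
    data.frame(time_min = x@timeMin, focal_percent = x@focalPercent)
}

#' Per-interval log-odds growth advantage of the focal clone
#'
#' A convenience fitness statistic (not part of the published assay): for
#' consecutive time points with focal frequencies f1, f2 strictly inside
#' (0, 1), the selection coefficient per minute is
#' `s = (log(f2/(1-f2)) - log(f1/(1-f1))) / (t2 - t1)`. Positive values
#' mean the focal clone out-propagates the rest of the pool; intervals with
#' a frequency at exactly 0% or 100% yield `NA`.
#'
#' @param course a [CPATimeCourse-class].
#' @return numeric vector of length `n - 1`, log-odds advantage per minute.
#' @export
#' @examples
#' tc <- new("CPATimeCourse", timeMin = c(0, 150),
#'     focalPercent = c(50, 75), focalPeptide = "WSLGYTG")
#' relativeFitness(tc)  # log(3)/150
relativeFitness <- function(course) {
    f <- course@focalPercent / 100
    t <- course@timeMin
    logit <- ifelse(f > 0 & f < 1, stats::qlogis(f), NA_real_)
    diff(logit) / diff(t)
}

setMethod("show", "CPATimeCourse", function(object) {
    cat(sprintf("CPATimeCourse (%s): %d time point(s)\n",
        if (is.na(object@focalPeptide)) "plaque-based"
        else paste0("focal ", object@focalPeptide),
        length(object@timeMin)))
    for (i in seq_along(object@timeMin))
        cat(sprintf("  t = %4g min  %5.1f%%\n", object@timeMin[i],
            object@focalPercent[i]))
})
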