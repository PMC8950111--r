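#' Round half away from zero
#'
#' Plaque/read percentages and ratios are reported to a fixed number of
#' decimals with ties rounded up (5 rounds away from zero), the convention
#' used in bench reporting of titration tables, rather than the IEEE
#' round-half-even of [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' roundHalfUp(6.625, 1)  # 6.6
#' roundHalfUp(8.85, 1)   # 8.9
roundHalfUp <- function(x, digits = 1) {
    p <- 10^digits
    # nudge by a few ulps so values printed as x.x5 round up despite binary
    # representation sitting just below the tie
    sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' @noRd
stopDomain <- function(msg, class = "domain_error") {
    stop(structure(
        class = c(class, "error", "condition"),
        list(message = msg, call = sys.call(-1))
    ))
}

#' @noRd
assertScalarNumber <- function(x, name, positive = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
        stopDomain(sprintf("'%s' must be a single non-missing number", name))
    if (positive && x <= 0)
        stopDomain(sprintf("'%s' must be > 0", name))
    invisible(x)
}
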