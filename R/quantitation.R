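#' Convert a dsDNA mass concentration to genome copies per microliter
#'
#' Standard absolute-quantification arithmetic for qPCR of phage DNA:
#' `gc/uL = (g/uL) / (size_bp * 607.4 + 157.9) * 6.02e23`, where
#' `size_bp * 607.4 + 157.9` is the molar mass (g/mol) of a double-stranded
#' DNA molecule of that length. Any dilution factor is applied by the
#' caller, after the formula.
#'
#' @param dsdnaGPerUl dsDNA concentration in g/uL (> 0).
#' @param dnaSizeBp DNA length in base pairs (> 0).
#' @return genome copies per microliter.
#' @export
#' @examples
#' genomeCopiesPerUl(1e-15, 7222)  # ~137.2 gc/uL
genomeCopiesPerUl <- function(dsdnaGPerUl, dnaSizeBp) {
    assertScalarNumber(dsdnaGPerUl, "dsdnaGPerUl", positive = TRUE)
    assertScalarNumber(dnaSizeBp, "dnaSizeBp", positive = TRUE)
    dsdnaGPerUl / (dnaSizeBp * 607.4 + 157.9) * 6.02e23
}

#' Plaque-assay titer from a plate count
#'
#' `pfu/mL = count * dilution_factor / plated_volume_mL`. Counts outside
#' the reliable counting window of 50-300 plaques per plate are flagged
#' with a warning (attribute `out_of_range`), not rejected. The default
#' plated volume is 0.01 mL (10 uL of supernatant).
#'
#' @param plaqueCount integer plaque count (>= 0).
#' @param dilutionFactor 10-fold serial dilution factor (>= 1).
#' @param platedVolumeMl plated volume in mL (> 0, default 0.01).
#' @return titer in pfu/mL, with logical attribute `out_of_range`.
#' @export
#' @examples
#' titerPfuPerMl(100, 1e6)  # 1e10 pfu/mL
titerPfuPerMl <- function(plaqueCount, dilutionFactor,
                          platedVolumeMl = 0.01) {
    if (plaqueCount < 0) stopDomain("plaque count must be >= 0")
    if (dilutionFactor < 1) stopDomain("dilution factor must be >= 1")
    if (platedVolumeMl <= 0) stopDomain("plated volume must be > 0")
    out <- plaqueCount < 50 || plaqueCount > 300
    if (out)
        warning(sprintf(
            "plaque count %d outside the reliable 50-300 window",
            as.integer(plaqueCount)), call. = FALSE)
    structure(plaqueCount * dilutionFactor / platedVolumeMl,
              out_of_range = out)
}

#' ELISA binding ratio of a phage clone
#'
#' Absorbances at 450 nm are reference-subtracted at 540 nm for both the
#' target-coated and the PBS-coated (no-target) wells; the binding ratio is
#' the target signal over the PBS signal. A ratio near 1 means no specific
#' binding.
#'
#' @param od450Target,od540Target absorbances of the target-coated well.
#' @param od450Pbs,od540Pbs absorbances of the PBS-coated well.
#' @return dimensionless binding ratio.
#' @export
#' @examples
#' elisaBindingRatio(1.0, 0.1, 0.2, 0.1)  # 9
elisaBindingRatio <- function(od450Target, od540Target, od450Pbs,
                              od540Pbs) {
    denom <- od450Pbs - od540Pbs
    if (denom <= 0)
        stopDomain("reference-subtracted PBS signal must be > 0")
    (od450Target - od540Target) / denom
}

#' Fit a qPCR standard curve and convert Ct values to genome copies
#'
#' `fitStandardCurve` fits Ct on log10 copies by ordinary least squares;
#' `ctToCopies` inverts the line: `copies = 10^((ct - intercept) / slope)`.
#'
#' @param points data.frame with columns `log10_copies` and `ct`, at least
#'   two distinct `log10_copies` values.
#' @return a [QPCRStandard-class].
#' @export
#' @examples
#' std <- fitStandardCurve(
#'     data.frame(log10_copies = 1:6, ct = 40 - 3.32 * (1:6)))
#' ctToCopies(std, 40 - 3.32 * 3)  # 1000
fitStandardCurve <- function(points) {
    if (!all(c("log10_copies", "ct") %in% names(points)))
        stopDomain("points needs columns log10_copies and ct")
    if (nrow(points) < 2L || length(unique(points$log10_copies)) < 2L)
        stopDomain("need at least 2 distinct log10_copies values")
    fit <- stats::lm(ct ~ log10_copies, data = points)
    slope <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
    if (slope >= 0)
        warning("fitted slope is non-negative; not a valid amplification",
                call. = FALSE)
    new("QPCRStandard", points = as.data.frame(points), slope = slope,
        intercept = intercept)
}

#' @rdname fitStandardCurve
#' @param std a [QPCRStandard-class].
#' @param ct observed cycle-threshold value(s).
#' @export
ctToCopies <- function(std, ct) {
    10^((ct - std@intercept) / std@slope)
}

setMethod("show", "QPCRStandard", function(object) {
    cat(sprintf("QPCRStandard: Ct = %.3f %+.3f * log10(copies) (%d points)\n",
        object@intercept, object@slope, nrow(object@points)))
})
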