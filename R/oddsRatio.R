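#' @include AllClasses.R AllGenerics.R lineage.R
NULL

#' Lineage odds ratio and X-attributable proportion
#'
#' The core statistic: for affected-proband counts a (female/paternal),
#' b (female/maternal), c (male/paternal), d (male/maternal),
#' \deqn{OR = (a/b) / (c/d).}
#' Because the X transmission channel is closed only in the male/paternal
#' cell, an X-borne risk component inflates a, b and d but not c, so OR > 1
#' signals X-mediated risk while sex-specific ascertainment and
#' lineage-level confounders cancel between numerator and denominator.
#'
#' Inference is the Wald interval on the log odds ratio: the standard error
#' is \eqn{\sqrt{1/a + 1/b + 1/c + 1/d}}, the interval
#' \eqn{\exp(\log OR \pm z_{level} \cdot se)}, and the two-sided p-value
#' comes from the standard-normal tail of \eqn{z = \log OR / se}.
#'
#' Zero cells are a hard error by default because silently shifting counts
#' would change the estimand; \code{correct = TRUE} opts into the
#' Haldane-Anscombe correction (add 0.5 to every cell) and flags the result
#' as corrected.
#'
#' @param x a \code{\linkS4class{LineageCountTable}}, or a 2x2 matrix /
#'   length-4 numeric vector in (a, b, c, d) order.
#' @param level confidence level (default 0.95).
#' @param correct apply the +0.5 continuity correction to zero cells?
#' @return An \code{\linkS4class{ORResult}}.
#' @examples
#' res <- oddsRatio(LineageCountTable(629, 582, 343, 296))
#' orPoint(res)   # 0.93
#' confInt(res)   # 0.77 - 1.13
#' pValue(res)    # 0.48
#' @seealso \code{\link{xAttributableProportion}}
#' @aliases oddsRatio
#' @export
setMethod("oddsRatio", "LineageCountTable",
    function(x, level = 0.95, correct = FALSE) {
        .oddsRatioCore(lineageCounts(x), level = level, correct = correct,
                       label = x@label)
    })

#' @rdname oddsRatio-LineageCountTable-method
#' @export
setMethod("oddsRatio", "matrix", function(x, level = 0.95, correct = FALSE) {
    stopifnot(identical(dim(x), c(2L, 2L)))
    .oddsRatioCore(c(a = x[1, 1], b = x[1, 2], c = x[2, 1], d = x[2, 2]),
                   level = level, correct = correct, label = "")
})

#' @rdname oddsRatio-LineageCountTable-method
#' @export
setMethod("oddsRatio", "numeric", function(x, level = 0.95, correct = FALSE) {
    stopifnot(length(x) == 4L)
    .oddsRatioCore(c(a = x[1], b = x[2], c = x[3], d = x[4]),
                   level = level, correct = correct, label = "")
})

.oddsRatioCore <- function(k, level = 0.95, correct = FALSE, label = "") {
    stopifnot(level > 0, level < 1, all(k >= 0))
    corrected <- FALSE
    if (any(k == 0)) {
        if (!correct)
            stop("zero cell in the 2x2 table; the Wald log-OR is undefined. ",
                 "Set correct = TRUE for the Haldane-Anscombe +0.5 ",
                 "correction (changes the estimand).", call. = FALSE)
        k <- k + 0.5
        corrected <- TRUE
    }
    lo <- log(k[["a"]]) - log(k[["b"]]) - log(k[["c"]]) + log(k[["d"]])
    se <- sqrt(sum(1 / k))
    zc <- stats::qnorm(1 - (1 - level) / 2)
    z <- lo / se
    or <- exp(lo)
    new("ORResult", orPoint = or, logOR = lo, seLogOR = se,
        ciLow = exp(lo - zc * se), ciHigh = exp(lo + zc * se),
        level = level, z = z,
        pTwoSided = 2 * stats::pnorm(-abs(z)),
        xProportionPct = (or - 1) / or * 100,
        corrected = corrected, counts = k, label = label)
}

#' Proportion of lineage-borne genetic risk attributable to the X chromosome
#'
#' \deqn{(OR - 1)/OR \times 100\%.} An OR of 1 means no X-borne risk; an OR
#' of 1.2 puts 17\% of the risk on the X chromosome; an OR of 1.33 puts
#' 25\% there. The proportion is strictly increasing in OR and approaches
#' 100\% as OR grows. Values at or below zero (OR <= 1) are returned signed,
#' with the interpretation attribute \code{"no X-mediated risk detected"}
#' rather than being clamped, since OR < 1 is read as a null result.
#'
#' @param orPoint positive odds ratio (vectorized).
#' @return Signed percent(s); attribute \code{interpretation} flags
#'   non-positive values.
#' @examples
#' xAttributableProportion(1.2)    # ~16.7, rounds to 17
#' xAttributableProportion(1.33)   # ~24.8, rounds to 25
#' xAttributableProportion(1.0)    # 0
#' @export
xAttributableProportion <- function(orPoint) {
    if (any(!is.finite(orPoint)) || any(orPoint <= 0))
        stop("orPoint must be positive and finite", call. = FALSE)
    pct <- (orPoint - 1) / orPoint * 100
    if (any(pct <= 0))
        attr(pct, "interpretation") <- "no X-mediated risk detected"
    pct
}

#' @describeIn ORResult-class point odds ratio.
#' @export
setMethod("orPoint", "ORResult", function(x) x@orPoint)

#' @describeIn ORResult-class two-sided p-value.
#' @export
setMethod("pValue", "ORResult", function(x) x@pTwoSided)

#' @describeIn ORResult-class named confidence bounds (lower, upper).
#' @export
setMethod("confInt", "ORResult",
    function(x) c(lower = x@ciLow, upper = x@ciHigh))

#' @describeIn ORResult-class X-attributable proportion in percent.
#' @export
setMethod("xProportion", "ORResult", function(x) x@xProportionPct)

setMethod("show", "ORResult", function(object) {
    cat("Lineage odds ratio",
        if (nzchar(object@label)) paste0("(", object@label, ")"), "\n")
    cat(sprintf("  OR = %.2f, %d%% CI %.2f - %.2f (P = %.2f)\n",
                object@orPoint, round(object@level * 100),
                object@ciLow, object@ciHigh, object@pTwoSided))
    cat(sprintf("  X-attributable proportion: %.0f%%%s\n",
                object@xProportionPct,
                if (object@xProportionPct <= 0)
                    " (no X-mediated risk detected)" else ""))
    if (object@corrected)
        cat("  [Haldane-Anscombe +0.5 correction applied]\n")
    invisible(object)
})

#' @describeIn ORResult-class full-precision JSON report.
#' @param x,... object and arguments passed to \code{jsonlite::toJSON}.
#' @export
setMethod("reportJSON", "ORResult", function(x, ...) {
    jsonlite::toJSON(list(
        label = x@label, counts = as.list(x@counts),
        or_point = x@orPoint, log_or = x@logOR, se_log_or = x@seLogOR,
        level = x@level, ci_low = x@ciLow, ci_high = x@ciHigh,
        z = x@z, p_two_sided = x@pTwoSided,
        x_proportion_pct = x@xProportionPct,
        flags = c(if (x@corrected) "continuity_corrected",
                  if (x@xProportionPct <= 0) "no X-mediated risk detected")),
        auto_unbox = TRUE, digits = NA, null = "null", ...)
})
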