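#' @include AllClasses.R AllGenerics.R
NULL

.stratumKey <- function(sex, birth_start, born_in_state)
    paste(sex, birth_start, ifelse(born_in_state, "instate", "outstate"),
          sep = "|")

#' Cohort-specific disease death rates
#'
#' Builds a \code{\linkS4class{CohortRateTable}} from stratum death counts.
#' Cohorts are classified by sex, 5-year birth band (encoded half-open by
#' the band start year) and an in-state birthplace flag; the rate of each
#' stratum is the ratio of disease deaths to all deaths in the cohort.
#' These denominators are deaths, not person-years: the resulting expected
#' counts standardize the probands against the death-certificate
#' population, which differs from a conventional person-time SIR.
#'
#' @param strata data.frame with columns \code{sex}, \code{birth_start},
#'   \code{born_in_state}, \code{n_deaths}, \code{n_case_deaths}.
#' @return A \code{CohortRateTable}; strata with zero deaths carry an NA
#'   (undefined) rate and may not be referenced downstream.
#' @examples
#' rt <- cohortRates(data.frame(sex = "female", birth_start = 1900,
#'                              born_in_state = TRUE,
#'                              n_deaths = 1000, n_case_deaths = 30))
#' cohortStrata(rt)$rate   # 0.03
#' @export
cohortRates <- function(strata) {
    stopifnot(is.data.frame(strata),
              all(c("sex", "birth_start", "born_in_state",
                    "n_deaths", "n_case_deaths") %in% names(strata)))
    s <- strata
    s$sex <- tolower(as.character(s$sex))
    s$born_in_state <- as.logical(s$born_in_state)
    s$rate <- ifelse(s$n_deaths > 0, s$n_case_deaths / s$n_deaths, NA_real_)
    s$stratum <- .stratumKey(s$sex, s$birth_start, s$born_in_state)
    if (any(s$n_deaths == 0))
        warning(sum(s$n_deaths == 0),
                " stratum/strata with zero deaths: rate undefined",
                call. = FALSE)
    new("CohortRateTable",
        strata = s[, c("stratum", "sex", "birth_start", "born_in_state",
                       "n_deaths", "n_case_deaths", "rate")])
}

#' @describeIn CohortRateTable-class the stratum data.frame with rates.
#' @param x a \code{CohortRateTable}.
#' @export
setMethod("cohortStrata", "CohortRateTable", function(x) x@strata)

setMethod("show", "CohortRateTable", function(object) {
    cat("CohortRateTable with", nrow(object@strata), "strata\n")
    print(utils::head(object@strata, 6))
    if (nrow(object@strata) > 6) cat("...\n")
    invisible(object)
})

#' Expected case count by indirect standardization
#'
#' Multiplies the number of probands in each cohort stratum by that
#' stratum's disease rate and sums over strata:
#' \eqn{E = \sum_c n_c r_c}. Linear in the proband counts. Referencing a
#' stratum whose rate is undefined (zero deaths), or one absent from the
#' rate table, is an error.
#'
#' @param x a \code{\linkS4class{ConstellationCounts}} object, or a
#'   data.frame with columns \code{stratum} and \code{n_probands}.
#' @param rates a \code{\linkS4class{CohortRateTable}}.
#' @return The expected number of cases (non-negative real).
#' @aliases expectedCount
#' @export
setMethod("expectedCount", "ConstellationCounts", function(x, rates) {
    expectedCount(x@probands, rates)
})

#' @rdname expectedCount-ConstellationCounts-method
#' @export
setMethod("expectedCount", "data.frame", function(x, rates) {
    stopifnot(is(rates, "CohortRateTable"),
              all(c("stratum", "n_probands") %in% names(x)))
    s <- rates@strata
    i <- match(x$stratum, s$stratum)
    if (anyNA(i))
        stop("unknown stratum: ",
             paste(x$stratum[is.na(i)], collapse = ", "), call. = FALSE)
    r <- s$rate[i]
    if (anyNA(r))
        stop("constellation references rate-undefined (zero-death) ",
             "stratum: ", paste(x$stratum[is.na(r)], collapse = ", "),
             call. = FALSE)
    sum(x$n_probands * r)
})

## Garwood exact Poisson interval for the mean of an observed count.
## lower = qchisq(alpha/2, 2*O)/2 (0 when O = 0),
## upper = qchisq(1 - alpha/2, 2*(O + 1))/2.
.poissonExactCI <- function(observed, level = 0.95) {
    alpha <- 1 - level
    lo <- if (observed == 0) 0 else stats::qchisq(alpha / 2, 2 * observed) / 2
    hi <- stats::qchisq(1 - alpha / 2, 2 * (observed + 1)) / 2
    c(lower = lo, upper = hi)
}

## Two-sided exact Poisson test of mean == expected: sum the probabilities
## of all outcomes no more likely than the observed one (minimum-likelihood
## method). midp halves the contribution of outcomes exactly as likely as
## the observed count. normal is the z = (O - E)/sqrt(E) approximation.
.poissonExactP <- function(observed, expected,
                           method = c("exact", "midp", "normal")) {
    method <- match.arg(method)
    if (method == "normal") {
        z <- (observed - expected) / sqrt(expected)
        return(2 * stats::pnorm(-abs(z)))
    }
    upper <- ceiling(expected + 20 * sqrt(expected) + 20) + observed
    k <- 0:upper
    dk <- stats::dpois(k, expected)
    dobs <- stats::dpois(observed, expected)
    tol <- dobs * 1e-7
    lesser <- dk < dobs - tol
    equal <- abs(dk - dobs) <= tol
    p <- if (method == "midp")
        sum(dk[lesser]) + 0.5 * sum(dk[equal])
    else
        sum(dk[lesser]) + sum(dk[equal])
    min(1, p)
}

#' Observed/expected familial relative risk with exact Poisson inference
#'
#' The standardized familial relative risk RR = observed/expected, where
#' the expected count comes from \code{\link{expectedCount}}. The
#' confidence interval treats the observed count as Poisson: the exact
#' (Garwood) interval for its mean is obtained from chi-square quantiles
#' and divided by the expected count. The two-sided p-value is the exact
#' Poisson test of mean = expected, summing the probabilities of all
#' outcomes no more likely than the observed count; a mid-p variant and
#' the normal approximation \eqn{z = (O-E)/\sqrt{E}} are available for
#' sensitivity analysis.
#'
#' When observed = 0 the lower bound is 0 and the upper bound is the
#' one-sided exact bound.
#'
#' @param observed non-negative integer case count.
#' @param expected positive expected count.
#' @param level confidence level (default 0.95).
#' @param pMethod \code{"exact"} (default), \code{"midp"} or
#'   \code{"normal"}.
#' @param label constellation label carried into the result.
#' @return An \code{\linkS4class{RRResult}}.
#' @examples
#' res <- relativeRisk(582, 523.37)
#' res          # RR 1.11, 95% CI 1.02 - 1.21
#' @export
relativeRisk <- function(observed, expected, level = 0.95,
                         pMethod = c("exact", "midp", "normal"),
                         label = "") {
    pMethod <- match.arg(pMethod)
    if (!is.finite(expected) || expected <= 0)
        stop("expected must be > 0", call. = FALSE)
    if (observed < 0 || observed != round(observed))
        stop("observed must be a non-negative integer", call. = FALSE)
    ci <- .poissonExactCI(observed, level) / expected
    new("RRResult", observed = as.numeric(observed),
        expected = as.numeric(expected), rr = observed / expected,
        ciLow = ci[["lower"]], ciHigh = ci[["upper"]], level = level,
        pTwoSided = .poissonExactP(observed, expected, pMethod),
        pMethod = pMethod, label = as.character(label))
}

#' @describeIn RRResult-class two-sided p-value.
#' @param x an \code{RRResult}.
#' @export
setMethod("pValue", "RRResult", function(x) x@pTwoSided)

#' @describeIn RRResult-class named confidence bounds (lower, upper).
#' @export
setMethod("confInt", "RRResult",
    function(x) c(lower = x@ciLow, upper = x@ciHigh))

setMethod("show", "RRResult", function(object) {
    cat("Familial relative risk",
        if (nzchar(object@label)) paste0("(", object@label, ")"), "\n")
    cat(sprintf(
        "  Obs %d / Exp %.2f: RR = %.2f, %d%% CI %.2f - %.2f (P = %.2g, %s)\n",
        as.integer(object@observed), object@expected, object@rr,
        round(object@level * 100), object@ciLow, object@ciHigh,
        object@pTwoSided, object@pMethod))
    invisible(object)
})

#' @describeIn RRResult-class full-precision JSON report.
#' @param ... passed to \code{jsonlite::toJSON}.
#' @export
setMethod("reportJSON", "RRResult", function(x, ...) {
    jsonlite::toJSON(list(
        label = x@label, observed = x@observed, expected = x@expected,
        rr = x@rr, level = x@level, ci_low = x@ciLow, ci_high = x@ciHigh,
        p_two_sided = x@pTwoSided, p_method = x@pMethod),
        auto_unbox = TRUE, digits = NA, ...)
})
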