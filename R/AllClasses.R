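#' @import methods
NULL

## Controlled vocabularies for the sex x lineage cross-classification.
.SEX_LEVELS <- c("female", "male")
.LINEAGE_LEVELS <- c("paternal", "maternal")
.CHANNELS <- c("autosomal_22", "x_chromosome", "y_chromosome")
.DEGREE_LEVELS <- c("first", "second", "third")

#' Levels of the domain factors
#'
#' Controlled vocabularies used throughout the package: proband sex
#' (\code{"female"}, \code{"male"}), unilateral parental lineage side
#' (\code{"paternal"}, \code{"maternal"}), chromosomal transmission channels
#' (\code{"autosomal_22"}, \code{"x_chromosome"}, \code{"y_chromosome"}) and
#' relative-degree labels (\code{"first"}, \code{"second"}, \code{"third"}).
#'
#' @return A character vector of admissible level names.
#' @examples
#' sexLevels()
#' lineageLevels()
#' @export
sexLevels <- function() .SEX_LEVELS

#' @rdname sexLevels
#' @export
lineageLevels <- function() .LINEAGE_LEVELS

#' @rdname sexLevels
#' @export
transmissionChannels <- function() .CHANNELS

#' @rdname sexLevels
#' @export
degreeLevels <- function() .DEGREE_LEVELS

setClassUnion("characterOrNULL", c("character", "NULL"))

#' LineageCountTable: affected probands by sex and parental lineage
#'
#' The central 2x2 contingency table: counts of affected probands with
#' unilateral parental disease history, cross-classified by proband sex
#' (rows: female, male) and affected lineage side (columns: paternal,
#' maternal). The four cells are conventionally labelled
#' \code{a} (female/paternal), \code{b} (female/maternal),
#' \code{c} (male/paternal) and \code{d} (male/maternal).
#'
#' Bilateral family histories are not representable: every proband record
#' carries exactly one lineage side, and the CSV reader rejects rows
#' labelled otherwise.
#'
#' @slot counts 2x2 integer matrix, rows \code{female}/\code{male},
#'   columns \code{paternal}/\code{maternal}; all entries non-negative.
#' @slot label free-text label for the analysis (e.g. the relative degree
#'   that defined the family history).
#'
#' @param a,b,c,d non-negative integer cell counts (see above).
#' @param label optional analysis label.
#'
#' @return \code{LineageCountTable()} returns a validated object.
#' @examples
#' tab <- LineageCountTable(a = 37, b = 67, c = 25, d = 46,
#'                          label = "second-degree relatives")
#' lineageCounts(tab)
#' totalProbands(tab)
#' @aliases LineageCountTable
#' @export LineageCountTable
#' @exportClass LineageCountTable
setClass("LineageCountTable",
    representation(counts = "matrix", label = "character"),
    prototype(counts = matrix(0L, 2, 2,
                  dimnames = list(.SEX_LEVELS, .LINEAGE_LEVELS)),
              label = ""))

setValidity("LineageCountTable", function(object) {
    cnt <- object@counts
    msg <- character()
    if (!is.numeric(cnt) || !identical(dim(cnt), c(2L, 2L)))
        msg <- c(msg, "'counts' must be a 2x2 numeric matrix")
    else {
        if (!identical(rownames(cnt), .SEX_LEVELS) ||
            !identical(colnames(cnt), .LINEAGE_LEVELS))
            msg <- c(msg, "dimnames must be female/male x paternal/maternal")
        if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt)))
            msg <- c(msg, "all counts must be non-negative integers")
    }
    if (length(object@label) != 1L)
        msg <- c(msg, "'label' must be a single string")
    if (length(msg)) msg else TRUE
})

LineageCountTable <- function(a, b, c, d, label = "") {
    cnt <- matrix(as.integer(round(c(a, c, b, d))), nrow = 2, ncol = 2,
                  dimnames = list(.SEX_LEVELS, .LINEAGE_LEVELS))
    stopifnot(all(c(a, b, c, d) == round(c(a, b, c, d))),
              all(c(a, b, c, d) >= 0))
    new("LineageCountTable", counts = cnt, label = as.character(label))
}

#' ORResult: odds ratio over the sex-by-lineage table
#'
#' Result container for the lineage odds ratio
#' OR = (a/b) / (c/d), its Wald log-scale interval and normal test, and the
#' X-attributable proportion (OR - 1)/OR x 100.
#'
#' @slot orPoint point odds ratio (dimensionless).
#' @slot logOR natural log of the point estimate.
#' @slot seLogOR standard error of \code{logOR},
#'   sqrt(1/a + 1/b + 1/c + 1/d).
#' @slot ciLow,ciHigh confidence bounds, symmetric about the point on the
#'   log scale.
#' @slot level confidence level (default 0.95).
#' @slot z standard-normal statistic \code{logOR/seLogOR}.
#' @slot pTwoSided two-sided normal-tail p-value.
#' @slot xProportionPct (orPoint - 1)/orPoint x 100, signed percent.
#' @slot corrected \code{TRUE} if the Haldane-Anscombe +0.5 continuity
#'   correction was applied to a zero cell.
#' @slot counts named numeric vector (a, b, c, d) actually used (after any
#'   correction).
#' @slot label analysis label carried over from the input table.
#' @aliases ORResult
#' @exportClass ORResult
setClass("ORResult",
    representation(orPoint = "numeric", logOR = "numeric",
                   seLogOR = "numeric", ciLow = "numeric", ciHigh = "numeric",
                   level = "numeric", z = "numeric", pTwoSided = "numeric",
                   xProportionPct = "numeric", corrected = "logical",
                   counts = "numeric", label = "character"))

setValidity("ORResult", function(object) {
    msg <- character()
    if (object@orPoint <= 0) msg <- c(msg, "orPoint must be positive")
    if (!(object@ciLow <= object@orPoint && object@orPoint <= object@ciHigh))
        msg <- c(msg, "CI must bracket the point estimate")
    if (object@level <= 0 || object@level >= 1)
        msg <- c(msg, "level must be in (0,1)")
    if (length(msg)) msg else TRUE
})

#' RRResult: observed/expected familial relative risk
#'
#' Result of the indirectly standardized familial relative risk
#' RR = observed / expected, with an exact Poisson (Garwood) confidence
#' interval for the Poisson mean of the observed count divided by the
#' expected count, and a two-sided exact Poisson test of mean = expected.
#'
#' @slot observed observed case count among the probands.
#' @slot expected expected case count from cohort-specific rates (> 0).
#' @slot rr observed/expected.
#' @slot ciLow,ciHigh exact Poisson interval on the RR scale.
#' @slot level confidence level.
#' @slot pTwoSided two-sided exact Poisson p-value (minimum-likelihood
#'   method), or its mid-p or normal-approximation variant.
#' @slot pMethod one of \code{"exact"}, \code{"midp"}, \code{"normal"}.
#' @slot label constellation label.
#' @aliases RRResult
#' @exportClass RRResult
setClass("RRResult",
    representation(observed = "numeric", expected = "numeric",
                   rr = "numeric", ciLow = "numeric", ciHigh = "numeric",
                   level = "numeric", pTwoSided = "numeric",
                   pMethod = "character", label = "character"))

setValidity("RRResult", function(object) {
    msg <- character()
    if (object@expected <= 0) msg <- c(msg, "expected must be > 0")
    if (object@observed < 0 || object@observed != round(object@observed))
        msg <- c(msg, "observed must be a non-negative integer")
    if (object@observed > 0 &&
        !(object@ciLow <= object@rr && object@rr <= object@ciHigh))
        msg <- c(msg, "CI must bracket the RR")
    if (length(msg)) msg else TRUE
})

#' CohortRateTable: cohort-specific disease death rates
#'
#' Strata are cohorts classified by sex, 5-year birth band (half-open
#' [start, start + 5) on birth year) and in-state birthplace flag. The rate
#' in each stratum is the ratio of disease deaths to all deaths in the
#' cohort (a per-death proportion, not a person-year rate).
#'
#' @slot strata data.frame with columns \code{sex}, \code{birth_start},
#'   \code{born_in_state}, \code{n_deaths}, \code{n_case_deaths},
#'   \code{rate}, plus a \code{stratum} key. A stratum with zero deaths has
#'   an undefined (NA) rate and may not be referenced by any constellation.
#' @aliases CohortRateTable
#' @exportClass CohortRateTable
setClass("CohortRateTable", representation(strata = "data.frame"))

setValidity("CohortRateTable", function(object) {
    s <- object@strata
    need <- c("stratum", "sex", "birth_start", "born_in_state",
              "n_deaths", "n_case_deaths", "rate")
    if (!all(need %in% names(s)))
        return(paste("strata must have columns:", paste(need, collapse = ", ")))
    msg <- character()
    if (!all(s$sex %in% .SEX_LEVELS)) msg <- c(msg, "unknown sex level")
    if (any(s$n_case_deaths > s$n_deaths))
        msg <- c(msg, "n_case_deaths must not exceed n_deaths")
    if (any(s$n_deaths < 0) || any(s$n_case_deaths < 0))
        msg <- c(msg, "death counts must be non-negative")
    if (anyDuplicated(s$stratum)) msg <- c(msg, "duplicate stratum keys")
    ok <- s$n_deaths > 0
    if (any(abs(s$rate[ok] - s$n_case_deaths[ok] / s$n_deaths[ok]) > 1e-12))
        msg <- c(msg, "rates inconsistent with counts")
    if (any(!is.na(s$rate[!ok])))
        msg <- c(msg, "zero-death strata must have NA rate")
    if (length(msg)) msg else TRUE
})

#' ConstellationCounts: probands sharing one family-history constellation
#'
#' The probands carrying one family-history constellation (for example
#' "at least one affected maternal uncle"), counted per cohort stratum,
#' together with the observed number of case probands among them.
#'
#' @slot label constellation name.
#' @slot probands data.frame with columns \code{stratum} (key into a
#'   \code{CohortRateTable}) and \code{n_probands}.
#' @slot observed observed case count among the probands.
#' @aliases ConstellationCounts
#' @export ConstellationCounts
#' @exportClass ConstellationCounts
setClass("ConstellationCounts",
    representation(label = "character", probands = "data.frame",
                   observed = "integer"))

setValidity("ConstellationCounts", function(object) {
    p <- object@probands
    msg <- character()
    if (!all(c("stratum", "n_probands") %in% names(p)))
        msg <- c(msg, "probands needs columns stratum, n_probands")
    else if (any(p$n_probands < 0))
        msg <- c(msg, "proband counts must be non-negative")
    if (object@observed < 0)
        msg <- c(msg, "observed must be non-negative")
    if (all(c("stratum", "n_probands") %in% names(p)) &&
        object@observed > sum(p$n_probands))
        msg <- c(msg, "observed cannot exceed total probands")
    if (length(msg)) msg else TRUE
})

#' @param label constellation name.
#' @param probands data.frame with columns \code{stratum}, \code{n_probands}.
#' @param observed observed case count.
#' @rdname ConstellationCounts-class
#' @export
ConstellationCounts <- function(label, probands, observed) {
    new("ConstellationCounts", label = as.character(label),
        probands = as.data.frame(probands), observed = as.integer(observed))
}

#' SimConfig: generative parameters for the synthetic proband population
#'
#' Parameters of the multiplicative sex-linked liability model. Each
#' simulated proband draws a sex, a unilateral lineage side and an affected
#' flag; the per-cell affection probability is the baseline rate times the
#' autosomal relative risk, times the X relative risk when the X channel is
#' open for that (sex, lineage) cell, times the Y relative risk when the Y
#' channel is open (male probands with paternal lineage), times an optional
#' maternal-lineage multiplier (mitochondrial/gestational effects) applied
#' to both sexes equally.
#'
#' Under this model the odds ratio of the four cell probabilities equals
#' \code{rrX/rrY} exactly, whatever the priors, the baseline rate, the
#' autosomal component and the maternal multiplier — the estimand the
#' lineage odds ratio targets.
#'
#' @slot nProbands number of probands per simulated population.
#' @slot pFemale probability a proband is female.
#' @slot pMaternal probability the affected lineage is maternal.
#' @slot baselineRate disease probability with no transmissible genetic
#'   component (rare-disease regime; keep small).
#' @slot rrAutosomal,rrX,rrY relative risks of the autosomal, X-borne and
#'   Y-borne components (rrY = 1 encodes "negligible Y risk").
#' @slot maternalEffect multiplier on both maternal-lineage cells
#'   (default 1; cancels from the odds ratio).
#' @slot seed mandatory integer seed; fully determines the output.
#' @aliases SimConfig
#' @exportClass SimConfig
setClass("SimConfig",
    representation(nProbands = "integer", pFemale = "numeric",
                   pMaternal = "numeric", baselineRate = "numeric",
                   rrAutosomal = "numeric", rrX = "numeric", rrY = "numeric",
                   maternalEffect = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    inUnit <- function(x) length(x) == 1L && is.finite(x) && x > 0 && x < 1
    if (object@nProbands < 1L) msg <- c(msg, "nProbands must be >= 1")
    if (!inUnit(object@pFemale)) msg <- c(msg, "pFemale must be in (0,1)")
    if (!inUnit(object@pMaternal)) msg <- c(msg, "pMaternal must be in (0,1)")
    if (!inUnit(object@baselineRate))
        msg <- c(msg, "baselineRate must be in (0,1)")
    for (nm in c("rrAutosomal", "rrX", "rrY", "maternalEffect")) {
        v <- slot(object, nm)
        if (length(v) != 1L || !is.finite(v) || v < 0)
            msg <- c(msg, paste(nm, "must be a finite ratio >= 0"))
    }
    pmax_ <- object@baselineRate * object@rrAutosomal *
        max(object@rrX, object@rrY) * max(1, object@maternalEffect)
    if (is.finite(pmax_) && pmax_ > 1)
        msg <- c(msg, "cell probability would exceed 1; configuration rejected")
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "seed is mandatory")
    if (length(msg)) msg else TRUE
})

#' @param nProbands,pFemale,pMaternal,baselineRate numeric; see slots.
#' @param rrAutosomal,rrX,rrY,maternalEffect numeric ratios; see slots.
#' @param seed integer seed (mandatory, no default).
#' @rdname SimConfig-class
#' @export
SimConfig <- function(nProbands = 200000L, pFemale = 0.5, pMaternal = 0.5,
                      baselineRate = 0.01, rrAutosomal = 2, rrX = 1, rrY = 1,
                      maternalEffect = 1, seed) {
    if (missing(seed)) stop("'seed' is mandatory in SimConfig")
    new("SimConfig", nProbands = as.integer(nProbands),
        pFemale = as.numeric(pFemale), pMaternal = as.numeric(pMaternal),
        baselineRate = as.numeric(baselineRate),
        rrAutosomal = as.numeric(rrAutosomal), rrX = as.numeric(rrX),
        rrY = as.numeric(rrY), maternalEffect = as.numeric(maternalEffect),
        seed = as.integer(seed))
}

#' SimPopulation: a simulated proband population
#'
#' @slot records data.frame with one row per proband: \code{sex},
#'   \code{lineage} (factors over the package levels) and \code{affected}
#'   (logical).
#' @slot config the generating \code{SimConfig}.
#' @slot trueOR the estimand rrX/rrY under the generating model.
#' @aliases SimPopulation
#' @exportClass SimPopulation
setClass("SimPopulation",
    representation(records = "data.frame", config = "SimConfig",
                   trueOR = "numeric"))

setValidity("SimPopulation", function(object) {
    msg <- character()
    if (nrow(object@records) != object@config@nProbands)
        msg <- c(msg, "record count must equal nProbands")
    if (!all(c("sex", "lineage", "affected") %in% names(object@records)))
        msg <- c(msg, "records need columns sex, lineage, affected")
    if (length(msg)) msg else TRUE
})

setClassUnion("ORResultOrNULL", c("ORResult", "NULL"))

#' AnalysisReport: serializable record of one pipeline run
#'
#' Bundles the input, the estimates and provenance of one analysis so that
#' it can be written as JSON (full precision) and rendered as markdown
#' (report rounding: 2 decimals for OR/RR/CI, whole percent for the
#' X-attributable proportion).
#'
#' @slot label analysis label.
#' @slot input list describing the input (path, counts, ...).
#' @slot orResult an \code{ORResult}, or NULL for RR-only reports.
#' @slot rrResults list of \code{RRResult} objects (possibly empty).
#' @slot provenance list: package version, timestamp, seed and options.
#' @aliases AnalysisReport
#' @exportClass AnalysisReport
setClass("AnalysisReport",
    representation(label = "character", input = "list",
                   orResult = "ORResultOrNULL", rrResults = "list",
                   provenance = "list"))
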