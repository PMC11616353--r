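#' @include AllClasses.R AllGenerics.R lineage.R oddsRatio.R
NULL

#' Per-cell affection probabilities under the generative model
#'
#' Closed form for P(affected | sex, lineage): the baseline rate times the
#' autosomal relative risk, times rrX where the X channel is open (all
#' cells except male/paternal), times rrY where the Y channel is open
#' (male/paternal only), times the maternal-effect multiplier on both
#' maternal-lineage cells. The odds ratio of the four probabilities,
#' (p_FP/p_FM)/(p_MP/p_MM), collapses to rrX/rrY exactly: the baseline,
#' autosomal and maternal components, and any sex or lineage priors,
#' cancel — the model-level statement of the confounder-cancellation
#' argument behind the lineage odds ratio.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @return Named numeric vector of the four probabilities, names
#'   \code{female.paternal}, \code{female.maternal}, \code{male.paternal},
#'   \code{male.maternal}.
#' @examples
#' cfg <- SimConfig(rrX = 1.25, seed = 1)
#' p <- cellProbabilities(cfg)
#' (p[["female.paternal"]] / p[["female.maternal"]]) /
#'   (p[["male.paternal"]] / p[["male.maternal"]])   # 1.25
#' @aliases cellProbabilities
#' @export
setMethod("cellProbabilities", "SimConfig", function(config) {
    base <- config@baselineRate * config@rrAutosomal
    cells <- expand.grid(sex = .SEX_LEVELS, lineage = .LINEAGE_LEVELS,
                         stringsAsFactors = FALSE)
    p <- vapply(seq_len(nrow(cells)), function(i) {
        ch <- openChannels(cells$sex[i], cells$lineage[i], includeY = TRUE)
        base *
            (if ("x_chromosome" %in% ch) config@rrX else 1) *
            (if ("y_chromosome" %in% ch) config@rrY else 1) *
            (if (cells$lineage[i] == "maternal") config@maternalEffect else 1)
    }, numeric(1))
    names(p) <- paste(cells$sex, cells$lineage, sep = ".")
    if (any(p > 1)) stop("cell probability exceeds 1; invalid config",
                         call. = FALSE)
    p[c("female.paternal", "female.maternal",
        "male.paternal", "male.maternal")]
})

#' Simulate a proband population
#'
#' Draws \code{nProbands} records: sex ~ Bernoulli(pFemale), lineage ~
#' Bernoulli(pMaternal), affected ~ Bernoulli(cell probability). The seed
#' in the config fully determines the output; the caller's RNG state is
#' left untouched.
#'
#' @param config a \code{\linkS4class{SimConfig}} (seed mandatory).
#' @return A \code{\linkS4class{SimPopulation}}.
#' @examples
#' pop <- simulatePopulation(SimConfig(nProbands = 1000, seed = 7))
#' tabulateLineage(probandRecords(pop))
#' @aliases simulatePopulation
#' @export
setMethod("simulatePopulation", "SimConfig", function(config) {
    p <- cellProbabilities(config)
    n <- config@nProbands
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv()))
                rm(".Random.seed", envir = globalenv()))
    set.seed(config@seed)
    sex <- ifelse(stats::runif(n) < config@pFemale, "female", "male")
    lineage <- ifelse(stats::runif(n) < config@pMaternal,
                      "maternal", "paternal")
    pcell <- p[paste(sex, lineage, sep = ".")]
    affected <- stats::runif(n) < pcell
    new("SimPopulation",
        records = probandRecord(sex, lineage, affected),
        config = config, trueOR = config@rrX / config@rrY)
})

#' @describeIn SimPopulation-class the proband record data.frame.
#' @param x a \code{SimPopulation}.
#' @export
setMethod("probandRecords", "SimPopulation", function(x) x@records)

#' @describeIn SimPopulation-class the estimand rrX/rrY of the generating
#'   model.
#' @export
setMethod("trueOR", "SimPopulation", function(x) x@trueOR)

setMethod("show", "SimPopulation", function(object) {
    cat("SimPopulation:", nrow(object@records), "probands,",
        sum(object@records$affected), "affected; true OR =",
        signif(object@trueOR, 4), "\n")
    invisible(object)
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig\n")
    for (nm in slotNames(object))
        cat(sprintf("  %-14s %s\n", nm, format(slot(object, nm))))
    invisible(object)
})

#' Parameter-recovery experiment for the lineage odds ratio
#'
#' Runs simulate -> tabulate -> oddsRatio over \code{nReps} replicate
#' populations. Replicate r uses seed \code{config@seed + r} (a simple
#' counter scheme, reproducible and parallelizable). Replicates with a
#' zero cell are excluded from the summaries and their rate reported.
#'
#' @param config a \code{\linkS4class{SimConfig}}; its seed is the master
#'   seed.
#' @param nReps number of replicates (>= 2).
#' @param level nominal confidence level for the coverage assessment.
#' @return List with \code{true_or}; \code{n_reps}; \code{n_excluded} and
#'   \code{exclusion_rate} (zero-cell replicates); \code{or_mean},
#'   \code{or_median}, \code{or_bias} (mean minus true),
#'   \code{x_proportion_mean}, \code{x_proportion_median} (percent);
#'   \code{coverage} of the true OR by the nominal interval; and the
#'   per-replicate \code{or_points}.
#' @examples
#' recoveryExperiment(SimConfig(nProbands = 5000, rrX = 1.25, seed = 11),
#'                    nReps = 5)$or_median
#' @export
recoveryExperiment <- function(config, nReps, level = 0.95) {
    stopifnot(is(config, "SimConfig"), nReps >= 2)
    trueVal <- config@rrX / config@rrY
    ors <- rep(NA_real_, nReps)
    covered <- rep(NA, nReps)
    excluded <- 0L
    for (r in seq_len(nReps)) {
        cfg <- config
        cfg@seed <- config@seed + r
        pop <- simulatePopulation(cfg)
        tab <- tabulateLineage(probandRecords(pop))
        if (any(lineageCounts(tab) == 0)) {
            excluded <- excluded + 1L
            next
        }
        res <- oddsRatio(tab, level = level)
        ors[r] <- orPoint(res)
        ci <- confInt(res)
        covered[r] <- ci[["lower"]] <= trueVal && trueVal <= ci[["upper"]]
    }
    ok <- !is.na(ors)
    list(true_or = trueVal, n_reps = nReps,
         n_excluded = excluded, exclusion_rate = excluded / nReps,
         or_mean = if (any(ok)) mean(ors[ok]) else NA_real_,
         or_median = if (any(ok)) stats::median(ors[ok]) else NA_real_,
         or_bias = if (any(ok)) mean(ors[ok]) - trueVal else NA_real_,
         x_proportion_mean = if (any(ok))
             mean((ors[ok] - 1) / ors[ok] * 100) else NA_real_,
         x_proportion_median = if (any(ok))
             stats::median((ors[ok] - 1) / ors[ok] * 100) else NA_real_,
         coverage = if (any(ok)) mean(covered[ok]) else NA_real_,
         or_points = ors)
}

#' Read a simulator configuration from YAML or JSON
#'
#' Recognized fields: \code{n_probands}, \code{p_female}, \code{p_maternal},
#' \code{baseline_rate}, \code{rr_autosomal}, \code{rr_x}, \code{rr_y},
#' \code{maternal_effect}, \code{seed} (mandatory), and optionally
#' \code{n_reps} (returned as attribute \code{"n_reps"}). Unknown fields
#' are an error so that typos fail loudly.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A \code{\linkS4class{SimConfig}}.
#' @export
readSimConfig <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    known <- c("n_probands", "p_female", "p_maternal", "baseline_rate",
               "rr_autosomal", "rr_x", "rr_y", "maternal_effect",
               "seed", "n_reps")
    bad <- setdiff(names(raw), known)
    if (length(bad))
        stop("unknown simulator config field(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
    if (is.null(raw$seed))
        stop("simulator config schema error: 'seed' is mandatory",
             call. = FALSE)
    args <- list(seed = raw$seed)
    map <- c(n_probands = "nProbands", p_female = "pFemale",
             p_maternal = "pMaternal", baseline_rate = "baselineRate",
             rr_autosomal = "rrAutosomal", rr_x = "rrX", rr_y = "rrY",
             maternal_effect = "maternalEffect")
    for (nm in names(map))
        if (!is.null(raw[[nm]])) args[[map[[nm]]]] <- raw[[nm]]
    cfg <- do.call(SimConfig, args)
    if (!is.null(raw$n_reps)) attr(cfg, "n_reps") <- as.integer(raw$n_reps)
    cfg
}
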