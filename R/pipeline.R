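#' @include AllClasses.R AllGenerics.R oddsRatio.R familialRR.R simulate.R
NULL

.provenance <- function(input, options = list()) {
    list(package = "XLinkRisk",
         version = as.character(utils::packageVersion("XLinkRisk")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         input = input, options = options)
}

#' Path to a packaged fixture
#'
#' The package ships the published summary counts as CSV fixtures:
#' \code{table4_sdr.csv} (175 probands whose parental lineage was
#' determined by second-degree relatives), \code{table5_tdr.csv} (1850
#' probands, third-degree relatives), \code{tables23_rr.csv} (the
#' observed/expected rows behind them) and \code{sim_config.yaml}
#' (an example simulator configuration).
#'
#' @param name fixture file name; with no argument, lists the fixtures.
#' @return A file path, or a character vector of available names.
#' @examples
#' xlinkFixture()
#' readCountTable(xlinkFixture("table4_sdr.csv"))
#' @export
xlinkFixture <- function(name) {
    dir <- system.file("extdata", package = "XLinkRisk")
    if (missing(name)) return(list.files(dir))
    path <- file.path(dir, name)
    if (!file.exists(path))
        stop("no packaged fixture named '", name, "'; available: ",
             paste(list.files(dir), collapse = ", "), call. = FALSE)
    path
}

#' Run the lineage odds-ratio analysis on a count-table CSV
#'
#' Reads a sex-by-lineage count table (see \code{\link{readCountTable}}),
#' computes the odds ratio, interval, test and X-attributable proportion,
#' and wraps everything in an \code{\linkS4class{AnalysisReport}} with
#' provenance. Validation and zero-cell errors propagate with their
#' original messages.
#'
#' @param countTablePath path to the CSV.
#' @param level confidence level.
#' @param correct apply the +0.5 correction to zero cells?
#' @param label report label (defaults to the file name).
#' @return An \code{AnalysisReport}.
#' @examples
#' rep <- runORAnalysis(xlinkFixture("table5_tdr.csv"))
#' cat(renderMarkdown(rep))
#' @export
runORAnalysis <- function(countTablePath, level = 0.95, correct = FALSE,
                          label = NULL) {
    tab <- readCountTable(countTablePath, label = label)
    res <- oddsRatio(tab, level = level, correct = correct)
    new("AnalysisReport", label = tableLabel(tab),
        input = list(path = countTablePath,
                     counts = as.list(lineageCounts(tab)),
                     total = totalProbands(tab)),
        orResult = res, rrResults = list(),
        provenance = .provenance(countTablePath,
                                 list(level = level, correct = correct)))
}

#' Run observed/expected relative-risk analyses
#'
#' Two input modes. Summary mode: a CSV with columns \code{label},
#' \code{observed}, \code{expected} gives one RR per row. Cohort mode: a
#' cohort CSV (\code{sex}, \code{birth_start}, \code{born_in_state},
#' \code{n_deaths}, \code{n_case_deaths}) plus a constellation CSV
#' (\code{label}, \code{sex}, \code{birth_start}, \code{born_in_state},
#' \code{n_probands}, \code{observed}) first derives each constellation's
#' expected count by indirect standardization, then computes the RRs.
#' Rows with expected <= 0 are skipped with a warning and recorded in the
#' report provenance.
#'
#' @param obsExpPath CSV of (label, observed, expected) rows; or NULL in
#'   cohort mode.
#' @param cohortPath,constellationPath cohort-mode inputs.
#' @param level confidence level.
#' @param pMethod p-value method, see \code{\link{relativeRisk}}.
#' @return An \code{AnalysisReport} whose \code{rrResults} holds one
#'   \code{\linkS4class{RRResult}} per usable row.
#' @examples
#' rep <- runRRAnalysis(xlinkFixture("tables23_rr.csv"))
#' length(rrResults(rep))
#' @export
runRRAnalysis <- function(obsExpPath = NULL, cohortPath = NULL,
                          constellationPath = NULL, level = 0.95,
                          pMethod = "exact") {
    skipped <- character()
    if (!is.null(obsExpPath)) {
        df <- utils::read.csv(obsExpPath, stringsAsFactors = FALSE)
        names(df) <- tolower(names(df))
        if (!all(c("label", "observed", "expected") %in% names(df)))
            stop("expected columns label, observed, expected in ",
                 obsExpPath, call. = FALSE)
        input <- list(path = obsExpPath, mode = "summary")
    } else {
        if (is.null(cohortPath) || is.null(constellationPath))
            stop("provide either obsExpPath or both cohortPath and ",
                 "constellationPath", call. = FALSE)
        coh <- utils::read.csv(cohortPath, stringsAsFactors = FALSE)
        rates <- cohortRates(coh)
        con <- utils::read.csv(constellationPath, stringsAsFactors = FALSE)
        need <- c("label", "sex", "birth_start", "born_in_state",
                  "n_probands", "observed")
        if (!all(need %in% names(con)))
            stop("expected columns ", paste(need, collapse = ", "),
                 " in ", constellationPath, call. = FALSE)
        con$stratum <- .stratumKey(tolower(con$sex), con$birth_start,
                                   as.logical(con$born_in_state))
        df <- do.call(rbind, lapply(split(con, con$label), function(g) {
            data.frame(label = g$label[1],
                       observed = g$observed[1],
                       expected = expectedCount(
                           data.frame(stratum = g$stratum,
                                      n_probands = g$n_probands), rates))
        }))
        input <- list(path = c(cohortPath, constellationPath),
                      mode = "cohort")
    }
    results <- list()
    for (i in seq_len(nrow(df))) {
        if (!is.finite(df$expected[i]) || df$expected[i] <= 0) {
            warning("skipping '", df$label[i],
                    "': expected must be > 0", call. = FALSE)
            skipped <- c(skipped, df$label[i])
            next
        }
        results[[length(results) + 1L]] <-
            relativeRisk(df$observed[i], df$expected[i], level = level,
                         pMethod = pMethod, label = df$label[i])
    }
    new("AnalysisReport", label = "familial relative risk",
        input = input, orResult = NULL, rrResults = results,
        provenance = .provenance(input,
            list(level = level, pMethod = pMethod, skipped = skipped)))
}

#' Run a simulation / parameter-recovery experiment from a config file
#'
#' Loads a YAML or JSON \code{\linkS4class{SimConfig}} (field \code{seed}
#' mandatory, optional \code{n_reps}), runs
#' \code{\link{recoveryExperiment}}, and writes a JSON summary plus a
#' small human-readable table if an output directory is given.
#'
#' @param configPath path to the YAML/JSON config.
#' @param nReps replicate count; overrides the file's \code{n_reps}
#'   (default 100 when neither is given).
#' @param outDir optional output directory for \code{recovery_summary.json}
#'   and \code{recovery_summary.md}.
#' @return The recovery summary list, invisibly augmented with the config.
#' @export
runSimulation <- function(configPath, nReps = NULL, outDir = NULL) {
    cfg <- readSimConfig(configPath)
    if (is.null(nReps))
        nReps <- if (!is.null(attr(cfg, "n_reps"))) attr(cfg, "n_reps")
                 else 100L
    summ <- recoveryExperiment(cfg, nReps = nReps)
    summ$seed <- cfg@seed
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        jsonlite::write_json(summ[setdiff(names(summ), "or_points")],
                             file.path(outDir, "recovery_summary.json"),
                             auto_unbox = TRUE, digits = NA)
        md <- c("| quantity | value |", "|---|---|",
                sprintf("| true OR | %.4f |", summ$true_or),
                sprintf("| median OR | %.4f |", summ$or_median),
                sprintf("| mean OR | %.4f |", summ$or_mean),
                sprintf("| median X-proportion (%%) | %.1f |",
                        summ$x_proportion_median),
                sprintf("| CI coverage | %.3f |", summ$coverage),
                sprintf("| replicates (excluded) | %d (%d) |",
                        summ$n_reps, summ$n_excluded),
                sprintf("| master seed | %d |", summ$seed))
        writeLines(md, file.path(outDir, "recovery_summary.md"))
    }
    invisible(summ)
}

#' @describeIn AnalysisReport-class the list of RR results.
#' @param x an \code{AnalysisReport}.
#' @export
rrResults <- function(x) {
    stopifnot(is(x, "AnalysisReport"))
    x@rrResults
}

#' @describeIn AnalysisReport-class the OR result (or NULL).
#' @export
orResult <- function(x) {
    stopifnot(is(x, "AnalysisReport"))
    x@orResult
}

#' @describeIn AnalysisReport-class full-precision JSON serialization.
#' @param ... passed to \code{jsonlite::toJSON}.
#' @export
setMethod("reportJSON", "AnalysisReport", function(x, ...) {
    body <- list(label = x@label, input = x@input,
                 provenance = x@provenance)
    if (!is.null(x@orResult))
        body$or <- jsonlite::fromJSON(reportJSON(x@orResult))
    if (length(x@rrResults))
        body$rr <- lapply(x@rrResults,
                          function(r) jsonlite::fromJSON(reportJSON(r)))
    jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA, null = "null",
                     ...)
})

#' @describeIn AnalysisReport-class markdown rendering with report
#'   rounding (2 dp for OR/RR/CI, whole percent for the proportion).
#' @export
setMethod("renderMarkdown", "AnalysisReport", function(x, ...) {
    out <- c(paste("##", x@label), "")
    if (!is.null(x@orResult)) {
        o <- x@orResult
        k <- o@counts
        out <- c(out,
            sprintf("Counts (a,b,c,d): %s; total %s.",
                    paste(k, collapse = ", "), sum(k)),
            sprintf("OR %.2f (%.2f-%.2f), P = %.2f.",
                    o@orPoint, o@ciLow, o@ciHigh, o@pTwoSided),
            sprintf("X-attributable proportion: %.0f%%%s.",
                    o@xProportionPct,
                    if (o@xProportionPct <= 0)
                        " (no X-mediated risk detected)" else ""))
        if (o@corrected)
            out <- c(out, "Haldane-Anscombe +0.5 correction applied.")
    }
    if (length(x@rrResults)) {
        out <- c(out, "", "| constellation | Obs | Exp | RR | 95% CI | P |",
                 "|---|---|---|---|---|---|")
        for (r in x@rrResults)
            out <- c(out, sprintf(
                "| %s | %d | %.2f | %.2f | %.2f-%.2f | %.2g |",
                r@label, as.integer(r@observed), r@expected, r@rr,
                r@ciLow, r@ciHigh, r@pTwoSided))
    }
    paste(c(out, ""), collapse = "\n")
})

setMethod("show", "AnalysisReport", function(object) {
    cat(renderMarkdown(object))
    invisible(object)
})

#' Write an analysis report to disk
#'
#' Writes \code{<stem>.json} (full precision) and \code{<stem>.md}
#' (report rounding).
#'
#' @param report an \code{\linkS4class{AnalysisReport}}.
#' @param stem output path without extension.
#' @return The two paths, invisibly.
#' @export
writeReport <- function(report, stem) {
    jpath <- paste0(stem, ".json")
    mpath <- paste0(stem, ".md")
    writeLines(as.character(reportJSON(report)), jpath)
    writeLines(renderMarkdown(report), mpath)
    invisible(c(json = jpath, markdown = mpath))
}
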