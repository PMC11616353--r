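#' @include AllClasses.R
NULL

#' @export
setGeneric("oddsRatio", function(x, level = 0.95, correct = FALSE)
    standardGeneric("oddsRatio"))

#' @export
setGeneric("lineageCounts", function(x) standardGeneric("lineageCounts"))

#' @export
setGeneric("totalProbands", function(x) standardGeneric("totalProbands"))

#' @export
setGeneric("tableLabel", function(x) standardGeneric("tableLabel"))

#' @export
setGeneric("orPoint", function(x) standardGeneric("orPoint"))

#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))

#' @export
setGeneric("xProportion", function(x) standardGeneric("xProportion"))

#' @export
setGeneric("expectedCount", function(x, rates) standardGeneric("expectedCount"))

#' @export
setGeneric("cohortStrata", function(x) standardGeneric("cohortStrata"))

#' @export
setGeneric("cellProbabilities", function(config)
    standardGeneric("cellProbabilities"))

#' @export
setGeneric("simulatePopulation", function(config)
    standardGeneric("simulatePopulation"))

#' @export
setGeneric("probandRecords", function(x) standardGeneric("probandRecords"))

#' @export
setGeneric("trueOR", function(x) standardGeneric("trueOR"))

#' @export
setGeneric("reportJSON", function(x, ...) standardGeneric("reportJSON"))

#' @export
setGeneric("renderMarkdown", function(x, ...) standardGeneric("renderMarkdown"))
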