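#' @include AllClasses.R AllGenerics.R
NULL

#' Open transmission channels for a (sex, lineage) cell
#'
#' Which chromosomal channels can carry lineage-borne genetic risk to a
#' proband. Every proband inherits the 22 autosomes from both parents, so
#' the autosomal channel is always open. A female proband receives an X
#' chromosome from each parent, so the X channel is open on both lineage
#' sides; a male proband receives his single X from his mother, so the X
#' channel is open only for maternal lineage. Father-to-son transmission of
#' the Y chromosome opens the Y channel for (male, paternal) when
#' \code{includeY = TRUE}; by default the Y-borne risk is treated as
#' negligible and the channel is omitted.
#'
#' @param sex \code{"female"} or \code{"male"}.
#' @param lineage \code{"paternal"} or \code{"maternal"}.
#' @param includeY include the Y channel for father-to-son transmission?
#' @return Character vector of channel names; always contains
#'   \code{"autosomal_22"}.
#' @examples
#' openChannels("female", "paternal")           # autosomes + X
#' openChannels("male",   "paternal")           # autosomes only
#' openChannels("male",   "paternal", TRUE)     # autosomes + Y
#' @export
openChannels <- function(sex, lineage, includeY = FALSE) {
    sex <- match.arg(sex, .SEX_LEVELS)
    lineage <- match.arg(lineage, .LINEAGE_LEVELS)
    ch <- "autosomal_22"
    if (!(sex == "male" && lineage == "paternal"))
        ch <- c(ch, "x_chromosome")
    if (includeY && sex == "male" && lineage == "paternal")
        ch <- c(ch, "y_chromosome")
    ch
}

#' Build a proband record data.frame
#'
#' Convenience constructor for the record layout used by
#' \code{\link{tabulateLineage}} and returned in simulated populations.
#' Each proband carries exactly one lineage side (bilateral histories are
#' not representable).
#'
#' @param sex,lineage character vectors over the package levels.
#' @param affected logical vector.
#' @param degree optional relative-degree label (\code{"first"},
#'   \code{"second"}, \code{"third"}).
#' @return data.frame with factor columns \code{sex}, \code{lineage},
#'   logical \code{affected} and optionally \code{degree}.
#' @export
probandRecord <- function(sex, lineage, affected, degree = NULL) {
    stopifnot(all(sex %in% .SEX_LEVELS), all(lineage %in% .LINEAGE_LEVELS),
              is.logical(as.logical(affected)))
    df <- data.frame(
        sex = factor(sex, levels = .SEX_LEVELS),
        lineage = factor(lineage, levels = .LINEAGE_LEVELS),
        affected = as.logical(affected))
    if (!is.null(degree)) {
        stopifnot(all(degree %in% .DEGREE_LEVELS))
        df$degree <- factor(degree, levels = .DEGREE_LEVELS)
    }
    df
}

#' Tabulate affected probands into a LineageCountTable
#'
#' Counts affected proband records in each (sex, lineage) cell; unaffected
#' records contribute nothing. Counting is permutation-invariant and
#' additive over concatenated record sets.
#'
#' @param records data.frame as produced by \code{\link{probandRecord}} or
#'   \code{\link{probandRecords}} on a simulated population.
#' @param label analysis label stored on the resulting table.
#' @return A \code{\linkS4class{LineageCountTable}}.
#' @examples
#' rec <- probandRecord(c("female", "male"), c("paternal", "maternal"),
#'                      c(TRUE, TRUE))
#' lineageCounts(tabulateLineage(rec))
#' @export
tabulateLineage <- function(records, label = "") {
    stopifnot(is.data.frame(records),
              all(c("sex", "lineage", "affected") %in% names(records)))
    aff <- records[as.logical(records$affected), , drop = FALSE]
    cnt <- table(factor(aff$sex, levels = .SEX_LEVELS),
                 factor(aff$lineage, levels = .LINEAGE_LEVELS))
    LineageCountTable(a = cnt["female", "paternal"],
                      b = cnt["female", "maternal"],
                      c = cnt["male", "paternal"],
                      d = cnt["male", "maternal"], label = label)
}

#' @describeIn LineageCountTable-class named cell counts (a, b, c, d).
#' @export
setMethod("lineageCounts", "LineageCountTable", function(x) {
    cnt <- x@counts
    c(a = cnt["female", "paternal"], b = cnt["female", "maternal"],
      c = cnt["male", "paternal"], d = cnt["male", "maternal"])
})

#' @describeIn LineageCountTable-class total proband count a+b+c+d.
#' @export
setMethod("totalProbands", "LineageCountTable",
    function(x) sum(x@counts))

#' @describeIn LineageCountTable-class the analysis label.
#' @export
setMethod("tableLabel", "LineageCountTable", function(x) x@label)

setMethod("show", "LineageCountTable", function(object) {
    cat("LineageCountTable",
        if (nzchar(object@label)) paste0("(", object@label, ")"), "\n")
    print(object@counts)
    cat("total probands:", sum(object@counts), "\n")
    invisible(object)
})

.validateCountCell <- function(count, where) {
    count <- suppressWarnings(as.numeric(count))
    if (anyNA(count) || any(count < 0) || any(count != round(count)))
        stop("invalid count in ", where,
             ": counts must be non-negative integers", call. = FALSE)
    as.integer(count)
}

#' Read and write lineage count tables as CSV
#'
#' Two dialects are accepted and auto-detected from the header:
#' \describe{
#'   \item{long}{columns \code{sex}, \code{lineage}, \code{count}; one row
#'     per cell (duplicate cells are summed).}
#'   \item{wide}{columns \code{sex}, \code{paternal}, \code{maternal}; one
#'     row per sex.}
#' }
#' Unknown sex or lineage labels — including \code{"both"}, since a proband
#' record carries exactly one lineage side — and negative or non-integer
#' counts raise validation errors. \code{writeCountTable} writes the long
#' dialect; write followed by read is the identity.
#'
#' @param path CSV file path.
#' @param label label stored on the table (defaults to the file name).
#' @return \code{readCountTable} returns a
#'   \code{\linkS4class{LineageCountTable}}.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeCountTable(LineageCountTable(629, 582, 343, 296), tf)
#' totalProbands(readCountTable(tf))   # 1850
#' @export
readCountTable <- function(path, label = NULL) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          strip.white = TRUE)
    names(df) <- tolower(names(df))
    if (is.null(label)) label <- basename(path)
    if (all(c("sex", "lineage", "count") %in% names(df))) {
        df$sex <- tolower(trimws(df$sex))
        df$lineage <- tolower(trimws(df$lineage))
        bad <- !df$sex %in% .SEX_LEVELS
        if (any(bad))
            stop("unknown sex label(s): ",
                 paste(unique(df$sex[bad]), collapse = ", "), call. = FALSE)
        bad <- !df$lineage %in% .LINEAGE_LEVELS
        if (any(bad))
            stop("unknown lineage label(s): ",
                 paste(unique(df$lineage[bad]), collapse = ", "),
                 "; probands must have a unilateral (paternal or maternal) ",
                 "lineage", call. = FALSE)
        df$count <- .validateCountCell(df$count, path)
        cell <- function(s, l) sum(df$count[df$sex == s & df$lineage == l])
        LineageCountTable(a = cell("female", "paternal"),
                          b = cell("female", "maternal"),
                          c = cell("male", "paternal"),
                          d = cell("male", "maternal"), label = label)
    } else if (all(c("sex", "paternal", "maternal") %in% names(df))) {
        df$sex <- tolower(trimws(df$sex))
        if (!setequal(df$sex, .SEX_LEVELS) || nrow(df) != 2L)
            stop("wide layout needs exactly one female and one male row",
                 call. = FALSE)
        pat <- .validateCountCell(df$paternal, path)
        mat <- .validateCountCell(df$maternal, path)
        i <- match(.SEX_LEVELS, df$sex)
        LineageCountTable(a = pat[i[1]], b = mat[i[1]],
                          c = pat[i[2]], d = mat[i[2]], label = label)
    } else {
        stop("unrecognized count-table header; expected columns ",
             "(sex, lineage, count) or (sex, paternal, maternal)",
             call. = FALSE)
    }
}

#' @param table a \code{LineageCountTable}.
#' @rdname readCountTable
#' @export
writeCountTable <- function(table, path) {
    stopifnot(is(table, "LineageCountTable"))
    k <- lineageCounts(table)
    df <- data.frame(
        sex = c("female", "female", "male", "male"),
        lineage = c("paternal", "maternal", "paternal", "maternal"),
        count = as.integer(k))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' JSON serialization of a lineage count table
#'
#' @param x a \code{LineageCountTable}.
#' @param ... passed to \code{jsonlite::toJSON}.
#' @return JSON string with the label, the four cells and the total.
#' @export
setMethod("reportJSON", "LineageCountTable", function(x, ...) {
    k <- lineageCounts(x)
    jsonlite::toJSON(list(label = x@label, counts = as.list(k),
                          total = sum(k)), auto_unbox = TRUE, ...)
})
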