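# Two-group inference from printed summary statistics (mean, SD, n) and the
# packaged clinical comparison tables.

#' Two-sample t statistic from group summaries
#'
#' \deqn{t = \frac{|\bar x_1 - \bar x_2|}
#'            {\sqrt{s_1^2/n_1 + s_2^2/n_2}}}
#' With equal group sizes this coincides with the pooled-variance two-sample
#' t, so the Welch/pooled distinction is moot for balanced designs. The
#' unsigned value is returned, matching the convention of clinical tables
#' that print positive t regardless of direction.
#'
#' @param a,b \linkS4class{GroupSummary} objects.
#' @return The nonnegative t statistic.
#' @examples
#' tFromSummaries(groupSummary(9.43, 2.25, 36),
#'                groupSummary(16.07, 2.87, 36))  # 10.924...
#' @export
tFromSummaries <- function(a, b) {
    stopifnot(is(a, "GroupSummary"), is(b, "GroupSummary"))
    abs(a@mean - b@mean) / sqrt(a@sd^2 / a@n + b@sd^2 / b@n)
}

#' Pearson chi-squared statistic for a 2x2 count table
#'
#' The standard Pearson statistic without continuity correction,
#' equivalently \eqn{n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))} for a 2x2 table.
#'
#' @param counts 2x2 matrix of nonnegative integer counts; all row and
#'   column marginals must be positive.
#' @return The nonnegative statistic.
#' @examples
#' chiSquare2x2(matrix(c(20, 19, 16, 17), 2))
#' @export
chiSquare2x2 <- function(counts) {
    counts <- as.matrix(counts)
    if (!all(dim(counts) == 2L))
        stop("invalid input: counts must be a 2x2 table")
    if (any(counts < 0) || any(counts != round(counts)))
        stop("invalid input: counts must be nonnegative integers")
    if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
        stop("invalid input: zero marginal in the 2x2 table")
    unname(suppressWarnings(
        stats::chisq.test(counts, correct = FALSE))$statistic)
}

#' Path to the packaged clinical comparison table fixture
#'
#' Tab-separated mirror of the published three-table clinical comparison
#' (cardiac function; inflammatory factors and vascular endothelial
#' function; serum NO, NOS and iNOS), one row per variable and timepoint:
#' observation-group mean/SD, control-group mean/SD, group size n = 36, and
#' the printed t value. Units are preserved verbatim from the source tables,
#' including their oddities (ET-1 in umol/L; NOS and iNOS in U/L at 0.03
#' scale).
#'
#' @return File path of the TSV fixture.
#' @export
clinicalTablesPath <- function() {
    system.file("extdata", "clinical_tables.tsv", package = "tensorCut",
                mustWork = TRUE)
}

#' Read a comparison-table fixture
#'
#' @param path TSV with columns \code{table, variable, timepoint, obs_mean,
#'   obs_sd, ctrl_mean, ctrl_sd, n, printed_t}; defaults to the packaged
#'   clinical tables.
#' @return A data.frame, one comparison row per line.
#' @export
readComparisonTable <- function(path = clinicalTablesPath()) {
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = TRUE)
}

#' Recompute and verify printed t statistics
#'
#' For every fixture row, recomputes the two-sample t from the printed
#' mean/SD/n cells and compares it with the printed t at the given absolute
#' tolerance (default 0.001, i.e. agreement at the printed 3-decimal
#' precision). Mismatches are reported, not raised.
#'
#' @param rows a fixture data.frame as returned by
#'   \code{\link{readComparisonTable}}.
#' @param tol absolute tolerance on |computed - printed|.
#' @return The input with columns \code{computed_t} and \code{pass} added.
#' @examples
#' report <- verifyTableFixture()
#' all(report$pass)
#' @export
verifyTableFixture <- function(rows = readComparisonTable(), tol = 0.001) {
    if (!nrow(rows)) {
        rows$computed_t <- numeric(0)
        rows$pass <- logical(0)
        return(rows)
    }
    rows$computed_t <- vapply(seq_len(nrow(rows)), function(k)
        tFromSummaries(
            groupSummary(rows$obs_mean[k], rows$obs_sd[k], rows$n[k]),
            groupSummary(rows$ctrl_mean[k], rows$ctrl_sd[k], rows$n[k])),
        numeric(1))
    rows$pass <- abs(rows$computed_t - rows$printed_t) <= tol
    rows
}
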