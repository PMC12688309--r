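# Descriptive comparison tables: group means/SDs or counts/percentages by
# outcome status with t-tests and chi-squared tests.

#' Pearson chi-squared test of independence
#'
#' Pearson statistic without continuity correction on a full contingency
#' table, `df = (r-1)(c-1)`.
#'
#' @param table matrix (or table) of nonnegative counts.
#' @return List with `statistic`, `df`, `p_value`, and the `expected`
#'   counts.
#' @export
chi_square_test <- function(table) {
  x <- as.matrix(table)
  if (any(!is.finite(x)) || any(x < 0))
    stop_invalid("contingency table must contain finite nonnegative counts")
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop_invalid("contingency table must be at least 2x2")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0))
    stop_invalid("invalid table: a zero row or column marginal leaves expected counts undefined")
  ht <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = ht$expected)
}

#' Descriptive comparison by outcome status
#'
#' For each requested variable, compares the outcome groups the way survey
#' descriptive tables do: continuous variables get mean and SD per group
#' with a two-sample t-test (Welch by default), categorical variables get
#' counts and percentages per group (denominator = outcome-group total) with
#' a Pearson chi-squared test over the full contingency table.
#'
#' @param data cohort data frame.
#' @param outcome name of a binary (2-level factor) column.
#' @param variables character vector of columns to describe.
#' @param t_test `"welch"` (default) or `"pooled"` variance flavour.
#' @return A data frame of class `descriptive_table`: one row per variable
#'   level (or one row per continuous variable) with `value_*` (count or
#'   mean) and `spread_*` (percentage or SD) for the no/yes/total groups,
#'   plus the test statistic, df, p-value and test name. Percentages and
#'   means are stored unrounded.
#' @export
describe_by_outcome <- function(data, outcome, variables,
                                t_test = c("welch", "pooled")) {
  t_test <- match.arg(t_test)
  if (!outcome %in% names(data)) stop_invalid("outcome column '%s' not found", outcome)
  g <- factor(data[[outcome]])
  if (nlevels(droplevels(g)) != 2L)
    stop_invalid("degenerate group: outcome '%s' does not split the data in two", outcome)
  miss <- setdiff(variables, names(data))
  if (length(miss)) stop_invalid("variable(s) not found: %s", paste(miss, collapse = ", "))
  lv <- levels(droplevels(g))
  rows <- lapply(variables, function(v) {
    x <- data[[v]]
    ok <- !is.na(x)
    xi <- x[ok]; gi <- droplevels(g[ok])
    if (is.numeric(xi)) {
      ht <- stats::t.test(xi ~ gi, var.equal = (t_test == "pooled"))
      data.frame(variable = v, level = NA_character_, measure = "mean_sd",
                 value_no = mean(xi[gi == lv[1]]), spread_no = stats::sd(xi[gi == lv[1]]),
                 value_yes = mean(xi[gi == lv[2]]), spread_yes = stats::sd(xi[gi == lv[2]]),
                 value_total = mean(xi), spread_total = stats::sd(xi),
                 statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value,
                 test = if (t_test == "welch") "Welch t-test" else "pooled t-test")
    } else {
      xi <- droplevels(factor(xi))
      tab <- table(xi, gi)
      ht <- chi_square_test(tab)
      n_no <- sum(tab[, lv[1]]); n_yes <- sum(tab[, lv[2]])
      data.frame(variable = v, level = rownames(tab), measure = "count_pct",
                 value_no = as.vector(tab[, lv[1]]),
                 spread_no = 100 * as.vector(tab[, lv[1]]) / n_no,
                 value_yes = as.vector(tab[, lv[2]]),
                 spread_yes = 100 * as.vector(tab[, lv[2]]) / n_yes,
                 value_total = as.vector(rowSums(tab)),
                 spread_total = 100 * as.vector(rowSums(tab)) / (n_no + n_yes),
                 statistic = ht$statistic, df = ht$df, p_value = ht$p_value,
                 test = "Pearson chi-squared")
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("descriptive_table", "data.frame")
  out
}

#' Printed survey descriptive counts (Table-1-style fixture)
#'
#' Cell counts of the 2018 national risk-factor survey sample by overweight
#' status, as published: sex, education, physical-activity level and
#' fruit/vegetable adequacy cross-classified with overweight (no: n = 5,268;
#' yes: n = 11,142; total 16,410). The fruit/vegetable rows are known to be
#' typographically inconsistent in the published table (their margins do not
#' reconcile with the group totals) and should not be used as a calibration
#' anchor.
#'
#' @return A data frame with columns `variable`, `level`, `count_no`,
#'   `count_yes`.
#' @export
enfr_table1_counts <- function() {
  utils::read.csv(system.file("extdata", "enfr_table1_counts.csv",
                              package = "climmed"),
                  stringsAsFactors = FALSE)
}

#' Expand printed cell counts into an individual-level data frame
#'
#' Turns rows of a counts table for one variable into one row per
#' individual, with the variable and a binary outcome column — the input
#' shape for oracle checks that refit models on published contingency
#' tables.
#'
#' @param counts as returned by [enfr_table1_counts()].
#' @param variable which variable to expand.
#' @param levels optional level ordering (first = reference).
#' @return Data frame with columns `outcome` (factor no/yes) and the
#'   variable (factor).
#' @export
expand_table1 <- function(counts, variable, levels = NULL) {
  cc <- counts[counts$variable == variable, , drop = FALSE]
  if (!nrow(cc)) stop_invalid("variable '%s' not present in counts", variable)
  lv <- levels %||% cc$level
  out <- data.frame(
    outcome = factor(rep(rep(c("no", "yes"), nrow(cc)),
                         as.vector(t(cc[, c("count_no", "count_yes")]))),
                     levels = c("no", "yes")),
    value = factor(rep(cc$level, cc$count_no + cc$count_yes), levels = lv))
  names(out)[2] <- variable
  out
}
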