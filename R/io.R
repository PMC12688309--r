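# Cohort CSV schema: fixed header, lower-case category tokens, missing
# fruit/vegetable status written as an empty field.

.cohort_columns <- c("province_id", "mean_temp_c", "sex", "age", "education",
                     "fv_adequate", "pa_level", "overweight", "obesity")

.cohort_tokens <- list(
  sex = c("male", "female"),
  education = .education_levels,
  fv_adequate = c("no", "yes"),
  pa_level = .pa_levels,
  overweight = c("no", "yes"),
  obesity = c("no", "yes"))

#' Write a cohort to CSV
#'
#' Writes the documented cohort schema: columns `province_id, mean_temp_c,
#' sex, age, education, fv_adequate, pa_level, overweight, obesity`,
#' categories as lower-case tokens, missing fruit/vegetable status as an
#' empty field. Numeric columns are written with 17 significant digits so
#' that [load_cohort_csv()] round-trips bit-identically.
#'
#' @param cohort cohort data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  miss <- setdiff(.cohort_columns, names(cohort))
  if (length(miss)) stop_invalid("cohort lacks column(s): %s", paste(miss, collapse = ", "))
  out <- cohort[.cohort_columns]
  out$mean_temp_c <- sprintf("%.17g", out$mean_temp_c)
  out$age <- sprintf("%.17g", out$age)
  for (v in names(.cohort_tokens)) out[[v]] <- as.character(out[[v]])
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Load a cohort from CSV
#'
#' Reads and validates a cohort file against the documented schema: the
#' header must contain the nine required columns, every category cell must
#' be one of the allowed lower-case tokens (empty allowed only for
#' `fv_adequate`, parsed as missing), temperature must be constant within a
#' province, and only `fv_adequate` may be missing. Row numbers are reported
#' in schema errors; the row count and the number of missing mediator
#' values are logged via `message()`.
#'
#' @param path CSV file path.
#' @return A validated cohort data frame with the package's factor levels
#'   (reference categories first).
#' @export
load_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = NULL)
  miss <- setdiff(.cohort_columns, names(raw))
  if (length(miss))
    stop_invalid("missing required column(s): %s", paste(miss, collapse = ", "))
  raw <- raw[.cohort_columns]
  for (v in names(.cohort_tokens)) {
    vals <- raw[[v]]
    allowed <- .cohort_tokens[[v]]
    blank <- vals == ""
    if (v != "fv_adequate" && any(blank))
      stop_invalid("column '%s' has a missing value at row %d", v, which(blank)[1])
    bad <- !blank & !(vals %in% allowed)
    if (any(bad))
      stop_invalid("column '%s' has unknown token '%s' at row %d",
                   v, vals[which(bad)[1]], which(bad)[1])
  }
  num <- function(v) {
    x <- suppressWarnings(as.numeric(raw[[v]]))
    if (anyNA(x))
      stop_invalid("column '%s' is not numeric at row %d", v, which(is.na(x))[1])
    x
  }
  cohort <- data.frame(
    province_id = {
      x <- num("province_id")
      if (any(x != round(x))) stop_invalid("column 'province_id' must be integer")
      as.integer(x)
    },
    mean_temp_c = num("mean_temp_c"),
    sex = factor(raw$sex, levels = .cohort_tokens$sex),
    age = num("age"),
    education = factor(raw$education, levels = .education_levels),
    fv_adequate = factor(ifelse(raw$fv_adequate == "", NA, raw$fv_adequate),
                         levels = c("no", "yes")),
    pa_level = factor(raw$pa_level, levels = .pa_levels),
    overweight = factor(raw$overweight, levels = c("no", "yes")),
    obesity = factor(raw$obesity, levels = c("no", "yes")))
  by_prov <- tapply(cohort$mean_temp_c, cohort$province_id,
                    function(x) diff(range(x)))
  if (any(by_prov > 0))
    stop_invalid("mean_temp_c is not constant within province %s",
                 names(which(by_prov > 0))[1])
  n_missing <- sum(is.na(cohort$fv_adequate))
  message(sprintf("loaded %d rows (%d with missing fv_adequate)",
                  nrow(cohort), n_missing))
  cohort
}
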