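#' Per-tract covariate and count table
#'
#' The central data container: one row per census tract with its identifier,
#' household total, outlet count and the socioeconomic covariates that enter
#' the disadvantage index.  Rows with missing covariate cells are flagged at
#' construction and removed later by [filter_missing()] (mirroring the usual
#' exclude-then-model workflow for survey-derived tract covariates).
#'
#' @param df data frame holding at least the id, household and count columns.
#' @param id,households,count column names.
#' @param covariates character vector of covariate column names; defaults to
#'   every remaining numeric column.
#' @return `df` classed as `tract_table` with attributes `id_col`,
#'   `households_col`, `count_col`, `covariate_cols`.
#' @export
tract_table <- function(df, id = "tract_id", households = "households",
                        count = "count", covariates = NULL) {
  for (col in c(id, households, count))
    if (!col %in% names(df))
      stop("required column '", col, "' not found")
  if (is.null(covariates))
    covariates <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
                          c(households, count))
  missing_cov <- setdiff(covariates, names(df))
  if (length(missing_cov))
    stop("covariate column(s) not found: ", paste(missing_cov, collapse = ", "))
  ids <- as.character(df[[id]])
  if (anyDuplicated(ids))
    stop("duplicated tract_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (col in c(households, count)) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v != round(v)))
      stop("column '", col, "' must hold non-negative integers")
  }
  structure(df, class = c("tract_table", "data.frame"),
            id_col = id, households_col = households, count_col = count,
            covariate_cols = covariates)
}

# internal accessors
tt_ids <- function(x) as.character(x[[attr(x, "id_col")]])
tt_h   <- function(x) as.integer(x[[attr(x, "households_col")]])
tt_y   <- function(x) as.integer(x[[attr(x, "count_col")]])
tt_cov <- function(x) as.matrix(x[, attr(x, "covariate_cols"), drop = FALSE])

#' @export
print.tract_table <- function(x, ...) {
  cat("Tract table: ", nrow(x), " tracts, ",
      length(attr(x, "covariate_cols")), " covariates; ",
      sum(apply(is.na(tt_cov(x)), 1, any)), " tract(s) with missing cells\n",
      sep = "")
  NextMethod()
}

#' Read a tract table from CSV
#'
#' @param path CSV file with a header row.
#' @inheritParams tract_table
#' @return a [tract_table()].
#' @export
read_tract_table <- function(path, id = "tract_id", households = "households",
                             count = "count", covariates = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  for (col in c(id, households, count))
    if (!col %in% names(df)) stop("required column '", col, "' not found in ", path)
  if (is.null(covariates))
    covariates <- setdiff(names(df), c(id, households, count))
  num_cols <- c(households, count, covariates)
  for (col in num_cols) {
    if (!col %in% names(df)) stop("covariate column '", col, "' not found in ", path)
    raw <- trimws(df[[col]])
    raw[raw == ""] <- NA
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(v))
    if (length(bad))
      stop("non-numeric value '", raw[bad[1L]], "' in column '", col,
           "', row ", bad[1L])
    df[[col]] <- v
  }
  tract_table(df, id = id, households = households, count = count,
              covariates = covariates)
}

#' Drop tracts with missing covariate values
#'
#' Tracts missing any covariate are excluded before modelling; the exclusion
#' report records each dropped tract and the offending variables.
#'
#' @param table a [tract_table()].
#' @return the filtered `tract_table`, with attribute `"exclusions"`: a data
#'   frame of `tract_id` and comma-separated `missing_variables`.
#' @export
filter_missing <- function(table) {
  stopifnot(inherits(table, "tract_table"))
  xm <- tt_cov(table)
  miss <- is.na(xm)
  drop <- which(apply(miss, 1, any))
  report <- data.frame(
    tract_id = tt_ids(table)[drop],
    missing_variables = vapply(drop, function(i)
      paste(colnames(xm)[miss[i, ]], collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  out <- table[setdiff(seq_len(nrow(table)), drop), , drop = FALSE]
  attrs <- attributes(table)
  for (a in c("id_col", "households_col", "count_col", "covariate_cols"))
    attr(out, a) <- attrs[[a]]
  class(out) <- class(table)
  attr(out, "exclusions") <- report
  out
}

#' Expected counts under the constant overall rate
#'
#' The overall rate is total outlets per total household,
#' `r = sum(y) / sum(h)`; each tract expects `E_i = r * h_i`.  The expected
#' counts reproduce the observed total exactly, which makes the Poisson
#' relative risk `theta_i` a ratio to the state-wide rate.
#'
#' @param y non-negative integer outlet counts.
#' @param h non-negative integer household totals (`sum(h) > 0`).
#' @return list with `rate` (scalar `r`) and `E` (per-tract expected counts).
#' @export
expected_counts <- function(y, h) {
  stopifnot(length(y) == length(h), all(y >= 0), all(h >= 0))
  if (sum(h) <= 0) stop("sum of households must be positive")
  r <- sum(y) / sum(h)
  list(rate = r, E = r * h)
}

#' Per-tract outcome rates
#'
#' Crude rates `y_i / h_i`; tracts with zero households carry no rate and are
#' excluded with a report.
#'
#' @inheritParams expected_counts
#' @return list with `rate` (vector over retained tracts), `kept` (indices)
#'   and `excluded` (indices with `h == 0`).
#' @export
outcome_rates <- function(y, h) {
  stopifnot(length(y) == length(h))
  keep <- which(h > 0)
  list(rate = y[keep] / h[keep], kept = keep,
       excluded = which(h == 0))
}
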