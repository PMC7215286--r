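#' Orient covariates toward the hypothesized positive direction
#'
#' Covariates entering the disadvantage index must all point the same way:
#' larger value, more disadvantage.  Amount-scaled variables (income, rent,
#' housing costs) are inverted with `max(x) - x`; proportion variables
#' (share with a bachelor's degree) are complemented with `1 - x`.
#'
#' @param values numeric vector; `NA`s pass through.
#' @return the transformed vector.
#' @export
invert_scale <- function(values) {
  if (all(is.na(values))) stop("cannot invert an all-missing vector")
  max(values, na.rm = TRUE) - values
}

#' @rdname invert_scale
#' @export
complement_proportion <- function(values) {
  v <- values[!is.na(values)]
  if (any(v < 0 | v > 1))
    stop("complement_proportion requires values in [0, 1]")
  1 - values
}

#' Decile scores of a covariate
#'
#' Empirical decile membership coded 0-9: score `floor(10 * (rank - 1) / n)`
#' with minimum ranks, so tied values share the score of their lowest rank
#' block and any strictly monotone transform of the input leaves the scores
#' unchanged.  With distinct values and `n` divisible by 10 every decile
#' holds exactly `n/10` tracts.
#'
#' @param values numeric vector with no missing entries (filter first).
#' @return integer scores in `0:9`.
#' @export
decile_scores <- function(values) {
  if (anyNA(values)) stop("decile_scores requires complete values; filter first")
  n <- length(values)
  if (n == 0L) stop("empty vector")
  if (n < 10L)
    warning("fewer than 10 values; decile scores computed from available ranks")
  r <- rank(values, ties.method = "min")
  as.integer(floor(10 * (r - 1) / n))
}

#' Build the decile score matrix for a tract table
#'
#' Applies the per-variable orientation, then decile-scores each column.
#'
#' @param table a [tract_table()] with no missing covariate cells (see
#'   [filter_missing()]).
#' @param orientation named character vector over the covariates with values
#'   `"identity"`, `"invert"` or `"complement"`; unnamed covariates default
#'   to `"identity"`.
#' @return integer matrix `n x C` of scores 0-9, with the orientation record
#'   in attribute `"orientation"`.
#' @export
decile_matrix <- function(table, orientation = NULL) {
  stopifnot(inherits(table, "tract_table"))
  xm <- tt_cov(table)
  if (anyNA(xm)) stop("missing covariate cells; apply filter_missing() first")
  ori <- stats::setNames(rep("identity", ncol(xm)), colnames(xm))
  if (!is.null(orientation)) {
    bad <- setdiff(names(orientation), colnames(xm))
    if (length(bad)) stop("orientation names unknown: ", paste(bad, collapse = ", "))
    ori[names(orientation)] <- orientation
  }
  if (!all(ori %in% c("identity", "invert", "complement")))
    stop("orientation must be identity, invert or complement")
  q <- matrix(0L, nrow(xm), ncol(xm), dimnames = dimnames(xm))
  for (j in seq_len(ncol(xm))) {
    v <- switch(ori[[j]],
                identity   = xm[, j],
                invert     = invert_scale(xm[, j]),
                complement = complement_proportion(xm[, j]))
    q[, j] <- decile_scores(v)
  }
  attr(q, "orientation") <- ori
  q
}

#' Suggest covariate orientations from univariate screening
#'
#' For each covariate, fits a univariate Poisson log-linear model of the
#' counts on the raw covariate (offset `log E`) and suggests `"invert"` (or
#' `"complement"` for variables bounded in \[0, 1\]) whenever the estimated
#' slope is negative.  A convenience for reproducible configuration, not a
#' substitute for a recorded orientation choice.
#'
#' @param table a [tract_table()].
#' @return named character vector of suggested orientations.
#' @export
suggest_orientation <- function(table) {
  stopifnot(inherits(table, "tract_table"))
  y <- tt_y(table); h <- tt_h(table)
  keep <- h > 0
  E <- expected_counts(y[keep], h[keep])$E
  xm <- tt_cov(table)[keep, , drop = FALSE]
  out <- character(ncol(xm))
  for (j in seq_len(ncol(xm))) {
    ok <- !is.na(xm[, j]) & E > 0
    slope <- tryCatch(
      stats::coef(stats::glm(y[keep][ok] ~ xm[ok, j],
                             offset = log(E[ok]), family = stats::poisson()))[2L],
      error = function(e) NA_real_)
    if (is.na(slope) || slope >= 0) {
      out[j] <- "identity"
    } else {
      v <- xm[ok, j]
      out[j] <- if (all(v >= 0 & v <= 1)) "complement" else "invert"
    }
  }
  stats::setNames(out, colnames(xm))
}

#' Moran's I with a permutation test
#'
#' Global spatial autocorrelation of a tract-level variable under the binary
#' neighbourhood weights of `graph` (row-standardised weights optional).  The
#' pseudo p-value comes from random permutations of the values over tracts:
#' `p = (1 + #{I_perm at least as extreme}) / (1 + permutations)`.
#'
#' @param values numeric vector, non-constant, no `NA`.
#' @param graph an [adjacency_graph()].
#' @param permutations number of random permutations (at least 99).
#' @param seed integer seed for the permutation draw.
#' @param alternative `"greater"` (default; positive autocorrelation),
#'   `"less"` or `"two.sided"`.
#' @param row_standardize divide each tract's weights by its degree.
#' @return list with `statistic`, `expectation` (`-1/(n-1)`), `p_value`,
#'   `permutations`.
#' @export
moran_i <- function(values, graph, permutations = 999, seed = 1,
                    alternative = c("greater", "less", "two.sided"),
                    row_standardize = FALSE) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(graph, "adjacency_graph"),
            length(values) == graph$n, permutations >= 99)
  if (anyNA(values)) stop("values contain NA")
  if (stats::sd(values) == 0) stop("Moran's I undefined for a constant vector")
  n <- graph$n
  ei <- rep.int(seq_len(n), graph$degree)    # edge list (directed, both ways)
  ej <- unlist(graph$nb)
  wt <- if (row_standardize) 1 / graph$degree[ei] else rep(1, length(ei))
  s0 <- sum(wt)
  stat <- function(x) {
    z <- x - mean(x)
    (n / s0) * sum(wt * z[ei] * z[ej]) / sum(z^2)
  }
  obs <- stat(values)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  perm <- vapply(seq_len(permutations), function(k) stat(sample(values)),
                 numeric(1))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  p <- switch(alternative,
    greater   = (1 + sum(perm >= obs)) / (1 + permutations),
    less      = (1 + sum(perm <= obs)) / (1 + permutations),
    two.sided = (1 + sum(abs(perm - mean(perm)) >= abs(obs - mean(perm)))) /
                (1 + permutations))
  list(statistic = obs, expectation = -1 / (n - 1), p_value = p,
       permutations = permutations)
}
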