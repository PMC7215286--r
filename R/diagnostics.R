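#' Geweke convergence z-score
#'
#' Compares the mean of an early segment of a chain with the mean of a late
#' segment: `z = (mean_first - mean_last) / sqrt(Var_first + Var_last)`,
#' each segment's variance-of-the-mean estimated from its spectral density
#' at frequency zero (lag-windowed autocovariance sum with a Bartlett window
#' of width proportional to the square root of the segment length).  The
#' usual convergence call is `|z| < 2`.
#'
#' @param trace numeric sample path (length at least 100).
#' @param frac_first,frac_last fractions of the chain used for the early and
#'   late segments (defaults 0.1 and 0.5).
#' @return list with `z` and logical `converged` (`|z| < 2`).
#' @export
geweke_z <- function(trace, frac_first = 0.1, frac_last = 0.5) {
  trace <- as.numeric(trace)
  if (length(trace) < 100) stop("trace too short for a Geweke diagnostic")
  if (stats::sd(trace) == 0) stop("Geweke z undefined for a constant trace")
  n <- length(trace)
  first <- trace[seq_len(max(2, floor(frac_first * n)))]
  last <- trace[seq.int(n - max(2, floor(frac_last * n)) + 1, n)]
  v1 <- spectrum0(first) / length(first)
  v2 <- spectrum0(last) / length(last)
  z <- (mean(first) - mean(last)) / sqrt(v1 + v2)
  list(z = z, converged = is.finite(z) && abs(z) < 2)
}

# spectral density at frequency zero via a Bartlett lag window of width
# floor(sqrt(n)); falls back to the marginal variance if the windowed sum
# degenerates
spectrum0 <- function(x) {
  n <- length(x)
  L <- max(1L, floor(sqrt(n)))
  ac <- stats::acf(x, lag.max = L, type = "covariance", plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  w <- 1 - seq_len(L) / (L + 1)
  s0 <- ac[1] + 2 * sum(w * ac[-1])
  if (!is.finite(s0) || s0 <= 0) s0 <- ac[1]
  s0
}

#' Deviance information criterion from traces
#'
#' `pD = mean(D) - D(at posterior means)` and `DIC = mean(D) + pD`
#' (equivalently `D(at posterior means) + 2 pD`).  A drop of 10 or more in
#' DIC between candidate models is treated as a meaningful improvement.
#'
#' @param deviance_trace per-iteration deviances of the retained draws.
#' @param deviance_at_means deviance evaluated at the posterior means of the
#'   parameters entering the likelihood.
#' @return list with `DIC`, `pD`, `Dbar`, `Dhat`.
#' @export
dic_from_deviance <- function(deviance_trace, deviance_at_means) {
  dbar <- mean(deviance_trace)
  pd <- dbar - deviance_at_means
  list(DIC = dbar + pd, pD = pd, Dbar = dbar, Dhat = deviance_at_means)
}

#' @rdname dic_from_deviance
#' @param fit an `ndi_fit` object.  The plug-in deviance uses the posterior
#'   means of every component of the linear predictor (`beta0`, `beta1`,
#'   `w`, `u`, `v`, `a`), a choice `pD` is sensitive to and therefore fixed
#'   and documented here.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "ndi_fit"))
  po <- fit$post
  a_hat <- if (fit$control$global_mixing) rep(po$a, fit$n) else po$a
  idx_hat <- as.vector(fit$data$q %*% po$w)
  eta_hat <- log_relative_risk(
    list(beta0 = po$beta0, beta1 = po$beta1, u = po$u, v = po$v, a = a_hat),
    idx_hat, fit$variant)
  dhat <- -2 * poisson_loglik(fit$data$y, fit$data$E, eta_hat)
  dic_from_deviance(fit$draws$deviance, dhat)
}

#' Compare fitted variants by DIC
#'
#' @param ... `ndi_fit` objects (or a single list of them).
#' @param delta meaningful-improvement margin (default 10).
#' @return data frame with one row per fit: variant, DIC, pD, mean deviance,
#'   `delta_dic` relative to the best, and flags `best` and
#'   `meaningful_vs_next` (improvement of at least `delta` over the
#'   next-simplest fitted variant).
#' @export
compare_dic <- function(..., delta = 10) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "ndi_fit")) fits <- fits[[1]]
  stopifnot(all(vapply(fits, inherits, logical(1), "ndi_fit")))
  tab <- do.call(rbind, lapply(fits, function(f) {
    d <- dic(f)
    data.frame(variant = f$variant, DIC = d$DIC, pD = d$pD, Dbar = d$Dbar)
  }))
  tab <- tab[order(tab$variant), , drop = FALSE]
  tab$delta_dic <- tab$DIC - min(tab$DIC)
  tab$best <- seq_len(nrow(tab)) == which.min(tab$DIC)
  tab$meaningful_vs_prev <- c(NA, -diff(tab$DIC) >= delta)
  rownames(tab) <- NULL
  tab
}

#' Equal-tailed credible interval with a significance call
#'
#' @param trace posterior draws of a scalar.
#' @param level interval mass (default 0.95).
#' @param null optional reference value; the parameter is called significant
#'   when the interval does not contain `null` (containment inclusive, so a
#'   degenerate interval at the null is not significant).  Relative risks use
#'   `null = 1`.
#' @return list with `lower`, `upper`, and (when `null` given) `significant`.
#' @export
credible_interval <- function(trace, level = 0.95, null = NULL) {
  stopifnot(length(trace) > 0)
  alpha <- (1 - level) / 2
  qs <- unname(stats::quantile(trace, c(alpha, 1 - alpha), names = FALSE))
  out <- list(lower = qs[1], upper = qs[2])
  if (!is.null(null))
    out$significant <- (null < qs[1]) || (null > qs[2])
  out
}

#' Exceedance probabilities and hotspot flags
#'
#' For each tract, the posterior probability that its relative risk exceeds
#' `c`: the fraction of retained draws with `theta_i > c`.  Tracts whose
#' exceedance probability passes `cutoff` are flagged as significantly
#' elevated.
#'
#' @param theta matrix of retained relative-risk draws (`G x n`) or an
#'   `ndi_fit` object fitted with `store_theta = TRUE`.
#' @param c risk threshold (default 1: elevated relative to the overall
#'   rate).
#' @param cutoff flagging cutoff on the exceedance probability (default
#'   0.90).
#' @return data frame with `tract_id` (when available), `exceedance` and
#'   logical `elevated`.
#' @export
exceedance_probabilities <- function(theta, c = 1, cutoff = 0.90) {
  ids <- NULL
  if (inherits(theta, "ndi_fit")) {
    ids <- theta$tract_id
    theta <- theta$draws$theta
    if (is.null(theta))
      stop("fit was run with store_theta = FALSE; no relative-risk traces")
  }
  stopifnot(is.matrix(theta))
  q <- colMeans(theta > c)
  out <- data.frame(exceedance = q, elevated = q > cutoff)
  if (!is.null(ids)) out <- cbind(tract_id = ids, out)
  rownames(out) <- NULL
  out
}

#' Export fit results to CSV / GeoJSON
#'
#' Writes the per-tract table (posterior mean relative risk, exceedance
#' probability, hotspot flag), the weight table (posterior means and 95%
#' intervals per index variable), and, when polygons are supplied, a GeoJSON
#' whose features carry the per-tract values as properties.
#'
#' @param fit an `ndi_fit`.
#' @param dir output directory (created if absent).
#' @param polygons optional named polygon list matching the fitted tracts.
#' @param c,cutoff exceedance settings, see [exceedance_probabilities()].
#' @return invisible character vector of the files written.
#' @export
export_results <- function(fit, dir, polygons = NULL, c = 1, cutoff = 0.90) {
  stopifnot(inherits(fit, "ndi_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  exc <- exceedance_probabilities(fit, c = c, cutoff = cutoff)
  tract_tab <- data.frame(tract_id = fit$tract_id,
                          theta_mean = fit$post$theta,
                          exceedance = exc$exceedance,
                          elevated = exc$elevated)
  f1 <- file.path(dir, "tract_summary.csv")
  utils::write.csv(tract_tab, f1, row.names = FALSE)
  wt <- fit$draws$w
  wtab <- data.frame(
    variable = colnames(wt) %||% paste0("w", seq_len(ncol(wt))),
    mean = colMeans(wt),
    lower = apply(wt, 2, stats::quantile, 0.025),
    upper = apply(wt, 2, stats::quantile, 0.975),
    important = colMeans(wt) > equal_weight_threshold(ncol(wt)))
  f2 <- file.path(dir, "weights.csv")
  utils::write.csv(wtab, f2, row.names = FALSE)
  files <- c(f1, f2)
  if (!is.null(polygons)) {
    missing_ids <- setdiff(fit$tract_id, names(polygons))
    if (length(missing_ids))
      stop("polygons missing tract id(s): ", paste(missing_ids, collapse = ", "))
    f3 <- file.path(dir, "tract_summary.geojson")
    write_geojson_polygons(polygons[fit$tract_id], f3, properties = tract_tab)
    files <- c(files, f3)
  }
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
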