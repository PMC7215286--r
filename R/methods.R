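#' @export
print.ndi_fit <- function(x, ...) {
  labels <- c("unstructured heterogeneity", "ICAR spatial", "convolution",
              "convolution mixture")
  cat("Bayesian disadvantage-index model (variant ", x$variant, ": ",
      labels[x$variant], ")\n", sep = "")
  cat(x$n, " tracts, ", x$C, " index covariates; overall rate ",
      signif(x$data$rate, 4), " outlets/household\n", sep = "")
  cat("MCMC: ", x$control$n_iter, " iterations, burn-in ", x$m,
      ", thin ", x$thin, " (", x$G, " retained draws), seed ", x$seed,
      "\n", sep = "")
  rr <- exp(x$draws$beta1)
  ci <- credible_interval(rr, null = 1)
  cat("RR per index unit: ", signif(mean(rr), 4), " (95% CI ",
      signif(ci$lower, 4), "-", signif(ci$upper, 4),
      if (ci$significant) ", significant" else "", ")\n", sep = "")
  invisible(x)
}

#' @export
coef.ndi_fit <- function(object, ...) {
  c(beta0 = object$post$beta0, beta1 = object$post$beta1,
    stats::setNames(object$post$w, paste0("w.", names(object$post$w))))
}

#' @export
fitted.ndi_fit <- function(object, ...) {
  object$data$E * object$post$theta
}

#' @export
residuals.ndi_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  mu <- fitted(object)
  r <- object$data$y - mu
  if (type == "pearson") r <- r / sqrt(pmax(mu, .Machine$double.eps))
  r
}

#' @export
simulate.ndi_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(object$draws$theta))
    stop("fit was run with store_theta = FALSE; cannot simulate")
  g <- sample.int(object$G, nsim, replace = TRUE)
  out <- vapply(g, function(k)
    stats::rpois(object$n, object$draws$theta[k, ] * object$data$E),
    numeric(object$n))
  colnames(out) <- paste0("sim_", seq_len(nsim))
  as.data.frame(out)
}

#' @export
plot.ndi_fit <- function(x, pars = c("beta0", "beta1", "deviance"), ...) {
  op <- graphics::par(mfrow = c(length(pars), 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  for (p in pars) {
    tr <- x$draws[[p]]
    if (is.null(tr)) next
    if (is.matrix(tr)) tr <- tr[, 1]
    graphics::plot(tr, type = "l", ylab = p, xlab = "",
                   main = paste("trace of", p), ...)
  }
  invisible(x)
}

#' Summarize a fitted disadvantage-index model
#'
#' Produces the full fit summary: posterior means, SDs and 95% intervals for
#' the fixed effects and scales, the relative risk per index unit with its
#' significance call, the weight table with the equal-contribution
#' importance flags, Geweke convergence z-scores, DIC/pD, and the
#' exceedance-probability hotspot count.
#'
#' @param object an `ndi_fit`.
#' @param level credible level (default 0.95).
#' @param c,cutoff exceedance settings (defaults 1 and 0.90).
#' @param ... unused.
#' @return an object of class `summary.ndi_fit`.
#' @export
summary.ndi_fit <- function(object, level = 0.95, c = 1, cutoff = 0.90, ...) {
  dr <- object$draws
  scalar_tab <- function(name, trace, null = NULL) {
    ci <- credible_interval(trace, level, null)
    gz <- if (stats::sd(trace) > 0) geweke_z(trace)$z else NA_real_
    data.frame(parameter = name, mean = mean(trace), sd = stats::sd(trace),
               lower = ci$lower, upper = ci$upper, geweke_z = gz)
  }
  params <- rbind(
    scalar_tab("beta0", dr$beta0),
    scalar_tab("beta1", dr$beta1),
    scalar_tab("RR_per_unit", exp(dr$beta1)),
    if (object$variant %in% c(1, 3, 4)) scalar_tab("sigma_u", dr$sigma_u),
    if (object$variant %in% c(2, 3, 4)) scalar_tab("sigma_v", dr$sigma_v),
    scalar_tab("sigma_1", dr$sigma_1),
    scalar_tab("deviance", dr$deviance))
  rr_ci <- credible_interval(exp(dr$beta1), level, null = 1)
  thr <- equal_weight_threshold(object$C)
  weights <- data.frame(
    variable = colnames(dr$w) %||% paste0("w", seq_len(object$C)),
    mean = colMeans(dr$w),
    sd = apply(dr$w, 2, stats::sd),
    lower = apply(dr$w, 2, stats::quantile, (1 - level) / 2),
    upper = apply(dr$w, 2, stats::quantile, 1 - (1 - level) / 2))
  weights$important <- weights$mean > thr
  rownames(weights) <- NULL
  d <- dic(object)
  exc <- if (!is.null(dr$theta))
    exceedance_probabilities(object, c = c, cutoff = cutoff)
  structure(list(
    variant = object$variant, n = object$n, C = object$C,
    parameters = params, rr = list(mean = mean(exp(dr$beta1)),
                                   lower = rr_ci$lower, upper = rr_ci$upper,
                                   significant = rr_ci$significant),
    weights = weights, weight_threshold = thr,
    dic = d, exceedance = exc,
    n_elevated = if (!is.null(exc)) sum(exc$elevated) else NA_integer_,
    converged = all(abs(params$geweke_z) < 2, na.rm = TRUE),
    acceptance = object$acceptance),
    class = "summary.ndi_fit")
}

#' @export
print.summary.ndi_fit <- function(x, ...) {
  cat("Variant ", x$variant, " fit over ", x$n, " tracts (",
      x$C, "-variable index)\n\n", sep = "")
  pr <- x$parameters
  pr[-1] <- lapply(pr[-1], signif, 4)
  print(pr, row.names = FALSE)
  cat("\nRR per index unit: ", signif(x$rr$mean, 4), " (",
      signif(x$rr$lower, 4), ", ", signif(x$rr$upper, 4), ") -- ",
      if (x$rr$significant) "significant" else "not significant",
      "\n", sep = "")
  cat("\nIndex weights (importance threshold ",
      signif(x$weight_threshold, 3), "):\n", sep = "")
  wt <- x$weights[order(-x$weights$mean), ]
  wt[c("mean", "sd", "lower", "upper")] <-
    lapply(wt[c("mean", "sd", "lower", "upper")], round, 3)
  print(wt, row.names = FALSE)
  cat("\nDIC = ", round(x$dic$DIC, 1), " (pD = ", round(x$dic$pD, 1),
      ", mean deviance = ", round(x$dic$Dbar, 1), ")\n", sep = "")
  if (!is.null(x$exceedance))
    cat(x$n_elevated, " tract(s) with significantly elevated risk\n", sep = "")
  cat(if (x$converged) "All monitored Geweke |z| < 2\n"
      else "WARNING: some monitored parameters have |Geweke z| >= 2\n")
  invisible(x)
}
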