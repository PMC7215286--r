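#' Weighted decile disadvantage index
#'
#' The neighborhood disadvantage index is a convex combination of the decile
#' scores: `index_i = sum_j w_j q_ij` with weights on the simplex, so under
#' 0-9 decile coding the index lives in \[0, 9\] and `w_j` reads as the
#' relative importance of variable `j`.
#'
#' @param q integer decile matrix (`n x C`), see [decile_matrix()].
#' @param w weight vector of length `C` on the simplex.
#' @return numeric index vector of length `n`.
#' @export
ndi_index <- function(q, w) {
  if (ncol(q) != length(w))
    stop("weight length ", length(w), " does not match ", ncol(q), " covariates")
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("weights must be non-negative and sum to 1")
  as.vector(q %*% w)
}

#' Equal-contribution weight threshold
#'
#' With `C` variables in the index, a weight above `1/C` marks a variable
#' contributing more than its equal share to the association; for the default
#' 12-variable index the threshold is 1/12, printed as 0.083.
#'
#' @param C number of index variables.
#' @return `1/C`.
#' @export
equal_weight_threshold <- function(C) {
  stopifnot(C >= 1)
  1 / C
}

#' Log relative risk under the four model variants
#'
#' * variant 1: `beta0 + beta1 * index + u`  (unstructured heterogeneity)
#' * variant 2: `beta0 + beta1 * index + v`  (ICAR spatial effects)
#' * variant 3: `... + u + v`                (convolution)
#' * variant 4: `... + a*u + (1-a)*v`        (convolution mixture)
#'
#' @param state list with `beta0`, `beta1` scalars and vectors `u`, `v`, `a`
#'   as the variant requires.
#' @param index disadvantage index vector.
#' @param variant integer 1-4.
#' @return per-tract log relative risk vector.
#' @export
log_relative_risk <- function(state, index, variant) {
  n <- length(index)
  base <- state$beta0 + state$beta1 * index
  switch(as.character(variant),
    "1" = base + state$u,
    "2" = base + state$v,
    "3" = base + state$u + state$v,
    "4" = base + state$a * state$u + (1 - state$a) * state$v,
    stop("variant must be 1, 2, 3 or 4"))
}

#' Poisson log-likelihood with expected-count offsets
#'
#' `sum_i [ y_i (log E_i + log theta_i) - E_i theta_i - log y_i! ]`.
#' Tracts with `E_i = 0` are only admissible when `y_i = 0`, in which case
#' they contribute zero.
#'
#' @param y counts; @param E expected counts; @param log_theta log relative
#'   risks.
#' @return scalar log-likelihood.
#' @export
poisson_loglik <- function(y, E, log_theta) {
  stopifnot(length(y) == length(E), length(E) == length(log_theta))
  zero <- E == 0
  if (any(zero & y > 0))
    stop("E_i = 0 with y_i > 0 is impossible under the model")
  if (all(zero)) return(0)
  y <- y[!zero]; E <- E[!zero]; lt <- log_theta[!zero]
  sum(y * (log(E) + lt) - E * exp(lt) - lfactorial(y))
}

#' Intrinsic CAR (ICAR) log-density
#'
#' Pairwise-difference form of the improper Gaussian Markov random field:
#' `((n - k)/2) log(tau) - (tau/2) * sum_{i~j} (v_i - v_j)^2`, where the sum
#' runs over unordered neighbour pairs and `k` is the number of connected
#' components (the rank deficiency).  Its full conditionals are
#' `v_i | v_{-i} ~ Normal(mean of neighbours, 1/(tau * degree_i))`.
#'
#' @param v spatial effect vector.
#' @param tau precision (`1/sigma_v^2`), positive.
#' @param graph an [adjacency_graph()].
#' @param strict error when an island tract carries a non-zero effect
#'   (islands have no ICAR information and are pinned at 0 by the sampler).
#' @return scalar log-density up to the additive constant of the improper
#'   prior (the `tau`-dependent normalising term is included so the density
#'   can drive scale updates).
#' @export
icar_logdensity <- function(v, tau, graph, strict = FALSE) {
  stopifnot(inherits(graph, "adjacency_graph"), length(v) == graph$n, tau > 0)
  if (strict && any(graph$degree == 0 & v != 0))
    stop("island tract with non-zero spatial effect")
  ei <- rep.int(seq_len(graph$n), graph$degree)
  ej <- unlist(graph$nb)
  ss <- sum((v[ei] - v[ej])^2) / 2      # each unordered pair counted once
  k <- max(graph$component)
  ((graph$n - k) / 2) * log(tau) - (tau / 2) * ss
}

# pairwise sum of squared neighbour differences, used by the sampler
icar_ss <- function(v, graph) {
  ei <- rep.int(seq_len(graph$n), graph$degree)
  sum((v[ei] - v[unlist(graph$nb)])^2) / 2
}

#' Prior specification
#'
#' Collects every prior hyperparameter of the hierarchy:
#' * index weights `w ~ Dirichlet(alpha)` (default all-ones: flat on the
#'   simplex);
#' * unstructured effects `u_i ~ Normal(0, sigma_u^2)`;
#' * spatial effects `v ~ ICAR(tau_v)` with sum-to-zero constraint;
#' * mixing `a_i ~ Beta(mixing[1], mixing[2])` (default Beta(1,1), uniform);
#' * intercept flat (improper uniform);
#' * index coefficient `beta1 ~ Normal(beta1_mean, sigma_1^2)`;
#' * scales `sigma_u, sigma_v, sigma_1 ~ Uniform(0, sigma_bound)`.
#'
#' `beta1_mean` defaults to 0; set it to 1 to reproduce the printed prior of
#' the original analysis (see the methods vignette for why 0 is the default).
#'
#' @param C number of index covariates.
#' @param alpha Dirichlet parameters, recycled to length `C`; all positive.
#' @param sigma_bound upper bound of the uniform scale priors (default 100).
#' @param beta1_mean prior mean of the index coefficient.
#' @param mixing Beta parameters of the mixing prior.
#' @return an object of class `ndi_prior`.
#' @export
ndi_prior <- function(C, alpha = 1, sigma_bound = 100, beta1_mean = 0,
                      mixing = c(1, 1)) {
  alpha <- rep_len(alpha, C)
  stopifnot(all(alpha > 0), sigma_bound > 0, length(mixing) == 2,
            all(mixing > 0))
  structure(list(C = C, alpha = alpha, sigma_bound = sigma_bound,
                 beta1_mean = beta1_mean, mixing = mixing),
            class = "ndi_prior")
}

#' Joint log-prior of a parameter state
#'
#' Sums the log-densities of every prior active under `variant`; states
#' outside the support return `-Inf`.
#'
#' @param state list with `beta0`, `beta1`, `w`, `u`, `v`, `a`, `sigma_u`,
#'   `sigma_v`, `sigma_1` (components unused by the variant may be absent).
#' @param prior an [ndi_prior()].
#' @param graph adjacency graph (needed for variants with spatial effects).
#' @param variant integer 1-4.
#' @return scalar log prior density (up to the ICAR improper constant).
#' @export
log_prior <- function(state, prior, graph = NULL, variant = 1) {
  b <- prior$sigma_bound
  w <- state$w
  if (any(w <= 0) || abs(sum(w) - 1) > 1e-8) return(-Inf)
  for (s in c("sigma_u", "sigma_v", "sigma_1"))
    if (!is.null(state[[s]]) && (state[[s]] <= 0 || state[[s]] >= b))
      return(-Inf)
  lp <- lgamma(sum(prior$alpha)) - sum(lgamma(prior$alpha)) +
    sum((prior$alpha - 1) * log(w))
  lp <- lp + stats::dnorm(state$beta1, prior$beta1_mean, state$sigma_1,
                          log = TRUE) - log(b)   # beta1 | sigma_1, and sigma_1
  # beta0: improper flat, contributes 0
  if (variant %in% c(1, 3, 4))
    lp <- lp + sum(stats::dnorm(state$u, 0, state$sigma_u, log = TRUE)) - log(b)
  if (variant %in% c(2, 3, 4)) {
    if (is.null(graph)) stop("spatial variants need an adjacency graph")
    lp <- lp + icar_logdensity(state$v, 1 / state$sigma_v^2, graph) - log(b)
  }
  if (variant == 4) {
    a <- state$a
    if (any(a <= 0 | a >= 1)) return(-Inf)
    lp <- lp + sum(stats::dbeta(a, prior$mixing[1], prior$mixing[2], log = TRUE))
  }
  lp
}
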