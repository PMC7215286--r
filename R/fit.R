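#' MCMC control settings
#'
#' @param n_iter total iterations of the single chain.
#' @param burnin iterations discarded (adaptation of proposal scales is
#'   frozen at the end of burn-in, so retained draws come from a fixed
#'   kernel).
#' @param thin retain every `thin`-th post-burn-in draw.
#' @param target_accept Metropolis acceptance target for the adaptive scales
#'   (0.44, the single-site random-walk optimum).
#' @param adapt adapt proposal scales during burn-in.
#' @param store_theta keep the per-tract relative-risk traces (needed for
#'   exceedance probabilities; an `n x G` matrix).
#' @param store_effects additionally keep full traces of `u`, `v`, `a`
#'   (memory-heavy; meant for small diagnostic runs).
#' @param prior_only disable the likelihood so the chain samples the joint
#'   prior (the intercept, which is improper, must then be fixed; it is
#'   pinned at 0 automatically).
#' @param fixed named list of parameters held fixed at given values; any of
#'   `beta0`, `beta1`, `w`, `u`, `v`, `a`, `sigma_u`, `sigma_v`, `sigma_1`.
#'   Fixing `u` (or `v`) also freezes its scale unless that scale is supplied
#'   too.
#' @param global_mixing use a single mixing parameter shared by all tracts
#'   instead of the per-tract mixing of variant 4.
#' @return a list of class `ndi_control`.
#' @export
ndi_control <- function(n_iter = 6000, burnin = floor(n_iter / 2), thin = 1,
                        target_accept = 0.44, adapt = TRUE,
                        store_theta = TRUE, store_effects = FALSE,
                        prior_only = FALSE, fixed = list(),
                        global_mixing = FALSE) {
  stopifnot(n_iter >= 2, burnin >= 0, burnin < n_iter, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burnin = as.integer(burnin),
                 thin = as.integer(thin), target_accept = target_accept,
                 adapt = adapt, store_theta = store_theta,
                 store_effects = store_effects, prior_only = prior_only,
                 fixed = fixed, global_mixing = global_mixing),
            class = "ndi_control")
}

#' @rdname ndi_control
#' @details `paper_protocol()` returns the long single-chain protocol of the
#'   original analysis: 60,000 iterations, 30,000 burn-in, thinning 1.
#' @export
paper_protocol <- function(...) {
  ndi_control(n_iter = 60000, burnin = 30000, thin = 1, ...)
}

# restrict an adjacency graph to a subset of tracts (used when zero-household
# tracts are excluded before fitting)
subset_graph <- function(graph, keep) {
  map <- match(seq_len(graph$n), keep)
  nb <- lapply(graph$nb[keep], function(x) sort(map[x][!is.na(map[x])]))
  suppressWarnings(adjacency_graph(nb, graph$ids[keep]))
}

#' Fit a Bayesian disadvantage-index model
#'
#' Fits the Poisson relative-risk model
#' `y_i ~ Poisson(theta_i * E_i)` with
#' `log(theta_i) = beta0 + beta1 * sum_j w_j q_ij + (random effects)` by an
#' adaptive Metropolis-within-Gibbs sampler.  The random-effect structure is
#' chosen by `variant`: 1 unstructured, 2 ICAR, 3 convolution, 4 convolution
#' mixture (see [log_relative_risk()]).  Expected counts are computed from
#' the data ([expected_counts()]); tracts with zero households are excluded
#' and reported.
#'
#' @param data a [tract_table()] with complete covariates (apply
#'   [filter_missing()] first).
#' @param graph an [adjacency_graph()] over the rows of `data`; required for
#'   variants 2-4.
#' @param variant model variant, 1-4.
#' @param orientation per-variable orientation passed to [decile_matrix()].
#' @param q optional precomputed decile matrix (overrides `orientation`).
#' @param prior an [ndi_prior()]; defaults to a flat Dirichlet, Beta(1,1)
#'   mixing, Uniform(0,100) scales and a Normal(0, sigma_1^2) coefficient
#'   prior.
#' @param control an [ndi_control()].
#' @param seed integer seed; fits are bit-reproducible given
#'   seed + data + settings.
#' @return an object of class `ndi_fit`; see Details.
#' @details The returned object carries the retained draws (`$draws`),
#'   posterior means of latent fields (`$post`), burn-in/retention counts
#'   (`$m`, `$G`), the per-block acceptance ledger (`$acceptance`) and the
#'   data actually fitted.  Methods: `print`, `summary`, `coef`, `fitted`,
#'   `residuals`, `simulate`, `plot`.
#' @export
ndi_fit <- function(data, graph = NULL, variant = 1, orientation = NULL,
                    q = NULL, prior = NULL, control = ndi_control(),
                    seed = 1) {
  stopifnot(inherits(data, "tract_table"))
  variant <- as.integer(variant)
  if (!variant %in% 1:4) stop("variant must be 1, 2, 3 or 4")
  if (variant >= 2 && is.null(graph))
    stop("variants 2-4 require an adjacency graph")
  if (!is.null(graph) && graph$n != nrow(data))
    stop("adjacency graph size does not match the tract table")
  if (nrow(data) == 0) stop("empty tract table; nothing to fit")
  xm <- tt_cov(data)
  if (anyNA(xm))
    stop("missing covariate cells; apply filter_missing() before fitting")
  if (is.null(q)) q <- decile_matrix(data, orientation)
  y_all <- tt_y(data); h_all <- tt_h(data)
  keep <- which(h_all > 0)
  excluded <- data.frame(tract_id = tt_ids(data)[h_all == 0],
                         reason = rep("zero households", sum(h_all == 0)),
                         stringsAsFactors = FALSE)
  y <- y_all[keep]; h <- h_all[keep]
  q <- q[keep, , drop = FALSE]
  g <- if (!is.null(graph)) {
    if (length(keep) < graph$n) subset_graph(graph, keep) else graph
  }
  if (sum(y) == 0 && !control$prior_only)
    stop("no events observed; the relative-risk model is degenerate")
  ec <- expected_counts(y, h)
  res <- run_chain(y = y, E = ec$E, q = q, graph = g, variant = variant,
                   prior = if (is.null(prior)) ndi_prior(ncol(q)) else prior,
                   control = control, seed = seed)
  res$call <- match.call()
  res$tract_id <- tt_ids(data)[keep]
  res$data <- list(y = y, h = h, E = ec$E, rate = ec$rate, q = q)
  res$graph <- g
  res$excluded <- excluded
  res$orientation <- attr(q, "orientation")
  class(res) <- "ndi_fit"
  res
}

# ---------------------------------------------------------------------------
# the sampler ---------------------------------------------------------------
# ---------------------------------------------------------------------------

run_chain <- function(y, E, q, graph, variant, prior, control, seed) {
  set.seed(as.integer(seed))
  n <- length(y)
  C <- ncol(q)
  if (prior$C != C) stop("prior specifies ", prior$C, " covariates, data has ", C)
  fixed <- control$fixed
  use_u <- variant %in% c(1, 3, 4)
  use_v <- variant %in% c(2, 3, 4)
  use_a <- variant == 4
  prior_only <- isTRUE(control$prior_only)
  if (prior_only && is.null(fixed$beta0)) fixed$beta0 <- 0
  if (use_u && !is.null(fixed$u) && is.null(fixed$sigma_u)) fixed$sigma_u <- 1
  if (use_v && !is.null(fixed$v) && is.null(fixed$sigma_v)) fixed$sigma_v <- 1

  # state initialisation: neutral and reproducible
  st <- list(
    beta0 = if (!is.null(fixed$beta0)) fixed$beta0 else 0,
    beta1 = if (!is.null(fixed$beta1)) fixed$beta1 else 0,
    w = if (!is.null(fixed$w)) fixed$w else prior$alpha / sum(prior$alpha),
    u = if (!is.null(fixed$u)) rep_len(fixed$u, n) else rep(0, n),
    v = if (!is.null(fixed$v)) rep_len(fixed$v, n) else rep(0, n),
    a = if (!is.null(fixed$a)) rep_len(fixed$a, if (control$global_mixing) 1 else n)
        else rep(0.5, if (control$global_mixing) 1 else n),
    sigma_u = if (!is.null(fixed$sigma_u)) fixed$sigma_u else 1,
    sigma_v = if (!is.null(fixed$sigma_v)) fixed$sigma_v else 1,
    sigma_1 = if (!is.null(fixed$sigma_1)) fixed$sigma_1 else 1)
  if (abs(sum(st$w) - 1) > 1e-8 || any(st$w <= 0))
    stop("initial weights must lie in the interior of the simplex")

  # spatial bookkeeping
  if (use_v) {
    comp <- graph$component
    island <- graph$degree == 0L
    if (any(island)) st$v[island] <- 0
    color <- graph_coloring(graph)
    classes <- lapply(seq_len(max(color)), function(k)
      which(color == k & !island))
    classes <- classes[lengths(classes) > 0]
    rank_icar <- n - max(comp)
    ei <- rep.int(seq_len(n), graph$degree)
    ej <- unlist(graph$nb)
  }

  a_long <- function() if (control$global_mixing) rep(st$a, n) else st$a
  eta_of <- function() log_relative_risk(
    list(beta0 = st$beta0, beta1 = st$beta1, u = st$u, v = st$v,
         a = a_long()), idx, variant)
  ll_vec <- function(eta) if (prior_only) numeric(n) else y * eta - E * exp(eta)

  idx <- as.vector(q %*% st$w)
  eta <- eta_of()
  ll <- ll_vec(eta)
  if (any(!is.finite(ll)))
    stop("non-finite likelihood at initialization (component: linear predictor)")

  # adaptive proposal scales (log scale); frozen after burn-in
  ls <- list(beta0 = log(0.1), beta1 = log(0.05), z = rep(log(0.3), C),
             u = rep(log(0.5), n), v = rep(log(0.5), n),
             a = rep(log(0.5), if (control$global_mixing) 1 else n),
             sigma_u = log(0.5), sigma_v = log(0.5), sigma_1 = log(0.5))
  target <- control$target_accept
  acc_n <- acc_d <- list()
  bump <- function(block, acc, gamma) {
    if (adapting && control$adapt)
      ls[[block]] <<- ls[[block]] + gamma * (acc - target)
    if (!adapting) {
      acc_n[[block]] <<- (acc_n[[block]] %||% 0) + sum(acc)
      acc_d[[block]] <<- (acc_d[[block]] %||% 0) + length(acc)
    }
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a

  n_iter <- control$n_iter; burnin <- control$burnin; thin <- control$thin
  G <- (n_iter - burnin) %/% thin
  draws <- list(beta0 = numeric(G), beta1 = numeric(G),
                w = matrix(NA_real_, G, C, dimnames = list(NULL, colnames(q))),
                sigma_u = numeric(G), sigma_v = numeric(G),
                sigma_1 = numeric(G), deviance = numeric(G))
  if (control$store_theta) draws$theta <- matrix(NA_real_, G, n)
  if (control$store_effects) {
    if (use_u) draws$u <- matrix(NA_real_, G, n)
    if (use_v) draws$v <- matrix(NA_real_, G, n)
    if (use_a) draws$a <- matrix(NA_real_, G, length(st$a))
  }
  sums <- list(u = numeric(n), v = numeric(n), a = numeric(length(st$a)),
               theta = numeric(n))
  alpha <- prior$alpha
  b1m <- prior$beta1_mean
  bnd <- prior$sigma_bound
  mix_p <- prior$mixing
  g_idx <- 0L

  for (t in seq_len(n_iter)) {
    adapting <- t <= burnin
    gamma <- min(0.25, 3 / sqrt(t))

    ## intercept ------------------------------------------------------------
    if (is.null(fixed$beta0)) {
      d <- stats::rnorm(1, 0, exp(ls$beta0))
      eta2 <- eta + d
      ll2 <- ll_vec(eta2)
      lr <- sum(ll2) - sum(ll)
      acc <- is.finite(lr) && log(stats::runif(1)) < lr
      if (acc) { st$beta0 <- st$beta0 + d; eta <- eta2; ll <- ll2 }
      bump("beta0", as.numeric(acc), gamma)
    }

    ## index coefficient ----------------------------------------------------
    if (is.null(fixed$beta1)) {
      d <- stats::rnorm(1, 0, exp(ls$beta1))
      b1p <- st$beta1 + d
      eta2 <- eta + d * idx
      ll2 <- ll_vec(eta2)
      lr <- sum(ll2) - sum(ll) +
        stats::dnorm(b1p, b1m, st$sigma_1, log = TRUE) -
        stats::dnorm(st$beta1, b1m, st$sigma_1, log = TRUE)
      acc <- is.finite(lr) && log(stats::runif(1)) < lr
      if (acc) { st$beta1 <- b1p; eta <- eta2; ll <- ll2 }
      bump("beta1", as.numeric(acc), gamma)
    }

    ## index weights: random-pair mass-exchange moves on the simplex --------
    ## coordinate j trades mass with a random partner k through a logit-scale
    ## random walk on the split p = w_j/(w_j + w_k); the Dirichlet prior and
    ## the transform Jacobian combine to alpha_j*log p + alpha_k*log(1-p)
    if (is.null(fixed$w) && C > 1) {
      accs <- numeric(C)
      for (j in seq_len(C)) {
        k <- sample.int(C - 1L, 1L)
        if (k >= j) k <- k + 1L
        s2 <- st$w[j] + st$w[k]
        p <- st$w[j] / s2
        pp <- stats::plogis(stats::qlogis(p) + stats::rnorm(1, 0, exp(ls$z[j])))
        wp <- st$w
        wp[j] <- s2 * pp
        wp[k] <- s2 * (1 - pp)
        if (wp[j] <= 0 || wp[k] <= 0) next
        idx2 <- idx + (wp[j] - st$w[j]) * q[, j] + (wp[k] - st$w[k]) * q[, k]
        eta2 <- eta + st$beta1 * (idx2 - idx)
        ll2 <- ll_vec(eta2)
        lr <- sum(ll2) - sum(ll) +
          alpha[j] * (log(pp) - log(p)) + alpha[k] * (log1p(-pp) - log1p(-p))
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          st$w <- wp; idx <- idx2; eta <- eta2; ll <- ll2
          accs[j] <- 1
        }
      }
      bump("z", accs, gamma)
    }

    ## unstructured effects (independent single-site moves, vectorised) -----
    if (use_u && is.null(fixed$u)) {
      cu <- if (use_a) a_long() else 1
      up <- st$u + stats::rnorm(n, 0, exp(ls$u))
      eta2 <- eta + cu * (up - st$u)
      ll2 <- ll_vec(eta2)
      lr <- (ll2 - ll) +
        stats::dnorm(up, 0, st$sigma_u, log = TRUE) -
        stats::dnorm(st$u, 0, st$sigma_u, log = TRUE)
      acc <- !is.na(lr) & log(stats::runif(n)) < lr
      if (any(acc)) {
        st$u[acc] <- up[acc]; eta[acc] <- eta2[acc]; ll[acc] <- ll2[acc]
      }
      bump("u", as.numeric(acc), gamma)
    }

    ## spatial effects (single-site moves by colour class) ------------------
    if (use_v && is.null(fixed$v)) {
      cv <- if (use_a) 1 - a_long() else rep(1, n)
      tau_v <- 1 / st$sigma_v^2
      accs <- logical(0)
      for (K in classes) {
        nbsum <- vapply(K, function(i) sum(st$v[graph$nb[[i]]]), numeric(1))
        degK <- graph$degree[K]
        vK <- st$v[K]
        vp <- vK + stats::rnorm(length(K), 0, exp(ls$v[K]))
        etaK2 <- eta[K] + cv[K] * (vp - vK)
        llK2 <- if (prior_only) numeric(length(K))
                else y[K] * etaK2 - E[K] * exp(etaK2)
        lr <- (llK2 - ll[K]) -
          (tau_v * degK / 2) * ((vp - nbsum / degK)^2 - (vK - nbsum / degK)^2)
        acc <- !is.na(lr) & log(stats::runif(length(K))) < lr
        if (any(acc)) {
          ii <- K[acc]
          st$v[ii] <- vp[acc]; eta[ii] <- etaK2[acc]; ll[ii] <- llK2[acc]
        }
        accs <- c(accs, acc)
        if (adapting && control$adapt)
          ls$v[K] <- ls$v[K] + gamma * (acc - target)
      }
      if (!adapting) {
        acc_n[["v"]] <- (acc_n[["v"]] %||% 0) + sum(accs)
        acc_d[["v"]] <- (acc_d[["v"]] %||% 0) + length(accs)
      }
      # sum-to-zero per connected component, level absorbed by the intercept
      shift <- stats::ave(st$v, comp)
      st$v <- st$v - shift
      if (is.null(fixed$beta0)) st$beta0 <- st$beta0 + mean(shift)
      eta <- eta_of()
      ll <- ll_vec(eta)
    }

    ## mixing parameters (variant 4) ----------------------------------------
    if (use_a && is.null(fixed$a)) {
      tt <- stats::qlogis(st$a)
      tp <- tt + stats::rnorm(length(tt), 0, exp(ls$a))
      ap <- stats::plogis(tp)
      dprior <- mix_p[1] * (log(ap) - log(st$a)) +
        mix_p[2] * (log1p(-ap) - log1p(-st$a))
      if (control$global_mixing) {
        eta2 <- eta + (ap - st$a) * (st$u - st$v)
        ll2 <- ll_vec(eta2)
        lr <- sum(ll2) - sum(ll) + dprior
        acc <- is.finite(lr) && log(stats::runif(1)) < lr
        if (acc) { st$a <- ap; eta <- eta2; ll <- ll2 }
        bump("a", as.numeric(acc), gamma)
      } else {
        eta2 <- eta + (ap - st$a) * (st$u - st$v)
        ll2 <- ll_vec(eta2)
        lr <- (ll2 - ll) + dprior
        acc <- !is.na(lr) & log(stats::runif(n)) < lr
        if (any(acc)) {
          st$a[acc] <- ap[acc]; eta[acc] <- eta2[acc]; ll[acc] <- ll2[acc]
        }
        bump("a", as.numeric(acc), gamma)
      }
    }

    ## scales ----------------------------------------------------------------
    if (use_u && is.null(fixed$sigma_u)) {
      sp <- st$sigma_u + stats::rnorm(1, 0, exp(ls$sigma_u))
      acc <- FALSE
      if (sp > 0 && sp < bnd) {
        lr <- sum(stats::dnorm(st$u, 0, sp, log = TRUE)) -
          sum(stats::dnorm(st$u, 0, st$sigma_u, log = TRUE))
        acc <- is.finite(lr) && log(stats::runif(1)) < lr
        if (acc) st$sigma_u <- sp
      }
      bump("sigma_u", as.numeric(acc), gamma)
    }
    if (use_v && is.null(fixed$sigma_v)) {
      sp <- st$sigma_v + stats::rnorm(1, 0, exp(ls$sigma_v))
      acc <- FALSE
      if (sp > 0 && sp < bnd) {
        ss <- icar_ss(st$v, graph)
        tau_new <- 1 / sp^2; tau_old <- 1 / st$sigma_v^2
        lr <- (rank_icar / 2) * (log(tau_new) - log(tau_old)) -
          (tau_new - tau_old) / 2 * ss
        acc <- is.finite(lr) && log(stats::runif(1)) < lr
        if (acc) st$sigma_v <- sp
      }
      bump("sigma_v", as.numeric(acc), gamma)
    }
    if (is.null(fixed$sigma_1)) {
      sp <- st$sigma_1 + stats::rnorm(1, 0, exp(ls$sigma_1))
      acc <- FALSE
      if (sp > 0 && sp < bnd) {
        lr <- stats::dnorm(st$beta1, b1m, sp, log = TRUE) -
          stats::dnorm(st$beta1, b1m, st$sigma_1, log = TRUE)
        acc <- is.finite(lr) && log(stats::runif(1)) < lr
        if (acc) st$sigma_1 <- sp
      }
      bump("sigma_1", as.numeric(acc), gamma)
    }

    ## joint scaling moves: rescale a scale parameter together with its
    ## latent field (sigma' = sigma e^eps, field' = field e^eps).  The prior
    ## terms and the transform Jacobian collapse to a single factor e^eps
    ## times the likelihood ratio, which lets the chain traverse the
    ## (scale, field) ridge that single-coordinate walks climb slowly.
    if (use_u && is.null(fixed$sigma_u) && is.null(fixed$u)) {
      eps <- stats::rnorm(1, 0, 0.4)
      sp <- st$sigma_u * exp(eps)
      if (sp < bnd) {
        cu <- if (use_a) a_long() else 1
        up <- st$u * exp(eps)
        eta2 <- eta + cu * (up - st$u)
        ll2 <- ll_vec(eta2)
        lr <- sum(ll2) - sum(ll) + eps
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          st$sigma_u <- sp; st$u <- up; eta <- eta2; ll <- ll2
        }
      }
    }
    if (use_v && is.null(fixed$sigma_v) && is.null(fixed$v)) {
      eps <- stats::rnorm(1, 0, 0.4)
      sp <- st$sigma_v * exp(eps)
      if (sp < bnd) {
        cv <- if (use_a) 1 - a_long() else rep(1, n)
        vp <- st$v * exp(eps)          # sum-to-zero is scale-invariant
        eta2 <- eta + cv * (vp - st$v)
        ll2 <- ll_vec(eta2)
        lr <- sum(ll2) - sum(ll) + eps
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          st$sigma_v <- sp; st$v <- vp; eta <- eta2; ll <- ll2
        }
      }
    }
    if (is.null(fixed$sigma_1) && is.null(fixed$beta1)) {
      eps <- stats::rnorm(1, 0, 0.4)
      sp <- st$sigma_1 * exp(eps)
      if (sp < bnd) {
        b1p <- b1m + (st$beta1 - b1m) * exp(eps)
        eta2 <- eta + (b1p - st$beta1) * idx
        ll2 <- ll_vec(eta2)
        lr <- sum(ll2) - sum(ll) + eps
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          st$sigma_1 <- sp; st$beta1 <- b1p; eta <- eta2; ll <- ll2
        }
      }
    }

    ## periodic refresh guards against float drift in the incremental
    ## index/linear-predictor bookkeeping
    if (t %% 512L == 0L) {
      idx <- as.vector(q %*% st$w)
      eta <- eta_of()
      ll <- ll_vec(eta)
    }

    ## retention -------------------------------------------------------------
    if (t > burnin && (t - burnin) %% thin == 0L) {
      g_idx <- g_idx + 1L
      draws$beta0[g_idx] <- st$beta0
      draws$beta1[g_idx] <- st$beta1
      draws$w[g_idx, ] <- st$w
      draws$sigma_u[g_idx] <- st$sigma_u
      draws$sigma_v[g_idx] <- st$sigma_v
      draws$sigma_1[g_idx] <- st$sigma_1
      draws$deviance[g_idx] <-
        if (prior_only) NA_real_ else -2 * poisson_loglik(y, E, eta)
      theta <- exp(eta)
      if (control$store_theta) draws$theta[g_idx, ] <- theta
      if (control$store_effects) {
        if (use_u) draws$u[g_idx, ] <- st$u
        if (use_v) draws$v[g_idx, ] <- st$v
        if (use_a) draws$a[g_idx, ] <- st$a
      }
      sums$u <- sums$u + st$u
      sums$v <- sums$v + st$v
      sums$a <- sums$a + st$a
      sums$theta <- sums$theta + theta
    }
  }

  acceptance <- mapply(function(num, den) num / den, acc_n, acc_d)
  list(variant = variant, n = n, C = C,
       draws = draws,
       post = list(beta0 = mean(draws$beta0), beta1 = mean(draws$beta1),
                   w = colMeans(draws$w),
                   u = sums$u / G, v = sums$v / G, a = sums$a / G,
                   theta = sums$theta / G),
       m = burnin, G = G, thin = thin, seed = as.integer(seed),
       prior = prior, control = control, acceptance = acceptance)
}
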