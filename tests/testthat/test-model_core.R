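test_that("the weighted decile index is a convex combination of scores", {
  q <- matrix(3L, 4, 12)
  expect_equal(ndi_index(q, rep(1 / 12, 12)), rep(3, 4))
  q2 <- matrix(c(1L, 5L, 9L, 2L, 0L, 7L), 3, 2)
  expect_equal(ndi_index(q2, c(1, 0)), c(1, 5, 9))
  expect_equal(ndi_index(matrix(c(2L, 8L), 1, 2), c(0.5, 0.5)), 5)
  expect_error(ndi_index(q2, rep(1 / 3, 3)), "match")
  expect_error(ndi_index(q2, c(0.7, 0.7)), "sum to 1")
})

test_that("equal-contribution threshold for a 12-variable index prints as 0.083", {
  expect_equal(round(equal_weight_threshold(12), 3), 0.083)
  expect_equal(equal_weight_threshold(4), 0.25)
})

test_that("the four log-relative-risk structures nest as advertised", {
  n <- 5
  idx <- c(5, 2, 0, 9, 4)
  st <- list(beta0 = 0, beta1 = 0, u = rep(0, n), v = rep(0, n),
             a = rep(0.5, n))
  expect_equal(log_relative_risk(st, idx, 1), rep(0, n))   # null model

  set.seed(2)
  st <- list(beta0 = 0.3, beta1 = 0.1, u = stats::rnorm(n),
             v = stats::rnorm(n), a = stats::runif(n))
  # mixture at the boundaries reproduces the pure variants
  st1 <- st; st1$a <- rep(1, n)
  expect_equal(log_relative_risk(st1, idx, 4), log_relative_risk(st, idx, 1))
  st0 <- st; st0$a <- rep(0, n)
  expect_equal(log_relative_risk(st0, idx, 4), log_relative_risk(st, idx, 2))
  # convolution arithmetic
  st3 <- list(beta0 = 0.1, beta1 = 0.2, u = rep(0.05, n), v = rep(-0.05, n))
  expect_equal(log_relative_risk(st3, rep(5, n), 3), rep(1.1, n))
  expect_error(log_relative_risk(st, idx, 7), "variant")
})

test_that("the Poisson log-likelihood has its closed form and MLE", {
  expect_equal(poisson_loglik(0, 1, 0), -1)
  expect_equal(poisson_loglik(2, 1, 0), -1 - log(2))
  # agrees with dpois up to vector accumulation
  set.seed(4)
  y <- stats::rpois(20, 3); E <- stats::runif(20, 0.5, 4)
  lt <- stats::rnorm(20, 0, 0.3)
  expect_equal(poisson_loglik(y, E, lt),
               sum(stats::dpois(y, E * exp(lt), log = TRUE)))
  # numeric maximisation oracle: theta-hat = y/E maximises each term
  for (i in c(1, 7, 13)) {
    if (y[i] == 0) next
    f <- function(t) poisson_loglik(y[i], E[i], log(t))
    opt <- stats::optimize(f, c(1e-4, 60), maximum = TRUE)
    expect_equal(opt$maximum, y[i] / E[i], tolerance = 1e-3)
  }
  # zero-expectation tracts contribute nothing when empty, error otherwise
  expect_equal(poisson_loglik(c(0, 2), c(0, 1), c(0, 0)), -1 + 2 * 0 - log(2))
  expect_error(poisson_loglik(1, 0, 0), "impossible")
})

test_that("ICAR log-density equals its full-conditional quadratic form", {
  g2 <- path_graph(2)
  expect_equal(icar_logdensity(c(1, -1), 1, g2), -2)
  # full conditional of a node with neighbour values {0, 2}: mean 1, prec 2*tau
  g3 <- path_graph(3)
  tau <- 1.7
  f <- function(vi) icar_logdensity(c(0, vi, 2), tau, g3)
  vs <- seq(-1, 3, 0.5)
  ll <- vapply(vs, f, numeric(1))
  fitq <- stats::lm(ll ~ vs + I(vs^2))
  curv <- -2 * unname(stats::coef(fitq)[3])          # conditional precision
  mu <- unname(stats::coef(fitq)[2]) / curv          # conditional mean
  expect_equal(curv, 2 * tau, tolerance = 1e-8)
  expect_equal(mu, 1, tolerance = 1e-8)
  # pairwise-difference form equals the Laplacian quadratic form, random states
  g <- grid_graph(4, 4)
  L <- graph_laplacian(g)
  set.seed(12)
  for (k in 1:5) {
    v <- stats::rnorm(16)
    tau <- stats::runif(1, 0.2, 3)
    expect_equal(icar_logdensity(v, tau, g),
                 (g$n - 1) / 2 * log(tau) -
                   tau / 2 * as.numeric(t(v) %*% L %*% v),
                 tolerance = 1e-10)
  }
})

test_that("ICAR density is invariant to constant shifts within a component", {
  g <- grid_graph(3, 3)
  set.seed(5)
  v <- stats::rnorm(9)
  expect_equal(icar_logdensity(v, 0.8, g), icar_logdensity(v + 3.7, 0.8, g))
})

test_that("the joint log prior assembles the stated pieces", {
  C <- 4
  pr <- ndi_prior(C)
  mk_state <- function(...) {
    st <- list(beta0 = 0.2, beta1 = 0.1, w = rep(1 / C, C),
               u = rep(0.1, 6), v = c(rep(0.05, 3), rep(-0.05, 3)),
               a = rep(0.4, 6), sigma_u = 1, sigma_v = 1, sigma_1 = 1)
    utils::modifyList(st, list(...))
  }
  g <- path_graph(6)
  # flat Dirichlet: any interior point has the same prior density
  w2 <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(log_prior(mk_state(), pr, g, 4),
               log_prior(mk_state(w = w2), pr, g, 4))
  # Beta(1,1) mixing contributes 0: changing a leaves the prior unchanged
  expect_equal(log_prior(mk_state(), pr, g, 4),
               log_prior(mk_state(a = rep(0.9, 6)), pr, g, 4))
  # out-of-support scale
  expect_equal(log_prior(mk_state(sigma_v = 150), pr, g, 4), -Inf)
  expect_equal(log_prior(mk_state(w = c(0.5, 0.5, 0, 0)), pr, g, 4), -Inf)
  # flat intercept: beta0 does not enter
  expect_equal(log_prior(mk_state(beta0 = 57), pr, g, 4),
               log_prior(mk_state(), pr, g, 4))
})

test_that("proper priors break the intercept/random-effect translation invariance", {
  # with a proper Normal prior on u, moving level from beta0 into u must
  # change the joint prior (catches accidentally improper parameterisations)
  pr <- ndi_prior(2)
  g <- path_graph(4)
  st <- list(beta0 = 0, beta1 = 0, w = c(0.5, 0.5), u = rep(0, 4),
             v = rep(0, 4), a = rep(0.5, 4), sigma_u = 1, sigma_v = 1,
             sigma_1 = 1)
  st2 <- st; st2$beta0 <- 1; st2$u <- st$u - 1
  expect_false(isTRUE(all.equal(log_prior(st, pr, g, 1),
                                log_prior(st2, pr, g, 1))))
})

test_that("variant-4 likelihood at unit mixing equals variant 1 exactly", {
  set.seed(8)
  n <- 10
  idx <- stats::runif(n, 0, 9)
  y <- stats::rpois(n, 2); E <- stats::runif(n, 0.5, 3)
  st <- list(beta0 = 0.1, beta1 = 0.05, u = stats::rnorm(n, 0, 0.3),
             v = stats::rnorm(n, 0, 0.3), a = rep(1, n))
  expect_identical(
    poisson_loglik(y, E, log_relative_risk(st, idx, 4)),
    poisson_loglik(y, E, log_relative_risk(st, idx, 1)))
})

test_that("prior hyperparameters are validated and serialisable", {
  expect_error(ndi_prior(3, alpha = c(1, -1, 1)), "alpha")
  pr <- ndi_prior(5, alpha = 2, beta1_mean = 1)
  expect_equal(pr$alpha, rep(2, 5))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(f, pr, ndi_control(n_iter = 500, burnin = 100), 3)
  cfg <- read_model_config(f)
  expect_equal(cfg$prior$alpha, pr$alpha)
  expect_equal(cfg$prior$beta1_mean, 1)
  expect_equal(cfg$variant, 3)
  expect_equal(cfg$control$n_iter, 500L)
})
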