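test_that("identical seed, spec and data give identical draws", {
  tab <- make_table(n = 16, C = 3, seed = 2)
  g <- grid_graph(4, 4)
  ctl <- ndi_control(n_iter = 600, burnin = 200)
  f1 <- ndi_fit(tab, graph = g, variant = 3, control = ctl, seed = 42)
  f2 <- ndi_fit(tab, graph = g, variant = 3, control = ctl, seed = 42)
  expect_identical(f1$draws, f2$draws)
  f3 <- ndi_fit(tab, graph = g, variant = 3, control = ctl, seed = 43)
  expect_false(identical(f1$draws$beta1, f3$draws$beta1))
})

test_that("parameters named in `fixed` never move", {
  tab <- make_table(n = 16, C = 3, seed = 2)
  w_fix <- c(0.2, 0.3, 0.5)
  ctl <- ndi_control(n_iter = 500, burnin = 100,
                     fixed = list(beta1 = 0.25, w = w_fix))
  fit <- ndi_fit(tab, variant = 1, control = ctl, seed = 1)
  expect_true(all(fit$draws$beta1 == 0.25))
  expect_true(all(apply(fit$draws$w, 1, function(w) all(w == w_fix))))
})

test_that("retained draws respect the simplex and bound constraints", {
  tab <- make_table(n = 25, C = 4, seed = 6)
  g <- grid_graph(5, 5)
  fit <- ndi_fit(tab, graph = g, variant = 4,
                 control = ndi_control(n_iter = 1500, burnin = 500,
                                       store_effects = TRUE), seed = 9)
  expect_equal(rowSums(fit$draws$w), rep(1, fit$G), tolerance = 1e-12)
  expect_true(all(fit$draws$w > 0))
  expect_true(all(fit$draws$sigma_u > 0 & fit$draws$sigma_u < 100))
  expect_true(all(fit$draws$sigma_v > 0 & fit$draws$sigma_v < 100))
  expect_true(all(fit$draws$a > 0 & fit$draws$a < 1))
  # sum-to-zero recentring holds after every sweep
  expect_lt(max(abs(rowSums(fit$draws$v))), 1e-8)
  # G bookkeeping
  expect_equal(fit$G, (1500 - 500) %/% 1)
  expect_equal(fit$m, 500)
})

test_that("adaptive scaling settles scalar blocks into a sane acceptance band", {
  cfg <- sim_config(rows = 8, cols = 8, C = 3, beta1_true = 0.2,
                    variant = 1, seed = 31)
  sim <- simulate_tracts(cfg)
  fit <- ndi_fit(sim$data, variant = 1,
                 control = ndi_control(n_iter = 4000, burnin = 2000),
                 seed = 32)
  for (b in c("beta0", "beta1", "z")) {
    expect_gt(fit$acceptance[[b]], 0.2)
    expect_lt(fit$acceptance[[b]], 0.6)
  }
})

test_that("with the likelihood disabled each block reproduces its prior", {
  tab <- make_table(n = 8, C = 4, seed = 3, households = rep(100L, 8))
  # flat Dirichlet weights: component means 1/C; every draw on the simplex
  ctl <- ndi_control(n_iter = 20000, burnin = 4000, prior_only = TRUE,
                     fixed = list(sigma_1 = 1))
  fit <- quiet_deciles(ndi_fit(tab, variant = 1, control = ctl, seed = 51))
  expect_equal(unname(colMeans(fit$draws$w)), rep(0.25, 4), tolerance = 0.03)
  # beta1 reproduces its Normal(0, sigma_1^2) prior
  expect_equal(mean(fit$draws$beta1), 0, tolerance = 0.1)
  expect_equal(stats::sd(fit$draws$beta1), 1, tolerance = 0.1)

  # asymmetric Dirichlet: mean of the loaded component is alpha_1/sum(alpha)
  pr <- ndi_prior(4, alpha = c(10, 1, 1, 1))
  fit2 <- quiet_deciles(ndi_fit(tab, variant = 1, prior = pr,
                                control = ctl, seed = 52))
  expect_equal(unname(colMeans(fit2$draws$w)[1]), 10 / 13, tolerance = 0.03)
})

test_that("near-degenerate unstructured scale pins the random effects", {
  tab <- make_table(n = 16, C = 2, seed = 4)
  ctl <- ndi_control(n_iter = 800, burnin = 300, store_effects = TRUE,
                     fixed = list(sigma_u = 1e-5))
  fit <- ndi_fit(tab, variant = 1, control = ctl, seed = 8)
  expect_lt(max(abs(fit$draws$u)), 1e-2)
})

test_that("prior-only ICAR sampling matches the constrained analytic covariance", {
  # path of 3 nodes, sigma_v fixed: covariance of the constrained field is
  # sigma^2 times the Laplacian pseudo-inverse
  g <- path_graph(3)
  tab <- make_table(n = 3, C = 2, seed = 5, households = rep(50L, 3))
  ctl <- ndi_control(n_iter = 30000, burnin = 5000, prior_only = TRUE,
                     store_effects = TRUE,
                     fixed = list(sigma_v = 1, sigma_1 = 1, beta1 = 0))
  fit <- quiet_deciles(ndi_fit(tab, graph = g, variant = 2, control = ctl,
                               seed = 13))
  emp <- stats::cov(fit$draws$v)
  ana <- MASS::ginv(graph_laplacian(g))
  expect_equal(emp, ana, tolerance = 0.12)
  # pairwise-difference variances in particular
  expect_equal(stats::var(fit$draws$v[, 1] - fit$draws$v[, 2]),
               ana[1, 1] + ana[2, 2] - 2 * ana[1, 2], tolerance = 0.1)
})

test_that("flat mixing likelihood reverts the mixing parameter to its prior", {
  # u == v makes the likelihood constant in a, so a must look Beta(1,1)
  tab <- make_table(n = 9, C = 2, seed = 7, households = rep(200L, 9))
  g <- grid_graph(3, 3)
  ctl <- ndi_control(n_iter = 15000, burnin = 3000, store_effects = TRUE,
                     fixed = list(u = rep(0, 9), v = rep(0, 9),
                                  sigma_1 = 1))
  fit <- quiet_deciles(ndi_fit(tab, graph = g, variant = 4, control = ctl,
                               seed = 14))
  a <- as.vector(fit$draws$a)
  expect_equal(mean(a), 0.5, tolerance = 0.02)
  expect_equal(stats::var(a), 1 / 12, tolerance = 0.01)
  expect_true(all(a > 0 & a < 1))
})

test_that("variant-3 posterior for beta1 matches an importance-sampling oracle", {
  # 5-tract path; all scales fixed so the prior is fully proper and an
  # independent importance sampler from the prior is exact in the limit
  set.seed(61)
  n <- 5
  g <- path_graph(n)
  h <- rep(400L, n)
  idx_fix_w <- c(0.5, 0.5)
  x <- matrix(stats::runif(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- c(1L, 3L, 0L, 2L, 4L)
  tab <- tract_table(data.frame(tract_id = paste0("T", 1:n),
                                households = h, count = y, x))
  E <- expected_counts(y, h)$E
  q <- quiet_deciles(decile_matrix(tab))
  idx <- ndi_index(q, idx_fix_w)
  su <- 0.3; sv <- 0.3
  ctl <- ndi_control(n_iter = 40000, burnin = 8000,
                     fixed = list(beta0 = 0, w = idx_fix_w,
                                  sigma_u = su, sigma_v = sv, sigma_1 = 1))
  fit <- quiet_deciles(ndi_fit(tab, graph = g, variant = 3, control = ctl,
                               seed = 62))
  # oracle: importance sampling from the (proper) prior
  M <- 200000
  b1 <- stats::rnorm(M, 0, 1)
  U <- matrix(stats::rnorm(M * n, 0, su), M, n)
  L <- graph_laplacian(g)
  eg <- eigen(L, symmetric = TRUE)
  pos <- eg$values > 1e-9
  Z <- matrix(stats::rnorm(M * sum(pos)), M, sum(pos))
  V <- Z %*% diag(1 / sqrt(eg$values[pos]), sum(pos)) %*%
    t(eg$vectors[, pos]) * sv
  eta <- outer(b1, idx) + U + V
  lw <- eta %*% y - exp(eta) %*% E
  lw <- lw - max(lw)
  wgt <- exp(lw)
  mu_or <- sum(wgt * b1) / sum(wgt)
  sd_or <- sqrt(sum(wgt * (b1 - mu_or)^2) / sum(wgt))
  expect_equal(mean(fit$draws$beta1), mu_or, tolerance = 0.03)
  expect_equal(stats::sd(fit$draws$beta1), sd_or, tolerance = 0.03)
})

test_that("a short recovery run lands within posterior uncertainty of the truth", {
  cfg <- sim_config(rows = 10, cols = 10, C = 4, rho = 0.3,
                    w_true = c(0.4, 0.3, 0.2, 0.1), beta1_true = 0.3,
                    variant = 1, sigma_u_true = 0.15, seed = 71)
  rh <- recovery_harness(cfg, control = ndi_control(n_iter = 6000,
                                                    burnin = 2500),
                         seed = 72)
  expect_lt(abs(rh$report$beta1_mean - 0.3), 3 * rh$report$beta1_sd)
  expect_true(rh$report$rr_significant)
})

test_that("the sampler refuses impossible starts and degenerate data", {
  tab <- make_table(n = 10, C = 2, seed = 1, counts = rep(0L, 10))
  expect_error(ndi_fit(tab, variant = 1), "no events")
  tab2 <- make_table(n = 10, C = 2, seed = 1)
  expect_error(ndi_fit(tab2, variant = 2), "adjacency")
  expect_error(ndi_fit(tab2, variant = 1,
                       control = ndi_control(fixed = list(w = c(2, -1)))),
               "simplex")
})
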