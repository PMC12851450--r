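test_that("prior sampling respects ranges and the w-simplex", {
  draws <- sample_prior(5000, seed = 2)
  expect_true(all(draws$p_m >= 0 & draws$p_m <= 1))
  expect_true(all(draws$p_p >= 0 & draws$p_p <= 0.015))
  expect_true(all(draws$w_wm + draws$w_bv <= 1))

  wm_only <- sample_prior(100, variant = "wm-only", seed = 3)
  expect_true(all(wm_only$w_bv == 0))

  # uniform on the triangle w_wm + w_bv <= 1 has marginal mean 1/3
  big <- sample_prior(1e5, seed = 4)
  expect_equal(mean(big$w_wm), 1 / 3, tolerance = 0.01)
  expect_equal(mean(big$w_bv), 1 / 3, tolerance = 0.01)
})

test_that("rejection keeps the closest fraction and reports delta", {
  set.seed(6)
  d <- runif(5000)
  rej <- abc_rejection(d, 0.01)
  expect_identical(rej$n_accept, 50L)
  expect_identical(length(rej$indices), 50L)
  expect_equal(rej$delta, sort(d)[50])
  expect_identical(sort(rej$indices), sort(order(d)[1:50]))

  all_in <- abc_rejection(d, 1)
  expect_identical(all_in$n_accept, length(d))
  expect_equal(all_in$delta, max(d))
  expect_error(abc_rejection(d, 1e-6), "at least 1")
  expect_error(abc_rejection(c(1, NA, 2), 0.5), "finite")
})

test_that("rejection is invariant under monotone distance transforms", {
  set.seed(9)
  d <- runif(300)
  a <- abc_rejection(d, 0.1)
  b <- abc_rejection(exp(3 * d) - 1, 0.1)
  expect_identical(sort(a$indices), sort(b$indices))
})

test_that("regression adjustment recovers a linear relationship", {
  # theta = a + b s + noise around s_obs; the adjusted sample must
  # concentrate at a + b s_obs, matching a closed-form WLS oracle
  set.seed(12)
  n <- 60
  a <- 0.45; b <- 1.2; s_obs <- 0.05
  s <- s_obs + runif(n, -0.04, 0.04)
  theta <- tibble::tibble(p_m = a + b * (s - s_obs) + rnorm(n, 0, 1e-3))
  dist <- abs(s - s_obs)
  delta <- max(dist)
  adj <- abc_regression_adjust(theta, matrix(s, ncol = 1), s_obs, dist, delta,
                               prior = prior_spec())
  expect_true(isTRUE(attr(adj, "adjusted")))
  expect_lt(max(abs(adj$p_m - a)), 1e-2)

  # closed-form WLS oracle on the logit scale
  w <- 1 - (dist / delta)^2
  X <- cbind(1, s - s_obs)
  z <- qlogis(theta$p_m)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * z))
  z_adj <- z - (s - s_obs) * beta[2]
  expect_equal(adj$p_m, plogis(z_adj), tolerance = 1e-12)
})

test_that("regression adjustment degrades gracefully and respects the prior", {
  theta <- tibble::tibble(p_m = runif(20, 0.3, 0.7))
  stats <- matrix(0.5, 20, 1)
  # all simulated statistics equal the observation: delta = 0, no adjustment
  adj <- abc_regression_adjust(theta, stats, 0.5, rep(0, 20), 0)
  expect_identical(adj$p_m, theta$p_m)
  expect_false(isTRUE(attr(adj, "adjusted")))

  # adjusted samples always stay strictly inside the prior range
  set.seed(15)
  n <- 40
  s <- rnorm(n)
  theta2 <- tibble::tibble(p_p = runif(n, 0.014, 0.015))  # near the upper edge
  dist <- abs(s); delta <- max(dist)
  adj2 <- abc_regression_adjust(theta2, matrix(s, ncol = 1), 0, dist, delta)
  expect_true(all(adj2$p_p > 0 & adj2$p_p < 0.015))

  # constant parameters (wm-only variant) pass through unchanged
  theta3 <- tibble::tibble(p_m = runif(n, 0.2, 0.8), w_bv = rep(0, n))
  adj3 <- abc_regression_adjust(theta3, matrix(s, ncol = 1), 0, dist, delta)
  expect_identical(adj3$w_bv, rep(0, n))
})

test_that("posterior point estimation matches a quadrature oracle", {
  # all samples at one interior point
  pe <- posterior_point_estimate(rep(0.42, 50), c(0, 1))
  expect_equal(pe$estimate, 0.42, tolerance = 1e-3)

  # samples symmetric about the range midpoint
  x <- c(0.3, 0.7, 0.4, 0.6, 0.5)
  pe <- posterior_point_estimate(x, c(0, 1))
  expect_equal(pe$estimate, 0.5, tolerance = 1e-9)

  # 50 draws from a truncated normal vs an independent fine-grid oracle
  set.seed(19)
  x <- pmin(pmax(rnorm(50, 0.6, 0.15), 0.01), 0.99)
  pe <- posterior_point_estimate(x, c(0, 1))
  g <- seq(0, 1, length.out = 10001)
  h <- 0.1
  f <- vapply(g, function(gi) {
    u <- (gi - x) / h
    sum(ifelse(abs(u) <= 1, 0.75 * (1 - u^2), 0))
  }, numeric(1))
  dg <- g[2] - g[1]
  mean_or <- sum(g * f) / sum(f)
  expect_equal(pe$estimate, mean_or, tolerance = 1e-4)
  cdf <- cumsum(f) / sum(f)
  expect_equal(pe$q10, g[which.min(abs(cdf - 0.1))], tolerance = 2e-3)
  expect_equal(pe$q90, g[which.min(abs(cdf - 0.9))], tolerance = 2e-3)

  # the scaled prior range maps back to natural units
  pe2 <- posterior_point_estimate(rep(0.0075, 30), c(0, 0.015))
  expect_equal(pe2$estimate, 0.0075, tolerance = 1e-5)
})

test_that("estimation error implements the relative-error average", {
  truth <- c(p_m = 0.5, p_p = 0.005, w_wm = 0.2, w_bv = 0.3)
  perfect <- tibble::tibble(p_m = 0.5, p_p = 0.005, w_wm = 0.2, w_bv = 0.3)
  expect_equal(estimation_error(truth, perfect)$E, 0)

  # one parameter off by 100%, the rest exact -> E_i = 1/4
  off <- perfect; off$p_m <- 1.0
  expect_equal(estimation_error(truth, off)$E_i, 0.25)

  set.seed(22)
  many <- tibble::tibble(p_m = runif(10), p_p = runif(10, 0, 0.015),
                         w_wm = runif(10), w_bv = runif(10))
  err <- estimation_error(truth, many)
  expect_equal(err$E, mean(err$E_i))
  expect_error(estimation_error(c(p_m = 0, p_p = 1), many), "undefined")
})

test_that("model support counts accepted simulations per model", {
  set.seed(25)
  # two statistically identical pools: support near 1/2 each
  stats <- matrix(rnorm(2000 * 3), ncol = 3)
  model <- rep(c("full", "wm_only"), each = 1000)
  sup <- model_support(stats, model, s_obs = c(0, 0, 0), accept_frac = 0.05)
  expect_equal(sum(sup$fraction), 1)
  expect_lt(abs(sup$fraction[1] - 0.5), 0.2)

  # one model strictly dominated: its fraction is 0
  far <- rbind(matrix(rnorm(500 * 2), ncol = 2),
               matrix(rnorm(500 * 2, mean = 50), ncol = 2))
  sup2 <- model_support(far, rep(c("near", "far"), each = 500),
                        s_obs = c(0, 0), accept_frac = 0.05)
  expect_equal(sup2$fraction[sup2$model == "far"], 0)
  expect_equal(sup2$fraction[sup2$model == "near"], 1)

  # counting oracle on random labels
  stats3 <- matrix(runif(400), ncol = 1)
  lab3 <- sample(c("a", "b"), 400, replace = TRUE)
  sup3 <- model_support(stats3, lab3, s_obs = 0, accept_frac = 0.1)
  idx <- order(abs(stats3[, 1] - median(stats3[, 1])))  # not the same rule
  rej <- abc_rejection(abs(stats3[, 1]) / stats::mad(stats3[, 1]), 0.1)
  acc_lab <- lab3[rej$indices]
  expect_equal(sup3$n_accepted[sup3$model == "a"], sum(acc_lab == "a"))
})

test_that("rescaling converts per-step probabilities to physical rates", {
  r <- rescale_parameters(p_m = 0.5, p_p = 0, duration_days = 60,
                          spacing_um = 43, steps = 1800)
  expect_equal(r$dt_hours, 0.8)
  expect_equal(r$P_m_um_per_h, 26.875)

  r2 <- rescale_parameters(p_m = 0, p_p = 0.01, duration_days = 90,
                           spacing_um = 43, steps = 1800)
  expect_equal(r2$P_p_per_day, 0.2)  # 20 steps per day
  expect_equal(rescale_parameters(0, 0, 10)$P_m_um_per_h, 0)
  expect_error(rescale_parameters(0.5, 0.01, -1), "positive")
})

test_that("end-to-end fit recovers an observation planted in the pool", {
  # degenerate configuration: the observed simulation is in the pool and the
  # acceptance count is 1, so it must accept itself at distance 0
  atl <- generate_synthetic_atlas(shape = c(20, 20, 20), seed = 6)
  init <- initialize_tumor(atl, radius = 2)
  draws <- sample_prior(20, seed = 7)
  pool <- simulate_pool(draws, atl, init, steps = 30, seed = 8)
  obs_stats <- unlist(pool[7, gliomalatt:::.stat_names])
  fit <- abc_fit(pool, obs_stats, accept_frac = 1 / nrow(pool), adjust = FALSE)
  expect_equal(fit$delta, 0)
  expect_equal(fit$accepted$p_m[1], pool$p_m[7])
  expect_equal(unname(glance(fit)$n_accepted), 1L)

  # tidy() exposes the per-parameter estimates
  fit2 <- abc_fit(pool, obs_stats, accept_frac = 0.8, adjust = TRUE)
  td <- tidy(fit2)
  expect_true(all(c("parameter", "estimate", "q10", "q90") %in% names(td)))
  expect_identical(nrow(td), 4L)
  expect_true(all(td$q10 <= td$q90))
})
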