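test_that("single-predictor coefficients reduce to cov/var on the published matrix", {
  G <- pregnancy_example_G()
  b <- ranef_coefficients(G, "map:intercept", "weight:intercept")
  expect_equal(unname(b), 25.574 / 119.611, tolerance = 1e-12)
  expect_equal(unname(b), 0.2138, tolerance = 1e-4)
})

test_that("a predictor proportional to the outcome recovers the proportionality constant", {
  c0 <- 2.5
  G <- matrix(c(4, c0 * 4, c0 * 4, c0^2 * 4 + 1), 2, 2,
    dimnames = rep(list(c("x", "y")), 2)
  )
  expect_equal(unname(ranef_coefficients(G, "y", "x")), c0, tolerance = 1e-12)
})

test_that("multi-predictor coefficients match OLS on a huge sample of random-effect draws", {
  withr::with_seed(101, {
    A <- matrix(rnorm(16), 4)
    G <- crossprod(A) + diag(0.5, 4)
    dimnames(G) <- rep(list(c("u0", "u1", "u2", "u3")), 2)
    beta <- ranef_coefficients(G, "u0", c("u1", "u2", "u3"))
    draws <- MASS::mvrnorm(1e6, rep(0, 4), G)
    ols <- lm.fit(cbind(1, draws[, 2:4]), draws[, 1])$coefficients[-1]
    expect_equal(unname(beta), unname(ols), tolerance = 1e-2)
  })
})

test_that("coefficients are invariant to predictor reordering", {
  G <- toy_G()
  b1 <- ranef_coefficients(G, "y2:slope2", c("y1:slope1", "y1:intercept", "y2:intercept"))
  b2 <- ranef_coefficients(G, "y2:slope2", c("y2:intercept", "y1:slope1", "y1:intercept"))
  expect_equal(b1[names(b2)], b2, tolerance = 1e-12)
})

test_that("collinear predictors and malformed queries are rejected", {
  G <- toy_G()
  Gc <- rbind(cbind(G, dup = G[, 1]), dup = c(G[1, ], G[1, 1]))
  colnames(Gc)[7] <- rownames(Gc)[7] <- "dup"
  expect_error(
    ranef_coefficients(Gc, "y2:slope2", c("y1:intercept", "dup")),
    "collinear"
  )
  expect_error(ranef_coefficients(G, "y1:slope1", "y1:slope1"), "outcome")
  expect_error(ranef_coefficients(G, "nope", "y1:slope1"), "unknown outcome")
})

test_that("moment-based SEs reproduce a textbook regression exactly", {
  withr::with_seed(5, {
    n <- 250
    X <- MASS::mvrnorm(n, rep(0, 3), toy_G()[1:3, 1:3])
    y <- 0.4 * X[, 1] - 0.2 * X[, 2] + rnorm(n)
    S <- stats::cov(cbind(y = y, x1 = X[, 1], x2 = X[, 2], x3 = X[, 3]))
    se <- ranef_se_moment(S, "y", c("x1", "x2", "x3"), n = n)
    beta <- ranef_coefficients(S, "y", c("x1", "x2", "x3"))
    lmfit <- lm(y ~ X)
    expect_equal(unname(beta), unname(coef(lmfit)[-1]), tolerance = 1e-10)
    expect_equal(unname(se), unname(summary(lmfit)$coefficients[-1, 2]), tolerance = 1e-10)
  })
})

test_that("moment-based SE closed form and scaling law hold", {
  G <- diag(c(1, 1))
  dimnames(G) <- rep(list(c("y", "x")), 2)
  expect_equal(
    unname(ranef_se_moment(G, "y", "x", n = 101)), sqrt(1 / 99),
    tolerance = 1e-12
  )
  se_small <- ranef_se_moment(toy_G(), "y2:slope2", "y1:slope1", n = 52)
  se_big <- ranef_se_moment(toy_G(), "y2:slope2", "y1:slope1", n = 102)
  expect_equal(unname(se_small / se_big), sqrt(2), tolerance = 1e-12)
  expect_error(
    ranef_se_moment(matrix(c(1, 2, 2, 1), 2, dimnames = rep(list(c("y", "x")), 2)), "y", "x", n = 100),
    "positive semi-definite"
  )
})

test_that("delta-method SEs match the closed form and finite differences", {
  # p = 1 closed form: beta = s01/s11, gradient (1/s11, -s01/s11^2)
  G <- toy_G()
  fit <- toy_fit_cache()
  Gh <- fit$G; Gam <- fit$gamma
  s01 <- Gh["y2:slope2", "y1:slope1"]; s11 <- Gh["y1:slope1", "y1:slope1"]
  g <- c(1 / s11, -s01 / s11^2)
  nm <- c("y1:slope1||y2:slope2", "y1:slope1||y1:slope1")
  se_closed <- sqrt(drop(t(g) %*% Gam[nm, nm] %*% g))
  se_pkg <- ranef_se_delta(Gh, Gam, "y2:slope2", "y1:slope1")
  expect_equal(unname(se_pkg), se_closed, tolerance = 1e-12)

  # p = 3: analytic Jacobian vs central finite differences of the solver
  preds <- c("y1:slope1", "y1:intercept", "y2:intercept")
  jb <- parallelgrowth:::beta_jacobian(Gh, "y2:slope2", preds)
  h <- 1e-6
  for (k in seq_len(nrow(jb$entries))) {
    ti <- jb$entries$term_i[k]; tj <- jb$entries$term_j[k]
    Gp <- Gh; Gp[ti, tj] <- Gp[ti, tj] + h; Gp[tj, ti] <- Gp[ti, tj]
    Gm <- Gh; Gm[ti, tj] <- Gm[ti, tj] - h; Gm[tj, ti] <- Gm[ti, tj]
    fd <- (ranef_coefficients(Gp, "y2:slope2", preds) -
      ranef_coefficients(Gm, "y2:slope2", preds)) / (2 * h)
    expect_equal(unname(jb$J[, k]), unname(fd), tolerance = 1e-4)
  }
})

test_that("zero sampling covariance gives zero delta SEs and degenerate simulation intervals", {
  G <- toy_G()
  pairs <- parallelgrowth:::vech_pairs(rownames(G))
  Gam0 <- matrix(0, nrow(pairs), nrow(pairs), dimnames = list(pairs$name, pairs$name))
  expect_equal(
    unname(ranef_se_delta(G, Gam0, "y2:slope2", c("y1:slope1", "y1:intercept"))),
    c(0, 0)
  )
  sim <- ranef_se_simulate(G, Gam0, "y2:slope2", "y1:slope1", q = 2000, seed = 1)
  expect_equal(sim$estimate_sim, sim$estimate, tolerance = 1e-12)
  expect_equal(sim$conf.low, sim$conf.high, tolerance = 1e-12)
  expect_equal(sim$n_skipped, 0L)
})

test_that("the simulation method is deterministic under a fixed seed and requires one", {
  fit <- toy_fit_cache()
  a <- ranef_se_simulate(fit$G, fit$gamma, "y2:slope2", "y1:slope1", q = 2000, seed = 77)
  b <- ranef_se_simulate(fit$G, fit$gamma, "y2:slope2", "y1:slope1", q = 2000, seed = 77)
  expect_identical(a, b)
  expect_error(
    ranef_se_simulate(fit$G, fit$gamma, "y2:slope2", "y1:slope1", q = 2000),
    "seed"
  )
  expect_warning(
    ranef_se_simulate(fit$G, fit$gamma, "y2:slope2", "y1:slope1", q = 500, seed = 1),
    "1000"
  )
})

test_that("simulation SEs approach delta SEs as the sampling uncertainty shrinks", {
  # the delta method is a first-order expansion: at a fixed large Gamma the
  # simulated coefficient distribution keeps second-order spread the expansion
  # drops, so agreement is asymptotic in Gamma -> 0
  fit <- toy_fit_cache()
  preds <- c("y1:slope1", "y1:intercept")
  rel_gap <- function(scale) {
    se_d <- ranef_se_delta(fit$G, fit$gamma * scale, "y2:slope2", preds)
    sim <- ranef_se_simulate(
      fit$G, fit$gamma * scale, "y2:slope2", preds, q = 1e5, seed = 3
    )
    max(abs(sim$std.error - se_d) / se_d)
  }
  gap_full <- rel_gap(1)
  gap_small <- rel_gap(1 / 100)
  expect_lt(gap_small, 0.02)
  expect_lt(gap_small, gap_full)
  # p = 1 with small Gamma: percentile interval matches the symmetric delta
  # interval to first order
  se1 <- ranef_se_delta(fit$G, fit$gamma / 100, "y2:slope2", "y1:slope1")
  sim1 <- ranef_se_simulate(
    fit$G, fit$gamma / 100, "y2:slope2", "y1:slope1", q = 1e5, seed = 4
  )
  beta1 <- ranef_coefficients(fit$G, "y2:slope2", "y1:slope1")
  expect_equal(sim1$conf.low, unname(beta1 - 1.96 * se1), tolerance = 0.02)
  expect_equal(sim1$conf.high, unname(beta1 + 1.96 * se1), tolerance = 0.02)
})

test_that("model-estimated G, not the covariance of shrunken predictions, carries the signal", {
  sim <- simulate_growth(toy_gspec(n = 150, seed = 61))
  fit <- fit_mlm(sim$data, mlm_spec(toy_specs()))
  blups <- ranef_blup(fit)
  emp <- diag(stats::cov(as.matrix(blups[-1])))
  model <- diag(fit$G)
  # shrinkage: every empirical BLUP variance understates the model variance
  expect_true(all(emp <= model + 1e-8))
  expect_gt(mean(1 - emp / model), 0.05)
})

test_that("true random effects validate the adjusted coefficients at large n", {
  gs <- toy_gspec(n = 1500, seed = 71)
  sim <- simulate_growth(gs)
  fit <- fit_mlm(sim$data, mlm_spec(toy_specs()))
  preds <- c("y1:slope1", "y1:intercept")
  beta_hat <- ranef_coefficients(fit$G, "y2:slope2", preds)
  u <- as.matrix(sim$random_effects[-1])
  ols <- lm.fit(cbind(1, u[, preds]), u[, "y2:slope2"])$coefficients[-1]
  se <- ranef_se_delta(fit$G, fit$gamma, "y2:slope2", preds)
  expect_lt(max(abs(beta_hat - ols) / se), 3)
})

test_that("reporting scale factors only rescale the output", {
  fit <- toy_fit_cache()
  plain <- ranef_regression(fit, "y2:slope2", "y1:slope1", methods = "delta")
  scaled <- ranef_regression(
    fit, "y2:slope2", "y1:slope1", methods = "delta",
    scale_factors = c("y1:slope1" = 10)
  )
  expect_equal(scaled$estimate, 10 * plain$estimate)
  expect_equal(scaled$std.error, 10 * plain$std.error)
  expect_equal(scaled$conf.low, 10 * plain$conf.low)
})

test_that("correlation reconstruction handles clean and degenerate variances", {
  G <- toy_G()
  C <- ranef_correlations(G)
  expect_equal(diag(C), rep(1, 6), ignore_attr = TRUE)
  expect_equal(C["y1:slope1", "y1:intercept"], 0.30 / sqrt(4 * 0.2), tolerance = 1e-12)
  expect_equal(ranef_correlations(diag(c(2, 3))), diag(2), ignore_attr = TRUE)
  Gz <- G; Gz[2, 2] <- 0
  expect_warning(Cz <- ranef_correlations(Gz), "undefined")
  expect_true(is.na(Cz[1, 2]))
})
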