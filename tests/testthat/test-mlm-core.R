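test_that("log-likelihood of a single standard-normal observation is -log(2*pi)/2", {
  spec <- mlm_spec(toy_specs()["y1"])
  data <- tibble::tibble(id = 1, time = 3, response = "y1", value = 2.5)
  G <- matrix(0, 3, 3, dimnames = rep(list(ranef_index(toy_specs()["y1"])$term), 2))
  ll <- mlm_loglik(data, spec,
    fixef = c("y1:intercept" = 2.5, "y1:slope1" = 0, "y1:slope2" = 0),
    G = G, R = 1
  )
  expect_equal(ll, -0.5 * log(2 * pi), tolerance = 1e-12)
})

test_that("log-likelihood matches the brute-force stacked-normal oracle", {
  withr::with_seed(314, {
    for (rep in 1:25) {
      inst <- random_tiny_instance(bivariate = rep %% 2 == 0)
      ours <- mlm_loglik(inst$data, mlm_spec(inst$specs), inst$fixef, inst$G, inst$R)
      oracle <- oracle_loglik(inst$data, inst$specs, inst$fixef, inst$G, inst$R)
      expect_equal(ours, oracle, tolerance = 1e-10)
    }
  })
})

test_that("log-likelihood is additive over independent individuals", {
  withr::with_seed(7, inst <- random_tiny_instance())
  spec <- mlm_spec(inst$specs)
  ll1 <- mlm_loglik(inst$data, spec, inst$fixef, inst$G, inst$R)
  doubled <- dplyr::bind_rows(
    inst$data, dplyr::mutate(inst$data, id = id + 100)
  )
  ll2 <- mlm_loglik(doubled, spec, inst$fixef, inst$G, inst$R)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-10)
})

test_that("non-positive-definite covariances yield -Inf, not an error", {
  withr::with_seed(7, inst <- random_tiny_instance())
  Gbad <- inst$G
  Gbad[1, 1] <- -5
  expect_identical(
    mlm_loglik(inst$data, mlm_spec(inst$specs), inst$fixef, Gbad, inst$R),
    -Inf
  )
})

test_that("univariate ML fit agrees with an independent mixed-model fitter", {
  skip_if_not_installed("lme4")
  lin <- spline_spec("y", 0, numeric(), 10)
  gs <- generator_spec(
    n_individuals = 120, specs = list(lin),
    fixed_effects = list(y = c(10, 0.8)),
    G_true = matrix(c(4, 0.5, 0.5, 0.25), 2, 2),
    R_true = 1, schedule = 0:10, seed = 42
  )
  sim <- simulate_growth(gs)
  fit <- fit_mlm(sim$data, mlm_spec(list(lin)))
  lf <- lme4::lmer(value ~ time + (time | id), data = sim$data, REML = FALSE)
  expect_equal(fit$deviance, deviance(lf), tolerance = 1e-6)
  expect_equal(
    unname(fit$fixef$estimate), unname(lme4::fixef(lf)),
    tolerance = 1e-4
  )
  vc <- lme4::VarCorr(lf)
  expect_equal(fit$G[1, 1], vc$id[1, 1], tolerance = 1e-3)
  expect_equal(fit$G[2, 2], vc$id[2, 2], tolerance = 1e-3)
  expect_equal(fit$G[1, 2], vc$id[1, 2], tolerance = 1e-3)
  expect_equal(fit$R[1, 1], attr(vc, "sc")^2, tolerance = 1e-3)
})

test_that("bivariate fit recovers generator truth at moderate sample size", {
  sim <- simulate_growth(toy_gspec(n = 400, seed = 9))
  fit <- fit_mlm(sim$data, mlm_spec(toy_specs()))
  expect_true(fit$convergence$converged)
  pr <- fit$pairs
  se <- sqrt(diag(fit$gamma))
  z <- (fit$G[cbind(pr$a, pr$b)] - toy_G()[cbind(pr$a, pr$b)]) / se
  expect_lt(max(abs(z)), 4)
  # fixed effects recovered
  fe_true <- c(10, 0.8, -0.3, 50, -0.5, 0.6)
  expect_lt(max(abs(fit$fixef$estimate - fe_true) / fit$fixef$std.error), 4)
  # occasion-level covariance recovered
  expect_equal(fit$R[1, 2], 0.3, tolerance = 0.15)
})

test_that("constrained entries are exact zeros and the deviance is monotone in constraints", {
  sim <- simulate_growth(toy_gspec(n = 80, seed = 13))
  spec <- mlm_spec(toy_specs())
  full <- fit_mlm(sim$data, spec)
  cs1 <- constrain_pairs(toy_specs(), "y1:slope1~y2:slope2")
  cs2 <- constrain_precedence(toy_specs(), "y1", "y2")
  f1 <- fit_mlm(sim$data, spec, constraints = cs1)
  f2 <- fit_mlm(sim$data, spec, constraints = cs2)
  expect_identical(f1$G["y1:slope1", "y2:slope2"], 0)
  expect_identical(unname(f1$gamma["y1:slope1||y2:slope2", ]), rep(0, nrow(f1$pairs)))
  expect_gte(f1$deviance, full$deviance - 1e-6)
  expect_gte(f2$deviance, f1$deviance - 1e-6)  # cs1 is a subset of cs2
  expect_true(all(cs1$term_a %in% cs2$term_a))
})

test_that("fitting constraints that are true under the generator costs little deviance", {
  G_ind <- toy_G()
  G_ind["y1:slope1", "y2:slope2"] <- 0
  G_ind["y2:slope2", "y1:slope1"] <- 0
  sim <- simulate_growth(toy_gspec(n = 150, seed = 17, G_true = G_ind))
  spec <- mlm_spec(toy_specs())
  full <- fit_mlm(sim$data, spec)
  restr <- fit_mlm(
    sim$data, spec,
    constraints = constrain_pairs(toy_specs(), "y1:slope1~y2:slope2")
  )
  out <- lrt(full, restr)
  expect_lt(out$statistic, qchisq(0.999, df = 1))
})

test_that("the fit is invariant to individual relabelling and row order", {
  sim <- simulate_growth(toy_gspec(n = 50, seed = 23))
  spec <- mlm_spec(toy_specs())
  f1 <- fit_mlm(sim$data, spec)
  perm <- withr::with_seed(1, sample(nrow(sim$data)))
  shuffled <- sim$data[perm, ]
  shuffled$id <- shuffled$id + 1000L
  f2 <- fit_mlm(shuffled, spec)
  expect_equal(f1$deviance, f2$deviance, tolerance = 1e-8)
  expect_equal(f1$G, f2$G, tolerance = 1e-6)
  expect_equal(f1$fixef$estimate, f2$fixef$estimate, tolerance = 1e-6)
})

test_that("likelihood-ratio tests enforce nesting and shared data", {
  sim1 <- simulate_growth(toy_gspec(n = 40, seed = 31))
  sim2 <- simulate_growth(toy_gspec(n = 40, seed = 32))
  spec <- mlm_spec(toy_specs())
  cs <- constrain_pairs(toy_specs(), "y1:slope1~y2:slope2")
  full1 <- fit_mlm(sim1$data, spec)
  restr1 <- fit_mlm(sim1$data, spec, constraints = cs)
  restr2 <- fit_mlm(sim2$data, spec, constraints = cs)
  expect_error(lrt(full1, restr2), "different data")
  expect_error(lrt(restr1, full1), "superset")
  expect_silent(lrt(full1, restr1))
})

test_that("deviance arithmetic handles edge cases", {
  out <- lrt_from_deviance(100, 100, 1)
  expect_equal(out$statistic, 0)
  expect_equal(out$p.value, 1)
  expect_warning(neg <- lrt_from_deviance(100, 99, 2), "non-convergence")
  expect_equal(neg$p.value, 1)
})

test_that("degenerate inputs are rejected with diagnostics", {
  spec <- mlm_spec(toy_specs())
  d <- tibble::tibble(id = 1, time = 3, response = "y1", value = 1)
  expect_error(fit_mlm(d, spec), "never observed")
  dup <- tibble::tibble(
    id = c(1, 1), time = c(3, 3), response = c("y1", "y1"), value = 1:2
  )
  expect_error(fit_mlm(dup, mlm_spec(toy_specs()["y1"])), "duplicate")
  early <- tibble::tibble(id = 1, time = -2, response = "y1", value = 1)
  expect_error(fit_mlm(early, mlm_spec(toy_specs()["y1"])), "baseline")
})

test_that("sparse designs trigger the identifiability warning but still fit", {
  gs <- toy_gspec(n = 120, seed = 41, schedule = list(
    times = 0:10, count_offset = 1, count_size = 3, count_prob = 0.5, enrich = 0
  ))
  sim <- simulate_growth(gs)
  keep <- dplyr::slice_head(
    dplyr::group_by(sim$data, id, response), n = 2
  )
  expect_warning(
    fit <- fit_mlm(dplyr::ungroup(keep), mlm_spec(toy_specs())),
    "fewer occasions"
  )
  expect_s3_class(fit, "mlm_fit")
})

test_that("tidiers expose fixed effects, variance parameters and fit summary", {
  fit <- toy_fit_cache()
  fx <- tidy(fit)
  expect_named(fx, c("term", "estimate", "std.error"))
  expect_equal(nrow(fx), 6L)
  vp <- tidy(fit, effects = "ran_pars")
  expect_equal(sum(vp$level == "individual"), 21L)  # 6*7/2 unique entries
  expect_equal(sum(vp$level == "occasion"), 3L)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_individuals, 120L)
  expect_equal(gl$deviance, -2 * fit$logLik)
})

test_that("staged fitting seeds the multivariate model from univariate fits", {
  sim <- simulate_growth(toy_gspec(n = 60, seed = 51))
  spec <- mlm_spec(toy_specs())
  f_direct <- fit_mlm(sim$data, spec)
  f_staged <- fit_mlm_staged(sim$data, spec)
  expect_equal(f_staged$deviance, f_direct$deviance, tolerance = 1e-5)
})
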