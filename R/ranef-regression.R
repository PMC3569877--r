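#' Mutually adjusted regression coefficients among random effects
#'
#' Given the individual-level random-effect covariance matrix `G`, the
#' regression of one random effect (say, blood-pressure change in a period)
#' on `p` others (say, earlier weight gain, adjusting for baseline values)
#' solves the normal equations `Sigma beta = sigma0`, where `Sigma` is the
#' p x p covariance block of the predictors and `sigma0` the vector of
#' covariances between the outcome effect and each predictor. With a single
#' predictor this is `cov / var`. The model-estimated `G` must be used (not
#' the empirical covariance of predicted per-individual effects, which is
#' attenuated by shrinkage; see [ranef_blup()]).
#'
#' @param G M x M symmetric covariance matrix with row/column names matching
#'   random-effect terms (e.g. the `G` of an [fit_mlm()] fit).
#' @param outcome Term name of the outcome random effect.
#' @param predictors Character vector of predictor term names (distinct, not
#'   containing the outcome).
#' @return Named numeric vector `beta` of length p.
#' @examples
#' G <- pregnancy_example_G()
#' ranef_coefficients(G, "map:intercept", "weight:intercept")
#' # 25.574 / 119.611 = 0.2138 mmHg per kg
#' @export
ranef_coefficients <- function(G, outcome, predictors) {
  q <- check_query(G, outcome, predictors)
  beta <- solve_sigma(q$Sigma, q$sigma0, predictors)
  setNames(drop(beta), predictors)
}

check_query <- function(G, outcome, predictors) {
  stopifnot(is.matrix(G), nrow(G) == ncol(G))
  terms <- rownames(G)
  if (is.null(terms)) abort("`G` must have row/column names (random-effect terms).")
  if (length(outcome) != 1L || !outcome %in% terms) {
    abort(sprintf("unknown outcome term '%s'.", paste(outcome, collapse = ",")))
  }
  if (!length(predictors) || anyDuplicated(predictors)) {
    abort("`predictors` must be a non-empty set of distinct terms.")
  }
  if (outcome %in% predictors) abort("the outcome may not be one of the predictors.")
  if (length(miss <- setdiff(predictors, terms))) {
    abort(paste0("unknown predictor term(s): ", paste(miss, collapse = ", ")))
  }
  list(
    Sigma = G[predictors, predictors, drop = FALSE],
    sigma0 = G[predictors, outcome],
    s00 = G[outcome, outcome]
  )
}

solve_sigma <- function(Sigma, sigma0, predictors) {
  rc <- rcond(Sigma)
  if (!is.finite(rc) || rc < 1e-12) {
    abort(sprintf(
      "predictor covariance block is numerically singular (rcond = %.2e); predictors {%s} are collinear.",
      rc, paste(predictors, collapse = ", ")
    ))
  }
  solve(Sigma, sigma0)
}

#' Moment-based standard errors (Method 1)
#'
#' Treats the entries of `G` as sample moments of `n` observed random-effect
#' vectors and applies textbook multiple-regression formulae: with residual
#' variance `s2 = s00 - sigma0' Sigma^{-1} sigma0` and `d` the diagonal of
#' `Sigma^{-1}`, `SE_j = sqrt(s2 * d_j / (n - p - 1))`. Fed the empirical
#' moments of an actual sample, these reproduce `lm()`'s standard errors
#' exactly. Because the random effects are never observed -- only their
#' covariance is estimated -- these intervals ignore the estimation
#' uncertainty in `G` and are anti-conservative; Methods 2 and 3 account
#' for it.
#'
#' @inheritParams ranef_coefficients
#' @param n Number of individuals behind the estimate of `G`; must exceed
#'   `p + 1`.
#' @return Named numeric vector of standard errors.
#' @export
ranef_se_moment <- function(G, outcome, predictors, n) {
  q <- check_query(G, outcome, predictors)
  p <- length(predictors)
  stopifnot(n > p + 1)
  Sinv <- solve(q$Sigma)
  s2 <- q$s00 - drop(crossprod(q$sigma0, Sinv %*% q$sigma0))
  if (s2 < 0) {
    abort(sprintf(
      "negative residual variance (%.3g): `G` is not positive semi-definite on the queried block.", s2
    ))
  }
  setNames(sqrt(s2 * diag(Sinv) / (n - p - 1)), predictors)
}

# gradient of beta with respect to the unique entries of G used by the query:
# d beta = Sigma^{-1} (d sigma0 - d Sigma beta). Returns the p x n_theta
# Jacobian and the canonical entry names "a||b".
beta_jacobian <- function(G, outcome, predictors) {
  q <- check_query(G, outcome, predictors)
  p <- length(predictors)
  beta <- solve_sigma(q$Sigma, q$sigma0, predictors)
  Sinv <- solve(q$Sigma)
  ent <- query_entries(rownames(G), outcome, predictors)
  J <- matrix(0, p, nrow(ent), dimnames = list(predictors, ent$name))
  for (k in seq_len(nrow(ent))) {
    dsigma0 <- numeric(p)
    dSigma <- matrix(0, p, p)
    if (ent$part[k] == "sigma0") {
      dsigma0[ent$i[k]] <- 1
    } else {
      dSigma[ent$i[k], ent$j[k]] <- 1
      dSigma[ent$j[k], ent$i[k]] <- 1
    }
    J[, k] <- drop(Sinv %*% (dsigma0 - dSigma %*% beta))
  }
  list(J = J, entries = ent, beta = setNames(drop(beta), predictors))
}

# unique G entries a regression query depends on, with canonical pair names
# matching the Gamma dimnames of an mlm_fit ("term_a||term_b" in ranef order)
query_entries <- function(terms, outcome, predictors, include_outcome_var = FALSE) {
  p <- length(predictors)
  ent <- tibble::tibble(
    part = character(), i = integer(), j = integer(),
    term_i = character(), term_j = character()
  )
  ent <- dplyr::bind_rows(ent, tibble::tibble(
    part = "sigma0", i = seq_len(p), j = rep(NA_integer_, p),
    term_i = outcome, term_j = predictors
  ))
  for (i in seq_len(p)) {
    for (j in i:p) {
      ent <- dplyr::bind_rows(ent, tibble::tibble(
        part = "Sigma", i = i, j = j,
        term_i = predictors[i], term_j = predictors[j]
      ))
    }
  }
  if (include_outcome_var) {
    ent <- dplyr::bind_rows(ent, tibble::tibble(
      part = "s00", i = NA_integer_, j = NA_integer_,
      term_i = outcome, term_j = outcome
    ))
  }
  ia <- match(ent$term_i, terms)
  ib <- match(ent$term_j, terms)
  ent$name <- ifelse(
    ia <= ib,
    paste(ent$term_i, ent$term_j, sep = "||"),
    paste(ent$term_j, ent$term_i, sep = "||")
  )
  ent
}

subset_gamma <- function(Gamma, names) {
  if (is.null(rownames(Gamma))) {
    abort("`Gamma` must carry pair names 'term_a||term_b' on rows/columns.")
  }
  if (length(miss <- setdiff(names, rownames(Gamma)))) {
    abort(paste0(
      "`Gamma` does not cover the entries: ", paste(miss, collapse = ", ")
    ))
  }
  Gamma[names, names, drop = FALSE]
}

ensure_psd <- function(Gamma, label = "Gamma") {
  ev <- eigen(Gamma, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1)) {
    warn(sprintf(
      "%s is not positive semi-definite (min eigenvalue %.3g); projecting to the nearest PSD matrix.",
      label, min(ev$values)
    ))
    vals <- pmax(ev$values, 0)
    Gamma <- ev$vectors %*% (vals * t(ev$vectors))
  }
  Gamma
}

#' Delta-method standard errors (Method 2)
#'
#' Propagates the sampling covariance `Gamma` of the estimated unique
#' entries of `G` through the coefficient map by a first-order expansion:
#' `SE_j = sqrt(g_j' Gamma g_j)` with `g_j` the analytic gradient of
#' `beta_j` with respect to the stacked entries, computed from
#' `d beta = Sigma^{-1}(d sigma0 - d Sigma beta)`.
#'
#' @inheritParams ranef_coefficients
#' @param Gamma Sampling covariance of the unique entries of `G`, with
#'   dimnames `"term_a||term_b"` (as in the `gamma` element of an
#'   [fit_mlm()] fit). A non-PSD `Gamma` is projected to the nearest PSD
#'   matrix with a warning.
#' @return Named numeric vector of standard errors.
#' @export
ranef_se_delta <- function(G, Gamma, outcome, predictors) {
  jb <- beta_jacobian(G, outcome, predictors)
  Gsub <- ensure_psd(subset_gamma(Gamma, jb$entries$name))
  V <- jb$J %*% Gsub %*% t(jb$J)
  setNames(sqrt(pmax(diag(V), 0)), predictors)
}

#' Simulation-based estimates and percentile intervals (Method 3)
#'
#' Draws `q` realisations of the unique `G` entries the query depends on
#' (including the outcome variance) from a multivariate normal with mean at
#' the estimates and covariance `Gamma`, re-solves the normal equations for
#' each realisation, and summarises the draws by their mean and 2.5th/97.5th
#' percentiles (or another percentile pair). Draws whose predictor block is
#' singular or whose implied (outcome + predictors) covariance is not
#' positive-definite are skipped and counted; more than 50% skipped draws is
#' an error, as the normal approximation for the (co)variance estimates has
#' broken down (it is a large-sample device).
#'
#' @inheritParams ranef_se_delta
#' @param q Number of realisations (default 10000; below 1000 a warning).
#' @param seed Integer seed, required for reproducibility.
#' @param probs Lower/upper percentile pair (default 95% interval).
#' @return A tibble with one row per predictor: `term`, `estimate` (plug-in
#'   beta), `estimate_sim` (mean over draws), `conf.low`, `conf.high`,
#'   `std.error` (SD over draws), `n_draws`, `n_skipped`.
#' @export
ranef_se_simulate <- function(G, Gamma, outcome, predictors, q = 10000L,
                              seed, probs = c(0.025, 0.975)) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is required: Method 3 is a simulation and must be reproducible.")
  }
  stopifnot(length(probs) == 2L, probs[1] < probs[2])
  q <- as.integer(q)
  if (q < 1000L) warn("fewer than 1000 realisations; percentile intervals will be noisy.")
  qy <- check_query(G, outcome, predictors)
  p <- length(predictors)
  beta_hat <- ranef_coefficients(G, outcome, predictors)
  ent <- query_entries(rownames(G), outcome, predictors, include_outcome_var = TRUE)
  mu <- vapply(seq_len(nrow(ent)), function(k) {
    G[ent$term_i[k], ent$term_j[k]]
  }, numeric(1))
  Gsub <- ensure_psd(subset_gamma(Gamma, ent$name))
  draws <- withr::with_seed(seed, MASS::mvrnorm(q, mu = mu, Sigma = Gsub))
  if (q == 1L) draws <- matrix(draws, 1L)

  is_s0 <- ent$part == "sigma0"
  is_Si <- ent$part == "Sigma"
  s00_col <- which(ent$part == "s00")
  Si_i <- ent$i[is_Si]; Si_j <- ent$j[is_Si]
  betas <- matrix(NA_real_, q, p)
  skipped <- 0L
  Sig_h <- matrix(0, p, p)
  full_h <- matrix(0, p + 1L, p + 1L)
  for (h in seq_len(q)) {
    v <- draws[h, ]
    Sig_h[cbind(Si_i, Si_j)] <- v[is_Si]
    Sig_h[cbind(Si_j, Si_i)] <- v[is_Si]
    s0_h <- v[is_s0]
    full_h[seq_len(p), seq_len(p)] <- Sig_h
    full_h[p + 1L, seq_len(p)] <- s0_h
    full_h[seq_len(p), p + 1L] <- s0_h
    full_h[p + 1L, p + 1L] <- v[s00_col]
    ok <- !inherits(tryCatch(chol(full_h), error = identity), "error")
    if (!ok) {
      skipped <- skipped + 1L
      next
    }
    betas[h, ] <- solve(Sig_h, s0_h)
  }
  if (skipped > q / 2) {
    abort(sprintf(
      "%d of %d simulated covariance matrices were not positive-definite; `Gamma` is too large relative to `G` for the normal approximation (large samples only).",
      skipped, q
    ))
  }
  kept <- betas[stats::complete.cases(betas), , drop = FALSE]
  tibble::tibble(
    term = predictors,
    estimate = unname(beta_hat),
    estimate_sim = colMeans(kept),
    std.error = apply(kept, 2L, stats::sd),
    conf.low = apply(kept, 2L, quantile, probs = probs[1]),
    conf.high = apply(kept, 2L, quantile, probs = probs[2]),
    n_draws = nrow(kept),
    n_skipped = skipped
  )
}

#' Adjusted random-effect regression with all standard-error methods
#'
#' Convenience wrapper running [ranef_coefficients()] on a fitted model's
#' `G` together with any of the three standard-error methods, returning one
#' tidy row per predictor and method. Scale factors (e.g. per 10 kg of
#' baseline weight, per 0.4 kg/week of weight gain) multiply the reported
#' coefficient and interval of the corresponding predictor at presentation;
#' coefficients are estimated in natural units.
#'
#' @param fit An [fit_mlm()] object (or a list with elements `G`, `gamma`,
#'   `n_individuals`).
#' @param outcome,predictors Random-effect term names.
#' @param methods Subset of `c("moment", "delta", "simulate")`.
#' @param q,seed,probs Passed to [ranef_se_simulate()].
#' @param scale_factors Optional named vector of per-predictor reporting
#'   multipliers.
#' @param conf_level Confidence level for the symmetric (moment/delta)
#'   intervals; the simulation interval uses `probs`.
#' @return A `ranef_reg` tibble: `outcome`, `term`, `method`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`, `scale`.
#' @export
ranef_regression <- function(fit, outcome, predictors,
                             methods = c("moment", "delta", "simulate"),
                             q = 10000L, seed = NULL, probs = c(0.025, 0.975),
                             scale_factors = NULL, conf_level = 0.95) {
  methods <- match.arg(methods, several.ok = TRUE)
  G <- fit$G
  Gamma <- fit$gamma
  n <- fit$n_individuals
  beta <- ranef_coefficients(G, outcome, predictors)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  rows <- list()
  if ("moment" %in% methods) {
    se <- ranef_se_moment(G, outcome, predictors, n = n)
    rows$moment <- tibble::tibble(
      term = predictors, method = "moment", estimate = unname(beta),
      std.error = unname(se),
      conf.low = unname(beta - zq * se), conf.high = unname(beta + zq * se)
    )
  }
  if ("delta" %in% methods) {
    se <- ranef_se_delta(G, Gamma, outcome, predictors)
    rows$delta <- tibble::tibble(
      term = predictors, method = "delta", estimate = unname(beta),
      std.error = unname(se),
      conf.low = unname(beta - zq * se), conf.high = unname(beta + zq * se)
    )
  }
  if ("simulate" %in% methods) {
    sim <- ranef_se_simulate(G, Gamma, outcome, predictors,
      q = q, seed = seed, probs = probs
    )
    rows$simulate <- tibble::tibble(
      term = sim$term, method = "simulate", estimate = sim$estimate,
      estimate_sim = sim$estimate_sim, std.error = sim$std.error,
      conf.low = sim$conf.low, conf.high = sim$conf.high,
      n_skipped = sim$n_skipped
    )
  }
  out <- dplyr::bind_rows(rows)
  out$outcome <- outcome
  sc <- rep(1, nrow(out))
  if (!is.null(scale_factors)) {
    hit <- out$term %in% names(scale_factors)
    sc[hit] <- scale_factors[out$term[hit]]
  }
  out$scale <- sc
  for (col in intersect(c("estimate", "estimate_sim", "std.error", "conf.low", "conf.high"), names(out))) {
    out[[col]] <- out[[col]] * sc
  }
  out <- dplyr::relocate(out, "outcome")
  class(out) <- c("ranef_reg", class(out))
  out
}

#' Correlation matrix of random effects
#'
#' `corr_ab = G_ab / sqrt(G_aa G_bb)`, with unit diagonal. Entries involving
#' a zero variance are undefined and returned as `NA` with a warning.
#'
#' @param G Symmetric covariance matrix with positive diagonal.
#' @return Correlation matrix of the same dimension.
#' @examples
#' round(ranef_correlations(pregnancy_example_G())["map:intercept", "weight:intercept"], 2)
#' @export
ranef_correlations <- function(G) {
  stopifnot(is.matrix(G), nrow(G) == ncol(G))
  d <- diag(G)
  if (any(d <= 0)) {
    warn("zero or negative variance(s): the corresponding correlations are undefined (NA).")
  }
  s <- sqrt(ifelse(d > 0, d, NA_real_))
  C <- G / (s %o% s)
  diag(C) <- ifelse(d > 0, 1, NA_real_)
  C
}
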