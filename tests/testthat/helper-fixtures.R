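# Shared fixtures and independent oracles for the test suite.

example_specs <- function() pregnancy_example_specs()

# two-response toy design with one knot each; small enough for fast fits
toy_specs <- function() {
  list(
    y1 = spline_spec("y1", baseline = 0, knots = 5, horizon = 10),
    y2 = spline_spec("y2", baseline = 0, knots = 5, horizon = 10)
  )
}

toy_gspec <- function(n = 80, seed = 1, G_true = toy_G(),
                      R_true = matrix(c(1, 0.3, 0.3, 2), 2, 2),
                      schedule = 0:10, drop_prob = NULL) {
  generator_spec(
    n_individuals = n, specs = toy_specs(),
    fixed_effects = list(y1 = c(10, 0.8, -0.3), y2 = c(50, -0.5, 0.6)),
    G_true = G_true, R_true = R_true,
    schedule = schedule, seed = seed, drop_prob = drop_prob
  )
}

toy_G <- function() {
  G <- matrix(
    c(
      4.0,  0.30, 0.10, 1.00, 0.05, 0.02,
      0.30, 0.20, 0.04, 0.10, 0.06, 0.01,
      0.10, 0.04, 0.15, 0.05, 0.02, 0.05,
      1.00, 0.10, 0.05, 6.00, 0.20, 0.10,
      0.05, 0.06, 0.02, 0.20, 0.25, 0.06,
      0.02, 0.01, 0.05, 0.10, 0.06, 0.30
    ),
    6, 6
  )
  idx <- ranef_index(toy_specs())
  dimnames(G) <- list(idx$term, idx$term)
  G
}

# interval-overlap oracle for a single spline component: the value of spline
# l at time t is the length of the intersection of period l with [baseline, t]
# (the last period is open-ended).
oracle_basis <- function(spec, t, l) {
  b <- c(spec$baseline, spec$knots, spec$horizon)
  lo <- b[l]
  hi <- if (l == length(b) - 1L) Inf else b[l + 1L]
  max(0, min(hi, t) - max(lo, spec$baseline))
}

# Brute-force stacked-normal log-likelihood: builds each individual's mean
# vector and covariance matrix entry by entry from the model's covariance
# rules, then evaluates a generic multivariate-normal log-density.
oracle_loglik <- function(data, specs, fixef, G, R) {
  specs <- if (inherits(specs, "spline_spec")) list(specs) else specs
  names(specs) <- vapply(specs, function(s) s$response, character(1))
  responses <- names(specs)
  if (is.null(dim(R))) R <- matrix(R, 1, 1)
  idx <- ranef_index(specs)
  ll <- 0
  for (k in unique(data$id)) {
    d <- data[data$id == k, ]
    n <- nrow(d)
    mu <- numeric(n)
    V <- matrix(0, n, n)
    zrow <- function(i) {
      s <- specs[[d$response[i]]]
      z <- numeric(nrow(idx))
      cols <- which(idx$response == d$response[i])
      z[cols[1]] <- 1
      for (l in seq_len(n_splines(s))) {
        z[cols[1 + l]] <- oracle_basis(s, d$time[i], l)
      }
      z
    }
    for (i in seq_len(n)) {
      s <- specs[[d$response[i]]]
      zi <- zrow(i)
      fe <- fixef[paste0(d$response[i], ":", c("intercept", paste0("slope", seq_len(n_splines(s)))))]
      mu[i] <- fe[1] + sum(fe[-1] * zi[idx$response == d$response[i]][-1])
      for (j in seq_len(n)) {
        zj <- zrow(j)
        V[i, j] <- drop(t(zi) %*% G %*% zj)
        ri <- match(d$response[i], responses)
        rj <- match(d$response[j], responses)
        if (d$time[i] == d$time[j]) {
          if (i == j) {
            V[i, j] <- V[i, j] + R[ri, ri]
          } else if (ri != rj) {
            V[i, j] <- V[i, j] + R[ri, rj]
          }
        }
      }
    }
    ll <- ll - 0.5 * (n * log(2 * pi) + determinant(V)$modulus +
      drop(t(d$value - mu) %*% solve(V) %*% (d$value - mu)))
  }
  as.numeric(ll)
}

# random tiny dataset + parameters for likelihood property tests
random_tiny_instance <- function(bivariate = TRUE) {
  specs <- if (bivariate) toy_specs() else toy_specs()["y1"]
  idx <- ranef_index(specs)
  M <- nrow(idx)
  A <- matrix(rnorm(M * M, sd = 0.5), M)
  G <- crossprod(A) + diag(0.2, M)
  dimnames(G) <- list(idx$term, idx$term)
  nresp <- length(specs)
  B <- matrix(rnorm(nresp * nresp, sd = 0.5), nresp)
  R <- crossprod(B) + diag(0.3, nresp)
  dimnames(R) <- list(names(specs), names(specs))
  fixef <- setNames(
    rnorm(M, sd = 2),
    unlist(lapply(specs, function(s) {
      paste0(s$response, ":", c("intercept", paste0("slope", seq_len(n_splines(s)))))
    }))
  )
  rows <- list()
  for (k in 1:3) {
    for (r in names(specs)) {
      times <- sort(sample(0:10, sample(1:4, 1)))
      if (r == "y2" && runif(1) < 0.5 && length(rows)) {
        # sometimes share occasions with y1 to exercise the matched-pair path
        prev <- rows[[length(rows)]]
        if (all(prev$id == k)) times <- prev$time[seq_len(min(length(prev$time), length(times)))]
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = k, time = as.numeric(times), response = r,
        value = rnorm(length(times), sd = 3)
      )
    }
  }
  list(
    data = dplyr::bind_rows(rows), specs = specs,
    fixef = fixef, G = G, R = R
  )
}

# small fitted bivariate model cached across tests within a run
toy_fit_cache <- local({
  fit <- NULL
  function(n = 120, seed = 5) {
    if (is.null(fit)) {
      sim <- simulate_growth(toy_gspec(n = n, seed = seed))
      fit <<- fit_mlm(sim$data, mlm_spec(toy_specs()))
    }
    fit
  }
})
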