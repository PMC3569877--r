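#' Reference covariance matrix for the pregnancy example
#'
#' The 9 x 9 individual-level covariance matrix among the random effects of
#' the bivariate weight/mean-arterial-pressure spline model (weight: baseline
#' 8 weeks, knots 18 and 29; MAP: baseline 8, knots 18, 29 and 36), as
#' published for a large pregnancy cohort. Units: kg and mmHg, slopes per
#' week. It is the default truth of the synthetic-data generator and the
#' worked-example input for the random-effect regressions; as printed (3
#' decimal places) it is already positive-definite.
#'
#' @return A named symmetric 9 x 9 matrix; rows/columns follow
#'   [ranef_index()] order for `pregnancy_example_specs()`.
#' @export
pregnancy_example_G <- function() {
  upper <- list(
    c(119.611, -0.585, -0.317, 0.044, 25.574, 0.387, -0.530, 0.196, -0.435),
    c(0.050, 0.011, 0.005, -0.113, 0.001, 0.012, -0.012, 0.003),
    c(0.033, 0.018, -0.124, 0.006, 0.011, 0.000, 0.006),
    c(0.044, -0.018, 0.006, 0.006, 0.021, 0.027),
    c(36.579, -1.071, -0.278, 0.127, -0.176),
    c(0.180, -0.035, -0.029, 0.015),
    c(0.113, -0.042, -0.012),
    c(0.352, -0.108),
    1.314
  )
  terms <- ranef_index(pregnancy_example_specs())$term
  G <- matrix(0, 9L, 9L, dimnames = list(terms, terms))
  for (i in 1:9) {
    G[i, i:9] <- upper[[i]]
    G[i:9, i] <- upper[[i]]
  }
  G
}

#' Spline specifications for the pregnancy example
#'
#' Weight with knots at 18 and 29 weeks and mean arterial pressure with
#' knots at 18, 29 and 36 weeks, both with baseline 8 weeks and horizon 44
#' weeks of gestation.
#'
#' @return A named list of two [spline_spec()]s (`weight`, `map`).
#' @export
pregnancy_example_specs <- function() {
  list(
    weight = spline_spec("weight", baseline = 8, knots = c(18, 29), horizon = 44),
    map = spline_spec("map", baseline = 8, knots = c(18, 29, 36), horizon = 44)
  )
}

#' Nearest positive-definite projection by eigenvalue clipping
#'
#' Symmetrises, clips eigenvalues at `eps`, and reconstructs. The maximum
#' absolute change is attached as attribute `"adjustment"` (0 when the input
#' was already positive-definite).
#'
#' @param M Square matrix.
#' @param eps Eigenvalue floor.
#' @return The projected matrix.
#' @export
nearest_pd <- function(M, eps = 1e-8) {
  S <- (M + t(M)) / 2
  ev <- eigen(S, symmetric = TRUE)
  out <- ev$vectors %*% (pmax(ev$values, eps) * t(ev$vectors))
  dimnames(out) <- dimnames(M)
  structure(out, adjustment = max(abs(out - S)))
}

#' Specify the synthetic-data generator
#'
#' Describes an unbalanced bivariate longitudinal design with the structure
#' the model assumes: per-individual random effects drawn from `G_true`,
#' piecewise-linear population trajectories, and bivariate occasion-level
#' noise with covariance `R_true` when both responses are measured at a
#' visit. Defaults emulate the pregnancy weight / mean-arterial-pressure
#' setting: 9429 individuals with a per-woman visit count of median 10 and
#' range 1 to 18 at irregular integer weeks 8-43 (mildly enriched in late
#' pregnancy), both responses measured at every visit, and `G_true` equal to
#' the published covariance matrix [pregnancy_example_G()].
#'
#' @param n_individuals Number of individuals.
#' @param specs List of [spline_spec()]s; default [pregnancy_example_specs()].
#' @param fixed_effects Named list (by response) of `c(intercept, slopes...)`.
#'   Defaults shaped like average pregnancy trajectories: weight about 62 kg
#'   at 8 weeks rising 0.3 / 0.5 / 0.4 kg per week across its periods; MAP
#'   about 84 mmHg dipping 0.25 mmHg per week to 18 weeks then rising 0.1 /
#'   0.6 / 0.9 mmHg per week.
#' @param G_true Individual-level covariance matrix (positive-definite after
#'   [nearest_pd()] projection, which is applied automatically).
#' @param R_true Occasion-level covariance across responses (matrix, or a
#'   scalar for one response). Default: weight residual variance 1.2 kg^2,
#'   MAP residual variance 33 mmHg^2, covariance 0.5.
#' @param schedule Either a numeric vector of fixed visit times used for
#'   every individual (a balanced design), or a list with elements `times`
#'   (candidate integer weeks, default `8:43`), `count_offset`, `count_size`,
#'   `count_prob` (visit count is `offset + Binomial(size, prob)`, default
#'   `1 + Binomial(17, 0.53)`: median 10, range 1-18), and `enrich` (linear
#'   tilt of the time-sampling weights towards late weeks, default 0.02).
#' @param drop_prob Named per-response probability that a scheduled visit
#'   omits that response (default 0: both responses at every visit).
#' @param covariate_model Optional list with `rng`, a `function(n)` returning
#'   a tibble of per-individual covariates, and `coefs`, a named list (by
#'   response) of named coefficient vectors shifting that response's
#'   intercept.
#' @param seed Integer seed (required at generation time).
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_individuals = 9429L,
                           specs = pregnancy_example_specs(),
                           fixed_effects = NULL,
                           G_true = pregnancy_example_G(),
                           R_true = NULL,
                           schedule = list(),
                           drop_prob = NULL,
                           covariate_model = NULL,
                           seed = NULL) {
  specs <- as_spec_list(specs)
  responses <- names(specs)
  if (is.null(fixed_effects)) {
    if (!identical(responses, c("weight", "map"))) {
      abort("`fixed_effects` must be supplied for non-default responses.")
    }
    fixed_effects <- list(
      weight = c(62, 0.3, 0.5, 0.4),
      map = c(84, -0.25, 0.1, 0.6, 0.9)
    )
  }
  for (r in responses) {
    if (length(fixed_effects[[r]]) != n_splines(specs[[r]]) + 1L) {
      abort(sprintf(
        "`fixed_effects$%s` must have length %d (intercept + slopes).",
        r, n_splines(specs[[r]]) + 1L
      ))
    }
  }
  idx <- ranef_index(specs)
  if (!identical(dim(G_true), c(nrow(idx), nrow(idx)))) {
    abort(sprintf("`G_true` must be %d x %d.", nrow(idx), nrow(idx)))
  }
  if (min(eigen((G_true + t(G_true)) / 2, symmetric = TRUE, only.values = TRUE)$values) < 0) {
    G_true <- nearest_pd(G_true)  # printed/rounded inputs can be marginally indefinite
    inform(sprintf(
      "`G_true` projected to the nearest positive-definite matrix (max change %.3g).",
      attr(G_true, "adjustment")
    ))
  }
  dimnames(G_true) <- list(idx$term, idx$term)
  if (is.null(R_true)) {
    if (!identical(responses, c("weight", "map"))) {
      abort("`R_true` must be supplied for non-default responses.")
    }
    R_true <- matrix(c(1.2, 0.5, 0.5, 33), 2L, 2L)
  }
  if (is.null(dim(R_true))) R_true <- matrix(R_true, 1L, 1L)
  dimnames(R_true) <- list(responses, responses)
  if (is.list(schedule)) {
    schedule <- utils::modifyList(
      list(
        times = 8:43, count_offset = 1L, count_size = 17L,
        count_prob = 0.53, enrich = 0.02
      ),
      schedule
    )
  }
  dp <- setNames(rep(0, length(responses)), responses)
  if (!is.null(drop_prob)) dp[names(drop_prob)] <- drop_prob
  structure(
    list(
      n_individuals = as.integer(n_individuals), specs = specs,
      fixed_effects = fixed_effects, G_true = G_true, R_true = R_true,
      schedule = schedule, drop_prob = dp,
      covariate_model = covariate_model, seed = seed
    ),
    class = "generator_spec"
  )
}

#' Simulate an unbalanced multivariate longitudinal dataset
#'
#' Per individual: a random-effect vector is drawn from
#' `MVN(0, G_true)`; visit times are drawn from the schedule model; at each
#' visit the occasion-level residual vector is drawn from `MVN(0, R_true)`
#' across responses, and each retained response value is
#' `intercept + basis(t) . slopes + covariate shift + u . (1, basis(t)) +
#' residual`. The true random effects are returned for oracle tests. The
#' generator is deterministic under `seed`.
#'
#' @param gspec A [generator_spec()] (its `seed` must be set, or supply
#'   `seed` here).
#' @param seed Optional override of `gspec$seed`.
#' @return A list of class `growth_sim`: `data` (long tibble: `id`, `time`,
#'   `response`, `value`, covariates), `random_effects` (tibble: `id` plus
#'   one column per random-effect term), and `gspec`.
#' @export
simulate_growth <- function(gspec, seed = NULL) {
  stopifnot(inherits(gspec, "generator_spec"))
  seed <- seed %||% gspec$seed
  if (is.null(seed)) abort("a `seed` is required for reproducible generation.")
  withr::with_seed(as.integer(seed), simulate_growth_impl(gspec))
}

simulate_growth_impl <- function(gspec) {
  n <- gspec$n_individuals
  specs <- gspec$specs
  responses <- names(specs)
  idx <- ranef_index(specs)
  M <- nrow(idx)

  u <- MASS::mvrnorm(n, mu = rep(0, M), Sigma = gspec$G_true)
  if (n == 1L) u <- matrix(u, 1L)
  colnames(u) <- idx$term

  covars <- NULL
  if (!is.null(gspec$covariate_model)) {
    covars <- tibble::as_tibble(gspec$covariate_model$rng(n))
  }

  sched <- gspec$schedule
  if (is.numeric(sched)) {
    times_list <- rep(list(sort(as.numeric(sched))), n)
  } else {
    counts <- sched$count_offset + rbinom(n, sched$count_size, sched$count_prob)
    wts <- 1 + sched$enrich * (sched$times - min(sched$times))
    times_list <- purrr::map(counts, function(ct) {
      ct <- min(ct, length(sched$times))
      sort(sample(sched$times, ct, prob = wts))
    })
  }
  occ <- tibble::tibble(
    id = rep(seq_len(n), lengths(times_list)),
    time = as.numeric(unlist(times_list))
  )
  n_occ <- nrow(occ)
  eps <- MASS::mvrnorm(n_occ, mu = rep(0, length(responses)), Sigma = gspec$R_true)
  if (n_occ == 1L) eps <- matrix(eps, 1L)

  out <- vector("list", length(responses))
  for (r in seq_along(responses)) {
    s <- specs[[responses[r]]]
    keep <- occ$time >= s$baseline &
      runif(n_occ) >= gspec$drop_prob[responses[r]]
    rows <- which(keep)
    B <- spline_basis(s, occ$time[rows])
    fe <- gspec$fixed_effects[[responses[r]]]
    value <- fe[1L] + drop(B %*% fe[-1L])
    cols <- which(idx$response == responses[r])
    value <- value + u[occ$id[rows], cols[1L]] +
      rowSums(B * u[occ$id[rows], cols[-1L], drop = FALSE])
    if (!is.null(covars)) {
      cf <- gspec$covariate_model$coefs[[responses[r]]]
      if (!is.null(cf)) {
        value <- value +
          drop(as.matrix(covars[occ$id[rows], names(cf), drop = FALSE]) %*% cf)
      }
    }
    value <- value + eps[rows, r]
    out[[r]] <- tibble::tibble(
      id = occ$id[rows], time = occ$time[rows],
      response = responses[r], value = value
    )
  }
  data <- dplyr::arrange(dplyr::bind_rows(out), .data$id, .data$time, .data$response)
  if (!is.null(covars)) {
    data <- dplyr::left_join(
      data, dplyr::mutate(covars, id = seq_len(n)), by = "id"
    )
  }
  structure(
    list(
      data = data,
      random_effects = dplyr::bind_cols(
        tibble::tibble(id = seq_len(n)), tibble::as_tibble(u)
      ),
      gspec = gspec
    ),
    class = "growth_sim"
  )
}

#' @export
print.growth_sim <- function(x, ...) {
  cat(sprintf(
    "<growth_sim> %d individuals, %d rows, responses: %s\n",
    x$gspec$n_individuals, nrow(x$data),
    paste(names(x$gspec$specs), collapse = ", ")
  ))
  invisible(x)
}

#' Mean arterial pressure from systolic and diastolic blood pressure
#'
#' `MAP = systolic / 3 + 2 * diastolic / 3`, the conventional weighting that
#' accounts for the longer diastolic phase of the cardiac cycle.
#'
#' @param systolic,diastolic Pressures in mmHg; warns when
#'   `systolic < diastolic` or `diastolic <= 0`.
#' @return Numeric vector of mean arterial pressures.
#' @examples
#' map_from_bp(120, 80)  # 93.33
#' @export
map_from_bp <- function(systolic, diastolic) {
  if (any(systolic < diastolic, na.rm = TRUE) || any(diastolic <= 0, na.rm = TRUE)) {
    warn("implausible blood pressures: expected systolic >= diastolic > 0.")
  }
  systolic / 3 + 2 * diastolic / 3
}

#' Thin repeated measurements to at most one per time window
#'
#' Within each individual x response x consecutive window of `window` time
#' units (anchored at `origin`), one row is retained, chosen uniformly at
#' random, preventing frequently measured individuals from dominating a fit.
#'
#' @param data Long-format tibble with `id`, `time`, `response` columns.
#' @param window Window width (default 2, e.g. a 2-week window).
#' @param origin Anchor of the first window; default the smallest time in
#'   the data.
#' @param seed Integer seed making the random selection reproducible.
#' @return The thinned tibble (row count at most the input's).
#' @export
thin_to_window <- function(data, window = 2, origin = NULL, seed = NULL) {
  stopifnot(window > 0)
  data <- tibble::as_tibble(data)
  origin <- origin %||% min(data$time)
  pick <- function() {
    data$..win <- floor((data$time - origin) / window)
    keep <- dplyr::slice_sample(
      dplyr::group_by(data, .data$id, .data$response, .data$..win),
      n = 1L
    )
    keep <- dplyr::ungroup(keep)
    keep$..win <- NULL
    dplyr::arrange(keep, .data$id, .data$time, .data$response)
  }
  if (!is.null(seed)) withr::with_seed(as.integer(seed), pick()) else pick()
}
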