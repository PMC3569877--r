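#' Define a linear-spline trajectory specification for one response
#'
#' A spline specification fixes, for one repeated-measures response, the
#' baseline time at which the intercept is defined, the interior knot points
#' at which the slope of the piecewise-linear trajectory may change, and the
#' horizon (end of the observation window). With `k` interior knots the
#' trajectory has `m = k + 1` linear pieces, and time is partitioned into `m`
#' closed periods sharing their boundary points:
#' `[baseline, knot1], [knot1, knot2], ..., [knot_k, horizon]`.
#'
#' The horizon only delimits the last period for adjacency reasoning in the
#' hypothesis generators (see [constrain_same_adjacent()]); the last spline
#' itself is open-ended and keeps accruing beyond the horizon.
#'
#' @param response Character label for the response (e.g. `"weight"`).
#' @param baseline Time at which all splines are zero (intercept time).
#' @param knots Strictly increasing numeric vector of interior knots, all
#'   strictly between `baseline` and `horizon`.
#' @param horizon End of the observation window, strictly after the last knot.
#' @param units Optional character label for the time axis (default "weeks").
#' @return An object of class `spline_spec`.
#' @examples
#' wt <- spline_spec("weight", baseline = 8, knots = c(18, 29), horizon = 44)
#' spline_basis(wt, c(8, 25, 44))
#' period_intervals(wt)
#' @export
spline_spec <- function(response, baseline, knots, horizon, units = "weeks") {
  stopifnot(is.character(response), length(response) == 1L, nzchar(response))
  baseline <- as.numeric(baseline)
  knots <- as.numeric(knots)
  horizon <- as.numeric(horizon)
  if (length(baseline) != 1L || !is.finite(baseline)) {
    abort("`baseline` must be a single finite time.")
  }
  if (length(horizon) != 1L || !is.finite(horizon)) {
    abort("`horizon` must be a single finite time.")
  }
  if (length(knots) > 0L) {
    if (any(!is.finite(knots))) abort("`knots` must be finite.")
    if (is.unsorted(knots, strictly = TRUE)) {
      abort("`knots` must be strictly increasing.")
    }
    if (knots[1L] <= baseline || knots[length(knots)] >= horizon) {
      abort(sprintf(
        "knots must lie strictly inside (baseline, horizon) = (%g, %g).",
        baseline, horizon
      ))
    }
  } else if (horizon <= baseline) {
    abort("`horizon` must exceed `baseline`.")
  }
  structure(
    list(
      response = response, baseline = baseline, knots = knots,
      horizon = horizon, units = units
    ),
    class = "spline_spec"
  )
}

#' @export
print.spline_spec <- function(x, ...) {
  cat(sprintf(
    "<spline_spec> %s: baseline %g, knots {%s}, horizon %g (%d periods, %s)\n",
    x$response, x$baseline, paste(x$knots, collapse = ", "),
    x$horizon, n_splines(x), x$units
  ))
  invisible(x)
}

#' Number of linear splines (periods) in a specification
#' @param spec A [spline_spec()].
#' @return Integer count of linear pieces, `length(knots) + 1`.
#' @export
n_splines <- function(spec) {
  stopifnot(inherits(spec, "spline_spec"))
  length(spec$knots) + 1L
}

period_boundaries <- function(spec) {
  c(spec$baseline, spec$knots, spec$horizon)
}

#' Evaluate the linear-spline basis at given times
#'
#' Component `l` of the basis is the time accrued within period `l` up to
#' time `t`: `max(0, min(t, b_l) - b_{l-1})` with `b_0 = baseline` and the
#' period boundaries `b_1 < ... < b_m`. All components are nonnegative and,
#' for `baseline <= t <= horizon`, they sum to `t - baseline`, so the fitted
#' mean trajectory `intercept + basis %*% slopes` is continuous and piecewise
#' linear with kinks exactly at the knots.
#'
#' Times beyond the horizon are allowed (the last spline keeps accruing) but
#' raise a warning; times before baseline are an error because the model is
#' undefined there.
#'
#' @param spec A [spline_spec()].
#' @param t Numeric vector of times.
#' @param label Optional label (e.g. individual/occasion) used in the error
#'   message when `t < baseline`.
#' @return A `length(t)` by `m` numeric matrix; columns named `slope1..m`.
#' @export
spline_basis <- function(spec, t, label = NULL) {
  stopifnot(inherits(spec, "spline_spec"))
  t <- as.numeric(t)
  if (any(bad <- t < spec$baseline)) {
    where <- if (!is.null(label)) paste0(" (", label, ")") else ""
    abort(sprintf(
      "time before baseline %g for response '%s'%s: %s",
      spec$baseline, spec$response, where,
      paste(utils::head(t[bad], 5L), collapse = ", ")
    ))
  }
  if (any(t > spec$horizon)) {
    warn(sprintf(
      "times beyond horizon %g for response '%s'; last spline keeps accruing.",
      spec$horizon, spec$response
    ))
  }
  b <- period_boundaries(spec)
  m <- length(b) - 1L
  out <- matrix(0, length(t), m, dimnames = list(NULL, paste0("slope", seq_len(m))))
  for (l in seq_len(m)) {
    hi <- if (l == m) t else pmin(t, b[l + 1L])  # last spline is open-ended
    out[, l] <- pmax(0, hi - b[l])
  }
  out
}

#' Period intervals of a spline specification
#'
#' Periods are CLOSED intervals sharing boundary points; two periods are
#' adjacent when their closed intervals intersect (overlap or touch). This
#' convention drives the hypothesis generators.
#'
#' @param spec A [spline_spec()].
#' @return A tibble with columns `response`, `period`, `start`, `end`.
#' @export
period_intervals <- function(spec) {
  stopifnot(inherits(spec, "spline_spec"))
  b <- period_boundaries(spec)
  m <- length(b) - 1L
  tibble::tibble(
    response = spec$response,
    period = seq_len(m),
    start = b[seq_len(m)],
    end = b[seq_len(m) + 1L]
  )
}

#' Round observation times to whole weeks
#'
#' Rounding the time axis to integer resolution reduces between-individual
#' variability in measurement timing (and makes occasions of different
#' responses match), which eases estimation; antenatal gestational ages are
#' conventionally recorded in completed weeks.
#'
#' @param t Numeric vector of times.
#' @return `round(t)` as a numeric vector.
#' @export
round_weeks <- function(t) round(as.numeric(t))

#' Build spline specifications from a configuration list or YAML file
#'
#' The configuration holds one block per response with fields `baseline`,
#' `knots` and `horizon` (and optionally `units`), e.g.
#' ```yaml
#' responses:
#'   weight: {baseline: 8, knots: [18, 29], horizon: 44}
#'   map:    {baseline: 8, knots: [18, 29, 36], horizon: 44}
#' ```
#'
#' @param x A named list of per-response blocks, or a list with a `responses`
#'   element holding them.
#' @param path Path to a YAML file with the same structure (used when `x` is
#'   missing).
#' @return A named list of [spline_spec()] objects.
#' @export
spline_specs_from_config <- function(x, path = NULL) {
  if (missing(x) || is.null(x)) {
    stopifnot(!is.null(path))
    x <- yaml::read_yaml(path)
  }
  if (!is.null(x$responses)) x <- x$responses
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    abort("configuration blocks must be named by response.")
  }
  purrr::imap(x, function(block, nm) {
    spline_spec(
      response = nm,
      baseline = block$baseline,
      knots = unlist(block$knots) %||% numeric(),
      horizon = block$horizon,
      units = block$units %||% "weeks"
    )
  })
}

#' Serialise spline specifications to a configuration list
#'
#' @param specs A list of [spline_spec()] objects.
#' @return A list suitable for [yaml::write_yaml()] and round-trippable via
#'   [spline_specs_from_config()].
#' @export
spline_specs_to_config <- function(specs) {
  specs <- as_spec_list(specs)
  list(responses = purrr::map(
    setNames(specs, purrr::map_chr(specs, "response")),
    function(s) list(
      baseline = s$baseline, knots = as.numeric(s$knots),
      horizon = s$horizon, units = s$units
    )
  ))
}

as_spec_list <- function(specs) {
  if (inherits(specs, "spline_spec")) specs <- list(specs)
  stopifnot(all(purrr::map_lgl(specs, inherits, "spline_spec")))
  nm <- purrr::map_chr(specs, "response")
  if (anyDuplicated(nm)) abort("duplicate response labels in spline specs.")
  setNames(specs, nm)
}
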