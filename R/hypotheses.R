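#' Constraint sets: temporal hypotheses as zero covariances
#'
#' Hypotheses about the temporal ordering of two change processes are encoded
#' by fixing selected individual-level random-effect covariances to zero and
#' comparing the restricted fit to the full fit by likelihood ratio; the LRT
#' degrees of freedom equal the number of constrained covariances, i.e. the
#' number of rows of the constraint set.
#'
#' A `constraint_set` is a tibble with columns `term_a`, `term_b` naming an
#' unordered pair of random effects (see [ranef_index()]); variances are never
#' constrained, so `term_a != term_b` always.
#'
#' @name constraint_set
NULL

new_constraint_set <- function(pairs, idx, label = NULL, lag = NULL) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("term_a", "term_b") %in% names(pairs)))
  pairs <- validate_constraints(pairs, idx)
  attr(pairs, "label") <- label
  attr(pairs, "lag") <- lag
  class(pairs) <- c("constraint_set", class(pairs))
  pairs
}

validate_constraints <- function(pairs, idx) {
  pairs <- tibble::as_tibble(pairs)[c("term_a", "term_b")]
  terms <- idx$term
  unknown <- setdiff(c(pairs$term_a, pairs$term_b), terms)
  if (length(unknown)) {
    abort(paste0("unknown random-effect term(s): ", paste(unknown, collapse = ", ")))
  }
  if (any(pairs$term_a == pairs$term_b)) {
    abort("variances cannot be constrained: a pair may not repeat the same effect.")
  }
  ia <- match(pairs$term_a, terms)
  ib <- match(pairs$term_b, terms)
  swap <- ia > ib
  a <- ifelse(swap, pairs$term_b, pairs$term_a)
  b <- ifelse(swap, pairs$term_a, pairs$term_b)
  out <- tibble::tibble(term_a = a, term_b = b)
  out[!duplicated(out), ]
}

#' @export
print.constraint_set <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf(
    "<constraint_set>%s %d covariance(s) fixed to zero (LRT df = %d)\n",
    if (!is.null(lab)) paste0(" [", lab, "]") else "", nrow(x), nrow(x)
  ))
  if (nrow(x)) print(tibble::as_tibble(x), ...)
  invisible(x)
}

slope_rows <- function(idx) idx[idx$kind == "slope", ]

closed_disjoint <- function(s1, e1, s2, e2) e1 < s2 | e2 < s1

#' Same-or-adjacent-periods hypothesis
#'
#' Constrains the covariance between every pair of slope random effects whose
#' closed period intervals are disjoint (neither overlapping nor sharing an
#' endpoint), so that changes may only be correlated in the same or adjacent
#' time periods. Intercepts are never constrained: baseline levels may
#' correlate with change in any period.
#'
#' @param specs A list of [spline_spec()]s (adjacency needs the horizon, which
#'   every spec carries).
#' @param include_within If `TRUE` (default) within-response slope pairs are
#'   constrained as well as cross-response pairs; `FALSE` restricts the
#'   hypothesis to cross-response pairs only.
#' @return A [constraint_set].
#' @examples
#' wt <- spline_spec("weight", 8, c(18, 29), 44)
#' map <- spline_spec("map", 8, c(18, 29, 36), 44)
#' nrow(constrain_same_adjacent(list(wt, map)))          # 8
#' nrow(constrain_same_adjacent(list(wt, map), FALSE))   # 4
#' @export
constrain_same_adjacent <- function(specs, include_within = TRUE) {
  idx <- ranef_index(specs)
  sl <- slope_rows(idx)
  pr <- tidyr::expand_grid(i = seq_len(nrow(sl)), j = seq_len(nrow(sl)))
  pr <- pr[pr$i < pr$j, ]
  a <- sl[pr$i, ]
  b <- sl[pr$j, ]
  keep <- closed_disjoint(a$start, a$end, b$start, b$end)
  if (!include_within) keep <- keep & (a$response != b$response)
  new_constraint_set(
    tibble::tibble(term_a = a$term[keep], term_b = b$term[keep]),
    idx,
    label = if (include_within) "same-or-adjacent periods" else
      "same-or-adjacent periods (cross-response only)"
  )
}

#' Temporal-precedence hypothesis
#'
#' Constrains the covariance between every slope of `from` in period A and
#' every slope of `to` in a subsequent period B, where "subsequent" means
#' `start(B) >= end(A)` (the immediately following, boundary-sharing period
#' counts as subsequent). Under this restriction changes in `from` are not
#' associated with later changes in `to`; comparing to the full model tests
#' whether changes in `to` precede changes in `from`.
#'
#' @param specs A list of [spline_spec()]s.
#' @param from,to Response labels.
#' @return A [constraint_set].
#' @export
constrain_precedence <- function(specs, from, to) {
  idx <- ranef_index(specs)
  sl <- slope_rows(idx)
  A <- sl[sl$response == from, ]
  B <- sl[sl$response == to, ]
  if (!nrow(A) || from %in% idx$response == FALSE) abort(sprintf("unknown response '%s'", from))
  if (!to %in% idx$response) abort(sprintf("unknown response '%s'", to))
  pr <- tidyr::expand_grid(i = seq_len(nrow(A)), j = seq_len(nrow(B)))
  keep <- B$start[pr$j] >= A$end[pr$i]
  new_constraint_set(
    tibble::tibble(term_a = A$term[pr$i][keep], term_b = B$term[pr$j][keep]),
    idx,
    label = sprintf("no association of %s change with subsequent %s change", from, to)
  )
}

#' Block one random effect from an entire response
#'
#' Constrains the covariance of a single random effect with every random
#' effect of another response (optionally including that response's
#' intercept). For example: early blood-pressure change not allowed to
#' correlate with baseline weight or weight change in any period.
#'
#' @param specs A list of [spline_spec()]s.
#' @param effect Term name of the blocked effect (see [ranef_index()]),
#'   e.g. `"map:slope1"`.
#' @param other_response Response label whose effects are blocked from
#'   `effect`; must differ from `effect`'s response.
#' @param include_intercept Constrain the other response's intercept too
#'   (default `TRUE`).
#' @return A [constraint_set].
#' @export
constrain_block <- function(specs, effect, other_response, include_intercept = TRUE) {
  idx <- ranef_index(specs)
  row <- idx[idx$term == effect, ]
  if (!nrow(row)) abort(sprintf("unknown random-effect term '%s'", effect))
  if (!other_response %in% idx$response) {
    abort(sprintf("unknown response '%s'", other_response))
  }
  if (row$response == other_response) {
    abort("`other_response` must differ from the blocked effect's response.")
  }
  oth <- idx[idx$response == other_response, ]
  if (!include_intercept) oth <- oth[oth$kind == "slope", ]
  new_constraint_set(
    tibble::tibble(term_a = effect, term_b = oth$term),
    idx,
    label = sprintf("%s uncorrelated with %s effects", effect, other_response)
  )
}

#' Lagged-association hypothesis
#'
#' Constrains covariances between slopes of `from` in period A and slopes of
#' `to` in subsequent periods B (`start(B) >= end(A)`) whose period-index gap
#' `period(B) - period(A)` is at most `delta_s`; associations beyond the
#' hypothesised lag remain free. With `delta_s` large enough this reduces to
#' [constrain_precedence()]. The lag is counted in period indices (the rule is
#' stated for responses sharing one knot set; for unequal knot sets the
#' index-gap rule is retained).
#'
#' @param specs A list of [spline_spec()]s.
#' @param from,to Response labels.
#' @param delta_s Positive integer lag in periods.
#' @return A [constraint_set].
#' @export
constrain_lag <- function(specs, from, to, delta_s) {
  stopifnot(length(delta_s) == 1L, delta_s >= 1, delta_s == as.integer(delta_s))
  idx <- ranef_index(specs)
  sl <- slope_rows(idx)
  A <- sl[sl$response == from, ]
  B <- sl[sl$response == to, ]
  if (!to %in% idx$response) abort(sprintf("unknown response '%s'", to))
  pr <- tidyr::expand_grid(i = seq_len(nrow(A)), j = seq_len(nrow(B)))
  subsq <- B$start[pr$j] >= A$end[pr$i]
  keep <- subsq & (B$period[pr$j] - A$period[pr$i]) <= delta_s
  if (delta_s >= max(nrow(A), nrow(B))) {
    warn("`delta_s` spans all periods; the lag constraint saturates to full precedence.")
  }
  new_constraint_set(
    tibble::tibble(term_a = A$term[pr$i][keep], term_b = B$term[pr$j][keep]),
    idx,
    label = sprintf("lag of %d period(s) from %s to %s", delta_s, from, to),
    lag = as.integer(delta_s)
  )
}

#' Explicit list of constrained pairs
#'
#' @param specs A list of [spline_spec()]s.
#' @param pairs A data frame with columns `term_a`, `term_b`, or a character
#'   vector of `"a~b"` strings.
#' @param label Optional label.
#' @return A [constraint_set].
#' @export
constrain_pairs <- function(specs, pairs, label = "explicit") {
  idx <- ranef_index(specs)
  if (is.character(pairs)) {
    sp <- strsplit(pairs, "~", fixed = TRUE)
    pairs <- tibble::tibble(
      term_a = purrr::map_chr(sp, 1L),
      term_b = purrr::map_chr(sp, 2L)
    )
  }
  new_constraint_set(pairs, idx, label = label)
}

#' Compile a named hypothesis block into a constraint set
#'
#' Accepts configuration blocks of the form
#' `list(type = "same_adjacent", include_within = TRUE)`,
#' `list(type = "precedence", from = "map", to = "weight")`,
#' `list(type = "block", effect = "map:slope1", other_response = "weight",
#'  include_intercept = TRUE)`,
#' `list(type = "lag", from = "weight", to = "map", delta_s = 1)`, or
#' `list(type = "pairs", pairs = c("weight:slope1~map:slope3"))`.
#'
#' @param specs A list of [spline_spec()]s.
#' @param block A named list as above.
#' @return A [constraint_set].
#' @export
constraints_from_config <- function(specs, block) {
  type <- block$type %||% abort("hypothesis block needs a `type`.")
  switch(type,
    same_adjacent = constrain_same_adjacent(
      specs, include_within = block$include_within %||% TRUE
    ),
    precedence = constrain_precedence(specs, block$from, block$to),
    block = constrain_block(
      specs, block$effect, block$other_response,
      include_intercept = block$include_intercept %||% TRUE
    ),
    lag = constrain_lag(specs, block$from, block$to, block$delta_s),
    pairs = constrain_pairs(specs, unlist(block$pairs)),
    abort(sprintf("unknown hypothesis type '%s'", type))
  )
}
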