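#' Index of individual-level random effects
#'
#' The multivariate spline model carries, per response, a random intercept
#' (the individual's deviation from the mean value at baseline) and one random
#' slope per spline period. Effects are ordered response by response, within
#' response intercept first then slopes by period; this ordering fixes the
#' rows/columns of the random-effect covariance matrix `G` everywhere in the
#' package.
#'
#' @param specs A [spline_spec()] or list of them.
#' @return A tibble with columns `term`, `response`, `kind`
#'   (`"intercept"`/`"slope"`), `period` (NA for intercepts), `start`, `end`
#'   (period interval, NA for intercepts).
#' @examples
#' wt <- spline_spec("weight", 8, c(18, 29), 44)
#' map <- spline_spec("map", 8, c(18, 29, 36), 44)
#' ranef_index(list(wt, map))
#' @export
ranef_index <- function(specs) {
  specs <- as_spec_list(specs)
  purrr::map_dfr(specs, function(s) {
    iv <- period_intervals(s)
    tibble::tibble(
      term = c(
        paste0(s$response, ":intercept"),
        paste0(s$response, ":slope", iv$period)
      ),
      response = s$response,
      kind = c("intercept", rep("slope", nrow(iv))),
      period = c(NA_integer_, iv$period),
      start = c(NA_real_, iv$start),
      end = c(NA_real_, iv$end)
    )
  })
}

#' Specify a multivariate linear-spline multilevel model
#'
#' Bundles the per-response spline specifications, the individual-level
#' covariates entering each response's fixed part (as intercept-shifting main
#' effects), and an optional set of zero-constraints on random-effect
#' covariances.
#'
#' @param specs A [spline_spec()] or list of them (one per response).
#' @param covariates Character vector of covariate column names shared by all
#'   responses, or a named list (by response) of character vectors.
#' @param constraints Optional `constraint_set` (see e.g.
#'   [constrain_same_adjacent()]) of covariances fixed to zero.
#' @return An object of class `mlm_spec`.
#' @export
mlm_spec <- function(specs, covariates = character(), constraints = NULL) {
  specs <- as_spec_list(specs)
  if (is.list(covariates) && !is.null(names(covariates))) {
    cov_by_resp <- purrr::map(
      setNames(names(specs), names(specs)),
      function(r) as.character(covariates[[r]] %||% character())
    )
  } else {
    covariates <- as.character(covariates)
    cov_by_resp <- purrr::map(setNames(names(specs), names(specs)), ~covariates)
  }
  idx <- ranef_index(specs)
  if (!is.null(constraints)) {
    constraints <- validate_constraints(constraints, idx)
  }
  structure(
    list(
      specs = specs, covariates = cov_by_resp,
      constraints = constraints, ranef = idx
    ),
    class = "mlm_spec"
  )
}

#' @export
print.mlm_spec <- function(x, ...) {
  cat(sprintf(
    "<mlm_spec> %d response(s): %s; %d random effects; %d constrained covariance(s)\n",
    length(x$specs), paste(names(x$specs), collapse = ", "),
    nrow(x$ranef),
    if (is.null(x$constraints)) 0L else nrow(x$constraints)
  ))
  invisible(x)
}

#' Validate a long-format repeated-measures table
#'
#' Checks that `data` has the long layout expected throughout the package:
#' one row per individual x occasion x response, with columns `id`, `time`,
#' `response`, `value` plus any time-constant covariate columns. Rejects
#' duplicate (id, time, response) triples, times before the response's
#' baseline (named in the error), and covariates varying within individual.
#'
#' @param data A data frame in long format.
#' @param spec An [mlm_spec()] (or list of [spline_spec()]s) giving baselines
#'   and covariate names.
#' @return The data as a tibble, invisibly validated.
#' @export
validate_long_data <- function(data, spec) {
  if (inherits(spec, "mlm_spec")) {
    specs <- spec$specs
    covars <- unique(unlist(spec$covariates))
  } else {
    specs <- as_spec_list(spec)
    covars <- character()
  }
  data <- tibble::as_tibble(data)
  need <- c("id", "time", "response", "value", covars)
  if (length(miss <- setdiff(need, names(data)))) {
    abort(paste0("missing columns: ", paste(miss, collapse = ", ")))
  }
  if (!all(unique(data$response) %in% names(specs))) {
    extra <- setdiff(unique(data$response), names(specs))
    abort(paste0("responses absent from the model spec: ", paste(extra, collapse = ", ")))
  }
  dup <- duplicated(data[c("id", "time", "response")])
  if (any(dup)) {
    d <- data[dup, ][1L, ]
    abort(sprintf(
      "duplicate (id, time, response) rows, e.g. id %s, time %g, response %s.",
      as.character(d$id), d$time, d$response
    ))
  }
  for (r in unique(data$response)) {
    b <- specs[[r]]$baseline
    bad <- data$response == r & data$time < b
    if (any(bad)) {
      d <- data[bad, ][1L, ]
      abort(sprintf(
        "occasion before baseline %g for response '%s': individual %s at time %g.",
        b, r, as.character(d$id), d$time
      ))
    }
  }
  for (cv in covars) {
    nvals <- tapply(data[[cv]], data$id, function(v) length(unique(v)))
    if (any(nvals > 1L)) {
      abort(sprintf(
        "covariate '%s' varies within individual %s.",
        cv, names(nvals)[which(nvals > 1L)[1L]]
      ))
    }
  }
  data
}

#' Read long-format growth data from CSV
#'
#' Thin wrapper over `read.csv` returning a tibble with the columns
#' `id`, `time`, `response`, `value` (plus covariates) expected by
#' [fit_mlm()]. Missing occasions are simply absent rows (missing at random
#' is assumed by the likelihood).
#'
#' @param path CSV path.
#' @param ... Passed to `utils::read.csv`.
#' @return A tibble.
#' @export
read_growth_data <- function(path, ...) {
  tibble::as_tibble(utils::read.csv(path, ...))
}
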