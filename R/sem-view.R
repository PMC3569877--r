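#' Structural-equation (latent growth curve) layout of the spline model
#'
#' The multilevel spline model has an equivalent latent growth curve
#' parameterisation on a balanced grid of occasions: each response's
#' measurements load on an intercept factor (loading 1 everywhere) and one
#' slope factor per spline period, with the slope loadings equal to the
#' spline basis evaluated at the grid times. The factor covariance matrix is
#' identified with the individual-level `G` and the per-occasion residual
#' structure with the occasion-level `R` (residual variances constant over
#' time within response; a common cross-response residual covariance at each
#' shared time point). Unbalanced data correspond to treating the design as
#' balanced with missing cells under full-information maximum likelihood.
#'
#' @param specs A list of [spline_spec()]s.
#' @param grid Ordered numeric vector of occasion times (e.g. whole weeks).
#'   Grid points before a response's baseline are allowed but flagged
#'   unusable for that response and excluded from implied moments.
#' @return A `sem_layout`: list with `loadings` (stacked Lambda, one row per
#'   response x usable grid time, columns in [ranef_index()] order), `rows`
#'   (tibble: response, time), `grid`, `specs`, and `unusable` (tibble of
#'   flagged response/time pairs).
#' @examples
#' wt <- spline_spec("weight", 8, c(18, 29), 44)
#' sem_layout(list(wt), grid = c(8, 18, 29, 44))$loadings
#' @export
sem_layout <- function(specs, grid) {
  specs <- as_spec_list(specs)
  grid <- as.numeric(grid)
  if (!length(grid)) abort("`grid` must contain at least one occasion time.")
  if (is.unsorted(grid, strictly = TRUE)) abort("`grid` must be strictly increasing.")
  idx <- ranef_index(specs)
  M <- nrow(idx)
  rows <- list(); load <- list(); unus <- list()
  for (r in names(specs)) {
    s <- specs[[r]]
    usable <- grid >= s$baseline
    if (any(!usable)) {
      unus[[r]] <- tibble::tibble(response = r, time = grid[!usable])
    }
    tg <- grid[usable]
    B <- spline_basis(s, tg)
    Lam <- matrix(0, length(tg), M, dimnames = list(NULL, idx$term))
    cols <- which(idx$response == r)
    Lam[, cols[1L]] <- 1
    Lam[, cols[-1L]] <- B
    rows[[r]] <- tibble::tibble(response = r, time = tg)
    load[[r]] <- Lam
  }
  structure(
    list(
      loadings = do.call(rbind, load),
      rows = dplyr::bind_rows(rows),
      grid = grid,
      specs = specs,
      unusable = if (length(unus)) dplyr::bind_rows(unus) else NULL
    ),
    class = "sem_layout"
  )
}

#' @export
print.sem_layout <- function(x, ...) {
  cat(sprintf(
    "<sem_layout> %d grid time(s), %d response(s), %d measurement rows, %d factors\n",
    length(x$grid), length(x$specs), nrow(x$rows), ncol(x$loadings)
  ))
  invisible(x)
}

#' Implied mean and covariance of the balanced measurement vector
#'
#' `mean = Lambda nu` with `nu` the factor means (per-response intercept and
#' slope fixed effects; covariates at their reference level), and
#' `cov = Lambda G Lambda' + R-expansion`, where the residual expansion
#' places each response's occasion variance on the diagonal and the
#' cross-response residual covariance between rows of different responses
#' sharing a grid time.
#'
#' @param layout A [sem_layout()].
#' @param fixef Named fixed-effect vector (`response:intercept`,
#'   `response:slope1..m`; covariate coefficients, if present, are ignored
#'   since covariates sit at reference level 0).
#' @param G Factor (random-effect) covariance matrix in [ranef_index()]
#'   order.
#' @param R Occasion-level covariance matrix across responses.
#' @return List with `mean`, `cov` and the layout's `rows` tibble.
#' @export
sem_implied_moments <- function(layout, fixef, G, R) {
  stopifnot(inherits(layout, "sem_layout"))
  Lam <- layout$loadings
  M <- ncol(Lam)
  if (!identical(dim(G), c(M, M))) abort("`G` does not match the layout's factor count.")
  if (is.null(dim(R))) R <- matrix(R, 1L, 1L)
  responses <- names(layout$specs)
  if (nrow(R) != length(responses)) abort("`R` does not match the response count.")
  nu <- factor_means(layout, fixef)
  mu <- drop(Lam %*% nu)
  V <- Lam %*% G %*% t(Lam)
  ri <- match(layout$rows$response, responses)
  tt <- layout$rows$time
  n <- nrow(layout$rows)
  V <- V + diag(diag(R)[ri], nrow = n)
  if (length(responses) > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (tt[i] == tt[j] && ri[i] != ri[j]) {
          V[i, j] <- V[i, j] + R[ri[i], ri[j]]
          V[j, i] <- V[i, j]
        }
      }
    }
  }
  list(mean = mu, cov = V, rows = layout$rows)
}

factor_means <- function(layout, fixef) {
  idx <- ranef_index(layout$specs)
  want <- ifelse(
    idx$kind == "intercept",
    paste0(idx$response, ":intercept"),
    paste0(idx$response, ":slope", idx$period)
  )
  if (is.null(names(fixef))) {
    abort("`fixef` must be named (response:intercept, response:slope1, ...).")
  }
  if (length(miss <- setdiff(want, names(fixef)))) {
    abort(paste0("missing fixed effects: ", paste(miss, collapse = ", ")))
  }
  unname(fixef[want])
}

#' Check moment equivalence of the multilevel and structural-equation views
#'
#' Builds the latent growth curve layout on a grid, computes the implied
#' moments from the fitted model's parameters via the loading algebra, and
#' compares them with the multilevel model's marginal moments for an
#' individual observed on exactly that grid. The two are algebraically
#' identical, so discrepancies beyond numerical precision indicate an
#' implementation inconsistency.
#'
#' @param fit An [fit_mlm()] object.
#' @param grid Occasion times; defaults to whole weeks from the latest
#'   baseline to the earliest horizon across responses.
#' @return A list with `max_abs_mean_diff`, `max_abs_cov_diff`, the `layout`
#'   and both moment sets.
#' @export
sem_check_equivalence <- function(fit, grid = NULL) {
  stopifnot(inherits(fit, "mlm_fit"))
  specs <- fit$spec$specs
  if (is.null(grid)) {
    lo <- max(purrr::map_dbl(specs, "baseline"))
    hi <- min(purrr::map_dbl(specs, "horizon"))
    grid <- seq(ceiling(lo), floor(hi))
  }
  layout <- sem_layout(specs, grid)
  fixef <- setNames(fit$fixef$estimate, fit$fixef$term)
  sem <- sem_implied_moments(layout, fixef, fit$G, fit$R)
  mlm <- mlm_marginal_moments(fit, grid)
  ord_sem <- order(match(sem$rows$response, names(specs)), sem$rows$time)
  ord_mlm <- order(match(mlm$rows$response, names(specs)), mlm$rows$time)
  if (!identical(sem$rows[ord_sem, ], mlm$rows[ord_mlm, ])) {
    abort("the two views produced different measurement rows; check the grid against the baselines.")
  }
  dm <- sem$mean[ord_sem] - mlm$mean[ord_mlm]
  dV <- sem$cov[ord_sem, ord_sem] - mlm$cov[ord_mlm, ord_mlm]
  list(
    max_abs_mean_diff = max(abs(dm)),
    max_abs_cov_diff = max(abs(dV)),
    layout = layout,
    sem = sem,
    mlm = mlm
  )
}
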