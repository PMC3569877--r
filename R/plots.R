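#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot fitted mean trajectories
#'
#' Draws each response's population mean trajectory (intercept plus spline
#' slopes at reference covariate levels) over the observation window, with
#' vertical guides at the knots.
#'
#' @param object An [fit_mlm()] object.
#' @param step Grid resolution along the time axis.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mlm_fit
#' @export
autoplot.mlm_fit <- function(object, step = 0.25, ...) {
  specs <- object$spec$specs
  fixef <- setNames(object$fixef$estimate, object$fixef$term)
  df <- purrr::map_dfr(specs, function(s) {
    tt <- seq(s$baseline, s$horizon, by = step)
    B <- spline_basis(s, tt)
    fe <- fixef[paste0(s$response, ":", c("intercept", colnames(B)))]
    tibble::tibble(
      response = s$response, time = tt,
      mean = fe[1L] + drop(B %*% fe[-1L])
    )
  })
  knots <- purrr::map_dfr(specs, function(s) {
    tibble::tibble(response = s$response, knot = s$knots)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mean)) +
    ggplot2::geom_vline(
      data = knots, ggplot2::aes(xintercept = .data$knot),
      linetype = "dotted", colour = "grey50"
    ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~response, scales = "free_y") +
    ggplot2::labs(
      x = "time", y = "fitted population mean",
      title = "Fitted linear-spline mean trajectories"
    )
}

#' Plot adjusted random-effect regression coefficients
#'
#' Point estimates with confidence intervals, one panel per outcome, dodged
#' by standard-error method.
#'
#' @param object A [ranef_regression()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ranef_reg
#' @export
autoplot.ranef_reg <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$term, y = .data$estimate,
      ymin = .data$conf.low, ymax = .data$conf.high,
      colour = .data$method
    )
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::labs(
      x = NULL, y = "adjusted coefficient",
      title = "Random-effect regression coefficients"
    )
}
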