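#' Plot an influx fit
#'
#' Observed replicate-level rates with the fitted rate curve overlaid; for
#' two-stage fits the activation threshold is marked by a dashed line.
#'
#' @param object An `influx_fit`.
#' @param n_grid Number of points for the fitted curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.influx_fit <- function(object, n_grid = 200, ...) {
  d <- object$data
  grid <- seq(min(d$S_mM), max(d$S_mM), length.out = n_grid)
  curve <- if (object$model == "mono") {
    tibble::tibble(S_mM = grid, v = mm_rate(object$params, grid))
  } else {
    tibble::tibble(S_mM = grid, v = two_stage_rate(object$params, grid))
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$S_mM)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$v_umol_per_gDW_h),
                        alpha = 0.6) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$v),
                       colour = "#2166ac") +
    ggplot2::labs(
      x = "external concentration (mM)",
      y = expression(influx ~ (mu * mol ~ g^-1 ~ DW ~ h^-1)),
      title = if (object$model == "mono")
        "Single-phase Michaelis-Menten fit"
      else "Two-stage Michaelis-Menten fit"
    )
  if (object$model == "two_stage")
    p <- p + ggplot2::geom_vline(xintercept = object$params$T,
                                 linetype = "dashed", colour = "grey40")
  p
}

#' Plot the threshold profile of a two-stage fit
#'
#' SSE of the profiled fit at each candidate activation threshold; the
#' selected threshold is highlighted.
#'
#' @param fit A two-stage `influx_fit`.
#' @return A ggplot object.
#' @export
plot_t_profile <- function(fit) {
  stopifnot(inherits(fit, "influx_fit"))
  if (is.null(fit$t_profile))
    abort("fit has no threshold profile (mono model?)",
          class = "ninflux_config_error")
  ggplot2::ggplot(fit$t_profile, ggplot2::aes(x = .data$T, y = .data$sse)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = fit$params$T, linetype = "dashed",
                        colour = "#b2182b") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "candidate activation threshold T (mM)",
                  y = "profiled SSE",
                  title = "Threshold profile")
}

#' Heat map of a fold-change matrix
#'
#' The treatment-mean log2 fold-changes as a tile plot, one row per
#' row key, one column per treatment.
#'
#' @param object A `fold_change_matrix` from [log2fc_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fold_change_matrix <- function(object, ...) {
  d <- object$by_treatment
  d$row <- do.call(paste, c(d[object$row_cols], sep = " / "))
  d$treatment <- factor(d$treatment, levels = unique(d$treatment))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$treatment, y = .data$row,
                                  fill = .data$log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#ffffbf", mid = "#abd9e9",
                                  high = "#2c7bb6", midpoint = 0,
                                  name = expression(log[2] * FC)) +
    ggplot2::labs(x = "treatment", y = NULL,
                  title = "log2 fold-change vs across-treatment mean")
}
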