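# ggplot2 views of the main result types. These are working plots for
# analysis notebooks, not publication figures.

#' Plot POD distributions per cell type
#'
#' Box plots of log10 POD by cell type, split by phenotype category, with
#' censored PODs drawn at their bound.
#'
#' @param pods A [fit_pod_table()] result.
#' @return A ggplot object.
#' @export
plot_pod_distribution <- function(pods) {
  ggplot2::ggplot(
    pods,
    ggplot2::aes(x = .data$cell_type, y = .data$pod, fill = .data$category)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "POD (uM, censored at bound)",
                  fill = "phenotype category") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @describeIn toxpi_profile Ranked stacked-bar view of slice contributions
#'   to each chemical's overall ToxPi score.
#' @param object A `toxpi_profiles` tibble.
#' @param top_n Show only the `top_n` highest-ranked chemicals (default all).
#' @param ... Unused.
#' @method autoplot toxpi_profiles
#' @export
autoplot.toxpi_profiles <- function(object, top_n = NULL, ...) {
  weights <- attr(object, "weights")
  df <- object %>%
    dplyr::mutate(contribution = .data$slice_score * unname(weights[.data$slice]))
  if (!is.null(top_n)) df <- df %>% dplyr::filter(.data$rank <= top_n)
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = stats::reorder(.data$chemical, -.data$rank),
                 y = .data$contribution, fill = .data$slice)
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "overall ToxPi score (slice contributions)",
                  fill = "cell type") +
    ggplot2::theme_minimal()
}

#' @describeIn feature_importance Bar chart of the top features.
#' @param object An `importance_table`.
#' @param ... Unused.
#' @method autoplot importance_table
#' @export
autoplot.importance_table <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = stats::reorder(.data$feature, .data$importance),
                 y = .data$importance)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL,
                  y = "mean held-out accuracy drop (percentage points)") +
    ggplot2::theme_minimal()
}

#' @describeIn margin_of_exposure Per-chemical MoE dot plot against the
#'   concern benchmark.
#' @param object An `moe_table`.
#' @param ... Unused.
#' @method autoplot moe_table
#' @export
autoplot.moe_table <- function(object, ...) {
  bench <- attr(object, "benchmark") %||% 100
  df <- object %>% dplyr::filter(is.finite(.data$moe))
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = stats::reorder(.data$chemical, .data$moe),
                 y = .data$moe, colour = .data$concern,
                 shape = .data$moe_is_lower_bound)
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = bench, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "margin of exposure (POD_AED / exposure)",
                  colour = sprintf("MoE < %g", bench),
                  shape = "lower bound") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_hill Concentration-response points with the fitted curve
#'   and the 1-SD benchmark band.
#' @param object A `hill_fit`.
#' @param vehicle_sd Optional benchmark band half-width (% of control).
#' @param ... Unused.
#' @method autoplot hill_fit
#' @export
autoplot.hill_fit <- function(object, vehicle_sd = NULL, ...) {
  rng <- range(object$data$conc_uM)
  curve <- tibble::tibble(
    conc_uM = 10^seq(log10(rng[1]) - 1, log10(rng[2]), length.out = 200)
  )
  curve$response_pct <- if (object$converged && object$direction != "flat") {
    predict_hill(object, curve$conc_uM)
  } else {
    rep(mean(object$data$response_pct), nrow(curve))
  }
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$conc_uM, y = .data$response_pct)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (uM)", y = "response (% of control)") +
    ggplot2::theme_minimal()
  if (!is.null(vehicle_sd)) {
    p <- p + ggplot2::geom_hline(yintercept = 100 + c(-1, 1) * vehicle_sd,
                                 linetype = "dotted")
  }
  p
}
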