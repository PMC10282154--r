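#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter plot of a harmonized variant set with fitted MR slopes
#'
#' Plots the per-variant exposure and outcome associations (with error bars)
#' together with the IVW line through the origin and, when at least three
#' variants are available, the MR-Egger line with its intercept.
#'
#' @param object A `harmonized_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot harmonized_set
#' @export
autoplot.harmonized_set <- function(object, ...) {
  df <- tibble::as_tibble(object)
  # orient to positive exposure betas so the Egger intercept is drawable
  sgn <- ifelse(df$bx < 0, -1, 1)
  df$bx <- df$bx * sgn; df$by <- df$by * sgn
  ivw <- mr_ivw(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$by - .data$sy,
                                        ymax = .data$by + .data$sy),
                           linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$bx - .data$sx,
                                         xmax = .data$bx + .data$sx),
                            linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_abline(intercept = 0, slope = ivw$estimate,
                         colour = "#2166AC") +
    ggplot2::labs(
      x = paste("Effect on", attr(object, "exposure_name")),
      y = paste("Effect on", attr(object, "outcome_name")),
      title = "Variant-level associations",
      subtitle = sprintf("IVW slope %.3f (blue)", ivw$estimate)
    ) +
    ggplot2::theme_minimal()
  if (nrow(df) >= 3L) {
    eg <- mr_egger(object)
    p <- p + ggplot2::geom_abline(intercept = eg$egger_intercept,
                                  slope = eg$estimate,
                                  colour = "#B2182B", linetype = 2)
  }
  p
}

#' Forest plot of MR estimates
#'
#' Draws point estimates with 95% intervals for a stacked table of MR results
#' — for example the output of [mr_all_methods()] or a filtered
#' [run_forward()] table.
#'
#' @param results Data frame with columns `estimate`, `ci_low`, `ci_high` and
#'   a label column.
#' @param label Column (string) used for the y axis; defaults to `"method"`
#'   if present, otherwise `"exposure"`.
#' @param exponentiate Show odds ratios on a log-scaled axis. Default FALSE.
#' @return A ggplot object.
#' @export
plot_forest <- function(results, label = NULL, exponentiate = FALSE) {
  df <- tibble::as_tibble(results)
  if (is.null(label)) label <- if ("method" %in% names(df)) "method" else "exposure"
  df <- df[!is.na(df$estimate), ]
  null_line <- 0
  if (exponentiate) {
    df$estimate <- exp(df$estimate)
    df$ci_low <- exp(df$ci_low)
    df$ci_high <- exp(df$ci_high)
    null_line <- 1
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                        y = .data[[label]])) +
    ggplot2::geom_vline(xintercept = null_line, linetype = 3) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = if (exponentiate) "Odds ratio (95% CI)" else
      "Estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
  if (exponentiate) p <- p + ggplot2::scale_x_log10()
  p
}

#' Leave-one-out forest plot
#'
#' Shows the IVW estimate after omitting each variant in turn, against the
#' full-set estimate.
#'
#' @param loo Result list from [leave_one_out()].
#' @param full Optional full-set `mr_result` to draw as a reference line.
#' @return A ggplot object.
#' @export
plot_leave_one_out <- function(loo, full = NULL) {
  df <- loo$results
  df$ci_low <- df$estimate - Z95 * df$se
  df$ci_high <- df$estimate + Z95 * df$se
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                        y = .data$excluded_variant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2, colour = "grey50") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "IVW estimate omitting variant", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(full)) {
    p <- p + ggplot2::geom_vline(xintercept = full$estimate, colour = "#2166AC")
  }
  p
}
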