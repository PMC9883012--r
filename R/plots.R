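# ggplot2 visualisations for the main result types.

#' Scatter plot of a harmonised instrument set
#'
#' Outcome versus exposure betas with error bars and the IVW (and, when
#' J >= 3, Egger) fitted lines.
#'
#' @param object An `mr_harmonised` set.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_harmonised
#' @export
autoplot.mr_harmonised <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$b_x, y = .data$b_y)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$b_y - .data$se_y,
                                        ymax = .data$b_y + .data$se_y),
                           linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$b_x - .data$se_x,
                                         xmax = .data$b_x + .data$se_x),
                            linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "effect on exposure (beta)",
                  y = "effect on outcome (beta)")
  if (nrow(df) >= 2) {
    ivw <- mr_ivw(object)
    p <- p + ggplot2::geom_abline(slope = ivw$estimate, intercept = 0,
                                  colour = "#2166AC")
  }
  if (nrow(df) >= 3) {
    eg <- mr_egger(object)
    p <- p + ggplot2::geom_abline(slope = eg$slope$estimate,
                                  intercept = eg$intercept$estimate,
                                  colour = "#B2182B", linetype = "dashed")
  }
  p
}

#' Radial (Galbraith) plot with per-variant Q contributions
#'
#' @param hset An `mr_harmonised` set.
#' @param alpha Outlier significance level for colouring.
#' @return A ggplot object.
#' @export
plot_radial <- function(hset, alpha = 0.05) {
  fit <- radial_fit(hset)
  df <- tibble(
    variant_id = hset$variant_id,
    precision = sqrt(fit$weights),
    radial_y = (hset$b_y / hset$b_x) * sqrt(fit$weights),
    outlier = fit$q_j > qchisq(1 - alpha, df = 1)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$precision, y = .data$radial_y,
                                   colour = .data$outlier)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = fit$theta, intercept = 0,
                         colour = "#2166AC") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "#B2182B")) +
    ggplot2::labs(x = "precision (sqrt weight)",
                  y = "ratio estimate x precision", colour = "outlier")
}

#' Volcano-style overview of a screen
#'
#' MRE IVW estimate against -log10 FDR-adjusted p-value, coloured by verdict.
#'
#' @param object An `mr_screen` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_screen
#' @export
autoplot.mr_screen <- function(object, ...) {
  df <- as_tibble(object)[as_tibble(object)$status == "analysed", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                   y = -log10(.data$fdr_p),
                                   colour = .data$verdict)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "MRE IVW estimate (beta)",
                  y = "-log10 FDR-adjusted p", colour = NULL)
}

#' Marginal inclusion probability plot for an MR-BMA result
#'
#' @param object A `bma_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bma_result
#' @export
autoplot.bma_result <- function(object, ...) {
  df <- object$traits
  df$trait_id <- factor(df$trait_id, levels = rev(df$trait_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mip, y = .data$trait_id)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$mip,
                                       yend = .data$trait_id),
                          colour = "grey60") +
    ggplot2::geom_point(colour = "#2166AC") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "marginal inclusion probability", y = NULL)
}

#' Leave-one-out forest plot
#'
#' @param qc An `mr_qc` report.
#' @return A ggplot object.
#' @export
plot_loo <- function(qc) {
  df <- qc$loo
  df$left_out <- factor(df$left_out, levels = rev(df$left_out))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$left_out)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$estimate - qnorm(0.975) * .data$se,
      xmax = .data$estimate + qnorm(0.975) * .data$se), height = 0.2) +
    ggplot2::geom_vline(xintercept = qc$ivw$estimate, colour = "#2166AC",
                        linetype = "dashed") +
    ggplot2::labs(x = "MRE IVW estimate omitting one variant", y = NULL)
}
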