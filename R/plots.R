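#' Volcano-style plot of a scored screen
#'
#' Mean normalized log2 fold-change against -log10 empirical FDR, coloured by
#' hit call, with the hit-calling thresholds drawn as dashed lines.
#'
#' @param object An `apa_screen_result` from [screen_score()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot apa_screen_result
#' @export
autoplot.apa_screen_result <- function(object, ...) {
  df <- tidy(object)
  params <- attr(object, "params")
  n_sub <- params$n_sub %||% 10000
  df$fdr_plot <- pmax(df$fdr, 1 / n_sub)   # keep zero-FDR targets on the panel
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_l2fc,
                                   y = -log10(.data$fdr_plot),
                                   colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * (params$lfc_cut %||% 0.5),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(params$fdr_cut %||% 0.05),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(enriched = "#1b9e77",
                                            depleted = "#7570b3",
                                            not_called = "grey70")) +
    ggplot2::labs(x = "mean normalized log2(fold-change)",
                  y = "-log10(empirical FDR)",
                  colour = NULL,
                  title = paste("pgRNA screen:", attr(object, "arm"))) +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential APA
#'
#' Change in log2(distal/proximal) between groups against -log10 p, shortened
#' genes left, lengthened right.
#'
#' @param object An `apa_diff` from [diff_apa()].
#' @param alpha Significance threshold drawn as the horizontal line.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot apa_diff
#' @export
autoplot.apa_diff <- function(object, alpha = 0.05, ...) {
  df <- tidy(object) |>
    mutate(status = ifelse(.data$p >= alpha, "ns", .data$direction))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_red,
                                   y = -log10(pmax(.data$p, 1e-300)),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(shortened = "#377eb8",
                                            lengthened = "#e6ab02",
                                            ns = "grey70")) +
    ggplot2::labs(x = expression(Delta ~ log[2](distal / proximal)),
                  y = expression(-log[10](italic(p))), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot of a stratified cohort
#'
#' Step survival curves for the short- and long-3'-UTR terciles with the
#' logrank p value in the subtitle.
#'
#' @param object A `utr_km` from [km_logrank()] or [gene_stratify()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot utr_km
#' @export
autoplot.utr_km <- function(object, ...) {
  df <- tidy(object)
  # prepend t = 0, S = 1 for each curve
  start <- df |> distinct(.data$tercile) |>
    mutate(time = 0, estimate = 1)
  ggplot2::ggplot(bind_rows(start, df),
                  ggplot2::aes(x = .data$time, y = .data$estimate,
                               colour = .data$tercile)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c(short = "#377eb8",
                                            long = "#e6ab02")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability", colour = "3' UTR",
                  subtitle = sprintf("logrank p = %.3g", object$p)) +
    ggplot2::theme_minimal()
}
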