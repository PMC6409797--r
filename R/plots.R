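#' @import ggplot2
NULL

#' Plot methylation by genomic element class
#'
#' Bar chart of the fraction of CpG sites called methylated per element
#' class, annotated with the number of covered CpGs.
#'
#' @param summary An `element_summary` object (see [element_summary()]).
#' @return A ggplot object.
#' @export
plot_element_summary <- function(summary) {
  dat <- summary$by_class
  dat$class <- factor(dat$class, levels = dat$class)
  ggplot(dat, aes(x = .data$class, y = .data$frac_methylated)) +
    geom_col(fill = "steelblue") +
    geom_text(
      aes(label = paste0("n=", .data$n_cpg)),
      vjust = -0.4, size = 3
    ) +
    labs(
      x = NULL, y = "Fraction of CpGs called methylated",
      title = "CpG methylation by genomic element"
    ) +
    theme_minimal()
}

#' Plot a fitted normal mixture over its data
#'
#' Histogram of the values (zeroes removed when the fit removed them)
#' with the fitted component densities and their weighted sum overlaid.
#'
#' @param object A `mixture_fit` from [fit_normal_mixture()].
#' @param values The data the mixture was fitted to.
#' @param bins Histogram bin count (default 60).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mixture_fit
#' @export
autoplot.mixture_fit <- function(object, values, bins = 60, ...) {
  v <- values[is.finite(values) & values != 0]
  grid <- seq(min(v), max(v), length.out = 512)
  comp <- purrr::map_dfr(seq_len(object$k), function(j) {
    tibble(
      x = grid,
      density = object$weights[j] * dnorm(grid, object$means[j],
                                          object$sds[j]),
      component = factor(j)
    )
  })
  total <- comp |>
    dplyr::group_by(.data$x) |>
    dplyr::summarise(density = sum(.data$density), .groups = "drop")
  ggplot() +
    geom_histogram(
      data = tibble(v = v),
      aes(x = .data$v, y = after_stat(density)),
      bins = bins, fill = "grey85", colour = "grey70"
    ) +
    geom_line(
      data = comp,
      aes(x = .data$x, y = .data$density, colour = .data$component)
    ) +
    geom_line(
      data = total, aes(x = .data$x, y = .data$density),
      linewidth = 0.8
    ) +
    labs(
      x = "CpG O/E", y = "Density",
      title = sprintf("Normal mixture fit (k = %d)", object$k)
    ) +
    theme_minimal()
}

#' @rdname autoplot.mixture_fit
#' @param fit A `mixture_fit`.
#' @export
plot_mixture <- function(fit, values, bins = 60) {
  autoplot.mixture_fit(fit, values, bins)
}

#' Plot differential expression against differential methylation
#'
#' Scatter of log2 fold change versus the between-population difference
#' in weighted methylation level, highlighting the genes that passed the
#' top-differential-methylation filter, with the Spearman correlation
#' over the flagged genes in the subtitle.
#'
#' @param diff_table Output of [differential_table()].
#' @return A ggplot object.
#' @export
plot_differential <- function(diff_table) {
  sp <- attr(diff_table, "spearman")
  ggplot(diff_table, aes(x = .data$delta_w, y = .data$log2_fc)) +
    geom_point(aes(colour = .data$passed_top), alpha = 0.6, size = 1) +
    scale_colour_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    labs(
      x = "Differential methylation (delta W, A - B)",
      y = "log2 fold change (A / B)",
      colour = "Top |delta W|",
      subtitle = if (!is.null(sp) && is.finite(sp$rho)) {
        sprintf("Spearman rho = %.3f, p = %.3g (flagged genes)",
                sp$rho, sp$p_value)
      } else {
        NULL
      }
    ) +
    theme_minimal()
}

#' Plot expression stability against methylation
#'
#' Scatter of the per-gene standard deviation of log2(FPKM) across
#' individuals against the gene's weighted methylation level.
#'
#' @param stability_table Output of [expression_stability()].
#' @param x_metric `"w_level"` (default) or `"frac_sites_called"`.
#' @return A ggplot object.
#' @export
plot_stability <- function(stability_table,
                           x_metric = c("w_level", "frac_sites_called")) {
  x_metric <- match.arg(x_metric)
  ggplot(
    stability_table,
    aes(x = .data[[x_metric]], y = .data$sd_log2_fpkm)
  ) +
    geom_point(alpha = 0.5, size = 1) +
    geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                colour = "firebrick") +
    labs(
      x = if (x_metric == "w_level") {
        "Weighted methylation level"
      } else {
        "Fraction of CpG sites called methylated"
      },
      y = "SD of log2(FPKM) across individuals"
    ) +
    theme_minimal()
}

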