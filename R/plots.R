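#' @import ggplot2
NULL

#' @export
ggplot2::autoplot

#' Plot diversity summaries across demographies
#'
#' Boxplots of a per-replicate sample summary statistic (for example
#' `prop_ns` or `load`) by demography, from the `sample_summaries` table of
#' [run_experiment()].
#'
#' @param summaries The `sample_summaries` tibble.
#' @param stat Column to plot.
#' @return A ggplot object.
#' @export
plot_sample_summaries <- function(summaries, stat = "prop_ns") {
  ggplot(summaries, aes(x = .data$demography, y = .data[[stat]],
                        fill = .data$demography)) +
    geom_boxplot(show.legend = FALSE) +
    labs(x = NULL, y = stat) +
    theme_minimal()
}

#' Cumulative additive-variance share below a population frequency
#'
#' Reproduces the rare-variant variance-partition view: for each demography,
#' the mean fraction of target `V_A` explained by causal SNPs below each
#' population frequency threshold.
#'
#' @param va_by_frequency The `va_by_frequency` tibble of [run_experiment()].
#' @return A ggplot object (log-scaled frequency axis).
#' @export
plot_va_by_frequency <- function(va_by_frequency) {
  df <- dplyr::summarise(
    dplyr::group_by(va_by_frequency, .data$demography, .data$tau,
                    .data$threshold),
    fraction = mean(.data$fraction, na.rm = TRUE), .groups = "drop")
  ggplot(df, aes(x = .data$threshold, y = .data$fraction,
                 colour = .data$demography)) +
    geom_line() + geom_point() +
    scale_x_log10() +
    facet_wrap(~tau, labeller = label_both) +
    labs(x = "population frequency threshold",
         y = "fraction of target V_A below threshold") +
    theme_minimal()
}

#' Cumulative variance explained by the top-k causal SNPs
#'
#' @param topk The `topk` tibble of [run_experiment()].
#' @param of `"V_P"` (share of phenotypic variance) or `"V_A"` (share of
#'   target additive variance).
#' @return A ggplot object.
#' @export
plot_topk <- function(topk, of = c("V_P", "V_A")) {
  of <- match.arg(of)
  col <- if (of == "V_P") "frac_V_P" else "frac_V_A"
  df <- dplyr::summarise(
    dplyr::group_by(topk, .data$demography, .data$tau, .data$k),
    fraction = mean(.data[[col]], na.rm = TRUE), .groups = "drop")
  ggplot(df, aes(x = .data$k, y = .data$fraction,
                 colour = .data$demography)) +
    geom_line() + geom_point() +
    facet_wrap(~tau, labeller = label_both) +
    labs(x = "top k causal SNPs (by per-SNP variance)",
         y = paste("fraction of", of, "explained")) +
    theme_minimal()
}

#' Autoplot an association result as a rank-ordered P-value plot
#'
#' @param object An [assoc_test()] result.
#' @param ... Unused.
#' @return A ggplot object with the conventional significance thresholds.
#' @export
autoplot.assoc_result <- function(object, ...) {
  df <- tidy.assoc_result(object)
  df <- df[df$testable, ]
  df <- df[order(df$p_value), ]
  df$rank <- seq_len(nrow(df))
  ggplot(df, aes(x = .data$rank, y = -log10(.data$p_value))) +
    geom_point() +
    geom_hline(yintercept = -log10(c(1e-2, 1e-5, 5e-8)), linetype = "dashed") +
    labs(x = "causal SNP rank", y = expression(-log[10](italic(P)))) +
    theme_minimal()
}
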