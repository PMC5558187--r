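#' Bar-with-error plot of group phenotype means
#'
#' Bar chart of per-group phenotype means with standard-deviation error
#' bars, one panel per phenotype, mirroring the usual severity-group
#' comparison figures. Requires ggplot2.
#'
#' @param summary Output of [summarize_groups()].
#' @return A ggplot object.
#' @export
plot_group_phenotypes <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("plot_group_phenotypes() requires the ggplot2 package.")
  }
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = factor(.data$score), y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.25, na.rm = TRUE) +
    ggplot2::facet_wrap(~phenotype, scales = "free_y") +
    ggplot2::labs(x = "Severity score group", y = "Mean (error bars: SD)") +
    ggplot2::theme_minimal()
}
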