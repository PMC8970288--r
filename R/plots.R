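#' Plot per-cell shell densities by cell type
#'
#' Dot plot of individual cell densities per type and marker, the per-type
#' spread behind the model's mean estimates.
#'
#' @param records density tibble from [compute_densities()].
#' @return A ggplot object.
#' @export
plot_densities <- function(records) {
  records <- dplyr::filter(tibble::as_tibble(records), !is.na(.data$cell_type))
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$cell_type, y = .data$density_per_1000um3)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, linewidth = 0.3, colour = "red") +
    ggplot2::facet_wrap(~marker, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "varicosities per 1,000 µm³ of shell") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Forest plot of posterior density ratios
#'
#' Median and 95% credible interval per contrast and marker on a log axis;
#' the dashed line at 1 marks equal densities.
#'
#' @param object an `nb_glmm` fit.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.nb_glmm <- function(object, ...) {
  ratios <- density_ratios(object)
  ratios$contrast <- paste(ratios$type_a, "vs", ratios$type_b)
  ggplot2::ggplot(ratios, ggplot2::aes(x = .data$median, y = .data$contrast)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~marker, ncol = 1) +
    ggplot2::labs(x = "density ratio (posterior median, 95% CrI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Posterior mean densities with credible intervals
#'
#' @param fit an `nb_glmm` fit.
#' @return A ggplot object.
#' @export
plot_mean_densities <- function(fit) {
  d <- mean_densities(fit)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cell_type, y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi)) +
    ggplot2::facet_wrap(~marker, scales = "free_y") +
    ggplot2::labs(x = NULL,
                  y = "mean density (per 1,000 µm³, posterior median, 95% CrI)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
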