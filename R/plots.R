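#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a per-gene copy-number profile
#'
#' Genes along the x axis, log2(cn + pseudocount) on the y axis, colored
#' by gain/loss call when present; dashed lines mark the diploid and
#' single-copy baselines.
#'
#' @param profile Profile from [to_copy_number()] /
#'   [call_gain_loss()].
#' @param pseudocount Added before log2 (default 0.01).
#' @return A ggplot object.
#' @export
plot_cn_profile <- function(profile, pseudocount = 0.01) {
  profile$index <- seq_len(nrow(profile))
  profile$log2_cn <- log2(profile$cn + pseudocount)
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = index, y = log2_cn)) +
    ggplot2::geom_hline(yintercept = log2(c(1, 2)), linetype = "dashed",
                        color = "grey60") +
    ggplot2::labs(x = "gene", y = "log2 copy number") +
    ggplot2::theme_minimal()
  if ("call" %in% names(profile)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = call), size = 1) +
      ggplot2::scale_color_manual(
        values = c(gain = "red", neutral = "grey40", loss = "forestgreen")
      )
  } else {
    p <- p + ggplot2::geom_point(size = 1, color = "grey40")
  }
  p
}

#' Plot a substitution spectrum
#'
#' @param spectrum Tibble from [substitution_spectrum()].
#' @return A ggplot bar chart of class percentages.
#' @export
plot_spectrum <- function(spectrum) {
  spectrum$class <- factor(spectrum$class, levels = spectrum$class)
  ggplot2::ggplot(spectrum,
                  ggplot2::aes(x = class, y = percentage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of substitutions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Scatter + regression line for a plasma ratio fit
#'
#' @param object A `plasma_fit`.
#' @param ... Unused.
#' @return A ggplot object: ratio vs log10 load with the fitted line and
#'   the Pearson r annotated.
#' @method autoplot plasma_fit
#' @export
autoplot.plasma_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = log10_load, y = ratio)) +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         color = "red") +
    ggplot2::annotate(
      "text", x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
      label = sprintf("r = %.3f, y = %.2f x %+.2f",
                      object$pearson_r, object$slope, object$intercept)
    ) +
    ggplot2::labs(x = "log10 EBV DNA load (copies/ml)",
                  y = "CCND1/CDKN2A ratio") +
    ggplot2::theme_minimal()
}
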