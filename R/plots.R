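#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Manhattan plot of a genome scan
#'
#' @param object A [snp_scan()] tibble.
#' @param statistic Which p-value column to draw (`"ej"` or `"epj"`).
#' @param threshold Optional genome-wide significance level to draw as a
#'   horizontal line (on the p scale, e.g. `bonferroni_threshold(0.05, m)`).
#' @param ... Unused.
#' @return A ggplot object: `-log10(p)` against cumulative position in Mb,
#'   coloured by alternating chromosome.
#' @export
autoplot.snp_scan <- function(object, statistic = c("ej", "epj"),
                              threshold = NULL, ...) {
  statistic <- match.arg(statistic)
  pcol <- paste0("pvalue_", statistic)
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df[[pcol]]), , drop = FALSE]
  offs <- df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(span = max(.data$pos_mb), .groups = "drop") |>
    dplyr::mutate(offset = cumsum(dplyr::lag(.data$span + 5, default = 0)))
  df <- dplyr::left_join(df, offs, by = "chrom") |>
    dplyr::mutate(x = .data$pos_mb + .data$offset,
                  y = -log10(.data[[pcol]]),
                  parity = factor(as.integer(factor(.data$chrom)) %% 2))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                         colour = .data$parity)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("grey35", "steelblue4")) +
    ggplot2::labs(x = "position (Mb, cumulative)",
                  y = expression(-log[10](italic(p))),
                  title = paste0("Genome scan (SNP_", statistic, ")")) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(threshold),
                                   linetype = 2, colour = "red")
  }
  gg
}

#' QQ plot of a plasmode run
#'
#' Observed against expected order statistics of `-log10(p)`, with the
#' pointwise 95% envelope from the uniform reference replicates.
#'
#' @param object A [run_plasmode()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plasmode_result <- function(object, ...) {
  qq <- tidyr::pivot_longer(object$qq, dplyr::starts_with("observed_"),
                            names_to = "statistic", values_to = "observed",
                            names_prefix = "observed_")
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$expected)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$envelope_lower,
                                      ymax = .data$envelope_upper),
                         fill = "grey85") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed,
                                    colour = .data$statistic)) +
    ggplot2::labs(x = expression(Expected~-log[10](italic(p))),
                  y = expression(Observed~-log[10](italic(p))),
                  colour = "statistic",
                  title = paste0("Plasmode QQ (", object$config$scenario, ")")) +
    ggplot2::theme_minimal()
}
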