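#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   facet_wrap labs theme_minimal scale_x_continuous
#' @export
ggplot2::autoplot

#' Plot mean true / putative false positives across the VAF ladder
#'
#' The benchmarking view: one line per depth, mean true positives (and
#' putative false positives) against the spiked allele frequency.
#'
#' @param object A `umispike_eval_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.umispike_eval_summary <- function(object, ...) {
  df <- tidy(object) |>
    mutate(metric = dplyr::recode(.data$metric,
                                  mean_tp = "Mean true positives",
                                  mean_fp = "Mean putative false positives"),
           depth = factor(.data$depth))
  ggplot(df, aes(x = .data$vaf, y = .data$value, colour = .data$depth,
                 group = .data$depth)) +
    geom_line() + geom_point() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "Spiked variant allele frequency", y = NULL,
         colour = "Depth (x)") +
    theme_minimal()
}

#' UpSet-style bar chart of exclusive caller intersections
#'
#' @param object A `umispike_intersections`.
#' @param ... Unused.
#' @return A ggplot object: exclusive counts per caller subset, largest
#'   first; single-point bars are variants called by exactly one caller.
#' @export
autoplot.umispike_intersections <- function(object, ...) {
  df <- object$table |>
    arrange(dplyr::desc(.data$count)) |>
    mutate(callers = factor(.data$callers, levels = .data$callers))
  ggplot(df, aes(x = .data$callers, y = .data$count)) +
    geom_col() +
    labs(x = "Caller subset (exclusive)", y = "Variants",
         title = sprintf("Union of %d variants", object$union_size)) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot empirical against intended VAF per spiked dataset
#'
#' @param per_locus Tibble from [pileup_alt_fraction()] with an added
#'   `tvaf` column (intended level).
#' @return A ggplot object comparing per-locus empirical VAFs with the
#'   intended level.
#' @export
plot_vaf_recovery <- function(per_locus) {
  assert_columns(per_locus, c("vaf", "tvaf"), "per_locus")
  ggplot(per_locus, aes(x = factor(.data$tvaf), y = .data$vaf)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$tvaf),
                        data = distinct(per_locus, .data$tvaf),
                        linetype = "dashed", colour = "red") +
    labs(x = "Intended VAF", y = "Empirical per-locus VAF") +
    theme_minimal()
}
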