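#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an evaluation summary
#'
#' @param x A `umispike_eval_summary` from [summarize_replicates()].
#' @param ... Unused.
#' @return A long tibble: `depth`, `vaf`, `metric` (`mean_tp` / `mean_fp`),
#'   `value`, `n_replicates`.
#' @export
tidy.umispike_eval_summary <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(c("mean_tp", "mean_fp"),
                        names_to = "metric", values_to = "value")
}

#' Tidy an intersection table
#'
#' @param x A `umispike_intersections`.
#' @param ... Unused.
#' @return The exclusive-count tibble with the private fractions joined on
#'   single-caller rows.
#' @export
tidy.umispike_intersections <- function(x, ...) {
  x$table |>
    left_join(rename(x$private, callers = "caller"), by = "callers")
}

#' One-row summary of a pipeline run
#'
#' @param x A `umispike_run` from [run_all()].
#' @param ... Unused.
#' @return A one-row tibble: datasets, panel size, total calls, total TP,
#'   total putative FP, and the overall sensitivity across datasets.
#' @export
glance.umispike_run <- function(x, ...) {
  tibble(
    n_datasets = nrow(x$per_dataset),
    panel_size = nrow(x$panel),
    total_calls = sum(x$per_dataset$total),
    total_tp = sum(x$per_dataset$tp),
    total_putative_fp = sum(x$per_dataset$putative_fp),
    mean_sensitivity = mean(x$per_dataset$tp / nrow(x$panel))
  )
}

#' Glance at an evaluation tibble
#'
#' @param x A `umispike_eval` from [evaluate_datasets()].
#' @param ... Unused.
#' @return One-row tibble with dataset count and TP/FP totals.
#' @export
glance.umispike_eval <- function(x, ...) {
  tibble(n_datasets = nrow(x), total_calls = sum(x$total),
         total_tp = sum(x$tp), total_putative_fp = sum(x$putative_fp))
}
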