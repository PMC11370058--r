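#' Match a call set against a spike-in truth set
#'
#' A call is a true positive iff its (contig, pos, ref, alt) key exactly
#' matches a truth record; each truth record can be matched at most once.
#' Everything else is a putative false positive — in spiked-in data built on
#' a real cfDNA background true negatives are unknowable, so specificity is
#' inferred from total calls minus true positives.
#'
#' @param calls Filtered call tibble.
#' @param truth Truth tibble (`contig`, `pos`, `ref`, `alt`).
#' @return `calls` with a logical `tp` column; attribute `"summary"` is a
#'   one-row tibble (`total`, `tp`, `putative_fp`).
#' @export
match_truth <- function(calls, truth) {
  if (is.null(truth) || nrow(truth) == 0) {
    abort("truth set is empty", class = "umispike_config_error")
  }
  key <- variant_key(calls)
  tkey <- variant_key(truth)
  tp <- key %in% tkey & !duplicated(key)
  out <- calls
  out$tp <- tp
  attr(out, "summary") <- tibble(total = nrow(out), tp = sum(tp),
                                 putative_fp = nrow(out) - sum(tp))
  out
}

#' Summarise true/false positives over replicates
#'
#' @param per_dataset Tibble with one row per dataset: `depth`, `vaf`,
#'   `replicate`, `tp`, `putative_fp` (and optionally `total`).
#' @return A tibble of class `umispike_eval_summary` with per-(depth, vaf)
#'   arithmetic means `mean_tp`, `mean_fp` and the replicate count.
#' @export
summarize_replicates <- function(per_dataset) {
  assert_columns(per_dataset, c("depth", "vaf", "tp", "putative_fp"),
                 "per_dataset")
  out <- per_dataset |>
    group_by(.data$depth, .data$vaf) |>
    summarise(mean_tp = mean(.data$tp), mean_fp = mean(.data$putative_fp),
              n_replicates = n(), .groups = "drop") |>
    arrange(.data$depth, .data$vaf)
  class(out) <- c("umispike_eval_summary", class(out))
  out
}

#' Fraction of calls annotated in the COSMIC-style database
#'
#' For data without a spike-in truth set, the percentage of filtered calls
#' that are known somatic recurrences gives an insight into the plausibility
#' of a call set; the total call count is reported alongside because a high
#' percentage of very few calls means something different from the same
#' percentage of thousands.
#'
#' @param calls Call tibble with a logical `cosmic` column
#'   ([cosmic_annotate()]).
#' @return One-row tibble (`percent` — to 1 decimal place, `n_flagged`,
#'   `total`). With zero calls the fraction is undefined and reported as
#'   `NA` with a warning, never as zero.
#' @export
cosmic_fraction <- function(calls) {
  assert_columns(calls, "cosmic", "calls")
  total <- nrow(calls)
  if (total == 0) {
    warn("no calls: COSMIC fraction is undefined")
    return(tibble(percent = NA_real_, n_flagged = 0L, total = 0L))
  }
  flagged <- sum(calls$cosmic, na.rm = TRUE)
  tibble(percent = round(100 * flagged / total, 1),
         n_flagged = as.integer(flagged), total = as.integer(total))
}

#' Exclusive intersections of multiple call sets
#'
#' For every non-empty subset S of callers, counts the variant keys present
#' in exactly the callers of S (the exclusive counts an UpSet plot draws).
#' A caller's private fraction is the share of the union it called alone —
#' a high private fraction suggests false-positive discovery.
#'
#' @param callsets Named list (>= 2 elements) of character vectors of
#'   variant keys, or of call tibbles (keys are then built from
#'   contig/pos/ref/alt).
#' @return A list of class `umispike_intersections`: `table` (tibble
#'   `callers`, `degree`, `count`, exclusive counts summing to the union
#'   size), `private` (tibble `caller`, `exclusive`, `private_pct` to 1
#'   decimal place), `union_size`.
#' @examples
#' intersections(list(A = c("k1", "k2"), B = c("k2", "k3")))
#' @export
intersections <- function(callsets) {
  if (length(callsets) < 2 || is.null(names(callsets)) ||
      any(!nzchar(names(callsets)))) {
    abort("callsets must be a named list of at least 2 call sets")
  }
  keys <- map(callsets, function(x) {
    if (is.data.frame(x)) unique(variant_key(x)) else unique(as.character(x))
  })
  callers <- names(keys)
  universe <- unique(unlist(keys, use.names = FALSE))
  membership <- vapply(keys, function(k) universe %in% k,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1,
                                                  dimnames = list(NULL, callers))
  pattern <- apply(membership, 1, function(row)
    paste(callers[row], collapse = "&"))
  tab <- tibble(callers = pattern) |>
    count(.data$callers, name = "count") |>
    mutate(degree = lengths(strsplit(.data$callers, "&", fixed = TRUE))) |>
    select("callers", "degree", "count") |>
    arrange(.data$degree, .data$callers)
  private <- tibble(
    caller = callers,
    exclusive = map_int(callers, function(cl) {
      i <- match(cl, tab$callers)
      if (is.na(i)) 0L else tab$count[i]
    }),
    private_pct = NA_real_)
  private$private_pct <- round(100 * private$exclusive /
                                 max(length(universe), 1L), 1)
  structure(list(table = tab, private = private,
                 union_size = length(universe)),
            class = "umispike_intersections")
}

#' @export
print.umispike_intersections <- function(x, ...) {
  cat(sprintf("<umispike_intersections> %d caller set(s), union of %d variants\n",
              nrow(x$private), x$union_size))
  print(x$table)
  invisible(x)
}

#' Score every dataset of a spike-in run with one caller
#'
#' Convenience wrapper around the per-dataset loop: call variants on each
#' mixed read set, filter, match against the dataset's truth, and collect a
#' per-dataset report ready for [summarize_replicates()].
#'
#' @param datasets A `umispike_datasets` object from [generate_datasets()].
#' @param ref Reference object.
#' @param dbsnp,cosmic Annotation databases (optional).
#' @param config A [filter_config()].
#' @param caller A function `(fragments, ref) -> call tibble`; defaults to
#'   the built-in naive pileup caller.
#' @return A tibble of class `umispike_eval` with one row per dataset:
#'   `dataset_id`, `depth`, `vaf`, `replicate`, `total`, `tp`,
#'   `putative_fp`.
#' @export
evaluate_datasets <- function(datasets, ref, dbsnp = NULL, cosmic = NULL,
                              config = filter_config(),
                              caller = call_pileup) {
  stopifnot(inherits(datasets, "umispike_datasets"))
  rows <- map(names(datasets$datasets), function(id) {
    frags <- datasets$datasets[[id]]
    truth <- datasets$truth[[id]]
    calls <- caller(frags, ref)
    filtered <- suppressMessages(
      filter_calls(calls, dbsnp = dbsnp, cosmic = cosmic, config = config))
    scored <- match_truth(filtered, truth)
    s <- attr(scored, "summary")
    meta <- datasets$manifest[datasets$manifest$dataset_id == id, ]
    tibble(dataset_id = id, depth = meta$depth, vaf = meta$vaf,
           replicate = meta$replicate, total = s$total, tp = s$tp,
           putative_fp = s$putative_fp)
  })
  out <- bind_rows(rows)
  class(out) <- c("umispike_eval", class(out))
  out
}
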