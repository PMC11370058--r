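#' Filtering configuration
#'
#' Defaults mirror standard conservative practice for targeted ctDNA panels:
#' discard calls with read depth or variant quality below 50 (QUAL 50
#' corresponds to a 99.999 percent probability the call is correct, see
#' [qual_to_probability()]); discard variants recorded in a dbSNP-style
#' database at >= 5 percent frequency in all recorded populations; annotate
#' against a COSMIC-style database pre-filtered to recurrence sample counts
#' of at least 3.
#'
#' @param min_depth Minimum read depth (DP) to retain a call.
#' @param min_qual Minimum variant quality (QUAL, PHRED-scaled).
#' @param qual_filter Whether quality filtering is enabled at all. Even when
#'   enabled it auto-disables (with a notice) on call sets whose QUAL column
#'   is uniformly missing, as for callers that do not report QUAL.
#' @param dbsnp_af_cutoff Population allele-frequency cutoff for dbSNP
#'   exclusion.
#' @param cosmic_min_samples Minimum COSMIC sample count for a database
#'   entry to be usable for annotation.
#' @return A list of class `umispike_filter_config`.
#' @export
filter_config <- function(min_depth = 50, min_qual = 50, qual_filter = TRUE,
                          dbsnp_af_cutoff = 0.05, cosmic_min_samples = 3) {
  stopifnot(min_depth >= 0, min_qual >= 0, dbsnp_af_cutoff >= 0,
            cosmic_min_samples >= 0)
  structure(list(min_depth = min_depth, min_qual = min_qual,
                 qual_filter = isTRUE(qual_filter),
                 dbsnp_af_cutoff = dbsnp_af_cutoff,
                 cosmic_min_samples = cosmic_min_samples),
            class = "umispike_filter_config")
}

#' Convert a PHRED-scaled variant quality to a correctness probability
#'
#' `1 - 10^(-qual/10)`: QUAL 50 corresponds to a 99.999 percent probability
#' that the call is correct, which is what the default quality threshold
#' enforces.
#'
#' @param qual PHRED-scaled quality, >= 0 (vectorised).
#' @return Probability in \[0, 1\].
#' @examples
#' qual_to_probability(50)  # 0.99999
#' @export
qual_to_probability <- function(qual) {
  if (any(qual < 0, na.rm = TRUE)) {
    abort("qual must be >= 0", class = "umispike_domain_error")
  }
  1 - 10^(-qual / 10)
}

#' Depth and quality filtering of variant calls
#'
#' Retains records with `DP >= min_depth` and, when quality filtering is
#' active, `QUAL >= min_qual`. When the QUAL column is uniformly missing the
#' quality criterion auto-disables with a logged notice (callers that do not
#' report QUAL are filtered on depth only). Records with a missing DP fail
#' the depth criterion (conservative) and are noted.
#'
#' @param records Call tibble with `dp` and `qual` columns (`NA` allowed).
#' @param config A [filter_config()].
#' @return The retained records, input order preserved.
#' @export
depth_quality_filter <- function(records, config = filter_config()) {
  if (nrow(records) == 0) return(records)
  dp <- if ("dp" %in% names(records)) records$dp else rep(NA_integer_, nrow(records))
  qual <- if ("qual" %in% names(records)) records$qual else rep(NA_real_, nrow(records))
  if (anyNA(dp)) {
    inform(sprintf("%d record(s) without a parseable DP fail the depth filter",
                   sum(is.na(dp))))
  }
  keep <- !is.na(dp) & dp >= config$min_depth
  use_qual <- config$qual_filter
  if (use_qual && all(is.na(qual))) {
    inform("QUAL uniformly missing: quality filtering disabled for this call set")
    use_qual <- FALSE
  }
  if (use_qual) keep <- keep & !is.na(qual) & qual >= config$min_qual
  records[keep, , drop = FALSE]
}

#' Exclude calls matching common database polymorphisms
#'
#' Discards a record iff it exactly matches a dbSNP-style entry
#' (contig, pos, ref, alt) whose allele frequency is at or above `cutoff`
#' in *all* populations recorded for that entry; a record common in one
#' population but rare in another is retained.
#'
#' @param records Call tibble.
#' @param db A dbSNP-kind annotation db (with `af` list-column).
#' @param cutoff Frequency cutoff (default 0.05).
#' @return Retained records, order preserved.
#' @export
dbsnp_exclude <- function(records, db, cutoff = 0.05) {
  stopifnot(identical(db_kind(db), "dbsnp"))
  if (nrow(records) == 0) return(records)
  common <- vapply(db$af, function(a) length(a) > 0 && all(a >= cutoff),
                   logical(1))
  bad_keys <- variant_key(db[common, , drop = FALSE])
  records[!variant_key(records) %in% bad_keys, , drop = FALSE]
}

#' Annotate calls against a COSMIC-style database
#'
#' The database is first pre-filtered to entries with sample count >=
#' `min_samples`; each record is then flagged iff it exactly matches a
#' surviving entry. Annotation never drops records.
#'
#' @param records Call tibble.
#' @param db A cosmic-kind annotation db (with `cnt` column).
#' @param min_samples Minimum sample count (default 3).
#' @return `records` with logical `cosmic` and integer `cosmic_cnt` columns.
#' @export
cosmic_annotate <- function(records, db, min_samples = 3) {
  stopifnot(identical(db_kind(db), "cosmic"))
  usable <- as_tibble(db)[db$cnt >= min_samples, , drop = FALSE]
  idx <- match(variant_key(records), variant_key(usable))
  records$cosmic <- !is.na(idx)
  records$cosmic_cnt <- usable$cnt[idx]
  records
}

variant_key <- function(df) {
  if (nrow(df) == 0) return(character(0))
  paste(df$contig, df$pos, df$ref, df$alt, sep = ":")
}

#' Run the full filtering and annotation pipeline on a call set
#'
#' Stages, in order: depth/quality filtering, dbSNP exclusion, COSMIC
#' annotation. When `bypass_depth_quality = NA` (the default) the first
#' stage is bypassed automatically — with a logged notice — iff the DP field
#' is unparseable on every record, the situation of UMI-aware caller VCFs
#' whose non-standard fields defeat depth/quality tools; the bypass is
#' recorded in the stage log.
#'
#' @param records Call tibble (e.g. from [read_vcf()]).
#' @param dbsnp,cosmic Annotation databases (either may be `NULL` to skip
#'   that stage).
#' @param config A [filter_config()].
#' @param bypass_depth_quality `TRUE`, `FALSE`, or `NA` for auto-detection.
#' @return The filtered, annotated tibble; attribute `"stage_log"` is a
#'   tibble (`stage`, `n_in`, `n_retained`, `n_discarded`, `note`).
#' @export
filter_calls <- function(records, dbsnp = NULL, cosmic = NULL,
                         config = filter_config(),
                         bypass_depth_quality = NA) {
  log <- list()
  push <- function(stage, n_in, n_out, note = "") {
    log[[length(log) + 1L]] <<- tibble(stage = stage, n_in = n_in,
                                       n_retained = n_out,
                                       n_discarded = n_in - n_out, note = note)
  }
  dp_all_missing <- !"dp" %in% names(records) || all(is.na(records$dp))
  bypass <- if (is.na(bypass_depth_quality)) dp_all_missing
            else isTRUE(bypass_depth_quality)
  out <- records
  if (bypass) {
    if (nrow(records) > 0) {
      inform("depth/quality filtering bypassed: DP unparseable on every record (UMI-aware caller dialect)")
    }
    push("depth_quality", nrow(out), nrow(out), "bypassed")
  } else {
    n0 <- nrow(out)
    out <- depth_quality_filter(out, config)
    push("depth_quality", n0, nrow(out))
  }
  if (!is.null(dbsnp)) {
    n0 <- nrow(out)
    out <- dbsnp_exclude(out, dbsnp, config$dbsnp_af_cutoff)
    push("dbsnp_exclude", n0, nrow(out))
  }
  if (!is.null(cosmic)) {
    n0 <- nrow(out)
    out <- cosmic_annotate(out, cosmic, config$cosmic_min_samples)
    push("cosmic_annotate", n0, nrow(out), "annotation only")
  }
  attr(out, "stage_log") <- bind_rows(log)
  out
}
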