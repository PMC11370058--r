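#' Encode UMI-assigned reads in one of the three standard dialects
#'
#' Downstream UMI-aware pipelines consume synthetic UMIs in different
#' shapes; all three encode the identical (read, UMI) map:
#'
#' * `three_file` — an R1 / UMI / R2 FASTQ triple with matching read names
#'   and order; the UMI records carry constant Q37 qualities.
#' * `prepended` — the UMI (and its Q37 qualities) concatenated 5' of the
#'   R1 sequence; R2 unchanged.
#' * `rx_tag` — a coordinate-sorted SAM whose records carry `RX:Z:<umi>`.
#'
#' @param fragments Fragment tibble with UMIs assigned ([assign_umis()]).
#' @param dialect One of `"three_file"`, `"prepended"`, `"rx_tag"`.
#' @param prefix Output path prefix (files get suffixes per dialect).
#' @param ref Reference, required for the `rx_tag` dialect.
#' @return Named character vector of written paths, invisibly classed so it
#'   can be fed to [decode_umi()].
#' @export
encode_umi <- function(fragments, dialect = c("three_file", "prepended", "rx_tag"),
                       prefix, ref = NULL) {
  dialect <- match.arg(dialect)
  assert_columns(fragments, c("id", "r1_seq", "r1_qual", "r2_seq", "r2_qual",
                              "umi", "umi_qual"), "fragments")
  if (anyNA(fragments$umi)) {
    abort("fragments carry unassigned UMIs; run assign_umis() first",
          class = "umispike_integrity_error")
  }
  paths <- switch(dialect,
    three_file = {
      p <- c(r1 = paste0(prefix, "_R1.fastq"),
             umi = paste0(prefix, "_UMI.fastq"),
             r2 = paste0(prefix, "_R2.fastq"))
      write_fastq(tibble(id = fragments$id, seq = fragments$r1_seq,
                         qual = fragments$r1_qual), p[["r1"]])
      write_fastq(tibble(id = fragments$id, seq = fragments$umi,
                         qual = fragments$umi_qual), p[["umi"]])
      write_fastq(tibble(id = fragments$id, seq = fragments$r2_seq,
                         qual = fragments$r2_qual), p[["r2"]])
      p
    },
    prepended = {
      p <- c(r1 = paste0(prefix, "_R1.fastq"),
             r2 = paste0(prefix, "_R2.fastq"))
      write_fastq(tibble(id = fragments$id,
                         seq = paste0(fragments$umi, fragments$r1_seq),
                         qual = paste0(fragments$umi_qual, fragments$r1_qual)),
                  p[["r1"]])
      write_fastq(tibble(id = fragments$id, seq = fragments$r2_seq,
                         qual = fragments$r2_qual), p[["r2"]])
      p
    },
    rx_tag = {
      if (is.null(ref)) abort("ref is required for the rx_tag dialect")
      p <- c(sam = paste0(prefix, ".sam"))
      write_sam(fragments, p[["sam"]], ref)
      p
    })
  structure(paths, dialect = dialect, umi_length = nchar(fragments$umi[1]))
}

#' Decode a (read, UMI) map back from any encoding dialect
#'
#' @param paths The path vector returned by [encode_umi()] (or an equivalent
#'   named vector; the dialect is taken from its attribute or `dialect`).
#' @param dialect Dialect override when `paths` lacks the attribute.
#' @param umi_length UMI length for the `prepended` dialect (default 9).
#' @return Tibble with `id` and `umi`, one row per read pair.
#' @export
decode_umi <- function(paths, dialect = NULL, umi_length = NULL) {
  dialect <- dialect %||% attr(paths, "dialect", exact = TRUE)
  umi_length <- umi_length %||% attr(paths, "umi_length", exact = TRUE) %||% 9L
  if (is.null(dialect)) abort("dialect must be supplied")
  switch(dialect,
    three_file = {
      r1 <- read_fastq(paths[["r1"]])
      um <- read_fastq(paths[["umi"]])
      if (!identical(r1$id, um$id)) {
        abort("R1 and UMI FASTQ read names disagree",
              class = "umispike_integrity_error")
      }
      tibble(id = r1$id, umi = um$seq)
    },
    prepended = {
      r1 <- read_fastq(paths[["r1"]])
      tibble(id = r1$id, umi = substr(r1$seq, 1L, umi_length))
    },
    rx_tag = {
      sam <- read_sam(paths[["sam"]])
      first <- sam[bitwAnd(sam$flag, 64L) > 0L, ]
      if (anyNA(first$rx)) {
        abort("SAM records missing RX tags", class = "umispike_integrity_error")
      }
      tibble(id = first$qname, umi = first$rx) |>
        distinct()
    },
    abort(sprintf("unknown dialect '%s'", dialect)))
}
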