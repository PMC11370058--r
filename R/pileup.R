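#' Per-locus alternate-allele fractions by brute-force pileup
#'
#' Walks every read individually — no shared machinery with the vectorised
#' caller pileup — extracting the base each mate reports at each requested
#' locus, and tallies alternate-supporting over total covering read bases.
#' Deliberately simple and loop-based so it can serve as an independent
#' oracle for the mixing machinery.
#'
#' @param fragments Fragment tibble.
#' @param ref Reference object.
#' @param loci Tibble with `contig`, `pos` (1-based), `ref`, `alt`.
#' @return `loci` with added `depth`, `alt_count` and `vaf`
#'   (`alt_count / depth`; `NA` where depth is 0).
#' @export
pileup_alt_fraction <- function(fragments, ref, loci) {
  rl <- ref$read_length
  depth <- integer(nrow(loci))
  alt_n <- integer(nrow(loci))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(nrow(loci))) {
    p0 <- loci$pos[i] - 1L
    alt <- loci$alt[i]
    f <- fragments[fragments$contig == loci$contig[i] &
                     fragments$frag_start <= p0 &
                     fragments$frag_end > p0, , drop = FALSE]
    for (j in seq_len(nrow(f))) {
      off1 <- p0 - f$frag_start[j] + 1L
      if (off1 >= 1L && off1 <= rl) {
        b <- substr(f$r1_seq[j], off1, off1)
        depth[i] <- depth[i] + 1L
        if (b == alt) alt_n[i] <- alt_n[i] + 1L
      }
      off2 <- f$frag_end[j] - p0
      if (off2 >= 1L && off2 <= rl) {
        b <- substr(f$r2_seq[j], off2, off2)
        depth[i] <- depth[i] + 1L
        if (b == comp[[alt]]) alt_n[i] <- alt_n[i] + 1L
      }
    }
  }
  loci |>
    mutate(depth = depth, alt_count = alt_n,
           vaf = ifelse(depth > 0, alt_n / depth, NA_real_))
}

# Vectorised base-level pileup over all covered positions of a fragment set.
# Returns, per (contig, pos0, base), the number of supporting read bases,
# plus total depth per position.
pileup_counts <- function(fragments, ref) {
  rl <- ref$read_length
  res <- list()
  for (ct in unique(fragments$contig)) {
    f <- fragments[fragments$contig == ct, ]
    if (nrow(f) == 0) next
    # forward-strand bases of both mates
    seqs <- c(f$r1_seq, revcomp(f$r2_seq))
    starts <- c(f$frag_start, f$frag_end - rl)
    chars <- strsplit(paste(seqs, collapse = ""), "")[[1]]
    pos0 <- rep(starts, each = rl) + rep.int(seq_len(rl) - 1L, length(starts))
    tb <- tibble(pos0 = pos0, base = chars) |>
      count(.data$pos0, .data$base, name = "n")
    tb$contig <- ct
    res[[ct]] <- tb
  }
  counts <- bind_rows(res)
  depth <- counts |>
    group_by(.data$contig, .data$pos0) |>
    summarise(depth = sum(.data$n), .groups = "drop")
  left_join(counts, depth, by = c("contig", "pos0"))
}

#' A deliberately naive pileup variant caller
#'
#' Calls an SNV wherever some non-reference base is supported by at least
#' `min_alt` reads and at least fraction `min_frac` of the read bases at the
#' position. This caller exists to exercise the downstream filtering and
#' evaluation stages end-to-end without any external variant caller; it is
#' used in tests and demonstrations, not intended as a production caller.
#' QUAL is the PHRED-scaled binomial tail probability of seeing that many
#' alternate bases from sequencing error alone (capped at 999).
#'
#' @param fragments Fragment tibble (the mixed, spiked read set).
#' @param ref Reference object.
#' @param min_alt Minimum alternate-supporting read bases (default 3).
#' @param min_frac Minimum alternate fraction (default 0.004).
#' @param error_rate Assumed per-base error rate for the QUAL model.
#' @return Call tibble: `contig`, `pos` (1-based), `ref`, `alt`, `dp`,
#'   `alt_count`, `qual`.
#' @export
call_pileup <- function(fragments, ref, min_alt = 3, min_frac = 0.004,
                        error_rate = 0.001) {
  counts <- pileup_counts(fragments, ref)
  if (nrow(counts) == 0) {
    return(tibble(contig = character(), pos = integer(), ref = character(),
                  alt = character(), dp = integer(), alt_count = integer(),
                  qual = double()))
  }
  counts$refbase <- substring(ref$contigs[counts$contig],
                              counts$pos0 + 1L, counts$pos0 + 1L)
  cand <- counts |>
    filter(.data$base != .data$refbase, .data$base %in% DNA_BASES,
           .data$n >= min_alt, .data$n / .data$depth >= min_frac)
  # keep the best-supported alternate per position
  cand <- cand |>
    group_by(.data$contig, .data$pos0) |>
    arrange(dplyr::desc(.data$n), .data$base, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup()
  qual <- -10 * log10(pmax(
    pbinom(cand$n - 1L, cand$depth, error_rate, lower.tail = FALSE),
    1e-100))
  tibble(contig = cand$contig, pos = as.integer(cand$pos0 + 1L),
         ref = cand$refbase, alt = cand$base,
         dp = as.integer(cand$depth), alt_count = as.integer(cand$n),
         qual = pmin(round(qual, 1), 999)) |>
    arrange(.data$contig, .data$pos)
}
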