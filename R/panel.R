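#' Draw a random SNV panel over the reference targets
#'
#' Samples unique target loci and assigns each a single-nucleotide alternate
#' allele differing from the reference base, standing in for a curated panel
#' of known somatic SNVs (the scale of a COSMIC-derived spike-in panel). The
#' default of 303 variants matches the spike-in truth-set size used
#' throughout this package's evaluation defaults.
#'
#' @param ref A [make_reference()] object.
#' @param n_variants Number of SNVs (default 303). Must not exceed the total
#'   number of target bases.
#' @param seed Integer seed.
#' @return A tibble with columns `id`, `contig`, `pos` (1-based, VCF
#'   convention), `ref`, `alt` — one row per SNV, loci unique and inside
#'   target intervals, `ref` equal to the reference base.
#' @examples
#' ref <- make_reference(1, 4, 2000, seed = 1)
#' panel <- make_variant_panel(ref, 303, seed = 3)
#' @export
make_variant_panel <- function(ref, n_variants = 303, seed = 1) {
  stopifnot(inherits(ref, "umispike_reference"))
  tb <- target_bases(ref)
  if (n_variants > tb) {
    abort(sprintf("panel of %d variants exceeds the %d available target bases",
                  n_variants, tb), class = "umispike_capacity_error")
  }
  tg <- ref$targets
  offsets <- c(0L, cumsum(tg$end - tg$start))
  with_seed(seed, {
    flat <- sample.int(tb, n_variants)          # unique flat target offsets
    tgt <- findInterval(flat - 1L, offsets, left.open = FALSE,
                        rightmost.closed = TRUE)
    tgt <- pmin(tgt, nrow(tg))
    pos0 <- tg$start[tgt] + (flat - 1L - offsets[tgt])
    contig <- tg$contig[tgt]
    ref_base <- substring(ref$contigs[contig], pos0 + 1L, pos0 + 1L)
    alt <- map_chr(ref_base, function(b) sample(setdiff(DNA_BASES, b), 1L))
    tibble(
      id = sprintf("snv%04d", seq_len(n_variants)),
      contig = contig,
      pos = as.integer(pos0 + 1L),
      ref = ref_base,
      alt = alt
    ) |>
      arrange(.data$contig, .data$pos)
  })
}

#' Build toy dbSNP- and COSMIC-style annotation databases
#'
#' Constructs two small annotation tables around a variant panel: a
#' dbSNP-style table of germline polymorphisms with population allele
#' frequencies straddling the conventional 5 percent common-variant cutoff,
#' and a COSMIC-style table with recurrence sample counts spanning 1..10.
#' Every panel locus is entered in the COSMIC table with a sample count of
#' at least `panel_min_count`, so truth variants survive the database
#' pre-filter used before annotation.
#'
#' @param panel A variant panel tibble (may have zero rows).
#' @param ref Reference used to invent decoy loci outside the panel.
#' @param seed Integer seed.
#' @param n_dbsnp,n_cosmic_decoys Number of dbSNP records and of COSMIC decoy
#'   records (in addition to the panel entries).
#' @param dbsnp_afs Population allele frequencies to cycle through for dbSNP
#'   records. Each record carries 1 or 2 population frequencies (the
#'   multi-population case exercises the "common in all populations" rule).
#' @param panel_min_count Minimum COSMIC sample count given to panel loci.
#' @return A list with elements `dbsnp` and `cosmic`, each a tibble of class
#'   `umispike_annotation_db` with attribute `kind`. `dbsnp` has an `af`
#'   list-column (one numeric frequency per population recorded); `cosmic`
#'   has an integer `cnt` column.
#' @export
make_annotation_dbs <- function(panel, ref, seed = 1, n_dbsnp = 40,
                                n_cosmic_decoys = 20,
                                dbsnp_afs = seq(0.01, 0.10, by = 0.01),
                                panel_min_count = 3) {
  stopifnot(inherits(ref, "umispike_reference"))
  with_seed(seed, {
    decoys <- decoy_loci(ref, n_dbsnp + n_cosmic_decoys, panel)
    db_loci <- decoys[seq_len(n_dbsnp), , drop = FALSE]
    afs <- rep(dbsnp_afs, length.out = n_dbsnp)
    two_pop <- seq_len(n_dbsnp) %% 5 == 0   # every 5th record multi-population
    dbsnp <- db_loci |>
      mutate(af = map2(afs, two_pop, function(a, two) {
        if (two) c(a, min(1, a + 0.02)) else a
      }))

    cos_decoys <- decoys[n_dbsnp + seq_len(n_cosmic_decoys), , drop = FALSE]
    cos_decoys$cnt <- as.integer(rep(1:10, length.out = n_cosmic_decoys))
    cosmic <- cos_decoys
    if (nrow(panel) > 0) {
      pan <- panel |>
        select("contig", "pos", "ref", "alt") |>
        mutate(cnt = as.integer(panel_min_count +
                                  rpois(nrow(panel), 2)))
      cosmic <- bind_rows(pan, cos_decoys) |>
        distinct(.data$contig, .data$pos, .data$ref, .data$alt,
                 .keep_all = TRUE)
    }
    list(
      dbsnp = new_annotation_db(dbsnp, "dbsnp"),
      cosmic = new_annotation_db(arrange(cosmic, .data$contig, .data$pos),
                                 "cosmic")
    )
  })
}

new_annotation_db <- function(df, kind) {
  structure(df, kind = kind,
            class = c("umispike_annotation_db", class(df)))
}

db_kind <- function(db) attr(db, "kind", exact = TRUE)

# Random SNV-like loci inside targets, avoiding panel loci.
decoy_loci <- function(ref, n, panel) {
  tg <- ref$targets
  taken <- paste(panel$contig, panel$pos)
  out <- list()
  got <- 0L
  while (got < n) {
    k <- (n - got) * 2L
    tgt <- sample.int(nrow(tg), k, replace = TRUE, prob = tg$end - tg$start)
    pos0 <- tg$start[tgt] +
      floor(runif(k) * (tg$end[tgt] - tg$start[tgt]))
    cand <- tibble(contig = tg$contig[tgt], pos = as.integer(pos0 + 1L))
    cand <- cand[!paste(cand$contig, cand$pos) %in% taken, , drop = FALSE]
    cand <- distinct(cand)
    out[[length(out) + 1L]] <- cand
    taken <- c(taken, paste(cand$contig, cand$pos))
    got <- got + nrow(cand)
  }
  loci <- head(bind_rows(out), n)
  ref_base <- substring(ref$contigs[loci$contig], loci$pos, loci$pos)
  loci$ref <- ref_base
  loci$alt <- map_chr(ref_base, function(b) sample(setdiff(DNA_BASES, b), 1L))
  loci
}
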