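#' Mint a random UMI string
#'
#' Draws a random string over {A, T, C, G} of the given length, rejection
#' resampling until it differs from every string in `existing`. Uniqueness is
#' only enforced against the supplied set (conventionally the UMIs already
#' minted within one duplicate set); collisions across duplicate sets are
#' allowed and biologically meaningful.
#'
#' @param existing Character vector of UMI strings to avoid.
#' @param length UMI length in bases (default 9).
#' @return A single UMI string not present in `existing`.
#' @examples
#' mint_umi()
#' @export
mint_umi <- function(existing = character(), length = 9) {
  if (base::length(existing) >= 4^length) {
    abort(sprintf("UMI alphabet exhausted: 4^%d strings already in use", length),
          class = "umispike_capacity_error")
  }
  repeat {
    u <- paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
    if (!u %in% existing) return(u)
  }
}

#' Assign synthetic UMI families within PCR-duplicate groups
#'
#' Partitions each duplicate group (reads sharing fragment start/end
#' coordinates and origin) into UMI families and attaches a random 9-mer UMI
#' at constant quality Q37 to every member, both mates of a pair sharing the
#' UMI. Two interpretations of Poisson family assignment are provided:
#'
#' * `mode = "label"` (default): each member independently draws an integer
#'   label from Poisson(`lam`); members of a group sharing a label form one
#'   family. This is the per-read reading of Poisson sampling.
#' * `mode = "carve"`: family sizes `max(1, Poisson(lam))` are cut
#'   sequentially off the group until it is exhausted.
#'
#' Either way every member belongs to exactly one family, and distinct
#' families within one duplicate group receive distinct UMI strings.
#'
#' @param fragments Fragment tibble (one row per read pair).
#' @param lam Poisson mean for family assignment (default 0.5). Must be > 0.
#' @param mode `"label"` or `"carve"` (see above).
#' @param seed Integer seed.
#' @param umi_length UMI length in bases (default 9).
#' @param umi_qual Constant PHRED quality of UMI bases (default 37).
#' @return The fragment tibble with `umi` and `umi_qual` columns filled.
#'   Attributes: `"umi_draws"` — the raw Poisson draws, for statistical
#'   checks; `"families"` — a tibble (`group_id`, `umi`, `size`, `origin`).
#' @examples
#' ref <- make_reference(1, 2, 600, seed = 1)
#' tmpl <- make_template(ref, 30, 3, seed = 7)
#' fam <- assign_umis(tmpl, lam = 0.5, seed = 5)
#' attr(fam, "families")
#' @export
assign_umis <- function(fragments, lam = 0.5, mode = c("label", "carve"),
                        seed = 1, umi_length = 9, umi_qual = 37) {
  mode <- match.arg(mode)
  if (!is.numeric(lam) || lam <= 0) {
    abort("lam must be > 0", class = "umispike_domain_error")
  }
  assert_columns(fragments, "group_id", "fragments")
  n <- nrow(fragments)
  if (n == 0) abort("fragments must be non-empty")
  with_seed(seed, {
    ord <- order(fragments$group_id)
    gid <- fragments$group_id[ord]
    if (mode == "label") {
      draws <- rpois(n, lam)          # one label per member, in sorted order
      fam_key <- paste(gid, draws, sep = ":")
    } else {
      draws <- integer(0)
      fam_key <- character(n)
      i <- 1L
      while (i <= n) {
        run_end <- i
        while (run_end < n && gid[run_end + 1L] == gid[i]) run_end <- run_end + 1L
        j <- i
        fam <- 0L
        while (j <= run_end) {
          d <- rpois(1L, lam)
          draws <- c(draws, d)
          sz <- max(1L, d)
          take <- min(sz, run_end - j + 1L)
          fam_key[j:(j + take - 1L)] <- paste(gid[i], fam, sep = ":")
          j <- j + take
          fam <- fam + 1L
        }
        i <- run_end + 1L
      }
    }
    # one UMI per family, distinct within each duplicate group
    fams <- tibble(group_id = gid, fam_key = fam_key)
    uf <- fams[!duplicated(fams$fam_key), ]
    uf$umi <- random_dna(nrow(uf), umi_length)
    repeat {
      dup <- duplicated(paste(uf$group_id, uf$umi))
      if (!any(dup)) break
      uf$umi[dup] <- random_dna(sum(dup), umi_length)
    }
    umi_by_key <- setNames(uf$umi, uf$fam_key)
    out <- fragments
    out$umi[ord] <- unname(umi_by_key[fam_key])
    out$umi_qual <- phred_string(umi_qual, umi_length)
    fam_tbl <- tibble(group_id = gid, umi = unname(umi_by_key[fam_key]),
                      origin = if ("origin" %in% names(fragments))
                        fragments$origin[ord] else NA_character_) |>
      count(.data$group_id, .data$umi, .data$origin, name = "size") |>
      select("group_id", "umi", "size", "origin")
    attr(out, "umi_draws") <- draws
    attr(out, "families") <- fam_tbl
    out
  })
}

#' Check that no UMI family mixes reference and alternate origins
#'
#' Duplicate groups are atomic under VAF mixing precisely so that a spiked
#' variant is carried by every member of its UMI families. This check
#' verifies the property on encoded output: no family (same fragment
#' coordinates, same UMI) may contain fragments of both origins.
#'
#' @param fragments Fragment tibble with `origin` and `umi` set.
#' @param strict If `TRUE`, violations raise an integrity error naming the
#'   offending family; otherwise they are returned for inspection.
#' @return A tibble of violating families (`contig`, `frag_start`,
#'   `frag_end`, `umi`, `n_origins`, `size`); zero rows when the invariant
#'   holds.
#' @export
family_preservation_check <- function(fragments, strict = FALSE) {
  assert_columns(fragments, c("contig", "frag_start", "frag_end",
                              "origin", "umi"), "fragments")
  report <- fragments |>
    group_by(.data$contig, .data$frag_start, .data$frag_end, .data$umi) |>
    summarise(n_origins = dplyr::n_distinct(.data$origin), size = n(),
              .groups = "drop") |>
    filter(.data$n_origins > 1)
  if (strict && nrow(report) > 0) {
    abort(sprintf(
      "UMI family spans the ref/alt boundary: %s:%d-%d UMI %s (%d reads)",
      report$contig[1], report$frag_start[1], report$frag_end[1],
      report$umi[1], report$size[1]),
      class = "umispike_integrity_error")
  }
  report
}
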