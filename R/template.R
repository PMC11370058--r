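#' Simulate a duplicated cfDNA-like template library
#'
#' Draws paired-end fragments over the reference targets with an explicit
#' PCR-duplicate structure: duplicate groups (fragments sharing start/end
#' coordinates) have sizes `1 + Poisson(mean_dupset_size - 1)`, so sizes are
#' zero-truncated by construction and have the requested mean. Fragment
#' lengths follow a normal distribution centred on the cfDNA mononucleosome
#' peak; each read copy carries independent per-base substitution errors so
#' that putative-false-positive evaluation downstream is non-degenerate.
#'
#' @param ref A [make_reference()] object.
#' @param mean_target_depth Requested mean read depth over target bases
#'   (fold-coverage, counting both mates). Achieved within ~15 percent.
#' @param mean_dupset_size Mean duplicate-group size (>= 1).
#' @param seed Integer seed.
#' @param fragment_mean,fragment_sd Fragment length distribution in bases
#'   (defaults 166 / 40, the cfDNA mononucleosome profile). Lengths are
#'   clamped to `[read_length, target_len]`.
#' @param error_rate Independent per-base substitution probability applied to
#'   every read copy (default 0.001, i.e. Q30-scale error).
#' @param base_qual Constant PHRED quality reported for template bases.
#' @return A tibble of read pairs (one row per pair) with columns `id`,
#'   `contig`, `frag_start`, `frag_end` (0-based half-open fragment
#'   coordinates), `group_id` (duplicate-group key), `r1_seq`, `r1_qual`,
#'   `r2_seq`, `r2_qual` (sequencer orientation: R2 is the reverse
#'   complement of the fragment 3' end), `origin` (`NA` until allele
#'   painting) and `umi` (`NA` until UMI assignment).
#' @examples
#' ref <- make_reference(1, 2, 600, seed = 1)
#' tmpl <- make_template(ref, mean_target_depth = 50, mean_dupset_size = 2, seed = 7)
#' @export
make_template <- function(ref, mean_target_depth, mean_dupset_size = 3,
                          seed = 1, fragment_mean = 166, fragment_sd = 40,
                          error_rate = 0.001, base_qual = 30) {
  stopifnot(inherits(ref, "umispike_reference"))
  if (mean_target_depth <= 0) abort("mean_target_depth must be > 0")
  if (mean_dupset_size < 1) abort("mean_dupset_size must be >= 1")
  rl <- ref$read_length
  tb <- target_bases(ref)
  n_pairs <- mean_target_depth * tb / (2 * rl)
  n_groups <- max(1L, round(n_pairs / mean_dupset_size))

  with_seed(seed, {
    sizes <- 1L + rpois(n_groups, mean_dupset_size - 1)
    # place each group on a target, length-weighted
    tg <- ref$targets
    tgt_idx <- sample.int(nrow(tg), n_groups, replace = TRUE,
                          prob = tg$end - tg$start)
    tlen <- (tg$end - tg$start)[tgt_idx]
    frag_len <- pmin(pmax(round(rnorm(n_groups, fragment_mean, fragment_sd)),
                          rl), tlen)
    start <- tg$start[tgt_idx] +
      floor(runif(n_groups) * (tlen - frag_len + 1))
    groups <- tibble(
      group_id = sprintf("g%06d", seq_len(n_groups)),
      contig = tg$contig[tgt_idx],
      frag_start = as.integer(start),
      frag_end = as.integer(start + frag_len),
      size = sizes
    )
    members <- groups[rep(seq_len(n_groups), sizes), ]
    members$size <- NULL
    members$id <- sprintf("read%07d", seq_len(nrow(members)))

    frag_seq <- substring(ref$contigs[members$contig],
                          members$frag_start + 1L, members$frag_end)
    r1 <- substring(frag_seq, 1L, rl)
    r2 <- revcomp(substring(frag_seq, nchar(frag_seq) - rl + 1L,
                            nchar(frag_seq)))
    r1 <- inject_errors(r1, error_rate)
    r2 <- inject_errors(r2, error_rate)
    qual <- phred_string(base_qual, rl)
    tibble(
      id = members$id,
      contig = members$contig,
      frag_start = members$frag_start,
      frag_end = members$frag_end,
      group_id = members$group_id,
      r1_seq = r1, r1_qual = qual,
      r2_seq = r2, r2_qual = qual,
      origin = NA_character_,
      umi = NA_character_
    )
  })
}

# Independent per-base substitutions at `rate` across a character vector of
# equal-length sequences. Substituted bases are drawn from the three
# alternatives so an "error" never reproduces the original base.
inject_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  len <- nchar(seqs[1])
  hit <- which(runif(length(seqs) * len) < rate)
  if (length(hit) == 0) return(seqs)
  read_i <- ((hit - 1L) %/% len) + 1L
  pos_i <- ((hit - 1L) %% len) + 1L
  for (k in seq_along(hit)) {
    i <- read_i[k]; p <- pos_i[k]
    old <- substr(seqs[i], p, p)
    substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, old), 1L)
  }
  seqs
}

#' Mean read depth over target bases of a fragment set
#'
#' Counts read bases (both mates) falling on target intervals, divided by the
#' number of target bases. Used to check depth targets after template
#' simulation or group subsampling.
#'
#' @param fragments A fragment tibble (see [make_template()]).
#' @param ref The reference the fragments were drawn from.
#' @return Mean fold-coverage over target bases (double).
#' @export
mean_target_depth <- function(fragments, ref) {
  rl <- ref$read_length
  tb <- target_bases(ref)
  cov <- 0
  for (i in seq_len(nrow(ref$targets))) {
    t <- ref$targets[i, ]
    f <- fragments[fragments$contig == t$contig, ]
    for (mate in list(c(0L, rl), c(-rl, 0L))) {
      rs <- if (mate[2] == 0L) f$frag_end - rl else f$frag_start
      re <- rs + rl
      ov <- pmin(re, t$end) - pmax(rs, t$start)
      cov <- cov + sum(pmax(ov, 0))
    }
  }
  cov / tb
}
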