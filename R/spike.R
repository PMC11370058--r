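#' Paint one allele onto every read overlapping panel loci
#'
#' Produces the 100%-alternate (or 100%-reference) copy of a template: every
#' read base overlapping a panel locus is overwritten with the chosen allele
#' on both mates (reverse-complemented on the reverse mate), all other bases
#' and all qualities are left untouched, and every fragment's `origin` field
#' is set. Loci covered by no read are reported in the `uncovered` attribute
#' with a warning — they stay in the truth set, since losing them at low
#' depth is the phenomenon the benchmark measures, not an error.
#'
#' @param fragments A template fragment tibble (see [make_template()]).
#' @param ref The reference the template was simulated from.
#' @param panel A variant panel tibble (`contig`, `pos` 1-based, `ref`,
#'   `alt`).
#' @param allele `"alt"` to paint the alternate allele, `"ref"` for the
#'   reference allele.
#' @return The fragment tibble with painted reads and `origin` set; the
#'   attribute `"uncovered"` holds the sub-panel with zero covering reads.
#' @examples
#' ref <- make_reference(1, 2, 600, seed = 1)
#' tmpl <- make_template(ref, 40, 2, seed = 7)
#' panel <- make_variant_panel(ref, 5, seed = 3)
#' alt_lib <- paint_alleles(tmpl, ref, panel, "alt")
#' @export
paint_alleles <- function(fragments, ref, panel, allele = c("alt", "ref")) {
  allele <- match.arg(allele)
  assert_columns(fragments, c("contig", "frag_start", "frag_end",
                              "r1_seq", "r2_seq"), "fragments")
  rl <- ref$read_length
  out <- fragments
  covered <- logical(nrow(panel))
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  for (ct in unique(panel$contig)) {
    pan <- panel[panel$contig == ct, ]
    idx <- which(out$contig == ct)
    if (length(idx) == 0) next
    frag_r <- IRanges::IRanges(out$frag_start[idx] + 1L, out$frag_end[idx])
    loci_r <- IRanges::IRanges(pan$pos, pan$pos)
    hits <- IRanges::findOverlaps(loci_r, frag_r)
    li <- S4Vectors::queryHits(hits)          # index into pan
    fi <- idx[S4Vectors::subjectHits(hits)]   # index into out
    pos0 <- pan$pos[li] - 1L
    base <- if (allele == "alt") pan$alt[li] else pan$ref[li]

    # R1 covers [frag_start, frag_start + rl); R2 covers [frag_end - rl, frag_end)
    r1_off <- pos0 - out$frag_start[fi] + 1L
    r2_off <- out$frag_end[fi] - pos0            # 1-based index into R2 string
    on_r1 <- r1_off >= 1L & r1_off <= rl
    on_r2 <- r2_off >= 1L & r2_off <= rl
    covered_here <- tabulate(li[on_r1 | on_r2], nbins = nrow(pan)) > 0
    covered[panel$contig == ct] <- covered[panel$contig == ct] | covered_here

    out$r1_seq[idx] <- paint_mate(out$r1_seq[idx],
                                  match(fi, idx)[on_r1], r1_off[on_r1],
                                  base[on_r1])
    out$r2_seq[idx] <- paint_mate(out$r2_seq[idx],
                                  match(fi, idx)[on_r2], r2_off[on_r2],
                                  unname(comp[base[on_r2]]))
  }
  out$origin <- allele
  uncovered <- panel[!covered, , drop = FALSE]
  if (nrow(uncovered) > 0) {
    warn(sprintf("%d panel locus/loci covered by no read; recorded in attr(, 'uncovered')",
                 nrow(uncovered)))
  }
  attr(out, "uncovered") <- uncovered
  out
}

# Assign single bases into possibly-repeated string indices. `substr<-` is
# vectorised but silently keeps only the first write per duplicated element,
# so repeat vectorised passes until each target element was written once.
paint_mate <- function(seqs, el, at, base) {
  while (length(el) > 0) {
    first <- !duplicated(el)
    i <- el[first]
    substr(seqs[i], at[first], at[first]) <- base[first]
    el <- el[!first]; at <- at[!first]; base <- base[!first]
  }
  seqs
}

#' Mix reference and alternate libraries to a target VAF and depth
#'
#' Combines the 100%-reference and 100%-alternate copies of a template into
#' one read set with the requested expected variant allele frequency.
#' Selection operates on whole duplicate groups — for each matched group key
#' the alternate copy is chosen with probability `vaf`, otherwise the
#' reference copy — so a group is never split between origins and spiked
#' variants later share UMI families. Before mixing, groups are uniformly
#' subsampled to approach `depth_target`.
#'
#' @param ref_lib,alt_lib Painted fragment tibbles from [paint_alleles()],
#'   derived from the same template (matched `group_id`s).
#' @param vaf Target variant allele frequency, in (0, 1).
#' @param depth_target Target mean on-target depth (fold-coverage), or `NULL`
#'   to keep the template depth. If it exceeds the available depth it is
#'   capped with a warning.
#' @param ref Reference object (needed to measure depth for subsampling).
#' @param seed Integer seed.
#' @param mode `"bernoulli"` (default): each group is alternate independently
#'   with probability `vaf`. `"exact"`: exactly `round(vaf * n_groups)`
#'   groups are alternate, sampled with probability proportional to group
#'   size.
#' @return A fragment tibble of the selected groups with `origin` marking
#'   each group's side; attribute `"selection"` is a tibble of
#'   (`group_id`, `origin`, `size`).
#' @export
mix_to_vaf <- function(ref_lib, alt_lib, vaf, depth_target = NULL, ref = NULL,
                       seed = 1, mode = c("bernoulli", "exact")) {
  mode <- match.arg(mode)
  if (!is.numeric(vaf) || length(vaf) != 1 || vaf <= 0 || vaf >= 1) {
    abort("vaf must be a single number in (0, 1)",
          class = "umispike_domain_error")
  }
  keys <- sort(unique(ref_lib$group_id))
  if (!setequal(keys, unique(alt_lib$group_id))) {
    abort("ref_lib and alt_lib must derive from the same template (matched group keys)")
  }
  with_seed(seed, {
    if (!is.null(depth_target)) {
      if (is.null(ref)) abort("ref is required when depth_target is set")
      avail <- mean_target_depth(ref_lib, ref)
      if (depth_target >= avail) {
        if (depth_target > avail * 1.001) {
          warn(sprintf("depth_target %.0f exceeds available depth %.0f; capped",
                       depth_target, avail))
        }
      } else {
        keep <- runif(length(keys)) < depth_target / avail
        keys <- keys[keep]
      }
    }
    n <- length(keys)
    sizes <- tabulate(factor(ref_lib$group_id, levels = keys), nbins = n)
    is_alt <- switch(mode,
      bernoulli = runif(n) < vaf,
      exact = {
        n_alt <- round(vaf * n)
        sel <- logical(n)
        if (n_alt > 0) {
          sel[sample.int(n, n_alt, prob = sizes)] <- TRUE
        }
        sel
      })
    alt_keys <- keys[is_alt]
    ref_keys <- keys[!is_alt]
    out <- bind_rows(
      alt_lib[alt_lib$group_id %in% alt_keys, ],
      ref_lib[ref_lib$group_id %in% ref_keys, ]
    ) |>
      arrange(.data$contig, .data$frag_start, .data$frag_end, .data$id)
    attr(out, "selection") <- tibble(group_id = keys,
                                     origin = ifelse(is_alt, "alt", "ref"),
                                     size = sizes)
    out
  })
}

#' Define a spike-in experiment plan
#'
#' Bundles the panel, the VAF ladder, the depth targets, the replicate count
#' and the master seed for [generate_datasets()]. Defaults follow the
#' standard low-frequency benchmarking design: VAF levels 0.005, 0.01, 0.02,
#' 0.04, 0.05, 0.075; depths 200x, 450x and 850x; 5 replicates; and at the
#' 200x depth the two lowest levels (0.005, 0.01) are excluded, because at
#' that depth such variants are often supported by no read at all.
#'
#' @param panel Variant panel tibble.
#' @param vaf_levels Numeric vector of VAF levels, each in (0, 0.5].
#' @param depth_targets Numeric vector of target depths (fold-coverage).
#' @param replicates Replicates per (depth, VAF) cell (>= 1).
#' @param seed Master seed; per-dataset seeds are derived from it with
#'   [derive_seed()].
#' @param min_vaf_by_depth Named numeric vector: minimum VAF level admitted
#'   at a given depth (names are depths). The default drops levels below
#'   0.02 at depth 200.
#' @param mode Group selection mode passed to [mix_to_vaf()].
#' @return An object of class `umispike_plan`.
#' @examples
#' ref <- make_reference(1, 4, 2000, seed = 1)
#' plan <- spike_plan(make_variant_panel(ref, 303, seed = 3), seed = 11)
#' nrow(plan_grid(plan))  # 80 datasets under the defaults
#' @export
spike_plan <- function(panel,
                       vaf_levels = c(0.005, 0.01, 0.02, 0.04, 0.05, 0.075),
                       depth_targets = c(200, 450, 850),
                       replicates = 5,
                       seed = 1,
                       min_vaf_by_depth = c("200" = 0.02),
                       mode = c("bernoulli", "exact")) {
  if (any(vaf_levels <= 0 | vaf_levels > 0.5)) {
    abort("vaf_levels must lie in (0, 0.5]", class = "umispike_domain_error")
  }
  if (replicates < 1) abort("replicates must be >= 1")
  structure(list(panel = panel,
                 vaf_levels = sort(vaf_levels),
                 depth_targets = sort(depth_targets),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed),
                 min_vaf_by_depth = min_vaf_by_depth,
                 mode = match.arg(mode)),
            class = "umispike_plan")
}

#' Expand a spike plan into its dataset grid
#'
#' @param plan A [spike_plan()].
#' @return A tibble with one row per dataset: `dataset_id`, `depth`, `vaf`,
#'   `replicate` and the derived `seed`, honouring the per-depth minimum-VAF
#'   exclusion rule.
#' @export
plan_grid <- function(plan) {
  stopifnot(inherits(plan, "umispike_plan"))
  grid <- tidyr::expand_grid(depth = plan$depth_targets,
                             vaf = plan$vaf_levels,
                             replicate = seq_len(plan$replicates))
  min_vaf <- rep(0, nrow(grid))
  if (length(plan$min_vaf_by_depth) > 0) {
    rule <- plan$min_vaf_by_depth[as.character(grid$depth)]
    min_vaf[!is.na(rule)] <- rule[!is.na(rule)]
  }
  grid <- grid[grid$vaf >= min_vaf, , drop = FALSE]
  grid |>
    mutate(
      dataset_id = sprintf("d%.0fx_v%s_r%d", .data$depth,
                           sub("^0\\.", "", format(.data$vaf, scientific = FALSE)),
                           .data$replicate),
      seed = map_dbl(seq_len(nrow(grid)), function(i)
        derive_seed(plan$seed, "spike", grid$depth[i], grid$vaf[i],
                    grid$replicate[i]))
    ) |>
    select("dataset_id", "depth", "vaf", "replicate", "seed")
}

#' Generate all spike-in datasets of a plan
#'
#' Runs the full spiking workflow: paints the 100%-reference and
#' 100%-alternate copies of the template once, then for each (depth, VAF,
#' replicate) cell of the plan subsamples and mixes duplicate groups with a
#' dataset-specific derived seed, and (optionally) writes per-dataset
#' R1/R2 FASTQ, a coordinate-sorted SAM and a truth VCF carrying the
#' intended VAF in the INFO key `TVAF`, plus a manifest TSV.
#'
#' @param template Fragment tibble from [make_template()].
#' @param ref Reference object.
#' @param plan A [spike_plan()].
#' @param outdir Output directory, or `NULL` to keep everything in memory.
#' @return A list of class `umispike_datasets`: `manifest` (dataset tibble
#'   with file paths when written), `datasets` (named list of fragment
#'   tibbles), `truth` (named list of truth tibbles with `tvaf`), and
#'   `uncovered` (panel loci with no covering read in the template).
#' @export
generate_datasets <- function(template, ref, plan, outdir = NULL) {
  stopifnot(inherits(plan, "umispike_plan"))
  ref_lib <- suppressWarnings(paint_alleles(template, ref, plan$panel, "ref"))
  alt_lib <- suppressWarnings(paint_alleles(template, ref, plan$panel, "alt"))
  uncovered <- attr(alt_lib, "uncovered")
  grid <- plan_grid(plan)

  datasets <- vector("list", nrow(grid))
  truth <- vector("list", nrow(grid))
  paths <- vector("list", nrow(grid))
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    mixed <- suppressWarnings(
      mix_to_vaf(ref_lib, alt_lib, g$vaf, depth_target = g$depth, ref = ref,
                 seed = g$seed, mode = plan$mode))
    tr <- plan$panel |> mutate(tvaf = g$vaf, dataset_id = g$dataset_id,
                               depth = g$depth, replicate = g$replicate)
    datasets[[i]] <- mixed
    truth[[i]] <- tr
    if (!is.null(outdir)) {
      base <- file.path(outdir, g$dataset_id)
      p <- c(r1 = paste0(base, "_R1.fastq"), r2 = paste0(base, "_R2.fastq"),
             sam = paste0(base, ".sam"), truth = paste0(base, "_truth.vcf"))
      write_fastq(tibble(id = mixed$id, seq = mixed$r1_seq,
                         qual = mixed$r1_qual), p[["r1"]])
      write_fastq(tibble(id = mixed$id, seq = mixed$r2_seq,
                         qual = mixed$r2_qual), p[["r2"]])
      write_sam(mixed, p[["sam"]], ref)
      write_truth_vcf(tr, p[["truth"]])
      paths[[i]] <- as.list(p)
    }
  }
  names(datasets) <- grid$dataset_id
  names(truth) <- grid$dataset_id
  manifest <- grid
  if (!is.null(outdir)) {
    manifest <- dplyr::bind_cols(grid, bind_rows(lapply(paths, as_tibble)))
    readr::write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  }
  structure(list(manifest = manifest, datasets = datasets, truth = truth,
                 uncovered = uncovered),
            class = "umispike_datasets")
}
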