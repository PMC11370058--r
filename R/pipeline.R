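#' Assemble a run configuration
#'
#' One flat list of every knob the end-to-end pipeline uses, round-trippable
#' through a plain key-value file so a run can be reproduced from its
#' manifest alone. Every stochastic stage derives its effective seed from
#' `seed` via [derive_seed()].
#'
#' @param seed Master seed.
#' @param n_contigs,target_count,target_len,read_length Reference geometry.
#' @param panel_size Number of spiked SNVs.
#' @param depths,vafs,replicates Spike plan grid.
#' @param mean_dupset_size,error_rate Template library parameters.
#' @param lam,umi_mode,umi_length Poisson mean, family-assignment mode and
#'   UMI length for [assign_umis()].
#' @param dialect UMI encoding dialect for the written output.
#' @param min_depth,min_qual,dbsnp_af_cutoff,cosmic_min_samples Filtering
#'   thresholds ([filter_config()]).
#' @return A list of class `umispike_run_config`.
#' @export
run_config <- function(seed = 1,
                       n_contigs = 1, target_count = 4, target_len = 2000,
                       read_length = 100, panel_size = 303,
                       depths = c(200, 450, 850),
                       vafs = c(0.005, 0.01, 0.02, 0.04, 0.05, 0.075),
                       replicates = 5,
                       mean_dupset_size = 3, error_rate = 0.001,
                       lam = 0.5, umi_mode = "label", umi_length = 9,
                       dialect = "three_file",
                       min_depth = 50, min_qual = 50,
                       dbsnp_af_cutoff = 0.05, cosmic_min_samples = 3) {
  structure(list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
                 target_count = as.integer(target_count),
                 target_len = as.integer(target_len),
                 read_length = as.integer(read_length),
                 panel_size = as.integer(panel_size),
                 depths = as.numeric(depths), vafs = as.numeric(vafs),
                 replicates = as.integer(replicates),
                 mean_dupset_size = as.numeric(mean_dupset_size),
                 error_rate = as.numeric(error_rate),
                 lam = as.numeric(lam), umi_mode = umi_mode,
                 umi_length = as.integer(umi_length), dialect = dialect,
                 min_depth = as.numeric(min_depth),
                 min_qual = as.numeric(min_qual),
                 dbsnp_af_cutoff = as.numeric(dbsnp_af_cutoff),
                 cosmic_min_samples = as.numeric(cosmic_min_samples)),
            class = "umispike_run_config")
}

#' A small run configuration for demonstrations and smoke tests
#'
#' Same pipeline, desk-scale sizes: one contig, two targets, a 40-variant
#' panel, two depths, three VAF levels, two replicates.
#' @inheritParams run_config
#' @return A `umispike_run_config`.
#' @export
run_config_small <- function(seed = 1) {
  run_config(seed = seed, target_count = 2, target_len = 1500,
             panel_size = 40, depths = c(150, 300),
             vafs = c(0.02, 0.05, 0.075), replicates = 2)
}

#' Write / read a run configuration as a flat key-value file
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `path` invisibly (write); a `umispike_run_config` (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "umispike_run_config"))
  vals <- vapply(config, function(v)
    paste(format(v, scientific = FALSE, trim = TRUE), collapse = ","),
    character(1))
  writeLines(c(sprintf("# umispike %s",
                       as.character(utils::packageVersion("umispike"))),
               sprintf("%s=%s", names(config), vals)), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- stringr::str_split_fixed(lines, "=", 2)
  vals <- setNames(as.list(kv[, 2]), kv[, 1])
  proto <- run_config()
  unknown <- setdiff(names(vals), names(proto))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "umispike_parse_error")
  }
  for (k in names(vals)) {
    v <- strsplit(vals[[k]], ",", fixed = TRUE)[[1]]
    proto[[k]] <- if (is.character(proto[[k]])) v
                  else if (is.integer(proto[[k]])) as.integer(v)
                  else as.numeric(v)
  }
  proto
}

#' Run the whole pipeline end-to-end on synthetic fixtures
#'
#' Fixtures, allele painting, VAF mixing, UMI family assignment (with a
#' strict ref/alt preservation check), dialect encoding, the naive pileup
#' caller, filtering/annotation, truth matching, and replicate summaries —
#' all from one master seed. With an `outdir`, per-dataset reads
#' (FASTQ/SAM), truth VCFs, the manifest, the effective configuration and
#' the report TSVs are written; reruns with the same configuration are
#' byte-identical.
#'
#' @param config A [run_config()] (or [run_config_small()]).
#' @param outdir Output directory, or `NULL` for in-memory only.
#' @return A list of class `umispike_run`: `config`, `ref`, `panel`, `dbs`,
#'   `datasets` (manifest + reads + truth), `per_dataset` (per-dataset
#'   TP/FP tibble), `summary` (per-cell means), `intersections` (replicate
#'   concordance in the deepest/highest-VAF cell, `NULL` with < 2
#'   replicates), `report_paths`.
#' @export
run_all <- function(config = run_config_small(), outdir = NULL) {
  stopifnot(inherits(config, "umispike_run_config"))
  ref <- make_reference(config$n_contigs, config$target_count,
                        config$target_len,
                        seed = derive_seed(config$seed, "reference"),
                        read_length = config$read_length)
  template <- make_template(ref, mean_target_depth = max(config$depths),
                            mean_dupset_size = config$mean_dupset_size,
                            seed = derive_seed(config$seed, "template"),
                            error_rate = config$error_rate)
  panel <- make_variant_panel(ref, config$panel_size,
                              seed = derive_seed(config$seed, "panel"))
  dbs <- make_annotation_dbs(panel, ref,
                             seed = derive_seed(config$seed, "dbs"))
  plan <- spike_plan(panel, vaf_levels = config$vafs,
                     depth_targets = config$depths,
                     replicates = config$replicates, seed = config$seed,
                     min_vaf_by_depth = c("200" = 0.02))
  ds <- generate_datasets(template, ref, plan,
                          outdir = if (is.null(outdir)) NULL
                                   else file.path(outdir, "datasets"))

  # synthetic UMIs per dataset + preservation check + encoding
  for (id in names(ds$datasets)) {
    ds$datasets[[id]] <- assign_umis(
      ds$datasets[[id]], lam = config$lam, mode = config$umi_mode,
      seed = derive_seed(config$seed, "umi", id),
      umi_length = config$umi_length)
    family_preservation_check(ds$datasets[[id]], strict = TRUE)
    if (!is.null(outdir)) {
      dir.create(file.path(outdir, "umi"), recursive = TRUE,
                 showWarnings = FALSE)
      encode_umi(ds$datasets[[id]], dialect = config$dialect,
                 prefix = file.path(outdir, "umi", id), ref = ref)
    }
  }

  fc <- filter_config(min_depth = config$min_depth,
                      min_qual = config$min_qual,
                      dbsnp_af_cutoff = config$dbsnp_af_cutoff,
                      cosmic_min_samples = config$cosmic_min_samples)
  per_dataset <- evaluate_datasets(ds, ref, dbsnp = dbs$dbsnp,
                                   cosmic = dbs$cosmic, config = fc)
  summary <- summarize_replicates(per_dataset)

  inter <- NULL
  if (config$replicates >= 2) {
    top <- ds$manifest |>
      filter(.data$depth == max(.data$depth), .data$vaf == max(.data$vaf))
    sets <- setNames(
      map(top$dataset_id, function(id) {
        calls <- call_pileup(ds$datasets[[id]], ref)
        filtered <- suppressMessages(filter_calls(calls, dbs$dbsnp, dbs$cosmic,
                                                  config = fc))
        variant_key(filtered)
      }),
      sprintf("rep%d", top$replicate))
    inter <- intersections(sets)
  }

  report_paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    report_paths <- c(
      config = file.path(outdir, "run_config.txt"),
      per_dataset = file.path(outdir, "per_dataset.tsv"),
      summary = file.path(outdir, "summary.tsv"))
    write_run_config(config, report_paths[["config"]])
    readr::write_tsv(per_dataset, report_paths[["per_dataset"]])
    readr::write_tsv(as_tibble(summary), report_paths[["summary"]])
    if (!is.null(inter)) {
      report_paths <- c(report_paths,
                        intersections = file.path(outdir, "intersections.tsv"))
      readr::write_tsv(inter$table, report_paths[["intersections"]])
    }
  }
  structure(list(config = config, ref = ref, panel = panel, dbs = dbs,
                 datasets = ds, per_dataset = per_dataset, summary = summary,
                 intersections = inter, report_paths = report_paths),
            class = "umispike_run")
}

#' @export
print.umispike_run <- function(x, ...) {
  cat(sprintf("<umispike_run> seed %d: %d dataset(s), %d-variant panel\n",
              x$config$seed, nrow(x$per_dataset), nrow(x$panel)))
  print(x$summary)
  invisible(x)
}
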