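test_that("alt painting drives covered panel loci to allele fraction 1", {
  alt_lib <- tiny_alt_lib()
  pf <- pileup_alt_fraction(alt_lib, tiny_ref(), tiny_panel())
  covered <- pf[pf$depth > 0, ]
  expect_gt(nrow(covered), 0)
  expect_true(all(covered$vaf == 1))
  expect_true(all(alt_lib$origin == "alt"))
})

test_that("ref painting of an error-free template only sets origin tags", {
  tmpl <- clean_template()
  panel <- tiny_panel()
  painted <- suppressWarnings(paint_alleles(tmpl, tiny_ref(), panel, "ref"))
  expect_identical(painted$r1_seq, tmpl$r1_seq)
  expect_identical(painted$r2_seq, tmpl$r2_seq)
  expect_identical(painted$r1_qual, tmpl$r1_qual)
  expect_true(all(painted$origin == "ref"))
})

test_that("loci covered by no read are reported as uncovered", {
  ref <- tiny_ref()
  # a sparse template is guaranteed to leave target bases bare
  tmpl <- make_template(ref, mean_target_depth = 2, mean_dupset_size = 1,
                        seed = 13)
  all_pos <- unlist(purrr::map2(ref$targets$start, ref$targets$end,
                                function(s, e) seq(s, e - 1)))
  covered <- unlist(purrr::map2(tmpl$frag_start, tmpl$frag_end,
                                function(s, e) seq(s, e - 1)))
  bare0 <- setdiff(all_pos, unique(covered))
  expect_gt(length(bare0), 0)
  pos <- bare0[1] + 1L
  ct <- ref$targets$contig[ref$targets$start <= pos - 1 &
                             ref$targets$end > pos - 1][1]
  rb <- substring(ref$contigs[ct], pos, pos)
  panel <- tibble::tibble(id = "x", contig = ct, pos = pos, ref = rb,
                          alt = setdiff(c("A", "C", "G", "T"), rb)[1])
  expect_warning(out <- paint_alleles(tmpl, ref, panel, "alt"),
                 "uncovered")
  expect_equal(nrow(attr(out, "uncovered")), 1)
})

test_that("mixing rejects out-of-domain VAFs", {
  expect_error(mix_to_vaf(tiny_ref_lib(), tiny_alt_lib(), 0, seed = 1),
               class = "umispike_domain_error")
  expect_error(mix_to_vaf(tiny_ref_lib(), tiny_alt_lib(), 1.2, seed = 1),
               class = "umispike_domain_error")
})

test_that("the vaf -> 0 limit selects pure reference groups", {
  mixed <- mix_to_vaf(tiny_ref_lib(), tiny_alt_lib(), 1e-12, seed = 5)
  expect_true(all(mixed$origin == "ref"))
  sel <- attr(mixed, "selection")
  expect_true(all(sel$origin == "ref"))
})

test_that("duplicate groups stay atomic and reads are conserved under mixing", {
  mixed <- mix_to_vaf(tiny_ref_lib(), tiny_alt_lib(), 0.3, seed = 6)
  per_group <- tapply(mixed$origin, mixed$group_id,
                      function(o) length(unique(o)))
  expect_true(all(per_group == 1))
  sel <- attr(mixed, "selection")
  expect_equal(nrow(mixed), sum(sel$size))
})

test_that("empirical VAF matches an independent per-locus pileup", {
  # build a larger mix so several loci carry alternate reads
  ref <- make_reference(1, 2, 2000, seed = 21)
  tmpl <- make_template(ref, 150, 3, seed = 22)
  panel <- make_variant_panel(ref, 20, seed = 23)
  rl <- suppressWarnings(paint_alleles(tmpl, ref, panel, "ref"))
  al <- suppressWarnings(paint_alleles(tmpl, ref, panel, "alt"))
  mixed <- mix_to_vaf(rl, al, 0.5, seed = 24)
  pf <- pileup_alt_fraction(mixed, ref, panel)

  # independent oracle: recompute one covered locus from the selection table
  # and raw read strings, walking reads one by one
  sel <- attr(mixed, "selection")
  loc <- pf[which(pf$depth > 0)[1], ]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  alt_n <- 0L; tot <- 0L
  p0 <- loc$pos - 1L
  for (j in seq_len(nrow(mixed))) {
    if (mixed$contig[j] != loc$contig) next
    o1 <- p0 - mixed$frag_start[j]
    if (o1 >= 0 && o1 < ref$read_length) {
      tot <- tot + 1L
      if (substr(mixed$r1_seq[j], o1 + 1, o1 + 1) == loc$alt) alt_n <- alt_n + 1L
    }
    o2 <- mixed$frag_end[j] - p0
    if (o2 >= 1 && o2 <= ref$read_length) {
      tot <- tot + 1L
      if (substr(mixed$r2_seq[j], o2, o2) == comp[[loc$alt]]) alt_n <- alt_n + 1L
    }
  }
  expect_equal(loc$depth, tot)
  expect_equal(loc$alt_count, alt_n)
  expect_equal(loc$vaf, alt_n / tot)

  # pooled VAF concentrates around the target (duplicate groups are the
  # independent units, so the binomial error is taken over covering groups)
  g_cov <- length(unique(mixed$group_id))
  se <- sqrt(0.5 * 0.5 / g_cov)
  pooled <- sum(pf$alt_count) / sum(pf$depth)
  expect_lt(abs(pooled - 0.5), 3 * se + 0.02)
})

test_that("depth subsampling approaches the requested target", {
  ref <- make_reference(1, 2, 2000, seed = 21)
  tmpl <- make_template(ref, 150, 3, seed = 22)
  panel <- make_variant_panel(ref, 5, seed = 23)
  rl <- suppressWarnings(paint_alleles(tmpl, ref, panel, "ref"))
  al <- suppressWarnings(paint_alleles(tmpl, ref, panel, "alt"))
  mixed <- mix_to_vaf(rl, al, 0.05, depth_target = 75, ref = ref, seed = 30)
  d <- mean_target_depth(mixed, ref)
  expect_gt(d, 75 * 0.85)
  expect_lt(d, 75 * 1.15)
  # asking beyond the available depth caps with a warning
  expect_warning(mix_to_vaf(rl, al, 0.05, depth_target = 10 * 150, ref = ref,
                            seed = 30),
                 "capped")
})

test_that("expected alternate read count is monotone in the VAF ladder", {
  rl <- tiny_ref_lib(); al <- tiny_alt_lib()
  alt_reads <- purrr::map_dbl(c(0.02, 0.075, 0.2, 0.4), function(v) {
    sel <- attr(mix_to_vaf(rl, al, v, seed = 40), "selection")
    sum(sel$size[sel$origin == "alt"])
  })
  expect_true(all(diff(alt_reads) >= 0))
})

test_that("exact-count mode fixes the number of alternate groups", {
  mixed <- mix_to_vaf(tiny_ref_lib(), tiny_alt_lib(), 0.25, seed = 8,
                      mode = "exact")
  sel <- attr(mixed, "selection")
  expect_equal(sum(sel$origin == "alt"), round(0.25 * nrow(sel)))
})

test_that("the default plan expands to the published dataset grid", {
  panel <- tiny_panel()
  plan <- spike_plan(panel, seed = 11)
  grid <- plan_grid(plan)
  # 5 replicates x (6 VAFs at 450x + 6 at 850x + 4 at 200x)
  expect_equal(nrow(grid), 80)
  at200 <- grid[grid$depth == 200, ]
  expect_false(any(at200$vaf %in% c(0.005, 0.01)))
  expect_equal(sort(unique(at200$vaf)), c(0.02, 0.04, 0.05, 0.075))
  expect_equal(length(unique(grid$seed)), nrow(grid))

  single <- plan_grid(spike_plan(panel, vaf_levels = 0.05,
                                 depth_targets = 450, replicates = 1))
  expect_equal(nrow(single), 1)
})

test_that("invalid plans are rejected", {
  expect_error(spike_plan(tiny_panel(), vaf_levels = c(0.05, 0.7)),
               class = "umispike_domain_error")
  expect_error(spike_plan(tiny_panel(), replicates = 0))
})

test_that("generated datasets carry full truth VCFs and are reproducible", {
  ref <- tiny_ref()
  tmpl <- tiny_template()
  panel <- tiny_panel()
  plan <- spike_plan(panel, vaf_levels = c(0.05, 0.075), depth_targets = 40,
                     replicates = 2, seed = 11, min_vaf_by_depth = NULL)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  ds1 <- generate_datasets(tmpl, ref, plan, outdir = d1)
  ds2 <- generate_datasets(tmpl, ref, plan, outdir = d2)
  expect_equal(nrow(ds1$manifest), 4)
  for (i in seq_len(nrow(ds1$manifest))) {
    expect_identical(readLines(ds1$manifest$sam[i]),
                     readLines(ds2$manifest$sam[i]))
    truth <- read_vcf(ds1$manifest$truth[i])
    expect_equal(nrow(truth), nrow(panel))
    expect_equal(unique(truth$tvaf), ds1$manifest$vaf[i])
  }
  # in-memory fragments match what was written
  id <- ds1$manifest$dataset_id[1]
  back <- sam_to_fragments(ds1$manifest$sam[1])
  mem <- dplyr::arrange(ds1$datasets[[id]], id)[, names(back)]
  expect_equal(plain(dplyr::arrange(back, id)), plain(mem))
})
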