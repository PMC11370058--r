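test_that("a singleton duplicate set forms exactly one family", {
  frag <- tiny_template()[1, ]
  out <- assign_umis(frag, seed = 1)
  fams <- attr(out, "families")
  expect_equal(nrow(fams), 1)
  expect_equal(fams$size, 1)
  expect_equal(out$umi, fams$umi)
})

test_that("raw Poisson draws have the configured mean", {
  n <- 1e5
  big_group <- tibble::tibble(
    id = sprintf("r%06d", seq_len(n)), contig = "chr1",
    frag_start = 0L, frag_end = 166L, group_id = "g1",
    r1_seq = "A", r1_qual = "?", r2_seq = "A", r2_qual = "?",
    origin = NA_character_, umi = NA_character_)
  out <- assign_umis(big_group, lam = 0.5, seed = 17)
  draws <- attr(out, "umi_draws")
  expect_length(draws, n)
  se <- sqrt(0.5 / n)  # Poisson variance equals the mean
  expect_lt(abs(mean(draws) - 0.5), 3 * se)
})

test_that("family sizes are conserved and replayable from the generator state", {
  group <- tiny_template()[1:12, ]
  group$group_id <- "g1"
  out <- assign_umis(group, lam = 0.5, seed = 99)
  fams <- attr(out, "families")
  expect_equal(sum(fams$size), 12)
  # replay oracle: the same seeded generator yields the same label stream
  replay <- withr::with_seed(as.integer(99), rpois(12, 0.5))
  expect_identical(attr(out, "umi_draws"), replay)
  # and the family partition implied by the labels matches
  expect_equal(sort(as.integer(table(replay))), sort(fams$size))
})

test_that("both modes partition every duplicate set completely", {
  tmpl <- tiny_template()
  for (mode in c("label", "carve")) {
    out <- assign_umis(tmpl, mode = mode, seed = 3)
    expect_false(anyNA(out$umi))
    fams <- attr(out, "families")
    expect_equal(sum(fams$size), nrow(tmpl))
    # per duplicate set: family sizes sum to the set size, UMIs distinct
    per_group <- split(fams, fams$group_id)
    sizes <- table(tmpl$group_id)
    for (g in names(per_group)) {
      expect_equal(sum(per_group[[g]]$size), unname(sizes[g]))
      expect_false(any(duplicated(per_group[[g]]$umi)))
    }
    # members of one family share the UMI across mates by construction
    expect_true(all(nchar(out$umi) == 9))
  }
})

test_that("minted UMIs have the right alphabet, length and uniqueness", {
  withr::with_seed(5L, {
    u <- mint_umi()
    expect_equal(nchar(u), 9)
    expect_true(grepl("^[ATCG]+$", u))
    seen <- character()
    for (i in 1:1000) seen <- c(seen, mint_umi(seen))
    expect_equal(length(unique(seen)), 1000)
    expect_error(mint_umi(c("A", "C", "G", "T"), length = 1),
                 class = "umispike_capacity_error")
  })
})

test_that("lam <= 0 is rejected", {
  expect_error(assign_umis(tiny_template(), lam = 0, seed = 1),
               class = "umispike_domain_error")
})

test_that("multi-family frequency matches the Poisson label model", {
  # P(a set of size n stays one family) = sum_k P(all n labels = k)
  lam <- 0.5
  p_single <- function(n) {
    k <- 0:60
    sum(dpois(k, lam)^n)
  }
  n_sets <- 4000
  for (n in c(2, 4, 6)) {
    groups <- tibble::tibble(
      id = sprintf("r%06d", seq_len(n * n_sets)), contig = "chr1",
      frag_start = 0L, frag_end = 166L,
      group_id = rep(sprintf("g%05d", seq_len(n_sets)), each = n),
      r1_seq = "A", r1_qual = "?", r2_seq = "A", r2_qual = "?",
      origin = NA_character_, umi = NA_character_)
    out <- assign_umis(groups, lam = lam, seed = 100 + n)
    fams <- attr(out, "families")
    n_fam <- table(fams$group_id)
    frac_multi <- mean(n_fam >= 2)
    expected <- 1 - p_single(n)
    se <- sqrt(expected * (1 - expected) / n_sets)
    expect_lt(abs(frac_multi - expected), 3 * se + 1e-6)
  }
})

test_that("all three encoding dialects decode to the same read->UMI map", {
  frags <- assign_umis(tiny_template(), seed = 21)
  d <- withr::local_tempdir()
  p3 <- encode_umi(frags, "three_file", file.path(d, "t"))
  pp <- encode_umi(frags, "prepended", file.path(d, "p"))
  pr <- encode_umi(frags, "rx_tag", file.path(d, "r"), ref = tiny_ref())
  m3 <- dplyr::arrange(decode_umi(p3), id)
  mp <- dplyr::arrange(decode_umi(pp), id)
  mr <- dplyr::arrange(decode_umi(pr), id)
  expect_equal(m3, mp)
  expect_equal(m3, mr)
  # and the decoded map matches the in-memory assignment
  mem <- dplyr::arrange(tibble::tibble(id = frags$id, umi = frags$umi), id)
  expect_equal(m3, mem)
})

test_that("the prepended dialect prefixes 9 UMI bases at Q37", {
  frags <- assign_umis(tiny_template(), seed = 22)
  d <- withr::local_tempdir()
  pp <- encode_umi(frags, "prepended", file.path(d, "p"))
  r1 <- read_fastq(pp[["r1"]])
  rl <- tiny_ref()$read_length
  expect_true(all(nchar(r1$seq) == 9 + rl))
  expect_true(all(substr(r1$qual, 1, 9) == strrep("F", 9)))  # PHRED 37
})

test_that("the three-file dialect writes matched names and Q37 UMI records", {
  frags <- assign_umis(tiny_template(), seed = 23)
  d <- withr::local_tempdir()
  p3 <- encode_umi(frags, "three_file", file.path(d, "t"))
  r1 <- read_fastq(p3[["r1"]]); um <- read_fastq(p3[["umi"]])
  r2 <- read_fastq(p3[["r2"]])
  expect_identical(r1$id, um$id)
  expect_identical(r1$id, r2$id)
  expect_true(all(um$qual == strrep("F", 9)))
})

test_that("rx_tag records carry identical RX values within a family", {
  frags <- assign_umis(tiny_template(), seed = 24)
  d <- withr::local_tempdir()
  pr <- encode_umi(frags, "rx_tag", file.path(d, "r"), ref = tiny_ref())
  sam <- read_sam(pr[["sam"]])
  expect_false(anyNA(sam$rx))
  per_read <- tapply(sam$rx, sam$qname, function(u) length(unique(u)))
  expect_true(all(per_read == 1))
})

test_that("no UMI family spans the ref/alt origin boundary after mixing", {
  mixed <- mix_to_vaf(tiny_ref_lib(), tiny_alt_lib(), 0.2, seed = 31)
  mixed <- assign_umis(mixed, seed = 32)
  expect_equal(nrow(family_preservation_check(mixed)), 0)

  # vaf -> 0: trivially clean
  pure <- mix_to_vaf(tiny_ref_lib(), tiny_alt_lib(), 1e-12, seed = 33)
  pure <- assign_umis(pure, seed = 34)
  expect_equal(nrow(family_preservation_check(pure)), 0)

  # planted fault: keep both origin copies of one duplicate group under the
  # same coordinates and UMI
  rl <- tiny_ref_lib(); al <- tiny_alt_lib()
  g <- rl$group_id[1]
  fault <- dplyr::bind_rows(rl[rl$group_id == g, ], al[al$group_id == g, ])
  fault$umi <- "AAAAAAAAA"
  rep <- family_preservation_check(fault)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$n_origins, 2)
  expect_error(family_preservation_check(fault, strict = TRUE),
               class = "umispike_integrity_error")
})
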