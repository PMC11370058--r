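test_that("depth filtering retains records with DP of at least 50", {
  rec <- toy_records(200, qual = 99)
  kept <- depth_quality_filter(rec, filter_config())
  expect_equal(min(kept$dp), 50)
  expect_equal(nrow(kept), 151)
  expect_identical(kept$dp, sort(kept$dp))  # order preserved
})

test_that("quality filtering applies the PHRED 50 threshold", {
  rec <- toy_records(10, qual = 99)
  rec$dp <- 100
  rec$qual <- c(0, 10, 49, 49.9, 50, 50.1, 60, 99, 200, NA)
  kept <- depth_quality_filter(rec, filter_config())
  expect_equal(sort(kept$qual), c(50, 50.1, 60, 99, 200))
})

test_that("uniformly missing QUAL reduces filtering to depth only", {
  rec <- toy_records(100)
  rec$qual <- NA_real_
  expect_message(kept <- depth_quality_filter(rec, filter_config()),
                 "disabled")
  expect_equal(nrow(kept), 51)
  expect_equal(min(kept$dp), 50)
})

test_that("records without a parseable DP fail the depth filter, with notice", {
  rec <- toy_records(4, qual = 99)
  rec$dp <- c(100L, NA, 100L, NA)
  expect_message(kept <- depth_quality_filter(rec, filter_config()),
                 "without a parseable DP")
  expect_equal(nrow(kept), 2)
})

test_that("empty input passes through every stage empty", {
  rec <- toy_records(0)
  expect_equal(nrow(depth_quality_filter(rec)), 0)
  db <- make_annotation_dbs(tiny_panel(), tiny_ref(), seed = 2)
  expect_equal(nrow(dbsnp_exclude(rec, db$dbsnp)), 0)
  expect_equal(nrow(cosmic_annotate(rec, db$cosmic)), 0)
})

test_that("PHRED qualities convert to correctness probabilities", {
  expect_equal(qual_to_probability(50), 0.99999)
  expect_equal(qual_to_probability(0), 0)
  expect_equal(qual_to_probability(10), 0.9)
  expect_equal(qual_to_probability(c(20, 30)), c(0.99, 0.999))
  expect_error(qual_to_probability(-1), class = "umispike_domain_error")
})

make_dbsnp <- function(df) umispike:::new_annotation_db(df, "dbsnp")

test_that("dbSNP exclusion removes only variants common in all populations", {
  rec <- tibble::tibble(contig = "chr1", pos = 1:12, ref = "A", alt = "T",
                        qual = 99, dp = 100)
  db <- make_dbsnp(tibble::tibble(
    contig = "chr1", pos = 1:10, ref = "A", alt = "T",
    af = as.list(seq(0.01, 0.10, by = 0.01))))
  kept <- dbsnp_exclude(rec, db, cutoff = 0.05)
  matched <- kept[kept$pos <= 10, ]
  afs <- seq(0.01, 0.10, by = 0.01)[matched$pos]
  expect_true(all(afs <= 0.04 + 1e-12))
  # records absent from the db are retained
  expect_true(all(11:12 %in% kept$pos))

  # multi-population entry at {4%, 6%}: not common in ALL populations
  db2 <- make_dbsnp(tibble::tibble(contig = "chr1", pos = c(1L, 2L),
                                   ref = "A", alt = "T",
                                   af = list(c(0.04, 0.06), c(0.05, 0.06))))
  kept2 <- dbsnp_exclude(rec[1:2, ], db2, cutoff = 0.05)
  expect_equal(kept2$pos, 1L)  # {4%,6%} retained, {5%,6%} discarded
})

test_that("dbSNP exclusion agrees with a truth table over the conjunction", {
  # oracle: discard iff min(af) >= cutoff
  withr::with_seed(7L, {
    rec <- tibble::tibble(contig = "chr1", pos = 1:50, ref = "A", alt = "T")
    afl <- lapply(1:50, function(i) round(runif(sample(1:3, 1)), 2))
    db <- make_dbsnp(tibble::tibble(contig = "chr1", pos = 1:50, ref = "A",
                                    alt = "T", af = afl))
    kept <- dbsnp_exclude(rec, db, cutoff = 0.5)
    discard_oracle <- vapply(afl, function(a) min(a) >= 0.5, logical(1))
    expect_setequal(kept$pos, which(!discard_oracle))
  })
})

test_that("COSMIC annotation flags without dropping records", {
  rec <- tibble::tibble(contig = "chr1", pos = 1:12, ref = "A", alt = "T")
  db <- umispike:::new_annotation_db(
    tibble::tibble(contig = "chr1", pos = 1:10, ref = "A", alt = "T",
                   cnt = 1:10), "cosmic")
  out <- cosmic_annotate(rec, db, min_samples = 3)
  expect_equal(nrow(out), 12)                       # annotation-only stage
  expect_equal(out$pos[out$cosmic], 3:10)           # counts 1,2 unusable
  expect_true(all(out$cosmic_cnt[out$cosmic] >= 3))
  expect_false(any(out$cosmic[11:12]))
})

test_that("raising any threshold never enlarges the retained set", {
  withr::with_seed(11L, {
    rec <- tibble::tibble(
      contig = "chr1", pos = 1:120, ref = "A", alt = "T",
      qual = round(runif(120, 0, 120), 1), dp = sample(1:200, 120, TRUE))
    db <- make_dbsnp(tibble::tibble(
      contig = "chr1", pos = sample(1:120, 40), ref = "A", alt = "T",
      af = as.list(round(runif(40, 0, 0.12), 3))))
    for (i in 1:15) {
      d1 <- runif(1, 0, 150); d2 <- d1 + runif(1, 0, 50)
      q1 <- runif(1, 0, 100); q2 <- q1 + runif(1, 0, 30)
      c2 <- runif(1, 0, 0.12); c1 <- c2 + runif(1, 0, 0.05)
      loose <- suppressMessages(filter_calls(
        rec, dbsnp = db, config = filter_config(min_depth = d1, min_qual = q1,
                                                dbsnp_af_cutoff = c1)))
      tight <- suppressMessages(filter_calls(
        rec, dbsnp = db, config = filter_config(min_depth = d2, min_qual = q2,
                                                dbsnp_af_cutoff = c2)))
      expect_true(all(tight$pos %in% loose$pos))
    }
  })
})

test_that("depth/quality and dbSNP stages commute", {
  withr::with_seed(13L, {
    rec <- tibble::tibble(
      contig = "chr1", pos = 1:80, ref = "A", alt = "T",
      qual = round(runif(80, 0, 120), 1), dp = sample(1:200, 80, TRUE))
    db <- make_dbsnp(tibble::tibble(
      contig = "chr1", pos = sample(1:80, 30), ref = "A", alt = "T",
      af = as.list(round(runif(30, 0, 0.12), 3))))
    cfg <- filter_config()
    ab <- dbsnp_exclude(depth_quality_filter(rec, cfg), db, cfg$dbsnp_af_cutoff)
    ba <- depth_quality_filter(dbsnp_exclude(rec, db, cfg$dbsnp_af_cutoff), cfg)
    expect_equal(as.data.frame(ab), as.data.frame(ba))
  })
})

test_that("UMI-aware call sets without parseable DP bypass depth/quality", {
  rec <- tibble::tibble(contig = "chr1", pos = 1:20, ref = "A", alt = "T",
                        qual = NA_real_, dp = NA_integer_)
  expect_message(out <- filter_calls(rec), "bypassed")
  log <- attr(out, "stage_log")
  expect_equal(nrow(out), 20)
  expect_equal(log$note[log$stage == "depth_quality"], "bypassed")
  expect_equal(log$n_discarded[log$stage == "depth_quality"], 0)

  # but a mixed DP column is NOT bypassed (conservative)
  rec$dp[1] <- 100L
  out2 <- suppressMessages(filter_calls(rec))
  expect_equal(nrow(out2), 1)
})

test_that("the stage log accounts for every record", {
  db <- make_annotation_dbs(tiny_panel(), tiny_ref(), seed = 2)
  rec <- toy_records(120, qual = 99)
  out <- suppressMessages(
    filter_calls(rec, dbsnp = db$dbsnp, cosmic = db$cosmic))
  log <- attr(out, "stage_log")
  expect_equal(log$n_in[1], 120)
  expect_true(all(log$n_in - log$n_retained == log$n_discarded))
  expect_equal(log$n_retained[nrow(log)], nrow(out))
  expect_true(all(c("cosmic", "cosmic_cnt") %in% names(out)))
})
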