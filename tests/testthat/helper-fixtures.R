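# Shared small fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

tiny_ref <- function() cached("tiny_ref", make_reference(1, 2, 600, seed = 1))

tiny_template <- function() {
  cached("tiny_template",
         make_template(tiny_ref(), mean_target_depth = 60,
                       mean_dupset_size = 3, seed = 7))
}

tiny_panel <- function() cached("tiny_panel",
                                make_variant_panel(tiny_ref(), 10, seed = 3))

# An error-free template (no sequencing substitutions) for identity checks.
clean_template <- function() {
  cached("clean_template",
         make_template(tiny_ref(), mean_target_depth = 40,
                       mean_dupset_size = 2, seed = 9, error_rate = 0))
}

# Painted copies of the tiny template over the tiny panel.
tiny_ref_lib <- function() {
  cached("tiny_ref_lib",
         suppressWarnings(paint_alleles(tiny_template(), tiny_ref(),
                                        tiny_panel(), "ref")))
}

tiny_alt_lib <- function() {
  cached("tiny_alt_lib",
         suppressWarnings(paint_alleles(tiny_template(), tiny_ref(),
                                        tiny_panel(), "alt")))
}

# Drop non-structural attributes (selection/families/uncovered) so data
# frames can be compared by content.
plain <- function(df) {
  df <- as.data.frame(df)
  attributes(df) <- attributes(df)[c("names", "class", "row.names")]
  df
}

# A toy call-record tibble spanning the filter thresholds.
toy_records <- function(n = 200, qual = 99) {
  tibble::tibble(
    contig = "chr1",
    pos = seq_len(n),
    ref = "A",
    alt = "T",
    qual = rep(qual, n),
    dp = seq_len(n)
  )
}
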