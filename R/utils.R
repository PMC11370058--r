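DNA_BASES <- c("A", "C", "G", "T")

#' Derive a stage seed from a master seed
#'
#' Fans a single master seed out to per-stage / per-dataset seeds via a
#' stable string hash, so any stage of a run can be reproduced in isolation
#' from the manifest without replaying the whole random stream.
#'
#' @param seed Master seed (integer).
#' @param ... Further components (coerced to character) identifying the
#'   stage, e.g. `derive_seed(11, "spike", depth, vaf, replicate)`.
#' @return A single integer in `[1, 2^31 - 2]`, identical across platforms
#'   for identical inputs.
#' @examples
#' derive_seed(11, "spike", 450, 0.075, 1)
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed, scientific = FALSE), vapply(list(...), function(x)
    paste(format(x, scientific = FALSE), collapse = ","), character(1))),
    collapse = "|")
  codes <- utf8ToInt(key)
  h <- 104729
  m <- 2147483647  # 2^31 - 1, keeps the state an R integer
  for (code in codes) {
    # multiplier small enough that h * mult + code stays below 2^53
    h <- (h * 69069 + code) %% m
  }
  as.integer(h %% (m - 2L) + 1L)
}

# Run code with a temporarily-seeded RNG, restoring global state afterwards.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

phred_char <- function(q) {
  intToUtf8(33L + as.integer(q))
}

phred_string <- function(q, len) {
  strrep(phred_char(q), len)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA strings, vectorised: n strings of length len.
random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}

str_reverse <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
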