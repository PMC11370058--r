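#' Build a small synthetic reference with target intervals
#'
#' Generates random contig sequences and non-overlapping target intervals on
#' them, standing in for a genome plus a targeted-panel BED (the scale of a
#' small cancer gene panel rather than a whole genome). Targets are laid out
#' deterministically with fixed inter-target gaps, so disjointness holds by
#' construction.
#'
#' @param n_contigs Number of contigs.
#' @param target_count Total number of target intervals (distributed
#'   round-robin across contigs).
#' @param target_len Length of each target interval in bases. Must be at
#'   least `3 * read_length` so paired reads fit inside a target.
#' @param seed Integer seed; identical seeds give byte-identical references.
#' @param read_length Read length the reference must accommodate (bases).
#' @param gap Gap between consecutive targets and flanking contig ends.
#' @return An object of class `umispike_reference`: a list with `contigs`
#'   (named character vector of A/C/G/T sequences) and `targets` (a tibble
#'   with `contig`, `start`, `end`; 0-based half-open).
#' @examples
#' ref <- make_reference(1, 4, 2000, seed = 1)
#' ref$targets
#' @export
make_reference <- function(n_contigs = 1, target_count = 4, target_len = 2000,
                           seed = 1, read_length = 100, gap = 200) {
  stopifnot(n_contigs >= 1, target_count >= 1, read_length >= 1)
  if (target_len < 3 * read_length) {
    abort(sprintf(
      "target_len (%d) too small for read placement: need >= 3 * read_length (%d)",
      target_len, 3 * read_length), class = "umispike_sizing_error")
  }
  contig_of <- rep(seq_len(n_contigs), length.out = target_count)
  per_contig <- tabulate(contig_of, nbins = n_contigs)
  with_seed(seed, {
    contigs <- character(n_contigs)
    targets <- vector("list", n_contigs)
    for (i in seq_len(n_contigs)) {
      k <- max(per_contig[i], 0L)
      len <- gap + max(k, 1L) * (target_len + gap)
      contigs[i] <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
      if (k > 0) {
        starts <- gap + (seq_len(k) - 1L) * (target_len + gap)
        targets[[i]] <- tibble(
          contig = sprintf("chr%d", i),
          start = starts,
          end = starts + target_len
        )
      }
    }
    names(contigs) <- sprintf("chr%d", seq_len(n_contigs))
    structure(
      list(contigs = contigs,
           targets = dplyr::bind_rows(targets),
           read_length = as.integer(read_length)),
      class = "umispike_reference")
  })
}

#' @export
print.umispike_reference <- function(x, ...) {
  cat(sprintf("<umispike_reference> %d contig(s), %s bp total, %d target(s), %s target bp\n",
              length(x$contigs), format(sum(nchar(x$contigs)), big.mark = ","),
              nrow(x$targets), format(target_bases(x), big.mark = ",")))
  invisible(x)
}

#' Total number of target bases in a reference
#' @param ref A `umispike_reference`.
#' @return Integer count of bases covered by target intervals.
#' @export
target_bases <- function(ref) {
  sum(ref$targets$end - ref$targets$start)
}

#' Write a reference as FASTA + BED
#'
#' @param ref A `umispike_reference`.
#' @param fasta,bed Output paths. BED is written 0-based half-open (BED3).
#' @return Invisibly, a named character vector of the two paths.
#' @export
write_reference <- function(ref, fasta, bed) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$contigs), fasta)
  readr::write_tsv(ref$targets, bed, col_names = FALSE)
  invisible(c(fasta = fasta, bed = bed))
}

#' Read a reference back from FASTA + BED
#'
#' @inheritParams write_reference
#' @param read_length Read length to record on the object.
#' @return A `umispike_reference`.
#' @export
read_reference <- function(fasta, bed, read_length = 100) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  contigs <- setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  targets <- readr::read_tsv(bed, col_names = c("contig", "start", "end"),
                             col_types = "cii", progress = FALSE)
  bad <- targets$end > nchar(contigs[targets$contig]) | targets$start < 0
  if (any(bad, na.rm = TRUE) || anyNA(bad)) {
    abort("BED intervals fall outside the FASTA contigs",
          class = "umispike_parse_error")
  }
  structure(list(contigs = contigs, targets = targets,
                 read_length = as.integer(read_length)),
            class = "umispike_reference")
}
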