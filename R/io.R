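#' Write reads as FASTQ (Phred+33)
#'
#' @param reads Tibble with columns `id`, `seq`, `qual` (quality string of
#'   equal length to `seq`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  assert_columns(reads, c("id", "seq", "qual"), "reads")
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    abort("sequence/quality length mismatch", class = "umispike_parse_error")
  }
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ path (Phred+33).
#' @return Tibble with `id`, `seq`, `qual`, in file order.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble(id = sub("\\s.*$", "", names(x)),
         seq = unname(as.character(x)),
         qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' Write fragments as a coordinate-sorted SAM file
#'
#' Emits one properly-paired record per mate (flags 99/147) with `@HD`/`@SQ`
#' headers, CIGAR `<read length>M`, and — when UMIs are assigned — the UMI
#' in the `RX:Z:` optional tag. Reverse-mate SEQ/QUAL are stored in
#' forward-strand orientation per the SAM convention. Plain SAM is the
#' canonical artifact here so every file in a run is inspectable text; BAM
#' can be produced from it with standard tools when needed.
#'
#' @param fragments Fragment tibble.
#' @param path Output path.
#' @param ref Reference (for `@SQ` lines and read length).
#' @return `path`, invisibly.
#' @export
write_sam <- function(fragments, path, ref) {
  rl <- ref$read_length
  f <- arrange(fragments, .data$contig, .data$frag_start, .data$frag_end,
               .data$id)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(ref$contigs),
                      nchar(ref$contigs)))
  tlen <- f$frag_end - f$frag_start
  pos1 <- f$frag_start + 1L
  pos2 <- f$frag_end - rl + 1L
  tags <- sprintf("\tMI:Z:%s", f$group_id)
  if (!all(is.na(f$origin))) tags <- paste0(tags, sprintf("\tXO:Z:%s", f$origin))
  if (!all(is.na(f$umi))) tags <- paste0(tags, sprintf("\tRX:Z:%s", f$umi))
  cigar <- sprintf("%dM", rl)
  rec1 <- sprintf("%s\t99\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s%s",
                  f$id, f$contig, pos1, cigar, pos2, tlen, f$r1_seq,
                  f$r1_qual, tags)
  rec2 <- sprintf("%s\t147\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s%s",
                  f$id, f$contig, pos2, cigar, pos1, -tlen,
                  revcomp(f$r2_seq), str_reverse(f$r2_qual), tags)
  pos <- c(pos1, pos2)
  recs <- c(rec1, rec2)[order(rep(f$contig, 2), pos)]
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Read a SAM file into a tibble of alignment records
#'
#' Strict parser for the subset of SAM this package emits (and any
#' conformant single-segment records): 11 mandatory fields plus optional
#' tags; the `RX:Z:` UMI tag is extracted into its own column. Malformed
#' records raise a parse error naming the line.
#'
#' @param path SAM path.
#' @return Tibble with `qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`,
#'   `rnext`, `pnext`, `tlen`, `seq`, `qual`, `rx` (NA when absent).
#' @export
read_sam <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0) {
    return(tibble(qname = character(), flag = integer(), rname = character(),
                  pos = integer(), mapq = integer(), cigar = character(),
                  rnext = character(), pnext = integer(), tlen = integer(),
                  seq = character(), qual = character(), rx = character(),
                  mi = character(), xo = character()))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11)) {
    abort(sprintf("malformed SAM record at line %d: %d field(s), need >= 11",
                  which(!startsWith(lines, "@"))[which(nf < 11)[1]],
                  min(nf)), class = "umispike_parse_error")
  }
  field <- function(i) map_chr(parts, i)
  tag <- function(prefix) map_chr(parts, function(p) {
    hit <- p[startsWith(p, prefix)]
    if (length(hit) > 0) substring(hit[1], nchar(prefix) + 1L) else NA_character_
  })
  out <- tibble(
    qname = field(1), flag = as.integer(field(2)), rname = field(3),
    pos = as.integer(field(4)), mapq = as.integer(field(5)),
    cigar = field(6), rnext = field(7), pnext = as.integer(field(8)),
    tlen = as.integer(field(9)), seq = field(10), qual = field(11),
    rx = tag("RX:Z:"), mi = tag("MI:Z:"), xo = tag("XO:Z:"))
  if (anyNA(out$pos) || any(out$pos < 0)) {
    abort("malformed SAM record: non-numeric or negative POS",
          class = "umispike_parse_error")
  }
  out
}

vcf_header <- function(info_defs, contigs = NULL, extra = character()) {
  c("##fileformat=VCFv4.2",
    sprintf("##source=umispike"),
    extra,
    if (!is.null(contigs))
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), nchar(contigs)),
    info_defs,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"))
}

write_vcf_body <- function(df, path, info, info_defs, contigs = NULL,
                           extra = character()) {
  qual <- if ("qual" %in% names(df)) {
    ifelse(is.na(df$qual), ".", format(round(df$qual, 2), trim = TRUE,
                                       scientific = FALSE))
  } else rep(".", nrow(df))
  id <- if ("id" %in% names(df)) df$id else rep(".", nrow(df))
  recs <- sprintf("%s\t%d\t%s\t%s\t%s\t%s\tPASS\t%s",
                  df$contig, df$pos, id, df$ref, df$alt, qual, info)
  writeLines(c(vcf_header(info_defs, contigs, extra), recs), path)
  invisible(path)
}

#' Write a spike-in truth set as VCF v4.2
#'
#' One record per spiked panel variant; the intended variant allele
#' frequency is stored in the INFO key `TVAF`.
#'
#' @param truth Tibble with `contig`, `pos`, `ref`, `alt`, `tvaf` (and
#'   optionally `id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_vcf <- function(truth, path) {
  assert_columns(truth, c("contig", "pos", "ref", "alt", "tvaf"), "truth")
  write_vcf_body(
    truth, path,
    info = sprintf("TVAF=%s", format(truth$tvaf, scientific = FALSE, trim = TRUE)),
    info_defs = "##INFO=<ID=TVAF,Number=1,Type=Float,Description=\"Intended spiked-in variant allele frequency\">")
}

#' Write an annotation database (dbSNP- or COSMIC-style) as VCF v4.2
#'
#' dbSNP-style tables emit `AF=` with one value per recorded population;
#' COSMIC-style tables emit the recurrence sample count as `CNT=`.
#'
#' @param db An annotation db tibble from [make_annotation_dbs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_vcf <- function(db, path) {
  kind <- db_kind(db)
  if (identical(kind, "dbsnp")) {
    info <- map_chr(db$af, function(a)
      sprintf("AF=%s", paste(format(a, scientific = FALSE, trim = TRUE),
                             collapse = ",")))
    defs <- "##INFO=<ID=AF,Number=.,Type=Float,Description=\"Population allele frequency, one value per population\">"
  } else if (identical(kind, "cosmic")) {
    info <- sprintf("CNT=%d", db$cnt)
    defs <- "##INFO=<ID=CNT,Number=1,Type=Integer,Description=\"Number of samples with this mutation\">"
  } else {
    abort("db must carry kind 'dbsnp' or 'cosmic'")
  }
  write_vcf_body(as_tibble(db), path, info, defs)
}

#' Write variant calls as VCF v4.2
#'
#' @param calls Tibble with `contig`, `pos`, `ref`, `alt` and optionally
#'   `qual`, `dp`, `alt_count`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path) {
  assert_columns(calls, c("contig", "pos", "ref", "alt"), "calls")
  info <- rep("", nrow(calls))
  defs <- character()
  if ("dp" %in% names(calls)) {
    info <- sprintf("DP=%d", calls$dp)
    defs <- c(defs, "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth at the site\">")
  }
  if ("alt_count" %in% names(calls)) {
    info <- paste0(info, ifelse(nzchar(info), ";", ""),
                   sprintf("AC=%d", calls$alt_count))
    defs <- c(defs, "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alternate-supporting read count\">")
  }
  info[!nzchar(info)] <- "."
  write_vcf_body(
    calls, path, info, defs,
    extra = "##umispike_multiallelic=records are split to biallelic before filtering")
}

#' Read a VCF into a tidy record tibble
#'
#' Parses with `vcfR`, splits multiallelic records into biallelic rows
#' (each alternate allele gets its own row, so filtering and exact-key
#' matching never see comma-separated ALTs), and extracts commonly used
#' INFO keys into typed columns.
#'
#' @param path VCF path (plain text or gzipped).
#' @return A tibble with `contig`, `pos`, `id`, `ref`, `alt`, `qual`
#'   (numeric, `NA` when missing), `filter`, plus `dp` (from `INFO/DP`),
#'   `tvaf`, `cnt` and list-column `af` when those keys are present.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  names(fix) <- tolower(names(fix))
  if (nrow(fix) == 0) {
    return(tibble(contig = character(), pos = integer(), id = character(),
                  ref = character(), alt = character(), qual = double(),
                  filter = character()))
  }
  out <- tibble(
    contig = fix$chrom,
    pos = suppressWarnings(as.integer(fix$pos)),
    id = fix$id %||% NA_character_,
    ref = fix$ref,
    alt = fix$alt,
    qual = suppressWarnings(as.numeric(fix$qual)),
    filter = fix$filter %||% NA_character_,
    info = fix$info %||% NA_character_
  )
  if (anyNA(out$pos) || any(out$pos < 1)) {
    abort("malformed VCF: POS must be a 1-based positive integer",
          class = "umispike_parse_error")
  }
  # biallelic split
  out <- tidyr::separate_longer_delim(out, "alt", delim = ",")
  grab <- function(key) {
    m <- stringr::str_match(out$info, sprintf("(?:^|;)%s=([^;]*)", key))[, 2]
    m
  }
  dp <- grab("DP")
  if (any(!is.na(dp))) out$dp <- suppressWarnings(as.integer(dp))
  tvaf <- grab("TVAF")
  if (any(!is.na(tvaf))) out$tvaf <- suppressWarnings(as.numeric(tvaf))
  cnt <- grab("CNT")
  if (any(!is.na(cnt))) out$cnt <- suppressWarnings(as.integer(cnt))
  af <- grab("AF")
  if (any(!is.na(af))) {
    out$af <- map(strsplit(af, ",", fixed = TRUE), function(a)
      suppressWarnings(as.numeric(a)))
  }
  out$info <- NULL
  out
}

#' Read an annotation VCF back as an annotation db
#'
#' @param path VCF path.
#' @param kind `"dbsnp"` or `"cosmic"`.
#' @return A `umispike_annotation_db` tibble.
#' @export
read_annotation_vcf <- function(path, kind = c("dbsnp", "cosmic")) {
  kind <- match.arg(kind)
  df <- read_vcf(path)
  keep <- c("contig", "pos", "ref", "alt",
            if (kind == "dbsnp") "af" else "cnt")
  new_annotation_db(df[, intersect(keep, names(df))], kind)
}

#' Reconstruct a fragment tibble from a SAM file written by this package
#'
#' Pairs first/second mates by read name, converts the reverse mate back to
#' sequencer orientation, and restores the duplicate-group id (`MI` tag),
#' origin (`XO` tag) and UMI (`RX` tag) when present.
#'
#' @param path SAM path.
#' @return A fragment tibble equivalent to the one [write_sam()] received.
#' @export
sam_to_fragments <- function(path) {
  sam <- read_sam(path)
  first <- sam[bitwAnd(sam$flag, 64L) > 0L, ]
  second <- sam[bitwAnd(sam$flag, 128L) > 0L, ]
  second <- second[match(first$qname, second$qname), ]
  if (anyNA(second$qname)) {
    abort("unpaired records in SAM", class = "umispike_integrity_error")
  }
  rl <- nchar(first$seq[1])
  tibble(
    id = first$qname,
    contig = first$rname,
    frag_start = first$pos - 1L,
    frag_end = second$pos + rl - 1L,
    group_id = first$mi,
    r1_seq = first$seq, r1_qual = first$qual,
    r2_seq = revcomp(second$seq), r2_qual = str_reverse(second$qual),
    origin = first$xo,
    umi = first$rx
  ) |>
    arrange(.data$id)
}
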