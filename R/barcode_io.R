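#' Count barcodes in a FASTQ file
#'
#' Reads standard 4-line FASTQ records, computes a per-read quality
#' statistic over the barcode region (the mean per-base Phred score by
#' default) and counts the exact barcode sequence of every read whose
#' statistic reaches `quality_threshold`. No clustering or error
#' correction is performed: reads carrying a sequencing error count as a
#' distinct (typically off-library) barcode.
#'
#' The default threshold of 56 follows the admission rule used for the
#' published data; note that it exceeds the per-base range of most real
#' base callers, so its exact semantics are a property of that pipeline.
#' Both the statistic and the threshold are plain parameters here.
#'
#' @param path FASTQ file (uncompressed, 4-line records).
#' @param quality_threshold minimum value of the quality statistic.
#' @param barcode_start 1-based offset of the barcode within the read.
#' @param barcode_length barcode length; `NULL` uses the full read.
#' @param quality_offset ASCII offset of the quality encoding (33 for
#'   Sanger/Illumina 1.8+, 64 for legacy Illumina).
#' @param stat function mapping a numeric vector of per-base Phred scores
#'   to the read's quality statistic (default `mean`).
#' @return named integer vector of barcode counts.
#' @export
extract_barcodes <- function(path, quality_threshold = 56,
                             barcode_start = 1, barcode_length = NULL,
                             quality_offset = 33, stat = mean) {
  if (!quality_offset %in% c(33, 64)) {
    stop("unknown quality encoding: offset must be 33 or 64")
  }
  lines <- readLines(path)
  if (length(lines) == 0L) return(integer(0))
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: ", length(lines),
         " lines is not a multiple of 4 (truncated record ",
         length(lines) %/% 4L + 1L, ")")
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seqs) != nchar(qual))
  if (length(bad) > 0L) {
    stop("malformed FASTQ record ", bad[1], " in ", path)
  }
  # Biostrings does the quality decoding; offset-64 scores are 31 above
  # the offset-33 interpretation of the same bytes
  q <- methods::as(Biostrings::PhredQuality(qual), "IntegerList")
  shift <- if (quality_offset == 64) 31L else 0L
  if (!is.null(barcode_length)) {
    idx <- seq(barcode_start, length.out = barcode_length)
    seqs <- substr(seqs, barcode_start, barcode_start + barcode_length - 1L)
    scores <- vapply(q, function(v) stat(v[idx] - shift), numeric(1))
  } else {
    scores <- vapply(q, function(v) stat(v - shift), numeric(1))
  }
  keep <- seqs[scores >= quality_threshold]
  if (length(keep) == 0L) return(integer(0))
  counts <- table(keep)
  stats::setNames(as.integer(counts), names(counts))
}

#' Build a barcode reference library from plasmid replicates
#'
#' Pools replicate barcode count tables of the plasmid library and admits a
#' barcode if and only if its pooled frequency is at least `min_freq`
#' (default 0.0002%) and it appears in at least `min_replicates` replicate
#' tables (default 2). Admitted frequencies are renormalised to sum to 1.
#'
#' @param tables list of at least `min_replicates` named count vectors (or
#'   `data.frame`s with `barcode`/`count` columns), one per replicate.
#' @param min_freq minimum pooled frequency (as a fraction; 0.0002% =
#'   `2e-6`).
#' @param min_replicates minimum number of replicates a barcode must
#'   appear in.
#' @return a `reference_library`: `data.frame` with columns `barcode` and
#'   `frequency`, and attribute `n_library`.
#' @export
build_reference_library <- function(tables, min_freq = 2e-6,
                                    min_replicates = 2) {
  tables <- lapply(tables, function(t) {
    if (is.data.frame(t)) t <- stats::setNames(t$count, t$barcode)
    t[t > 0]
  })
  if (length(tables) < min_replicates) {
    stop("need at least ", min_replicates, " replicate tables")
  }
  if (any(vapply(tables, length, integer(1)) == 0L)) {
    stop("empty count table supplied")
  }
  all_bc <- sort(unique(unlist(lapply(tables, names))))
  pooled <- numeric(length(all_bc))
  present <- integer(length(all_bc))
  for (t in tables) {
    i <- match(names(t), all_bc)
    pooled[i] <- pooled[i] + t
    present[i] <- present[i] + 1L
  }
  freq <- pooled / sum(pooled)
  admit <- freq >= min_freq & present >= min_replicates
  if (!any(admit)) stop("no barcode passed the library filters")
  out <- data.frame(barcode = all_bc[admit],
                    frequency = freq[admit] / sum(freq[admit]),
                    stringsAsFactors = FALSE)
  structure(out, n_library = nrow(out),
            class = c("reference_library", "data.frame"))
}

#' Restrict counts to library barcodes
#'
#' Drops every barcode that is not in the reference library; the total of
#' the dropped counts is reported in attribute `dropped_total` (output
#' total + dropped total = input total).
#'
#' @param counts named count vector.
#' @param library a `reference_library`.
#' @param fill_missing if `TRUE`, library barcodes absent from `counts`
#'   are included with count 0 (useful before clone-loss measurements).
#' @return named count vector with attribute `dropped_total`.
#' @export
filter_counts_by_library <- function(counts, library, fill_missing = FALSE) {
  stopifnot(inherits(library, "reference_library"))
  keep <- names(counts) %in% library$barcode
  out <- counts[keep]
  if (fill_missing) {
    missing <- setdiff(library$barcode, names(out))
    out <- c(out, stats::setNames(rep(0, length(missing)), missing))
    out <- out[library$barcode]
  }
  attr(out, "dropped_total") <- sum(counts[!keep])
  out
}
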