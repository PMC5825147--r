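#' Synthetic initial clone-size distributions
#'
#' Generates an initial barcode count table of `C` clones totalling exactly
#' `n` cells. The `"uniform"` mode spreads cells as evenly as possible
#' (sizes differ by at most 1; with the standard 14,000 clones over 3e5
#' cells every clone gets 21 or 22 cells). The skewed mode emulates a
#' right-skewed library, in which many clones hold fewer than 10 cells:
#' sizes are drawn from a log-normal with the given log-SD, rescaled to
#' total `n`, with a minimum clone size of 1.
#'
#' @param C number of clones (`<= n`).
#' @param n total number of cells.
#' @param shape `"uniform"`, or a positive number used as the log-normal
#'   log-SD of the skewed mode (larger = more skew).
#' @return named integer vector of `C` clone sizes summing to `n`.
#' @export
synth_initial_distribution <- function(C, n, shape = "uniform") {
  stopifnot(C >= 1)
  if (C > n) stop("cannot spread ", C, " clones over ", n, " cells")
  sizes <- if (identical(shape, "uniform")) {
    largest_remainder(rep(1, C), n)
  } else {
    sdlog <- as.numeric(shape)
    if (!is.finite(sdlog) || sdlog <= 0) {
      stop("shape must be \"uniform\" or a positive log-normal log-SD")
    }
    s <- largest_remainder(stats::rlnorm(C, meanlog = 0, sdlog = sdlog), n)
    # enforce minimum size 1 by moving cells from the largest clones
    while (any(s == 0)) {
      z <- which(s == 0)
      donors <- order(s, decreasing = TRUE)[seq_along(z)]
      s[z] <- 1L
      s[donors] <- s[donors] - 1L
    }
    s
  }
  stats::setNames(sizes, sprintf("bc%05d", seq_len(C)))
}

#' Synthetic barcode reference library
#'
#' Builds a stand-in reference library of random distinct barcode
#' sequences with Dirichlet(1)-distributed pooled frequencies, for use by
#' the FASTQ generator and the contamination model when no real plasmid
#' library is available. This object is synthetic: it mimics the format
#' and invariants of a real admitted library, not its sequence content.
#'
#' @param n_barcodes number of barcodes.
#' @param width barcode length in bases (default 20).
#' @param uniform if `TRUE`, all frequencies are equal instead of
#'   Dirichlet-distributed.
#' @return a `reference_library` (see [build_reference_library()]).
#' @export
synth_reference_library <- function(n_barcodes, width = 20,
                                    uniform = FALSE) {
  stopifnot(n_barcodes >= 1, width >= 1)
  if (4^width < n_barcodes * 2) {
    stop("barcode width too small for ", n_barcodes, " distinct sequences")
  }
  seqs <- character(0)
  while (length(seqs) < n_barcodes) {
    more <- vapply(seq_len(n_barcodes - length(seqs)), function(i) {
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
            collapse = "")
    }, character(1))
    seqs <- unique(c(seqs, more))
  }
  w <- if (uniform) rep(1, n_barcodes) else stats::rgamma(n_barcodes, 1)
  out <- data.frame(barcode = seqs, frequency = w / sum(w),
                    stringsAsFactors = FALSE)
  structure(out, n_library = n_barcodes,
            class = c("reference_library", "data.frame"))
}

#' Read/write a reference library as TSV
#' @param path TSV file with columns `barcode` and `frequency`.
#' @return a `reference_library`.
#' @export
read_reference_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(df[c("barcode", "frequency")], n_library = nrow(df),
            class = c("reference_library", "data.frame"))
}

#' @rdname read_reference_library
#' @param library a `reference_library`.
#' @export
write_reference_library <- function(library, path) {
  utils::write.table(as.data.frame(library), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate synthetic FASTQ reads from barcode counts
#'
#' Writes one read per counted cell (or `depth` reads subsampled without
#' replacement), each carrying its clone's barcode sequence with
#' independent per-base substitution errors at `error_rate` and constant
#' per-base Phred qualities. With `error_rate = 0` and `quality` above the
#' admission threshold, [extract_barcodes()] recovers the counts exactly.
#'
#' @param counts named count vector; every name must be a barcode sequence
#'   present in `library`.
#' @param library a `reference_library` providing the admissible sequences.
#' @param path output FASTQ file.
#' @param error_rate per-base substitution probability.
#' @param quality constant per-base Phred score (default 70, comfortably
#'   above the default admission threshold of 56).
#' @param depth optional total number of reads (multivariate hypergeometric
#'   subsample of the counted cells).
#' @return `path`, invisibly; attribute `n_reads` holds the read count.
#' @export
synth_fastq <- function(counts, library, path, error_rate = 0,
                        quality = 70L, depth = NULL) {
  stopifnot(inherits(library, "reference_library"),
            error_rate >= 0, error_rate <= 1)
  counts <- counts[counts > 0]
  missing <- setdiff(names(counts), library$barcode)
  if (length(missing) > 0L) {
    stop("barcode(s) without a library sequence: ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  if (!is.null(depth)) {
    counts <- stats::setNames(mv_hypergeom(counts, depth), names(counts))
  }
  reads <- rep(names(counts), counts)
  if (length(reads) > 0L) reads <- sample(reads) # shuffle read order
  if (error_rate > 0 && length(reads) > 0L) {
    width <- nchar(reads[1])
    mat <- matrix(unlist(strsplit(reads, "")), ncol = width, byrow = TRUE)
    hit <- which(stats::runif(length(mat)) < error_rate)
    if (length(hit) > 0L) {
      alphabet <- c("A", "C", "G", "T")
      subs <- vapply(mat[hit], function(b) {
        sample(setdiff(alphabet, b), 1)
      }, character(1))
      mat[hit] <- subs
      reads <- apply(mat, 1, paste, collapse = "")
    }
  }
  dna <- Biostrings::DNAStringSet(reads)
  names(dna) <- sprintf("read%06d", seq_along(reads))
  qual_str <- vapply(nchar(reads), function(w) {
    strrep(intToUtf8(quality + 33L), w)
  }, character(1))
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual_str))
  attr(path, "n_reads") <- length(reads)
  invisible(path)
}

#' Contaminate counts with spurious reads
#'
#' Adds, to every barcode of the reference library, a spurious count drawn
#' from `Poisson(contamination_rate * total_counts * library_frequency)`.
#' Spurious reads only ever add counts, so barcodes that were extinct in
#' the sample can reappear - which is why contamination biases measured
#' clone loss downward much more than it biases the Gini coefficient.
#' This is an explicit, parameterised stand-in for sequencing-error
#' contamination confined to a known library; the real error process is
#' sequence-dependent.
#'
#' @param counts named count vector (the "sequenced" clone sizes).
#' @param library a `reference_library`.
#' @param contamination_rate expected total spurious reads as a fraction of
#'   the total input counts, `>= 0`.
#' @return named count vector over the union of `counts` and library
#'   barcodes; every count is `>=` its input value.
#' @export
contaminate_with_spurious_reads <- function(counts, library,
                                            contamination_rate) {
  stopifnot(inherits(library, "reference_library"), contamination_rate >= 0)
  if (contamination_rate == 0) return(counts)
  total <- sum(counts)
  spur <- stats::rpois(nrow(library),
                       contamination_rate * total * library$frequency)
  all_bc <- union(names(counts), library$barcode)
  out <- stats::setNames(rep(0, length(all_bc)), all_bc)
  out[names(counts)] <- counts
  out[library$barcode] <- out[library$barcode] + spur
  out
}
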