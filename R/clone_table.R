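#' Clone size tables
#'
#' A `clone_table` records the size (number of cells) of every clone in a
#' barcoded population. The initial clone count `C0` is fixed at creation and
#' never changes afterwards: clones that go extinct are retained with size 0,
#' so that inequality statistics are always computed over the same set of
#' founder clones. Sizes are integer counts for the stochastic models; the
#' deterministic growth model is allowed to carry real-valued sizes between
#' passages.
#'
#' @param sizes numeric vector of clone sizes, all `>= 0`.
#' @param barcode optional character vector of barcode identifiers (defaults
#'   to `names(sizes)` or `"bc<i>"`).
#' @param integer_sizes if `TRUE` (default) sizes must be whole numbers.
#' @return an object of class `clone_table`: a list with elements `barcode`,
#'   `size` and `C0`.
#' @examples
#' tab <- clone_table(c(a = 5, b = 3, c = 0))
#' n_cells(tab)
#' gini_coefficient(tab)
#' @export
clone_table <- function(sizes, barcode = NULL, integer_sizes = TRUE) {
  if (length(sizes) < 1L) {
    stop("a clone table needs at least one clone (C0 >= 1)")
  }
  sizes <- as.numeric(sizes)
  if (anyNA(sizes) || any(sizes < 0)) {
    stop("clone sizes must be non-negative and non-missing")
  }
  if (integer_sizes && any(abs(sizes - round(sizes)) > 1e-8)) {
    stop("clone sizes must be whole numbers (use integer_sizes = FALSE for ",
         "the deterministic model)")
  }
  if (is.null(barcode)) {
    barcode <- if (!is.null(names(sizes))) names(sizes) else
      sprintf("bc%05d", seq_along(sizes))
  }
  if (length(barcode) != length(sizes)) {
    stop("barcode and sizes must have the same length")
  }
  structure(
    list(barcode = as.character(barcode), size = unname(sizes),
         C0 = length(sizes)),
    class = "clone_table"
  )
}

#' @export
print.clone_table <- function(x, ...) {
  cat(sprintf(
    "<clone_table> C0 = %d clones, %d surviving, n = %g cells\n",
    x$C0, sum(x$size > 0), sum(x$size)))
  invisible(x)
}

#' @rdname clone_table
#' @param table a `clone_table`.
#' @export
n_cells <- function(table) {
  stopifnot(inherits(table, "clone_table"))
  sum(table$size)
}

#' @export
#' @method as.data.frame clone_table
as.data.frame.clone_table <- function(x, ...) {
  data.frame(barcode = x$barcode, count = x$size, stringsAsFactors = FALSE)
}

#' Read and write clone tables as TSV
#'
#' Clone tables are exchanged as tab-separated files with columns
#' `barcode` and `count`, the format used for barcode count tables of
#' sequencing pipelines.
#'
#' @param path file path.
#' @param integer_sizes passed on to [clone_table()].
#' @return `read_clone_table()` returns a `clone_table`;
#'   `write_clone_table()` returns `path` invisibly.
#' @export
read_clone_table <- function(path, integer_sizes = TRUE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("barcode", "count") %in% names(df))) {
    stop("expected TSV columns 'barcode' and 'count' in ", path)
  }
  clone_table(df$count, barcode = df$barcode, integer_sizes = integer_sizes)
}

#' @rdname read_clone_table
#' @param table a `clone_table`.
#' @export
write_clone_table <- function(table, path) {
  stopifnot(inherits(table, "clone_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gini coefficient of a clone size distribution
#'
#' Measures clonal dominance as the mean absolute difference between all
#' ordered pairs of clone sizes, normalised by twice the mean size:
#' \deqn{G = \frac{1}{2 C_0} \sum_{i=1}^{C_0} \sum_{j=1}^{C_0}
#'   \frac{|N_i - N_j|}{n}}
#' where \eqn{C_0} is the number of clones at initialization, \eqn{N_i} the
#' size of clone \eqn{i} and \eqn{n} the total number of cells. Extinct
#' clones enter the sum as zeros, so progressive clone loss alone raises the
#' coefficient. `G = 0` means all clones are equal; the supremum
#' \eqn{(C_0-1)/C_0} is approached when a single clone holds every cell.
#'
#' The implementation uses the sorted-rank identity
#' \eqn{G = \sum_i (2i - C_0 - 1)\, N_{(i)} / (C_0\, n)} (sizes sorted
#' ascending), which is algebraically equal to the double sum but O(C log C).
#'
#' @param table a [clone_table()].
#' @return the Gini coefficient, a number in `[0, 1)`.
#' @export
gini_coefficient <- function(table) {
  stopifnot(inherits(table, "clone_table"))
  n <- sum(table$size)
  if (n <= 0) {
    stop("Gini coefficient is undefined for an empty population (n = 0)")
  }
  c0 <- table$C0
  x <- sort(table$size)
  sum((2 * seq_len(c0) - c0 - 1) * x) / (c0 * n)
}

#' Percentage of initial clones lost
#'
#' @param table a [clone_table()].
#' @return percentage (0-100) of the `C0` founder clones whose current size
#'   is zero. The complement, `100 - clone_loss()`, is the percentage of
#'   clones remaining.
#' @export
clone_loss <- function(table) {
  stopifnot(inherits(table, "clone_table"))
  100 * sum(table$size == 0) / table$C0
}

#' Number of major clones
#'
#' Major clones hold strictly more than a given fraction of the population
#' (by convention more than 1%).
#'
#' @param table a [clone_table()].
#' @param threshold population fraction a clone must strictly exceed
#'   (default `0.01`).
#' @return integer count of major clones.
#' @export
count_major_clones <- function(table, threshold = 0.01) {
  stopifnot(inherits(table, "clone_table"))
  n <- sum(table$size)
  if (n <= 0) {
    stop("major clones are undefined for an empty population (n = 0)")
  }
  sum(table$size / n > threshold)
}

#' Clonal dominance curve
#'
#' Sorts clones from large to small and returns the cumulative percentage of
#' clones against the cumulative percentage of the population those clones
#' hold. For a perfectly even population the curve is the diagonal; the more
#' the curve bows above the diagonal, the stronger the dominance.
#'
#' @param table a [clone_table()].
#' @return a `data.frame` with columns `percent_clones` and
#'   `percent_population`, ending at (100, 100).
#' @export
dominance_curve <- function(table) {
  stopifnot(inherits(table, "clone_table"))
  n <- sum(table$size)
  if (n <= 0) {
    stop("dominance curve is undefined for an empty population (n = 0)")
  }
  sizes <- sort(table$size, decreasing = TRUE)
  data.frame(
    percent_clones = 100 * seq_along(sizes) / table$C0,
    percent_population = 100 * cumsum(sizes) / n
  )
}
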