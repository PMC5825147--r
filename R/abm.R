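#' Agent-based model parameters
#'
#' In the agent-based model (ABM) every cell is represented individually and
#' carries a barcode and a heritable division rate. Initial rates are
#' `r_i = r0 * max(X, 0)` with `X ~ Normal(1, sigma0)`; at every division
#' each child draws `r_c = r_p * max(Y, 0)` with `Y ~ Normal(1, sigma_m)`.
#' A master population of `n_master` cells is built once, with barcode
#' abundances following the input counts and rates drawn under a fixed
#' `master_seed`, so that the same cell carries the same rate in every
#' simulation replicate; each replicate then samples `n_init` cells from it.
#'
#' `n_master` defaults to 5e6 cells at full scale; desk-scale runs shrink
#' `n_master`, `n_init` and the protocol sizes by a common factor.
#'
#' @param r0 mean initial division rate per day, `> 0`.
#' @param sigma0 relative SD of initial division rates, `>= 0`.
#' @param sigma_m relative SD of the per-division mutation multiplier, `>= 0`.
#' @param n_master master population size (cells).
#' @param n_init cells drawn from the master per replicate
#'   (`<= n_master`); defaults to the protocol's post-passage size 3e5.
#' @param master_seed integer seed shared across replicates for the
#'   barcode-to-rate assignment.
#' @return an `abm_params` list.
#' @export
abm_params <- function(r0 = 1, sigma0 = 0, sigma_m = 0, n_master = 5e6,
                       n_init = 3e5, master_seed = 20180212L) {
  stopifnot(r0 > 0, sigma0 >= 0, sigma_m >= 0, n_master >= 1,
            n_init >= 1, n_init <= n_master)
  structure(list(r0 = r0, sigma0 = sigma0, sigma_m = sigma_m,
                 n_master = n_master, n_init = n_init,
                 master_seed = as.integer(master_seed)),
            class = "abm_params")
}

new_cell_population <- function(barcode_idx, rate, tnext, now, barcodes) {
  structure(list(barcode = barcode_idx, rate = rate, tnext = tnext,
                 now = now, barcodes = barcodes),
            class = "cell_population")
}

#' @export
print.cell_population <- function(x, ...) {
  cat(sprintf(
    "<cell_population> %d cells, %d barcodes, mean rate %.4g/day, t = %.3g d\n",
    length(x$rate), length(unique(x$barcode)), mean(x$rate), x$now))
  invisible(x)
}

#' Build the ABM master population
#'
#' Creates `n_master` cells whose barcode frequencies follow the input
#' counts (largest-remainder rounding, so each barcode's cell count deviates
#' from its exact share by less than one cell) and assigns division rates
#' `r0 * max(X, 0)`, `X ~ Normal(1, sigma0)`, drawn under `master_seed`.
#' The assignment is a pure function of `(counts, params)`: rebuilding with
#' the same inputs reproduces every cell's rate exactly, which is what keeps
#' the barcode-to-rate mapping constant across simulation replicates. The
#' caller's RNG state is left untouched.
#'
#' @param counts named numeric vector (or `clone_table`) of barcode read
#'   counts; at least one must be positive.
#' @param params an [abm_params()].
#' @return a `cell_population` with unscheduled division times.
#' @export
build_master_population <- function(counts, params = abm_params()) {
  stopifnot(inherits(params, "abm_params"))
  if (inherits(counts, "clone_table")) {
    counts <- stats::setNames(counts$size, counts$barcode)
  }
  if (length(counts) == 0L || all(counts <= 0)) {
    stop("counts must contain at least one positive entry")
  }
  if (params$n_master < sum(counts > 0)) {
    stop("n_master is smaller than the number of barcodes")
  }
  barcodes <- names(counts)
  if (is.null(barcodes)) barcodes <- sprintf("bc%05d", seq_along(counts))
  cells_per_bc <- largest_remainder(pmax(counts, 0), params$n_master)
  idx <- rep(seq_along(counts), cells_per_bc)
  rate <- with_fixed_seed(params$master_seed, {
    params$r0 * pmax(stats::rnorm(params$n_master, 1, params$sigma0), 0)
  })
  new_cell_population(idx, rate, rep(Inf, params$n_master), now = 0,
                      barcodes = barcodes)
}

#' Draw a replicate's initial population from the master
#'
#' Samples `n_init` cells uniformly without replacement; each sampled cell
#' keeps its barcode and division rate, and gets a freshly scheduled
#' division time (see [schedule_division()]).
#'
#' @param master a `cell_population` from [build_master_population()].
#' @param n_init number of cells to draw (`<=` master size).
#' @return a `cell_population` of `n_init` cells at time 0.
#' @export
draw_initial_population <- function(master, n_init) {
  stopifnot(inherits(master, "cell_population"))
  n_master <- length(master$rate)
  if (n_init > n_master) stop("n_init exceeds the master population size")
  keep <- sample.int(n_master, n_init)
  rate <- master$rate[keep]
  new_cell_population(master$barcode[keep], rate,
                      schedule_division(rate, now = 0),
                      now = 0, barcodes = master$barcodes)
}

#' Schedule next division times
#'
#' Division waiting times are exponential: `t = now - ln(R) / r` with `R`
#' uniform on (0, 1]. Cells with rate 0 never divide and get time `Inf`.
#'
#' @param rate vector of division rates (per day), `>= 0`.
#' @param now current simulated time (days).
#' @return vector of absolute division times.
#' @export
schedule_division <- function(rate, now = 0) {
  stopifnot(all(rate >= 0))
  t <- rep(Inf, length(rate))
  pos <- rate > 0
  t[pos] <- now - log(stats::runif(sum(pos))) / rate[pos]
  t
}

#' Divide a cell
#'
#' Returns the division rates of the two children of a cell with rate
#' `rate`: each child independently draws `r_c = rate * max(Y, 0)`,
#' `Y ~ Normal(1, sigma_m)`. With `sigma_m = 0` both children inherit the
#' parent's rate exactly; a child whose `Y` draw is `<= 0` gets rate 0 and
#' never divides.
#'
#' @param rate parent division rate, `> 0`.
#' @param sigma_m mutation SD, `>= 0`.
#' @return numeric vector of length 2 with the children's rates.
#' @export
divide_cell <- function(rate, sigma_m = 0) {
  stopifnot(length(rate) == 1, rate > 0, sigma_m >= 0)
  if (sigma_m == 0) return(c(rate, rate))
  rate * pmax(stats::rnorm(2, 1, sigma_m), 0)
}

#' Grow an ABM population to a critical size
#'
#' Processes division events in time order (first-reaction method with a
#' binary event heap) until the population holds `n_crit` cells. Each
#' division replaces the parent by two children with mutated rates (see
#' [divide_cell()]) and freshly scheduled division times. The population
#' never shrinks: the ABM has no cell death.
#'
#' @param pop a `cell_population`.
#' @param n_crit target population size (cells).
#' @param sigma_m mutation SD applied at every division.
#' @return a list with `pop` (grown `cell_population`) and `elapsed`
#'   (simulated days).
#' @export
abm_grow <- function(pop, n_crit, sigma_m = 0) {
  stopifnot(inherits(pop, "cell_population"))
  if (length(pop$rate) >= n_crit) {
    return(list(pop = pop, elapsed = 0))
  }
  if (all(pop$rate <= 0)) {
    stop("no cell can divide (all rates are 0): n_crit is unreachable")
  }
  res <- cpp_abm_grow(as.integer(pop$barcode), pop$rate, pop$tnext,
                      pop$now, n_crit, sigma_m)
  if (isTRUE(res$stalled)) {
    stop("event queue emptied before reaching n_crit (all rates mutated to 0)")
  }
  out <- new_cell_population(res$barcode, res$rate, res$tnext, res$now,
                             pop$barcodes)
  list(pop = out, elapsed = res$elapsed)
}

#' Collapse an ABM population to a clone table
#'
#' Clone sizes are tabulated over every barcode known to the population, so
#' clones whose last cell was lost remain represented as zeros and the
#' founder clone count is preserved.
#'
#' @param pop a `cell_population`.
#' @return a [clone_table()].
#' @export
abm_clone_table <- function(pop) {
  stopifnot(inherits(pop, "cell_population"))
  sizes <- tabulate(pop$barcode, nbins = length(pop$barcodes))
  clone_table(sizes, barcode = pop$barcodes)
}

#' Export per-cell rates
#'
#' @param pop a `cell_population`.
#' @return a `data.frame` with columns `barcode` and `rate`, one row per
#'   cell, for rate-distribution diagnostics.
#' @export
abm_cell_rates <- function(pop) {
  stopifnot(inherits(pop, "cell_population"))
  data.frame(barcode = pop$barcodes[pop$barcode], rate = pop$rate,
             stringsAsFactors = FALSE)
}
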