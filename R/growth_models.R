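#' Growth model parameters
#'
#' Parameters of the clone-level growth engines. Defaults follow the
#' standard configuration of the iterated growth-and-passage simulations:
#' division rate `r = 1/day` (arbitrary, since growth always runs to a fixed
#' critical size), leap step `tau = 0.0005` days, and critical population
#' size `n_crit = 4e6` cells (roughly three days of growth at a 19-hour
#' doubling time starting from `3e5` cells).
#'
#' @param r division rate per day, `>= 0`.
#' @param tau tau-leap time step in days, `> 0`.
#' @param n_crit critical population size in cells, `> 0`.
#' @return a `growth_params` list.
#' @export
growth_params <- function(r = 1, tau = 5e-4, n_crit = 4e6) {
  stopifnot(r >= 0, tau > 0, n_crit > 0)
  structure(list(r = r, tau = tau, n_crit = n_crit), class = "growth_params")
}

#' Deterministic exponential growth
#'
#' Every clone grows as `N_i(t + t_growth) = N_i(t) * exp(r * t_growth)`.
#' Sizes become real-valued; relative clone frequencies are exactly
#' preserved.
#'
#' @param table a [clone_table()].
#' @param r division rate per day.
#' @param t_growth growth duration in days, `>= 0`.
#' @return a `clone_table` with real-valued sizes.
#' @export
deterministic_grow <- function(table, r, t_growth) {
  stopifnot(inherits(table, "clone_table"), r >= 0)
  if (t_growth < 0) stop("t_growth must be non-negative")
  clone_table(table$size * exp(r * t_growth), barcode = table$barcode,
              integer_sizes = FALSE)
}

#' Stochastic growth by tau-leaping
#'
#' Grows an integer-valued clone table as a pure birth process: in each leap
#' of length `tau`, clone `i` gains `k_i ~ Poisson(r * N_i * tau)` cells.
#' Leaps repeat until the total population reaches `n_crit` (the final leap
#' may overshoot; the overshoot is kept) or, optionally, until `t_max` days
#' of simulated time have elapsed. Size-0 clones are absorbing.
#'
#' @param table a [clone_table()] with integer sizes and at least one cell.
#' @param params a [growth_params()].
#' @param t_max optional cap on simulated time in days (default `Inf`);
#'   useful for fixed-duration runs that ignore `n_crit`.
#' @return a list with elements `table` (the grown `clone_table`),
#'   `elapsed` (simulated days) and `steps` (number of leaps).
#' @export
tau_leap_grow <- function(table, params = growth_params(), t_max = Inf) {
  stopifnot(inherits(table, "clone_table"), inherits(params, "growth_params"))
  if (any(abs(table$size - round(table$size)) > 1e-8)) {
    stop("tau_leap_grow() requires integer clone sizes")
  }
  n <- sum(table$size)
  if (n <= 0) stop("cannot grow an empty population")
  res <- cpp_tau_leap_grow(table$size, params$r, params$tau,
                           params$n_crit, t_max)
  list(table = clone_table(res$sizes, barcode = table$barcode),
       elapsed = res$elapsed, steps = res$steps)
}

#' Population doubling time
#'
#' @param n_start,n_end population sizes before and after growth (cells),
#'   with `n_end > n_start > 0`.
#' @param t_growth growth duration in hours.
#' @return doubling time in hours: `t_growth * log(2) / log(n_end/n_start)`.
#' @export
doubling_time <- function(n_start, n_end, t_growth) {
  stopifnot(n_start > 0, t_growth > 0)
  if (n_end <= n_start) {
    stop("doubling time undefined: population did not grow (n_end <= n_start)")
  }
  t_growth * log(2) / log(n_end / n_start)
}
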