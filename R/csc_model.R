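#' Cancer stem cell model parameters
#'
#' The age-structured cancer stem cell (CSC) growth model distinguishes
#' stem cells, which divide indefinitely at rate `r_csc`, from differentiated
#' cells (DCs), which divide at rate `r_dc` up to a maximum of `M` divisions
#' and then die at rate `r_dc`. A CSC division yields two CSCs with
#' probability `p1`, a CSC plus a DC with probability `p2`, or two DCs with
#' probability `p3` (`p1 + p2 + p3 = 1`). The long-run fate of the population
#' is governed by [csc_beta()]. Defaults are calibrated so that one growth
#' phase from 3e5 to 4e6 cells reproduces a 19-hour population doubling
#' time: `p1 = p2 = 0.5`, `p3 = 0`, 5% initial CSCs, `M = 10`,
#' `r_csc = 1/day`, `r_dc = 24/19 per day`.
#'
#' `sigma_r` adds per-clone division-rate heterogeneity: both rates of clone
#' `i` are multiplied by `X_i ~ Normal(1, sigma_r)` truncated at 0, drawn
#' once per clone at initialization and inherited by all its cells.
#'
#' @param p1,p2,p3 division-mode probabilities, summing to 1.
#' @param r_csc,r_dc division rates per day.
#' @param M maximum number of DC divisions (`>= 1`).
#' @param csc0 initial CSC fraction in `[0, 1]`.
#' @param sigma_r relative SD of the per-clone rate multiplier, `>= 0`.
#' @return a `csc_params` list.
#' @export
csc_params <- function(p1 = 0.5, p2 = 0.5, p3 = 0, r_csc = 1, r_dc = 24 / 19,
                       M = 10, csc0 = 0.05, sigma_r = 0) {
  stopifnot(p1 >= 0, p2 >= 0, p3 >= 0, r_csc >= 0, r_dc >= 0,
            M >= 1, csc0 >= 0, csc0 <= 1, sigma_r >= 0)
  if (abs(p1 + p2 + p3 - 1) > 1e-9) stop("p1 + p2 + p3 must equal 1")
  structure(list(p1 = p1, p2 = p2, p3 = p3, r_csc = r_csc, r_dc = r_dc,
                 M = as.integer(M), csc0 = csc0, sigma_r = sigma_r),
            class = "csc_params")
}

#' Net stem cell growth rate and regime
#'
#' The asymptotic behaviour of the CSC model is set by
#' `beta = (p1 - p3) * r_csc`: the population keeps growing for `beta > 0`,
#' reaches an equilibrium for `beta = 0`, and eventually goes extinct for
#' `beta < 0`.
#'
#' @param params a [csc_params()].
#' @return a list with `beta` (per day) and `regime`
#'   (`"growth"`, `"equilibrium"` or `"extinction"`).
#' @export
csc_beta <- function(params) {
  stopifnot(inherits(params, "csc_params"))
  beta <- (params$p1 - params$p3) * params$r_csc
  regime <- if (beta > 0) "growth" else if (beta < 0) "extinction" else
    "equilibrium"
  list(beta = beta, regime = regime)
}

#' Initialize the CSC state of a clone table
#'
#' Splits each clone of `N_i` cells into stem and differentiated
#' compartments: `N_CSC = round(csc0 * N_i)` (half rounds up), the
#' differentiated cells are spread evenly over `M` of the `M + 1` age
#' classes with `floor((1 - csc0) * N_i / M)` cells each, and any cells
#' left over by the rounding are placed uniformly at random over all
#' `M + 2` species of the clone. Per-clone totals are preserved exactly.
#' The per-clone rate multiplier `X_i` is drawn from `Normal(1, sigma_r)`
#' and clamped at 0 (`X_i = 1` everywhere when `sigma_r = 0`).
#'
#' Which `M` age classes receive the initial DCs is ambiguous in the
#' model's verbal description (ages run `0..M`, so there are `M + 1`
#' classes but only `M` shares). `dc_age_init` selects the reading:
#' `"1:M"` (default) seeds ages `1..M`, which is the only reading that
#' reproduces the 19-hour doubling-time calibration of the default
#' parameter set to within 1 hour; `"0:M-1"` leaves the terminal class
#' empty instead; `"0:M"` spreads the same per-class share over all
#' `M + 1` classes.
#'
#' @param table a [clone_table()] with integer sizes.
#' @param params a [csc_params()].
#' @param dc_age_init which age classes receive the initial DCs (see
#'   Details).
#' @return a `csc_state`: list with `csc` (length-C vector), `dc`
#'   (`C x (M+1)` matrix of age classes `0..M`), `x` (rate multipliers),
#'   `barcode` and `C0`.
#' @export
csc_init <- function(table, params = csc_params(),
                     dc_age_init = c("1:M", "0:M-1", "0:M")) {
  stopifnot(inherits(table, "clone_table"), inherits(params, "csc_params"))
  dc_age_init <- match.arg(dc_age_init)
  if (any(abs(table$size - round(table$size)) > 1e-8)) {
    stop("csc_init() requires integer clone sizes")
  }
  N <- round(table$size)
  C <- length(N)
  M <- params$M
  csc <- pmin(round_half_up(params$csc0 * N), N)
  classes <- switch(dc_age_init,
    "1:M" = seq_len(M) + 1L,      # matrix columns for ages 1..M
    "0:M-1" = seq_len(M),
    "0:M" = seq_len(M + 1L))
  per_class <- pmin(floor((1 - params$csc0) * N / M),
                    floor((N - csc) / length(classes)))
  dc <- matrix(0, nrow = C, ncol = M + 1)
  dc[, classes] <- per_class
  left <- N - csc - length(classes) * per_class
  # remainder cells go to a random species; a population initialized
  # without stem cells must stay stem-free, so the CSC slot is excluded
  # when csc0 = 0
  n_species <- if (params$csc0 > 0) M + 2L else M + 1L
  for (i in which(left > 0)) {
    extra <- tabulate(sample.int(n_species, left[i], replace = TRUE), M + 2)
    if (params$csc0 > 0) {
      csc[i] <- csc[i] + extra[1]
      dc[i, ] <- dc[i, ] + extra[-1]
    } else {
      dc[i, ] <- dc[i, ] + extra[seq_len(M + 1L)]
    }
  }
  x <- if (params$sigma_r > 0) pmax(stats::rnorm(C, 1, params$sigma_r), 0)
       else rep(1, C)
  structure(list(csc = csc, dc = dc, x = x, barcode = table$barcode,
                 C0 = table$C0),
            class = "csc_state")
}

#' @export
print.csc_state <- function(x, ...) {
  cat(sprintf("<csc_state> %d clones, %g CSCs + %g DCs = %g cells\n",
              length(x$csc), sum(x$csc), sum(x$dc), sum(x$csc) + sum(x$dc)))
  invisible(x)
}

#' Total clone sizes of a CSC state
#'
#' Collapses the stem/differentiated compartments back to a [clone_table()]
#' (clone size = CSCs plus DCs of every age).
#'
#' @param state a `csc_state`.
#' @return a `clone_table`.
#' @export
csc_clone_table <- function(state) {
  stopifnot(inherits(state, "csc_state"))
  clone_table(state$csc + rowSums(state$dc), barcode = state$barcode)
}

#' Grow a CSC state by tau-leaping
#'
#' Applies the five per-clone transitions of the CSC model with Poisson leap
#' counts (clamped so no compartment goes negative): symmetric CSC division,
#' asymmetric division, symmetric commitment, DC division with ageing, and
#' death of DCs at the maximum age. Per-clone propensities are multiplied by
#' the clone's rate multiplier `X_i`. Growth stops when the total population
#' reaches `n_crit`, when the population goes extinct (a valid terminal
#' outcome, flagged in the return value), or after `t_max` simulated days.
#'
#' @param state a `csc_state` from [csc_init()].
#' @param params a [csc_params()].
#' @param tau leap step in days.
#' @param n_crit critical population size (cells).
#' @param t_max optional cap on simulated time in days (default `Inf`).
#' @return a list with `state` (grown `csc_state`), `elapsed` (days),
#'   `steps`, `extinct` (logical) and `stalled` (logical; `TRUE` when the
#'   population can never reach `n_crit`, e.g. all rate multipliers are 0).
#' @export
csc_tau_leap_grow <- function(state, params = csc_params(), tau = 5e-4,
                              n_crit = 4e6, t_max = Inf) {
  stopifnot(inherits(state, "csc_state"), inherits(params, "csc_params"))
  if (sum(state$csc) + sum(state$dc) <= 0) {
    stop("cannot grow an extinct population")
  }
  res <- cpp_csc_tau_leap(state$csc, state$dc, state$x,
                          params$p1, params$p2, params$p3,
                          params$r_csc, params$r_dc, tau, n_crit, t_max)
  out <- state
  out$csc <- res$csc
  out$dc <- res$dc
  list(state = out, elapsed = res$elapsed, steps = res$steps,
       extinct = res$extinct, stalled = res$stalled)
}

#' Doubling-time calibration scan
#'
#' For each combination of the maximum DC division number `M` and the DC
#' division rate `r_dc`, runs one growth phase of the CSC model from a
#' uniform initial population of `n_pass` cells to `n_crit`, computes the
#' population doubling time, averages over `reps` replicates, and reports
#' the deviation from a reference doubling time (19 hours by default, the
#' in-vitro value the model is calibrated against). Parameter sets whose
#' populations go extinct (or stall) before reaching `n_crit` yield `NA`.
#'
#' @param M_values,r_dc_values grids of values to scan.
#' @param params baseline [csc_params()] (its `M` and `r_dc` are overridden).
#' @param n_pass,n_crit initial and critical population sizes (cells).
#' @param n_clones number of clones in the uniform initial population.
#' @param tau leap step in days.
#' @param reps replicates per grid point.
#' @param reference_hours reference doubling time in hours.
#' @return a `data.frame` with columns `M`, `r_dc`, `doubling_time_hours`
#'   and `deviation_hours` (simulated minus reference).
#' @export
doubling_time_scan <- function(M_values, r_dc_values, params = csc_params(),
                               n_pass = 3e5, n_crit = 4e6, n_clones = 14000,
                               tau = 5e-4, reps = 5, reference_hours = 19) {
  stopifnot(length(M_values) >= 1, length(r_dc_values) >= 1)
  grid <- expand.grid(M = M_values, r_dc = r_dc_values)
  init <- clone_table(largest_remainder(rep(1, n_clones), n_pass))
  grid$doubling_time_hours <- NA_real_
  for (g in seq_len(nrow(grid))) {
    p <- params
    p$M <- as.integer(grid$M[g])
    p$r_dc <- grid$r_dc[g]
    dts <- rep(NA_real_, reps)
    for (rep_i in seq_len(reps)) {
      st <- csc_init(init, p)
      run <- csc_tau_leap_grow(st, p, tau = tau, n_crit = n_crit)
      if (!run$extinct && !run$stalled) {
        n_end <- sum(run$state$csc) + sum(run$state$dc)
        dts[rep_i] <- doubling_time(n_pass, n_end, run$elapsed * 24)
      }
    }
    if (any(!is.na(dts))) {
      grid$doubling_time_hours[g] <- mean(dts, na.rm = TRUE)
    }
  }
  grid$deviation_hours <- grid$doubling_time_hours - reference_hours
  grid
}
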