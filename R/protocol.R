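#' Iterated growth-and-passage experiment configuration
#'
#' Describes one in-silico passaging experiment: the population grows to the
#' critical size `n_crit`, `n_pass` cells are sampled at random and carried
#' to the next passage, and this cycle repeats `n_passages` times over
#' `n_replicates` independent replicates. Defaults mirror the standard
#' protocol: `n_pass = 3e5`, `n_crit = 4e6`, 30 passages, 10 replicates.
#'
#' `scale` divides `n_pass`, `n_crit` and (for the ABM) `n_master` and
#' `n_init` by a common factor, preserving the ~13.33-fold expansion per
#' passage. Scaled runs keep the protocol's structure while staying
#' desk-sized; clone-level drift is stronger at small scale because clones
#' hold proportionally fewer cells.
#'
#' @param model one of `"deterministic"`, `"stochastic"`, `"csc"`, `"abm"`.
#' @param n_pass cells carried through each passage.
#' @param n_crit critical population size triggering a passage.
#' @param n_passages number of growth/passage cycles, `>= 0`.
#' @param n_replicates number of independent replicates.
#' @param params model parameters: [growth_params()] for
#'   `"deterministic"`/`"stochastic"`, [csc_params()] for `"csc"`,
#'   [abm_params()] for `"abm"` (a default is built when `NULL`).
#' @param eval_point where metrics are measured: on the `n_pass`-cell
#'   post-passage sample (default, mirrors sequencing an aliquot) or on the
#'   full pre-passage population.
#' @param t_growth growth duration in days for the deterministic model
#'   (which has no intrinsic stopping size), default 3 days.
#' @param seed base seed; replicate `k` uses `seed + k`.
#' @param scale common down-scaling factor (`>= 1`).
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(model = c("stochastic", "deterministic",
                                        "csc", "abm"),
                              n_pass = 3e5, n_crit = 4e6, n_passages = 30,
                              n_replicates = 10, params = NULL,
                              eval_point = c("post-passage", "pre-passage"),
                              t_growth = 3, seed = 1L, scale = 1) {
  model <- match.arg(model)
  eval_point <- match.arg(eval_point)
  stopifnot(scale >= 1, n_passages >= 0, n_replicates >= 1)
  n_pass <- round(n_pass / scale)
  n_crit <- round(n_crit / scale)
  if (n_pass >= n_crit) stop("n_pass must be smaller than n_crit")
  if (is.null(params)) {
    params <- switch(model,
      deterministic = growth_params(n_crit = n_crit),
      stochastic = growth_params(n_crit = n_crit),
      csc = csc_params(),
      abm = abm_params())
  }
  if (model %in% c("deterministic", "stochastic")) {
    params$n_crit <- n_crit
  }
  if (model == "abm" && scale > 1) {
    params$n_master <- round(params$n_master / scale)
    params$n_init <- round(params$n_init / scale)
  }
  if (model == "abm") {
    params$n_init <- min(params$n_init, n_pass)
  }
  structure(list(model = model, n_pass = n_pass, n_crit = n_crit,
                 n_passages = n_passages, n_replicates = n_replicates,
                 params = params, eval_point = eval_point,
                 t_growth = t_growth, seed = as.integer(seed),
                 scale = scale),
            class = "experiment_config")
}

#' Initialize clone sizes from barcode read counts
#'
#' Scales read counts proportionally so the clone sizes total exactly
#' `n_pass` cells (largest-remainder rounding). The founder clone count
#' `C0` is the number of barcodes with nonzero reads; rare barcodes may
#' receive zero cells after scaling and are retained as size-0 clones.
#'
#' @param read_counts named numeric vector of barcode read counts (or a
#'   two-column `data.frame` with `barcode` and `count`).
#' @param n_pass total number of cells after the initial passage.
#' @return a [clone_table()].
#' @export
init_from_counts <- function(read_counts, n_pass) {
  if (is.data.frame(read_counts)) {
    read_counts <- stats::setNames(read_counts$count, read_counts$barcode)
  }
  read_counts <- read_counts[read_counts > 0]
  if (length(read_counts) == 0L) {
    stop("read counts must contain at least one positive entry")
  }
  clone_table(largest_remainder(read_counts, n_pass),
              barcode = names(read_counts))
}

#' Random passage of a grown population
#'
#' Samples `n_pass` cells to seed the next passage, the in-silico analogue
#' of pipetting an aliquot:
#' * integer clone tables: multivariate hypergeometric sampling without
#'   replacement across clones (sequential conditional [stats::rhyper()]
#'   draws);
#' * CSC states: joint multivariate hypergeometric sampling across all
#'   stem/age species, preserving each sampled cell's identity;
#' * ABM populations: uniform sampling of cells without replacement;
#' * real-valued (deterministic-model) tables: multinomial sampling with
#'   probabilities `N_i / n`.
#'
#' @param population a `clone_table`, `csc_state` or `cell_population`.
#' @param n_pass number of cells to keep (`<=` total population).
#' @param ... unused.
#' @return an object of the same class with `n_pass` cells in total.
#' @export
passage_sample <- function(population, n_pass, ...) {
  UseMethod("passage_sample")
}

# sequential conditional hypergeometric draws: exact multivariate
# hypergeometric sample of `k` cells from integer pools `counts`
mv_hypergeom <- function(counts, k) {
  total <- sum(counts)
  if (k > total) stop("cannot sample ", k, " cells from ", total)
  out <- numeric(length(counts))
  remaining <- total
  for (i in seq_along(counts)) {
    if (k <= 0) break
    ci <- counts[i]
    if (ci > 0) {
      drawn <- stats::rhyper(1, ci, remaining - ci, k)
      out[i] <- drawn
      k <- k - drawn
    }
    remaining <- remaining - ci
  }
  out
}

#' @rdname passage_sample
#' @export
passage_sample.clone_table <- function(population, n_pass, ...) {
  sizes <- population$size
  if (sum(sizes) < n_pass) {
    stop("population smaller than n_pass: cannot passage")
  }
  integerish <- all(abs(sizes - round(sizes)) < 1e-8)
  kept <- if (integerish) {
    mv_hypergeom(round(sizes), n_pass)
  } else {
    as.numeric(stats::rmultinom(1, n_pass, prob = sizes / sum(sizes)))
  }
  clone_table(kept, barcode = population$barcode)
}

#' @rdname passage_sample
#' @export
passage_sample.csc_state <- function(population, n_pass, ...) {
  pools <- cbind(population$csc, population$dc) # C x (M + 2) species
  if (sum(pools) < n_pass) {
    stop("population smaller than n_pass: cannot passage")
  }
  kept <- mv_hypergeom(as.vector(pools), n_pass)
  kept <- matrix(kept, nrow = nrow(pools))
  out <- population
  out$csc <- kept[, 1]
  out$dc <- kept[, -1, drop = FALSE]
  out
}

#' @rdname passage_sample
#' @export
passage_sample.cell_population <- function(population, n_pass, ...) {
  n <- length(population$rate)
  if (n < n_pass) stop("population smaller than n_pass: cannot passage")
  keep <- sample.int(n, n_pass)
  new_cell_population(population$barcode[keep], population$rate[keep],
                      population$tnext[keep], population$now,
                      population$barcodes)
}

# --- internal: uniform model driver interface -------------------------------
# each driver: init(counts, config) -> state;
#              grow(state, config)  -> list(state, elapsed, extinct)
#              passage(state, config) -> state
#              table(state) -> clone_table ; mean_rate(state) -> numeric or NA

model_driver <- function(config) {
  p <- config$params
  switch(config$model,
    deterministic = list(
      init = function(counts) {
        tab <- init_from_counts(counts, config$n_pass)
        clone_table(tab$size, tab$barcode, integer_sizes = FALSE)
      },
      grow = function(state) {
        grown <- deterministic_grow(state, p$r, config$t_growth)
        list(state = grown, elapsed = config$t_growth, extinct = FALSE)
      },
      passage = function(state) passage_sample(state, config$n_pass),
      table = function(state) state,
      mean_rate = function(state) NA_real_),
    stochastic = list(
      init = function(counts) init_from_counts(counts, config$n_pass),
      grow = function(state) {
        run <- tau_leap_grow(state, p)
        list(state = run$table, elapsed = run$elapsed, extinct = FALSE)
      },
      passage = function(state) passage_sample(state, config$n_pass),
      table = function(state) state,
      mean_rate = function(state) NA_real_),
    csc = list(
      init = function(counts) {
        csc_init(init_from_counts(counts, config$n_pass), p)
      },
      grow = function(state) {
        run <- csc_tau_leap_grow(state, p, n_crit = config$n_crit)
        list(state = run$state, elapsed = run$elapsed,
             extinct = run$extinct || run$stalled)
      },
      passage = function(state) passage_sample(state, config$n_pass),
      table = function(state) csc_clone_table(state),
      mean_rate = function(state) NA_real_),
    abm = list(
      init = function(counts) {
        master <- build_master_population(counts, p)
        pop <- draw_initial_population(master, p$n_init)
        if (p$n_init > config$n_pass) {
          pop <- passage_sample(pop, config$n_pass)
        }
        pop
      },
      grow = function(state) {
        run <- abm_grow(state, config$n_crit, p$sigma_m)
        list(state = run$pop, elapsed = run$elapsed, extinct = FALSE)
      },
      passage = function(state) passage_sample(state, config$n_pass),
      table = function(state) abm_clone_table(state),
      mean_rate = function(state) mean(state$rate))
  )
}

record_metrics <- function(driver, state, replicate, passage) {
  tab <- driver$table(state)
  n <- sum(tab$size)
  vals <- c(
    clones_remaining_fraction = sum(tab$size > 0) / tab$C0,
    gini = if (n > 0) gini_coefficient(tab) else NA_real_,
    major_clone_count = if (n > 0) count_major_clones(tab) else NA_real_,
    mean_division_rate = driver$mean_rate(state)
  )
  data.frame(replicate = replicate, passage = passage,
             metric = names(vals), value = unname(vals),
             stringsAsFactors = FALSE)
}

#' Run the iterated growth-and-passage experiment
#'
#' For every replicate: initialize the population from the barcode counts,
#' record passage-0 metrics, then repeat `n_passages` cycles of growth to
#' `n_crit` followed by random passage down to `n_pass` cells, recording
#' clone loss, Gini coefficient, major-clone count and (for the ABM) the
#' mean division rate at the configured evaluation point. A replicate whose
#' population goes extinct before reaching `n_crit` (possible in the CSC
#' model) is flagged and keeps its metrics up to the extinction.
#'
#' @param config an [experiment_config()].
#' @param initial_counts named vector of barcode read counts (or a
#'   `clone_table` / `data.frame`; see [init_from_counts()]).
#' @return a `metric_series`: a `data.frame` with columns `replicate`,
#'   `passage`, `metric`, `value`, with attributes `extinct_replicates` and
#'   `config`. Use [aggregate_metrics()] for replicate means and SDs.
#' @export
run_iterated_experiment <- function(config, initial_counts) {
  stopifnot(inherits(config, "experiment_config"))
  if (inherits(initial_counts, "clone_table")) {
    initial_counts <- stats::setNames(initial_counts$size,
                                      initial_counts$barcode)
  }
  driver <- model_driver(config)
  rows <- list()
  extinct <- integer(0)
  for (rep_i in seq_len(config$n_replicates)) {
    set.seed(config$seed + rep_i)
    state <- driver$init(initial_counts)
    rows[[length(rows) + 1L]] <- record_metrics(driver, state, rep_i, 0L)
    for (pass_i in seq_len(config$n_passages)) {
      run <- driver$grow(state)
      if (run$extinct) {
        extinct <- c(extinct, rep_i)
        break
      }
      state <- run$state
      if (config$eval_point == "pre-passage") {
        rows[[length(rows) + 1L]] <-
          record_metrics(driver, state, rep_i, pass_i)
        state <- driver$passage(state)
      } else {
        state <- driver$passage(state)
        rows[[length(rows) + 1L]] <-
          record_metrics(driver, state, rep_i, pass_i)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "extinct_replicates") <- unique(extinct)
  attr(out, "config") <- config
  class(out) <- c("metric_series", class(out))
  out
}

#' Aggregate a metric series over replicates
#'
#' @param series a `metric_series` from [run_iterated_experiment()].
#' @return a `data.frame` with columns `passage`, `metric`, `mean`, `sd`
#'   and `n_replicates`.
#' @export
aggregate_metrics <- function(series) {
  stopifnot(inherits(series, "metric_series"))
  agg <- stats::aggregate(value ~ passage + metric, data = series,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(passage = agg$passage, metric = agg$metric,
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                    n_replicates = agg$value[, "n"],
                    stringsAsFactors = FALSE)
  out[order(out$metric, out$passage), ]
}

#' Write a metric series as CSV
#'
#' @param series a `metric_series`.
#' @param path output file; columns `replicate`, `passage`, `metric`,
#'   `value`.
#' @export
write_metrics <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}
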