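#' Reference metric trajectories
#'
#' Holds, per metric and passage, the mean and SD across biological (or
#' synthetic) replicates that simulations are fitted against. Metrics are
#' named `"loss"` (fraction of founder clones lost, in `[0, 1]`) and
#' `"gini"`.
#'
#' @param df a `data.frame` with columns `metric`, `passage`, `mean`, `sd`;
#'   every `sd` must be positive.
#' @return a `reference_metrics` data frame.
#' @export
reference_metrics <- function(df) {
  need <- c("metric", "passage", "mean", "sd")
  if (!all(need %in% names(df))) {
    stop("reference metrics need columns ", paste(need, collapse = ", "))
  }
  if (any(df$sd <= 0)) {
    stop("every reference SD must be positive (zero SD makes the ",
         "loglikelihood undefined)")
  }
  structure(df[need], class = c("reference_metrics", "data.frame"))
}

#' Read/write reference metrics as CSV
#' @param path CSV file with columns `metric`, `passage`, `mean`, `sd`.
#' @return a [reference_metrics()] object.
#' @export
read_reference_metrics <- function(path) {
  reference_metrics(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_reference_metrics
#' @param ref a `reference_metrics` object.
#' @export
write_reference_metrics <- function(ref, path) {
  utils::write.csv(as.data.frame(ref), path, row.names = FALSE)
  invisible(path)
}

#' Convert an aggregated metric series to fitting metrics
#'
#' Maps the simulation metrics to the fitting vocabulary: clone-loss
#' fraction (`1 - clones_remaining_fraction`) and Gini coefficient, at the
#' requested passages, averaged over replicates.
#'
#' @param series a `metric_series` from [run_iterated_experiment()].
#' @param passages passages to extract.
#' @return a `data.frame` with columns `metric`, `passage`, `value`.
#' @export
sim_metric_means <- function(series, passages = c(10, 20, 30)) {
  agg <- aggregate_metrics(series)
  agg <- agg[agg$passage %in% passages, ]
  loss <- agg[agg$metric == "clones_remaining_fraction", ]
  gini <- agg[agg$metric == "gini", ]
  rbind(
    data.frame(metric = "loss", passage = loss$passage,
               value = 1 - loss$mean, stringsAsFactors = FALSE),
    data.frame(metric = "gini", passage = gini$passage,
               value = gini$mean, stringsAsFactors = FALSE)
  )
}

#' Gaussian loglikelihood of simulated metric trajectories
#'
#' Treats the deviation of each simulated metric mean from its reference
#' mean as Gaussian with the reference SD:
#' \deqn{\ell = \sum_{m} \sum_{P} -\frac{(\bar m(P) - \mu_{m,P})^2}
#'   {2 \sigma_{m,P}^2}}
#' summed over the selected metrics and the passages present in the
#' reference. The additive normalisation constant is dropped, so
#' `loglikelihood <= 0` with equality exactly when every simulated mean
#' equals its reference mean.
#'
#' @param sim_means `data.frame` with columns `metric`, `passage`, `value`
#'   (see [sim_metric_means()]); must cover every reference term.
#' @param ref a [reference_metrics()] object.
#' @param metric which metrics enter the sum: `"both"`, `"loss"` or
#'   `"gini"`.
#' @return the loglikelihood (a non-positive number).
#' @export
loglikelihood <- function(sim_means, ref, metric = c("both", "loss", "gini")) {
  metric <- match.arg(metric)
  ref <- reference_metrics(ref) # re-validates sd > 0
  if (metric != "both") ref <- ref[ref$metric == metric, ]
  if (nrow(ref) == 0L) stop("no reference terms selected")
  key <- function(d) paste(d$metric, d$passage)
  idx <- match(key(ref), key(sim_means))
  if (anyNA(idx)) {
    stop("sim_means is missing terms: ",
         paste(key(ref)[is.na(idx)], collapse = "; "))
  }
  sum(-(sim_means$value[idx] - ref$mean)^2 / (2 * ref$sd^2))
}

#' Likelihood grid sweep over (sigma0, sigma_m)
#'
#' Evaluates the ABM at every point of a rectangular grid of initial
#' division rate SDs (`sigma0`) and mutation SDs (`sigma_m`): each point
#' runs `n_reps` replicates of the iterated experiment, averages the
#' clone-loss and Gini trajectories, and scores them against the reference
#' with [loglikelihood()]. A point whose simulation fails is recorded as
#' `NA`, not dropped.
#'
#' @param sigma0_values,sigma_m_values grid axes (non-empty).
#' @param config an [experiment_config()] with `model = "abm"`; its
#'   replicate count is overridden by `n_reps`.
#' @param ref a [reference_metrics()] object.
#' @param metric metric selection passed to [loglikelihood()].
#' @param n_reps simulation replicates per grid point (default 10).
#' @param initial_counts barcode counts used to initialize every run.
#' @return a `likelihood_grid`: `data.frame` with columns `sigma0`,
#'   `sigma_m`, `loglik`, plus the per-point simulated means in attribute
#'   `sim_means`.
#' @export
grid_sweep <- function(sigma0_values, sigma_m_values, config, ref,
                       initial_counts, metric = "both", n_reps = 10) {
  stopifnot(length(sigma0_values) >= 1, length(sigma_m_values) >= 1,
            inherits(config, "experiment_config"), config$model == "abm")
  ref <- reference_metrics(ref)
  passages <- sort(unique(ref$passage))
  grid <- expand.grid(sigma0 = sigma0_values, sigma_m = sigma_m_values)
  grid$loglik <- NA_real_
  sims <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- config
    cfg$n_replicates <- n_reps
    cfg$params$sigma0 <- grid$sigma0[g]
    cfg$params$sigma_m <- grid$sigma_m[g]
    res <- tryCatch({
      series <- run_iterated_experiment(cfg, initial_counts)
      sm <- sim_metric_means(series, passages)
      list(ll = loglikelihood(sm, ref, metric), sm = sm)
    }, error = function(e) {
      warning("grid point (", grid$sigma0[g], ", ", grid$sigma_m[g],
              ") failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      grid$loglik[g] <- res$ll
      sims[[g]] <- res$sm
    }
  }
  attr(grid, "sim_means") <- sims
  attr(grid, "sigma0_values") <- sort(unique(sigma0_values))
  attr(grid, "sigma_m_values") <- sort(unique(sigma_m_values))
  class(grid) <- c("likelihood_grid", class(grid))
  grid
}

#' Best-fitting grid point
#'
#' Returns the grid point with the highest loglikelihood. Ties are broken
#' towards the smallest `sigma_m`, then the smallest `sigma0`; all tied
#' points are reported alongside. A warning is raised when the optimum lies
#' on the grid boundary (the true optimum may be outside the scanned range).
#'
#' @param grid a `likelihood_grid` from [grid_sweep()].
#' @return a list with `sigma0`, `sigma_m`, `loglik` and `ties` (a
#'   `data.frame` of all maximizing points).
#' @export
best_fit <- function(grid) {
  stopifnot(inherits(grid, "likelihood_grid"))
  ok <- !is.na(grid$loglik)
  if (!any(ok)) stop("no evaluated grid points")
  best <- max(grid$loglik[ok])
  ties <- grid[ok & grid$loglik == best, c("sigma0", "sigma_m", "loglik")]
  ties <- ties[order(ties$sigma_m, ties$sigma0), ]
  pick <- ties[1, ]
  s0 <- attr(grid, "sigma0_values")
  sm <- attr(grid, "sigma_m_values")
  on_boundary <-
    (length(s0) > 1 && pick$sigma0 %in% range(s0)) ||
    (length(sm) > 1 && pick$sigma_m %in% range(sm))
  if (on_boundary) {
    warning("best fit lies on the grid boundary; consider widening the grid")
  }
  list(sigma0 = pick$sigma0, sigma_m = pick$sigma_m, loglik = pick$loglik,
       ties = ties)
}

#' Write a likelihood grid as CSV
#' @param grid a `likelihood_grid`.
#' @param path output CSV with columns `sigma0`, `sigma_m`, `loglik`.
#' @export
write_likelihood_grid <- function(grid, path) {
  utils::write.csv(as.data.frame(grid)[c("sigma0", "sigma_m", "loglik")],
                   path, row.names = FALSE)
  invisible(path)
}
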