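#' Largest-remainder allocation
#'
#' Distributes `total` integer units over categories proportionally to
#' `weights`, using the largest-remainder (Hamilton) rule: each category gets
#' the floor of its exact share and the leftover units go to the categories
#' with the largest fractional parts. The result always sums to `total`
#' exactly and each count differs from the exact share by less than 1.
#'
#' @param weights non-negative numeric weights, at least one positive.
#' @param total non-negative integer total to allocate.
#' @return integer vector of the same length as `weights`, summing to `total`.
#' @export
largest_remainder <- function(weights, total) {
  if (length(weights) == 0L || all(weights <= 0)) {
    stop("largest_remainder() needs at least one positive weight")
  }
  if (total < 0) stop("total must be non-negative")
  exact <- weights / sum(weights) * total
  base <- floor(exact)
  left <- round(total - sum(base))
  if (left > 0) {
    frac <- exact - base
    take <- order(frac, decreasing = TRUE)[seq_len(left)]
    base[take] <- base[take] + 1
  }
  as.integer(round(base))
}

# Evaluate expr with the global RNG temporarily seeded with `seed`,
# restoring the caller's RNG state afterwards. Used for the master-seed
# contract of the ABM (identical barcode -> rate mapping across replicates).
with_fixed_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# round-half-up, the conventional "nearest integer" rule (base round()
# rounds half to even, which is not what the initialization rules intend)
round_half_up <- function(x) floor(x + 0.5)
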