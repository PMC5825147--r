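# Independent oracles used by unit and acceptance tests. These deliberately
# re-derive quantities by brute force or textbook algorithms, never through
# the package's production code paths.

# O(C^2) double-sum Gini: sum_ij |Ni - Nj| / (2 * C0 * n)
gini_brute_force <- function(sizes) {
  c0 <- length(sizes)
  sum(abs(outer(sizes, sizes, "-"))) / (2 * c0 * sum(sizes))
}

# Exact stochastic simulation (direct / first-reaction Gillespie) of the
# pure birth process: one event at a time, exponential waiting times with
# total propensity r * n, event assigned to a clone proportionally to N_i.
ssa_direct_birth <- function(sizes, r, t_end) {
  t <- 0
  repeat {
    n <- sum(sizes)
    t <- t + stats::rexp(1, r * n)
    if (t > t_end) break
    i <- sample.int(length(sizes), 1, prob = sizes)
    sizes[i] <- sizes[i] + 1
  }
  sizes
}

# closed-form survival probability of a clone of size s under a
# hypergeometric passage of k cells out of n
hyper_survival <- function(s, n, k) {
  1 - exp(lchoose(n - s, k) - lchoose(n, k))
}

# standard uniform clone-size table: C clones spread over n cells
uniform_table <- function(C, n) {
  clonesim::clone_table(clonesim::largest_remainder(rep(1, C), n))
}
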