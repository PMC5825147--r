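test_that("deterministic growth is exact exponential scaling", {
  tab <- clone_table(c(100, 50, 10))
  expect_equal(deterministic_grow(tab, r = 0, t_growth = 5)$size, tab$size)
  # doubling time of 19 hours: r = (24/19) * ln 2 per day doubles in 19 h
  r19 <- 24 / 19 * log(2)
  grown <- deterministic_grow(clone_table(100), r19, 19 / 24)
  expect_equal(grown$size, 200, tolerance = 1e-12)
  grown <- deterministic_grow(clone_table(3e5), r19, 3)
  expect_equal(grown$size, 3e5 * 2^(72 / 19), tolerance = 1e-12)
  # relative frequencies exactly invariant
  g <- deterministic_grow(tab, r = 0.7, t_growth = 2.3)
  expect_equal(g$size / sum(g$size), tab$size / sum(tab$size))
  expect_error(deterministic_grow(tab, 1, -1), "non-negative")
})

test_that("tau_leap_grow hits its stopping contract", {
  tab <- clone_table(c(500, 500, 0))
  run <- tau_leap_grow(tab, growth_params(n_crit = 1000))
  expect_equal(run$elapsed, 0) # already at n_crit: zero leaps
  expect_equal(run$table$size, tab$size)

  run <- tau_leap_grow(tab, growth_params(n_crit = 3000))
  expect_gte(n_cells(run$table), 3000)
  expect_equal(run$table$size[3], 0)          # extinct clone is absorbing
  expect_true(all(run$table$size >= tab$size)) # pure birth: non-decreasing
  expect_error(tau_leap_grow(clone_table(0)), "empty")
  expect_error(tau_leap_grow(clone_table(c(1.5, 2), integer_sizes = FALSE)),
               "integer")
})

test_that("tau-leap Monte Carlo mean matches the closed form", {
  set.seed(201)
  reps <- 200
  finals <- replicate(reps, {
    n_cells(tau_leap_grow(clone_table(1000),
                          growth_params(r = 1, n_crit = Inf),
                          t_max = 1)$table)
  })
  se <- stats::sd(finals) / sqrt(reps)
  expect_lt(abs(mean(finals) - 1000 * exp(1)), 3 * se)
})

test_that("tau-leap per-clone means match the exact direct-method SSA", {
  set.seed(202)
  reps <- 200
  sizes0 <- c(40, 25, 10, 5) # 80-cell population, well under 1e3
  tau_final <- replicate(reps, {
    tau_leap_grow(clone_table(sizes0), growth_params(r = 1, n_crit = Inf),
                  t_max = 1.5)$table$size
  })
  ssa_final <- replicate(reps, ssa_direct_birth(sizes0, r = 1, t_end = 1.5))
  for (i in seq_along(sizes0)) {
    diff <- mean(tau_final[i, ]) - mean(ssa_final[i, ])
    se <- sqrt(stats::var(tau_final[i, ]) / reps +
                 stats::var(ssa_final[i, ]) / reps)
    expect_lt(abs(diff), 3 * se)
  }
})

test_that("stochastic engines are reproducible bit-for-bit under a seed", {
  tab <- clone_table(rep(20, 50))
  run <- function() {
    set.seed(42)
    tau_leap_grow(tab, growth_params(n_crit = 3000))$table$size
  }
  expect_identical(run(), run())
  p <- csc_params()
  runc <- function() {
    set.seed(43)
    st <- csc_init(tab, p)
    r <- csc_tau_leap_grow(st, p, n_crit = 3000)
    c(r$state$csc, as.vector(r$state$dc))
  }
  expect_identical(runc(), runc())
})

test_that("csc_init follows the stated rounding rules and preserves totals", {
  p <- csc_params(csc0 = 0.05, M = 10)
  st <- csc_init(clone_table(100), p)
  expect_equal(st$csc + rowSums(st$dc), 100)     # total preserved exactly
  expect_gte(st$csc, 5)                          # round(0.05*100) + remainder
  expect_equal(sum(st$dc >= 9), 10)              # 10 classes get floor(95/10)

  # csc0 = 1: everything is a stem cell
  st1 <- csc_init(clone_table(c(7, 3)), csc_params(csc0 = 1))
  expect_equal(st1$csc, c(7, 3))
  expect_true(all(st1$dc == 0))

  # sigma_r = 0 gives unit multipliers; totals preserved on random tables
  set.seed(203)
  sizes <- stats::rpois(200, 30)
  st2 <- csc_init(clone_table(sizes), p)
  expect_true(all(st2$x == 1))
  expect_equal(st2$csc + rowSums(st2$dc), sizes)
  st3 <- csc_init(clone_table(sizes), csc_params(sigma_r = 0.5))
  expect_true(all(st3$x >= 0))
  expect_gt(stats::sd(st3$x), 0)
})

test_that("csc_beta classifies the three growth regimes", {
  expect_equal(csc_beta(csc_params(p1 = 0.5, p2 = 0.5, p3 = 0, r_csc = 1)),
               list(beta = 0.5, regime = "growth"))
  expect_equal(csc_beta(csc_params(p1 = 0.25, p2 = 0.5, p3 = 0.25))$beta, 0)
  expect_equal(csc_beta(csc_params(p1 = 0.25, p2 = 0.5, p3 = 0.25))$regime,
               "equilibrium")
  lo <- csc_beta(csc_params(p1 = 0, p2 = 0.5, p3 = 0.5, r_csc = 1))
  expect_equal(lo$beta, -0.5)
  expect_equal(lo$regime, "extinction")
})

test_that("pure-CSC parameters reduce the CSC engine to the birth process", {
  # p1 = 1 and no initial DCs: transitions 2-5 never fire
  set.seed(204)
  p <- csc_params(p1 = 1, p2 = 0, p3 = 0, csc0 = 1, r_csc = 1)
  reps <- 100
  finals <- replicate(reps, {
    st <- csc_init(clone_table(rep(100, 5)), p)
    run <- csc_tau_leap_grow(st, p, t_max = 1, n_crit = Inf)
    expect_true(all(run$state$dc == 0))
    sum(run$state$csc)
  })
  se <- stats::sd(finals) / sqrt(reps)
  expect_lt(abs(mean(finals) - 500 * exp(1)), 3 * se)
})

test_that("populations without stem cells go extinct and are flagged", {
  set.seed(205)
  p <- csc_params(csc0 = 0)
  st <- csc_init(clone_table(rep(50, 4)), p)
  expect_equal(sum(st$csc), 0)
  run <- csc_tau_leap_grow(st, p, n_crit = 1e9)
  expect_true(run$extinct)
  expect_equal(sum(run$state$csc) + sum(run$state$dc), 0)
})

test_that("long-run CSC fraction forgets the initial CSC percentage", {
  # iterate growth+passage so the age/type structure equilibrates, then
  # compare the stem cell fractions reached from 5% and from 50% seeds
  set.seed(206)
  frac_after <- function(csc0) {
    p <- csc_params(csc0 = csc0)
    st <- csc_init(uniform_table(50, 2000), p)
    for (cycle in 1:4) {
      st <- csc_tau_leap_grow(st, p, n_crit = 2e4)$state
      st <- passage_sample(st, 2000)
    }
    sum(st$csc) / (sum(st$csc) + sum(st$dc))
  }
  f5 <- frac_after(0.05)
  f50 <- frac_after(0.50)
  # both should approach the same equilibrium (~3% for the defaults);
  # tolerance is coarse Monte-Carlo
  expect_lt(abs(f5 - f50), 0.02)
  expect_lt(f50, 0.10)
})

test_that("doubling_time inverts exponential growth", {
  expect_equal(doubling_time(100, 200, 7), 7)
  expect_equal(doubling_time(3e5, 4e6, 71), 71 * log(2) / log(40 / 3),
               tolerance = 1e-12)
  expect_equal(doubling_time(3e5, 4e6, 71), 19.0, tolerance = 0.01)
  expect_error(doubling_time(100, 100, 5), "did not grow")
})

test_that("doubling_time_scan reports the calibration ridge and NAs", {
  set.seed(207)
  # scaled sizes keep this a seconds-level test
  scan <- doubling_time_scan(M_values = 10,
                             r_dc_values = c(0.7, 24 / 19, 2.6),
                             n_pass = 3e3, n_crit = 4e4, n_clones = 140,
                             reps = 2)
  expect_equal(nrow(scan), 3)
  expect_true(all(is.finite(scan$doubling_time_hours)))
  # faster-dividing DCs shorten the doubling time monotonically
  expect_true(all(diff(scan$doubling_time_hours[order(scan$r_dc)]) < 0))
  # the default r_dc sits nearest the 19 h reference
  expect_equal(which.min(abs(scan$deviation_hours)), 2L)

  # an extinction regime yields NA, not an error
  pext <- csc_params(p1 = 0, p2 = 0, p3 = 1, csc0 = 0.05)
  scan2 <- doubling_time_scan(M_values = 2, r_dc_values = 1, params = pext,
                              n_pass = 200, n_crit = 4e3, n_clones = 10,
                              reps = 2)
  expect_true(is.na(scan2$doubling_time_hours))
})
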