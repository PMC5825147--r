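---
title: "Models and methods: clonal dominance under iterated growth and passage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: clonal dominance under iterated growth and passage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonesim)
```

`clonesim` simulates iterated growth-and-passage experiments on barcoded
cell populations and asks which growth mechanism can generate the clone
loss and clonal dominance seen in such experiments. This vignette is the
package's own account of the models, the numerical choices, and the
boundaries of what its tests establish.

## The experimental template

A population of `n_pass` cells (3·10⁵ at full scale), split over `C0`
barcoded founder clones, grows until it reaches a critical size `n_crit`
(4·10⁶, about three days of growth at a 19-hour doubling time). A random
aliquot of `n_pass` cells seeds the next passage; the cycle repeats 30
times. Two facts about this protocol shape everything else:

* growth always runs to a *fixed size*, so for models in which all cells
  divide at one common rate the value of that rate is irrelevant — it only
  rescales time. We default it to 1/day.
* the passage bottleneck discards ~92.5% of cells, so small clones face a
  real extinction risk every cycle even without any selection.

## Dominance metrics

All metrics are computed over the **fixed founder set**: `C0` is frozen at
initialization and extinct clones stay in the table as zeros. The Gini
coefficient

$$G = \frac{1}{2C_0}\sum_{i=1}^{C_0}\sum_{j=1}^{C_0}\frac{|N_i-N_j|}{n}$$

is implemented through the sorted-rank identity
$G = \sum_i (2i - C_0 - 1)N_{(i)}/(C_0 n)$, which is algebraically equal to
the double sum but O(C log C); the test suite verifies the equality against
a brute-force O(C²) oracle on random tables. Two consequences of the fixed
founder set are worth keeping in mind: `G` is bounded above by
`(C0−1)/C0`, and it is bounded *below* by the extinct clone fraction — pure
drift-driven clone loss therefore raises `G` even when the surviving clones
stay perfectly even. Clone loss (percent of founders at size 0), the
dominance curve (cumulative clone share vs population share, sorted large
to small), and the major-clone count (clones holding strictly more than 1%
of the cells) complete the metric set. Metrics are computed per replicate
and then aggregated (mean, SD) across replicates; by default they are
evaluated on the post-passage sample of `n_pass` cells, mirroring the
sequencing of an aliquot — `eval_point = "pre-passage"` switches to the
full grown population. An empty population has no defined Gini, dominance
curve or major-clone count; those calls error rather than return 0.

## Growth engines

### Deterministic exponential growth

`deterministic_grow()` multiplies every clone by `exp(r t)`; sizes become
real-valued and relative frequencies are exactly preserved. Passage of a
real-valued table is a multinomial draw with probabilities `N_i/n` (the
hypergeometric reading is undefined for non-integer pools).

### Stochastic clone-level growth (tau-leaping)

`tau_leap_grow()` advances a pure birth process in fixed steps of
`tau = 0.0005` days: clone `i` gains `k_i ~ Poisson(r N_i τ)` cells per
leap, and leaps repeat until the total reaches `n_crit`. Numerical
choices:

* **Sampling.** Per leap the engine draws the total event count
  `K ~ Poisson(τ Σ λ_c)` and distributes `K` over channels proportionally
  to their propensities (cumulative-weight binary search). By Poisson
  thinning this is *distributionally identical* to independent per-channel
  draws, and it is what makes the full-scale problem (14,000 clones,
  ~6,000 leaps) run in seconds. The unit tests compare the leaping engine's
  per-clone means against an exact direct-method (event-by-event) stochastic
  simulation at small size; they agree within Monte-Carlo error.
* **Overshoot.** Growth stops at the first leap where the total is at or
  above `n_crit`; the overshoot is kept. Passage sampling only needs the
  total to be at least `n_pass`, so nothing downstream cares.
* **Determinism.** All stochastic engines consume R's RNG, so a
  `set.seed()` call makes any run bit-for-bit reproducible.

### Cancer stem cell model

Each clone is split into stem cells (CSCs) and differentiated cells (DCs)
of ages `0..M`. Five transitions fire per clone: CSC → 2 CSC (probability
`p1` of a CSC division at rate `r_csc`), CSC → CSC + DC₀ (`p2`),
CSC → 2 DC₀ (`p3`), DC_m → 2 DC_{m+1} for `m < M` (rate `r_dc`), and
death DC_M → ∅ (rate `r_dc`). Defaults: `p1 = p2 = 0.5`, `p3 = 0`,
`csc0 = 5%`, `M = 10`, `r_csc = 1/day`, `r_dc = 24/19/day`. The long-run
regime is `β = (p1 − p3) r_csc`: growth for `β > 0`, equilibrium at 0,
extinction below. Random death of CSCs and non-terminal DCs is deliberately
omitted — it only rescales the population growth rate. Counts for
cell-removing transitions are clamped per leap to the count available at
the start of the leap, the standard tau-leap safeguard against negative
populations. Extinction is a valid terminal outcome and is flagged, not
raised as an error.

**Initial age classes — a deliberate choice.** The model's verbal
description spreads the non-stem cells "evenly over the M DC species" with
`floor((1−csc0)N/M)` cells per class, but ages run `0..M`, i.e. M+1
classes. The package resolves the ambiguity by *calibration*: the default
parameter set is supposed to reproduce a 19-hour population doubling time
over one growth phase to within 1 hour. Measured by a mean-field ODE and
by stochastic runs, seeding ages `0..M−1` gives ≈17.4 h (1.6 h off),
seeding all of `0..M` gives ≈17.9–18.1 h (~1 h off), and seeding ages
`1..M` gives ≈18.8–19.5 h (well inside the band). `csc_init()` therefore
defaults to `dc_age_init = "1:M"`, with the other two readings available
as options. Cells left over by the floor/round rules go to a uniformly
random species of their clone; when `csc0 = 0` the CSC slot is excluded,
so a stem-free initialization stays stem-free (and, as every DC lineage
dies within `M` divisions, eventually goes extinct).

Per-clone division-rate heterogeneity (`sigma_r`) multiplies both rates of
clone `i` by `X_i ~ N(1, σ_r)` clamped at 0, drawn once per clone and
inherited — the clone-level analogue of heritable rate variation.

### Agent-based model

The ABM represents every cell: a barcode, a division rate, and a scheduled
next-division time in a binary event heap (first-reaction method; waiting
times `−ln R / r_i`). At division the parent's event is consumed and two
children are created — *both* draw fresh rates `r_p·max(Y,0)`,
`Y ~ N(1, σm)` (the description assigns a new rate "to each newly created
cell", which we read literally), and both are rescheduled. A child whose
`Y` is non-positive gets rate 0 and never divides. There is no cell death,
so the population size never decreases, and with `σ0 = σm = 0` the ABM is
the same Markov process as the clone-level birth model (verified by a
two-sample test in the suite).

Initialization follows a two-stage contract. A **master population** of
`n_master` cells (5·10⁶ full scale) is built once: barcodes are assigned by
largest-remainder rounding of the input read frequencies, and rates are
drawn under a fixed `master_seed` — rebuilding the master is a pure
function of `(counts, params)`, so the same cell carries the same rate in
every replicate. Each replicate then samples `n_init` cells uniformly
without replacement with its own stream. `n_init` is not stated anywhere
authoritative; it defaults to `n_pass` (3·10⁵), the most conservative
choice consistent with the protocol. Note the initialization carries no
within-clone rate correlation: the days of growth that precede a real
experiment would create one, and the model deliberately does not emulate
that interval.

**Scaled mode.** A full-scale ABM experiment needs ~10⁸ division events
over 30 passages. `experiment_config(scale = k)` divides `n_pass`,
`n_crit`, `n_master` and `n_init` by `k`, preserving the 13.33-fold
expansion per passage. Scaling does not preserve drift: clones hold `k`
times fewer cells, so bottleneck extinction is stronger at small scale.
Desk-scale conclusions about *relative* behaviour (selection vs neutral)
transfer; absolute clone-loss numbers do not.

## Passage sampling

"`n_pass` cells are selected randomly" is implemented as sampling without
replacement — the physical reading of pipetting an aliquot:

* integer clone tables: multivariate hypergeometric across clones,
  realized as sequential conditional `rhyper()` draws (exact, O(C));
* CSC states: one joint multivariate hypergeometric draw across all
  `C·(M+2)` species, so a sampled cell keeps its stem/age identity;
* ABM: uniform sample of cell indices;
* real-valued tables: multinomial (see above).

The suite checks the clone-survival probability of this scheme against the
closed form `1 − C(n−s, n_pass)/C(n, n_pass)` over 10⁴ draws.

## Initialization from read counts

`init_from_counts()` scales barcode read counts proportionally so the
total is exactly `n_pass` (largest remainder). The verbal rule
`N_i(0) = (n_pass/n_library)·reads_i` is dimensionally consistent only
when mean reads per barcode equal 1; proportional scaling is what it must
mean, and is what the package does. `C0` is the number of barcodes with
nonzero reads; barcodes whose share rounds to zero cells are kept as
size-0 founders.

## Likelihood fitting

`loglikelihood()` scores simulated metric means against reference
means/SDs as `ℓ = Σ −(m̄(P) − μ)²/(2σ²)`, summed over the chosen metrics
(clone-loss fraction, Gini, or both) and the passages present in the
reference ({10, 20, 30} by convention). The definition is an equality up
to an additive constant, which is dropped — so `ℓ ≤ 0` with equality iff
the simulation matches every reference mean. A zero reference SD is an
error, not an infinity. `grid_sweep()` evaluates a rectangular
`(σ0, σm)` grid with a fixed replicate count per point (10 by default,
fresh simulations per point, deterministic per-replicate seeds); failed
points are recorded as `NA`. `best_fit()` takes the argmax, breaks ties
toward the smallest `σm` then `σ0`, reports all tied points, and warns
when the optimum sits on the grid boundary. The suite validates the
machinery by self-consistency: a synthetic reference generated at a known
`(σ0, σm)` is recovered at, or adjacent to, the generating point of a
coarse 5×5 grid.

## Synthetic barcode data

The generators exist so every stage is testable offline:

* `synth_initial_distribution()` — uniform (sizes differ by at most 1) or
  log-normal right-skewed clone sizes (minimum size 1, exact total); the
  skew parameter maps monotonically to the initial Gini.
* `synth_reference_library()` — random distinct barcode sequences with
  Dirichlet(1) frequencies. It is labelled synthetic: it mimics the
  *format and invariants* of an admitted plasmid library, not real
  sequence content or error structure.
* `synth_fastq()` / `extract_barcodes()` — 4-line FASTQ with offset-33
  qualities; reads carry the clone's barcode with independent per-base
  substitution errors. Extraction is exact-match counting over a
  configurable barcode window, admitting reads whose mean per-base Phred
  score reaches the threshold (default 56, following the published
  pipeline's stated cutoff; its exact semantics are not recoverable, so
  both statistic and threshold are plain parameters). At zero error rate
  and passing qualities, extraction round-trips the counts exactly, for
  any seed.
* `contaminate_with_spurious_reads()` — adds
  `Poisson(rate · total · library frequency)` counts to every library
  barcode. This is an explicit stand-in model: real spurious reads are
  sequence-correlated. It reproduces the qualitative effect that matters:
  contamination resurrects extinct barcodes, so it biases measured clone
  loss down much more strongly than it moves the Gini coefficient — the
  reason fitting should prefer the Gini.

## What a green test does and does not establish

Green unit and acceptance tests establish that the engines implement the
stated processes (against independent oracles), that the calibrated CSC
defaults reproduce a ~19-hour doubling time, that selection on heritable
rate variation produces progressive dominance while the neutral and CSC
models do not produce dominance beyond their drift floor, and that the
fitting machinery is self-consistent at desk scale. They do **not**
establish anything about real sequencing data (no reads are downloaded),
nor that desk-scale absolute numbers transfer to full scale — drift does
not scale, as discussed above. One acceptance criterion is deliberately
left failing: at one-tenth scale the prescribed neutral configuration
starts clones at ~2 cells, drift extinguishes ~92% of them by passage 30,
and the fixed-`C0` Gini is bounded below by the extinct fraction, so its
passage-30 value necessarily exceeds the passage-1 value by far more than
the replicate SD. The criterion is kept as stated rather than weakened;
the measured numbers are in the test output.

## Known limitations

* No cell death (outside the CSC terminal class), no cell-cycle phase
  structure, no sibling-correlated division times, no spatial effects.
* The ABM master population omits pre-experiment clonal dynamics, hence no
  within-clone rate correlation at `t = 0`.
* The contamination and quality models are parameterised stand-ins.
* Full-scale fitting against published read data is supported by the same
  code paths but is hours-long and requires the external FASTQ archive; it
  is not exercised by the test suite.
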