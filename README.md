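# clonesim

Simulation and analysis of clonal dynamics in barcoded tumour cell
populations under iterated growth and passage.

## The problem

In cellular-barcoding lineage tracing, a polyclonal cell line is tagged with
~10<sup>4</sup> heritable DNA barcodes, grown in vitro until the culture
reaches a critical size, and a random aliquot is passed to the next culture.
Repeating this cycle, experimentalists observe two things: barcodes
disappear (clone loss), and a handful of clones come to hold most of the
population (clonal dominance). `clonesim` provides the in-silico machinery
to ask *which mechanism produces that pattern*:

* **deterministic growth** — every clone grows as
  `N_i(t + t) = N_i(t) e^{rt}`; only the random passage bottleneck acts;
* **stochastic clone-level growth** — a pure birth process simulated by
  tau-leaping, `N_i <- N_i + k_i`, `k_i ~ Poisson(r N_i τ)`;
* **cancer stem cell (CSC) growth** — an age-structured model in which stem
  cells divide indefinitely (symmetric / asymmetric / committed divisions
  with probabilities `p1, p2, p3`) while differentiated cells divide at most
  `M` times and then die; the long-run regime is set by
  `β = (p1 − p3) r_CSC`;
* **an agent-based model (ABM)** — every cell carries a barcode and a
  heritable division rate `r_i`; initial rates are `r0·max(X,0)`,
  `X ~ N(1, σ0)`, and each division mutates the children's rates by
  `max(Y,0)`, `Y ~ N(1, σm)`. Division events are processed with a
  first-reaction event queue (exponential waiting times `−ln R / r_i`).

Dominance is quantified over the *fixed* founder set of `C0` clones
(extinct clones enter as zeros) with the Gini coefficient

```
G = (1 / 2 C0) · Σ_i Σ_j |N_i − N_j| / n,
```

plus clone loss, dominance curves, and major-clone counts (> 1% of the
population). A likelihood grid sweep fits `(σ0, σm)` to reference
trajectories by maximising
`ℓ = Σ_m Σ_P −(m̄(P) − μ_{m,P})² / 2σ²_{m,P}`.

A synthetic-data layer (initial clone-size distributions, barcode reference
libraries, FASTQ reads with per-base qualities, spurious-read
contamination) makes the whole pipeline testable without any downloads.

## Worked example

A desk-scale ABM experiment (one-tenth of the in-vitro sizes, preserving
the 13.3-fold expansion per passage) with initial rate variation
`σ0 = 0.1` and mutation `σm = 0.002`:

```r
library(clonesim)
set.seed(7)
counts <- synth_initial_distribution(1400, 3e4)      # uniform clones
cfg <- experiment_config("abm", n_pass = 3e4, n_crit = 4e5, n_passages = 10,
                         n_replicates = 5, seed = 7,
                         params = abm_params(sigma0 = 0.1, sigma_m = 0.002,
                                             n_master = 5e5, n_init = 3e4))
series <- run_iterated_experiment(cfg, counts)
subset(aggregate_metrics(series), passage %in% c(0, 5, 10))
```

```
 passage                    metric  mean       sd n_replicates
       0 clones_remaining_fraction 1.000 0.000000            5
       5 clones_remaining_fraction 0.958 0.006488            5
      10 clones_remaining_fraction 0.707 0.012521            5
       0                      gini 0.121 0.001400            5
       5                      gini 0.477 0.008669            5
      10                      gini 0.771 0.010105            5
       0         major_clone_count 0.000 0.000000            5
       5         major_clone_count 0.000 0.000000            5
      10         major_clone_count 9.600 2.302173            5
       0        mean_division_rate 1.000 0.000394            5
       5        mean_division_rate 1.121 0.001899            5
      10        mean_division_rate 1.221 0.006511            5
```

Reading: 29% of founder clones are lost by passage 10, the Gini coefficient
climbs from 0.12 to 0.77, ~10 major clones emerge, and the mean division
rate rises 22% — selection of fast dividers in action. Setting
`sigma0 = sigma_m = 0` reproduces the neutral control in which no
progressive dominance develops beyond what drift in the bottleneck causes.

A command-line interface is available after installation via
`exec/clonesim` (subcommands `simulate`, `metrics`, `doubling-time-scan`,
`fit`, `count-barcodes`, `build-library`, `synth-fastq`, `contaminate`).

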