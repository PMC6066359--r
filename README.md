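# methosc

Models and statistics for genome-scale oscillations in DNA methylation
during the exit from pluripotency.

When embryonic stem cells transition from the naïve to the primed state,
the de novo methyltransferases (DNMT3A/B) are strongly upregulated while
the TET demethylases remain expressed, so 5mC marks are continuously
written and erased. `methosc` implements a biophysical account of what
this turnover does to single-cell methylomes, together with the
statistics needed to detect it in bisulfite-sequencing data, and
synthetic-data generators with known ground truth so every analysis step
can be validated end to end.

## What is implemented

**Delayed turnover model.** Genome-averaged concentrations of unmodified
(`u`) and methylated (`v`) cytosines follow the dimensionless delay
system

    u'(τ) = v(τ − Δτ) − u(τ) v(τ)
    v'(τ) = u(τ) v(τ) − v(τ)

where de novo methylation is autocatalytic (the `u v` term, from
cooperative DNMT3 binding) and demethylation completes a multi-step
removal pipeline after a delay `Δτ`. Above a critical delay the balanced
state loses stability through a Hopf bifurcation and methylation levels
oscillate. The package integrates this system (RK4 method of steps, with
linear-denovo, Hill-nonlinearity and time-dependent-rate variants), scans
the threshold, and cross-checks it against the characteristic equation of
the linearisation.

**Stochastic simulation.** A delayed Gillespie algorithm simulates the
corresponding master equation for integer counts (C, M, in-transit), and
a read-noise model (exponential coverage, mean 14.3, truncated at 5;
binomial positive reads) maps true methylation rates onto observed
single-cell rate distributions.

**Synchronization theory.** A discrete-phase lattice of CpG oscillators
with local (kernel) and global (mean-field) coupling is simulated
exactly; strong-disorder coarse-graining reduces it to a heterogeneous
Kuramoto ensemble, with the critical coupling
`κ̃c = 2 / (π a g(ω̃0))`, the second-moment synchronization condition for
heterogeneous couplings, and the near-critical `r ∝ √μ` scaling law.

**Methylome statistics.** Coverage-based tiling into windows of a fixed
number of informative CpGs; excess variance
`Var(m) / [m̄ (1 − m̄) / c̄]` over binomial technical noise; binomial null
bands; quadratic detrending; Lomb-Scargle spectral enrichment with a
Monte-Carlo null on the same (uneven) time grid; amplicon-panel scans
with boundary-peak rejection and Fisher enrichment; Hartigan dip-test
bimodality scans; methylation pseudo-time from CpG-dense regions; and
long-lived-transcript size-factor normalization for expression data.

**Modality theory.** The cross-cell distribution of global methylation
during de novo methylation, `p(m, τ) = ∫ f(m; m̄(Δτ)) g(Δτ; τ) dΔτ`,
under three generative scenarios (unimodal onset, bimodal onset,
oscillatory), including the early/late lognormal variance asymptotics
that make bimodality at low and high methylation a signature of
oscillations.

## Worked example

```r
library(methosc)
library(data.table)

# where does the delay system start to oscillate?
scan <- hopf_threshold_scan(delay_model_params(1, u0 = 1.6, v0 = 0.4,
                                               t_max = 1000),
                            seq(0, 10, by = 0.25))
scan$threshold
#> [1] 5

oscillation_summary(integrate_dde(delay_model_params(8, 1.6, 0.4,
                                                     t_max = 1000)))[
  c("period", "amplitude_v")]
#> $period       [1] 10.9
#> $amplitude_v  [1] 2.2

# single-cell cohort with a known density-dependent oscillation
g     <- genome_spec()
cells <- generate_single_cell_dataset(g, n_cells = 50, coherence = 0.9,
                                      seed = 1)
tiles <- tile_by_informative_cpgs(cells$calls, window = 50,
                                  all_positions = g)
ev    <- excess_variance(tiles)
ev[, bin := cut(cpg_density, c(0, 0.01, 0.02, 0.03, 0.05, 0.1, 1))]
ev[, .(mean_excess = round(mean(excess_var), 1), n_tiles = .N),
   by = bin][order(bin)]
#>            bin mean_excess n_tiles
#> 1:    (0,0.01]         1.0       8
#> 2: (0.01,0.02]        19.4      16
#> 3: (0.02,0.03]        70.3      16
#> 4: (0.03,0.05]        49.3      16
#> 5:  (0.05,0.1]         7.0       8
#> 6:     (0.1,1]         1.0      32
```

The onset of sustained oscillations sits at a dimensionless delay of 5,
and above threshold the period grows linearly with the delay. In the
single-cell cohort, the cell-to-cell variance of tile methylation
exceeds binomial technical noise (excess variance 1 means technical
noise only) most strongly in the 2-3% CpG-density bin — the
enhancer-like regime where the generated oscillation amplitude peaks —
while CpG-rich tiles (density above 10%) show no excess variability.

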