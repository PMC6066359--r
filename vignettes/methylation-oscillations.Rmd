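---
title: "Delayed turnover, synchronization, and the statistics of oscillatory DNA methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delayed turnover, synchronization, and the statistics of oscillatory DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`methosc` models how continuous turnover of 5-methylcytosine — de novo
methylation by DNMT3A/B against active removal initiated by TET
enzymes — can generate coherent, genome-scale oscillations in DNA
methylation during the exit from naïve pluripotency, and implements the
statistics that reveal such oscillations in bulk and single-cell
bisulfite sequencing. This vignette documents the models, their
assumptions, the tunable parameters, the synthetic-data design, and the
numerical choices, in the package's own terms. Everything quantitative
stated here is computed by the test suite or the `analysis/` drivers;
nothing is imported from external data.

## 1. The delayed turnover model

### Model and assumptions

Let `u(τ)` and `v(τ)` be dimensionless concentrations of unmodified and
methylated cytosines averaged over a large genomic region, with time in
units of the inverse demethylation rate and concentrations in units of
the ratio of the two conversion rates. The baseline system is

```
u'(τ) = v(τ − Δτ) − u(τ) v(τ)
v'(τ) = u(τ) v(τ) − v(τ)
```

Three modelling assumptions matter:

* **Autocatalysis.** De novo methylation is proportional to `u·v`:
  DNMT3A/B bind cooperatively, bind preferentially to methylated DNA,
  and methylate groups of neighbouring CpGs, so existing marks catalyse
  new ones. Consequently `v = 0` (a fully unmethylated genome) is a
  fixed point; the `linear_denovo` variant adds a small
  methylation-independent channel `ε·u` that removes this artefact.
* **A single delay.** Removal of 5mC proceeds through oxidised
  intermediates, excision and repair; a cascade of such reactions acts,
  to leading order, like a fixed delay `Δτ` between removal of the mark
  and reappearance of an unmodified cytosine. In-transit material is
  therefore implicit: the quantity
  `u + v + ∫_{τ-Δτ}^{τ} v(s) ds` is conserved, which the integrator
  preserves to tolerance (`conservation_defect()`).
* **Constant history.** Trajectories are defined by constant values
  `(u0, v0)` on `[-Δτ, 0]`. Function-valued histories are out of scope.

Constant solutions with nonzero methylation satisfy `u·v = v`, i.e.
`u = 1` (the balanced branch); its methylated level follows from the
conserved quantity as `v̄ = (u0 + v0 + Δτ·v0 − 1)/(1 + Δτ)`
(`stationary_v()`). As `Δτ` grows the balanced state destabilises
through a Hopf bifurcation and the system settles on a limit cycle; for
the reference history `(u0, v0) = (1.6, 0.4)` the scanned onset sits at
a dimensionless delay of about 5, and the period grows linearly with the
delay. The characteristic equation of the linearisation about
`(1, v̄)`,
`λ² + v̄ λ + v̄ (1 − e^{−λΔτ}) = 0`, gives an independent check: the
purely imaginary crossing is available in closed form
(`hopf_delay_critical()`: `ω = √(v̄(2−v̄))`,
`Δτ_c = (2π − arccos(v̄−1))/ω`), and a damped-Newton search for the
rightmost root (`linearized_threshold()`) classifies stability without
integrating.

### Numerics

Fixed-step RK4 by the method of steps, with linear interpolation of the
stored solution for the delayed argument. The default step is
`min(Δτ/200, 0.005)`; steps coarser than `Δτ/10` are rejected. Small
negative undershoots are clamped to zero to preserve positivity.
Oscillations are summarised from the roots of `dv/dτ`: the period is
the mean spacing of next-nearest roots and the amplitude the mean
absolute difference of consecutive extremal values, both over the last
10 cycles of a run of total time 1000. "Sustained" requires the
amplitude to exceed `amp_tol = 1e-3` and to drift by less than 5%
between the last two 10-cycle windows; decaying spirals therefore
classify as non-oscillating. The `hill` variant (saturating conversion
terms with thresholds `A`, `B` and exponents `m`, `n`) and the
`time_dependent_rates` variant (multiplicative schedules on the two
channels, defaulting to a logistic ramp, with the delayed completion
using the schedule value at initiation time) are exercised for
positivity and boundedness; they do not reduce to the baseline.

## 2. Stochastic turnover and read noise

The corresponding master equation for integer counts uses propensities
`α·C·M` (methylation) and `β·M` (demethylation initiation). The delay
is implemented in the standard delayed-Gillespie way: an initiation
removes one M immediately and schedules one C to appear a fixed `Δt`
later; scheduled molecules are inert while in transit. This reading
("initiate now, complete later") is the mechanistic counterpart of the
delayed loss term and keeps `C + M + in_transit` exactly conserved on
every path. With `Δt = 0` the algorithm reduces to the plain direct
method, which the tests verify distributionally against an independent
R implementation.

Two initial conditions are meaningful. The default starts with an empty
demethylation pipeline (nothing scheduled), conserving `C0 + M0`
exactly. `seed_history = TRUE` instead pre-fills the pipeline with a
Poisson stream of completions on `(0, Δt]` at rate `β·M0`, which is the
stochastic counterpart of the deterministic model's constant
pre-history; this is the initialisation under which the ensemble mean of
`M/(C+M)` tracks the delay model (dimensionless mapping
`u = (α/β)·C`, `v = (α/β)·M`, `Δτ = β·Δt`).

Sequencing noise: element coverage `s` follows a discretised
exponential (`s = ceiling(x)`, `x ~ Exp(mean 14.3)`) truncated below 5 —
implemented by the memoryless shift, which is equivalent in distribution
to rejection — and positive reads are `k ~ Binomial(s, r)` at the true
rate `r = M/(C+M)`. The truncated mean,
`min_cov − 1 + 1/(1 − e^{−1/μ})`, exceeds the raw mean 14.3 and is the
frozen oracle for the sampler. `rate_distribution()` pushes ensembles of
simulations through this model to produce time-resolved observed-rate
histograms; the driver `analysis/02_stochastic_turnover.R` runs the
reference parameter set `α = 0.001, β = 1, Δt = 6` (counts scaled so the
dimensionless state starts at `(1.6, 0.4)`), at 4,800 simulations by
default and 48,000 with `--full`.

## 3. Emergence of genome-scale coherence

### Lattice model

Each CpG cycles through `n_states` chemical states, a discrete phase on
`[0, 2π)` advancing at an intrinsic rate `ω_i`. Two couplings bias the
stepping: a local kernel `l(d) = exp(−d/ξ)` (normalised over ordered
pairs, overall strength `λ`) representing processive DNMT3A/B/L action
on neighbouring CpGs, and a global mean-field term in which site `i`
responds with strength `κ_i` to contributions `σ_j` of all other sites,
representing genome-wide feedback through nuclear DNMT3A/B abundance.
The bias enters as forward/backward step weights
`(1 ± sin(ε·Δφ))/2` with sharpness `ε = 0.5` by default. The simulation
is an exact direct-method CTMC with incremental rate updates; an
uncoupled site steps as a Poisson process with mean `ω t n/(2π)`, which
the tests verify. The order parameter is the contribution-weighted mean
phasor, normalised by the total contribution so `r ∈ [0, 1]`.

### Coarse-graining

Strong-disorder coarse-graining merges, at each step, the neighbouring
block pair with the strongest mutual coupling (ties to the lowest
index; merges restricted to genomic neighbours): block frequencies
average with CpG weights (`Σ n_i ω̃_i` is exactly conserved), the local
coupling per merged pair rescales with the inverse block size, and the
global terms transform as `κ̃ = κ/n`, `σ̃ = n·σ`. Merging stops when the
strongest remaining pair coupling falls to the smaller of the partner
blocks' frequency and response scales. Two implementation notes: the
pair coupling is evaluated with the same normalised kernel as the
lattice (a scalar "λ̃ versus κ̃" comparison is uninformative because both
scale as `1/n`); and for a uniformly spaced genome without density
contrast the procedure degenerates to all-or-nothing merging — the
flow is designed for genomes with CpG-density structure, where dense
clusters collapse into blocks and gaps terminate the flow.

The block-level description is a heterogeneous Kuramoto model,
`φ̇_i = ω̃_i + κ̃_i r sin(Ψ − φ_i)` with the self-consistent field
`r e^{iΨ} = N^{-1} Σ σ̃_j e^{iφ_j}`. Because the `κ̃ = κ/n` convention is
tied to the growing state count of block phases, direct integration of
the continuous equations requires rescaling the response by the number
of microscopic sites and by the linearised bias slope `ε`
(`rescale_for_meanfield()`); with that rescaling the coarse-grained
ensemble reproduces the full lattice's asymptotic order parameter within
0.1 in the well-ordered regime (tested on a 300-site, 30-cluster
lattice — deep synchrony is used because the deterministic mean-field
limit omits the lattice's stochastic stepping noise, which is `O(1/n)`
in the state resolution).

### Thresholds and scaling

With factorising disorder and contributions proportional to responses
(`σ̃ = a κ̃`), synchronization requires
`⟨κ̃⟩² + Var(κ̃) ≥ 2/(π a g(ω̃0))`; homogeneous coupling has the critical
value `κ̃_c = 2/(π a g(ω̃0))` (so heterogeneity in DNMT3 binding
*promotes* coherence through the second moment, and identical
frequencies, `g → ∞`, synchronize at arbitrarily small coupling). Near
threshold `r ≈ √(16 μ / (π κ̃_c³ (−g''(ω̃0))))` with
`μ = (κ̃0 − κ̃_c)/κ̃_c`. Numerical design: the scaling law is asymptotic,
so `critical_scaling()` uses a default grid `μ ∈ {0.02, 0.04, 0.07,
0.1}` (the exact self-consistent `r` deviates from the √μ law by >10%
beyond `μ ≈ 0.15`), integrates to `max(150, 8/μ_min)` to outlast
critical slowing down, and draws frequencies by quantile matching
(stratified Gaussian sample) because near threshold the sample-to-sample
variability of the realised frequency density otherwise dominates the
estimate; seeds vary the initial phases. The prefactor is reported as
the mean of `r/√μ` over the grid. For Lorentzian disorder the exact
relation `r² = 1 − κ_c/κ` is used in reverse to estimate the critical
coupling from supercritical simulations
(`estimate_critical_coupling()`); Cauchy frequency draws are truncated
at `|ω| < 50γ` for step-size control — such oscillators never lock and
contribute only incoherent background. The integrator's default step
resolves the 99.5% quantile of `|ω|` for the same reason.

## 4. Methylome statistics

* **Tiling.** Chromosomes are segmented greedily into consecutive
  blocks of exactly `window` (50 or 100) informative CpGs (at least one
  read pooled over samples); the trailing partial block is dropped. CpG
  density is the number of CpGs in the tile's genomic span (from the
  full CpG map, covered or not) divided by the span length; coordinates
  are 1-based inclusive throughout (Bismark-coverage convention).
* **Excess variance.** Per tile, the coverage-weighted variance of
  per-sample rates (frequency weights normalised to one) divided by
  `m̄(1−m̄)/c̄` with the coverage-weighted mean rate and the arithmetic
  mean coverage. On technical noise alone its expectation is
  `(n−1)/n`, so for the cohort sizes used (50+ samples) the calibration
  target of 1 is met within the stated ±0.1 without a small-sample
  correction; tiles with `m̄ ∈ {0, 1}` are omitted. Binomial null bands
  (`technical_null_bounds()`) resample counts at the observed coverages
  (default 1000 replicates, 2.5/97.5 percentiles).
* **Spectral enrichment.** Series share one (possibly uneven) grid; slow
  trends are removed as residuals of a second-order polynomial fit. The
  Lomb-Scargle normalised periodogram (classic phase-offset form,
  invariant under time-origin shifts) is evaluated per element and
  compared, period by period, with Gaussian white noise simulated on the
  identical grid (default `n_null = 1e4` in function calls; the type-I
  calibration in the acceptance suite pools 100 cohorts because powers
  at nearby periods are strongly correlated within a cohort). Enrichment
  is a one-sided Welch t-test of element powers against null powers,
  significant at p < 0.05. For the default bulk design (31 uniform
  points over 56.5 h) a 150-min tone lies beyond the Nyquist period of
  the grid and aliases to ~458 min; the default scan band (90-300 min)
  targets the period range of interest, where the aliased power still
  concentrates at the true period's grid point.
* **Amplicon scans.** Points with more than 100 reads; loci with more
  than 20 valid time points; quadratic detrending; Lomb-Scargle over
  90-180 min in 5-min steps. A locus is significant when its peak lies
  strictly inside the scan band (boundary peaks are sampling artefacts
  and are discarded) and the peak power beats the Monte-Carlo null of
  the *maximum* power (multiplicity-corrected by construction).
  Treatment and control significant-locus counts are compared by a
  one-sided Fisher exact test.
* **Dip test.** The Hartigan dip statistic is implemented in C++ from
  first principles: over distinct values with lower/upper ecdf steps,
  the minimal sup-distance to a convex (ascending) fit is half the
  maximal gap between the upper steps and the greatest convex minorant
  of the lower steps; dually for concave suffixes; the dip minimises
  over the mode placement, including modes at a data point where an
  atom absorbs the jump. Hand-derived exact values (two points: 1/4;
  equally spaced: 1/(2n); half-and-half atoms: 1/4; three equal atoms:
  1/6) and a numerical population-dip oracle validate it. P-values are
  Monte-Carlo against the uniform null (the least-favourable unimodal
  case; 2000 draws by default), with null tables cached per sample
  size; they are reported unadjusted at p < 0.05 (a Benjamini-Hochberg
  adjustment can be applied downstream but is off by default, matching
  common practice for these scans). Note that this test is
  conservative: at 4σ mode separation and n = 80 its power is well
  below one (the package's calibration tests assert the honestly
  measured powers; ~5σ separation is needed for 80% power).
* **Bimodality scans** bin tiles by CpG density or by across-cell mean
  methylation and report the fraction of dip-significant tiles per bin
  with a bootstrap 95% CI (resampling tiles).
* **Pseudo-time** is the unweighted mean methylation rate over tiles
  with CpG density between 10% and 15% (window 100), per cell; cells
  with fewer than 5 qualifying covered tiles are excluded. Downstream
  series (2-3%-density tiles charted against pseudo-time) are linearly
  detrended and rescaled by the expected technical variance, per tile
  and for the cross-tile mean.
* **Expression.** Size factors are median-of-ratios
  (`DESeq2::estimateSizeFactorsForMatrix`) computed on transcripts with
  lifetimes above the median (~7 h) — long-lived transcripts cannot
  follow 2-3 h methylation oscillations and so anchor the
  normalisation — and applied to all genes; output is natural-log of
  normalised counts plus one. Feature correlations are
  coverage-weighted Pearson (coverage as frequency weights, via
  `cov.wt`); the density convention for features counts all CpGs, not
  only informative ones.

## 5. The modality theory of de novo methylation

A cell's mean methylation follows the sigmoid
`m̄(Δτ) = 1/(1 + e^{−Δτ})` in a signed dimensionless time measured from
its half-methylation point. The mixture integral for the population
density is taken over unbounded Gaussian onset variability: the early
asymptotic branch (`m̄ ≈ e^{Δτ}`, variance
`u(μ)^{-2} e^{σ²}(e^{σ²}−1)` with `u = e^{−μ}`) requires `Δτ ≪ 0`, so
restricting elapsed times to be positive would make low methylation
unreachable; the quadrature (composite Simpson, 2001 nodes) spans ±6
onset standard deviations. The late branch has variance
`u(μ)² e^{σ²}(e^{σ²}−1)`; both are exact lognormal moments, verified by
Monte Carlo within 5% inside their regimes of validity (mean level
within 0.1 of the respective boundary), and the variance across a full
time sweep has a single interior maximum.

Three scenarios define the conditional density `f(m; m̄)`:
Gaussian (unimodal onset), Gaussian with a two-component onset mixture
(early lineage segregation), and an equal two-Gaussian mixture at
`m̄ ± A/2` (oscillatory; default `A = 0.3`, widths 0.05). Because the
methylation scale saturates, the oscillation midpoint is clamped to
`[A/2, 1 − A/2]`: near saturation the oscillation carves excursions
away from the boundary, with modes at `1 − A` and 1 — this is what
makes *late*-time bimodality visible, where a naive `m̄ ± A/2` mixture
would push a mode outside the unit interval and vanish. Mode counting
uses topographic prominence (≥5% of the global maximum). The resulting
signatures at the characteristic early/intermediate/late stages
(`onset_mean + {−4, 0, +5}`) are: always unimodal; bimodal only at
intermediate times; bimodal early and late but not in between. The
intermediate-time washout window is narrow for the default parameters —
the onset-induced spread of `m̄` is capped near 0.26 by the requirement
that the logit-normal stage distribution itself stay unimodal
(`onset_sd < ~1.4`), which is comparable to `A` — an intrinsic feature
of the logistic-plus-Gaussian parametrisation worth keeping in mind
when choosing observation times.

## 6. Synthetic-data design

The generators define the study conditions under which every statistic
is validated:

* **Genome.** One synthetic chromosome of contiguous density blocks
  (0.5% to 18%, regular CpG spacing, realised density within 10% of
  target; 100 CpGs per block so blocks tile cleanly into 50/100-CpG
  windows). The ground-truth oscillation amplitude is log-Gaussian in
  density, peaking at 2.5% (`A0 = 0.22`, log-width 0.55) with a soft
  cutoff above 10% — a smooth stand-in for the observed divergence of
  biological variability near 2.5% density and its suppression in
  CpG-rich regions.
* **Steady-state single cells.** One oscillator phase per cell; block
  phases mix the cell phase with independent jitter (weight
  `coherence`); reads per covered CpG from the noise model (exponential
  mean 14.3, truncated at 5) with per-cell CpG dropout (default 0.3).
  `amplitude_scale = 0` yields technical-noise-only cohorts for
  calibration.
* **Epiblast-like cohort.** Cells carry developmental ages; CpG-poor
  blocks follow sigmoidal de novo trajectories with block-specific
  onset midpoints (uniform, half-range 3 transition-widths, so
  saturated-low, transit and saturated-high regions are all populated);
  CpG-dense blocks share a common midpoint and anchor pseudo-time.
  `age_cycles > 0` locks the oscillator phase to age (the regime probed
  by pseudo-time spectra); `age_cycles = 0` draws phases independent of
  age — the regime assumed by the onset-overshadowing argument, and the
  one used for modality-pattern checks. The default coherence is 0.5:
  with near-perfect coherence a single cohort-level phase draw makes
  all per-tile dip tests rise and fall together, and binned fractions
  lose meaning.
* **Bulk release time course.** 31 time points over 56.5 h in
  triplicate; block rates follow a logistic rise (0.15 to 0.6, midpoint
  15 h) plus the density-dependent oscillation at 150 min; replicate
  jitter sd 0.01; 200× binomial coverage per CpG.
* **Amplicon panel.** 14 treatment plus 14 control loci, 47 points at
  20-min spacing, Poisson coverage (mean 400); a fraction (default
  4/14) of treatment loci oscillates at 150 min with amplitude 0.08.
* **Expression.** 200 genes × 200 cells including the eight enzyme
  genes; the Dnmt/Tet log-expression summary is constructed to share a
  target squared correlation (default 0.06) with the true global
  methylation; lifetimes are lognormal with median ~7 h.

What the generators deliberately do **not** emulate: genome sequence
and annotation realism, read-level artefacts (bisulfite conversion
errors, mapping), strand structure, cell-cycle effects, replicate batch
structure, and region-to-region amplitude heterogeneity beyond the
density law. Passing the recovery suite therefore demonstrates that the
estimators detect what they claim to detect under binomial sampling and
the stated designs — not that real data will be as clean.

## 7. Problem sizes and reproducibility

All stochastic stages take explicit seeds, and generated datasets
round-trip bit-identically through the Bismark-coverage writers and
readers. The test and analysis runs use: Hopf scans of 41 delays at
total time 1000; 500 delayed-Gillespie paths of a 10,000-site region
for the mean-field check; Kuramoto ensembles of 1000-2000 oscillators;
single-cell cohorts of 50-80 cells over ~4,800-12,000 CpGs; spectral
nulls of 3,000-20,000 series (the reference analysis used orders of
magnitude more; the calibration properties do not depend on the null
size beyond Monte-Carlo resolution, which is why the scaled-down nulls
are adequate); and dip-test null tables of 2000 draws per sample size.

## 8. Known limitations

* The delay model's balanced-branch analysis assumes the constant
  history; different history classes shift the threshold.
* The delayed-Gillespie reading "initiate at `β·M(t)`, complete at
  `t + Δt`" is a modelling choice; a literal delayed-loss term with
  `M(t − Δt)` would permit transient negative excursions and is not
  implemented.
* The lattice-to-Kuramoto correspondence is quantitative only in the
  well-ordered regime; near threshold the lattice's intrinsic stepping
  noise (absent from the deterministic mean-field equations) depresses
  the order parameter.
* The dip test's power at moderate mode separations is intrinsically
  limited (see Section 4); bimodality-scan fractions are best read
  comparatively across bins, not as absolute prevalence.
* Pseudo-time assumes CpG-dense regions rise monotonically and carry no
  oscillation; violations (e.g. global demethylation phases) would
  corrupt the ordering.
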