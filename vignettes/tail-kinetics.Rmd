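---
title: "Modelling deadenylation and decay from poly(A)-tail chase data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling deadenylation and decay from poly(A)-tail chase data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailchase)
```

## The measurement and the model

Nanopore direct RNA sequencing reports an estimated poly(A)-tail length for
every read. In a chase experiment (transcription shut-off, export block, or
stress-induced shut-down) the cytoplasmic mRNA pool receives no new input,
so the sampled tail-length distribution at each timepoint is a snapshot of
ongoing deadenylation and decay. `tailchase` models those snapshots at three
levels.

**The tail-length law.** A steady tail-length profile is described by a
modified gamma distribution on integer adenosine counts,

$$p(i) \;\propto\; \tanh(\beta i)^{\gamma_\mathrm{shape}}
  \, e^{-\gamma_\mathrm{rate}\, i}.$$

The $\tanh$ factor is a mean-field description of Pab1 binding: each
adenosine contributes equally and additively to the interaction, so
protection saturates once one Pab1 footprint (~20 A) is covered. With
$\beta = 0.096$ per adenosine, `pab1_protection(20)` is 0.96, anchoring the
sharp left shoulder that real profiles show at 20 A, where decapping starts
to dominate. On the right arm, where $\tanh(\beta i) \approx 1$, the law is
geometric: the abundance ratio of tails differing by one adenosine is
$e^{-\gamma_\mathrm{rate}}$, a property used repeatedly below.
$\gamma_\mathrm{shape}$ has no direct mechanistic reading, but by analogy
with the Erlang distribution $\gamma_\mathrm{shape}+1$ counts the critical
events on the way to decay; empirical control profiles sit in the 3.5–4
range. $\beta$ is a fixed constant of the package, not a fitted parameter:
it encodes the Pab1 footprint, and refitting it per dataset would let it
absorb measurement artefacts.

**The kinetics.** Deadenylation is taken to be distributive with a constant
microscopic rate $k$ (adenosines/min), giving the chain of coupled
first-order reactions

$$\frac{dx_i}{dt} = -k x_i + k x_{i+1}, \qquad x_{N+1}=0 ,$$

whose closed-form solution is a Poisson convolution with
$\alpha = k t$ (`analytic_evolve()`); `ode_evolve()` integrates the same
system numerically and serves as an independent oracle (the two agree to
1e−8 per bin in the tests). The zero-length bin drains out of the system:
tails shortened to nothing leave the polyadenylated pool rather than piling
up, which matches the absence of a short-tail peak in real chases. The
protected variant multiplies the solution by $\tanh(\beta i)^{\alpha}$,
implementing accelerated loss of deprotected tails; the exponent follows the
closed form verbatim, which couples protection strength to elapsed time — a
deliberate, admittedly stylised choice (a fixed exponent is available via
`protection_exponent`).

**Apparent vs microscopic rate.** In a mixed population the loss of tails of
length $i$ is partly refilled from length $i+1$, so a fit to any single
bin's decay sees only

$$k_\mathrm{app} = k\,(1 - e^{-\gamma_\mathrm{rate}}).$$

At $\gamma_\mathrm{rate}\approx 0.1$ this is a ~10-fold reduction: an
apparent 1.09 A/min (terminal adenosine half-life
$60\ln 2/1.09 \approx 38$ s) corresponds to a microscopic rate of
~10.9 A/min under the small-rate approximation
($1-e^{-\gamma}\approx\gamma$), or 11.45 A/min without it.
`apparent_to_microscopic()` reports both.

## Estimators

**Profile fitting** (`fit_modgamma`). Unweighted nonlinear least squares of
the normalised empirical density against the internally renormalised law,
with $\beta$ fixed. We fit the density rather than raw counts so replicates
of different depth are directly comparable; a count-weighted option exists
but is off by default. Initialisation is at the centre of the empirically
observed ranges (shape 3.7, rate 0.10), with a deterministic ladder of
jittered restarts; bounds are shape $\in [0, 30]$, rate $\in [10^{-4}, 1]$.
Fits on fewer than 30 reads or 10 occupied bins are refused, and
non-convergence is flagged rather than silently returned.

**New-synthesis decomposition** (`new_synthesis_residual`). Control samples
contain tails made shortly before harvest, clustering at 40–60 A. The
component is modelled as Gaussian in $\log_2(\text{tail length})$. The
default method fits the base law and the component *jointly* as a
two-component mixture: a sequential subtract-then-fit lets the flexible base
law absorb a large part of the bump (on synthetic controls with a known 20%
component, the sequential route recovers only ~10–11%, the joint route
20.1%). The sequential procedure is retained as `method = "subtract"`. The
joint decomposition assumes the non-new pool is modified-gamma shaped, which
holds at chase start but not for protection-eroded later snapshots — it is a
control-profile tool, not a general mixture solver.

**Position half-lives** (`position_half_lives`). Snapshots are internally
normalised, so they are first put back on an absolute scale by multiplying
each profile by its pA$^+$ recovery coefficient (`adjust_for_decay`). Each
adenosine rank is then fitted by log-linear least squares over the chase,
and the half-lives over positions 40–80 — where decapping and resupply
edge effects are minimal — are averaged into the transcriptomic
terminal-adenosine half-life, with a bootstrap CI over window positions
(1000 resamples, fixed seed). Two details matter:

* The control (t = 0) snapshot is excluded from the per-position fits by
  default. It is off-trend for two reasons: its new-synthesis component
  inflates exactly the 40–60 A region, and the depletion phenotype takes a
  finite time to establish. The latter is measured, not assumed:
  `estimate_time_shift()` fits the per-position exponentials on depletion
  timepoints only and returns the forward offset at which the control sits
  on those trends (on data constructed with a 2.67-min offset it recovers
  2.67 min). That offset is then applied as a forward shift of the control
  time in decay-rate fitting (`filter_policy(control_time_shift_min = ...)`),
  shortening the first interval; it is a decay-fitting correction only and
  is not applied to quantile deadenylation fitting.
* The descriptive exponential-plus-asymptote curve across positions allows
  a negative amplitude: with time-coupled protection the short-position
  half-lives approach the asymptote from below.

**Right-arm slope** (`right_arm_slope`). $\gamma_\mathrm{rate}$ can be read
directly as minus the slope of log density against tail length on the
geometric arm. The function defaults to the window 25–60 A; the kinetics
workflow instead uses 40–70 A on the first depletion snapshot, because under
time-coupled protection the erosion frontier reaches ~35 A within the first
few minutes and bends the 25–35 segment (on synthetic data the 25–60 window
underestimates the rate by ~14%, the 40–70 window by ~3.5%, the residual
being measurement-noise blur).

**Virtual-deadenylation matching** (`alpha_match`). Each observed snapshot
is compared against the chase-start profile evolved over a grid of
$\alpha$ values; the regression slope of $\alpha_\mathrm{best}$ on time
estimates $k$ independently of the per-position route, and the Pearson
correlation measures how well a constant rate explains the series. Ties
break toward the smaller $\alpha$ and grid-boundary optima are flagged.
When the tail-length measurement noise is known (`noise_cv`), candidate
profiles are convolved with the corresponding log-normal binning kernel
before comparison: the evolved profiles develop a sharp protection-erosion
edge that blurred observations can never match, and without the convolution
$\alpha_\mathrm{best}$ saturates at late times (slope biased ~40% low on
synthetic data; essentially exact with it). The default grid upper bound
(15) suits sub-2-minute chases at 10.9 A/min; the workflows pass
`alpha_max = 180` for a 15-minute chase, using a coarse grid plus continuous
refinement inside the bracketing interval.

**Quantile rates** (`compute_quantiles`, `quantile_deadenylation_rate`,
`decay_rate`, `transcript_rate_table`). For individual transcripts the
profile machinery is underpowered, so rates are computed from trajectories
of the upper quantile tail lengths (75–95th; linear-interpolation
estimator). Filtering follows three rules: quantile estimates from fewer
than 10 reads are discarded; values above the control (reference) value are
removed (yeast lacks cytoplasmic adenylases, so increases are artefacts);
and negative pairwise coefficients that survive the reference filter are
kept unclamped, since clamping would bias rates upward. Each consecutive
usable pair gives a relative coefficient $c=\ln(L_1/L_2)/\Delta t$ (1/min);
its per-adenosine shortening rate is $c\sqrt{L_1 L_2}$ (A/min), the quantity
on which the terminal-adenosine half-life $60\ln 2 / \mathrm{rate}$ is
defined — the relative coefficient alone would make the half-life depend on
the unit of tail length. Intervals are averaged within a level with equal
weights (the pairwise formula is already per-minute), then across the upper
levels, then across replicates (mean of means); half-lives are recomputed
from the averaged constants so the $\ln 2$ duality holds exactly in the
output tables. mRNA decay constants use the same pairwise log-ratio on
abundance series.

**Abundance normalisation** (`normalize_abundance`). Spike-in-contaminated
transcripts (ENO2 by default) are removed before the library size is
computed; missing counts become 0.01 so log-ratios stay defined. Two scales
are offered. Counts per million corrects technical depth differences between
runs, but it also removes any decay component shared by the whole library —
on a chase this recentres decay constants on the library mean, and the
above-reference filter then censors every slower-than-average transcript.
When depth is proportional to the surviving RNA pool (as in the synthetic
generator, or spike-in-anchored libraries), `scale_mode = "none"` keeps the
absolute scale and avoids both artefacts. The package defaults to CPM for
real libraries and documents the choice per workflow.

## The synthetic chase generator

`truth_spec()`/`gen_chase()` produce complete DRS-like chases with known
ground truth; every estimator above is tested against it.

What it emulates: a heavy-tailed abundance distribution (a configurable top
block of transcripts carrying ~60% of reads, Zipf falloff within blocks);
per-transcript modified-gamma tail profiles (shapes uniform in 3.5–4, rate
0.1 by default); a 40–60 A new-synthesis component in control samples only
(20% of reads, Gaussian in $\log_2$ length around 50 A) — depletion shuts
synthesis off; exponential read-count decay with per-transcript constants
(log-normal, median $\ln 2/9.7$ per min, the scale of measured yeast mRNA
half-lives); multiplicative log-normal tail-measurement noise (CV 10% by
default — tail callers are noisy but no calibrated magnitude is available,
so robustness tests vary it); a 5% non-PASS QC tag rate; and per-timepoint
pA$^+$ recovery coefficients recorded as the surviving tail-mass ratio.

Two evolution modes:

* `mode = "analytic"` evolves each transcript's chase-start profile by the
  protected closed form — exactly the functional form the population
  estimators assume, which makes it the right benchmark for the
  position-half-life and $\alpha$-matching routes (their recovery of $k$
  is then a test of the estimators, not of model mismatch).
* `mode = "molecule"` draws each read as a molecule: birth tails from the
  profile truncated at the nuclear polyadenylation bound (90 A), Poisson
  shortening, and a decapping hazard (3/min) for the time the tail has
  spent below 20 A. The survivor law is available in closed form (the dwell
  time below threshold depends only on the observed length), so sampling is
  exact and fast. This mode produces genuinely declining per-transcript
  quantile trajectories — the signal the quantile estimator ranks — and
  drives the per-transcript benchmarks, with decay constants rank-correlated
  to deadenylation rates through a Gaussian copula.

Presets fix the reference conditions: `mex67_chase` (50 transcripts × 2000
reads, control + five 3-min-spaced timepoints, 3 replicates, global
$k = 10.9$ A/min, analytic mode — timepoint spacing exceeds the 2.67-min
depletion-onset lag and the span covers ~1.5 median mRNA half-lives),
`transcript_panel` (200 transcripts, per-transcript $k$ log-normal around
10.9 A/min, rank correlation 0.7 with decay, molecule mode, 4-min spacing
to 20 min), and `burst` (near-delta initial distribution at 60 A). These
problem sizes keep the full test suite under a minute while leaving
per-bin and per-transcript sampling errors small; all generation is
deterministic under a fixed seed, byte for byte.

What the generator does not emulate — and what passing tests therefore do
not show about real data: basecalling or alignment errors and their
length-dependent biases; the reduced DRS capture efficiency of short-tailed
RNAs; transcript-specific tail-caller failure modes; time evolution of
$\gamma_\mathrm{shape}$/$\gamma_\mathrm{rate}$ beyond what the assumed
kinetics induce; non-distributive (processive) deadenylase behaviour; and
any coupling between decay and deadenylation other than the imposed rank
correlation (in the molecule mode, read-count decay and tail kinetics are
deliberately decoupled bookkeeping, so transcripts can retain counts after
their tail pool is exhausted — tail tables are then empty while abundance
follows its own constant).

## Numerical choices

ODE integration uses `lsoda` at `rtol = 1e-12`, `atol = 1e-14`, tight enough
that the oracle-equivalence tolerance (1e−8 per bin) reflects the closed
form, not the integrator. The Poisson convolution is evaluated by shifting
with `dpois` weights (O(N²), N = 250, microseconds per call). Half-up
rounding at 1-adenosine resolution is applied at ingest, because the law is
defined on integer residue counts. Quantiles use the linear-interpolation
estimator (type 7). Bootstrap CIs resample window positions with a fixed
seed. All internal times are minutes; adenosine half-lives are reported in
seconds and mRNA half-lives in minutes, converted at the reporting boundary
only.

## Known limitations

* **Quantile rates measure distribution contraction, not enzymatic speed,
  on quasi-stationary populations.** On the geometric right arm of a
  modified-gamma population, distributive deadenylation at constant $k$
  decays every bin at the same rate $k(1-e^{-\gamma_\mathrm{rate}})$, so
  the *normalised* distribution — and with it every quantile — is nearly
  stationary; with time-coupled protection the left-side erosion actually
  pushes upper quantiles upward. Declining quantile trajectories in real
  chases therefore carry information that the idealised population model
  does not reproduce: bounded birth tails, evolving profile parameters, and
  transcript mixture effects. Concretely, on the analytic-mode reference
  chase the whole-transcriptome upper-quantile rate evaluates to
  ~0.37 A/min against an apparent rate of 1.04 A/min — the two estimators
  agree in rank-ordering transcripts (molecule-mode benchmark, Spearman
  ρ ≈ 0.63 against a construction of 0.64) but not in absolute scale under
  these idealised conditions. Users should treat per-transcript quantile
  rates as comparative, not enzymatic, quantities — which is also how the
  per-transcript tables are meant to be read.
* The time-coupled protection exponent makes late-time profile fits of the
  plain law degenerate (the eroded shape leaves the modified-gamma family);
  parameter-trend fitting is accordingly most meaningful over early
  timepoints or on data that stay within the family.
* $\beta$, the decapping threshold (20 A), the birth bound (90 A) and the
  decapping hazard (3/min) are fixed scientific constants of the package,
  chosen from footprinting, profile-shoulder and polyadenylation-limit
  evidence; none is refitted from data.
* The recovery coefficients are taken as known (measured pA$^+$ recovery);
  errors in them propagate multiplicatively into per-position rates.
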