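# tailchase

Deadenylation and decay kinetics of mRNA from poly(A)-tail chase experiments.

## The problem

In budding yeast, cytoplasmic mRNA decay is driven by stepwise shortening of
the 3' poly(A) tail (deadenylation by Ccr4-NOT and Pan2/3) until the tail can
no longer hold its last Pab1 molecule (~20 adenosines), at which point
decapping licenses rapid 5'→3' degradation. Nanopore direct RNA sequencing
(DRS) measures the tail length of every read, so a chase experiment — block
transcription or nuclear export, then sample the decaying cytoplasmic pool
over time — yields the full time evolution of the tail-length distribution.
`tailchase` turns those per-read tail-length tables into rate constants: the
microscopic (enzymatic) deadenylation rate, per-position adenosine
half-lives, and per-transcript deadenylation and mRNA decay rates.

## The model

The tail-length distribution is described by a protection-modified gamma law

    p(i) ∝ tanh(β·i)^γ_shape · exp(−γ_rate·i),        β = 0.096 /A

where `tanh(β·i)` is the saturable Pab1 protection factor (0.96 at one
~20-A footprint), `γ_rate` fixes the geometric ratio `e^(−γ_rate)` of
adjacent tail-length abundances on the right arm, and `γ_shape + 1` plays
the Erlang role of the number of critical events before decay.

Distributive deadenylation at a constant microscopic rate `k` gives the
coupled first-order system

    dx_i/dt = −k·x_i + k·x_{i+1},      x_{N+1} = 0,

with closed Poisson-convolution solution (α = k·t)

    x_i(t) = e^(−α) · Σ_{j≥i} n_j · α^(j−i)/(j−i)!,

optionally multiplied by `tanh(β·i)^α` to absorb decapping of deprotected
tails. Because a bin's loss is partly refilled from the bin above, a
population-level fit sees only the apparent rate

    k_app = k · (1 − e^(−γ_rate)),

so at `γ_rate ≈ 0.1` the enzymatic rate is ~10× the apparent one
(1.09 A/min apparent ↔ 38 s terminal-adenosine half-life ↔ ~10.9 A/min
microscopic). A quantile-based estimator covers transcripts with as few as
10 reads: exponential coefficients of the upper-quantile (75–95th)
tail-length trajectories, converted to per-adenosine shortening rates and
half-lives, plus pairwise-log-ratio mRNA decay constants from abundance
series.

Every estimator is validated against a built-in synthetic chase generator
with known ground truth (tail profiles, `k`, decay constants, new-synthesis
component, measurement noise), in two modes: the closed-form population
evolution above, and a per-molecule mode (Poisson shortening, decapping
hazard below 20 A, birth tails bounded by the nuclear polyadenylation
limit).

## Worked example

```r
library(tailchase)

# 1. a synthetic export-block chase: 50 transcripts x 2000 reads,
#    control + five timepoints (3-min spacing), 3 replicates,
#    truth: k = 10.9 A/min, gamma_rate = 0.1
run_synth(run_config(preset = "mex67_chase", out_dir = "chase_run",
                     seed = 42))

# 2. population kinetics: per-position half-lives -> apparent rate ->
#    microscopic rate; cross-checked by virtual-deadenylation matching
run_kinetics(run_config(run_dir = "chase_run", out_dir = "chase_run/kin",
                        seed = 1, alpha_max = 180, alpha_step = 2))
#> kinetics: apparent 1.039 A/min (half-life 40.0 s), microscopic 11.34 A/min,
#>           alpha slope 10.64 (r = 1.000)
```

Reading the output: the fitted per-position decay of decay-adjusted tail
levels over positions 40–80 gives the apparent rate 1.039 A/min (terminal
adenosine half-life 40 s); dividing by `1 − e^(−γ̂_rate)` with the right-arm
estimate `γ̂_rate = 0.096` recovers the microscopic rate 11.3 A/min, within
4% of the generator's truth (10.9 A/min). Matching each snapshot to virtual
deadenylation rounds gives an independent slope estimate of 10.6 A/min with
Pearson r = 1.000 against chase time.

Per-transcript rates and their decay–deadenylation correlation:

```r
run_quantile_rates(run_config(run_dir = "chase_run",
                              out_dir = "chase_run/rates",
                              abundance_scale = "none", seed = 1))
```

which writes `transcript_rates.tsv` (deadenylation coefficient in A/min,
terminal-adenosine half-life in s, decay coefficient in 1/min, mRNA
half-life in min, flags) and the Spearman correlation between the two rate
columns.

A command-line wrapper with the same subcommands
(`synth`, `fit-gamma`, `kinetics`, `quantile-rates`) is installed at
`inst/cli/tailchase`.

## Layout

- `R/tails_io.R` — tail-caller TSV ingest, QC filtering, histograms,
  abundance normalisation
- `R/modgamma.R` — the modified gamma law: density, NLS fitting, moments,
  new-synthesis decomposition, parameter time trends
- `R/kinetics.R` — ODE and closed-form evolution, decay adjustment,
  position half-lives, time-shift estimation, apparent↔microscopic
  conversion, α-matching
- `R/quantile_rates.R` — quantile trajectories, per-transcript
  deadenylation/decay rates, filters, group summaries
- `R/synthetic_data.R` — ground-truth chase generator and presets
- `R/pipelines.R` — workflow entry points and provenance
- `vignettes/tail-kinetics.Rmd` — the methods vignette: model, assumptions,
  estimator design, limitations
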