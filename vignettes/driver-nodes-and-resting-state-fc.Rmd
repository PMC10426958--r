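---
title: "Driver nodes and resting-state functional connectivity in Jansen-Rit brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Driver nodes and resting-state functional connectivity in Jansen-Rit brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Resting-state functional connectivity (FC) — the pattern of statistical
dependence between regional electrophysiological signals — is one of the most
used descriptors of whole-brain dynamics. Whole-brain network models couple a
neural-mass model per region through a structural connectome and ask which
ingredients of the model reproduce the empirical FC. `jrnet` implements one
such modelling framework built around a specific hypothesis: that a *small
set of driver regions receiving elevated noisy afferences* — the thalamus,
via the reticular activating system and its sensory relays — can push an
otherwise damped (non-oscillating) cortex into the functional interactions
seen in resting-state recordings.

The package provides every stage of that analysis: structural-connectome
handling with driver-region variants, a synthetic-data generator standing in
for unavailable subject data, the delayed stochastic Jansen-Rit network
simulator, alpha-band phase-locking metrics with dynamical-FC extensions,
coupling/drive parameter sweeps with working-point selection, and group-level
repeated-measures statistics.

## The node model

Each region is a Jansen-Rit cortical column: three interacting populations
(pyramidal cells, excitatory and inhibitory interneurons) whose average
post-synaptic potentials `y0, y1, y2` (mV) obey three second-order equations,
integrated as six first-order ones. Voltage is converted to firing rate by
the sigmoid

    S(v) = 2 vmax / (1 + exp(r (v0 - v)))

with `S(v0) = vmax`. The default parameters (`jr_parameters()`) are the
standard values: `A = 3.25` mV, `B = 22` mV, `a = 0.1` /ms, `b = 0.05` /ms,
`C1..C4 = 135, 108, 33.75, 33.75`, `vmax = 0.0025` /ms, `r = 0.56` /mV,
`v0 = 6` mV. The column's output signal is the pyramidal membrane potential
`y1 - y2`, the same quantity whose sigmoid drives inter-regional
communication.

As the mean input `p` (ms^-1) grows, the isolated column crosses two
qualitative transitions that the whole analysis leans on:

* below the onset (`p` up to about 0.11) it is a **damped oscillator**: a
  stable fixed point, activity decays, and with noisy input the output is a
  1/f-like fluctuation (`fixed_point()` returns the equilibria with
  stability flags; up to three coexist, with at most one stable);
* in a narrow window (first seen at `p = 0.12` on a 0.01 grid under this
  integrator) it falls onto the **slow limit cycle**: a high-amplitude
  (~10 mV peak-to-peak) oscillation around 2.5-4 Hz;
* above that (first seen at `p = 0.14`), a ~10-11 Hz **alpha limit cycle**
  with a few-mV amplitude, persisting up to `p` about 0.3.

These onsets were cross-checked against an independent adaptive ODE solver:
they are properties of the deterministic flow (for instance the fold that
creates the slow limit cycle sits near `p = 0.114`, and the transition to
the alpha cycle near `p = 0.137`, with zero initial conditions), and they
are insensitive to the modest input noise used here. Published descriptions
of the network experiment place these windows one 0.01 grid step lower
(`0.11-0.13` and `0.13-0.3`); in that setting the thalamic nodes were
embedded in a coupled network, where the coupling term contributes an
additional effective input of order 0.005-0.02 ms^-1, which shifts the
apparent onsets by about one grid step. For *isolated* nodes the values
above are what this parameterization produces, and the package reports them
as such.

## The network model

Nodes are coupled through a structural connectome: per subject a streamline
count matrix `w` and a mean tract-length matrix (mm). The input to node `i`
is

    input_i(t) = p_i + eta_i(t) + g * sum_j w_ji S[y1_j(t - d_ji) - y2_j(t - d_ji)]

with delays `d_ji` = tract length / conduction speed (15 mm/ms by default)
and a global coupling factor `g`. Weights are divided by their maximum per
subject before `g` applies, so `g` is comparable across connectomes; this is
an assumption (the empirical pipeline's scaling is not published) and it
fixes the position of the network bifurcation, which lands near `g = 7` for
the synthetic connectomes — within the network, rising `g` plays the role of
rising `p`, so the same damped/oscillatory distinction splits the coupling
axis into a *prebifurcation* and a *postbifurcation* regime
(`split_regimes()` labels sweeps either by the protocol threshold `g < 7` or
by an automatic extrema scan).

Integration is stochastic Heun at `dt = 0.1` ms with a circular delay
buffer. Per step and node the intrinsic input is drawn once from
`N(p_i, eta_i^2)` and held constant across both Heun stages, and the delayed
coupling term is evaluated once per step. This piecewise-constant noise
convention is stated rather than derived: the reference implementation's
discretization (including any sqrt(dt) scaling) is not recoverable, so
absolute `eta` values are comparable only within this package. `dt` is fixed
by default so that results are comparable across runs; halving `dt` moves
the limit-cycle spectral peak by well under 2%. Delays are rounded to
integration steps; the history buffer is pre-filled with the initial output
so early delayed reads are defined. Initial conditions are zero for all
state variables, and an initial transient (4 s for 60 s runs, 2 s for 10 s
runs) is discarded before any metric. The raw 10 kHz trajectory is low-pass
filtered and decimated to 1000 Hz, the sampling rate of the MEG recordings
the framework emulates.

One numerical point deserves emphasis: all zero-phase filtering
(anti-aliasing and band-pass) reflects the signal about its endpoints before
forward-backward filtering. Plain zero-padded `filtfilt` rings against the
JR output's +7 mV operating level and inflated post-transient extrema by a
factor of about 2.4 in early versions; the reflected variant reproduces the
adaptive-solver limit-cycle amplitude to four digits.

## Drive conditions and connectome variants

`drive_config()` sets the baseline cortical drive (`p = 0.09`,
`eta = 2.2e-8`, a damped, near-noise-free regime) and overrides the driver
group. The study contrast is `eta_driver = 0.022` (elevated afferences)
versus `2.2e-8` (none), crossed with three structural versions built by
`build_variant()`: `parceled` (driver nuclei kept separate), `single` (all
driver nuclei merged into one node: summed streamline counts,
weight-weighted mean lengths, within-group edges discarded) and `removed`.
The merge is an approximation — atlas-level parcellations derive the
single-node version from its own tractography — but it conserves the summed
driver-to-region streamline mass exactly, which is the property the tests
pin down.

## Synthetic data

The subject data behind the original analysis (MEG/MRI/dwMRI of ten adults)
are not deposited, so the `synthetic_data` module generates study-shaped
inputs:

* **Connectomes** (`generate_connectome()`): positions in a 150 mm box
  (drivers near the centre, like deep-brain structures), log-normal weights
  damped by an exponential distance decay (length 75 mm), and a driver group
  wired to a uniformly sampled, widespread cortical set. Defaults are
  calibrated to the two structural facts the hypothesis rests on: driver
  normalized degree near or slightly above the global mean
  (`driver_degree_factor = 1.05`) and driver normalized strength at roughly
  half the global mean (`driver_strength_factor = 0.48`, matching the
  reported ratio 0.111/0.231 of thalamic to global mean strength). Distances
  at 15 mm/ms give multi-millisecond delays. Default size is 20 cortical +
  6 driver nodes — large enough for structured FC, small enough for sweeps.
* **Cohorts** (`generate_cohort()`): per-subject seeds split
  deterministically from a master seed.
* **Pseudo-empirical targets** (`generate_pseudo_empirical()`): a hidden
  reference simulation (default 20 s) at truth parameters (g*, drive),
  reduced to a cortical alpha-band PLV matrix and a dFC correlation sample,
  plus additive Gaussian measurement noise (sd 0.02) on the FC
  off-diagonals, clipped to [0, 1]. The truth is stored for recovery
  experiments.

What the generator does *not* emulate: cortical geometry and atlas
parcellations, tractography biases, volume conduction and source leakage,
inter-subject variability structure beyond independent redraws, and any
empirical spectral content beyond what the model itself produces. Passing
tests therefore demonstrate internal consistency of the modelling chain, not
fidelity to any particular empirical dataset.

## Metrics

Functional connectivity is the alpha-band (8-12 Hz) phase-locking value:
4th-order Butterworth band-pass applied forward-backward (no net phase
shift), instantaneous phase from the analytic signal, and
`PLV_ij = |mean_t exp(i(phi_i - phi_j))|`, with 1 s edge regions excluded
from phase statistics. Model fit (`fc_similarity()`) is the Pearson
correlation between the strictly-upper triangles of simulated and reference
PLV matrices, always restricted to cortical regions on both sides (the
empirical restriction, applied symmetrically). Dynamical FC uses 4 s windows
with 50% overlap; the dFC matrix holds window-by-window correlations of the
PLV upper triangles, and `ks_distance()` compares the distributions of those
correlations (diagonal excluded — it is identically 1) between simulation
and reference. Spectra come from a Hann-windowed Welch estimator (4 s
segments, 50% overlap). SNR is defined as the post-transient half
peak-to-peak amplitude of driver signals divided by the driver noise sd —
"amplitude" is not pinned down in the published description, so values are
internally consistent but may differ from published ones by a constant
factor. Relative power is the ratio of mean total spectral area, cortex over
driver.

## Experiments and the working point

`g_sweep()` runs the full factorial (subject x condition x g x repetition)
with per-record derived seeds; `working_point()` averages repetitions,
restricts to a regime and picks the best fit (max r_PLV or min KSD, ties to
lower g). `grid_exploration()` produces the drive-parameter heatmap panels
(r_PLV, PLV mean/sd, spectral peak, driver SNR, extrema) over
`p_driver x g` or `eta_driver x g` grids at 10 s per cell.

A finding worth stating explicitly, because it shaped the package's recovery
interface: within the prebifurcation regime the simulated PLV *pattern* is
almost invariant to `g` (cross-`g` pattern correlations around 0.98, at the
level of same-`g` independent replicates), so the argmax of r_PLV does not
identify the generating coupling. The dFC correlation distribution does.
`recover_coupling()` therefore pools the dFC samples of all repetitions per
grid value and takes the argmin of the KS distance to the target sample as
`g_hat` (the argmax-r_PLV estimate is reported alongside). At desk scale
(20 s simulations, 3 repetitions, unit grid) this recovers a hidden `g* = 4`
within one grid step in 4 of 5 synthetic subjects; identifiability is
genuinely marginal at this simulation length, which is a property of the
method, not of the implementation.

## Group statistics

Working-point metrics feed `rm_anova_2way()` — a fully within-subject
two-factor ANOVA reporting F, generalized eta squared, Greenhouse-Geisser
epsilon (always) and the GG-corrected p whenever Mauchly's test rejects
sphericity at 0.05, with Shapiro normality diagnostics on cell residuals —
and `paired_wilcoxon_fdr()`, signed-rank tests with Cohen's d on paired
differences (mean/sd of the differences, the convention consistent with the
large published effect sizes) and Benjamini-Hochberg adjustment across the
comparison family. F statistics come from the univariate `aov`
decomposition and are cross-checked in the tests against both an independent
sums-of-squares oracle and the multivariate (`car`) route.

## Problem sizes and numerical choices

The published protocol (ten subjects, three 60 s simulations per cell,
`g` in [0, 60]) is configurable but not the default. The shipped experiments
and tests run: 26-node connectomes; 10 s simulations with 2 s transient for
explorations (20 s with 2 s transient for recovery); unit `g` grids spanning
the prebifurcation range; cohorts of 5. Tie-breaks always prefer lower `g`.
Degenerate inputs are errors with explicit messages (constant signals in
phase extraction, constant FC triangles in correlations, zero noise in SNR,
all-zero paired differences in the signed-rank test); divergent simulations
abort with a diagnostic in `simulate_network()` but are recorded as flagged
failed rows inside sweeps.

## Known limitations

* The noise discretization is a stated convention; absolute `eta` values do
  not transfer to other integrators.
* The `single` variant is a matrix-level merge, not a re-tractography.
* Pseudo-empirical targets share the model family with the simulations being
  scored — recovery experiments quantify identifiability, not empirical
  validity.
* Graph metrics assume the inverse-weight distance convention on
  max-normalized weights; published tables do not state their convention.
* `g_hat` from `recover_coupling()` is only as sharp as the dFC sample: at
  20 s per repetition the KS distance between neighbouring `g` values is of
  the same order as its sampling noise.
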