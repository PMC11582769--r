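---
title: "Modelling E2-driven ERalpha signalling and cell-cycle progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling E2-driven ERalpha signalling and cell-cycle progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(estrocycle)
```

## The models

`estrocycle` implements a family of ordinary-differential-equation models
for the response of MCF7 breast-cancer cells to 17beta-estradiol (E2), and
couples them to a minimal cell-cycle oscillator.

**Signalling layer.** E2 binds ERalpha to form the transcription-activating
E2–ERalpha complex. Three nested model variants describe how that complex
drives its target proteins GREB1, PR and TFF1:

* **Model I** — E2–ERalpha binds GREB1 (its coactivator); the resulting
  complex stimulates synthesis of all three targets.
* **Model II** — as Model I, but GREB1 and TFF1 stimulation additionally
  requires PR (multiplicatively), and TFF1 is driven by E2–ERalpha with PR
  rather than by the GREB1 complex.
* **Model III** — PR binds E2–ERalpha *before* GREB1 does, creating
  E2–ERalpha/PR and E2–ERalpha/PR/GREB1 intermediates; the large complex
  stimulates GREB1 and PR, while TFF1 is driven by E2–ERalpha and PR.

All bimolecular steps use the saturating form `p·X·Y/(1+X+Y)`, which keeps
every flux bounded by `p·min(X, Y)` and prevents unlimited accumulation.
Complexes only degrade — no dissociation terms are included, because no
complex-level measurements would identify them. Synthesis rates are never
free parameters: they are derived from degradation rates and initial states
(`s_X = d_X · X_init`), so the unexposed system starts exactly in steady
state. Binding and degradation constants live in `[0, 1]` per hour on the
fitted arbitrary-unit scale; stimulation rates are capped at `1e3`.

In Models I and II the printed GREB1 balance can be read with or without
the flux that consumes free GREB1 into its complex. The package defaults to
*including* it (mass-consistent, and symmetric with Model III, where the
consumption term is unambiguous); `greb1_consumption = FALSE` switches to
the strictly printed equation.

**Doses.** Cells perceive an *effective* concentration rather than the
nominal nanomolar dose; the map between them is part of the parameter set,
with the lowest nominal dose pinned at an effective 0.001 as the scale
anchor. The shipped dose map keeps two published anchors — 0.055 nM maps
to 0.104 and 100 nM to 0.837 — and the complete-medium E2-equivalent is
derived as `0.104 × 1.5 = 0.156` (`estimate_e2_equivalent()`).

**Cell-cycle layer.** Active CDK1 and active APC (fractions of total) form
a relaxation oscillator: CDK1 is produced at a basal rate, inactivated by
APC through a steep Hill function, and auto-activates through the Cdc25
loop; APC is activated by CDK1 and inactivated at rate `b2`. Two coupling
terms connect the layers one-way: a GREB1-dependent CDK1 activation
(`k_GREB1·GREB1`, the GREB1→Akt→p21 route collapsed into one term) and an
E2–ERalpha- and PR-dependent APC inactivation (`r·b2·APC·E2_ER·PR`, the
cyclin-D1 route). With `k_GREB1 = 0` and `r·E2_ER·PR ≡ 1` the base
oscillator is recovered exactly.

## Parameter provenance

The shipped signalling parameters are a **synthetic reference set**, not a
published fit (the original fitted values are not available in the main
text of any source we reproduce). They were chosen once so that the models
show the qualitative behaviour the data reports describe — biphasic GREB1
and TFF1 induction (fast rise over the first ~15 h, slower rise
afterwards), near-linear PR induction over 55 h, recovery of GREB1/PR
after starvation, and the knockdown dependency pattern (PR knockdown
lowers GREB1 and TFF1; GREB1 knockdown lowers PR; TFF1 knockdown affects
nothing else) — while keeping a slowly depleting free-E2 pool feeding
fast-turnover complexes. That separation of time scales is what lets a
single exposure sustain cell-cycle activity for ~100 h while a 24 h
starvation still drops the APC-inactivation drive far enough for G1
arrest.

The base oscillator constants are the classic steep-Hill relaxation
parameterisation (`b1 = a2 = a3 = 3`, `K = 0.5`, `n = 8`) with `a1 = 0.1`
and `b2 = 0.4`, giving a base period of ~4.75 time units; dividing the
five rate constants by 11 stretches this to ~52 h, matching the observed
MCF7 doubling time scale. `k_GREB1` and `r` are then tuned by
`calibrate_coupling()` (shipped as `inst/scripts/tune_coupling.R`) so that
the GREB1 term contributes ~30 % of basal CDK1 activation at the culture
steady state and the steady-culture period is 48 h. The resulting defaults
are frozen in the package.

## The in-silico protocol

`run_protocol()` mirrors the experimental flow:

1. **Culture** — E2 clamped at the complete-medium equivalent 0.156 until
   the signalling residual falls below `1e-8` and the oscillator sits on
   its limit cycle; `n_cells` initial CDK1/APC states are sampled at
   uniform random timepoints within one period (seeded).
2. **Knockdown** (optional, 24 h) — still clamped at 0.156 (transfection
   occurs in complete medium); all positive terms of the target's ODE are
   removed from here on.
3. **Starvation** (24 h) — E2 fixed at 0.
4. **Exposure** (100 h) — E2 set to the effective dose as an initial
   condition and left free; depletion through complex formation produces
   the biphasic decay without any prescribed clearance term.

Because coupling is one-way, the signalling layer is integrated once and
each cell's two-variable oscillator is driven by interpolants of that
trajectory — bit-identical to joint integration, at a fraction of the
cost. A cell is reported *arrested* when its exposure-window CDK1 trace
contains fewer than two maxima (a single terminal spike from completing
the ongoing cycle is tolerated, matching the "at most one further
division" reading of control behaviour).

```{r protocol, eval = FALSE}
sp <- sig_params("III")
sim <- run_protocol("III", sp, cycle_params(),
                    protocol(100, params = sp), n_cells = 100, seed = 1)
summary(sim)
```

## Phase calling

**In silico.** S-G2-M→G1 transitions sit at interior CDK1 minima. The APC
threshold is computed once per cell as the first interior APC minimum plus
5 % of the distance to the following APC maximum; a downward crossing
starts G1/S, an upward crossing starts S-G2-M. Interior extrema come from
sign changes of discrete differences refined by a local quadratic fit,
with plateau ties broken at the earliest index. Trajectories without
interior extrema get an arrest verdict (single-phase G1). The threshold is
frozen per cell from the first minimum; per-cycle re-thresholding is
deliberately off. If the window ends before a post-minimum maximum exists,
arrest is reported.

**From FUCCI intensities.** Tracks are min-max normalised per channel per
experiment, smoothed with a centred 10-sample rolling mean (5 left, 4
right — the convention is unstated upstream, so the extra sample goes to
the left; edges shrink), and the log10 Geminin:Cdt1 ratio with sentinels
±100 classifies each sample: G1/S whenever `|r| < 2` (the yellow-overlap
reading takes precedence over the channel comparison where the printed
conditions overlap), else G1 (r = −100 or Cdt1 > Geminin), else S-G2-M.
Two corrections follow: phase excursions of ≤ 4 samples flanked by one and
the same phase are overwritten (iterated to a fixpoint), and a G1/S run
sandwiched between S-G2-M and G1 — the mitotic artefact — is relabelled
G1. Division detection smooths Geminin with a *trailing* 2-sample window
and flags drops steeper than half the track's SD (taken over the smoothed
series, also unstated upstream). Durations count `k·Δ` for a run of `k`
samples at frame interval `Δ` (0.5 h in the FUCCI data; always taken from
the data, never hard-coded), and only runs with both ends inside the
observation window enter summaries.

## Calibration

`fit_signaling()` is a multi-start bounded least-squares fitter:
Latin-hypercube starts (one stratum per start and dimension; fixed
parameters are excluded from sampling), Levenberg–Marquardt with
finite-difference Jacobians in log-parameter space, and the steady-state
constraint applied *structurally* — synthesis is re-derived from the
current degradation rates and initial states inside every objective
evaluation, so no candidate ever violates it. Effective doses are fitted
jointly with the lowest pinned at 0.001; complex initial states are fixed
at 0; replicates enter as separate residual rows; weights are unit (the
choice is surfaced in the output rather than hidden). Converged starts are
clustered into optima (cost within 1 % relative, normalised L∞ parameter
distance < 5 %), and all clusters are reported — the package never picks
an optimum silently by cost alone. Finite-difference Jacobians stand in
for sensitivity-equation gradients; at this problem scale they find the
same optima with far less machinery.

A note on identifiability, since it shapes what the tests assert: the
signalling models are *sloppy*. On noiseless synthetic data the reachable
optima reproduce the observables to ~0.1 % relative error while individual
stimulation/degradation parameters can differ from the generating values
by large factors along compensating directions; direct probing shows the
zero-cost basin attracts only from within ~±20 % per parameter, which
blind multi-starts essentially never hit in 19–23 dimensions. The tests
therefore check the identifiable content — near-zero relative cost,
agreement of fitted observable trajectories with the generating model,
recovery of the directly observed initial states, and the multi-optimum
structure itself — rather than pretending the full parameter vector is
recoverable.

The starvation-phase degradation model (`fit_degradation()`) is the
opposite extreme: pure exponential decay per reporter, initialised from
the closed-form log-linear slope and refined by least squares; on exact
data it recovers rates to numerical precision.

## Image maps

The cell distance map (CDP) assigns each object pixel its Euclidean
distance to the nearest non-object pixel, max-normalised per object
(single-pixel objects resolve the 0/0 to 1). The neighbour distance map
(NDP) removes each object in turn, measures the distance to the remaining
objects, masks to the removed object, normalises, inverts, composites,
applies a flat 3×3 grayscale closing and raises to the 10th power.
Reconstruction smooths both maps (Gaussian, sigma 1.5), masks the CDP at
0.15, seeds from connected components of `CDP − NDP²` above 0.25 (seed
values are not clipped before thresholding), and floods a
marker-constrained watershed over the negated smoothed CDP inside the
mask. EBImage supplies distance transforms, blurring, closing and
labelling; the marker-constrained flood itself is implemented in the
package because no installed routine takes arbitrary markers, an elevation
surface and a mask together.

## Synthetic data

The generators exist to make every pipeline stage scoreable without
external data; all are bit-reproducible under a seed.

* `gen_expression_data()` simulates the chosen model per dose from the
  unexposed steady state and multiplies by lognormal replicate noise
  (default sigma 0.1, a stand-in matched to visual replicate spread, not
  an estimate from data).
* `gen_fucci_tracks()` scripts a binary lineage tree over G1 (16 h),
  G1/S (6 h) and S-G2-M (20 h) phases at 0.5 h frames and lays
  piecewise-constant intensity plateaus over it (Cdt1 0.8/0.3/0.002,
  Geminin 0.002/0.3/0.8, both 0 at the colourless division frame). The
  plateau switches are offset from the scripted boundaries by +4, −5 and
  +3 frames so that the smoothing and ratio rules of the pipeline place
  the recovered boundaries exactly on the script in the noiseless case —
  the shapes are templates keyed to phase, not a mechanistic Cdt1/Geminin
  model. One daughter reuses the mother's object ID, as real tracker
  exports do.
* `gen_label_movie()` draws drifting, non-touching elliptical nuclei with
  optional scripted splits and returns ground-truth lineage; drift beyond
  the 40 px linking limit is the negative control for the tracker.

What passing these oracles does *not* show: robustness to segmentation
errors, uneven illumination, apoptosis, track gaps, or realistic
Cdt1/Geminin kinetics — the generators emulate the statistical structure
the rules assume, not microscopy physics.

## Numerical choices

* Integration: lsoda with rtol `1e-8`, atol `1e-10` (fits use `1e-6` /
  `1e-8` for speed); right-hand sides are compiled (C), with the R
  implementation kept as the validating reference.
* E2 clamping zeroes the E2 derivative; states are floored at 0 inside
  the RHS to absorb solver round-off (solutions stay above −1e−9).
* Oscillation detection: ≥ 3 tail maxima, amplitude > 5 % of the observed
  range, inter-peak spacing varying < 10 %.
* Problem sizes used by the shipped tests and the acceptance script: 100
  virtual cells per protocol condition at 0.1 h output steps, 20
  optimization starts on the 6-dose × 56-timepoint × 3-replicate fit, 20
  synthetic nucleus fields for the round-trip rate. These sizes make the
  stochastic fractions stable to well under the asserted margins.

## Known limitations

* No stochastic cell-to-cell parameter variation: simulated phase-duration
  spread reflects only desynchronised starting positions, so it is
  narrower than measured single-cell variability.
* TFF1 is not coupled to the cell cycle (its long-term decay is not
  captured by the signalling models).
* The watershed flood is O(n log n) in pixels with an R-level frontier;
  it is meant for the package's small fixture images, not for full-frame
  microscopy stacks.
* The fitted parameter values themselves should be read as one point on a
  sloppy optimum manifold; only observable-space predictions are stable
  across optima.
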