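---
title: "Embodied excitable-network dynamics with homeostatic balancing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embodied excitable-network dynamics with homeostatic balancing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`embodiedGH` simulates a Greenberg–Hastings (GH) excitable network on a
structural connectome, embodied as an agent in a bounded 2D arena, and asks
how two homeostatic mechanisms — local inhibitory-threshold plasticity and
macroscopic task-negative balancing — stabilize the closed sensorimotor
loop. This vignette is the package's account of the model, its parameters,
the numerical choices behind the analysis suite, and the limits of what the
synthetic experiments can show.

## The neural model

Each of the N nodes is, at every epoch t, in one of three states: excited
(E), refractory (R) or quiescent (Q). The synchronous update uses only the
epoch-t states:

* E → R and R → Q with probability 1 (a hard two-epoch refractory cycle);
* Q → E spontaneously with probability `p_spont` (default 0.1), **or**
  deterministically when the weighted input exceeds the node's threshold:

  g · Σ_j (C_ij / max C) · b_j(t) > T_i,

  where C is the raw connectome weight matrix, g the global `coupling`, b_j
  the binarized activity (1 iff excited), and T_i the node's activation
  threshold, interpretable as local inhibition.

Weights are normalized by the global maximum inside the dynamics (the
loaded connectome is stored untouched), so `coupling` and
`initial_threshold` are dimensionless and comparable across connectomes.
The propagation inequality is strict. The initial state is all-quiescent
with uniform thresholds, the minimal assumption for a system whose activity
is meant to grow out of spontaneous firing.

Two structural consequences of the three-state cycle with `p_spont = 0.1`
are worth stating explicitly because they bound everything downstream:

* **Spontaneous floor.** An isolated node cycles E (1 epoch) → R (1 epoch)
  → Q (mean 1/p epochs), so its mean activity is p/(1 + 2p) = 1/12 ≈ 0.083
  regardless of thresholds. No homeostatic mechanism can push time-averaged
  activity below this floor, since thresholds gate only propagation, never
  spontaneous firing. Target rates `rho` below 1/12 are therefore
  unattainable: thresholds climb without bound (the homeostasis sweep flags
  this as divergence) while activity stays at the floor.
* **Refractory ceiling.** A node can be excited at most every third epoch
  unless forced, so sustained network-mean activity saturates near 1/3. The
  "high-activity" phase is a period-3 oscillation around that ceiling, not
  full saturation.

## Local homeostatic plasticity

Under the `local` and `combined` variants each node's threshold moves by

δT_i = α · (b_i(t) − ρ)

after every epoch: firing above the target rate ρ raises local inhibition,
silence lowers it. Thresholds are deliberately **not clamped**; under
prolonged silence they go negative, which makes any positive input
supra-threshold — the fixed point of the printed rule, which a clamp would
silently move. At rest (no sensory forcing) the rule converges tightly: for
ρ between the spontaneous floor and ~0.2 the time-mean activity over the
final half of a 5000-epoch run lands within a few 10⁻³ of ρ (recomputed by
`scripts/acceptance.R`), for learning rates α from 0.01 to 0.2.

**Which nodes adapt.** By default the exogenously forced nodes — the six
task-positive sensors and the four task-negative nodes — are excluded from
the threshold update (`homeostasis_exclude = NULL` resolves to those sets
at run time). The reason is mechanical: a node whose state is clamped to E
by the environment or the balancer accumulates δT = α(1 − ρ) per forced
epoch with no feedback loop to stop it; at α = 0.1 and a typical forced
duty cycle this is an unbounded linear drift of order +100 threshold units
per 2000-epoch run, which swamps every threshold-variability metric with an
artifact of the clamping. Passing `homeostasis_exclude = integer(0)`
restores the rule on all nodes for users who want the unrestricted variant.

## Macroscopic task-negative balancing

Under the `macro` and `combined` variants, four task-negative (TN) nodes —
two bilateral pairs, in a fixed priority order alternating left/right —
complement the forced task-positive (TP) sensors: with k = min(|forced
TP|, 4), the first 4 − k TN nodes are forced excited and the remaining k
forced quiescent. The exogenously activated count, with TP capped at 4,
is therefore exactly 4 at every epoch (a run-record invariant the tests
check). This is the network-balance analogue of task-negative (default-mode)
deactivation: sensory drive rises, TN activity falls, and the total
exogenous input to the recurrent network stays constant. The mapping from
up to 6 TP sensors onto a 4-node TN budget is under-determined in principle;
the clamped complement is the choice that preserves count constancy on its
feasible range.

Forcing semantics, used by both mechanisms: a forced state overrides the
computed one for that epoch only. A node forced E on consecutive epochs
stays E — its E → R rule is suspended while the forcing condition holds
(e.g. for somatosensory nodes, for every epoch of wall contact).

## Environmental embedding

The arena is a 20 × 20 world-unit rectangle (the far-vision range then
covers half the arena); the agent is a point with a position and heading,
starting at the center with a uniformly drawn heading.

Each epoch runs, in order: (1) sense — two rays cast at ±10° from the
heading (left ray = +10°; a top-down model has no vertical, so the offset
is read relative to the heading), exact ray/axis-aligned-wall intersection;
(2) balance — TN forcing from the TP forcing set (macro variants); (3) one
synchronous network step with both forcing sets; (4) threshold update
(local variants); (5) act — motor decoding and movement. Sensation precedes
dynamics precedes action.

Sensing thresholds: a ray distance below 2 world units forces that side's
near-visual node, between 2 and 10 units the far-visual node (mutually
exclusive per side); a collision on a side forces that side's somatosensory
node for every epoch the contact persists.

Motor decoding: an excited rotate node turns the agent 30° (= π/6 exactly)
toward its side, both rotate nodes cancel; forward drive is 0 / 0.5 / 2
world units for zero / one / both excited forward nodes ("both" is read as
a raw command of 2, not an increment), smoothed as v ← (7/8)·raw +
(1/8)·v_prev. Only the move command is smoothed; `smooth_turn = TRUE`
extends the same filter to the turn. Under maximal drive v approaches 2
geometrically and never exceeds it.

Collision resolution: if the displacement segment crosses a wall the agent
stops 10⁻³ units inside (never exactly on the boundary, which would
degenerate the ray cast). The collision side is left if the wall lies
counterclockwise of the heading — signed angle from the heading to the
into-wall normal > 0 — right otherwise, and a head-on hit (|angle| < 1°)
flags both sides. The agent is a point; no body geometry is modeled.

## The synthetic connectome

`generate_synthetic_connectome()` emulates the gross statistics of a
66-region streamline-count matrix: two hemispheres of 33, four modules per
hemisphere mirrored across the midline, denser intra-module connectivity
(0.3 vs 0.05), always-connected homologue pairs, and log-normal weights
(heavy-tailed, like streamline counts). It is symmetric, non-negative,
zero-diagonal, and bitwise-reproducible from its seed. What it does **not**
emulate: the true degree/strength distribution of any empirical
parcellation, spatial embedding, or distance-dependent weight decay. Role
nodes (sensors, motors, task-negative) are placed on arbitrary mirrored
pairs — deliberately so; no anatomical claim is attached, and results that
depend on the exact placement should not be read off this generator. A user
with an empirical matrix supplies it as CSV via `load_connectome()`.

## Avalanche statistics

Activity is binarized (excited = 1), summed over nodes, and grouped into
bins of `bin_dt` epochs (default 1; the trailing partial bin is dropped). A
cascade is a maximal run of non-silent bins bounded by silent bins; its
size K is the summed event count, its duration the run length. Cascades
touching the record boundaries are kept (a `censor_boundaries` flag drops
them).

* `fit_powerlaw_ls()`: ordinary least squares of log₁₀ P(K) on log₁₀ K
  over the observed sizes, no logarithmic binning (a log-binned variant
  sits behind a flag); the slope is the exponent, the residual sum of
  squares the fit error.
* `nll_reference()`: mean negative log-likelihood per cascade under the
  discrete reference law K^a normalized on the observed [min K, max K] —
  a finite 66-node system truncates the law, so the observed support is the
  only defensible normalization range.
* `kappa_statistic()`: κ = 1 + (1/m) Σ [F_ref(β_k) − F_emp(β_k)] at m = 10
  logarithmically spaced points, the conventional deviation measure; κ < 1
  is subcritical-like, κ > 1 supercritical-like, and κ of draws from the
  reference law converges to 1 (calibrated in the tests at n = 10⁵ within
  ±0.02). The reference exponent defaults to −1.5, the mean-field branching
  value.

**A caveat that matters at the default noise level:** with `p_spont = 0.1`
a 66-node network produces ≈ 5.5 spontaneous events per epoch, so silent
bins — the delimiters of the avalanche definition — essentially never occur
(the converged local regime yields one or two giant cascades per run, as
`scripts/acceptance.R` reports). Avalanche analysis of this model is
informative only at much lower spontaneous rates; the acceptance script
demonstrates the machinery on a near-critical run at `p_spont = 0.001`,
where thousands of cascades yield a least-squares exponent near −1.5 and
κ near 1. This is a property of the model at its printed noise level, not
of the estimator.

## Behavioral metrics

* **Movement entropy**: Shannon entropy (bits) of the joint (v, h)
  histogram on a 16 × 16 equal-width grid over each series' observed range;
  a constant axis collapses to one bin, so a frozen agent scores 0. The
  joint form (rather than summed marginals) captures the coupling between
  forward and turn commands; `joint = FALSE` gives the marginal sum.
  Bounded by 2·log₂(n_bins).
* **Trajectory fractal dimension**: the polyline is rasterized onto a
  1024² grid covering the arena (segments drawn by dense stepped sampling,
  marking every cell the ideal line passes through), and the box-counting
  dimension is the negative LS slope of log₂ N(s) vs log₂ s over box sizes
  s = resolution/2^k, k = 1 … log₂(res) − 2. The largest boxes are excluded
  (they saturate for any non-trivial path) and the smallest retained box is
  4 px (single-pixel boxes measure rasterization noise). Calibration: a
  straight line scores 1 ± 0.05, a filled raster 2 ± 0.05; a degenerate
  single-cell trajectory returns 0 with a flag.
* **Coupling correlations**: Pearson correlations over epochs between wall
  distance, network-mean activity and network-mean threshold, on raw series
  (no detrending or smoothing); constant series report r = 0 with a
  degenerate flag rather than NA.
* **Variability**: `activity_node_sd` is the across-node SD per epoch
  averaged over epochs; the alternative reading (SD over time of the
  network mean) is also reported as `activity_time_sd`. Threshold
  variability is the SD and coefficient of variation over time of the
  epoch-mean threshold.
* **Group comparisons**: pooled-variance two-sample t (df = n_a + n_b − 2,
  so 58 for two groups of 30), two-sided; zero pooled variance returns
  t = ±∞ with a degenerate flag. Per-run correlations are tested against
  zero after Fisher z-transformation (df = n − 1). No multiple-comparison
  correction is applied.

## Default operating point and experiment design

The defaults `coupling = 1.8`, `initial_threshold = 0.35` place the static
model at the phase transition of the default synthetic connectome, located
once from the package's own `phase_sweep()` (activity rises from the
spontaneous floor toward the refractory ceiling between g ≈ 1 and g ≈ 2 at
T = 0.35). At this point the embodied static model shows the signature trap
dynamics: free movement early, then pinning at a wall under saturated
activity and constant forward drive. The homeostatic defaults `alpha =
0.1`, `rho = 0.1` are the low-target/high-learning regime (with ρ safely
above the 1/12 floor).

Experiments derive one seed per cell and repeat from the master seed by an
integer hash, so sweep results are independent of evaluation order and any
subset of cells can be reproduced in isolation. Attained rates in the
homeostasis sweep are measured on the final half of each run, discounting
the adaptation transient. Problem sizes used by the test-suite and the
acceptance script: 5000-epoch runs for convergence and avalanche
summaries, 2000-epoch runs with 10 (tests) or 30 (script) repeats per
variant for the behavioral comparisons, 10⁵+ steps for the
spontaneous-rate estimate. Plots are conveniences, never analysis surfaces.

## What the synthetic experiments do and do not show

Passing tests establish that the implementation realizes this model exactly
(the update rule is checked against an exhaustive independent oracle on
small networks; the estimators are checked against closed forms and
synthetic draws) and that the homeostatic mechanisms behave as designed on
the synthetic connectome. They do not establish anything about empirical
brain dynamics: the connectome is synthetic, role placement is arbitrary,
the arena is a featureless box, and several qualitative behavioral
contrasts between variants are sensitive to the spontaneous-rate floor
discussed above. In particular, at `p_spont = 0.1` the noise-driven
movement of the static model is as entropy-rich as the target-rate-driven
movement of the homeostatic variants, so orderings of movement entropy
between variants are weak at this noise level even though the
trap/escape phenomenology and the wall-distance anti-correlation contrast
are robust.

## Known limitations

* No synaptic (weight) plasticity, conduction delays, or continuous-time
  dynamics; the fiber-length matrix of empirical datasets plays no role.
* No interior obstacles or multi-agent arenas; one rectangular room.
* Least-squares power-law fitting is used by design (with the fixed −1.5
  reference); no maximum-likelihood exponent estimation with KS cutoff
  selection is provided.
* The kappa and NLL reference laws are normalized on the observed size
  range; comparing κ across runs with very different supports conflates
  support and shape.
* Whether somatosensory forcing should persist for the duration of contact
  (as implemented) or a single epoch, and whether ±10° is relative to the
  heading (as implemented) or some other axis, are modeling choices exposed
  here rather than settled facts.
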