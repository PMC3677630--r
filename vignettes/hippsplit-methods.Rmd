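---
title: "Modelling object-in-context memory with split hippocampal circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling object-in-context memory with split hippocampal circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

hippsplit simulates a family of rate-coded hippocampal networks that store
and recall object-context associations, and asks how anatomical
differentiation — the posterior/anterior division of the hippocampus, the
superior and inferior blades of the dentate gyrus (DG), and the
distal/proximal subdivisions of CA3 and CA1 — changes recognition
performance when the inputs are noisy, incomplete or mismatched. This
vignette is the package's methods account: the model, its assumptions, the
parameters that matter, the numerical choices, and what the simulations can
and cannot show.

## The model

Two entorhinal layers provide input: LEC carries "object" patterns, MEC
carries "context" patterns; both are 64-unit binary vectors with 16 active
units. Each side of the hippocampus (posterior = object-dominated,
anterior = context-dominated) contains a DG (800 units, 1.5% activity), a
CA3 (256 units, 2.3%) with recurrent collaterals, and two CA1 subregions
(400 units each, 2.5%). Mossy-fiber DG→CA3 projections are 10 times
stronger than the perforant-path input. Proximal CA3 projects to distal
CA1 and distal CA3 to proximal CA1; distal CA1 receives LEC input and
proximal CA1 receives MEC input. Four output layers read from the four CA1
subregions:

* **O** — the object guess (posterior distal CA1),
* **OBCG** — the object-based context guess (posterior proximal CA1),
* **CBOG** — the context-based object guess (anterior distal CA1; three
  64-unit slots, one per object of the context),
* **C** — the context guess (anterior proximal CA1).

"Crossconnections" are MEC input to the posterior side and LEC input to
the anterior side, scaled by relative weight multipliers. Five variants are
built by `build_network(default_config(variant))`: **Baseline** (no split),
**SplitDG** (DG split into 400-unit blades), **AllSplit** (DG blades plus
128-unit proximal/distal CA3 regions; the inferior blade feeds proximal
CA3 only, the superior blade distal CA3 only), and the **"+"** variants
that double the split layers (SplitDG+ blades of 800; AllSplit+ blades of
800 and CA3 regions of 256) so their training error matches the Baseline.

Posterior crossconnection multipliers are 1.5 everywhere for the Baseline
(the compromise between the object stream, which profits from context, and
the OBCG stream, which is hurt by it), and in the split variants 3.0 into
the object-stream blade and CA3 region but 0.05 into the OBCG-stream
blade/CA3/proximal CA1. The anterior side shares a single LEC multiplier
across all variants.

## Inhibition, settling, learning

Each layer is inhibited by a k-winners-take-all rule: the threshold is
placed midway between the k-th and (k+1)-th largest net inputs (after a
deterministic index-order tie perturbation, so exactly k units exceed it
and ties resolve to the lowest index). Only winners transmit activity;
sub-threshold units transmit exactly zero. This follows the circuit logic
that only the top k most active neurons send their outputs onward: with
hundreds of units per layer, letting losers leak even modest graded
activity swamps the sparse winner signal and destroys the pattern
separation that DG and CA3 exist to provide.

A winner's activation is `tanh(gain * margin / mean winner margin)`, where
the margin is its suprathreshold net input. Two numerical choices matter
here and were made once, during engine bring-up:

* **Continuity at the threshold.** The activation is zero exactly at
  threshold. A rule that jumps to 0.5 at the winner boundary creates
  permanent flip-flop between near-tied units and the settling loop never
  converges.
* **Margin normalization.** Early in training the net-input margins are
  tiny (sums of near-uniform random weights), so any fixed-gain squashing
  of the raw margin produces hidden activations of order 0.01–0.1. That
  breaks contrastive learning, whose minus-phase term must be commensurate
  with plus-phase clamps at 1.0. Dividing by the layer's mean winner margin
  keeps activations O(1) at every drive scale. The gain default is 2.

Net input to a layer is the sum over incoming projections of
`rel_weight * (W %*% activations) / k_active(source)`; dividing by the
expected number of active senders makes the relative multipliers (the 10x
mossy fibers, the 1.5/3.0/0.05 crossconnections) comparable across source
layers of different sizes.

Settling is synchronous with under-relaxation (`step_size` 0.7) applied to
both the integrated net input and the activations; without damping the
CA3 recurrence and the CA1↔output loops settle into limit cycles rather
than fixed points. A phase ends when the largest activation change falls
below `tol` (1e-4) or after `max_cycles` (60; a cold minus phase needs
roughly 50 cycles at these settings). Non-convergence is flagged, never an
error. The output→CA1 return projections, which carry target information
into the hidden layers during the plus phase, use a relative weight of
0.25: at parity with the feedforward strength the anterior CA1↔output
loops oscillate indefinitely.

Learning is two-phase contrastive Hebbian (the generalized-recirculation
family): a minus phase with only LEC/MEC clamped, then a plus phase —
warm-started from the minus state — with the four output targets clamped
as well, followed by

    dw = rate * ((1 - hebb) * (x+ y+ − x− y−) + hebb * y+ (x+ − w))

with soft weight bounding (positive changes scaled by `1 − w`, negative by
`w`), keeping every weight in [0, 1]. Weights initialise uniformly in
[0.25, 0.75], independently per direction of a bidirectional pair.

### Learning-rate and Hebbian-mix calibration

The learning parameterization is not dictated by the circuit anatomy, so
it was calibrated once against the study's qualitative structure and then
frozen: `rate = 0.05`, `hebb = 0.125`. The Hebbian fraction is the
load-bearing choice. Because deep error-driven feedback is off (targets
reach CA1 but not CA3/DG), the DG and CA3 pathways learn only through the
Hebbian term; it is what turns CA3 into an autoassociative store. Below
about 0.1 the CA3 attractor never forms, pattern completion of partial
cues fails, and enlarging CA3 brings no benefit; above about 0.15 cue
cleanup becomes so strong that every network solves the moderate-noise
tests perfectly and the differences between variants vanish into the
floor. The calibrated point keeps both effects alive: completion improves
with CA3 size, and the split variants' access to clean crossconnection
input still matters at 30% noise. `rate = 0.05` similarly keeps the
20-epoch training errors near — but not pinned to — zero, which is the
regime in which splitting a layer shows its storage cost.

## The synthetic world and corruption benchmarks

`build_association_set()` draws 120 unique objects and 40 unique contexts
(3 objects per context) as random 16-of-64 binary patterns, redrawing
duplicates. Training presents all 120 matched pairs per epoch in random
order, for 20 epochs; weights are then frozen and recall is read from the
minus phase alone.

Corruption operators (`corrupt()`, assembled into trial sets by
`build_test_battery()`):

* **additive** — `round(level * 16)` zeros flipped to ones,
* **nonadditive** — the same number of 0→1 flips each paired with a 1→0
  flip (activity preserved),
* **partial** — the level is the *completeness*: `round(level * 16)` of
  the original ones retained, the rest zeroed,
* **mixed** — half additive, half non-additive (odd counts favor the
  additive half),
* **mismatch** — a derangement of the trained object→context pairing, so
  no object appears with its own context.

Levels are fractions of the pattern's original active count (16), not of
all 64 units — "40% complete" unambiguously counts the ones; a
`total_units` basis is available for sensitivity checks. Rounding is
half-away-from-zero. For the noise modes level 0 is the identity; for the
partial mode level 1 is. Ground truth under mismatch: O and OBCG are keyed
to the object's *trained* context, C and CBOG to the *presented* one. The
CBOG target concatenates the presented context's objects in ascending
object-id order, and its error is the slot-average of the normalized miss
rate. An absent input (the context-only recall test) is an all-zero clamp
on LEC: no activity is the weakest possible cue and needs no new
mechanism.

The recall error of an output is the fraction of target-active units
missing from the top-m binarized activation (m = the target's active
count). The error of an untrained network is therefore about
1 − 16/64 = 0.75 on a 64-unit output.

## Experiments

* `sweep_crossconnections()` reproduces the calibration sweep: per-output
  error on the sample tasks (O/C: 15% mixed noise in both inputs and
  40%-complete in both; OBCG: mismatch, 30% mixed context noise,
  40%-complete context; CBOG: the object-side mirror) as a function of the
  crossconnection multiplier. The object output prefers strong posterior
  crossconnections (3), OBCG prefers none (0) — the Baseline compromise is
  their midpoint 1.5.
* The anterior multiplier was calibrated the same way (argmin of the
  C + CBOG sample average over {0, 0.05, 0.25, 0.5, 1, 2}, 3 seeds): the
  optimum is a flat plateau across [0, 0.5]; the default is fixed at 0.05,
  keeping the anatomical projection present but weak.
* `training_error_comparison()` reports final training error per variant,
  flagging the equal-units trio (Baseline/SplitDG/AllSplit) and the
  equal-error trio (Baseline/SplitDG+/AllSplit+).
* `run_battery()` trains variants and evaluates the corrupted-input
  batteries over level grids (noise {0, .1, .2, .3, .4, .5}; completeness
  {1, .8, .6, .4, .2}; the grids are package choices — the study's curves
  do not print theirs). It reports per-output errors, and two whole-network
  scores: the combined score `mean(O, min(C, OBCG))` used for the
  partial-context comparison, and the plain O/C average used for the noise
  and partial-object comparisons.
* `sweep_ca3_size()` resizes the posterior CA3 of the Baseline and
  measures the object error on the 40%-complete partial-object task.

Replicates are seeds: one seed covers the network initialisation, the
presentation order of every epoch, and the corruption draws of the test
batteries. The association world itself is fixed per experiment — one
stimulus set, many subjects — and error bars are SEMs across seeds.

## Problem sizes used by the shipped tests

The packaged test suite replicates each comparative result at a reduced
replicate count chosen to keep a full run in the tens of minutes on one
CPU: memorization at 10 seeds, the crossconnection preference at 2 seeds
on the endpoint multipliers {0, 3}, the training-error comparison at 3-5
seeds per variant, the noise/partial orderings at 4 seeds at the 30%
level, and the CA3 sweep at 2 seeds over sizes {32, 128, 256, 512}. The
full-scale
versions of every figure-style experiment (all variants, full grids,
10 seeds) are exposed as one-liners through `reproduce_figure("fig6")` …
`reproduce_figure("fig14")` and take a few hours in total.

## What the synthetic benchmark does and does not show

The generator emulates the study's world exactly: uncorrelated sparse
binary patterns, a fixed many-to-one object→context map, and four
parametric corruptions. Real perirhinal/parahippocampal inputs are
correlated, graded and temporally structured; objects recur in several
contexts; context drifts rather than switching discretely. Passing these
tests therefore shows that the *circuit-level* claims — which anatomical
split helps under which kind of degradation — hold in the idealized
regime, not that the model generalizes to naturalistic stimuli. No
temporal/list-order structure is modelled (no temporal-context dynamics),
and the discussion-level mechanisms the study itself did not implement
(using OBCG as a backup context input, or matching the CBOG list against
the noisy object) are likewise out of scope.

## Known limitations and degenerate inputs

* kWTA guarantees at least one winner per layer (`k = max(1,
  round(fraction * size))`); a layer driven by all-zero input still
  settles, with near-zero winner activations.
* Settling is only guaranteed to terminate (at `max_cycles`), not to
  converge; the flag is preserved on the result. At the defaults,
  non-convergence is rare after the first training epoch.
* The corruption operators reject infeasible requests (more additions than
  zeros, swaps without active units, retaining more ones than exist)
  rather than truncating silently.
* Weight tables are dense; the mossy-fiber sparseness is represented
  purely by its 10x relative weight.
* `network_state` objects have reference semantics (environments): the
  engine updates weights and activations in place. Use `write_weights()` /
  `read_weights()` to snapshot a state.
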