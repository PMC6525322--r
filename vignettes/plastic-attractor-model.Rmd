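---
title: "A plastic-attractor model of working memory: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A plastic-attractor model of working memory: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastwm)
```

## The model

`plastwm` simulates a small firing-rate network in which working memory
arises from the interaction of two unit populations:

* **Feature units** `f` — fixed, labelled-line units, one per feature value
  per dimension. The canonical configuration has three dimensions (color,
  orientation, location) with four features each, i.e. 12 feature units.
  Any dimension can be reinterpreted (the task-set experiments treat the
  location dimension as motor plans).
* **Freely conjunctive units** `c` — four units with no built-in
  selectivity. Their meaning is carried entirely by two rapidly plastic
  weight matrices, `W_fc` (features to conjunctions) and `W_cf`
  (conjunctions to features), maintained as independent matrices with
  identical update rules.

One Euler step of the rate dynamics computes, for every unit, a drive

* features: `W_cf %*% c + i_ext − beta_f * (other same-dimension feature
  rates) + noise`
* conjunctions: `W_fc %*% f − beta_c * (other conjunction rates) + noise`

and relaxes the rate toward `phi(drive)` with time constant `tau`, clipping
to [0, 1]. The nonlinearity is a *baseline-rectified logistic*

```
phi(x) = max(0, (L(g (x − θ)) − L(−g θ)) / (1 − L(−g θ))),   L(x) = 1/(1+e^−x)
```

which is logistic in shape but satisfies `phi(0) = 0` exactly, so a silent
network with zero input is a true fixed point. Noise is a single Gaussian
draw per unit per step added to the drive.

Plasticity operates continuously — in every epoch, including blanks and
delays. Each step adds the Hebbian outer product `eta * c %o% f` to `W_fc`
(and its counterpart to `W_cf`) and renormalizes every postsynaptic unit's
incoming weight row to Euclidean norm `w_norm`. There is no decay term:
because active synapses grow under a fixed row norm, the synapses of
currently inactive patterns shrink mechanically. This normalization-driven
*erosion* is the model's only forgetting mechanism, and it is
event-driven: weights change only where pre- and postsynaptic rates are
both appreciably non-zero.

A trial presents items strictly sequentially. Encoding an item drives its
three feature units; the conjunctive units compete through `beta_c` and
exactly one wins, binding the item's features to itself in both
directions. The winning coalition — one conjunctive unit in mutual
excitation with three feature units — is the *focus of attention* and
persists as an attractor after input ends. A later item suppresses the
previous item's features (within-dimension `beta_f`), the deposed
conjunction loses its support and dies, and a new winner binds the new
item; the first item survives only in its strengthened synapses
(*activity-silent* storage). A probe re-drives a single stored feature;
pattern completion through the stored weights re-activates the full item,
and the behavioral report is the first report-dimension feature to cross
`readout_threshold`.

## Calibration and the canonical operating point

The constants shipped in `inst/extdata/canonical.yaml` (`tau = 5`,
`gain = 6`, `threshold = 0.6`, `beta_f = 1.4`, `beta_c = 1.0`,
`eta = 0.02`, `noise_sigma = 0.22`, `w_norm = 1`, `stim_drive = 1`,
`readout_threshold = 0.5`) were fixed with the grid search implemented in
`calibrate()`. The search is not cosmetic: the qualitative phenomena only
coexist in a narrow regime, and mapping it exposed three failure modes
worth recording because they constrain any re-tuning.

1. **Serial capture.** If the learning rate is large relative to the rate
   decay (`eta` high, `tau` long), the conjunction that encodes item 1
   re-binds itself to item 2 *while it is dying*, recovers, and captures
   every subsequent item; items merge instead of being stored separately.
   The cure is rate decay faster than rebinding (`tau = 5`, `eta = 0.02`).
2. **The incumbent's residual floor.** After row normalization a
   conjunction that learned one item retains residual weights of roughly
   0.15 toward everything else, giving it a drive of about 0.5 from any
   new item. If `threshold` is below this floor the incumbent never dies
   and, through `beta_c`, never lets a challenger ignite. `threshold =
   0.6` sits above the floor, so the deposed winner goes silent and a
   fresh conjunction takes the new item.
3. **Immortal attractors.** With a steep nonlinearity (gain ≳ 7) the
   attended attractor saturates and noise cannot dislodge it; then no
   probe can ever retrieve an unattended item, because the live winner
   suppresses the probed conjunction. At `gain = 6`, `noise_sigma = 0.22`
   the attractor is *metastable*: without noise it persists indefinitely
   whenever the winner resolves early enough in the encoding epoch to
   consolidate its weights (roughly half of random initializations; the
   persistence invariant is checked noiselessly on such an encoding), and
   with noise it collapses stochastically over a few hundred steps. Recall of
   unattended items is then genuine stochastic pattern completion: the
   probed feature's drive to its conjunction (≈ 0.52) sits just below
   threshold, and noise gates ignition. This one mechanism yields graded
   accuracy, reaction-time distributions (ignition latency), and the
   recency/primacy structure.

Epoch durations are dimensionless steps: stimulus 50, inter-item gap 10,
delay 200, cue 30, probe 100, readout 50, inter-trial blank 50, and a
10-step global inhibitory reset (−1 to all units) at trial onset, which
quenches rates without touching weights. The weak uniform pulse
(strength 1) lasts 30 steps so that re-activated traces have time to
express; the strong pulse (strength 3) lasts only 10 steps so that it
disrupts the active attractor while continuous plasticity has little time
to homogenize the stored weights. All durations are configuration keys.

## Experiments and what they show

Each experiment in `experiment_registry()` is a seeded protocol emitting a
long-format tibble (one row per trial per measurement) stamped with its
seed and configuration hash; `experiment_checks()` recomputes its
qualitative directional predictions with two-sample percentile bootstraps
at the 95% level. Weights persist across trials within a block (the
source of all trial-history effects); blocks are independent replicates
with counter-derived seeds. Per-trial seed isolation is impossible in
principle — trial *k*'s state depends on the whole weight history — so the
block is the unit of reproducibility.

Default problem sizes are 200 trials per condition (double that where a
criterion compares sub-conditions), 2000 sequential trials for the
trial-history series, and 200 recorded trials per decoding condition.
At these sizes the full battery runs in a few minutes, and directional
effects of ≈ 0.1 in accuracy are resolvable.

The capacity check is a joint one: observed mean accuracy strictly
decreasing over set sizes 1–4 together with a bootstrap-negative
accuracy-vs-set-size slope. Adjacent-pair contrasts are also reported,
but the pair at the top of the range (3 vs 4) is a ≈ 0.05 difference near
the 4-alternative chance floor, which a pairwise test at 200
trials/condition cannot resolve; the direction over set sizes is the
contract.

## Decoding analyses

The canonical decoder is a nearest-class-centroid linear classifier —
deterministic and parameter-free — with stratified k-fold cross-validation;
a weight-decay multinomial-logistic option exists behind a flag as a
robustness check. Cross-decoding (train on attended, test on unattended
representations of the same items) is compared against a 1000-fold
label-shuffle null; *below-chance* accuracy is the expected result, the
representational inversion produced by competitive inhibition of
unattended features. Decoding windows default to the final 50 delay steps
before the probe; the pulse experiment uses a pre-pulse window and the
pulse-evoked window (onset to offset + 10 steps), since re-activated
traces express during stimulation. Train/test partitions for
cross-decoding use disjoint trial sets generated under different seeds.

## The synthetic stimulus generator

Stimuli are discrete feature conjunctions drawn uniformly, unique per
dimension within a trial unless the shared-feature stress mode is
requested. The trial-history experiment varies two feature dimensions
(16 distinct items), matching the conjunction-violation analysis, which is
defined over a feature pair. What the generator does *not* emulate:
continuous feature spaces (no proximity structure within a dimension),
simultaneous array presentation, perceptual noise in the stimulus itself,
and verbal/phonological material. Passing tests therefore speak to the
binding-and-attention machinery, not to metric biases in human recall,
which require continuous features.

## Known limitations

Three behaviors of the published record do not express at the canonical
operating point, for reasons that are structural rather than accidental;
they are asserted as specified and left failing rather than weakened.

* **Delay-dependent forgetting of unattended items.** Erosion requires
  co-active pre- and postsynaptic floors; during a quiet delay, lateral
  inhibition plus the rectified nonlinearity clamp silent units to
  (near-)zero rates, so silent traces are effectively frozen, and
  Hebbian drift is quadratic in the noise floor. What changes with delay
  is instead the probability that the attended attractor has collapsed —
  which *releases* competition at the probe. Unattended accuracy
  therefore tends to rise slightly with delay while attended accuracy
  falls, inverting the expected load × delay interaction.
* **Pulse-restored decodability.** The weak uniform pulse re-ignites
  stored patterns, but the competition it re-instates is won
  preferentially by the fresher (attended) trace; the unattended item's
  expression stays near the decoding floor.
* **Retro-cue congruency.** The incidental cue re-activates the cued
  item only on trials where the attended attractor has already collapsed
  (otherwise within-dimension inhibition silences the cue's own input
  unit), and on exactly those trials the later probe could have performed
  the same re-ignition by itself. The activity *shift* toward the cued
  item is reliable, but the congruent-vs-incongruent accuracy difference
  is only ≈ +0.03 and is not detectable at 200 trials per arm.
* **Transposition gradient.** Errors flow predominantly toward the most
  recent (attended) item rather than toward serial neighbors, so
  neighbor transpositions do not exceed distant intrusions even under
  whole-sequence report.
* **Long-lag conjunctive stability.** The stimulus-to-conjunction
  assignment self-organizes into feature niches: a conjunction that last
  encoded an item keeps capturing items that overlap it, which re-writes
  the shared feature and perpetuates the niche. Same-stimulus pattern
  similarity therefore stays above different-stimulus similarity beyond
  ten trial lags, rather than vanishing after about six. Intervening
  conjunction *violations* do erode it — the violation contrast holds —
  but baseline churn alone does not.

The facilitation-only variant replaces Hebbian learning with a
presynaptic facilitation variable (`u` incremented by `(1−u)·U·rate` with
`U = 0.2`, decaying with a 150-step time constant) that multiplies the
outgoing efficacy of the fixed uniform weights. Because `u` is shared
across postsynaptic targets, transmission is boosted indiscriminately and
the uniform weights scaled by `u` stay below the rate threshold once
input ends, so no item-selective attractor survives. (An additive
efficacy form `1+u` would instead let a single item persist purely
through winner-take-all rate hysteresis — a useful boundary case, but not
this variant.) The frozen-feedback variant
(`no_c_to_f_plasticity`) cannot sustain persistent activity at the
canonical operating point: its feedback weights stay at the uniform
initialization value 0.5 (four entries, unit row norm), below the rate
threshold that the calibrated full model requires, so this variant loses
persistence as well as recall here. The conjunction-free variant stores
items in a plastic feature-feature matrix (diagonal held at zero) and
keeps persistence and cue-driven shifting while losing the shared
conjunctive bottleneck.

## Numerical choices

Euler integration with `tau` in steps; rates clipped to [0, 1] after each
update; weight rows renormalized after every Hebbian increment (a no-op
for silent rows); exact ties in winner or report argmax break to the
lowest index (reachable only in degenerate noiseless setups); non-reports
are scored incorrect; reaction time is the threshold-crossing step count
from probe onset, with no millisecond calibration. All randomness flows
through R's generator: a run seed expands into counter-derived block
seeds, and every output row records its block seed and configuration
hash.
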