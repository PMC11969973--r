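---
title: "A planar neuromusculoskeletal model of gait and freezing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A planar neuromusculoskeletal model of gait and freezing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fogsim)
```

## The model

`fogsim` simulates sagittal-plane bipedal gait with a seven-link body
(head-arms-torso lumped as one segment, plus thighs, shanks and feet),
eighteen Hill-type muscles (nine per leg: gluteus maximus GM, iliopsoas
IL, biceps femoris long and short heads BFL/BFS, rectus femoris RF,
vastus VA, gastrocnemius GC, soleus SO, tibialis anterior TA), and a
two-level neural controller:

* a **brainstem stage** modelling the midbrain locomotor region (MLR) as
  two coupled rate neurons, the pedunculopontine nucleus (PPN) and the
  cuneiform nucleus (CnF). CnF output drives the spinal rhythm
  generator; PPN output divides the posture-control command, so high
  PPN activity releases muscle tone and low PPN activity stiffens the
  body;
* a **spinal stage**: a central pattern generator (CPG) of twelve
  Matsuoka-type rate units with self-inhibitory adaptation, organized as
  flexor/extensor half-centre pairs for hip, knee and ankle of each leg,
  coupled ipsilaterally and contralaterally, and modulated by segment
  angle and limb-load feedback. Alpha-motoneurons combine CPG output
  with posture control through a decreasing sigmoid and excite the
  muscles.

The body model uses pin joints with linear viscous torques (hip 1.09,
knee 3.17, ankle 0.943 N m s/rad), elastic-plus-damping joint-limit
torques beyond the knee range [-2.8, -0.1] rad and ankle range
[-1.0, 0.54] rad (stiffness 2.0e3 N m/rad for both; damping 3.0e2 and
3.0e1 N m s/rad), and unilateral spring-damper ground contact (vertical
2.5e4 N/m and 1.0e3 N s/m, horizontal 5.0e3 N/m and 1.0e2 N s/m). The
vertical contact force is clamped at zero (the ground cannot pull) and
the horizontal spring anchors at the touchdown position and releases
when the foot unloads (a stick model; the anchor rule is our choice, as
only the coefficients are published).

Coordinates: x forward, y up; segment angles counterclockwise from the
vertical (feet: from the horizontal), so knee flexion is negative.
Gravity is 9.81 m/s^2.

### What is published and what is surrogate

All constants quoted above carry published values. The remaining
quantities are **surrogates**, chosen once from the planar-biped
modelling lineage this model belongs to and flagged `surrogate = TRUE`
in the configuration:

* segment masses/lengths/inertias for a ~70 kg, ~1.7 m adult;
* the muscle table (maximum isometric tensions, optimal lengths,
  velocity normalizers, damping and passive-elastic moduli, constant
  moment arms with rest length at the standing posture);
* MLR time constants (0.15 s for PPN, 0.05 s for CnF, preserving the
  published requirement that PPN is slower than CnF) and the
  decay/input coefficients, **calibrated so that the fixed point under
  unit higher-center input is exactly (1, 1)** — this is forced by the
  published steady state, given the published cross-couplings
  w(PPN<-CnF) = 0.10 and w(CnF<-PPN) = 0.01;
* CPG unit time constants (0.04 s and 0.25 s, adaptation gain 2.5),
  calibrated once for a roughly 1 s autonomous cycle under unit drive;
* the functional forms of the sensory-feedback and posture-control
  operators (below); and the motoneuron routing magnitudes.

A user with better tables can replace any of these through the
configuration object without touching code.

### Feedback and posture operators

The published controller parameterizes sensory feedback with 16 weights
and posture control with 23 weights but does not print the functional
forms. We implement both as fixed, mirror-symmetric structures whose
nonnegative weights are the optimizer's targets:

* **Feedback** (16 weights): linear combinations of the eight segment
  angles and the two vertical ground-reaction forces, wired as
  stretch-type reflexes (thigh/shank angle onto the hip and knee
  half-centres) and load-type reflexes (own and contralateral limb load
  onto flexor/extensor half-centres, load onto the ankle units, trunk
  pitch onto the hip flexors).
* **Posture control** (23 weights): stance-gated terms — antigravity
  support of the five extensor groups proportional to limb load,
  proportional-derivative control of trunk pitch at the hip, an ankle
  strategy responding to body sway and sway rate over the planted foot,
  knee-collapse support, swing-phase flexor/dorsiflexor assistance,
  single-support load transfer, and a tonic stance dorsiflexor weight
  that shifts the sway equilibrium (hence the centre of pressure)
  forward — the gait-initiation "lean" dial. Entries are signed so that, through the decreasing
  motoneuron sigmoid, a loaded leg's extensors are excited.

Both operators are isolated behind single functions
(`sensory_feedback()`, `posture_control()`) so exact forms can be
swapped in.

### Muscles and energetics

Muscle tension follows the Hill-type law with force-length relationship
`0.32 + 0.71 exp(-1.112 (xi - 1)) sin(3.722 (xi - 0.656))`,
force-velocity relationship `1 + tanh(3 eta)` (eta positive while
lengthening, so eccentric force exceeds isometric), a parallel damper,
and an exponential passive-elastic element. The raw law can turn
slightly negative through the damping term; the tendon force applied to
the skeleton is clamped at zero because muscles cannot push. Activation
comes directly from the motoneuron sigmoid, clamped to [0, 1]; no
additional activation filter is interposed because none is specified.

The metabolic model behind the cost of transport is a deliberate
surrogate (the published model's internals are not reproduced here): a
basal rate plus activation-proportional maintenance and
shortening-proportional terms, scaled by each muscle's force and
velocity capacity. It is nonnegative, nondecreasing in activation, and
proportional to maximum isometric tension — the properties the cost of
transport needs.

## Simulation

The coupled system is integrated with fixed-step fourth-order
Runge-Kutta at dt = 0.1 ms for 15 s, recording at 100 Hz. Contact
anchors are held across the four sub-evaluations of a step and updated
afterwards. A fall is declared when the hip drops below 60% of its
standing height or the trunk pitches beyond 1 rad; the run then ends
normally with the fall time recorded. The initial state is upright
double-support standing with a small forward lean and resting neural
states, except for a small fixed left/right-asymmetric seed in the CPG
internal states: a perfectly symmetric state is a degenerate
equilibrium of the bilaterally symmetric dynamics from which
alternating stepping can never emerge, and the seed stands in for the
infinitesimal fluctuation that selects which leg swings first.

The compiled (C++) engine mirrors an R reference implementation of the
full right-hand side; the test suite asserts their agreement to 1e-9 on
random states, and the engine is bitwise deterministic given identical
inputs.

Gait metrics: distance D (hip displacement until the fall or the end),
step count S (vertical-GRF onsets with a 0.15 s debounce on both the
preceding unloaded and following loaded phase — brief force spikes from
contact chatter are not steps), duration T, speed V = D/T, and gross
metabolic cost of transport C = (1/(T M V)) \int sum E dt. C is
reported missing (never infinite) when T or V is zero.

## Optimization and the command sweep

49 free parameters are optimized: the CnF-to-CPG input weight u0 (1),
feedback weights (16), free CPG connection gains (9, expanded by the
symmetry skeleton into the 12 x 12 matrix), and posture weights (23).
The optimizer is a standard real-coded generational GA — tournament-2
selection, per-gene blend crossover (rate 0.9), Gaussian mutation
(sd 5% of range, geometrically annealed to a 15% floor), elitism 2,
population 64 — maximizing the published two-branch fitness with the
-2.5 fall penalty. Failures score at the minimum fitness; evaluation
goes through a pluggable `lapply`-compatible map, so parallel backends
plug in without changing results; everything is seeded.

The abnormal-brainstem sweep varies the higher-center command
intensities (s_PPN, s_CnF) over 0.00 to 2.00 in 0.01 increments on a
half-open square — 200 values per axis, exactly 40,000 pairs, matching
the published count (a closed square would give 40,401) — applying each
command only during the first 3 s. Each cell records walked distance
(15 s and 3 s), the fall flag, the first-3-s freeze ratio and the
freezing-of-gait flag. Cells are independent, so results do not depend
on evaluation order or worker count.

## Freezing-of-gait detection

The detector consumes the anteroposterior acceleration of each shank
midpoint (second central difference of the 100 Hz position series) and
the shank angular velocities. Per 2-s window (0.5 s hop), the **freeze
ratio** is the FFT band power at 3-10 Hz divided by the band power at
0-3 Hz of the mean-detrended window (bands half-open, so the 3 Hz bin
belongs to the freeze band; windows with locomotor power below 1e-12
are capped at 100 and flagged degenerate). The **bilateral
correlation** is the windowed Pearson r between the shank angular
velocities; because normal alternating gait makes the two shanks
strongly anti-phase (r near -1), *low coupling* means low |r|. A window
is freezing-positive when the freeze ratio exceeds 2.0 and |r| falls
below 0.4; overlapping positive windows merge into episodes, episodes
shorter than 0.5 s are dropped, and a run is flagged FOG when an
episode intersects the first 3 s, where the abnormal command acts. The
window length, hop and thresholds are configuration values: the
algorithm's two statistics are published but its constants are not, so
the defaults were fixed once against the planted-episode fixtures
(100% recall, zero false episodes) before any sweep was run. By default
the larger of the two legs' ratios is used; a single leg can be
selected.

## Cluster analysis and statistics

Freezing-positive (s_PPN, s_CnF) pairs are clustered with Euclidean
distance and Ward's linkage (`hclust`, `ward.D2`). The *agglomeration
coefficient* for k clusters is the linkage height of the merge that
forms the k-cluster partition; the published stopping rule — a large
percent increase in the coefficient decrease followed by a plateau — is
implemented as: take the largest percent change whose successors all
stay below 70% of it (changes under 20% never count as spikes; a
featureless profile yields k = 1 with a warning). Ties in Ward merges
are resolved lowest-index-first for cross-platform reproducibility.

Cluster comparisons follow the published gate: Shapiro-Wilk normality
per cluster and Levene's variance-equality test select one-way ANOVA
with pairwise t-tests when both hold, otherwise Kruskal-Wallis with
pairwise Mann-Whitney U tests; pairwise p-values are Bonferroni
adjusted (min(1, p x comparisons)); singleton clusters are excluded
from pairwise testing with a warning.

## Synthetic fixtures

Two seeded generators make every stage testable without simulation:

* `synthetic_gait_signals()` builds anti-phase locomotor sinusoids with
  planted trembling intervals. The "uncorrelated" tremble component is
  a tone detuned by 1 Hz — an integer number of beat cycles per
  analysis window — so windowed correlations vanish by orthogonality
  rather than on average; planted ground truth is returned alongside.
  It emulates the band structure and bilateral coupling the detector
  uses, not full musculoskeletal dynamics: passing fixture tests shows
  the detector's statistics behave as specified, not that simulated
  trajectories resemble patient data.
* `synthetic_cluster_points()` draws seeded Gaussian blobs clipped to
  the command square, with labels, for the cluster pipeline (the
  default sizes 27/64/53/12 echo the published cluster cardinalities as
  a shape test).

## Numerical choices and limitations

* RK4 at 0.1 ms resolves the stiffest contact transients; the
  convergence test checks that halving dt changes a short trajectory
  far less than the step-size ratio.
* 1/u_PPN is floored at 1e-3 inside the motoneuron equation only, so
  zero PPN drive (a sweep cell) stays integrable while preserving
  "low PPN, high tone" behaviour.
* The problem sizes used by the shipped tests are chosen for a desk
  run: planted-fixture suites of ~10 seeds, 100-seed cluster recovery,
  1,000-replicate null calibration, and single 15-s simulations of the
  packaged controller rather than GA re-runs or the full 40,000-cell
  sweep; the sweep function itself accepts arbitrary grid subsets.
* The GA that produced the packaged controller was run in stages
  (short-horizon bootstraps at a coarsened integration step, template
  re-seeding, full-horizon refinement), with the final vector
  evaluated at the study step of 0.1 ms.
* **Known limitation — stance, not locomotion.** Under the packaged
  surrogate reflex and posture structures, the optimizer reliably
  discovers quiet upright stance (15 s without falling) but repeatedly
  fails to cross the fitness valley separating stance from coordinated
  stepping: single-step attempts always score below the stable stander
  under the published two-branch fitness, and multi-hour searches from
  several seedings (random, stance-templated, stance-plus-rhythm
  hybrids, forward-lean dialled, progression-only interim objectives)
  plateaued at stance. Gait initiation in this model family is known
  to be sensitive to the exact reflex forms, which here are surrogates
  for unpublished supplementary material; with the exact published
  forms the same pipeline (fitness, GA, sweep, detector, clustering)
  applies unchanged. Everything downstream of the simulator is
  exercised by synthetic fixtures and does not depend on a walking
  controller.
* 2-D dynamics cannot capture lateral balance or arm swing; the
  surrogate reflex forms, while faithful to the published parameter
  counts and symmetries, are one member of a family consistent with
  the text.
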