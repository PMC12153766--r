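---
title: "Tracking group-housed animals: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking group-housed animals: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentrack)
```

# The problem

Continuous monitoring of pigs (and other livestock) in pens is a
multi-object tracking problem: a detector proposes per-frame bounding
boxes, and an association step must link them into per-animal trajectories
that survive occlusion, lighting changes and detector lapses. In practice
the detector is the fragile part — at night or in an unfamiliar pen its
confidence drops and its boxes jitter — so the association strategy
determines whether identities survive. `pentrack` implements the
association and evaluation machinery only; it deliberately contains no
detector, and instead ships a detector *emulator* so every component can
be exercised and measured end to end.

# The association cascade

Detections are split by confidence: high (`conf ≥ τ_high`), low
(`τ_low ≤ conf < τ_high`), discarded (below `τ_low`). The idea, inherited
from the ByteTrack family, is that low-confidence detections are often
real animals that are partly hidden — throwing them away is what breaks
trajectories during occlusion.

Each live track carries a constant-velocity Kalman state
`(cx, cy, a, h)` plus velocities (`a` = width/height, `h` = height in
pixels). Matching proceeds in three stages, each a gated minimum-cost
bipartite assignment:

1. **IoU stage** — high detections vs. Kalman-predicted boxes, cost
   `1 − IoU`, pairs with IoU < `iou_gate_stage1` ineligible.
2. **Center-distance stage** — the leftovers of stage 1, cost in raw
   pixels. Under partial occlusion a detector box shrinks to the visible
   fragment: IoU with the prediction collapses while the *center* stays
   close, which is exactly the failure this stage repairs.
3. **Fused stage** — remaining tracks vs. low detections, cost
   `λ(1 − IoU) + (1 − λ) min(d_cos, 1)` with `d_cos` the cosine distance
   between the detection embedding and the track's appearance template.
   When either side lacks an embedding the pair falls back to pure IoU
   distance, so the stage degrades gracefully rather than failing.

Unmatched low detections are discarded — they are too unreliable to start
tracks — and only unmatched *high* detections found new tracks.

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `tau_high` | 0.6 | – | conventional high/low split of the ByteTrack lineage |
| `tau_low` | 0.1 | – | below this, detections are overwhelmingly clutter |
| `iou_gate_stage1` | 0.3 | IoU | loose enough for fast motion, tight enough to stop teleporting matches |
| `dist_gate_stage2` | half the mean predicted-box diagonal | px | scales with animal size, not image size — raw pixels, gated adaptively, no image-size normalization |
| `fuse_lambda` | 0.5 | – | equal weight of geometry and appearance; both terms live on `[0, 1]` because the cosine term is clipped |
| `fused_gate_stage3` | 0.7 | cost | admits a zero-IoU pair only when appearance distance is ≤ 0.4 at the default λ |
| `max_age` | 30 | frames | 1 s at the 30 fps the input video is standardized to |
| `n_init` | 3 | hits | suppresses one- and two-frame clutter tracks |
| `ema_alpha` | 0.9 | – | slow template drift; a heavily occluded crop should not overwrite an identity's appearance |
| Kalman `std_weight_position` | 1/20 | of box height | SORT-family convention |
| Kalman `std_weight_velocity` | 1/160 | of box height | SORT-family convention |

All of these are plumbed through `cascade_config()` / `tracker_config()`,
the YAML run configuration and the CLI flags.

## Track lifecycle

`tentative → confirmed → lost → removed`. A tentative track is removed on
its first miss; a confirmed track that misses becomes lost but keeps
coasting on its prediction — and stays eligible in **all three** stages —
until `max_age` frames pass. Tracks born on the very first processed
frame are confirmed immediately. This is the ByteTrack-lineage convention,
and it is also what makes the perfect-input law exact: on a noiseless
scenario where every animal is present from frame 1, no frames are lost
to the tentative phase and MOTA is exactly 1. A track born mid-sequence
still needs `n_init` consecutive hits, so a 100-frame appearance starting
after the first frame yields `100 − (n_init − 1)` output rows.

Output rows carry the *matched detection's* box rather than the updated
Kalman box: the detection is the measurement actually observed, and using
it keeps localization error attributable to the detector, not the filter.

# The Kalman filter

Standard linear-Gaussian filtering with measurement `(cx, cy, a, h)` and
process/measurement noise scaled by box height; the covariance update uses
the Joseph form so positive semidefiniteness survives long coasting runs.
Two properties matter and are tested:

- the filter is asymptotically exact on noiseless constant-velocity
  motion (the model class contains the truth), with prediction error
  decaying geometrically;
- the transient scales linearly with target speed, because the filter
  starts with zero velocity. For a 1 px/frame amble — a slow walk at
  30 fps — the tracked center sits within 0.1 px of truth after 10
  updates; a 4 px/frame trot needs proportionally longer.

# The domain-aware attention operator

The operator rescales the channels of a `C × H × W` feature map to adapt
a shared backbone to different scenes (day vs. night, familiar vs. novel
pen). Three ESE branches — each a single `C × C` fully connected layer on
the globally average-pooled channel vector, with no reduction ratio —
produce candidate channel descriptors. A `3 × C` projection of the same
pooled vector, through a max-stabilized softmax, yields domain weights on
the simplex; their convex combination is the domain-adaptive response,
and each channel is multiplied by the sigmoid of its response component.

Two readings of "weighting the stacked branch outputs" are possible; the
convex-combination reading is implemented because it is the only one that
produces a C-vector consumable by the final per-channel sigmoid scaling.
Similarly, branch activations are deferred to that final sigmoid rather
than applied inside each branch, avoiding double saturation. The operator
is inference-only: parameters are supplied (or loaded from a JSON
container with shape validation), never trained here — training belongs
to the detection network, which is out of scope.

Consequences that serve as invariants: outputs are strictly attenuated
copies of input channels; permuting the branches together with the rows
of the domain projection changes nothing; if the three branches are
identical the domain weights are irrelevant.

# Evaluation metrics

`clear_match()` implements the CLEAR-MOT correspondence protocol:
correspondences persisting from the previous frame are kept while their
IoU clears the threshold (0.5 by default, the MOTChallenge standard), the
remainder are matched by minimum `1 − IoU` assignment, and an identity
switch is logged when a ground-truth identity's matched hypothesis id
differs from its most recent earlier match. MOTA and MOTP read off this
log; IDF1 solves the global trajectory bijection; HOTA computes a single
per-frame matching from global alignment scores and thresholds it over
the 19 IoU levels.

Two printed-form ambiguities are resolved deliberately, with flags
preserving the literal alternatives:

- **MOTP** is reported as mean matched IoU (higher-better, matching how
  tracking tables mark it); `motp(log, as_distance = TRUE)` gives the
  literal distance-ratio form with center distance as `d`.
- **HOTA** uses the canonical geometric mean `sqrt(DetA · AssA)`;
  `hota(..., use_sqrt = FALSE)` gives the plain product sometimes printed
  without the root.

The whole suite is cross-checked against an independently written Python
reference evaluator (numpy + `scipy.optimize.linear_sum_assignment`,
bundled with the tests) to 1e-6 on noisy simulated scenarios — two
implementations, two languages, two assignment solvers.

The assignment solver itself is a Jonker–Volgenant shortest augmenting
path implementation written for this package (no LAP solver ships with
the environment's R), validated against brute-force permutation
enumeration on every matrix size it meets in practice.

# The synthetic pen world

`simulate_ground_truth()` emulates the structure of top-down pen
recordings: 2–20 animals that never leave a 1280×720 px pen, fixed
per-animal box sizes, overlap-free initial placement (animals do not
materialize on top of each other), correlated random walks (heading
persistence 0.9, 4 px/frame) with reflecting walls. Occlusion is generated causally:
episodes start as a Poisson process at `occlusion_rate` per 100 frames,
and in each episode one animal closes in on its nearest neighbour until
their boxes actually overlap, holds contact for 8–15 frames, then
resumes its walk. This makes the occlusion knob mean what it says — the
counted episode rate lands near the configured rate — rather than being
an indirect property of walk parameters. Visibility is
`1 − max fractional overlap` by any other box; no 3D depth ordering is
modelled, which is sufficient to trigger the occlusion code paths the
cascade exists for.

`emulate_detector()` degrades with occlusion on every axis: miss
probability interpolates `detector_miss_base → detector_miss_occluded`
with falling visibility, surviving boxes get Gaussian jitter, confidence
interpolates between its visible and occluded means, and embeddings are
unit-normalized identity prototypes plus visibility-dependent Gaussian
noise. False positives arrive as a Poisson stream of low-confidence boxes
with random embeddings. The `day` preset (6 animals, 5% base miss, clean
embeddings) and `night` preset (10 animals, 20% base miss, depressed
confidence straddling `tau_high`, noisy embeddings, more occlusion)
reproduce the qualitative contrast between well-lit and dim recordings;
the night preset is deliberately built so that a large fraction of
occluded animals surfaces only as low-confidence detections — the regime
the fused third stage exists for.

What the simulator does *not* emulate: appearance drift over time,
camera motion, animals entering or leaving, correlated (non-independent)
detector failures, and the systematic embedding degradation of a real
re-identification head on crowded crops. Passing the end-to-end laws
here therefore demonstrates the correctness and internal value of the
association machinery under controlled conditions, not field performance
on real video.

Reproducibility: each scenario draws from R's generator seeded with
`seed` (trajectories) and `seed + 1` (detector), each half consuming
draws in a fixed documented order, so outputs are bit-identical across
runs and the two halves are independently reproducible.

# Numerical choices

- Boxes are half-open real-valued rectangles; touching edges have IoU 0,
  and no pixel snapping occurs anywhere (Kalman predictions are
  sub-pixel).
- The cosine term of the fused cost is clipped to `[0, 1]` so both cost
  terms share a scale and the gate stays interpretable.
- Softmax subtracts the max logit before exponentiation.
- Gated assignment replaces ineligible entries by a cost exceeding any
  full eligible assignment, which first maximizes the number of eligible
  matches and then minimizes their cost — the tracking-literature
  convention — and the deterministic solver breaks ties reproducibly.
- Visibility values are clamped to `[0, 1]` against floating-point
  rounding of the overlap ratio.

# Problem sizes

The shipped tests run the oracle comparisons on 60-frame, 5-animal noisy
scenes (20 seeds), the ablation on the full 300-frame, 10-animal night
preset (20 seeds), and the perfect-input law on the 300-frame, 6-animal
noiseless scenario; the acceptance script uses the same sizes. These are
desk-scale choices: large enough to contain dozens of occlusion episodes
per run, small enough that the whole suite completes in minutes on one
CPU.

# Known limitations

- No camera-motion compensation and no appearance-gallery banks; the
  template is a single EMA vector per track.
- The Euclidean stage can, in principle, bridge two *different* nearby
  animals when both are unmatched and closer than the gate; the gate's
  size-adaptive default keeps this rare in practice but cannot exclude it.
- HOTA sub-metrics beyond `DetA`/`AssA` (localization decompositions) are
  not computed.
- Metrics assume one box per identity per frame in both inputs and
  reject duplicates rather than resolving them.
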