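# pentrack

Multi-object tracking and evaluation for top-down video of group-housed
animals (pigs in pens being the motivating case). The package provides the
association machinery of a tracking-by-detection pipeline — everything
downstream of the detector — together with the full evaluation suite and a
synthetic pen simulator, so the tracker can be developed, stress-tested and
benchmarked without a trained detection network or real video.

## What it implements

**Three-stage association cascade.** Per frame, detections are split by
confidence into a high group (`conf ≥ τ_high`), a low group
(`τ_low ≤ conf < τ_high`) and a discarded remainder. Tracks carry a
constant-velocity Kalman state over `(cx, cy, a, h)` — box center, aspect
ratio, height — whose predicted box enters the matching:

1. **IoU stage.** High-confidence detections vs. predicted track boxes,
   cost `1 − IoU`, solved by minimum-cost bipartite assignment (Hungarian
   problem), gated at IoU ≥ 0.3.
2. **Euclidean re-association.** Leftover tracks vs. leftover high
   detections on raw pixel center distance
   `d = sqrt((x_pred − x_det)² + (y_pred − y_det)²)`, recovering occluded
   targets whose distorted boxes no longer overlap their prediction.
3. **Fused low-confidence stage.** Remaining tracks vs. the low group on
   `λ·(1 − IoU) + (1 − λ)·min(d_cos, 1)`, where `d_cos` is the cosine
   distance between the detection's re-identification embedding and the
   track's template (an exponential moving average of matched embeddings).

New tracks are born only from unmatched high-confidence detections; lost
tracks coast on their Kalman prediction and stay matchable until `max_age`
frames pass.

**Domain-aware channel attention.** An inference-only feature-map operator
for scene/lighting adaptation: three effective squeeze-and-excitation (ESE)
branches on the globally average-pooled channel vector, softmax domain
weights `S = softmax(W_C · avgpool(F))`, their convex combination as the
domain-adaptive response, and channel-wise rescaling `F_c · σ(response_c)`.

**Evaluation suite.** CLEAR-MOT correspondence (persisting matches kept,
remainder by minimum `1 − IoU` assignment at IoU ≥ 0.5) feeding

- `MOTA = 1 − (FN + FP + IDSW) / GT`,
- `MOTP` (mean matched-pair IoU; a flag recovers the literal
  distance-ratio form),
- `IDF1 = 2·IDTP / (2·IDTP + IDFP + IDFN)` from the optimal global
  identity bijection,
- `HOTA = mean_α sqrt(DetA_α · AssA_α)` over α ∈ {0.05, …, 0.95},
- MT, ML, IDS, FP, FN.

**Synthetic pen scenarios.** Correlated random walks with reflecting walls
inside a 1280×720 pen, scheduled occlusion episodes (one animal closes in
on another until their boxes overlap), and a detector emulator whose miss
rate, box jitter, confidence and embedding noise all degrade with
occlusion. `day_night_presets()` packages a clean daytime regime and a
dim, denser nighttime regime; `zero_noise_config()` gives the perfect
detector against which the tracker must score MOTA = IDF1 = 1.

## Worked example

```r
library(pentrack)

pr  <- day_night_presets(seed = 1)
sc  <- simulate_scenario(pr$night)              # 10 animals, 300 frames
hyp <- run_sequence(sc$stream, tracker_config())
evaluate_tracking(sc$gt, hyp)
#>    MOTA  MOTP  IDF1  HOTA MT ML IDS FP   FN   GT n_gt_ids
#> 1 0.647 0.841 0.746 0.535  0  0  21  6 1033 3000       10
```

On this nighttime scene the emulated detector misses a third of the boxes
(FN = 1033 of 3000), yet identity is held well (IDF1 = 0.75). Disabling
the low-confidence fused stage (`cascade_config(enable_stage3 = FALSE)`)
collapses MOTA to 0.20 on the same input: the low-confidence detections
that stage 3 consumes carry most of the occluded animals. Averaged over
20 night seeds, stage 3 also reduces identity switches (mean IDS 11.9
vs. 18.9).

A command-line interface covers the same pipeline:

```sh
Rscript inst/cli/pentrack.R demo --preset zero --seed 3   # prints MOTA = 1.000
Rscript inst/cli/pentrack.R simulate --preset night --seed 1 --out-dir scene/
Rscript inst/cli/pentrack.R track --det scene/det.txt --emb scene/embeddings.txt --out scene/result.txt
Rscript inst/cli/pentrack.R evaluate --gt scene/gt.txt --result scene/result.txt
```

Files use the MOTChallenge text format; embeddings travel in a plain
`frame, ordinal, v1..vD` sidecar.

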