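# Independent oracles and fixture builders shared across tests.

# Brute-force minimum-cost assignment: enumerate every injection of the
# smaller side into the larger and take the cheapest total cost.
perm_assignment_min <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(0)
  if (n > m) return(perm_assignment_min(t(cost)))
  permute <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(permute(v[-i]), function(p) c(v[i], p))
    }))
  }
  best <- Inf
  for (cols in utils::combn(m, n, simplify = FALSE)) {
    for (p in permute(cols)) {
      tot <- sum(cost[cbind(seq_len(n), p)])
      if (tot < best) best <- tot
    }
  }
  best
}

# Pixel-enumeration IoU for integer-coordinate boxes: count unit pixels
# (half-open membership) inside both rectangles and inside either.
pixel_iou_oracle <- function(a, b) {
  xs <- seq(min(a[1], b[1]), max(a[1] + a[3], b[1] + b[3]) - 1)
  ys <- seq(min(a[2], b[2]), max(a[2] + a[4], b[2] + b[4]) - 1)
  grid <- expand.grid(x = xs, y = ys)
  in_box <- function(box) {
    grid$x >= box[1] & grid$x < box[1] + box[3] &
      grid$y >= box[2] & grid$y < box[2] + box[4]
  }
  ia <- in_box(a); ib <- in_box(b)
  sum(ia & ib) / sum(ia | ib)
}

# Cross-check against the independent Python reference evaluator.
run_mot_oracle <- function(gt, hyp) {
  gt_path <- tempfile(fileext = ".txt")
  hyp_path <- tempfile(fileext = ".txt")
  on.exit(unlink(c(gt_path, hyp_path)), add = TRUE)
  write_mot(cbind(gt[, c("frame", "id", "left", "top", "width", "height")],
                  conf = 1), gt_path)
  write_mot(hyp, hyp_path)
  out <- system2("python", c(test_path("oracle_mot.py"), gt_path, hyp_path),
                 stdout = TRUE, stderr = TRUE)
  jsonlite::fromJSON(paste(out, collapse = ""))
}

# Two targets crossing paths (passing through each other), with clean
# high-confidence detections and distinct constant embeddings.
make_crossing_stream <- function(n_frames = 50) {
  lapply(seq_len(n_frames), function(f) {
    xa <- 4 * (f - 1)               # left-to-right
    xb <- 4 * (n_frames - f)        # right-to-left, same row
    detections(rbind(c(xa, 100, 40, 40), c(xb, 100, 40, 40)),
               c(0.9, 0.9), rbind(c(1, 0), c(0, 1)), frame = f)
  })
}

# Two targets that approach head-on, collide mid-sequence and bounce back,
# with detection confidence dipping into the low band while they overlap.
# Holding identity through the bounce requires the low-confidence fused
# association stage: pure coasting extrapolates both tracks straight
# through the collision and swaps them.
make_bounce_stream <- function(n_frames = 20, bounce = 10) {
  lapply(seq_len(n_frames), function(f) {
    xa <- if (f <= bounce) 8 * f else 8 * bounce - 8 * (f - bounce)
    xb <- if (f <= bounce) 160 - 8 * f else 160 - 8 * bounce + 8 * (f - bounce)
    conf <- if (abs(xa - xb) < 40) c(0.3, 0.3) else c(0.9, 0.9)
    detections(rbind(c(xa, 100, 40, 40), c(xb, 100, 40, 40)),
               conf, rbind(c(1, 0), c(0, 1)), frame = f)
  })
}

# Ground truth matching make_bounce_stream / make_crossing_stream.
stream_to_gt <- function(stream) {
  do.call(rbind, lapply(stream, function(d) {
    data.frame(frame = d$frame, id = seq_len(d$n), left = d$boxes[, "left"],
               top = d$boxes[, "top"], width = d$boxes[, "width"],
               height = d$boxes[, "height"])
  }))
}

# Small noisy scenario for oracle agreement tests: modest size so the
# whole-suite runtime stays reasonable.
small_noisy_config <- function(seed) {
  scenario_config(n_identities = 5L, n_frames = 60L, occlusion_rate = 8,
                  detector_miss_base = 0.15, detector_miss_occluded = 0.5,
                  fp_rate = 0.4, box_jitter_std = 2.5,
                  confidence_mean_visible = 0.7,
                  confidence_mean_occluded = 0.3,
                  embedding_noise_std = 0.25,
                  embedding_noise_occluded_std = 0.5, seed = seed)
}

# Naive loop implementation of the attention forward pass, kept deliberately
# element-by-element as an oracle for the vectorized version.
daa_forward_loop <- function(F, params) {
  C <- dim(F)[1L]; H <- dim(F)[2L]; W <- dim(F)[3L]
  pooled <- numeric(C)
  for (c in seq_len(C)) {
    s <- 0
    for (i in seq_len(H)) for (j in seq_len(W)) s <- s + F[c, i, j]
    pooled[c] <- s / (H * W)
  }
  logits <- numeric(3)
  for (b in 1:3) {
    s <- 0
    for (c in seq_len(C)) s <- s + params$domain_fc[b, c] * pooled[c]
    logits[b] <- s
  }
  e <- exp(logits - max(logits))
  wts <- e / sum(e)
  branches <- matrix(0, 3, C)
  for (b in 1:3) {
    for (r in seq_len(C)) {
      s <- params$ese_biases[[b]][r]
      for (c in seq_len(C)) s <- s + params$ese_fcs[[b]][r, c] * pooled[c]
      branches[b, r] <- s
    }
  }
  sdc <- numeric(C)
  for (c in seq_len(C)) sdc[c] <- sum(wts * branches[, c])
  out <- F
  for (c in seq_len(C)) {
    sc <- 1 / (1 + exp(-sdc[c]))
    for (i in seq_len(H)) for (j in seq_len(W)) out[c, i, j] <- F[c, i, j] * sc
  }
  out
}

random_daa_params <- function(C) {
  daa_params(matrix(rnorm(3 * C), 3, C),
             lapply(1:3, function(b) matrix(rnorm(C * C), C, C)),
             lapply(1:3, function(b) rnorm(C)))
}

random_box <- function(max_pos = 200, max_size = 80) {
  c(runif(1, 0, max_pos), runif(1, 0, max_pos),
    runif(1, 5, max_size), runif(1, 5, max_size))
}
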