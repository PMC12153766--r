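#' Configuration of a synthetic pen scenario
#'
#' Describes a top-down rectangular pen with a fixed number of animals that
#' never enter or leave, a correlated-random-walk motion model with
#' reflecting walls and scheduled occlusion episodes, and a detector
#' emulator whose miss rate, box jitter, confidence and appearance-
#' embedding noise all degrade with occlusion — the levers that separate a
#' well-lit daytime recording from a dim nighttime one.
#'
#' @param n_identities number of animals (2-20)
#' @param pen_width,pen_height pen size in pixels
#' @param n_frames number of frames to simulate
#' @param speed_scale walk step length in px/frame
#' @param direction_persistence heading persistence in `[0, 1]`; 1 walks
#'   straight, 0 turns freely
#' @param occlusion_rate expected occlusion episodes per 100 frames,
#'   realized as scheduled pursuit episodes in which one animal closes in
#'   on another until their boxes overlap
#' @param detector_miss_base miss probability for a fully visible box
#' @param detector_miss_occluded miss probability for a fully occluded box
#'   (must be >= the base rate); intermediate visibility interpolates
#' @param fp_rate expected false-positive boxes per frame (Poisson)
#' @param box_jitter_std Gaussian jitter of surviving box coordinates, px
#' @param confidence_mean_visible,confidence_mean_occluded detector
#'   confidence for fully visible / fully occluded boxes
#' @param confidence_sd Gaussian spread around the confidence mean
#' @param embedding_dim dimension of the appearance embeddings
#' @param embedding_noise_std,embedding_noise_occluded_std Gaussian noise
#'   added to the identity prototype before unit normalization, for
#'   visible / occluded boxes
#' @param seed integer seed; the trajectory walk draws from `seed` and the
#'   detector emulator from `seed + 1`, so each half is reproducible on its
#'   own
#' @return a list with class `scenario_config`
#' @export
scenario_config <- function(n_identities = 6L, pen_width = 1280, pen_height = 720,
                            n_frames = 300L, speed_scale = 4,
                            direction_persistence = 0.9, occlusion_rate = 5,
                            detector_miss_base = 0.05,
                            detector_miss_occluded = 0.5,
                            fp_rate = 0.2, box_jitter_std = 2,
                            confidence_mean_visible = 0.85,
                            confidence_mean_occluded = 0.35,
                            confidence_sd = 0.05,
                            embedding_dim = 16L, embedding_noise_std = 0.1,
                            embedding_noise_occluded_std = 0.4, seed = 1L) {
  if (n_identities < 2 || n_identities > 20) {
    stop("n_identities must lie in 2..20", call. = FALSE)
  }
  for (p in c(detector_miss_base, detector_miss_occluded,
              confidence_mean_visible, confidence_mean_occluded)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (detector_miss_occluded < detector_miss_base) {
    stop("detector_miss_occluded must be >= detector_miss_base", call. = FALSE)
  }
  if (embedding_noise_occluded_std < embedding_noise_std) {
    stop("embedding_noise_occluded_std must be >= embedding_noise_std", call. = FALSE)
  }
  if (direction_persistence < 0 || direction_persistence > 1) {
    stop("direction_persistence must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(pen_width > 0, pen_height > 0, n_frames >= 1, speed_scale >= 0,
            occlusion_rate >= 0, fp_rate >= 0, box_jitter_std >= 0,
            confidence_sd >= 0, embedding_dim >= 1)
  # feasibility: the animals' boxes (at their maximum drawn size) must
  # comfortably fit in the pen
  if (n_identities * 110 * 80 > 0.5 * pen_width * pen_height) {
    stop("infeasible packing: pen too small for n_identities", call. = FALSE)
  }
  structure(list(
    n_identities = as.integer(n_identities), pen_width = pen_width,
    pen_height = pen_height, n_frames = as.integer(n_frames),
    speed_scale = speed_scale, direction_persistence = direction_persistence,
    occlusion_rate = occlusion_rate, detector_miss_base = detector_miss_base,
    detector_miss_occluded = detector_miss_occluded, fp_rate = fp_rate,
    box_jitter_std = box_jitter_std,
    confidence_mean_visible = confidence_mean_visible,
    confidence_mean_occluded = confidence_mean_occluded,
    confidence_sd = confidence_sd, embedding_dim = as.integer(embedding_dim),
    embedding_noise_std = embedding_noise_std,
    embedding_noise_occluded_std = embedding_noise_occluded_std,
    seed = as.integer(seed)), class = "scenario_config")
}

frac_overlap_matrix <- function(boxes) {
  n <- nrow(boxes)
  if (n < 2) return(matrix(0, n, n))
  x1 <- boxes[, "left"]; y1 <- boxes[, "top"]
  x2 <- x1 + boxes[, "width"]; y2 <- y1 + boxes[, "height"]
  ix1 <- outer(x1, x1, pmax); iy1 <- outer(y1, y1, pmax)
  ix2 <- outer(x2, x2, pmin); iy2 <- outer(y2, y2, pmin)
  inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  diag(inter) <- 0
  sweep(inter, 1L, boxes[, "width"] * boxes[, "height"], "/")
}

#' Simulate ground-truth trajectories in a pen
#'
#' Each animal gets a fixed box size and follows a correlated random walk
#' with reflecting walls; scheduled occlusion episodes steer one animal
#' toward another until their boxes overlap. Per-frame visibility is
#' `1 - max` fractional overlap of the animal's box by any other box.
#'
#' @param cfg a [scenario_config()]
#' @return a list with class `ground_truth_set`: `gt`, a data frame
#'   `(frame, id, left, top, width, height, visibility)`, and the `config`
#' @export
simulate_ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  n <- cfg$n_identities
  W <- cfg$pen_width; H <- cfg$pen_height

  w <- runif(n, 60, 100)
  h <- runif(n, 40, 70)
  # initial placement is overlap-free: animals never materialize on top of
  # each other in a top-down recording
  x <- y <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(1000L)) {
      xi <- runif(1, 0, W - w[i])
      yi <- runif(1, 0, H - h[i])
      prev <- seq_len(i - 1L)
      clear <- all(xi + w[i] <= x[prev] | x[prev] + w[prev] <= xi |
                     yi + h[i] <= y[prev] | y[prev] + h[prev] <= yi)
      if (clear) { x[i] <- xi; y[i] <- yi; placed <- TRUE; break }
    }
    if (!placed) stop("infeasible packing: could not place ", n,
                      " non-overlapping animals in the pen", call. = FALSE)
  }
  theta <- runif(n, 0, 2 * pi)
  sigma_turn <- (1 - cfg$direction_persistence) * pi

  pursuer <- integer(0)              # animals currently in an episode
  target <- integer(0)
  hold_left <- integer(0)            # frames of contact still to hold (NA = chasing)
  age <- integer(0)                  # total frames the episode has run

  out <- vector("list", cfg$n_frames)
  for (f in seq_len(cfg$n_frames)) {
    # maybe start a new pursuit episode: a free animal closes in on its
    # nearest free neighbour until their boxes overlap, holds contact for
    # a few frames, then resumes its walk
    if (cfg$occlusion_rate > 0 && n >= 2 &&
        runif(1) < cfg$occlusion_rate / 100) {
      free <- setdiff(seq_len(n), c(pursuer, target))
      if (length(free) >= 2) {
        p <- sample(free, 1L)
        others <- setdiff(free, p)
        cx <- x + w / 2; cy <- y + h / 2
        q <- others[which.min((cx[others] - cx[p])^2 + (cy[others] - cy[p])^2)]
        pursuer <- c(pursuer, p)
        target <- c(target, q)
        hold_left <- c(hold_left, NA_integer_)
        age <- c(age, 0L)
      }
    }
    # headings: correlated random walk, overridden for pursuers
    theta <- theta + rnorm(n, 0, sigma_turn)
    speed <- rep(cfg$speed_scale, n)
    if (length(pursuer)) {
      cx <- x + w / 2; cy <- y + h / 2
      for (e in seq_along(pursuer)) {
        p <- pursuer[e]; q <- target[e]
        theta[p] <- atan2(cy[q] - cy[p], cx[q] - cx[p])
        speed[p] <- 1.5 * cfg$speed_scale
      }
    }
    x <- x + speed * cos(theta)
    y <- y + speed * sin(theta)
    # reflecting walls
    for (i in seq_len(n)) {
      if (x[i] < 0) { x[i] <- -x[i]; theta[i] <- pi - theta[i] }
      if (x[i] > W - w[i]) { x[i] <- 2 * (W - w[i]) - x[i]; theta[i] <- pi - theta[i] }
      if (y[i] < 0) { y[i] <- -y[i]; theta[i] <- -theta[i] }
      if (y[i] > H - h[i]) { y[i] <- 2 * (H - h[i]) - y[i]; theta[i] <- -theta[i] }
      x[i] <- min(max(x[i], 0), W - w[i])
      y[i] <- min(max(y[i], 0), H - h[i])
    }
    boxes <- cbind(left = x, top = y, width = w, height = h)
    # advance episode phases: chase until contact, then hold, then release
    if (length(pursuer)) {
      fo <- frac_overlap_matrix(boxes)
      age <- age + 1L
      keep <- rep(TRUE, length(pursuer))
      for (e in seq_along(pursuer)) {
        p <- pursuer[e]; q <- target[e]
        contact <- max(fo[p, q], fo[q, p]) >= 0.2
        if (is.na(hold_left[e])) {
          if (contact) hold_left[e] <- sample(8:15, 1L)
          else if (age[e] > 80L) keep[e] <- FALSE   # give up on a stale chase
        } else {
          hold_left[e] <- hold_left[e] - 1L
          if (hold_left[e] <= 0L) keep[e] <- FALSE
        }
      }
      pursuer <- pursuer[keep]; target <- target[keep]
      hold_left <- hold_left[keep]; age <- age[keep]
    }
    vis <- pmin(pmax(1 - apply(frac_overlap_matrix(boxes), 1L, max), 0), 1)
    out[[f]] <- data.frame(frame = f, id = seq_len(n), left = x, top = y,
                           width = w, height = h, visibility = vis)
  }
  gt <- do.call(rbind, out)
  rownames(gt) <- NULL
  structure(list(gt = gt, config = cfg), class = "ground_truth_set")
}

#' @export
print.ground_truth_set <- function(x, ...) {
  cat("ground truth: ", x$config$n_identities, " identities over ",
      x$config$n_frames, " frames in a ", x$config$pen_width, "x",
      x$config$pen_height, " px pen\n", sep = "")
  invisible(x)
}

#' Count occlusion episodes in a ground-truth set
#'
#' An episode is a maximal run of consecutive frames during which a given
#' unordered pair of animals overlaps (intersection covering at least
#' `min_overlap` of the smaller box).
#'
#' @param gts a [simulate_ground_truth()] result
#' @param min_overlap overlap fraction that counts as occlusion
#' @return a list with the total `episodes` and `per_100_frames`
#' @export
count_occlusion_episodes <- function(gts, min_overlap = 0.1) {
  stopifnot(inherits(gts, "ground_truth_set"))
  gt <- gts$gt
  n <- gts$config$n_identities
  nf <- gts$config$n_frames
  episodes <- 0L
  active <- matrix(FALSE, n, n)
  for (f in seq_len(nf)) {
    g <- gt[gt$frame == f, , drop = FALSE]
    boxes <- as_box_matrix(g[, c("left", "top", "width", "height")])
    fo <- frac_overlap_matrix(boxes)
    big <- pmax(fo, t(fo))
    now <- big >= min_overlap & upper.tri(big)
    episodes <- episodes + sum(now & !active)
    active <- now
  }
  list(episodes = episodes, per_100_frames = 100 * episodes / nf)
}

#' Emulate a detector over a ground-truth set
#'
#' Each ground-truth box is dropped with a probability interpolating from
#' `detector_miss_base` (fully visible) to `detector_miss_occluded` (fully
#' occluded); survivors are jittered, given a visibility-dependent
#' confidence, and an appearance embedding equal to the unit-normalized sum
#' of the identity's prototype and visibility-dependent Gaussian noise.
#' False positives appear at `fp_rate` per frame with low confidence and
#' random unit embeddings.
#'
#' @param gts a [simulate_ground_truth()] result
#' @param cfg the matching [scenario_config()] (defaults to the one stored
#'   in `gts`)
#' @return a list of [detections()] objects, one per frame (frames with no
#'   surviving detection are present but empty), ready for
#'   [run_sequence()]
#' @export
emulate_detector <- function(gts, cfg = gts$config) {
  stopifnot(inherits(gts, "ground_truth_set"), inherits(cfg, "scenario_config"))
  set.seed(cfg$seed + 1L)
  D <- cfg$embedding_dim
  protos <- t(vapply(seq_len(cfg$n_identities),
                     function(i) normalize_embedding(rnorm(D)), numeric(D)))
  gt <- gts$gt
  mean_w <- mean(gt$width); mean_h <- mean(gt$height)
  stream <- vector("list", cfg$n_frames)
  for (f in seq_len(cfg$n_frames)) {
    g <- gt[gt$frame == f, , drop = FALSE]
    boxes <- conf <- emb <- NULL
    rows <- list(); confs <- numeric(0); embs <- list()
    for (k in seq_len(nrow(g))) {
      vis <- g$visibility[k]
      p_miss <- cfg$detector_miss_base +
        (cfg$detector_miss_occluded - cfg$detector_miss_base) * (1 - vis)
      if (runif(1) < p_miss) next
      b <- c(g$left[k], g$top[k], g$width[k], g$height[k])
      if (cfg$box_jitter_std > 0) {
        b <- b + rnorm(4, 0, cfg$box_jitter_std)
        b[3] <- max(b[3], 2); b[4] <- max(b[4], 2)
      }
      cf <- vis * cfg$confidence_mean_visible +
        (1 - vis) * cfg$confidence_mean_occluded
      if (cfg$confidence_sd > 0) cf <- cf + rnorm(1, 0, cfg$confidence_sd)
      cf <- min(max(cf, 0), 1)
      noise_sd <- cfg$embedding_noise_std +
        (cfg$embedding_noise_occluded_std - cfg$embedding_noise_std) * (1 - vis)
      e <- protos[g$id[k], ]
      if (noise_sd > 0) e <- e + rnorm(D, 0, noise_sd)
      rows[[length(rows) + 1L]] <- b
      confs <- c(confs, cf)
      embs[[length(embs) + 1L]] <- normalize_embedding(e)
    }
    n_fp <- if (cfg$fp_rate > 0) stats::rpois(1, cfg$fp_rate) else 0L
    for (k in seq_len(n_fp)) {
      fw <- max(2, mean_w * runif(1, 0.6, 1.4))
      fh <- max(2, mean_h * runif(1, 0.6, 1.4))
      rows[[length(rows) + 1L]] <- c(runif(1, 0, cfg$pen_width - fw),
                                     runif(1, 0, cfg$pen_height - fh), fw, fh)
      confs <- c(confs, runif(1, 0.1, 0.4))
      embs[[length(embs) + 1L]] <- normalize_embedding(rnorm(D))
    }
    stream[[f]] <- if (length(rows)) {
      detections(do.call(rbind, rows), confs, do.call(rbind, embs), frame = f)
    } else {
      detections(matrix(numeric(0), ncol = 4L), numeric(0),
                 matrix(numeric(0), ncol = D), frame = f)
    }
  }
  stream
}

#' Simulate a full scenario: ground truth plus emulated detections
#'
#' @param cfg a [scenario_config()]
#' @return a list with `gt` (MOT-style ground-truth data frame including a
#'   `visibility` column), `stream` (per-frame [detections()]) and the
#'   `config`
#' @export
simulate_scenario <- function(cfg) {
  gts <- simulate_ground_truth(cfg)
  list(gt = gts$gt, stream = emulate_detector(gts, cfg), config = cfg)
}

#' Day / night scenario presets
#'
#' Two fully specified detector-quality regimes: a well-lit daytime pen
#' (few misses, confident detections, clean embeddings) and a dim, denser
#' nighttime pen (frequent misses, depressed confidence, noisy embeddings,
#' more occlusion) — the contrast that makes the low-confidence third
#' association stage earn its keep.
#'
#' @param seed integer seed stored in both presets
#' @return a named list of two [scenario_config()]s, `day` and `night`
#' @export
day_night_presets <- function(seed = 1L) {
  list(
    day = scenario_config(
      n_identities = 6L, n_frames = 300L, occlusion_rate = 4,
      detector_miss_base = 0.05, detector_miss_occluded = 0.4,
      fp_rate = 0.1, box_jitter_std = 1.5,
      confidence_mean_visible = 0.85, confidence_mean_occluded = 0.45,
      embedding_noise_std = 0.1, embedding_noise_occluded_std = 0.3,
      seed = seed),
    night = scenario_config(
      n_identities = 10L, n_frames = 300L, occlusion_rate = 10,
      detector_miss_base = 0.2, detector_miss_occluded = 0.6,
      fp_rate = 0.5, box_jitter_std = 3,
      confidence_mean_visible = 0.62, confidence_mean_occluded = 0.3,
      embedding_noise_std = 0.3, embedding_noise_occluded_std = 0.6,
      seed = seed))
}

#' A noiseless scenario configuration
#'
#' Perfect detector: no misses, no jitter, no false positives, no
#' confidence or embedding noise, and no scheduled occlusion. A correct
#' tracker must score MOTA = 1, IDF1 = 1 and zero identity switches on it.
#'
#' @param ... overrides passed to [scenario_config()]
#' @return a [scenario_config()]
#' @export
zero_noise_config <- function(...) {
  defaults <- list(occlusion_rate = 0, detector_miss_base = 0,
                   detector_miss_occluded = 0, fp_rate = 0,
                   box_jitter_std = 0, confidence_sd = 0,
                   embedding_noise_std = 0, embedding_noise_occluded_std = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(scenario_config, args)
}
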