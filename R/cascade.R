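#' Configuration of the three-stage association cascade
#'
#' The cascade splits detections by confidence into a high group
#' (`conf >= tau_high`), a low group (`tau_low <= conf < tau_high`) and a
#' discarded remainder, then matches tracks to detections in three stages:
#' \enumerate{
#'   \item high-confidence detections against Kalman-predicted track boxes on
#'     IoU distance (`1 - IoU`), gated at `iou_gate_stage1`;
#'   \item leftover tracks against leftover high detections on raw pixel
#'     center distance, to recover occluded targets whose boxes barely
#'     overlap their prediction;
#'   \item remaining tracks against the low-confidence group on a weighted
#'     fusion of IoU distance and appearance (cosine) distance.
#' }
#'
#' @param tau_high confidence at or above which a detection is "high"
#' @param tau_low detections below this confidence are discarded
#' @param iou_gate_stage1 minimum IoU for a stage-1 match
#' @param dist_gate_stage2 stage-2 gate in pixels; `NULL` (default) uses
#'   half the mean diagonal of the participating predicted track boxes, so
#'   the gate scales with target size rather than image size
#' @param fuse_lambda weight of the IoU term in the stage-3 fused cost;
#'   `1 - fuse_lambda` weighs the cosine term (clipped to `[0, 1]` so the
#'   two terms share a scale)
#' @param fused_gate_stage3 maximum fused cost for a stage-3 match
#' @param enable_stage2,enable_stage3 switch individual stages off (for
#'   ablations)
#' @param stage2_include_low if `TRUE`, stage 2 also considers unmatched
#'   low-confidence detections (an alternative reading of "unmatched
#'   detection boxes"; the default restricts stage 2 to high detections)
#' @return a list with class `cascade_config`
#' @export
cascade_config <- function(tau_high = 0.6, tau_low = 0.1,
                           iou_gate_stage1 = 0.3, dist_gate_stage2 = NULL,
                           fuse_lambda = 0.5, fused_gate_stage3 = 0.7,
                           enable_stage2 = TRUE, enable_stage3 = TRUE,
                           stage2_include_low = FALSE) {
  if (!(tau_low >= 0 && tau_low < tau_high && tau_high <= 1)) {
    stop("need 0 <= tau_low < tau_high <= 1", call. = FALSE)
  }
  if (iou_gate_stage1 < 0 || iou_gate_stage1 > 1) {
    stop("iou_gate_stage1 must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(dist_gate_stage2) &&
      (!is.finite(dist_gate_stage2) || dist_gate_stage2 < 0)) {
    stop("dist_gate_stage2 must be finite and nonnegative", call. = FALSE)
  }
  if (fuse_lambda < 0 || fuse_lambda > 1) stop("fuse_lambda must lie in [0, 1]", call. = FALSE)
  if (!is.finite(fused_gate_stage3) || fused_gate_stage3 < 0) {
    stop("fused_gate_stage3 must be finite and nonnegative", call. = FALSE)
  }
  structure(list(
    tau_high = tau_high, tau_low = tau_low,
    iou_gate_stage1 = iou_gate_stage1, dist_gate_stage2 = dist_gate_stage2,
    fuse_lambda = fuse_lambda, fused_gate_stage3 = fused_gate_stage3,
    enable_stage2 = isTRUE(enable_stage2), enable_stage3 = isTRUE(enable_stage3),
    stage2_include_low = isTRUE(stage2_include_low)), class = "cascade_config")
}

#' A set of detections in one frame
#'
#' @param boxes an n x 4 box matrix (or single box) in
#'   `(left, top, width, height)` order
#' @param conf detector confidences in `[0, 1]`, one per box
#' @param embeddings optional n x D matrix of appearance embeddings; rows of
#'   `NA` mark detections without an embedding
#' @param frame 1-based frame index shared by all detections
#' @return a list with class `detections`
#' @export
detections <- function(boxes, conf, embeddings = NULL, frame = 1L) {
  boxes <- if (length(boxes)) as_box_matrix(boxes) else
    matrix(numeric(0), ncol = 4L, dimnames = list(NULL, c("left", "top", "width", "height")))
  n <- nrow(boxes)
  if (n > 0) check_boxes(boxes)
  conf <- as.numeric(conf)
  if (length(conf) != n) stop("need one confidence per box", call. = FALSE)
  if (n && (any(conf < 0) || any(conf > 1))) stop("confidence must lie in [0, 1]", call. = FALSE)
  if (!is.null(embeddings)) {
    embeddings <- as.matrix(embeddings)
    if (nrow(embeddings) != n) stop("need one embedding row per box", call. = FALSE)
  }
  frame <- as.integer(frame)
  if (length(frame) != 1L || is.na(frame) || frame < 1L) {
    stop("frame must be a single positive integer", call. = FALSE)
  }
  structure(list(boxes = boxes, conf = conf, embeddings = embeddings,
                 frame = frame, n = n), class = "detections")
}

subset_detections <- function(d, i) {
  detections(d$boxes[i, , drop = FALSE], d$conf[i],
             if (!is.null(d$embeddings)) d$embeddings[i, , drop = FALSE],
             d$frame)
}

det_embedding <- function(d, i) {
  if (is.null(d$embeddings)) return(NULL)
  e <- d$embeddings[i, ]
  if (anyNA(e)) NULL else as.numeric(e)
}

#' Split detections into high- and low-confidence groups
#'
#' @param dets a [detections()] object
#' @param cfg a [cascade_config()]
#' @return a list with elements `high`, `low` (both [detections()]) and
#'   index vectors `high_idx`, `low_idx`, `discarded_idx` into the input
#' @export
split_by_confidence <- function(dets, cfg = cascade_config()) {
  stopifnot(inherits(dets, "detections"))
  hi <- which(dets$conf >= cfg$tau_high)
  lo <- which(dets$conf >= cfg$tau_low & dets$conf < cfg$tau_high)
  disc <- which(dets$conf < cfg$tau_low)
  list(high = subset_detections(dets, hi), low = subset_detections(dets, lo),
       high_idx = hi, low_idx = lo, discarded_idx = disc)
}

#' Stage 1: IoU matching of high-confidence detections
#'
#' Cost is `1 - IoU` between Kalman-predicted track boxes and detection
#' boxes; pairs with IoU below `iou_gate_stage1` are ineligible.
#'
#' @param track_boxes predicted track boxes (n x 4 matrix)
#' @param dets a [detections()] object (the high-confidence group)
#' @param cfg a [cascade_config()]
#' @return an `assignment_result` (rows index tracks, cols detections)
#' @export
stage1_iou_match <- function(track_boxes, dets, cfg = cascade_config()) {
  n <- if (length(track_boxes)) nrow(as_box_matrix(track_boxes)) else 0L
  if (n == 0L || dets$n == 0L) {
    return(solve_assignment(matrix(numeric(0), nrow = n, ncol = dets$n)))
  }
  cost <- 1 - iou_matrix(track_boxes, dets$boxes)
  solve_assignment(cost, gate = 1 - cfg$iou_gate_stage1)
}

#' Stage 2: Euclidean re-association of leftover tracks
#'
#' Cost is the raw pixel distance between predicted and detected box
#' centers, recovering pairs whose occlusion-distorted boxes no longer
#' overlap. The gate defaults to half the mean diagonal of the
#' participating predicted boxes.
#'
#' @inheritParams stage1_iou_match
#' @export
stage2_euclid_match <- function(track_boxes, dets, cfg = cascade_config()) {
  n <- if (length(track_boxes)) nrow(as_box_matrix(track_boxes)) else 0L
  if (n == 0L || dets$n == 0L) {
    return(solve_assignment(matrix(numeric(0), nrow = n, ncol = dets$n)))
  }
  tb <- as_box_matrix(track_boxes)
  gate <- cfg$dist_gate_stage2
  if (is.null(gate)) {
    gate <- 0.5 * mean(sqrt(tb[, "width"]^2 + tb[, "height"]^2))
  }
  cost <- center_distance_matrix(tb, dets$boxes)
  solve_assignment(cost, gate = gate)
}

#' Stage 3: fused IoU + appearance matching of low-confidence detections
#'
#' Cost is `fuse_lambda * (1 - IoU) + (1 - fuse_lambda) * min(cosine, 1)`.
#' When either side lacks an embedding the cost for that pair falls back to
#' pure IoU distance.
#'
#' @inheritParams stage1_iou_match
#' @param track_embeddings a list of appearance templates aligned with the
#'   rows of `track_boxes`; `NULL` elements mark tracks without a template
#' @export
stage3_fused_match <- function(track_boxes, track_embeddings, dets,
                               cfg = cascade_config()) {
  n <- if (length(track_boxes)) nrow(as_box_matrix(track_boxes)) else 0L
  if (n == 0L || dets$n == 0L) {
    return(solve_assignment(matrix(numeric(0), nrow = n, ncol = dets$n)))
  }
  iou_cost <- 1 - iou_matrix(track_boxes, dets$boxes)
  cost <- iou_cost
  lam <- cfg$fuse_lambda
  if (lam < 1) {
    for (i in seq_len(n)) {
      ti <- track_embeddings[[i]]
      if (is.null(ti)) next
      for (j in seq_len(dets$n)) {
        ej <- det_embedding(dets, j)
        if (is.null(ej)) next
        emb <- min(cosine_distance(ti, ej), 1)
        cost[i, j] <- lam * iou_cost[i, j] + (1 - lam) * emb
      }
    }
  }
  solve_assignment(cost, gate = cfg$fused_gate_stage3)
}

#' Run the full three-stage association cascade on one frame
#'
#' @param tracks a list of track descriptors, each a list with `box` (the
#'   Kalman-predicted box for the current frame) and optionally `embedding`
#'   (the appearance template)
#' @param dets a [detections()] object holding every candidate detection of
#'   the frame
#' @param cfg a [cascade_config()]
#' @return a list:
#'   \describe{
#'     \item{matches}{integer matrix with columns `track`, `det`, `stage`
#'       (`det` indexes the input `dets`)}
#'     \item{unmatched_tracks}{indices of tracks left unmatched}
#'     \item{unmatched_high}{indices (into `dets`) of unmatched
#'       high-confidence detections — the only detections eligible to start
#'       new tracks}
#'     \item{discarded}{indices of detections below `tau_low`}
#'   }
#' @export
run_cascade <- function(tracks, dets, cfg = cascade_config()) {
  stopifnot(inherits(dets, "detections"))
  n_tracks <- length(tracks)
  track_boxes <- if (n_tracks) {
    do.call(rbind, lapply(tracks, function(t) as_box_matrix(t$box)))
  } else matrix(numeric(0), ncol = 4L)
  track_embs <- lapply(tracks, function(t) t$embedding)

  sp <- split_by_confidence(dets, cfg)
  matches <- matrix(integer(0), ncol = 3L,
                    dimnames = list(NULL, c("track", "det", "stage")))
  rem_tracks <- seq_len(n_tracks)

  # stage 1: high detections on IoU
  r1 <- stage1_iou_match(track_boxes, sp$high, cfg)
  if (nrow(r1$matches)) {
    matches <- rbind(matches, cbind(r1$matches[, "row"],
                                    sp$high_idx[r1$matches[, "col"]], 1L))
    rem_tracks <- setdiff(rem_tracks, r1$matches[, "row"])
  }
  rem_high <- r1$unmatched_cols            # positions within sp$high

  # stage 2: leftover tracks vs leftover high (optionally + low) on centers
  rem_low <- seq_len(sp$low$n)             # positions within sp$low
  if (cfg$enable_stage2 && length(rem_tracks)) {
    cand_idx <- sp$high_idx[rem_high]
    pool_high <- rep(TRUE, length(rem_high))
    if (cfg$stage2_include_low) {
      cand_idx <- c(cand_idx, sp$low_idx[rem_low])
      pool_high <- c(pool_high, rep(FALSE, length(rem_low)))
    }
    if (length(cand_idx)) {
      cand <- subset_detections(dets, cand_idx)
      r2 <- stage2_euclid_match(track_boxes[rem_tracks, , drop = FALSE], cand, cfg)
      if (nrow(r2$matches)) {
        matches <- rbind(matches, cbind(rem_tracks[r2$matches[, "row"]],
                                        cand_idx[r2$matches[, "col"]], 2L))
        rem_tracks <- setdiff(rem_tracks, rem_tracks[r2$matches[, "row"]])
        matched_cand <- r2$matches[, "col"]
        rem_high <- rem_high[!(seq_along(pool_high) %in% matched_cand)[seq_along(rem_high)]]
        if (cfg$stage2_include_low) {
          low_pos <- matched_cand[matched_cand > sum(pool_high)] - sum(pool_high)
          # positions above refer into rem_low before removal
          if (length(low_pos)) rem_low <- rem_low[-low_pos]
        }
      }
    }
  }

  # stage 3: remaining tracks vs low detections on fused IoU + appearance
  if (cfg$enable_stage3 && length(rem_tracks) && length(rem_low)) {
    low_idx <- sp$low_idx[rem_low]
    low <- subset_detections(dets, low_idx)
    r3 <- stage3_fused_match(track_boxes[rem_tracks, , drop = FALSE],
                             track_embs[rem_tracks], low, cfg)
    if (nrow(r3$matches)) {
      matches <- rbind(matches, cbind(rem_tracks[r3$matches[, "row"]],
                                      low_idx[r3$matches[, "col"]], 3L))
      rem_tracks <- setdiff(rem_tracks, rem_tracks[r3$matches[, "row"]])
    }
  }

  storage.mode(matches) <- "integer"
  list(matches = matches,
       unmatched_tracks = rem_tracks,
       unmatched_high = setdiff(sp$high_idx[rem_high], matches[, "det"]),
       discarded = sp$discarded_idx)
}
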