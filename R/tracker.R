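#' Tracker configuration
#'
#' Lifecycle parameters around the association cascade. A new track starts
#' tentative and is confirmed after `n_init` consecutive hits (set
#' `n_init = 1` for instant confirmation); tracks born on the very first
#' processed frame are confirmed immediately, following the ByteTrack
#' lineage, since nothing earlier could have vouched for them either way.
#' A confirmed track that misses a frame turns lost but keeps coasting on
#' its Kalman prediction, staying eligible in every cascade stage, and is
#' removed after `max_age` frames without a match.
#'
#' @param cascade a [cascade_config()]
#' @param max_age frames a lost track may coast before removal (30 = 1 s at
#'   the 30 fps the input video is standardized to)
#' @param n_init consecutive hits needed to confirm a tentative track
#' @param ema_alpha weight of the old template in the exponential moving
#'   average appearance update
#' @param kf Kalman filter constants from [kf_params()]
#' @return a list with class `tracker_config`
#' @export
tracker_config <- function(cascade = cascade_config(), max_age = 30L,
                           n_init = 3L, ema_alpha = 0.9, kf = kf_params()) {
  stopifnot(inherits(cascade, "cascade_config"), max_age >= 1, n_init >= 1,
            ema_alpha >= 0, ema_alpha <= 1)
  structure(list(cascade = cascade, max_age = as.integer(max_age),
                 n_init = as.integer(n_init), ema_alpha = ema_alpha, kf = kf),
            class = "tracker_config")
}

#' Create an empty tracker state
#'
#' @param cfg a [tracker_config()]
#' @return a tracker state (list of live tracks plus bookkeeping), class
#'   `tracker_state`
#' @export
tracker_init <- function(cfg = tracker_config()) {
  structure(list(tracks = list(), next_id = 1L, frame = 0L, started = FALSE,
                 cfg = cfg), class = "tracker_state")
}

#' @export
print.tracker_state <- function(x, ...) {
  st <- vapply(x$tracks, function(t) t$status, character(1))
  cat("tracker state at frame ", x$frame, ": ",
      sum(st == "confirmed"), " confirmed, ", sum(st == "tentative"),
      " tentative, ", sum(st == "lost"), " lost track(s)\n", sep = "")
  invisible(x)
}

#' Update a track's appearance template
#'
#' Exponential moving average in embedding space: the first matched
#' embedding is copied verbatim; afterwards
#' `template <- normalize(alpha * template + (1 - alpha) * new)`.
#'
#' @param template current template vector or `NULL`
#' @param new the matched detection's embedding
#' @param alpha EMA weight of the old template, in `[0, 1]`
#' @return the updated unit-norm template
#' @export
update_embedding <- function(template, new, alpha = 0.9) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (is.null(new)) return(template)
  if (is.null(template)) return(normalize_embedding(new))
  if (length(template) != length(new)) {
    stop("embedding dimension mismatch: ", length(template), " vs ",
         length(new), call. = FALSE)
  }
  if (alpha == 1) return(template)
  normalize_embedding(alpha * template + (1 - alpha) * new)
}

new_track <- function(id, det_box, det_emb, cfg, confirm_now) {
  list(track_id = id,
       motion = kf_initiate(det_box, cfg$kf),
       embedding = if (is.null(det_emb)) NULL else normalize_embedding(det_emb),
       status = if (confirm_now) "confirmed" else "tentative",
       frames_since_update = 0L,
       hits = 1L)
}

track_pred_box <- function(track) {
  # a long-coasting state can drift to a degenerate aspect/height; clamp
  m <- track$motion$mean
  m[3L] <- max(m[3L], 1e-6)
  m[4L] <- max(m[4L], 1e-6)
  state_to_box(list(mean = m, cov = track$motion$cov))
}

#' Advance the tracker by one frame
#'
#' Applies, in order: a Kalman predict for every live track; the
#' association cascade; measurement and appearance updates for matched
#' tracks; lifecycle transitions (tentative tracks are dropped on a miss,
#' confirmed tracks turn lost and are removed after `max_age` missed
#' frames); track birth from unmatched high-confidence detections; and row
#' emission for confirmed tracks matched this frame.
#'
#' @param state a `tracker_state`
#' @param dets a [detections()] object for the next frame; its `frame`
#'   must exceed the last processed frame
#' @return a list with the advanced `state` and `rows`, a data frame of
#'   emitted records `(frame, id, left, top, width, height, conf)`
#' @export
tracker_step <- function(state, dets) {
  stopifnot(inherits(state, "tracker_state"), inherits(dets, "detections"))
  cfg <- state$cfg
  if (dets$frame <= state$frame) {
    stop("out-of-order frame index: got ", dets$frame,
         " after frame ", state$frame, call. = FALSE)
  }
  first_frame <- !state$started

  # 1. predict every live track
  state$tracks <- lapply(state$tracks, function(t) {
    t$motion <- kf_predict(t$motion, cfg$kf)
    t
  })

  # 2. association cascade on predicted boxes + templates
  cand <- lapply(state$tracks, function(t)
    list(box = track_pred_box(t), embedding = t$embedding))
  cas <- run_cascade(cand, dets, cfg$cascade)

  rows <- list()
  matched_tracks <- integer(0)

  # 3. matched tracks: measurement + appearance update, status refresh
  if (nrow(cas$matches)) {
    for (k in seq_len(nrow(cas$matches))) {
      ti <- cas$matches[k, "track"]; dj <- cas$matches[k, "det"]
      t <- state$tracks[[ti]]
      dbox <- dets$boxes[dj, ]
      t$motion <- kf_update(t$motion, dbox, cfg$kf)
      t$embedding <- update_embedding(t$embedding, det_embedding(dets, dj),
                                      cfg$ema_alpha)
      t$hits <- t$hits + 1L
      t$frames_since_update <- 0L
      if (t$status == "lost") t$status <- "confirmed"
      if (t$status == "tentative" && t$hits >= cfg$n_init) t$status <- "confirmed"
      if (t$status == "confirmed") {
        rows[[length(rows) + 1L]] <- data.frame(
          frame = dets$frame, id = t$track_id,
          left = dbox[["left"]], top = dbox[["top"]],
          width = dbox[["width"]], height = dbox[["height"]],
          conf = dets$conf[dj])
      }
      state$tracks[[ti]] <- t
      matched_tracks <- c(matched_tracks, ti)
    }
  }

  # 4. unmatched tracks: age, demote, remove
  for (ti in setdiff(seq_along(state$tracks), matched_tracks)) {
    t <- state$tracks[[ti]]
    t$frames_since_update <- t$frames_since_update + 1L
    if (t$status == "tentative") {
      t$status <- "removed"
    } else {
      if (t$status == "confirmed") t$status <- "lost"
      if (t$frames_since_update > cfg$max_age) t$status <- "removed"
    }
    state$tracks[[ti]] <- t
  }
  state$tracks <- Filter(function(t) t$status != "removed", state$tracks)

  # 5. births from unmatched high-confidence detections
  confirm_now <- first_frame || cfg$n_init <= 1L
  for (dj in cas$unmatched_high) {
    t <- new_track(state$next_id, dets$boxes[dj, ], det_embedding(dets, dj),
                   cfg, confirm_now)
    state$next_id <- state$next_id + 1L
    if (t$status == "confirmed") {
      dbox <- dets$boxes[dj, ]
      rows[[length(rows) + 1L]] <- data.frame(
        frame = dets$frame, id = t$track_id,
        left = dbox[["left"]], top = dbox[["top"]],
        width = dbox[["width"]], height = dbox[["height"]],
        conf = dets$conf[dj])
    }
    state$tracks[[length(state$tracks) + 1L]] <- t
  }

  state$frame <- dets$frame
  state$started <- TRUE
  rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(0), id = integer(0), left = numeric(0),
               top = numeric(0), width = numeric(0), height = numeric(0),
               conf = numeric(0))
  rows <- rows[order(rows$id), , drop = FALSE]
  rownames(rows) <- NULL
  list(state = state, rows = rows)
}

#' Track a whole detection stream
#'
#' @param det_stream a list of [detections()] objects with strictly
#'   increasing frame indices (frames with no detections may be included as
#'   empty `detections`); see [mot_to_stream()] to build one from a
#'   MOTChallenge table
#' @param cfg a [tracker_config()]
#' @return a data frame of tracker output rows
#'   `(frame, id, left, top, width, height, conf)`, ordered by frame then
#'   id; track ids are assigned in order of birth starting at 1
#' @export
run_sequence <- function(det_stream, cfg = tracker_config()) {
  state <- tracker_init(cfg)
  out <- vector("list", length(det_stream))
  for (k in seq_along(det_stream)) {
    res <- tracker_step(state, det_stream[[k]])
    state <- res$state
    out[[k]] <- res$rows
  }
  rows <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(rows)) rows <- data.frame(
    frame = integer(0), id = integer(0), left = numeric(0), top = numeric(0),
    width = numeric(0), height = numeric(0), conf = numeric(0))
  rows
}
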