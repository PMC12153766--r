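#' Multi-object tracking evaluation
#'
#' Ground truth and hypotheses are tables with columns
#' `frame, id, left, top, width, height` (extra columns are ignored), one
#' box per object per frame, as produced by [read_mot()] or
#' [run_sequence()]. All metrics follow the MOTChallenge conventions:
#' CLEAR-MOT correspondence at IoU >= 0.5, identity metrics from the
#' optimal global trajectory bijection, and HOTA averaged over the 19 IoU
#' thresholds 0.05, 0.10, ..., 0.95.
#'
#' @name mot_metrics
NULL

check_mot_table <- function(x, what = "table") {
  need <- c("frame", "id", "left", "top", "width", "height")
  if (!all(need %in% names(x))) {
    stop(what, " must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(x) && anyDuplicated(x[, c("frame", "id")])) {
    stop(what, " has duplicate (frame, id) records", call. = FALSE)
  }
  x
}

split_frames <- function(x, frames) {
  lapply(frames, function(f) x[x$frame == f, , drop = FALSE])
}

#' CLEAR-MOT per-frame correspondence
#'
#' Builds the frame event log underlying MOTA/MOTP: per frame,
#' correspondences persisting from the previous frame are kept when their
#' IoU still clears the threshold; the remaining boxes are matched by
#' minimum-cost assignment on `1 - IoU` (pairs below the threshold are
#' ineligible). An identity switch is logged when a ground-truth identity
#' is matched to a hypothesis id different from its most recent earlier
#' match.
#'
#' @param gt,hyp MOT tables (see [mot_metrics])
#' @param iou_threshold minimum IoU for a valid correspondence
#' @return a list with class `frame_event_log`: per-frame counts
#'   (`frames`), matched pairs with their IoU and center distance
#'   (`matches`), per-sequence `totals` (FP, FN, IDSW, GT instances,
#'   match count) and per-identity coverage (`coverage`)
#' @export
clear_match <- function(gt, hyp, iou_threshold = 0.5) {
  check_mot_table(gt, "gt")
  check_mot_table(hyp, "hyp")
  stopifnot(iou_threshold > 0, iou_threshold < 1)
  frames <- sort(unique(c(gt$frame, hyp$frame)))
  last_match <- list()   # gt id (as character) -> most recent hyp id
  per_frame <- vector("list", length(frames))
  match_rows <- list()
  gt_present <- table(factor(gt$id))
  gt_matched <- integer(0)

  for (k in seq_along(frames)) {
    f <- frames[k]
    g <- gt[gt$frame == f, , drop = FALSE]
    h <- hyp[hyp$frame == f, , drop = FALSE]
    ng <- nrow(g); nh <- nrow(h)
    iou <- if (ng && nh) {
      iou_matrix(as_box_matrix(g[, c("left", "top", "width", "height")]),
                 as_box_matrix(h[, c("left", "top", "width", "height")]))
    } else matrix(0, ng, nh)

    pairs <- matrix(integer(0), ncol = 2L)
    used_g <- logical(ng); used_h <- logical(nh)
    # keep persisting correspondences first
    if (ng && nh) {
      for (i in seq_len(ng)) {
        prev <- last_match[[as.character(g$id[i])]]
        if (is.null(prev)) next
        j <- match(prev, h$id)
        if (!is.na(j) && !used_h[j] && iou[i, j] >= iou_threshold) {
          pairs <- rbind(pairs, c(i, j))
          used_g[i] <- TRUE; used_h[j] <- TRUE
        }
      }
      # minimum 1 - IoU assignment among the rest
      gi <- which(!used_g); hj <- which(!used_h)
      if (length(gi) && length(hj)) {
        r <- solve_assignment(1 - iou[gi, hj, drop = FALSE],
                              gate = 1 - iou_threshold)
        if (nrow(r$matches)) {
          pairs <- rbind(pairs, cbind(gi[r$matches[, "row"]],
                                      hj[r$matches[, "col"]]))
        }
      }
    }

    idsw <- 0L
    if (nrow(pairs)) {
      gids <- g$id[pairs[, 1L]]
      hids <- h$id[pairs[, 2L]]
      for (p in seq_len(nrow(pairs))) {
        key <- as.character(gids[p])
        prev <- last_match[[key]]
        if (!is.null(prev) && prev != hids[p]) idsw <- idsw + 1L
        last_match[[key]] <- hids[p]
      }
      gb <- as_box_matrix(g[pairs[, 1L], c("left", "top", "width", "height")])
      hb <- as_box_matrix(h[pairs[, 2L], c("left", "top", "width", "height")])
      d_iou <- vapply(seq_len(nrow(pairs)), function(p)
        box_iou(gb[p, ], hb[p, ]), numeric(1))
      d_cent <- vapply(seq_len(nrow(pairs)), function(p)
        center_distance(gb[p, ], hb[p, ]), numeric(1))
      match_rows[[length(match_rows) + 1L]] <- data.frame(
        frame = f, gt_id = gids, hyp_id = hids, iou = d_iou, dist = d_cent)
      gt_matched <- c(gt_matched, gids)
    }
    per_frame[[k]] <- data.frame(frame = f, c = nrow(pairs),
                                 fp = nh - nrow(pairs), fn = ng - nrow(pairs),
                                 idsw = idsw)
  }

  frames_df <- if (length(per_frame)) do.call(rbind, per_frame) else
    data.frame(frame = integer(0), c = integer(0), fp = integer(0),
               fn = integer(0), idsw = integer(0))
  matches_df <- if (length(match_rows)) do.call(rbind, match_rows) else
    data.frame(frame = integer(0), gt_id = integer(0), hyp_id = integer(0),
               iou = numeric(0), dist = numeric(0))
  rownames(frames_df) <- rownames(matches_df) <- NULL

  ids <- sort(unique(gt$id))
  coverage <- data.frame(
    gt_id = ids,
    n_frames = as.integer(table(factor(gt$id, levels = ids))),
    n_matched = as.integer(table(factor(gt_matched, levels = ids))))

  structure(list(
    frames = frames_df, matches = matches_df, coverage = coverage,
    iou_threshold = iou_threshold,
    totals = list(FP = sum(frames_df$fp), FN = sum(frames_df$fn),
                  IDSW = sum(frames_df$idsw), GT = nrow(gt),
                  n_matches = sum(frames_df$c))),
    class = "frame_event_log")
}

#' @export
print.frame_event_log <- function(x, ...) {
  t <- x$totals
  cat("frame event log over ", nrow(x$frames), " frame(s): ",
      t$n_matches, " matches, FP = ", t$FP, ", FN = ", t$FN,
      ", IDSW = ", t$IDSW, ", GT instances = ", t$GT, "\n", sep = "")
  invisible(x)
}

#' Multi-object tracking accuracy
#'
#' `MOTA = 1 - (FN + FP + IDSW) / GT`, at most 1 and unbounded below.
#'
#' @param log a [clear_match()] event log
#' @return a scalar
#' @export
mota <- function(log) {
  stopifnot(inherits(log, "frame_event_log"))
  t <- log$totals
  if (t$GT == 0) stop("MOTA is undefined without ground-truth objects", call. = FALSE)
  1 - (t$FN + t$FP + t$IDSW) / t$GT
}

#' Multi-object tracking precision
#'
#' Mean localization quality of matched pairs: mean IoU by default (higher
#' is better); with `as_distance = TRUE` the literal distance form
#' `sum(d) / sum(c)` with d = center distance in pixels (lower is better).
#'
#' @param log a [clear_match()] event log
#' @param as_distance report the center-distance ratio instead of mean IoU
#' @return a scalar
#' @export
motp <- function(log, as_distance = FALSE) {
  stopifnot(inherits(log, "frame_event_log"))
  if (log$totals$n_matches == 0) {
    stop("MOTP is undefined without any matched pair", call. = FALSE)
  }
  if (as_distance) sum(log$matches$dist) / log$totals$n_matches
  else mean(log$matches$iou)
}

#' Identity F1 score
#'
#' IDTP is obtained from the optimal global bijection between ground-truth
#' and hypothesis identities that maximizes whole-trajectory frame
#' co-occurrence at IoU >= `iou_threshold`; then
#' `IDF1 = 2 IDTP / (2 IDTP + IDFP + IDFN)`.
#'
#' @inheritParams clear_match
#' @return a list with `idf1` and the counts `IDTP`, `IDFP`, `IDFN`
#' @export
idf1 <- function(gt, hyp, iou_threshold = 0.5) {
  check_mot_table(gt, "gt")
  check_mot_table(hyp, "hyp")
  if (nrow(gt) == 0 && nrow(hyp) == 0) {
    stop("IDF1 is undefined on empty ground truth and hypotheses", call. = FALSE)
  }
  gids <- sort(unique(gt$id)); hids <- sort(unique(hyp$id))
  m <- matrix(0L, length(gids), length(hids))
  if (length(gids) && length(hids)) {
    for (f in intersect(unique(gt$frame), unique(hyp$frame))) {
      g <- gt[gt$frame == f, , drop = FALSE]
      h <- hyp[hyp$frame == f, , drop = FALSE]
      iou <- iou_matrix(as_box_matrix(g[, c("left", "top", "width", "height")]),
                        as_box_matrix(h[, c("left", "top", "width", "height")]))
      hit <- which(iou >= iou_threshold, arr.ind = TRUE)
      if (nrow(hit)) {
        gi <- match(g$id[hit[, 1L]], gids)
        hj <- match(h$id[hit[, 2L]], hids)
        for (p in seq_along(gi)) m[gi[p], hj[p]] <- m[gi[p], hj[p]] + 1L
      }
    }
  }
  idtp <- 0L
  if (length(gids) && length(hids)) {
    r <- solve_assignment(-m)        # maximize total co-occurrence
    if (nrow(r$matches)) idtp <- sum(m[r$matches])
  }
  idfn <- nrow(gt) - idtp
  idfp <- nrow(hyp) - idtp
  list(idf1 = 2 * idtp / (2 * idtp + idfp + idfn),
       IDTP = idtp, IDFP = idfp, IDFN = idfn)
}

#' Higher-order tracking accuracy
#'
#' HOTA jointly scores detection and association: a single per-frame
#' matching is computed by maximizing the product of the global trajectory
#' alignment score (the Jaccard index of accumulated similarity between a
#' ground-truth and a hypothesis identity) and the frame IoU; at each
#' threshold alpha in 0.05, 0.10, ..., 0.95 the matched pairs with
#' IoU >= alpha count as true positives, giving detection accuracy
#' `DetA = TP / (TP + FN + FP)` and association accuracy `AssA`, the
#' TP-weighted mean Jaccard association score of the matched identity
#' pairs. The per-alpha score is `sqrt(DetA * AssA)` and HOTA is their mean
#' over alpha (`use_sqrt = FALSE` gives the plain product instead).
#'
#' @inheritParams clear_match
#' @param use_sqrt combine DetA and AssA by geometric mean (the canonical
#'   definition); `FALSE` uses the plain product
#' @return a list with `hota` and `components`, a data frame of per-alpha
#'   `DetA`, `AssA` and score
#' @export
hota <- function(gt, hyp, use_sqrt = TRUE) {
  check_mot_table(gt, "gt")
  check_mot_table(hyp, "hyp")
  if (nrow(gt) == 0 && nrow(hyp) == 0) {
    stop("HOTA is undefined on empty ground truth and hypotheses", call. = FALSE)
  }
  alphas <- seq(0.05, 0.95, by = 0.05)
  gids <- sort(unique(gt$id)); hids <- sort(unique(hyp$id))
  ng <- length(gids); nh <- length(hids)
  gt_count <- as.numeric(table(factor(gt$id, levels = gids)))
  hyp_count <- as.numeric(table(factor(hyp$id, levels = hids)))
  frames <- sort(unique(c(gt$frame, hyp$frame)))

  frame_data <- lapply(frames, function(f) {
    g <- gt[gt$frame == f, , drop = FALSE]
    h <- hyp[hyp$frame == f, , drop = FALSE]
    sim <- if (nrow(g) && nrow(h)) {
      iou_matrix(as_box_matrix(g[, c("left", "top", "width", "height")]),
                 as_box_matrix(h[, c("left", "top", "width", "height")]))
    } else matrix(0, nrow(g), nrow(h))
    list(gi = match(g$id, gids), hj = match(h$id, hids), sim = sim)
  })

  # pass 1: accumulate the soft co-occurrence behind the alignment score
  potential <- matrix(0, ng, nh)
  for (fd in frame_data) {
    if (!length(fd$gi) || !length(fd$hj)) next
    sim <- fd$sim
    denom <- outer(rowSums(sim), colSums(sim), `+`) - sim
    soft <- matrix(0, nrow(sim), ncol(sim))
    ok <- denom > .Machine$double.eps
    soft[ok] <- sim[ok] / denom[ok]
    potential[fd$gi, fd$hj] <- potential[fd$gi, fd$hj] + soft
  }
  align <- potential / (outer(gt_count, hyp_count, `+`) - potential)

  # pass 2: one matching per frame on alignment x IoU, thresholded per alpha
  tp <- numeric(length(alphas))
  match_count <- lapply(alphas, function(a) matrix(0, ng, nh))
  for (fd in frame_data) {
    if (!length(fd$gi) || !length(fd$hj)) next
    score <- align[fd$gi, fd$hj, drop = FALSE] * fd$sim
    r <- solve_assignment(-score)
    if (!nrow(r$matches)) next
    sims <- fd$sim[r$matches]
    for (a in seq_along(alphas)) {
      ok <- sims >= alphas[a] - .Machine$double.eps
      if (!any(ok)) next
      tp[a] <- tp[a] + sum(ok)
      gi <- fd$gi[r$matches[ok, "row"]]
      hj <- fd$hj[r$matches[ok, "col"]]
      for (p in seq_along(gi)) {
        match_count[[a]][gi[p], hj[p]] <- match_count[[a]][gi[p], hj[p]] + 1
      }
    }
  }

  det_a <- ass_a <- numeric(length(alphas))
  for (a in seq_along(alphas)) {
    fn <- nrow(gt) - tp[a]
    fp <- nrow(hyp) - tp[a]
    det_a[a] <- if (tp[a] + fn + fp > 0) tp[a] / (tp[a] + fn + fp) else 0
    if (tp[a] > 0) {
      mc <- match_count[[a]]
      jac <- mc / (outer(gt_count, hyp_count, `+`) - mc)
      ass_a[a] <- sum(mc * jac) / tp[a]
    }
  }
  score <- if (use_sqrt) sqrt(det_a * ass_a) else det_a * ass_a
  list(hota = mean(score),
       components = data.frame(alpha = alphas, DetA = det_a, AssA = ass_a,
                               score = score))
}

#' Mostly-tracked / mostly-lost trajectory counts
#'
#' A ground-truth trajectory is mostly tracked when matched in at least
#' 80% of its frames, mostly lost when matched in at most 20%.
#'
#' @param log a [clear_match()] event log
#' @return a list with integer counts `MT` and `ML`
#' @export
mt_ml <- function(log) {
  stopifnot(inherits(log, "frame_event_log"))
  cov <- log$coverage
  if (!nrow(cov)) return(list(MT = 0L, ML = 0L))
  ratio <- cov$n_matched / cov$n_frames
  list(MT = sum(ratio >= 0.8), ML = sum(ratio <= 0.2))
}

#' Run the full tracking evaluation suite
#'
#' @inheritParams clear_match
#' @param motp_as_distance see [motp()]
#' @param hota_sqrt see [hota()]
#' @return a one-row data frame with MOTA, MOTP, IDF1, HOTA, MT, ML, IDS,
#'   FP, FN, the GT instance count and the number of ground-truth
#'   identities; MOTP is `NA` when nothing was matched
#' @export
evaluate_tracking <- function(gt, hyp, iou_threshold = 0.5,
                              motp_as_distance = FALSE, hota_sqrt = TRUE) {
  log <- clear_match(gt, hyp, iou_threshold)
  mtml <- mt_ml(log)
  data.frame(
    MOTA = mota(log),
    MOTP = if (log$totals$n_matches > 0) motp(log, motp_as_distance) else NA_real_,
    IDF1 = idf1(gt, hyp, iou_threshold)$idf1,
    HOTA = hota(gt, hyp, use_sqrt = hota_sqrt)$hota,
    MT = mtml$MT, ML = mtml$ML,
    IDS = log$totals$IDSW, FP = log$totals$FP, FN = log$totals$FN,
    GT = log$totals$GT, n_gt_ids = nrow(log$coverage))
}

#' Metric differences between two tracker variants
#'
#' Convenience for ablation arithmetic: absolute gains on higher-better
#' metric columns and the percent reduction in identity switches between a
#' baseline row and an improved row of a metrics table.
#'
#' @param tab a data frame with a `method` column and numeric metric
#'   columns (e.g. `HOTA`, `MOTA`, `IDF1`, `IDS`)
#' @param baseline,improved values of `method` naming the two rows
#' @return a named list of per-metric differences (improved - baseline);
#'   for `IDS` the list holds the raw counts and `ids_reduction_pct`, the
#'   percent reduction relative to the baseline
#' @export
metric_deltas <- function(tab, baseline, improved) {
  stopifnot("method" %in% names(tab))
  b <- tab[tab$method == baseline, , drop = FALSE]
  i <- tab[tab$method == improved, , drop = FALSE]
  if (nrow(b) != 1L || nrow(i) != 1L) {
    stop("baseline and improved must each select exactly one row", call. = FALSE)
  }
  out <- list()
  for (col in setdiff(names(tab), "method")) {
    if (!is.numeric(tab[[col]])) next
    if (toupper(col) == "IDS") {
      out$ids_baseline <- b[[col]]
      out$ids_improved <- i[[col]]
      out$ids_reduction_pct <- 100 * (b[[col]] - i[[col]]) / b[[col]]
    } else {
      out[[paste0(tolower(col), "_gain")]] <- i[[col]] - b[[col]]
    }
  }
  out
}
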