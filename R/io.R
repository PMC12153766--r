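#' MOTChallenge file input/output
#'
#' Files follow the 10-column MOTChallenge dialect: one record per line,
#' `frame,id,bb_left,bb_top,bb_width,bb_height,conf,x,y,z` with 1-based
#' frames and `-1` placeholders for the last three fields (and for the id
#' of raw detections). All writes are atomic: content goes to a temporary
#' file in the destination directory which is renamed into place, so an
#' interrupted run never leaves a truncated output.
#'
#' @name mot_io
NULL

atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move output into place: ", path,
                                    call. = FALSE)
  invisible(path)
}

#' Read a MOTChallenge file
#'
#' @param path file path
#' @param kind `"gt"` for ground truth (ids must be >= 1), `"det"` for raw
#'   detections (id may be -1) or `"result"` for tracker output
#' @return a data frame `(frame, id, left, top, width, height, conf)`
#'   sorted by frame then id; an empty file yields an empty (valid) frame
#' @export
read_mot <- function(path, kind = c("gt", "det", "result")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  empty <- data.frame(frame = integer(0), id = integer(0), left = numeric(0),
                      top = numeric(0), width = numeric(0),
                      height = numeric(0), conf = numeric(0))
  if (!length(lines_keep)) return(empty)
  recs <- vector("list", length(lines_keep))
  for (k in seq_along(lines_keep)) {
    ln <- lines_keep[k]
    fields <- strsplit(trimws(lines[ln]), ",", fixed = TRUE)[[1]]
    if (length(fields) < 7L) {
      stop("parse error in ", path, " line ", ln, ": expected at least 7 ",
           "comma-separated fields, got ", length(fields), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields[1:7]))
    if (anyNA(vals)) {
      stop("parse error in ", path, " line ", ln, ": non-numeric field",
           call. = FALSE)
    }
    recs[[k]] <- vals
  }
  m <- do.call(rbind, recs)
  out <- data.frame(frame = as.integer(m[, 1L]), id = as.integer(m[, 2L]),
                    left = m[, 3L], top = m[, 4L], width = m[, 5L],
                    height = m[, 6L], conf = m[, 7L])
  if (any(out$frame < 1L)) {
    stop("parse error in ", path, ": frames must be >= 1", call. = FALSE)
  }
  if (kind %in% c("gt", "result") && any(out$id < 1L)) {
    stop("parse error in ", path, ": ", kind, " records require id >= 1",
         call. = FALSE)
  }
  if (any(out$width <= 0) || any(out$height <= 0)) {
    stop("parse error in ", path, ": box width/height must be positive",
         call. = FALSE)
  }
  out <- out[order(out$frame, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a MOTChallenge file
#'
#' @param x a data frame with columns `frame, id, left, top, width, height`
#'   and optionally `conf` (defaults to 1 when absent; use `id = -1` for
#'   raw detections)
#' @param path destination path
#' @return the path, invisibly
#' @export
write_mot <- function(x, path) {
  need <- c("frame", "id", "left", "top", "width", "height")
  if (!all(need %in% names(x))) {
    stop("need columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  conf <- if ("conf" %in% names(x)) x$conf else rep(1, nrow(x))
  lines <- sprintf("%d,%d,%s,%s,%s,%s,%s,-1,-1,-1",
                   as.integer(x$frame), as.integer(x$id),
                   format(x$left, trim = TRUE, digits = 15),
                   format(x$top, trim = TRUE, digits = 15),
                   format(x$width, trim = TRUE, digits = 15),
                   format(x$height, trim = TRUE, digits = 15),
                   format(conf, trim = TRUE, digits = 15))
  atomic_write(path, function(p) writeLines(lines, p))
}

#' Embedding sidecar files
#'
#' A plain comma-separated table with one row per detection:
#' `frame, ordinal, v1, ..., vD`, where `ordinal` is the 1-based position
#' of the detection within its frame in the companion detection file. The
#' embedding dimension must be constant.
#'
#' @param stream a list of [detections()] carrying embeddings
#' @param path destination path
#' @return the path, invisibly
#' @export
write_embeddings <- function(stream, path) {
  rows <- character(0)
  for (d in stream) {
    if (d$n == 0L || is.null(d$embeddings)) next
    for (k in seq_len(d$n)) {
      rows <- c(rows, paste(c(d$frame, k,
                              format(d$embeddings[k, ], trim = TRUE, digits = 15)),
                            collapse = ","))
    }
  }
  atomic_write(path, function(p) writeLines(rows, p))
}

#' @rdname write_embeddings
#' @param det a detection table from [read_mot()] the sidecar must align
#'   with (one embedding row per detection record, same frame order)
#' @return `read_embeddings()` returns a list mapping frame index to the
#'   matrix of embeddings for that frame's detections.
#' @export
read_embeddings <- function(path, det) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  tab <- list()
  dim_seen <- NA_integer_
  for (k in seq_along(lines)) {
    fields <- suppressWarnings(as.numeric(strsplit(lines[k], ",", fixed = TRUE)[[1]]))
    if (length(fields) < 3L || anyNA(fields)) {
      stop("parse error in ", path, " line ", k, call. = FALSE)
    }
    D <- length(fields) - 2L
    if (is.na(dim_seen)) dim_seen <- D
    if (D != dim_seen) {
      stop("alignment error in ", path, " line ", k,
           ": embedding dimension changed from ", dim_seen, " to ", D,
           call. = FALSE)
    }
    f <- as.integer(fields[1L])
    tab[[as.character(f)]] <- rbind(tab[[as.character(f)]], fields[-(1:2)])
  }
  det_counts <- table(factor(det$frame))
  for (f in names(det_counts)) {
    got <- if (is.null(tab[[f]])) 0L else nrow(tab[[f]])
    if (got != det_counts[[f]]) {
      stop("alignment error: frame ", f, " has ", det_counts[[f]],
           " detection(s) but ", got, " embedding row(s)", call. = FALSE)
    }
  }
  extra <- setdiff(names(tab), names(det_counts))
  if (length(extra)) {
    stop("alignment error: embeddings for frame(s) ",
         paste(extra, collapse = ", "), " have no detections", call. = FALSE)
  }
  tab
}

#' Build a per-frame detection stream from a MOT detection table
#'
#' @param det a detection table from [read_mot()]
#' @param embeddings optional sidecar from [read_embeddings()]
#' @param n_frames total frames of the sequence (defaults to the largest
#'   frame index present); earlier frames without detections become empty
#' @return a list of [detections()], one per frame `1..n_frames`
#' @export
mot_to_stream <- function(det, embeddings = NULL, n_frames = NULL) {
  if (is.null(n_frames)) n_frames <- if (nrow(det)) max(det$frame) else 0L
  lapply(seq_len(n_frames), function(f) {
    d <- det[det$frame == f, , drop = FALSE]
    emb <- if (!is.null(embeddings)) embeddings[[as.character(f)]]
    detections(as.matrix(d[, c("left", "top", "width", "height")]),
               d$conf, emb, frame = f)
  })
}

#' Tracker output as a MOT result table
#'
#' @param rows the data frame returned by [run_sequence()]
#' @param path destination path
#' @return the path, invisibly
#' @export
write_result <- function(rows, path) {
  write_mot(rows, path)
}

#' Run configuration
#'
#' A flat YAML document with sections `cascade`, `tracker` and `metrics`;
#' every key has a default, so an empty (or absent) file is a valid
#' configuration.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults
#' @param overrides a named list of section lists merged over the file
#'   values (e.g. `list(cascade = list(tau_high = 0.7))`)
#' @return a list with `tracker` (a [tracker_config()]) and `metrics`
#'   (list of `iou_threshold`, `motp_as_distance`, `hota_sqrt`)
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
  }
  raw <- utils::modifyList(raw, overrides)
  cas <- do.call(cascade_config, utils::modifyList(
    list(), if (is.null(raw$cascade)) list() else raw$cascade))
  trk_args <- if (is.null(raw$tracker)) list() else raw$tracker
  trk <- do.call(tracker_config, c(list(cascade = cas), trk_args))
  met <- utils::modifyList(
    list(iou_threshold = 0.5, motp_as_distance = FALSE, hota_sqrt = TRUE),
    if (is.null(raw$metrics)) list() else raw$metrics)
  list(tracker = trk, metrics = met)
}
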