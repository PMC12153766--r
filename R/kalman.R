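#' Constant-velocity Kalman filter over bounding boxes
#'
#' The motion state follows the SORT/ByteTrack lineage: an 8-vector
#' `(cx, cy, a, h, vcx, vcy, va, vh)` holding the box center, aspect ratio
#' (width / height), height, and their per-frame velocities, with an 8 x 8
#' covariance. The measurement is `(cx, cy, a, h)`. Process and measurement
#' noise standard deviations are scaled by the current box height so the
#' filter behaves consistently across target sizes.
#'
#' @name kalman
#' @param std_weight_position position noise scale relative to box height
#' @param std_weight_velocity velocity noise scale relative to box height
#' @return `kf_params()` returns a list of filter constants.
NULL

#' @rdname kalman
#' @export
kf_params <- function(std_weight_position = 1 / 20, std_weight_velocity = 1 / 160) {
  stopifnot(std_weight_position > 0, std_weight_velocity > 0)
  list(wp = std_weight_position, wv = std_weight_velocity)
}

kf_transition <- function() {
  F <- diag(8)
  F[1:4, 5:8] <- diag(4)
  F
}

check_motion_state <- function(s) {
  if (!is.list(s) || !all(c("mean", "cov") %in% names(s))) {
    stop("motion state must have mean and cov", call. = FALSE)
  }
  if (length(s$mean) != 8L || !all(dim(s$cov) == c(8L, 8L))) {
    stop("motion state must be an 8-vector with an 8x8 covariance", call. = FALSE)
  }
  if (max(abs(s$cov - t(s$cov))) > 1e-9) {
    stop("covariance must be symmetric", call. = FALSE)
  }
  if (min(eigen(s$cov, symmetric = TRUE, only.values = TRUE)$values) < -1e-9) {
    stop("covariance must be positive semidefinite", call. = FALSE)
  }
  invisible(s)
}

box_to_measurement <- function(box) {
  m <- check_boxes(box)[1L, ]
  c(m[["left"]] + m[["width"]] / 2,
    m[["top"]] + m[["height"]] / 2,
    m[["width"]] / m[["height"]],
    m[["height"]])
}

#' Initialize a motion state from a detected box
#'
#' Position components are taken from the box; velocities start at zero with
#' a diagonal covariance scaled by box height (uncertainty about velocity is
#' an order of magnitude wider than about position, as in the SORT family).
#'
#' @param box a valid box `(left, top, width, height)`
#' @param params filter constants from [kf_params()]
#' @return a motion state: `list(mean = <8-vector>, cov = <8x8 matrix>)`
#' @export
kf_initiate <- function(box, params = kf_params()) {
  z <- box_to_measurement(box)
  h <- z[4L]
  std <- c(2 * params$wp * h, 2 * params$wp * h, 1e-2, 2 * params$wp * h,
           10 * params$wv * h, 10 * params$wv * h, 1e-5, 10 * params$wv * h)
  list(mean = c(z, 0, 0, 0, 0), cov = diag(std^2))
}

#' Advance a motion state by one frame
#'
#' Applies the constant-velocity transition and adds height-scaled process
#' noise, so positional uncertainty grows while a track coasts unmatched.
#'
#' @param s a motion state
#' @inheritParams kf_initiate
#' @return the predicted motion state
#' @export
kf_predict <- function(s, params = kf_params()) {
  check_motion_state(s)
  F <- kf_transition()
  h <- s$mean[4L]
  std <- c(params$wp * h, params$wp * h, 1e-2, params$wp * h,
           params$wv * h, params$wv * h, 1e-5, params$wv * h)
  Q <- diag(std^2)
  mean <- as.vector(F %*% s$mean)
  cov <- F %*% s$cov %*% t(F) + Q
  list(mean = mean, cov = (cov + t(cov)) / 2)
}

#' Fold a box observation into a motion state
#'
#' Standard Kalman measurement update on `(cx, cy, a, h)` with
#' height-scaled measurement noise; the posterior covariance trace never
#' exceeds the prior's.
#'
#' @param s a (typically predicted) motion state
#' @param box the observed box
#' @inheritParams kf_initiate
#' @return the posterior motion state
#' @export
kf_update <- function(s, box, params = kf_params()) {
  check_motion_state(s)
  z <- box_to_measurement(box)
  h <- s$mean[4L]
  std <- c(params$wp * h, params$wp * h, 1e-1, params$wp * h)
  R <- diag(std^2)
  H <- cbind(diag(4), matrix(0, 4, 4))
  S <- H %*% s$cov %*% t(H) + R
  K <- t(solve(S, H %*% s$cov))      # 8 x 4 gain
  innov <- z - as.vector(H %*% s$mean)
  mean <- s$mean + as.vector(K %*% innov)
  IKH <- diag(8) - K %*% H
  # Joseph form keeps the covariance symmetric PSD
  cov <- IKH %*% s$cov %*% t(IKH) + K %*% R %*% t(K)
  list(mean = mean, cov = (cov + t(cov)) / 2)
}

#' Convert a motion state back to a bounding box
#'
#' Exact inverse of the box -> (center, aspect, height) parameterization
#' used by [kf_initiate()].
#'
#' @param s a motion state
#' @return a length-4 box `(left, top, width, height)`
#' @export
state_to_box <- function(s) {
  m <- s$mean
  a <- m[3L]; h <- m[4L]
  if (!is.finite(a) || !is.finite(h) || a <= 0 || h <= 0) {
    stop("motion state has non-positive aspect ratio or height", call. = FALSE)
  }
  w <- a * h
  bbox(m[1L] - w / 2, m[2L] - h / 2, w, h)
}
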