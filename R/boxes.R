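#' Bounding-box geometry and pairwise association costs
#'
#' Boxes are axis-aligned pixel rectangles stored in MOTChallenge order
#' `(left, top, width, height)`, image origin at the top-left corner, x
#' rightward, y downward. A box denotes the half-open rectangle
#' `[left, left + width) x [top, top + height)`, so rectangles that merely
#' touch along an edge do not intersect. Single boxes are length-4 numeric
#' vectors; collections are n x 4 numeric matrices (one box per row).
#'
#' @param left,top box origin in pixels
#' @param width,height box extent in pixels; both must be strictly positive
#' @return `bbox()` returns a named length-4 numeric vector.
#' @examples
#' b <- bbox(0, 0, 10, 20)
#' box_center(b)
#' box_iou(b, bbox(5, 5, 10, 20))
#' @export
bbox <- function(left, top, width, height) {
  b <- c(left = left, top = top, width = width, height = height)
  check_boxes(b)
  b
}

#' Coerce boxes to an n x 4 matrix and validate them
#'
#' @param x a length-4 numeric vector (one box) or an n x 4 matrix/data.frame
#'   in `(left, top, width, height)` order
#' @return an n x 4 numeric matrix with columns left, top, width, height
#' @export
as_box_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != 4L) stop("a single box must have 4 components", call. = FALSE)
    x <- matrix(as.numeric(x), nrow = 1L)
  }
  if (ncol(x) != 4L) stop("box matrix must have 4 columns", call. = FALSE)
  storage.mode(x) <- "double"
  colnames(x) <- c("left", "top", "width", "height")
  x
}

check_boxes <- function(x) {
  m <- as_box_matrix(x)
  if (!all(is.finite(m))) stop("box coordinates must be finite", call. = FALSE)
  if (any(m[, "width"] <= 0) || any(m[, "height"] <= 0)) {
    stop("invalid box: width and height must be strictly positive", call. = FALSE)
  }
  invisible(m)
}

#' @rdname bbox
#' @param box a box or box matrix
#' @export
box_area <- function(box) {
  m <- check_boxes(box)
  unname(m[, "width"] * m[, "height"])
}

#' @rdname bbox
#' @export
box_center <- function(box) {
  m <- check_boxes(box)
  cbind(x = m[, "left"] + m[, "width"] / 2, y = m[, "top"] + m[, "height"] / 2)
}

#' Intersection over union of two boxes
#'
#' Overlap area divided by union area, in `[0, 1]`. Areas are continuous
#' (no pixel snapping); boxes touching only along an edge have IoU 0.
#'
#' @param a,b valid boxes
#' @return a scalar in `[0, 1]`
#' @export
box_iou <- function(a, b) {
  iou_matrix(a, b)[1L, 1L]
}

#' Pairwise IoU matrix between two box sets
#'
#' @param A,B box matrices (n x 4 and m x 4)
#' @return an n x m matrix of IoU values
#' @export
iou_matrix <- function(A, B) {
  A <- check_boxes(A)
  B <- check_boxes(B)
  n <- nrow(A); m <- nrow(B)
  ax2 <- A[, "left"] + A[, "width"]; ay2 <- A[, "top"] + A[, "height"]
  bx2 <- B[, "left"] + B[, "width"]; by2 <- B[, "top"] + B[, "height"]
  x1 <- outer(A[, "left"], B[, "left"], pmax)
  y1 <- outer(A[, "top"], B[, "top"], pmax)
  x2 <- outer(ax2, bx2, pmin)
  y2 <- outer(ay2, by2, pmin)
  inter <- pmax(x2 - x1, 0) * pmax(y2 - y1, 0)
  union <- outer(box_area(A), box_area(B), `+`) - inter
  out <- inter / union
  dim(out) <- c(n, m)
  out
}

#' Euclidean distance between box centers
#'
#' @param a,b valid boxes
#' @return a nonnegative scalar in pixels
#' @export
center_distance <- function(a, b) {
  center_distance_matrix(a, b)[1L, 1L]
}

#' Pairwise center-distance matrix between two box sets
#'
#' @param A,B box matrices
#' @return an n x m matrix of center distances in pixels
#' @export
center_distance_matrix <- function(A, B) {
  ca <- box_center(A)
  cb <- box_center(B)
  dx <- outer(ca[, "x"], cb[, "x"], `-`)
  dy <- outer(ca[, "y"], cb[, "y"], `-`)
  sqrt(dx * dx + dy * dy)
}

#' Cosine distance between appearance embeddings
#'
#' `1 - cos(e1, e2)`: 0 for parallel vectors, 1 for orthogonal, 2 for
#' anti-parallel. Invariant to positive rescaling of either argument.
#'
#' @param e1,e2 nonzero numeric vectors of equal dimension
#' @return a scalar in `[0, 2]`
#' @export
cosine_distance <- function(e1, e2) {
  if (length(e1) != length(e2)) {
    stop("embedding dimension mismatch: ", length(e1), " vs ", length(e2), call. = FALSE)
  }
  cosine_distance_matrix(matrix(e1, nrow = 1L), matrix(e2, nrow = 1L))[1L, 1L]
}

#' Pairwise cosine-distance matrix between two embedding sets
#'
#' @param E1,E2 matrices with one unit-of-appearance vector per row and a
#'   common column dimension
#' @return an n x m matrix of cosine distances in `[0, 2]`
#' @export
cosine_distance_matrix <- function(E1, E2) {
  E1 <- as.matrix(E1); E2 <- as.matrix(E2)
  if (ncol(E1) != ncol(E2)) {
    stop("embedding dimension mismatch: ", ncol(E1), " vs ", ncol(E2), call. = FALSE)
  }
  if (!all(is.finite(E1)) || !all(is.finite(E2))) {
    stop("embeddings must be finite", call. = FALSE)
  }
  n1 <- sqrt(rowSums(E1 * E1))
  n2 <- sqrt(rowSums(E2 * E2))
  if (any(n1 == 0) || any(n2 == 0)) {
    stop("degenerate embedding: zero-norm vector", call. = FALSE)
  }
  sim <- (E1 %*% t(E2)) / outer(n1, n2)
  # guard against rounding drift outside [-1, 1]
  1 - pmin(pmax(sim, -1), 1)
}

#' Unit-normalize an embedding vector
#'
#' @param e a nonzero numeric vector
#' @return `e / ||e||`
#' @export
normalize_embedding <- function(e) {
  n <- sqrt(sum(e * e))
  if (!is.finite(n) || n == 0) stop("degenerate embedding: zero-norm vector", call. = FALSE)
  e / n
}
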