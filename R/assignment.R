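#' Minimum-cost bipartite assignment with gating
#'
#' Solves the rectangular linear assignment problem (the Hungarian-method
#' problem) by the Jonker-Volgenant shortest-augmenting-path algorithm.
#' Entries whose cost exceeds `gate` (or is non-finite) are ineligible: no
#' returned pair ever uses one. Among eligible pairs the solver first
#' maximizes the number of matches, then minimizes their total cost, which
#' is the convention of the tracking-by-detection literature (ineligible
#' entries are internally replaced by a cost larger than any full eligible
#' assignment). The algorithm is deterministic, so ties are broken
#' reproducibly by index order.
#'
#' @param cost a numeric matrix; rows and columns are the two sides to match
#'   (conventionally tracks and detections)
#' @param gate pairs with `cost > gate` cannot be matched (default `Inf`)
#' @return a list with class `assignment_result`:
#'   \describe{
#'     \item{matches}{integer matrix with columns `row`, `col`, one matched
#'       pair per row, ordered by `row`}
#'     \item{unmatched_rows, unmatched_cols}{integer vectors of indices left
#'       unmatched}
#'     \item{total_cost}{sum of costs over matched pairs}
#'   }
#' @examples
#' solve_assignment(rbind(c(0.1, 0.9), c(0.9, 0.1)), gate = 1)
#' @export
solve_assignment <- function(cost, gate = Inf) {
  if (is.null(dim(cost))) cost <- matrix(cost, nrow = 1L)
  n <- nrow(cost); m <- ncol(cost)
  empty <- function() {
    structure(list(
      matches = matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("row", "col"))),
      unmatched_rows = seq_len(n), unmatched_cols = seq_len(m),
      total_cost = 0), class = "assignment_result")
  }
  if (n == 0L || m == 0L) return(empty())
  if (any(is.na(cost))) stop("cost matrix must not contain NA", call. = FALSE)

  eligible <- is.finite(cost) & cost <= gate
  if (!any(eligible)) return(empty())
  mx <- max(abs(cost[eligible]))
  big <- (mx + 1) * (min(n, m) + 1)
  work <- cost
  work[!eligible] <- big

  flipped <- n > m
  if (flipped) work <- t(work)
  assign_cols <- lap_augmenting_path(work)   # for each row of `work`, its column
  pairs <- cbind(seq_along(assign_cols), assign_cols)
  if (flipped) pairs <- pairs[, 2:1, drop = FALSE]

  keep <- eligible[pairs]
  pairs <- pairs[keep, , drop = FALSE]
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  colnames(pairs) <- c("row", "col")
  structure(list(
    matches = pairs,
    unmatched_rows = setdiff(seq_len(n), pairs[, "row"]),
    unmatched_cols = setdiff(seq_len(m), pairs[, "col"]),
    total_cost = if (nrow(pairs)) sum(cost[pairs]) else 0),
    class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat("assignment: ", nrow(x$matches), " matched pair(s), ",
      length(x$unmatched_rows), " unmatched row(s), ",
      length(x$unmatched_cols), " unmatched col(s); total cost ",
      format(x$total_cost), "\n", sep = "")
  invisible(x)
}

# Shortest-augmenting-path LAP core. `cost` has nrow <= ncol and all finite
# entries. Returns, for each row, the column assigned to it (full assignment
# of the smaller side). Potentials (u, v) maintain reduced costs; column
# index m + 1 is the virtual start column of each augmenting search.
lap_augmenting_path <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)       # p[j]: row currently matched to column j (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[m + 1L] <- i
    j0 <- m + 1L
    minv <- rep(INF, m)
    used <- logical(m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      j1 <- 0L
      delta <- INF
      free <- which(!used[seq_len(m)])
      if (length(free)) {
        cur <- cost[i0, free] - u[i0] - v[free]
        upd <- cur < minv[free]
        if (any(upd)) {
          minv[free[upd]] <- cur[upd]
          way[free[upd]] <- j0
        }
        k <- which.min(minv[free])
        delta <- minv[free[k]]
        j1 <- free[k]
      }
      usedj <- which(used)
      for (j in usedj) {
        if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
        v[j] <- v[j] - delta
      }
      if (length(free)) minv[free] <- minv[free] - delta
      j0 <- j1
      if (j0 == 0L || p[j0] == 0L) break
    }
    # augment along the alternating path back to the virtual column
    while (j0 != m + 1L) {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
    }
  }
  out <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) out[p[j]] <- j
  out
}
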