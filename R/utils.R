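#' @importFrom methods new validObject is slot setValidity
#' @importFrom stats density prcomp kmeans ks.test t.test wilcox.test
#'   rnorm runif sd bw.nrd0 psmirnov
#' @importFrom utils head tail read.table
NULL

## Coerce to an n x 3 numeric coordinate matrix, with checks.
as_coord_matrix <- function(x, what = "points") {
  if (is.null(dim(x))) {
    if (length(x) == 3L) x <- matrix(as.numeric(x), nrow = 1L)
    else stop(what, " must be an n x 3 coordinate matrix", call. = FALSE)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L)
    stop(what, " must have exactly 3 coordinate columns", call. = FALSE)
  if (!all(is.finite(x)))
    stop(what, " contains non-finite coordinates", call. = FALSE)
  dimnames(x) <- NULL
  x
}

## Squared Euclidean cross-distance matrix between two point sets (n x 3, m x 3).
## tcrossprod keeps this O(n m) with vectorised arithmetic; tiny negative
## values from cancellation are clamped at zero.
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

cross_dist <- function(a, b) sqrt(cross_dist2(a, b))

## Euclidean norms of the rows of a matrix.
row_norms <- function(m) sqrt(rowSums(m^2))

## Minimum distance from each point in `pts` to the polyline `axis`
## (point-to-segment, not vertex-only). `axis` is an ordered k x 3 matrix.
points_to_polyline_dist <- function(pts, axis) {
  if (nrow(axis) == 1L) return(row_norms(sweep(pts, 2, axis[1, ])))
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(axis) - 1L)) {
    p0 <- axis[i, ]
    v <- axis[i + 1L, ] - p0
    vv <- sum(v^2)
    w <- sweep(pts, 2, p0)
    t <- if (vv > 0) pmin(1, pmax(0, as.vector(w %*% v) / vv)) else rep(0, nrow(pts))
    d2 <- rowSums((w - outer(t, v))^2)
    best <- pmin(best, d2)
  }
  sqrt(best)
}

## Minimum squared distance between segments [p1,q1] and [p2,q2]
## (Lumelsky clamped-parameter method).
seg_seg_dist2 <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1^2); e <- sum(d2^2); f <- sum(d2 * r)
  if (a <= 1e-30 && e <= 1e-30) return(sum(r^2))
  if (a <= 1e-30) {
    t <- min(1, max(0, f / e))
    return(sum((r - t * d2)^2))
  }
  c_ <- sum(d1 * r)
  if (e <= 1e-30) {
    s <- min(1, max(0, -c_ / a))
    return(sum((r + s * d1)^2))
  }
  b <- sum(d1 * d2)
  denom <- a * e - b * b
  s <- if (denom > 1e-30) min(1, max(0, (b * f - c_ * e) / denom)) else 0
  t <- (b * s + f) / e
  if (t < 0) { t <- 0; s <- min(1, max(0, -c_ / a)) }
  else if (t > 1) { t <- 1; s <- min(1, max(0, (b - c_) / a)) }
  sum((r + s * d1 - t * d2)^2)
}

## Deterministic rotation matrix mapping the unit z axis onto unit vector u.
rotation_to <- function(u) {
  u <- u / sqrt(sum(u^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * u[3] - z[3] * u[2], z[3] * u[1] - z[1] * u[3], z[1] * u[2] - z[2] * u[1])
  c_ <- sum(z * u)
  if (sum(v^2) < 1e-14) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # 180 degrees about x
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
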