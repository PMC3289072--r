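# Small geometric helpers shared across modules.

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Squared Euclidean distances between two point sets
#'
#' @param a,b numeric matrices with 3 columns (points in rows).
#' @return an `nrow(a) x nrow(b)` matrix of squared distances.
#' @keywords internal
pairwise_dist2 <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

rotation_z <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  matrix(c(cos(t), -sin(t), 0,
           sin(t),  cos(t), 0,
           0,       0,      1), nrow = 3, byrow = TRUE)
}

#' Uniform random rotation matrix
#'
#' QR-based Haar sampling with the sign fix of Mezzadri (2007); used by the
#' equivariance tests and the synthetic-data pipeline.
#' @param n ignored (always 3x3)
#' @return a 3x3 rotation matrix with determinant +1.
#' @export
random_rotation <- function(n = 3) {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  d[d == 0] <- 1
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Apply the rigid motion x -> R x + t to points stored in rows.
apply_rigid <- function(xyz, rot, trans = c(0, 0, 0)) {
  sweep(xyz %*% t(rot), 2, trans, "+")
}

#' Angle between two undirected lines
#'
#' Folds the angle to `[0, 90]` degrees, i.e. `v` and `-v` are equivalent.
#' @param u,v nonzero 3-vectors.
#' @return angle in degrees.
#' @export
line_angle <- function(u, v) {
  cu <- unit_vec(u); cv <- unit_vec(v)
  co <- abs(sum(cu * cv))
  co <- min(1, co)
  rad2deg(acos(co))
}

# Canonical sign for an undirected unit vector: the largest-magnitude
# component is made nonnegative (ties broken by the first such component).
canonical_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}
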