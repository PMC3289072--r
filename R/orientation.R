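# Groove-orientation prediction: PCA over three representative atoms per
# DBU residue (the type's highest-propensity contact atom plus backbone CA
# and C) estimates the tangent direction of the DNA groove the DBU binds.

#' Representative atoms of a DBU
#'
#' Per residue: the atom ranked first in the type's reference frame (the
#' atom with the highest DNA-binding propensity), plus CA and C.  Missing
#' atoms are skipped with a warning.
#'
#' @param dbu a `dbu` object.
#' @param s the query `pdb_structure`.
#' @param frames a `reference_frames` object.
#' @return numeric matrix (points in rows); error if fewer than 3 points.
#' @export
representative_atoms <- function(dbu, s, frames) {
  a <- s$atoms
  rt <- residue_table(s)
  pts <- list()
  missing <- 0L
  for (rk in dbu$residues) {
    aa <- rt$resname[match(rk, rt$reskey)]
    top <- if (!is.null(frames[[aa]])) frames[[aa]]$atoms[1] else "CA"
    want <- unique(c(top, "CA", "C"))
    rows <- which(a$reskey == rk)
    idx <- rows[match(want, a$name[rows])]
    missing <- missing + sum(is.na(idx))
    idx <- idx[!is.na(idx)]
    if (length(idx) > 0) pts[[rk]] <- atom_xyz(s, idx)
  }
  if (missing > 0)
    warning(missing, " representative atom(s) missing; skipped")
  out <- do.call(rbind, pts)
  if (is.null(out) || nrow(out) < 3)
    stop("fewer than 3 representative atoms available for PCA")
  out
}

#' Principal direction of a point cloud
#'
#' The direction is the eigenvector of the centered 3x3 covariance with the
#' largest eigenvalue, reported as an undirected line (canonical sign:
#' largest-magnitude component nonnegative).  When the top two eigenvalues
#' coincide within 1e-9 the direction is degenerate; a warning is raised
#' and the canonical eigenvector returned.
#'
#' @param points numeric matrix of 3-D points in rows (>= 3, not all
#'   coincident).
#' @return object of class `orientation_prediction`: `list(anchor,
#'   direction, explained_fraction)`.
#' @export
pca_direction <- function(points) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) < 3) stop("PCA needs at least 3 points")
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  if (max(abs(x)) < 1e-12) stop("all points coincident")
  cv <- crossprod(x) / (nrow(points) - 1)
  ee <- eigen(cv, symmetric = TRUE)
  if (abs(ee$values[1] - ee$values[2]) < 1e-9)
    warning("degenerate principal direction (top eigenvalues equal)")
  dir <- canonical_sign(ee$vectors[, 1])
  structure(list(anchor = ctr, direction = dir,
                 explained_fraction = ee$values[1] / sum(ee$values)),
            class = "orientation_prediction")
}

#' Predict the groove tangent direction of a DBU
#'
#' @inheritParams representative_atoms
#' @return an `orientation_prediction`.
#' @export
predict_orientation <- function(dbu, s, frames) {
  pca_direction(representative_atoms(dbu, s, frames))
}

#' @export
print.orientation_prediction <- function(x, ...) {
  cat(sprintf(
    "orientation: direction (%.3f, %.3f, %.3f), %.0f%% variance, anchor (%.1f, %.1f, %.1f)\n",
    x$direction[1], x$direction[2], x$direction[3],
    100 * x$explained_fraction, x$anchor[1], x$anchor[2], x$anchor[3]))
  invisible(x)
}
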