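# Evaluation against a reference complex: location error to the closest
# base centroid (6 A failure cutoff), orientation error against the
# phosphate-derived groove tangent (success when cos > 0.9, i.e. < ~25.8
# degrees), and residue-level precision/sensitivity.

LOCATION_FAIL_CUTOFF <- 6.0
ORIENTATION_COS_SUCCESS <- 0.9

base_centroids <- function(ref) {
  a <- ref$atoms
  dna <- which(a$kind == "dna")
  if (length(dna) == 0) stop("reference structure contains no DNA")
  keys <- unique(a$reskey[dna])
  cent <- t(vapply(keys, function(k) {
    rows <- dna[a$reskey[dna] == k]
    moi <- rows[a$name[rows] %in% BASE_MOIETY_ATOMS]
    if (length(moi) >= 3) rows <- moi
    colMeans(atom_xyz(ref, rows))
  }, numeric(3)))
  rownames(cent) <- keys
  cent
}

#' Location error of a predicted base placement
#'
#' Euclidean distance from the predicted centroid to the centroid of the
#' closest base (base-moiety atoms when present) in the reference complex.
#'
#' @param pred a `base_placement`, or a numeric 3-vector.
#' @param ref the reference `pdb_structure` (must contain DNA).
#' @return distance in Angstrom.
#' @export
location_error <- function(pred, ref) {
  x <- if (inherits(pred, "base_placement")) pred$centroid else
    as.numeric(pred)
  cent <- base_centroids(ref)
  sqrt(min(pairwise_dist2(matrix(x, 1), cent)))
}

#' Orientation error between undirected directions
#'
#' `arccos(|cos theta|)`, folded to `[0, 90]` degrees; sign-invariant.
#'
#' @param pred an `orientation_prediction` or a nonzero 3-vector.
#' @param truth a nonzero 3-vector (or list of candidate vectors, in which
#'   case the smallest angle is returned).
#' @return angle in degrees.
#' @export
orientation_error <- function(pred, truth) {
  u <- if (inherits(pred, "orientation_prediction")) pred$direction else
    as.numeric(pred)
  cands <- if (is.list(truth)) truth else list(truth)
  min(vapply(cands, function(v) line_angle(u, v), numeric(1)))
}

#' Reference groove tangent for a DBU from a bound complex
#'
#' Identifies the centre base pair `i` as the DBU-contacted nucleotide whose
#' base centroid is nearest the DBU centroid (partner `j` = nearest base
#' centroid on another chain); assigns the groove by which side of the base
#' pair the DBU centroid falls on (the side of the C1' bisector is the
#' minor groove); and builds the phosphate tangent candidates - major:
#' P(i-3) -> P(i-4) and the j-analogue, minor: P(i) -> P(i+1) and the
#' j-analogue - where chain-order indices follow author numbering.
#'
#' @param ref the reference `pdb_structure` (bound complex).
#' @param dbu a `dbu` located on `ref`'s protein.
#' @param binding_cutoff contact threshold used to find DBU-contacted
#'   nucleotides (default 4.5).
#' @return list with `groove`, `candidates` (list of undirected unit
#'   vectors), `center_key`, `partner_key`; groove/candidates are NA with a
#'   warning when the required phosphates are absent.
#' @export
reference_tangent <- function(ref, dbu, binding_cutoff = 4.5) {
  a <- ref$atoms
  dbu_rows <- which(a$reskey %in% dbu$residues)
  dna_rows <- which(a$kind == "dna")
  if (length(dna_rows) == 0) stop("reference structure contains no DNA")
  d2 <- pairwise_dist2(atom_xyz(ref, dbu_rows), atom_xyz(ref, dna_rows))
  touched <- unique(a$reskey[dna_rows][apply(d2, 2, min) < binding_cutoff^2])
  cent <- base_centroids(ref)

  # Watson-Crick pairing proxy: each nucleotide pairs with the nearest base
  # centroid on another chain; the centre base pair is the contacted pair
  # whose pair centroid is nearest the DBU centroid (ties: smaller key).
  chains <- sub(":.*", "", rownames(cent))
  if (length(unique(chains)) < 2) stop("reference DNA has a single strand")
  partner_of <- vapply(rownames(cent), function(k) {
    others <- rownames(cent)[chains != sub(":.*", "", k)]
    dp <- pairwise_dist2(cent[k, , drop = FALSE],
                         cent[others, , drop = FALSE])
    others[order(dp[1, ], others)[1]]
  }, character(1))
  pool <- if (length(touched) > 0) touched else rownames(cent)
  pair_cent <- t(vapply(pool, function(k)
    (cent[k, ] + cent[partner_of[[k]], ]) / 2, numeric(3)))
  dc <- pairwise_dist2(matrix(dbu$centroid, 1), pair_cent)
  center_key <- pool[order(dc[1, ], pool)[1]]
  partner_key <- partner_of[[center_key]]
  center_chain <- sub(":.*", "", center_key)

  # groove side: axis point ~ midpoint of the two base centroids; the C1'
  # bisector points into the minor groove.
  axis_pt <- (cent[center_key, ] + cent[partner_key, ]) / 2
  c1 <- function(k) {
    r <- which(a$reskey == k & a$name == "C1'")
    if (length(r) == 0) return(NULL)
    c(a$x[r[1]], a$y[r[1]], a$z[r[1]])
  }
  c1i <- c1(center_key); c1j <- c1(partner_key)
  groove <- NA_character_
  if (!is.null(c1i) && !is.null(c1j)) {
    minor_dir <- (c1i + c1j) / 2 - axis_pt
    if (vec_norm(minor_dir) > 1e-6) {
      side <- sum((dbu$centroid - axis_pt) * unit_vec(minor_dir))
      groove <- if (side > 0) "minor" else "major"
    }
  }
  if (is.na(groove)) {
    warning("could not assign groove type; defaulting to major")
    groove <- "major"
  }

  seq_of <- function(k) as.integer(sub(".*:", "", k))
  p_of <- function(chain, resseq) {
    r <- which(a$chain == chain & a$resseq == resseq & a$name == "P" &
                 a$kind == "dna")
    if (length(r) == 0) NULL else c(a$x[r[1]], a$y[r[1]], a$z[r[1]])
  }
  i <- seq_of(center_key); j <- seq_of(partner_key)
  ci <- center_chain; cj <- sub(":.*", "", partner_key)
  specs <- if (groove == "major") {
    list(c(ci, i - 3, i - 4), c(cj, j - 3, j - 4))
  } else {
    list(c(ci, i, i + 1), c(cj, j, j + 1))
  }
  cands <- list()
  for (sp in specs) {
    p1 <- p_of(sp[1], as.integer(sp[2]))
    p2 <- p_of(sp[1], as.integer(sp[3]))
    if (is.null(p1) || is.null(p2)) next
    cands[[length(cands) + 1]] <- canonical_sign(unit_vec(p2 - p1))
  }
  if (length(cands) == 0) {
    warning("required phosphates absent; reference tangent unavailable")
    return(list(groove = groove, candidates = NA, center_key = center_key,
                partner_key = partner_key))
  }
  list(groove = groove, candidates = cands, center_key = center_key,
       partner_key = partner_key)
}

#' Residue-level precision and sensitivity
#'
#' True positives are predicted residues that actually contact DNA
#' (distance < 4.5 A) in the reference complex.  Precision = TP /
#' #predicted (0 when nothing is predicted, by convention); sensitivity =
#' TP / #contacts (NA when the reference has no contacts).
#'
#' @param predicted character vector of residue keys.
#' @param ref the reference complex.
#' @param binding_cutoff contact threshold (default 4.5).
#' @return named numeric vector `c(precision, sensitivity)`.
#' @export
residue_metrics <- function(predicted, ref, binding_cutoff = 4.5) {
  contacts <- binding_residues(ref, binding_cutoff)
  tp <- length(intersect(predicted, contacts))
  precision <- if (length(predicted) == 0) 0 else tp / length(predicted)
  sensitivity <- if (length(contacts) == 0) NA_real_ else
    tp / length(contacts)
  c(precision = precision, sensitivity = sensitivity)
}

#' Score one DBU prediction against a reference complex
#'
#' @param base_pred a `base_prediction` (top placement is evaluated).
#' @param orient_pred an `orientation_prediction`.
#' @param dbu the `dbu` the predictions belong to.
#' @param ref the reference complex.
#' @return list of class `evaluation_result`: `location_error`,
#'   `success_location` (error <= 6), `groove_type`, `orientation_error`
#'   (degrees, NA when location failed), `success_orientation`
#'   (cos > 0.9).
#' @export
evaluate_prediction <- function(base_pred, orient_pred, dbu, ref) {
  if (base_pred$status != "ok" || length(base_pred$placements) == 0) {
    return(structure(list(location_error = NA_real_,
                          success_location = FALSE,
                          groove_type = NA_character_,
                          orientation_error = NA_real_,
                          success_orientation = NA),
                     class = "evaluation_result"))
  }
  le <- location_error(base_pred$placements[[1]], ref)
  ok_loc <- le <= LOCATION_FAIL_CUTOFF
  groove <- NA_character_
  oe <- NA_real_
  ok_or <- NA
  if (ok_loc) {
    tang <- reference_tangent(ref, dbu)
    groove <- tang$groove
    if (is.list(tang$candidates)) {
      oe <- orientation_error(orient_pred, tang$candidates)
      ok_or <- cos(deg2rad(oe)) > ORIENTATION_COS_SUCCESS
    }
  }
  structure(list(location_error = le, success_location = ok_loc,
                 groove_type = groove, orientation_error = oe,
                 success_orientation = ok_or),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    "location error %.2f A (%s); groove %s; orientation error %s deg (%s)\n",
    x$location_error, ifelse(isTRUE(x$success_location), "success", "failure"),
    x$groove_type,
    ifelse(is.na(x$orientation_error), "NA",
           sprintf("%.1f", x$orientation_error)),
    ifelse(is.na(x$success_orientation), "NA",
           ifelse(x$success_orientation, "success", "failure"))))
  invisible(x)
}
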