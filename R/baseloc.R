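# Base-location prediction around a DBU: knowledgebase model instances are
# mapped into query coordinates through each member residue's local frame,
# scored by a Gaussian density over the placed atom cloud (normalized per
# amino-acid type), screened against the protein core, and thinned by
# greedy diversity selection on pairwise RMSD.

#' Scoring parameters for base placement
#'
#' @param kernel_sigma width (Angstrom) of the Gaussian kernel of the base
#'   density (default 2.0; unit peak, K(0) = 1).
#' @param core_sigma width of the Gaussian sum over query CA atoms used as
#'   the protein-core score (default 5.0).
#' @param clash_distance placement-to-protein distance (Angstrom) that
#'   terminates the core keep-loop (default 2.0).
#' @param diversity_rmsd minimum RMSD (Angstrom) between reported
#'   placements (default 5.0, strict `>`).
#' @return list of class `density_params`.
#' @export
density_params <- function(kernel_sigma = 2.0, core_sigma = 5.0,
                           clash_distance = 2.0, diversity_rmsd = 5.0) {
  vals <- c(kernel_sigma, core_sigma, clash_distance, diversity_rmsd)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all density parameters must be positive")
  structure(list(kernel_sigma = kernel_sigma, core_sigma = core_sigma,
                 clash_distance = clash_distance,
                 diversity_rmsd = diversity_rmsd),
            class = "density_params")
}

placement_centroid <- function(atoms) {
  moi <- rownames(atoms) %in% BASE_MOIETY_ATOMS
  if (sum(moi) >= 3) colMeans(atoms[moi, , drop = FALSE]) else colMeans(atoms)
}

#' Place knowledgebase model instances around a DBU
#'
#' For each residue `r` of the DBU, every instance of the model
#' `M[aa(r) - b]` is transformed from `r`'s local frame into world
#' coordinates.  The union over residues is the candidate sampling space.
#'
#' @param dbu a `dbu` object.
#' @param s the query `pdb_structure`.
#' @param kb a `knowledgebase`.
#' @param base base type, one of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return list of `base_placement` objects: `list(id, base, residue_key,
#'   model_key, instance_id, atoms, centroid)`; empty (with a warning) when
#'   every member type has an empty model.
#' @export
place_models <- function(dbu, s, kb, base) {
  stopifnot(base %in% STANDARD_BASES)
  rt <- residue_table(s)
  out <- list()
  for (rk in dbu$residues) {
    aa <- rt$resname[match(rk, rt$reskey)]
    key <- paste(aa, base, sep = "|")
    m <- kb$models[[key]]
    if (is.null(m) || length(m$instances) == 0) next
    fr <- tryCatch(suppressWarnings(local_frame(s, rk, kb$frames)),
                   error = function(e) NULL)
    if (is.null(fr)) next
    for (ii in seq_along(m$instances)) {
      inst <- m$instances[[ii]]
      world <- frame_to_world(fr, inst$atoms)
      rownames(world) <- rownames(inst$atoms)
      out[[length(out) + 1]] <- structure(
        list(id = sprintf("%s|%s|%d", rk, key, ii), base = base,
             residue_key = rk, model_key = key, instance_id = inst$id,
             atoms = world, centroid = placement_centroid(world)),
        class = "base_placement")
    }
  }
  if (length(out) == 0)
    warning("no model instances available for base ", base,
            " over this DBU")
  out
}

#' Base-density score at points in space
#'
#' `P_b(x) = sum over DBU residues r of (1 / n_aa(r)) * sum over atoms i
#' placed via r of exp(-|x - y_i|^2 / (2 sigma^2))`, where `n_aa(r)` is the
#' number of DBU residues sharing r's amino-acid type.  The kernel has unit
#' peak, so a point coinciding with the single atom placed by a 1-residue
#' DBU scores exactly 1.
#'
#' @param x a 3-vector or an n x 3 matrix of evaluation points.
#' @param placements list of `base_placement`s (from [place_models()]).
#' @param dbu the `dbu` the placements came from.
#' @param s the query `pdb_structure` (residue types).
#' @param params a [density_params()].
#' @return numeric vector of densities, one per evaluation point.
#' @export
density_score <- function(x, placements, dbu, s, params = density_params()) {
  if (length(placements) == 0) stop("no placements to score against")
  x <- matrix(as.numeric(x), ncol = 3)
  rt <- residue_table(s)
  aa_of <- stats::setNames(rt$resname, rt$reskey)
  dbu_aa <- aa_of[dbu$residues]
  n_aa <- table(dbu_aa)
  ycoords <- do.call(rbind, lapply(placements, function(p) p$atoms))
  w <- unlist(lapply(placements, function(p) {
    rep(1 / as.numeric(n_aa[[aa_of[[p$residue_key]]]]), nrow(p$atoms))
  }))
  d2 <- pairwise_dist2(x, ycoords)
  as.numeric(exp(-d2 / (2 * params$kernel_sigma^2)) %*% w)
}

#' Protein-core exclusion of placements
#'
#' Each placement's core score is the maximum over its atoms of a Gaussian
#' sum over the query protein's CA atoms.  Placements are kept in ascending
#' core-score order; the loop stops permanently at the first placement
#' whose minimum distance to any protein atom falls below
#' `clash_distance`.
#'
#' @inheritParams density_score
#' @return the kept placements (ascending core score), each annotated with
#'   `core_score` and `min_protein_distance`.
#' @export
core_filter <- function(placements, s, params = density_params()) {
  if (length(placements) == 0) return(placements)
  a <- s$atoms
  ca <- which(a$kind == "protein" & a$name == "CA")
  if (length(ca) == 0) stop("query protein has no CA atoms")
  prot <- which(a$kind == "protein")
  ca_xyz <- atom_xyz(s, ca)
  prot_xyz <- atom_xyz(s, prot)
  for (i in seq_along(placements)) {
    at <- placements[[i]]$atoms
    core <- rowSums(exp(-pairwise_dist2(at, ca_xyz) /
                          (2 * params$core_sigma^2)))
    placements[[i]]$core_score <- max(core)
    placements[[i]]$min_protein_distance <-
      sqrt(min(pairwise_dist2(at, prot_xyz)))
  }
  cs <- vapply(placements, function(p) p$core_score, numeric(1))
  ord <- order(cs, seq_along(placements))
  placements <- placements[ord]
  mind <- vapply(placements, function(p) p$min_protein_distance, numeric(1))
  clash <- which(mind < params$clash_distance)
  if (length(clash) > 0) placements <- placements[seq_len(clash[1] - 1)]
  placements
}

#' RMSD between two placements
#'
#' Computed over shared atom names in world coordinates without
#' re-superposition; pairs sharing fewer than 3 atoms are treated as
#' infinitely distant (both survive diversity selection).
#'
#' @param p1,p2 `base_placement`s.
#' @return RMSD in Angstrom (possibly `Inf`).
#' @export
placement_rmsd <- function(p1, p2) {
  shared <- intersect(rownames(p1$atoms), rownames(p2$atoms))
  if (length(shared) < 3) return(Inf)
  sqrt(mean(rowSums((p1$atoms[shared, , drop = FALSE] -
                       p2$atoms[shared, , drop = FALSE])^2)))
}

#' Greedy diversity selection of placements
#'
#' Scans placements in descending density (ties: input order) and keeps a
#' placement only when its RMSD to every previously kept placement exceeds
#' `diversity_rmsd`.  The first kept placement is the reported prediction.
#'
#' @param placements `base_placement`s carrying a `density` field.
#' @param params a [density_params()].
#' @return the kept placements, descending density.
#' @export
diverse_select <- function(placements, params = density_params()) {
  if (length(placements) == 0) return(placements)
  dens <- vapply(placements, function(p) p$density, numeric(1))
  ord <- order(-dens, seq_along(placements))
  kept <- list()
  for (i in ord) {
    ok <- all(vapply(kept, function(k)
      placement_rmsd(placements[[i]], k) > params$diversity_rmsd,
      logical(1)))
    if (ok) kept[[length(kept) + 1]] <- placements[[i]]
  }
  kept
}

#' Predict base locations around a DBU
#'
#' Pipeline: [place_models()] -> [core_filter()] -> density at surviving
#' placement centroids (the density field itself is built from the full
#' placed atom cloud) -> [diverse_select()].  The top-ranked placement is
#' the predicted centre location for base type `base`.
#'
#' @inheritParams place_models
#' @param params a [density_params()].
#' @return object of class `base_prediction`: `list(base, placements,
#'   n_candidates, status)`; `status = "empty"` when no models applied.
#' @export
predict_base_location <- function(dbu, s, kb, base,
                                  params = density_params()) {
  placed <- suppressWarnings(place_models(dbu, s, kb, base))
  if (length(placed) == 0)
    return(structure(list(base = base, placements = list(),
                          n_candidates = 0L, status = "empty"),
                     class = "base_prediction"))
  kept <- core_filter(placed, s, params)
  if (length(kept) == 0)
    return(structure(list(base = base, placements = list(),
                          n_candidates = length(placed),
                          status = "all-clashing"),
                     class = "base_prediction"))
  cent <- do.call(rbind, lapply(kept, function(p) p$centroid))
  dens <- density_score(cent, placed, dbu, s, params)
  for (i in seq_along(kept)) kept[[i]]$density <- dens[i]
  sel <- diverse_select(kept, params)
  structure(list(base = base, placements = sel,
                 n_candidates = length(placed), status = "ok"),
            class = "base_prediction")
}

#' @export
print.base_prediction <- function(x, ...) {
  if (x$status != "ok" || length(x$placements) == 0) {
    cat("base_prediction[", x$base, "]: ", x$status, "\n", sep = "")
    return(invisible(x))
  }
  top <- x$placements[[1]]
  cat(sprintf(
    "base_prediction[%s]: %d kept of %d candidates; top density %.4f at (%.2f, %.2f, %.2f) via %s\n",
    x$base, length(x$placements), x$n_candidates, top$density,
    top$centroid[1], top$centroid[2], top$centroid[3], top$residue_key))
  invisible(x)
}
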