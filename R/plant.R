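# Planting synthetic DNA-binding units (DBUs) into a generated duplex.
# Residues are laid out along the ground-truth groove tangent through a
# groove-floor point, with their side-chain tip snapped to a fixed offset
# from the nearest DNA atom so that every planted residue is guaranteed to
# be DNA-binding at the 4.5 A threshold when jitter is zero.

# Side-chain atoms planted per supported residue type, ordered tip-first.
SIDECHAIN_TRIPLES <- list(
  ARG = c("NH1", "NH2", "CZ"),
  LYS = c("NZ", "CE", "CD"),
  ASN = c("ND2", "OD1", "CG"),
  GLN = c("NE2", "OE1", "CD"),
  HIS = c("NE2", "ND1", "CG")
)

#' Specification of one planted DBU
#'
#' @param residue_types 3-letter codes of the residues to plant (supported:
#'   ARG, LYS, ASN, GLN, HIS); one residue is planted per entry, spaced
#'   5 Angstrom apart along the true groove tangent.
#' @param groove `"major"` or `"minor"`.
#' @param center_bp base-pair index of the DBU centre; must lie in
#'   `[4, n_bp - 5]` so the tangent phosphates exist.
#' @param offset distance (Angstrom) from the nearest DNA atom to the
#'   side-chain tip atom; default 3.3 keeps the residue inside the 4.5 A
#'   binding threshold with room for jitter.
#' @param jitter_sd per-coordinate Gaussian noise (Angstrom) added to every
#'   planted atom.
#' @param seed RNG seed for the jitter.
#' @return a list of class `dbu_spec`.
#' @export
dbu_spec <- function(residue_types = c("ARG", "LYS", "ASN"),
                     groove = c("major", "minor"), center_bp = 8,
                     offset = 3.3, jitter_sd = 0.3, seed = 1) {
  groove <- match.arg(groove)
  bad <- setdiff(residue_types, names(SIDECHAIN_TRIPLES))
  if (length(bad) > 0)
    stop("unsupported planted residue type(s): ", paste(bad, collapse = ", "))
  if (offset <= 0 || jitter_sd < 0) stop("offset must be > 0, jitter_sd >= 0")
  structure(list(residue_types = residue_types, groove = groove,
                 center_bp = center_bp, offset = offset,
                 jitter_sd = jitter_sd, seed = seed), class = "dbu_spec")
}

#' Plant a DBU of protein residues into a duplex
#'
#' Appends protein residues (chain C) positioned in the requested groove of
#' `dna` and records the ground truth (centre base pair, groove type, true
#' tangent, member residue keys) in the structure's `dbus` attribute.
#'
#' @param dna a duplex from [build_bdna()], possibly already carrying
#'   previously planted DBUs.
#' @param spec a [dbu_spec()].
#' @return the augmented `pdb_structure`.
#' @export
plant_dbu <- function(dna, spec) {
  if (!inherits(spec, "dbu_spec")) stop("spec must be a dbu_spec")
  hx <- attr(dna, "helix")
  if (is.null(hx)) stop("plant_dbu needs a duplex built by build_bdna")
  n <- hx$n_bp
  if (spec$center_bp < 4 || spec$center_bp > n - 5)
    stop("center_bp must lie in [4, n_bp - 5] = [4, ", n - 5, "]")

  truth <- true_groove_tangent(dna, spec$center_bp, spec$groove)
  tang <- truth$direction
  g <- groove_point(dna, spec$center_bp, spec$groove)
  dna_rows <- which(dna$atoms$kind == "dna")
  dxyz <- atom_xyz(dna, dna_rows)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  # Residues are spaced 5 A apart along the tangent, so a default 3-residue
  # DBU spans ~10 A -- about three successive bases, the spatial scale the
  # 11 A clustering stop is designed around.
  m <- length(spec$residue_types)
  offs <- (seq_len(m) - (m + 1) / 2) * 5.0
  prot_seq <- dna$atoms$resseq[dna$atoms$kind == "protein"]
  next_seq <- if (length(prot_seq) > 0) max(prot_seq) + 1L else 1L

  new_atoms <- list()
  res_keys <- character(0)
  for (k in seq_len(m)) {
    rt <- spec$residue_types[k]
    p0 <- g + offs[k] * tang
    d2 <- pairwise_dist2(matrix(p0, 1), dxyz)
    ynear <- dxyz[which.min(d2), ]
    dirv <- unit_vec(p0 - ynear)
    tip <- ynear + spec$offset * dirv
    ov <- unit_vec(c(tip[1] - hx$origin[1], tip[2] - hx$origin[2], 0))
    tv <- tang - sum(tang * ov) * ov
    tv <- if (vec_norm(tv) < 1e-9) unit_vec(cross3(ov, c(0, 0, 1))) else unit_vec(tv)
    names_sc <- SIDECHAIN_TRIPLES[[rt]]
    ca <- tip + 3.3 * ov
    pos <- rbind(tip,
                 tip + 1.3 * tv,
                 tip - 1.3 * tv + 0.5 * ov,
                 ca,
                 ca + 1.52 * (0.87 * tv + 0.5 * ov),
                 ca + 1.46 * (-0.87 * tv + 0.5 * ov))
    anames <- c(names_sc, "CA", "C", "N")
    if (spec$jitter_sd > 0)
      pos <- pos + matrix(stats::rnorm(length(pos), 0, spec$jitter_sd),
                          nrow(pos), 3)
    resseq <- next_seq + k - 1L
    new_atoms[[k]] <- data.frame(
      serial = 0L, name = anames, altloc = " ", resname = rt, chain = "C",
      resseq = resseq, icode = " ", x = pos[, 1], y = pos[, 2], z = pos[, 3],
      occ = 1, element = substr(anames, 1, 1), stringsAsFactors = FALSE)
    res_keys <- c(res_keys, make_reskey("C", resseq, " "))
  }
  add <- do.call(rbind, new_atoms)
  add$kind <- "protein"
  add$base <- NA_character_
  add$reskey <- make_reskey(add$chain, add$resseq, add$icode)
  atoms <- rbind(dna$atoms, add)
  atoms$serial <- seq_len(nrow(atoms))
  out <- new_structure(atoms, id = dna$id, source = dna$source)
  attr(out, "helix") <- hx
  dbus <- attr(dna, "dbus")
  if (is.null(dbus)) dbus <- list()
  dbus[[length(dbus) + 1]] <- list(
    center_bp = spec$center_bp, groove = spec$groove,
    tangent = truth$direction, candidates = truth$candidates,
    groove_point = g, residues = res_keys, seed = spec$seed, spec = spec)
  attr(out, "dbus") <- dbus
  out
}

#' Generate a synthetic protein-DNA fixture on disk
#'
#' Convenience wrapper: builds a duplex, plants one or more DBUs, writes the
#' complex (or, in unbound mode, only the protein part) as a PDB file plus a
#' JSON sidecar holding the ground truth, and returns the structure.
#'
#' @param dir output directory (created if needed).
#' @param name file stem for the PDB/JSON pair.
#' @param n_bp,sequence,rise,twist forwarded to [build_bdna()].
#' @param dbus list of [dbu_spec()]s; default one major-groove DBU at the
#'   duplex midpoint.
#' @param unbound if TRUE, DNA is omitted from the written PDB (the ground
#'   truth JSON still records it), emulating an unbound query structure.
#' @return list with `structure`, `pdb` and `truth` (file paths).
#' @export
make_fixture <- function(dir = tempdir(), name = "fixture", n_bp = 16,
                         sequence = NULL, rise = 3.38, twist = 36,
                         dbus = list(dbu_spec(center_bp = max(4, round(n_bp / 2)))),
                         unbound = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  s <- build_bdna(n_bp = n_bp, sequence = sequence, rise = rise, twist = twist)
  for (d in dbus) s <- plant_dbu(s, d)
  pdb_path <- file.path(dir, paste0(name, ".pdb"))
  truth_path <- file.path(dir, paste0(name, "_truth.json"))
  out_s <- s
  if (unbound) {
    keep <- s$atoms$kind != "dna"
    out_s <- new_structure(s$atoms[keep, , drop = FALSE], id = s$id)
  }
  write_pdb(out_s, pdb_path)
  truth <- lapply(attr(s, "dbus"), function(d) {
    list(center_bp = d$center_bp, groove = d$groove,
         tangent = as.numeric(d$tangent),
         candidates = lapply(d$candidates, as.numeric),
         residues = d$residues, seed = d$seed)
  })
  jsonlite::write_json(
    list(n_bp = n_bp, rise = rise, twist = twist, unbound = unbound,
         dbus = truth),
    truth_path, auto_unbox = TRUE, digits = NA)
  list(structure = s, pdb = pdb_path, truth = truth_path)
}
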