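# Ideal B-DNA duplex generator.  The duplex is stylized, not chemically
# exact: each nucleotide carries a phosphate (P), a sugar anchor (C1') and a
# planar ring template for its base, arranged on a right-handed helix with
# the canonical B-form rise and twist.  The two strands are related by the
# base-pair dyad (180 degree rotation about the pair's local x axis), which
# makes them antiparallel with Watson-Crick pairing i <-> (n_bp + 1 - i).
#
# Cylindrical placement constants (documented implementation choices):
#   P    radius 9.2 A, azimuth offset -94 deg, z offset +2.2 A
#   C1'  radius 5.9 A, azimuth offset +61.8 deg
#   base ring centroid radius 1.2 A at the C1' azimuth
# With the C1' atoms of a pair at azimuths +/-61.8 deg, their bisector
# (local +x) points into the minor groove and -x into the major groove.

BDNA_CONST <- list(r_p = 9.2, phi_p = -94, z_p = 2.2,
                   r_c1 = 5.9, phi_c1 = 61.8, r_base = 1.2,
                   bond = 1.39, r_groove = 6.0)

DNA_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

# Regular pentagon fused on edge A-B of a hexagon centred at hex_ctr;
# returns the three new vertices walking from B away from A.
fuse_pentagon <- function(a, b, hex_ctr, side = BDNA_CONST$bond) {
  m <- (a + b) / 2
  nrm <- unit_vec(c(m - hex_ctr, 0))[1:2]
  ctr <- m + (side / (2 * tan(pi / 5))) * nrm
  rp <- side / (2 * sin(pi / 5))
  ang_a <- atan2(a[2] - ctr[2], a[1] - ctr[1])
  ang_b <- atan2(b[2] - ctr[2], b[1] - ctr[1])
  step <- ang_b - ang_a
  step <- atan2(sin(step), cos(step))  # wrap to (-pi, pi]; |step| = 72 deg
  vapply(1:3, function(k) ctr + rp * c(cos(ang_b + k * step),
                                       sin(ang_b + k * step)),
         numeric(2))
}

# In-plane atom template for one base, zero-centred, glycosidic side
# toward +x.  Pyrimidines: six-ring N1..C6 with N1 outward; purines add the
# fused five-ring N7/C8/N9 with N9 outward.
base_template <- function(b) {
  s <- BDNA_CONST$bond
  hex_ang <- deg2rad(seq(0, 300, by = 60))
  if (b %in% c("C", "T")) {
    xy <- cbind(cos(hex_ang), sin(hex_ang)) * s
    rownames(xy) <- c("N1", "C2", "N3", "C4", "C5", "C6")
  } else {
    ctr <- c(-0.9, 0)
    xy <- sweep(cbind(cos(hex_ang), sin(hex_ang)) * s, 2, -ctr)
    rownames(xy) <- c("C4", "C5", "C6", "N1", "C2", "N3")
    pent <- t(fuse_pentagon(xy["C4", ], xy["C5", ], ctr))
    rownames(pent) <- c("N7", "C8", "N9")
    xy <- rbind(xy, pent)
  }
  sweep(xy, 2, colMeans(xy))
}

cyl <- function(r, phi_deg, z = 0) {
  c(r * cos(deg2rad(phi_deg)), r * sin(deg2rad(phi_deg)), z)
}

# Local (base-pair frame) heavy-atom coordinates of one strand-A-style
# nucleotide of base type b: named matrix, columns x/y/z.
nucleotide_local <- function(b) {
  k <- BDNA_CONST
  tpl <- base_template(b)
  rot <- matrix(c(cos(deg2rad(k$phi_c1)), -sin(deg2rad(k$phi_c1)),
                  sin(deg2rad(k$phi_c1)),  cos(deg2rad(k$phi_c1))),
                2, 2, byrow = TRUE)
  ctr <- cyl(k$r_base, k$phi_c1)[1:2]
  base_xy <- sweep(tpl %*% t(rot), 2, ctr, "+")
  out <- rbind(P = cyl(k$r_p, k$phi_p, k$z_p),
               "C1'" = cyl(k$r_c1, k$phi_c1, 0),
               cbind(base_xy, 0))
  colnames(out) <- c("x", "y", "z")
  out
}

#' Build an ideal B-DNA duplex
#'
#' Generates a straight double helix along `axis` with Watson-Crick pairing
#' `i <-> n_bp + 1 - i` (chains A and B, each numbered 1..n_bp in its own
#' 5'->3' order; chain A index increases along `axis`).
#'
#' @param n_bp number of base pairs (minimum 6).
#' @param sequence strand-A sequence over A/C/G/T; default cycles "ACGT".
#' @param rise helical rise per base pair in Angstrom (default 3.38).
#' @param twist helical twist per base pair in degrees (default 36).
#' @param axis,origin helix axis direction and start point; default +z at 0.
#' @return a `pdb_structure` with an attached `helix` attribute recording
#'   the generation parameters.
#' @export
build_bdna <- function(n_bp = 16, sequence = NULL, rise = 3.38, twist = 36,
                       axis = c(0, 0, 1), origin = c(0, 0, 0)) {
  if (n_bp < 6) stop("a duplex needs at least six base pairs")
  if (is.null(sequence))
    sequence <- paste(rep(c("A", "C", "G", "T"), length.out = n_bp),
                      collapse = "")
  seqv <- strsplit(toupper(sequence), "")[[1]]
  if (length(seqv) != n_bp || !all(seqv %in% c("A", "C", "G", "T")))
    stop("sequence must have n_bp characters over A/C/G/T")

  rows <- list()
  add_res <- function(chain, resseq, b, xyz) {
    data.frame(serial = 0L, name = rownames(xyz), altloc = " ",
               resname = paste0("D", b), chain = chain, resseq = resseq,
               icode = " ", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               occ = 1, element = substr(rownames(xyz), 1, 1),
               stringsAsFactors = FALSE)
  }
  dyad <- diag(c(1, -1, -1))
  for (i in seq_len(n_bp)) {
    theta <- (i - 1) * twist
    zi <- (i - 1) * rise
    rz <- rotation_z(theta)
    la <- nucleotide_local(seqv[i])
    xyz_a <- sweep(la %*% t(rz), 2, c(0, 0, zi), "+")
    rownames(xyz_a) <- rownames(la)
    rows[[length(rows) + 1]] <- add_res("A", i, seqv[i], xyz_a)
    lb0 <- nucleotide_local(unname(DNA_COMPLEMENT[seqv[i]]))
    xyz_b <- sweep((lb0 %*% t(dyad)) %*% t(rz), 2, c(0, 0, zi), "+")
    rownames(xyz_b) <- rownames(lb0)
    rows[[length(rows) + 1]] <- list(chain = "B", resseq = n_bp + 1 - i,
                                     b = unname(DNA_COMPLEMENT[seqv[i]]),
                                     xyz = xyz_b)
  }
  a_part <- do.call(rbind, Filter(is.data.frame, rows))
  b_rows <- Filter(function(r) !is.data.frame(r), rows)
  b_rows <- b_rows[order(vapply(b_rows, function(r) r$resseq, numeric(1)))]
  b_part <- do.call(rbind, lapply(b_rows, function(r)
    add_res("B", r$resseq, r$b, r$xyz)))
  atoms <- rbind(a_part, b_part)

  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  axis <- unit_vec(axis)
  if (!isTRUE(all.equal(axis, c(0, 0, 1)))) {
    v <- cross3(c(0, 0, 1), axis)
    sv <- vec_norm(v); cv <- sum(c(0, 0, 1) * axis)
    if (sv < 1e-12) {
      rot <- if (cv > 0) diag(3) else diag(c(1, -1, -1))
    } else {
      vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
                   3, 3, byrow = TRUE)
      rot <- diag(3) + vx + vx %*% vx * ((1 - cv) / sv^2)
    }
    xyz <- xyz %*% t(rot)
  }
  xyz <- sweep(xyz, 2, origin, "+")
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]

  atoms$serial <- seq_len(nrow(atoms))
  atoms$kind <- residue_kind(atoms$resname)
  atoms$base <- base_letter(atoms$resname)
  atoms$reskey <- make_reskey(atoms$chain, atoms$resseq, atoms$icode)
  s <- new_structure(atoms, id = sprintf("bdna%02d", n_bp))
  attr(s, "helix") <- list(n_bp = n_bp, rise = rise, twist = twist,
                           sequence = paste(seqv, collapse = ""),
                           axis = axis, origin = origin,
                           constants = BDNA_CONST)
  s
}

p_coord <- function(s, chain, resseq) {
  a <- s$atoms
  i <- which(a$chain == chain & a$resseq == resseq & a$name == "P" &
               a$kind == "dna")
  if (length(i) == 0) return(NULL)
  c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
}

#' Ground-truth groove tangent of a generated duplex
#'
#' Implements the phosphate-backbone convention: for a major-groove site at
#' base pair `i`, the tangent is the direction P(i-3) -> P(i-4) on the
#' reference strand (and the j-3/j-4 analogue on the complementary strand);
#' for a minor-groove site it is P(i) -> P(i+1) (and j/j+1).  Both strand
#' candidates are returned when their phosphates exist; `direction` is the
#' first available candidate (reference strand preferred).
#'
#' @param dna a duplex from [build_bdna()] (pairing `i <-> n_bp+1-i` between
#'   chains A and B is assumed).
#' @param center_bp base-pair index `i` on chain A.
#' @param groove `"major"` or `"minor"`.
#' @return list with `direction` (undirected unit 3-vector, canonical sign),
#'   `candidates` (list of 1-2 unit vectors), `groove`, `center_bp`.
#' @export
true_groove_tangent <- function(dna, center_bp, groove = c("major", "minor")) {
  groove <- match.arg(groove)
  hx <- attr(dna, "helix")
  n <- if (!is.null(hx)) hx$n_bp else max(dna$atoms$resseq[dna$atoms$kind == "dna"])
  i <- center_bp
  j <- n + 1 - i
  idx <- if (groove == "major") {
    list(c("A", i - 3, i - 4), c("B", j - 3, j - 4))
  } else {
    list(c("A", i, i + 1), c("B", j, j + 1))
  }
  cand <- list()
  missing <- character(0)
  for (spec in idx) {
    p1 <- p_coord(dna, spec[1], as.integer(spec[2]))
    p2 <- p_coord(dna, spec[1], as.integer(spec[3]))
    if (is.null(p1) || is.null(p2)) {
      missing <- c(missing, sprintf("%s:%s/%s", spec[1], spec[2], spec[3]))
      next
    }
    cand[[length(cand) + 1]] <- canonical_sign(unit_vec(p2 - p1))
  }
  if (length(cand) == 0)
    stop("phosphates missing for groove tangent at nucleotides ",
         paste(missing, collapse = ", "))
  list(direction = cand[[1]], candidates = cand, groove = groove,
       center_bp = center_bp)
}

# Point on the groove floor at base pair i: minor groove lies on the local
# +x side (C1' bisector), major on -x, at radius r_groove from the axis.
groove_point <- function(dna, center_bp, groove = c("major", "minor")) {
  groove <- match.arg(groove)
  hx <- attr(dna, "helix")
  if (is.null(hx)) stop("groove_point needs a duplex built by build_bdna")
  theta <- (center_bp - 1) * hx$twist + if (groove == "major") 180 else 0
  p <- cyl(hx$constants$r_groove, theta, (center_bp - 1) * hx$rise)
  # undo the axis/origin normalization used at build time
  axis <- hx$axis
  if (!isTRUE(all.equal(axis, c(0, 0, 1)))) {
    v <- cross3(c(0, 0, 1), axis)
    sv <- vec_norm(v); cv <- sum(c(0, 0, 1) * axis)
    if (sv < 1e-12) {
      rot <- if (cv > 0) diag(3) else diag(c(1, -1, -1))
    } else {
      vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
                   3, 3, byrow = TRUE)
      rot <- diag(3) + vx + vx %*% vx * ((1 - cv) / sv^2)
    }
    p <- as.numeric(rot %*% p)
  }
  p + hx$origin
}
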