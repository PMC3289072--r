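# Solvent accessibility.  Shrake-Rupley numerical SASA with a 1.4 A probe,
# normalized per residue by the Tien et al. (2013) theoretical maxima to
# give relative solvent accessibility (RSA).

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, DEFAULT = 1.70)

# Theoretical maximum accessible surface areas (A^2), Tien et al. 2013.
MAX_ASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
             GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
             LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
             SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' @param xyz n x 3 matrix of atom coordinates.
#' @param elements element symbols (radii default to carbon when unknown).
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sphere test points per atom (default 192).
#' @return numeric vector of per-atom SASA in Angstrom^2.
#' @export
shrake_rupley <- function(xyz, elements, probe = 1.4, n_points = 192) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- nrow(xyz)
  rad <- VDW_RADII[toupper(elements)]
  rad[is.na(rad)] <- VDW_RADII[["DEFAULT"]]
  rad <- unname(rad) + probe
  sphere <- fibonacci_sphere(n_points)
  d2 <- pairwise_dist2(xyz, xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    pts <- sweep(sphere * rad[i], 2, xyz[i, ], "+")
    if (length(nb) > 0) {
      pd2 <- pairwise_dist2(pts, xyz[nb, , drop = FALSE])
      buried <- rowSums(sweep(pd2, 2, rad[nb]^2, "<")) > 0
      frac <- mean(!buried)
    } else frac <- 1
    area[i] <- frac * 4 * pi * rad[i]^2
  }
  area
}

#' Relative solvent accessibility of protein residues
#'
#' SASA is computed over the protein atoms only (the DNA partner, if any,
#' is excluded so that bound and unbound forms of the same protein give the
#' same accessibility), summed per residue, and divided by the residue
#' type's theoretical maximum.
#'
#' @param s a `pdb_structure`.
#' @inheritParams shrake_rupley
#' @return named numeric vector of RSA values keyed by residue key.
#' @export
residue_rsa <- function(s, probe = 1.4, n_points = 192) {
  a <- s$atoms
  prot <- which(a$kind == "protein")
  if (length(prot) == 0) return(stats::setNames(numeric(0), character(0)))
  area <- shrake_rupley(atom_xyz(s, prot), a$element[prot],
                        probe = probe, n_points = n_points)
  per_res <- tapply(area, a$reskey[prot], sum)
  resname <- a$resname[prot][match(names(per_res), a$reskey[prot])]
  rsa <- as.numeric(per_res) / MAX_ASA[resname]
  stats::setNames(as.numeric(rsa), names(per_res))
}
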