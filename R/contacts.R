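# Contact queries at the method's two distance thresholds: 4.5 A for
# defining DNA-binding residues and 4.0 A for the atom-level counts that
# drive reference-frame selection and geometric-model construction.

dna_atom_rows <- function(s, base_atoms = c("residue", "base")) {
  base_atoms <- match.arg(base_atoms)
  a <- s$atoms
  rows <- which(a$kind == "dna")
  if (base_atoms == "base")
    rows <- rows[a$name[rows] %in% BASE_MOIETY_ATOMS]
  rows
}

#' DNA-binding residues of a structure
#'
#' A protein residue is DNA-binding when any of its atoms lies strictly
#' closer than `cutoff` (default 4.5 Angstrom) to any DNA atom.
#'
#' @param s a `pdb_structure` containing protein and DNA.
#' @param cutoff contact threshold in Angstrom (strict `<`).
#' @return character vector of residue keys (`chain:resseq`); empty when the
#'   structure has no DNA.
#' @export
binding_residues <- function(s, cutoff = 4.5) {
  a <- s$atoms
  prot <- which(a$kind == "protein")
  dna <- which(a$kind == "dna")
  if (length(prot) == 0 || length(dna) == 0) return(character(0))
  d2 <- pairwise_dist2(atom_xyz(s, prot), atom_xyz(s, dna))
  mind <- sqrt(apply(d2, 1, min))
  hit <- tapply(mind, a$reskey[prot], min)
  keys <- names(hit)[hit < cutoff]
  rt <- residue_table(s)
  keys[order(match(keys, rt$reskey))]
}

#' Protein-atom / base-residue contacts
#'
#' Lists every (protein atom, DNA residue) pair whose minimum atom-atom
#' distance is strictly below `cutoff` (default 4.0 Angstrom).  Each pair
#' appears once.  By default the distance to "a base" is the minimum over
#' all atoms of the nucleotide residue (sugar/phosphate included);
#' `base_atoms = "base"` restricts to base-moiety atoms only.
#'
#' @param s a `pdb_structure`.
#' @param cutoff contact threshold in Angstrom (strict `<`).
#' @param base_atoms `"residue"` (default) or `"base"`.
#' @return data frame with columns `atom_row` (row index into `s$atoms`),
#'   `protein_key`, `atom_name`, `aa`, `dna_key`, `base`, `dist`.
#' @export
atom_base_contacts <- function(s, cutoff = 4.0,
                               base_atoms = c("residue", "base")) {
  base_atoms <- match.arg(base_atoms)
  a <- s$atoms
  prot <- which(a$kind == "protein")
  dna <- dna_atom_rows(s, base_atoms)
  empty <- data.frame(atom_row = integer(0), protein_key = character(0),
                      atom_name = character(0), aa = character(0),
                      dna_key = character(0), base = character(0),
                      dist = numeric(0), stringsAsFactors = FALSE)
  if (length(prot) == 0 || length(dna) == 0) return(empty)
  d2 <- pairwise_dist2(atom_xyz(s, prot), atom_xyz(s, dna))
  out <- list()
  for (key in unique(a$reskey[dna])) {
    cols <- which(a$reskey[dna] == key)
    dmin <- sqrt(apply(d2[, cols, drop = FALSE], 1, min))
    hit <- which(dmin < cutoff)
    if (length(hit) == 0) next
    rows <- prot[hit]
    out[[key]] <- data.frame(
      atom_row = rows,
      protein_key = a$reskey[rows],
      atom_name = a$name[rows],
      aa = a$resname[rows],
      dna_key = key,
      base = a$base[dna[cols[1]]],
      dist = dmin[hit],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$atom_row, match(res$dna_key, unique(a$reskey[dna]))), ,
      drop = FALSE]
}
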