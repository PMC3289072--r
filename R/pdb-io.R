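# Fixed-column PDB (v3.x) reading and writing, plus the protein/DNA residue
# partition used throughout the package.  Only heavy atoms are retained:
# X-ray training structures mostly lack hydrogens, so hydrogens are dropped
# on input everywhere.

#' @keywords internal
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

# Nucleotide naming drifted across PDB eras; accept the modern DA/DC/DG/DT,
# legacy single letters and three-letter forms, all mapped to {A,C,G,T}.
NUC_MAP <- c(DA = "A", DC = "C", DG = "G", DT = "T",
             A = "A", C = "C", G = "G", T = "T",
             ADE = "A", CYT = "C", GUA = "G", THY = "T")

# Atom names belonging to the base moiety (ring + common exocyclic atoms),
# as opposed to the sugar/phosphate backbone of a nucleotide.
BASE_MOIETY_ATOMS <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9",
                       "O2", "O4", "O6", "N2", "N4", "N6", "C7", "C5M")

residue_kind <- function(resname) {
  resname <- toupper(trimws(resname))
  kind <- rep("other", length(resname))
  kind[resname %in% AA3] <- "protein"
  kind[resname %in% names(NUC_MAP)] <- "dna"
  kind
}

base_letter <- function(resname) {
  resname <- toupper(trimws(resname))
  out <- unname(NUC_MAP[resname])
  out
}

make_reskey <- function(chain, resseq, icode) {
  ic <- trimws(icode)
  paste0(chain, ":", resseq, ifelse(ic == "" | is.na(ic), "", ic))
}

guess_element <- function(name) {
  nm <- gsub("[^A-Za-z]", "", name)
  two <- toupper(substr(nm, 1, 2))
  el <- toupper(substr(nm, 1, 1))
  el[two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "SE")] <-
    two[two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "SE")]
  el
}

new_structure <- function(atoms, id = "", source = NA_character_) {
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, source = source),
            class = "pdb_structure")
}

#' Read a PDB-format structure file
#'
#' Parses ATOM and HETATM records from a fixed-column PDB file into a flat
#' atom table, resolves alternate locations to the highest-occupancy copy
#' (ties: first encountered), drops hydrogens, and partitions residues into
#' protein / dna / other.  Modified bases and non-standard amino acids are
#' tagged `other` and excluded from all downstream counting.
#'
#' @param path path to a PDB file.
#' @param model_index for multi-MODEL files, which model to read (default 1).
#' @return an object of class `pdb_structure`: a list with elements `id`,
#'   `atoms` (data frame with columns serial, name, altloc, resname, chain,
#'   resseq, icode, x, y, z, occ, element, kind, base, reskey) and `source`.
#' @export
read_pdb <- function(path, model_index = 1) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 0) {
    if (model_index > length(model_starts))
      stop("model_index ", model_index, " but file has only ",
           length(model_starts), " models")
    ends <- grep("^ENDMDL", lines)
    from <- model_starts[model_index]
    to <- ends[ends > from][1]
    if (is.na(to)) to <- length(lines)
    lines <- lines[from:to]
  }
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM") | grepl("^ATOM|^HETATM", rec)
  lines <- lines[keep]
  if (length(lines) == 0)
    stop("no ATOM/HETATM records found in ", path)

  atoms <- data.frame(
    serial  = suppressWarnings(as.integer(substr(lines, 7, 11))),
    name    = trimws(substr(lines, 13, 16)),
    altloc  = substr(lines, 17, 17),
    resname = trimws(substr(lines, 18, 20)),
    chain   = substr(lines, 22, 22),
    resseq  = suppressWarnings(as.integer(substr(lines, 23, 26))),
    icode   = substr(lines, 27, 27),
    x       = suppressWarnings(as.numeric(substr(lines, 31, 38))),
    y       = suppressWarnings(as.numeric(substr(lines, 39, 46))),
    z       = suppressWarnings(as.numeric(substr(lines, 47, 54))),
    occ     = suppressWarnings(as.numeric(substr(lines, 55, 60))),
    element = trimws(substr(lines, 77, 78)),
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z))
    stop("malformed coordinate fields in ", path)
  atoms$occ[is.na(atoms$occ)] <- 1
  noel <- atoms$element == ""
  atoms$element[noel] <- guess_element(atoms$name[noel])

  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(atoms) == 0) stop("no heavy atoms found in ", path)

  atoms$kind <- residue_kind(atoms$resname)
  atoms$base <- base_letter(atoms$resname)
  atoms$reskey <- make_reskey(atoms$chain, atoms$resseq, atoms$icode)

  # altloc resolution: per (residue, atom name) keep highest occupancy,
  # ties broken by file order.
  atoms$.orig <- seq_len(nrow(atoms))
  key <- paste(atoms$reskey, atoms$name)
  ord <- order(key, -atoms$occ, atoms$.orig)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$reskey, atoms$name)), , drop = FALSE]
  atoms <- atoms[order(atoms$.orig), , drop = FALSE]
  atoms$.orig <- NULL
  atoms$altloc <- " "

  new_structure(atoms,
                id = sub("\\.(pdb|ent)$", "", basename(path)),
                source = path)
}

#' Write a structure to a PDB file
#'
#' Emits fixed-column ATOM records at 3-decimal coordinate precision, with
#' TER records between chains.
#' @param s a `pdb_structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  a <- s$atoms
  fmt_name <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                     sprintf(" %-3s", a$name))
  out <- character(0)
  serial <- 0L
  for (ch in unique(a$chain)) {
    idx <- which(a$chain == ch)
    for (i in idx) {
      serial <- serial + 1L
      out <- c(out, sprintf(
        "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, fmt_name[i], " ",
        substr(a$resname[i], 1, 3), a$chain[i], a$resseq[i] %% 10000L,
        substr(a$icode[i], 1, 1), a$x[i], a$y[i], a$z[i], a$occ[i], 0,
        a$element[i]))
    }
    out <- c(out, "TER")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' @export
print.pdb_structure <- function(x, ...) {
  a <- x$atoms
  rt <- unique(a[, c("reskey", "kind")])
  cat("pdb_structure '", x$id, "': ", nrow(a), " atoms, ",
      sum(rt$kind == "protein"), " protein / ",
      sum(rt$kind == "dna"), " dna / ",
      sum(rt$kind == "other"), " other residues\n", sep = "")
  invisible(x)
}

atom_xyz <- function(s, rows = NULL) {
  a <- s$atoms
  if (!is.null(rows)) a <- a[rows, , drop = FALSE]
  cbind(a$x, a$y, a$z)
}

#' Residue-level summary table
#'
#' @param s a `pdb_structure`.
#' @return data frame with one row per residue (reskey, chain, resseq,
#'   icode, resname, kind, base, n_atoms) in file order.
#' @export
residue_table <- function(s) {
  a <- s$atoms
  first <- !duplicated(a$reskey)
  out <- a[first, c("reskey", "chain", "resseq", "icode", "resname",
                    "kind", "base"), drop = FALSE]
  out$n_atoms <- as.integer(table(a$reskey)[out$reskey])
  rownames(out) <- NULL
  out
}

residue_atoms <- function(s, reskey) {
  which(s$atoms$reskey == reskey)
}

# Apply a rigid motion to all atoms, returning a new structure.
transform_structure <- function(s, rot, trans = c(0, 0, 0)) {
  xyz <- apply_rigid(atom_xyz(s), rot, trans)
  s$atoms$x <- xyz[, 1]
  s$atoms$y <- xyz[, 2]
  s$atoms$z <- xyz[, 3]
  s
}
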