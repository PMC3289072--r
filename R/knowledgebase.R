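# The training knowledgebase: residue-level DNA-binding propensities,
# atom-level contact counts defining per-type reference frames, and the 80
# geometric models M[a-b] of base-atom clouds expressed in residue-local
# coordinates.

STANDARD_BASES <- c("A", "C", "G", "T")

#' Residue-level DNA-binding propensities
#'
#' For each of the 20 standard amino-acid types,
#' `propensity(a) = #binding residues of type a / #residues of type a`,
#' where a residue is binding when its distance to DNA atoms is < 4.5 A.
#' Counts are pooled over the training set; types never observed get 0.
#' An odds-ratio variant (`form = "odds"`) normalizes the binding fraction
#' of each type by the overall binding fraction.
#'
#' @param training list of `pdb_structure` complexes.
#' @param binding_cutoff contact threshold in Angstrom (default 4.5).
#' @param form `"ratio"` (default) or `"odds"`.
#' @return object of class `propensity_table`: data frame with columns
#'   `aa`, `n_binding`, `n_total`, `propensity`, plus attribute
#'   `mean_propensity` (unweighted mean over the 20 types).
#' @export
compute_propensities <- function(training, binding_cutoff = 4.5,
                                 form = c("ratio", "odds")) {
  form <- match.arg(form)
  if (length(training) == 0) stop("empty training set")
  nb <- stats::setNames(numeric(20), AA3)
  nt <- stats::setNames(numeric(20), AA3)
  for (s in training) {
    rt <- residue_table(s)
    prot <- rt[rt$kind == "protein" & rt$resname %in% AA3, , drop = FALSE]
    bind <- binding_residues(s, binding_cutoff)
    tt <- table(prot$resname)
    nt[names(tt)] <- nt[names(tt)] + as.numeric(tt)
    tb <- table(prot$resname[prot$reskey %in% bind])
    nb[names(tb)] <- nb[names(tb)] + as.numeric(tb)
  }
  prop <- ifelse(nt > 0, nb / nt, 0)
  if (form == "odds") {
    overall <- if (sum(nt) > 0) sum(nb) / sum(nt) else 0
    prop <- if (overall > 0) prop / overall else prop * 0
  }
  out <- data.frame(aa = AA3, n_binding = as.integer(nb),
                    n_total = as.integer(nt), propensity = as.numeric(prop),
                    stringsAsFactors = FALSE)
  attr(out, "mean_propensity") <- mean(out$propensity)
  attr(out, "form") <- form
  class(out) <- c("propensity_table", "data.frame")
  out
}

propensity_of <- function(prop, aa) {
  p <- prop$propensity[match(aa, prop$aa)]
  p[is.na(p)] <- 0
  p
}

#' Per-type reference frames from atom-level contact counts
#'
#' For every atom name of every amino-acid type, counts the number of
#' distinct base residues falling within `contact_cutoff` (default 4 A)
#' over the training set.  The top-3 atoms (descending count, ties by
#' lexicographic atom name) define the type's reference frame.  Types with
#' fewer than three contacting atom names fall back to the backbone frame
#' (CA, C, N) with a warning.
#'
#' @inheritParams compute_propensities
#' @param contact_cutoff contact threshold in Angstrom (default 4).
#' @param base_atoms passed to [atom_base_contacts()].
#' @return object of class `reference_frames`: named list over amino-acid
#'   types, each `list(atoms = <3 names>, counts = <named counts>)`.
#' @export
compute_reference_frames <- function(training, contact_cutoff = 4.0,
                                     base_atoms = c("residue", "base")) {
  base_atoms <- match.arg(base_atoms)
  if (length(training) == 0) stop("empty training set")
  tallies <- list()
  seen_aa <- character(0)
  for (s in training) {
    rt <- residue_table(s)
    seen_aa <- union(seen_aa, intersect(rt$resname, AA3))
    ct <- atom_base_contacts(s, contact_cutoff, base_atoms)
    ct <- ct[ct$aa %in% AA3, , drop = FALSE]
    if (nrow(ct) == 0) next
    key <- paste(ct$aa, ct$atom_name, sep = "|")
    tt <- table(key)
    for (k in names(tt))
      tallies[[k]] <- (if (is.null(tallies[[k]])) 0 else tallies[[k]]) + tt[[k]]
  }
  counts <- data.frame(
    aa = sub("\\|.*", "", names(tallies)),
    atom = sub(".*\\|", "", names(tallies)),
    n = as.numeric(unlist(tallies)), stringsAsFactors = FALSE)
  frames <- list()
  fallback <- character(0)
  for (aa in AA3) {
    sub <- counts[counts$aa == aa, , drop = FALSE]
    sub <- sub[order(-sub$n, sub$atom), , drop = FALSE]
    if (nrow(sub) >= 3) {
      frames[[aa]] <- list(atoms = sub$atom[1:3],
                           counts = stats::setNames(sub$n, sub$atom))
    } else {
      frames[[aa]] <- list(atoms = c("CA", "C", "N"),
                           counts = if (nrow(sub) > 0)
                             stats::setNames(sub$n, sub$atom) else
                               stats::setNames(numeric(0), character(0)))
      fallback <- c(fallback, aa)
    }
  }
  fallback <- intersect(fallback, seen_aa)
  if (length(fallback) > 0)
    warning("backbone fallback frame (CA, C, N) used for: ",
            paste(fallback, collapse = ", "))
  structure(frames, class = "reference_frames")
}

#' Canonical local frame of a residue
#'
#' Builds the orthonormal frame defined by three reference atoms: atom 1 at
#' the origin, atom 2 along +x, atom 3 in the xy half-plane with positive y
#' (Gram-Schmidt).  Exact for three points - no least-squares fitting.
#'
#' @param s a `pdb_structure`.
#' @param reskey residue key.
#' @param frame_atoms character(3) of atom names (e.g. from
#'   [compute_reference_frames()]); a whole `reference_frames` object is
#'   also accepted, in which case the residue's type selects the triple.
#' @return list with `rotation` (3x3, world -> local), `origin` (3-vector)
#'   and `atoms`; local coordinates of a point p are
#'   `rotation %*% (p - origin)`.  NULL (with a warning) when a frame atom
#'   is missing; error when the triple is collinear (angle < 1 degree).
#' @export
local_frame <- function(s, reskey, frame_atoms) {
  a <- s$atoms
  rows <- which(a$reskey == reskey)
  if (length(rows) == 0) stop("unknown residue: ", reskey)
  if (inherits(frame_atoms, "reference_frames"))
    frame_atoms <- frame_atoms[[a$resname[rows[1]]]]$atoms
  idx <- rows[match(frame_atoms, a$name[rows])]
  if (anyNA(idx)) {
    warning("residue ", reskey, " lacks frame atom(s) ",
            paste(frame_atoms[is.na(match(frame_atoms, a$name[rows]))],
                  collapse = ", "), "; skipped")
    return(NULL)
  }
  p <- atom_xyz(s, idx)
  v12 <- p[2, ] - p[1, ]
  v13 <- p[3, ] - p[1, ]
  ang <- line_angle(v12, v13)
  if (ang < 1) stop("degenerate (collinear) frame for residue ", reskey)
  ex <- unit_vec(v12)
  ey <- unit_vec(v13 - sum(v13 * ex) * ex)
  ez <- cross3(ex, ey)
  list(rotation = rbind(ex, ey, ez), origin = p[1, ], atoms = frame_atoms)
}

frame_to_local <- function(frame, xyz) {
  out <- sweep(xyz, 2, frame$origin) %*% t(frame$rotation)
  colnames(out) <- c("x", "y", "z")
  out
}

frame_to_world <- function(frame, xyz_local) {
  sweep(xyz_local %*% frame$rotation, 2, frame$origin, "+")
}

#' Build the geometric models M[a-b]
#'
#' For every DNA-binding residue occurrence of type `a` in the training
#' set, every nucleotide of base type `b` with any atom within
#' `contact_cutoff` contributes one instance: the nucleotide's atoms
#' expressed in the residue's canonical local frame.  At most 20 x 4 = 80
#' models; empty combinations are recorded as empty.
#'
#' @inheritParams compute_reference_frames
#' @param frames a `reference_frames` object.
#' @param binding_cutoff threshold defining binding residues (default 4.5).
#' @return named list `"AA|B"` -> `geometric_model`, each a list with `aa`,
#'   `base`, `instances` (list of `list(id, source, residue_key, base_key,
#'   atoms)` where `atoms` is a named matrix of frame-local coordinates)
#'   and `rmsd` (pairwise instance RMSD matrix, see
#'   [pairwise_instance_rmsd()]).
#' @export
build_models <- function(training, frames, contact_cutoff = 4.0,
                         binding_cutoff = 4.5,
                         base_atoms = c("residue", "base")) {
  base_atoms <- match.arg(base_atoms)
  models <- list()
  for (aa in AA3) for (b in STANDARD_BASES)
    models[[paste(aa, b, sep = "|")]] <-
      structure(list(aa = aa, base = b, instances = list(), rmsd = NULL),
                class = "geometric_model")
  for (s in training) {
    bind <- binding_residues(s, binding_cutoff)
    if (length(bind) == 0) next
    ct <- atom_base_contacts(s, contact_cutoff, base_atoms)
    a <- s$atoms
    for (rk in bind) {
      aa <- a$resname[which(a$reskey == rk)[1]]
      if (!(aa %in% AA3)) next
      fr <- tryCatch(suppressWarnings(local_frame(s, rk, frames)),
                     error = function(e) NULL)
      if (is.null(fr)) next
      touched <- unique(ct$dna_key[ct$protein_key == rk])
      for (bk in touched) {
        rows <- which(a$reskey == bk)
        b <- a$base[rows[1]]
        if (is.na(b) || !(b %in% STANDARD_BASES)) next
        loc <- frame_to_local(fr, atom_xyz(s, rows))
        rownames(loc) <- a$name[rows]
        key <- paste(aa, b, sep = "|")
        inst <- list(id = sprintf("%s:%s:%s", s$id, rk, bk), source = s$id,
                     residue_key = rk, base_key = bk, atoms = loc)
        models[[key]]$instances <-
          c(models[[key]]$instances, list(inst))
      }
    }
  }
  for (key in names(models))
    models[[key]]$rmsd <- pairwise_instance_rmsd(models[[key]])
  models
}

#' Pairwise RMSD between the instances of one geometric model
#'
#' RMSD over the intersection of atom names of two instances, computed on
#' the frame-local coordinates without re-superposition.  Pairs sharing
#' fewer than 3 atoms get `Inf`.
#'
#' @param m a `geometric_model`.
#' @return symmetric matrix (0 x 0 for empty models) with zero diagonal.
#' @export
pairwise_instance_rmsd <- function(m) {
  n <- length(m$instances)
  out <- matrix(0, n, n)
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ai <- m$instances[[i]]$atoms
    aj <- m$instances[[j]]$atoms
    shared <- intersect(rownames(ai), rownames(aj))
    v <- if (length(shared) < 3) Inf else
      sqrt(mean(rowSums((ai[shared, , drop = FALSE] -
                           aj[shared, , drop = FALSE])^2)))
    out[i, j] <- out[j, i] <- v
  }
  out
}

#' Build the full knowledgebase from training complexes
#'
#' @inheritParams build_models
#' @param propensity_form passed to [compute_propensities()].
#' @return object of class `knowledgebase`: list with `propensities`,
#'   `frames`, `models`, `params`, `provenance`.
#' @export
build_knowledgebase <- function(training, contact_cutoff = 4.0,
                                binding_cutoff = 4.5,
                                base_atoms = c("residue", "base"),
                                propensity_form = c("ratio", "odds")) {
  base_atoms <- match.arg(base_atoms)
  propensity_form <- match.arg(propensity_form)
  if (length(training) == 0) stop("empty training set")
  prop <- compute_propensities(training, binding_cutoff, propensity_form)
  frames <- compute_reference_frames(training, contact_cutoff, base_atoms)
  models <- build_models(training, frames, contact_cutoff, binding_cutoff,
                         base_atoms)
  structure(list(
    propensities = prop, frames = frames, models = models,
    params = list(contact_cutoff = contact_cutoff,
                  binding_cutoff = binding_cutoff,
                  base_atoms = base_atoms,
                  propensity_form = propensity_form),
    provenance = vapply(training, function(s) s$id, character(1))),
    class = "knowledgebase")
}

#' @export
print.knowledgebase <- function(x, ...) {
  ni <- vapply(x$models, function(m) length(m$instances), integer(1))
  cat("knowledgebase: ", length(x$provenance), " training structure(s), ",
      sum(ni > 0), "/80 non-empty models, ", sum(ni),
      " base instances\n", sep = "")
  invisible(x)
}

KB_FORMAT_VERSION <- "1"

#' Save / load a knowledgebase
#'
#' On disk: `kb.json` (version, parameters, provenance, propensity table,
#' frames) plus `models.tsv` (one row per instance atom: aa, base,
#' instance, atom, x, y, z at fixed 1e-6 precision).  RMSD matrices are
#' recomputed on load.  `save_kb(load_kb(dir))` is byte-identical.
#'
#' @param kb a `knowledgebase`.
#' @param dir directory to write to / read from.
#' @return `save_kb`: `dir` invisibly; `load_kb`: a `knowledgebase`.
#' @export
save_kb <- function(kb, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  frames_json <- lapply(kb$frames, function(f)
    list(atoms = f$atoms,
         counts = as.list(stats::setNames(as.numeric(f$counts),
                                          names(f$counts)))))
  meta <- list(version = KB_FORMAT_VERSION, params = kb$params,
               provenance = as.list(kb$provenance),
               mean_propensity = attr(kb$propensities, "mean_propensity"),
               propensities = kb$propensities[, c("aa", "n_binding",
                                                  "n_total", "propensity")],
               frames = frames_json)
  jsonlite::write_json(meta, file.path(dir, "kb.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  lines <- "aa\tbase\tinstance\tatom\tx\ty\tz"
  for (key in names(kb$models)) {
    m <- kb$models[[key]]
    for (inst in m$instances) {
      at <- inst$atoms
      lines <- c(lines, sprintf("%s\t%s\t%s\t%s\t%.6f\t%.6f\t%.6f",
                                m$aa, m$base, inst$id, rownames(at),
                                at[, 1], at[, 2], at[, 3]))
    }
  }
  writeLines(lines, file.path(dir, "models.tsv"))
  invisible(dir)
}

#' @rdname save_kb
#' @export
load_kb <- function(dir) {
  meta_path <- file.path(dir, "kb.json")
  tsv_path <- file.path(dir, "models.tsv")
  if (!file.exists(meta_path) || !file.exists(tsv_path))
    stop("not a knowledgebase directory: ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(as.character(meta$version), KB_FORMAT_VERSION))
    stop("knowledgebase format version mismatch: found '",
         meta$version, "', expected '", KB_FORMAT_VERSION, "'")
  prop <- as.data.frame(meta$propensities, stringsAsFactors = FALSE)
  attr(prop, "mean_propensity") <- meta$mean_propensity
  attr(prop, "form") <- meta$params$propensity_form
  class(prop) <- c("propensity_table", "data.frame")
  frames <- lapply(meta$frames, function(f)
    list(atoms = unlist(f$atoms),
         counts = unlist(f$counts)))
  frames <- structure(frames[AA3], class = "reference_frames")
  names(frames) <- AA3

  lines <- readLines(tsv_path)
  if (length(lines) < 1 || lines[1] != "aa\tbase\tinstance\tatom\tx\ty\tz")
    stop("parse error in ", tsv_path, " at line 1: bad header")
  models <- list()
  for (aa in AA3) for (b in STANDARD_BASES)
    models[[paste(aa, b, sep = "|")]] <-
      structure(list(aa = aa, base = b, instances = list(), rmsd = NULL),
                class = "geometric_model")
  if (length(lines) > 1) {
    parts <- strsplit(lines[-1], "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 7)
    if (length(bad) > 0)
      stop("parse error in ", tsv_path, " at line ", bad[1] + 1)
    tab <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
    names(tab) <- c("aa", "base", "instance", "atom", "x", "y", "z")
    tab$x <- as.numeric(tab$x); tab$y <- as.numeric(tab$y)
    tab$z <- as.numeric(tab$z)
    if (anyNA(tab$x) || anyNA(tab$y) || anyNA(tab$z))
      stop("parse error in ", tsv_path, ": non-numeric coordinates")
    for (key in unique(paste(tab$aa, tab$base, sep = "|"))) {
      sub <- tab[paste(tab$aa, tab$base, sep = "|") == key, , drop = FALSE]
      for (id in unique(sub$instance)) {
        ss <- sub[sub$instance == id, , drop = FALSE]
        at <- as.matrix(ss[, c("x", "y", "z")])
        rownames(at) <- ss$atom
        colnames(at) <- c("x", "y", "z")
        models[[key]]$instances <- c(
          models[[key]]$instances,
          list(list(id = id, source = sub("\\:.*", "", id),
                    residue_key = NA_character_, base_key = NA_character_,
                    atoms = at)))
      }
    }
  }
  for (key in names(models))
    models[[key]]$rmsd <- pairwise_instance_rmsd(models[[key]])
  structure(list(propensities = prop, frames = frames, models = models,
                 params = meta$params,
                 provenance = unlist(meta$provenance)),
            class = "knowledgebase")
}
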