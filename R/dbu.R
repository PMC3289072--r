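# DNA-binding unit (DBU) discovery: conserved residues are screened for
# surface exposure (RSA > 0.25), clustered spatially at the atom level
# (average linkage, 11 A stop), and the clusters ranked by summed
# DNA-binding propensity against a size x mean-propensity expectation.

#' Surface screen of conserved residues
#'
#' Keeps conserved residues with RSA strictly above `rsa_cutoff`
#' (default 0.25).  RSA is computed internally via [residue_rsa()] unless a
#' precomputed named vector is supplied (e.g. parsed from DSSP output and
#' normalized by the same maxima).
#'
#' @param s a `pdb_structure`.
#' @param conserved character vector of residue keys (`chain:resseq`); every
#'   key must exist in `s`.
#' @param rsa_cutoff strict lower RSA bound (default 0.25).
#' @param rsa optional named RSA vector keyed by residue key.
#' @return character vector of retained residue keys.
#' @export
surface_filter <- function(s, conserved, rsa_cutoff = 0.25, rsa = NULL) {
  rt <- residue_table(s)
  unknown <- setdiff(conserved, rt$reskey)
  if (length(unknown) > 0)
    stop("conserved residues absent from structure: ",
         paste(unknown, collapse = ", "))
  if (is.null(rsa)) rsa <- residue_rsa(s)
  have <- conserved %in% names(rsa)
  if (any(!have))
    warning("RSA unavailable for ", sum(!have), " residue(s); dropped")
  kept <- conserved[have]
  kept[rsa[kept] > rsa_cutoff]
}

#' Atom-level spatial clustering of residues
#'
#' Agglomerative clustering of the residues' atoms (Euclidean metric,
#' average linkage), cut where the next merge would exceed `stop_distance`
#' (default 11 A, about three successive bases along a DNA groove).
#' Residues whose atoms split across clusters are assigned by majority
#' vote; ties go to the cluster holding the residue's CA atom, then to the
#' larger cluster, then to the smaller cluster label.
#'
#' @param s a `pdb_structure`.
#' @param residues character vector of residue keys.
#' @param stop_distance dendrogram cut height in Angstrom.
#' @return list of character vectors of residue keys, ordered by decreasing
#'   cluster size (ties: first residue key).
#' @export
cluster_atoms <- function(s, residues, stop_distance = 11) {
  if (length(residues) == 0) return(list())
  rows <- which(s$atoms$reskey %in% residues)
  if (length(residues) == 1 || length(rows) == 1)
    return(list(sort(unique(residues))))
  xyz <- atom_xyz(s, rows)
  keys <- s$atoms$reskey[rows]
  names_ <- s$atoms$name[rows]
  hc <- stats::hclust(stats::dist(xyz), method = "average")
  lab <- stats::cutree(hc, h = stop_distance)
  sizes <- table(lab)
  assign <- character(length(residues))
  names(assign) <- residues
  for (rk in residues) {
    li <- lab[keys == rk]
    tt <- table(li)
    best <- names(tt)[tt == max(tt)]
    if (length(best) > 1) {
      ca <- li[names_[keys == rk] == "CA"]
      if (length(ca) == 1 && as.character(ca) %in% best) {
        best <- as.character(ca)
      } else {
        sz <- sizes[best]
        best <- best[sz == max(sz)]
        best <- best[order(as.integer(best))][1]
      }
    }
    assign[rk] <- best[1]
  }
  clusters <- split(names(assign), assign)
  clusters <- lapply(clusters, sort)
  ord <- order(-lengths(clusters),
               vapply(clusters, function(x) x[1], character(1)))
  unname(clusters[ord])
}

#' Rank residue clusters into DNA-binding units
#'
#' A cluster's score is the summed DNA-binding propensity of its members;
#' its expectation is `size x mean propensity of the 20 types`.  Only
#' clusters whose score strictly exceeds expectation are accepted, sorted
#' by score descending (ties: larger cluster, then smallest residue key).
#'
#' @param clusters list of residue-key vectors (from [cluster_atoms()]).
#' @param prop a `propensity_table`.
#' @param s the query `pdb_structure` (for residue types and centroids).
#' @return list of `dbu` objects: `list(residues, score, expectation,
#'   size, centroid, rank)`.
#' @export
rank_dbus <- function(clusters, prop, s) {
  if (length(clusters) == 0) return(list())
  rt <- residue_table(s)
  meanp <- attr(prop, "mean_propensity")
  dbus <- lapply(clusters, function(cl) {
    aa <- rt$resname[match(cl, rt$reskey)]
    score <- sum(propensity_of(prop, aa))
    rows <- which(s$atoms$reskey %in% cl)
    structure(list(residues = cl, score = score,
                   expectation = length(cl) * meanp,
                   size = length(cl),
                   centroid = colMeans(atom_xyz(s, rows)),
                   rank = NA_integer_), class = "dbu")
  })
  keep <- vapply(dbus, function(d) d$score > d$expectation, logical(1))
  dbus <- dbus[keep]
  if (length(dbus) == 0) return(list())
  ord <- order(-vapply(dbus, function(d) d$score, numeric(1)),
               -vapply(dbus, function(d) d$size, numeric(1)),
               vapply(dbus, function(d) d$residues[1], character(1)))
  dbus <- dbus[ord]
  for (i in seq_along(dbus)) dbus[[i]]$rank <- i
  dbus
}

#' @export
print.dbu <- function(x, ...) {
  cat(sprintf("DBU (rank %s): %d residues, score %.3f vs expectation %.3f\n",
              ifelse(is.na(x$rank), "?", x$rank), x$size, x$score,
              x$expectation))
  cat("  ", paste(x$residues, collapse = " "), "\n")
  invisible(x)
}

#' Read a conserved-residue list
#'
#' Plain-text stand-in for an external conservation tool: one `chain:resseq`
#' key per line (blank lines and `#` comments ignored).
#'
#' @param path file path.
#' @return character vector of residue keys.
#' @export
read_conserved <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  lines
}
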