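# Shared builders and independent brute-force oracles.  The oracles are
# deliberately naive (double loops, explicit agglomeration, power
# iteration) and never call the code paths they check.

# Build a pdb_structure directly from a minimal atom description.
mk_struct <- function(df, id = "synthetic") {
  defaults <- list(serial = NA_integer_, altloc = " ", icode = " ",
                   occ = 1, element = NA_character_)
  for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  if (anyNA(df$element)) df$element <- substr(df$name, 1, 1)
  df$serial <- seq_len(nrow(df))
  df$kind <- groovepred:::residue_kind(df$resname)
  df$base <- groovepred:::base_letter(df$resname)
  df$reskey <- groovepred:::make_reskey(df$chain, df$resseq, df$icode)
  cols <- c("serial", "name", "altloc", "resname", "chain", "resseq",
            "icode", "x", "y", "z", "occ", "element", "kind", "base",
            "reskey")
  groovepred:::new_structure(df[, cols], id = id)
}

# One atom-row helper.
arow <- function(name, resname, chain, resseq, x, y, z) {
  data.frame(name = name, resname = resname, chain = chain,
             resseq = resseq, x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

# A planted complex with known ground truth.
tiny_complex <- function(seed = 1, n_bp = 16, groove = "major",
                         center_bp = 8, jitter_sd = 0.3,
                         types = c("ARG", "LYS", "ASN")) {
  s <- build_bdna(n_bp)
  plant_dbu(s, dbu_spec(residue_types = types, groove = groove,
                        center_bp = center_bp, jitter_sd = jitter_sd,
                        seed = seed))
}

rigid_pair <- function(seed) {
  set.seed(seed)
  list(rot = random_rotation(), trans = stats::rnorm(3, 0, 15))
}

# ---- brute-force oracles ---------------------------------------------

# all (protein atom, dna residue) pairs with min atom distance < cutoff
bf_contacts <- function(s, cutoff) {
  a <- s$atoms
  prot <- which(a$kind == "protein")
  dna <- which(a$kind == "dna")
  out <- list()
  for (i in prot) {
    for (key in unique(a$reskey[dna])) {
      rows <- dna[a$reskey[dna] == key]
      dmin <- Inf
      for (j in rows) {
        d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                    (a$z[i] - a$z[j])^2)
        if (d < dmin) dmin <- d
      }
      if (dmin < cutoff)
        out[[length(out) + 1]] <- data.frame(
          atom_row = i, dna_key = key, dist = dmin,
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(atom_row = integer(0), dna_key = character(0),
                      dist = numeric(0)))
  do.call(rbind, out)
}

# average-linkage agglomeration on points (rows); returns cluster labels,
# merging in ascending linkage order and stopping once the cheapest merge
# exceeds h.  Lance-Williams update.
bf_average_linkage <- function(pts, h) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  members <- as.list(seq_len(n))
  active <- seq_len(n)
  repeat {
    if (length(active) < 2) break
    best <- c(NA, NA)
    bestv <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      i <- active[ii]; j <- active[jj]
      # average linkage = mean pairwise distance between members
      v <- mean(outer(members[[i]], members[[j]],
                      Vectorize(function(a, b)
                        sqrt(sum((pts[a, ] - pts[b, ])^2)))))
      if (v < bestv) { bestv <- v; best <- c(i, j) }
    }
    if (bestv > h) break
    i <- best[1]; j <- best[2]
    members[[i]] <- c(members[[i]], members[[j]])
    members[j] <- list(integer(0))
    active <- setdiff(active, j)
  }
  lab <- integer(n)
  for (k in seq_along(active)) lab[members[[active[k]]]] <- k
  lab
}

# dominant eigenvector of the covariance by power iteration
bf_principal_direction <- function(pts) {
  x <- sweep(pts, 2, colMeans(pts))
  cv <- crossprod(x) / (nrow(pts) - 1)
  v <- c(1, 1, 1) / sqrt(3)
  for (k in 1:100000) {
    w <- as.numeric(cv %*% v)
    w <- w / sqrt(sum(w^2))
    if (sum((w - v)^2) < 1e-30 || sum((w + v)^2) < 1e-30) break
    v <- w
  }
  w
}

bf_rmsd <- function(a, b) {
  shared <- intersect(rownames(a), rownames(b))
  if (length(shared) < 3) return(Inf)
  tot <- 0
  for (nm in shared) tot <- tot + sum((a[nm, ] - b[nm, ])^2)
  sqrt(tot / length(shared))
}

# Eq.-2-style double sum over DBU residues and their placed atoms
bf_density <- function(x, placements, dbu_residues, aa_of, sigma) {
  n_aa <- table(aa_of[dbu_residues])
  total <- 0
  for (p in placements) {
    w <- 1 / as.numeric(n_aa[[aa_of[[p$residue_key]]]])
    for (r in seq_len(nrow(p$atoms))) {
      d2 <- sum((x - p$atoms[r, ])^2)
      total <- total + w * exp(-d2 / (2 * sigma^2))
    }
  }
  total
}

# same-partition check independent of label numbering
same_partition <- function(l1, l2) {
  identical(as.integer(factor(l1, levels = unique(l1))),
            as.integer(factor(l2, levels = unique(l2))))
}
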