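# Propensities, reference frames, local frames, geometric models and
# knowledgebase serialization.

# ten ARG (three binding), five ALA (none binding), one DG nucleotide
propensity_fixture <- function() {
  rows <- list(arow("N9", "DG", "B", 1, 0, 0, 0))
  for (i in 1:10) {
    d <- if (i <= 3) 3.0 else 30 + i
    rows[[length(rows) + 1]] <- arow("CA", "ARG", "A", i, d, 0, 0)
  }
  for (i in 11:15)
    rows[[length(rows) + 1]] <- arow("CA", "ALA", "A", i, 50 + i, 0, 0)
  mk_struct(do.call(rbind, rows))
}

test_that("propensity is the binding fraction per type", {
  s <- propensity_fixture()
  prop <- compute_propensities(list(s))
  expect_equal(prop$propensity[prop$aa == "ARG"], 0.3)
  expect_equal(prop$propensity[prop$aa == "ALA"], 0)
  expect_equal(prop$n_total[prop$aa == "ARG"], 10L)
  expect_equal(attr(prop, "mean_propensity"), 0.3 / 20)

  # duplicating every training structure leaves the ratios unchanged
  prop2 <- compute_propensities(list(s, s))
  expect_equal(prop2$propensity, prop$propensity)

  # a training set with no DNA contacts: all zero
  far <- mk_struct(rbind(arow("N9", "DG", "B", 1, 0, 0, 0),
                         arow("CA", "ALA", "A", 1, 99, 0, 0)))
  prop0 <- compute_propensities(list(far))
  expect_true(all(prop0$propensity == 0))
  expect_equal(attr(prop0, "mean_propensity"), 0)

  expect_error(compute_propensities(list()), "empty")
})

test_that("reference frames rank atoms by distinct contacted bases", {
  # four isolated single-atom "bases" 7 A apart along x; protein atoms
  # placed so NH1 touches 2 bases, NH2 touches 2, CZ 1, CA none.
  bases <- do.call(rbind, lapply(1:4, function(i)
    arow("N9", "DG", "B", i, (i - 1) * 7, 0, 0)))
  s <- mk_struct(rbind(
    bases,
    arow("NH1", "ARG", "A", 1, 3.5, 1.5, 0),   # ~3.8 from b1 and b2
    arow("NH2", "ARG", "A", 1, 10.5, 1.5, 0),  # ~3.8 from b2 and b3
    arow("CZ", "ARG", "A", 1, 21, 3, 0),       # 3.0 from b4 -> 1 base
    arow("CA", "ARG", "A", 1, 35, 3, 0)))      # none
  fr <- compute_reference_frames(list(s))
  expect_identical(fr$ARG$atoms, c("NH1", "NH2", "CZ"))
  expect_equal(unname(fr$ARG$counts[c("NH1", "NH2", "CZ")]), c(2, 2, 1))
})

test_that("frame ties break lexicographically and sparse types fall back", {
  base <- arow("N9", "DG", "B", 1, 0, 0, 0)
  # NZ and CE each touch the same single base: tie -> CE first (lexicographic)
  s <- mk_struct(rbind(base,
                       arow("NZ", "LYS", "A", 1, 3, 0, 0),
                       arow("CE", "LYS", "A", 1, 0, 3, 0),
                       arow("CD", "LYS", "A", 1, 0, 0, 3),
                       arow("CA", "GLY", "A", 2, 50, 0, 0)))
  fr <- suppressWarnings(compute_reference_frames(list(s)))
  expect_identical(fr$LYS$atoms, c("CD", "CE", "NZ"))
  # glycine never contacts: backbone fallback with a warning
  expect_warning(compute_reference_frames(list(s)), "GLY")
  expect_identical(fr$GLY$atoms, c("CA", "C", "N"))
})

test_that("local_frame produces the canonical form and is rigid", {
  s <- mk_struct(rbind(arow("NH1", "ARG", "A", 1, 1, 2, 3),
                       arow("NH2", "ARG", "A", 1, 2.3, 2, 3),
                       arow("CZ", "ARG", "A", 1, 1.5, 3.1, 3.4),
                       arow("CA", "ARG", "A", 1, 4, 5, 6)))
  fr <- local_frame(s, "A:1", c("NH1", "NH2", "CZ"))
  xyz <- groovepred:::atom_xyz(s)
  loc <- groovepred:::frame_to_local(fr, xyz)
  expect_equal(unname(loc[1, ]), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(loc[2, 2:3]), c(0, 0), tolerance = 1e-12)
  expect_gt(loc[2, 1], 0)
  expect_equal(unname(loc[3, 3]), 0, tolerance = 1e-12)
  expect_gt(loc[3, 2], 0)
  # isometry: all pairwise distances preserved
  expect_equal(as.numeric(dist(loc)), as.numeric(dist(xyz)),
               tolerance = 1e-9)
  # two rigidly related copies give identical local coordinates
  rp <- rigid_pair(4)
  s2 <- groovepred:::transform_structure(s, rp$rot, rp$trans)
  fr2 <- local_frame(s2, "A:1", c("NH1", "NH2", "CZ"))
  loc2 <- groovepred:::frame_to_local(fr2, groovepred:::atom_xyz(s2))
  expect_equal(loc2, loc, tolerance = 1e-6)

  expect_error(local_frame(
    mk_struct(rbind(arow("NH1", "ARG", "A", 1, 0, 0, 0),
                    arow("NH2", "ARG", "A", 1, 1, 0, 0),
                    arow("CZ", "ARG", "A", 1, 2, 1e-5, 0))),
    "A:1", c("NH1", "NH2", "CZ")), "degenerate")
  expect_warning(local_frame(
    mk_struct(arow("NH1", "ARG", "A", 1, 0, 0, 0)),
    "A:1", c("NH1", "NH2", "CZ")), "lacks frame atom")
})

test_that("one contact pair yields one model instance, 79 empty models", {
  s <- mk_struct(rbind(arow("N9", "DG", "B", 1, 0, 0, 0),
                       arow("C8", "DG", "B", 1, 1.3, 0.3, 0),
                       arow("N7", "DG", "B", 1, 2.4, -0.4, 0.2),
                       arow("NH1", "ARG", "A", 1, 0, 3, 0),
                       arow("NH2", "ARG", "A", 1, 1.2, 3.4, 0),
                       arow("CZ", "ARG", "A", 1, 0.5, 3.6, 0.5)))
  fr <- suppressWarnings(compute_reference_frames(list(s)))
  models <- suppressWarnings(build_models(list(s), fr))
  ni <- vapply(models, function(m) length(m$instances), integer(1))
  expect_identical(sum(ni), 1L)
  expect_identical(unname(ni[["ARG|G"]]), 1L)
  inst <- models[["ARG|G"]]$instances[[1]]
  expect_setequal(rownames(inst$atoms), c("N9", "C8", "N7"))
  # all instance atoms lie within contact cutoff + base extent of origin
  expect_lt(max(sqrt(rowSums(inst$atoms^2))), 4 + 15)
})

test_that("models are invariant under rigid motion of the training data", {
  s <- tiny_complex(seed = 6)
  kb1 <- suppressWarnings(build_knowledgebase(list(s)))
  rp <- rigid_pair(7)
  s2 <- groovepred:::transform_structure(s, rp$rot, rp$trans)
  kb2 <- suppressWarnings(build_knowledgebase(list(s2)))
  expect_identical(names(kb1$models), names(kb2$models))
  for (key in names(kb1$models)) {
    i1 <- kb1$models[[key]]$instances
    i2 <- kb2$models[[key]]$instances
    expect_length(i2, length(i1))
    for (k in seq_along(i1))
      expect_equal(i1[[k]]$atoms, i2[[k]]$atoms, tolerance = 1e-6)
  }
})

test_that("instance totals equal the binding-residue/base contact pairs", {
  s <- tiny_complex(seed = 8)
  kb <- suppressWarnings(build_knowledgebase(list(s)))
  ct <- atom_base_contacts(s, 4.0)
  bind <- binding_residues(s, 4.5)
  pairs <- unique(ct[ct$protein_key %in% bind, c("protein_key", "dna_key")])
  ni <- vapply(kb$models, function(m) length(m$instances), integer(1))
  expect_identical(sum(ni), nrow(pairs))
})

test_that("pairwise instance RMSD: identity, translation, brute force", {
  s <- tiny_complex(seed = 12)
  kb <- suppressWarnings(build_knowledgebase(list(s)))
  keys <- names(kb$models)[vapply(kb$models, function(m)
    length(m$instances) > 0, logical(1))]
  m <- kb$models[[keys[1]]]
  expect_equal(diag(m$rmsd), rep(0, length(m$instances)))
  expect_equal(m$rmsd, t(m$rmsd))
  # translation by t gives RMSD |t|
  inst <- m$instances[[1]]
  shifted <- inst
  shifted$atoms <- sweep(inst$atoms, 2, c(1, 2, 2), "+")
  m2 <- list(instances = list(inst, shifted))
  expect_equal(pairwise_instance_rmsd(m2)[1, 2], 3, tolerance = 1e-12)
  # brute force on random instances
  set.seed(31)
  rand_inst <- function(nm) list(atoms = {
    a <- matrix(rnorm(3 * length(nm)), ncol = 3); rownames(a) <- nm; a
  })
  i1 <- rand_inst(c("N1", "C2", "N3", "C4"))
  i2 <- rand_inst(c("C2", "N3", "C4", "C5"))
  m3 <- list(instances = list(i1, i2))
  expect_equal(pairwise_instance_rmsd(m3)[1, 2],
               bf_rmsd(i1$atoms, i2$atoms), tolerance = 1e-12)
  # fewer than 3 shared atoms -> Inf
  i3 <- rand_inst(c("N1", "C2", "XX", "YY"))
  expect_identical(pairwise_instance_rmsd(
    list(instances = list(i2, i3)))[1, 2], Inf)
})

test_that("save/load round-trips the knowledgebase losslessly", {
  s <- tiny_complex(seed = 13)
  kb <- suppressWarnings(build_knowledgebase(list(s)))
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  save_kb(kb, dir1)
  kb2 <- load_kb(dir1)
  save_kb(kb2, dir2)
  expect_identical(readLines(file.path(dir1, "models.tsv")),
                   readLines(file.path(dir2, "models.tsv")))
  expect_equal(kb2$propensities$propensity, kb$propensities$propensity)
  expect_equal(attr(kb2$propensities, "mean_propensity"),
               attr(kb$propensities, "mean_propensity"))
  for (aa in names(kb$frames))
    expect_identical(unname(kb2$frames[[aa]]$atoms),
                     unname(kb$frames[[aa]]$atoms))
  ni <- function(k) vapply(k$models, function(m) length(m$instances),
                           integer(1))
  expect_identical(ni(kb2), ni(kb))
  for (key in names(kb$models)) {
    for (k in seq_along(kb$models[[key]]$instances))
      expect_equal(kb2$models[[key]]$instances[[k]]$atoms,
                   kb$models[[key]]$instances[[k]]$atoms,
                   tolerance = 1e-5)
  }

  # version mismatch is an explicit error
  meta <- jsonlite::read_json(file.path(dir1, "kb.json"))
  meta$version <- "999"
  jsonlite::write_json(meta, file.path(dir1, "kb.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(load_kb(dir1), "version mismatch")

  # truncated models.tsv names the offending line
  save_kb(kb, dir1)
  lines <- readLines(file.path(dir1, "models.tsv"))
  lines[3] <- substr(lines[3], 1, 10)
  writeLines(lines, file.path(dir1, "models.tsv"))
  expect_error(load_kb(dir1), "line 3")
})
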