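# Model placement, density scoring, core exclusion and diversity selection.

# a one-residue/one-base world whose model (ARG, G) has exactly one instance
mini_world <- function() {
  s <- mk_struct(rbind(arow("N9", "DG", "B", 1, 0, 0, 0),
                       arow("C8", "DG", "B", 1, 1.3, 0.3, 0),
                       arow("N7", "DG", "B", 1, 2.4, -0.4, 0.2),
                       arow("NH1", "ARG", "A", 1, 0, 3, 0),
                       arow("NH2", "ARG", "A", 1, 1.2, 3.4, 0),
                       arow("CZ", "ARG", "A", 1, 0.5, 4.2, 0.8),
                       arow("CA", "ARG", "A", 1, 0.8, 5.6, 1.2),
                       arow("C", "ARG", "A", 1, 2.2, 6.1, 1.0),
                       arow("N", "ARG", "A", 1, -0.4, 6.4, 1.4)))
  kb <- suppressWarnings(build_knowledgebase(list(s)))
  dbu <- structure(list(residues = "A:1", centroid = c(0, 3, 0)),
                   class = "dbu")
  list(s = s, kb = kb, dbu = dbu)
}

test_that("place_models maps one instance per training occurrence", {
  w <- mini_world()
  expect_length(place_models(w$dbu, w$s, w$kb, "G"), 1)
  # training the kb on three copies triples the sampling space
  kb3 <- suppressWarnings(build_knowledgebase(list(w$s, w$s, w$s)))
  expect_length(place_models(w$dbu, w$s, kb3, "G"), 3)
  # an empty model contributes nothing, with a warning not an error
  expect_warning(out <- place_models(w$dbu, w$s, w$kb, "T"), "no model")
  expect_length(out, 0)
  # self-training places the base exactly on itself
  pl <- place_models(w$dbu, w$s, w$kb, "G")[[1]]
  a <- w$s$atoms
  orig <- as.matrix(a[a$reskey == "B:1", c("x", "y", "z")])
  rownames(orig) <- a$name[a$reskey == "B:1"]
  expect_equal(pl$atoms[rownames(orig), ], orig, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("placements are rigid-motion equivariant", {
  w <- mini_world()
  rp <- rigid_pair(51)
  s2 <- groovepred:::transform_structure(w$s, rp$rot, rp$trans)
  p1 <- place_models(w$dbu, w$s, w$kb, "G")[[1]]
  p2 <- place_models(w$dbu, s2, w$kb, "G")[[1]]
  moved <- groovepred:::apply_rigid(p1$atoms, rp$rot, rp$trans)
  expect_equal(p2$atoms, moved, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("density has unit kernel peak, decays, and matches brute force", {
  w <- mini_world()
  one_atom <- structure(list(id = "x", base = "G", residue_key = "A:1",
                             atoms = matrix(c(1, 2, 3), 1, 3,
                                            dimnames = list("N9", NULL)),
                             centroid = c(1, 2, 3)),
                        class = "base_placement")
  expect_equal(density_score(c(1, 2, 3), list(one_atom), w$dbu, w$s), 1,
               tolerance = 1e-12)
  expect_lt(density_score(c(100, 100, 100), list(one_atom), w$dbu, w$s),
            1e-10)

  # brute-force double sum on a random cloud routed through two residues
  s2 <- mk_struct(rbind(arow("N9", "DG", "B", 1, 0, 0, 0),
                        arow("CA", "ARG", "A", 1, 3, 0, 0),
                        arow("CA", "ARG", "A", 2, 0, 3, 0),
                        arow("CA", "LYS", "A", 3, 0, 0, 3)))
  dbu2 <- structure(list(residues = c("A:1", "A:2", "A:3")), class = "dbu")
  set.seed(77)
  placements <- lapply(1:6, function(i) {
    rk <- c("A:1", "A:2", "A:3")[(i %% 3) + 1]
    nat <- sample(3:8, 1)
    at <- matrix(rnorm(nat * 3, 0, 6), ncol = 3)
    rownames(at) <- paste0("X", seq_len(nat))
    structure(list(id = paste0("p", i), base = "G", residue_key = rk,
                   atoms = at, centroid = colMeans(at)),
              class = "base_placement")
  })
  aa_of <- c("A:1" = "ARG", "A:2" = "ARG", "A:3" = "LYS")
  for (x in list(c(0, 0, 0), c(2, -3, 1), c(8, 8, -8))) {
    want <- bf_density(x, placements, dbu2$residues, aa_of, 2.0)
    got <- density_score(x, placements, dbu2, s2)
    expect_equal(got, want, tolerance = 1e-9)
  }

  # 1/n_aa normalization: duplicating a residue type leaves that type's
  # total contribution unchanged
  dbu_one <- structure(list(residues = "A:1"), class = "dbu")
  cloud <- placements[[1]]
  d1 <- density_score(c(1, 1, 1), list(cloud), dbu_one, s2)
  cloud_b <- cloud
  cloud_b$residue_key <- "A:2"
  dbu_two <- structure(list(residues = c("A:1", "A:2")), class = "dbu")
  d2 <- density_score(c(1, 1, 1), list(cloud, cloud_b), dbu_two, s2)
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("core_filter orders by burial and stops at the first clash", {
  # protein: a 5 A shell of CA atoms around the origin
  sph <- groovepred:::fibonacci_sphere(40) * 5
  shell <- do.call(rbind, lapply(seq_len(nrow(sph)), function(i)
    arow("CA", "GLY", "P", i, sph[i, 1], sph[i, 2], sph[i, 3])))
  s <- mk_struct(shell)
  mk_pl <- function(id, center) {
    at <- matrix(rep(center, 3), 3, 3, byrow = TRUE) +
      matrix(c(0, 0, 0, 0.5, 0, 0, 0, 0.5, 0), 3, 3, byrow = TRUE)
    rownames(at) <- c("N1", "C2", "N3")
    structure(list(id = id, base = "G", residue_key = "P:1", atoms = at,
                   centroid = colMeans(at)), class = "base_placement")
  }
  inside <- mk_pl("inside", c(0, 0, 0))        # buried at the centre
  outside <- mk_pl("outside", c(25, 0, 0))     # 20 A beyond the surface
  grazing <- mk_pl("grazing", c(6.0, 0, 0))    # ~1 A from the shell -> clash
  kept <- core_filter(list(inside, outside), s)
  expect_identical(vapply(kept, `[[`, "", "id"), c("outside", "inside"))
  expect_gt(kept[[2]]$core_score, kept[[1]]$core_score)

  # the clash terminates the keep-loop permanently
  kept2 <- core_filter(list(inside, grazing, outside), s)
  expect_identical(vapply(kept2, `[[`, "", "id"), "outside")
  # prefix property: the kept set is the ascending-core prefix of the
  # clash-free ordering
  full <- core_filter(list(inside, grazing, outside), s,
                      density_params(clash_distance = 1e-6))
  full_ids <- vapply(full, `[[`, "", "id")
  expect_identical(vapply(kept2, `[[`, "", "id"),
                   full_ids[seq_along(kept2)])
  expect_false(is.unsorted(vapply(full, `[[`, 0, "core_score")))

  # without clashes everything survives
  expect_length(core_filter(list(inside, outside), s), 2)
  expect_error(core_filter(list(inside), mk_struct(
    arow("CB", "GLY", "P", 1, 0, 0, 0))), "no CA")
})

test_that("diverse_select keeps the greedy RMSD > 5 subset", {
  mk_pl <- function(id, shift, dens) {
    at <- matrix(c(0, 0, 0, 1.5, 0, 0, 0, 1.5, 0), 3, 3, byrow = TRUE) +
      matrix(rep(shift, 3), 3, 3, byrow = TRUE)
    rownames(at) <- c("N1", "C2", "N3")
    structure(list(id = id, base = "G", residue_key = "r", atoms = at,
                   centroid = colMeans(at), density = dens),
              class = "base_placement")
  }
  a <- mk_pl("a", c(0, 0, 0), 5)
  dup <- mk_pl("dup", c(0, 0, 0), 4)       # identical -> dropped
  far <- mk_pl("far", c(10, 0, 0), 3)      # 10 A away -> kept
  out <- diverse_select(list(dup, a, far))
  expect_identical(vapply(out, `[[`, "", "id"), c("a", "far"))

  # brute-force greedy oracle on a random set
  set.seed(91)
  pls <- lapply(1:12, function(i)
    mk_pl(sprintf("p%02d", i), rnorm(3, 0, 5), runif(1)))
  got <- vapply(diverse_select(pls), `[[`, "", "id")
  ord <- order(-vapply(pls, `[[`, 0, "density"), seq_along(pls))
  kept <- list()
  for (i in ord) {
    ok <- all(vapply(kept, function(k)
      bf_rmsd(pls[[i]]$atoms, k$atoms) > 5, logical(1)))
    if (ok) kept[[length(kept) + 1]] <- pls[[i]]
  }
  expect_identical(got, vapply(kept, `[[`, "", "id"))
})

test_that("predict_base_location recovers the training geometry", {
  w <- mini_world()
  pred <- predict_base_location(w$dbu, w$s, w$kb, "G")
  expect_identical(pred$status, "ok")
  a <- w$s$atoms
  true_cent <- colMeans(as.matrix(a[a$reskey == "B:1", c("x", "y", "z")]))
  expect_lt(sqrt(sum((pred$placements[[1]]$centroid - true_cent)^2)), 1)

  # rotated copy of the query: location error < 2 A
  rp <- rigid_pair(61)
  s2 <- groovepred:::transform_structure(w$s, rp$rot, rp$trans)
  pred2 <- predict_base_location(w$dbu, s2, w$kb, "G")
  expect_lt(location_error(pred2$placements[[1]], s2), 2)

  # empty models give an explicit empty status
  empty <- suppressWarnings(predict_base_location(w$dbu, w$s, w$kb, "T"))
  expect_identical(empty$status, "empty")
  expect_length(empty$placements, 0)
})

test_that("end-to-end placement is rigid-motion equivariant", {
  s <- tiny_complex(seed = 16)
  kb <- suppressWarnings(build_knowledgebase(list(s)))
  truth <- attr(s, "dbus")[[1]]
  dbu <- structure(list(residues = truth$residues,
                        centroid = truth$groove_point), class = "dbu")
  bases <- names(which(vapply(kb$models, function(m)
    length(m$instances) > 0, logical(1))))
  b <- sub(".*\\|", "", bases[1])
  p1 <- predict_base_location(dbu, s, kb, b)
  rp <- rigid_pair(62)
  s2 <- groovepred:::transform_structure(s, rp$rot, rp$trans)
  dbu2 <- dbu
  dbu2$centroid <- as.numeric(rp$rot %*% dbu$centroid + rp$trans)
  p2 <- predict_base_location(dbu2, s2, kb, b)
  want <- as.numeric(rp$rot %*% p1$placements[[1]]$centroid + rp$trans)
  expect_equal(p2$placements[[1]]$centroid, want, tolerance = 1e-6)
})
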