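# Pharmacophore feature perception.

test_that("benzene yields exactly one aromatic ring centroid", {
  ens <- tiny_ensemble("c1ccccc1")
  fs <- perceive_features(ens)
  expect_equal(fs$points$kind, "ARO_RING")
  ring <- fs$points$source_atoms[[1]]
  expect_length(ring, 6)
  co <- ens$conformers[[1]]$coords
  cen <- colMeans(co[ring, ])
  expect_equal(as.numeric(fs$points[1, c("x", "y", "z")]), cen,
               tolerance = 1e-9)
  d <- sqrt(rowSums(sweep(co[ring, ], 2, cen)^2))
  expect_lt(diff(range(d)), 0.02)  # symmetric within minimization noise
})

test_that("methanol features follow the shipped pattern table", {
  fs <- perceive_features(tiny_ensemble("CO"))
  counts <- table(fs$points$kind)
  expect_equal(counts[["DON"]], 1)
  expect_equal(counts[["ACC"]], 1)
  expect_equal(counts[["PROJ_DON"]], 1)
  expect_equal(counts[["PROJ_ACC"]], 2)  # one per sp3 oxygen lone pair
  ens <- tiny_ensemble("CO")
  co <- ens$conformers[[1]]$coords
  o <- which(ens$elements == "O")
  h <- fs$points$source_atoms[[which(fs$points$kind == "PROJ_DON")]]
  h <- setdiff(h, o)
  pd <- as.numeric(fs$points[fs$points$kind == "PROJ_DON", c("x", "y", "z")])
  expect_equal(sqrt(sum((pd - co[o, ])^2)), 3.0, tolerance = 1e-9)
  along <- (pd - co[o, ]) / 3.0
  u <- (co[h, ] - co[o, ]) / sqrt(sum((co[h, ] - co[o, ])^2))
  expect_equal(along, u, tolerance = 1e-9)
})

test_that("every projected point sits exactly 3 A from its heteroatom", {
  for (smi in c("CO", "CC(=O)N", "c1ccncc1", "CC#N")) {
    ens <- tiny_ensemble(smi)
    fs <- perceive_features(ens)
    proj <- fs$points[fs$points$kind %in% c("PROJ_DON", "PROJ_ACC"), ,
                      drop = FALSE]
    co <- ens$conformers[[1]]$coords
    for (i in seq_len(nrow(proj))) {
      src <- proj$source_atoms[[i]]
      het <- src[ens$elements[src] %in% c("N", "O")][1]
      d <- sqrt(sum((as.numeric(proj[i, c("x", "y", "z")]) - co[het, ])^2))
      expect_equal(d, 3.0, tolerance = 1e-9)
    }
  }
})

test_that("ionized groups map to CAT and ANI features", {
  cat_fs <- perceive_features(tiny_ensemble("C[NH3+]"))
  expect_equal(sum(cat_fs$points$kind == "CAT"), 1)
  ani_fs <- perceive_features(tiny_ensemble("CC(=O)[O-]"))
  expect_equal(sum(ani_fs$points$kind == "ANI"), 1)
  # carboxylate ANI sits at the centroid of the two equivalent oxygens
  ens <- tiny_ensemble("CC(=O)[O-]")
  oxy <- which(ens$elements == "O")
  cen <- colMeans(ens$conformers[[1]]$coords[oxy, ])
  expect_equal(as.numeric(
    ani_fs$points[ani_fs$points$kind == "ANI", c("x", "y", "z")]),
    cen, tolerance = 1e-9)
})

test_that("amide nitrogen is a donor but not an acceptor", {
  fs <- perceive_features(tiny_ensemble("CC(=O)N"))
  ens <- tiny_ensemble("CC(=O)N")
  n_idx <- which(ens$elements == "N")
  acc_src <- unlist(fs$points$source_atoms[fs$points$kind == "ACC"])
  don_src <- unlist(fs$points$source_atoms[fs$points$kind == "DON"])
  expect_false(n_idx %in% acc_src)
  expect_true(n_idx %in% don_src)
})

test_that("aliphatic hydrophobes need three clean carbons", {
  fs <- perceive_features(tiny_ensemble("CCCc1ccccc1"))  # propylbenzene
  expect_equal(sum(fs$points$kind == "HYD"), 1)
  expect_length(fs$points$source_atoms[[which(fs$points$kind == "HYD")]], 3)
  # ethylbenzene: only 2 aliphatic carbons -> no hydrophobe
  fs2 <- perceive_features(tiny_ensemble("CCc1ccccc1"))
  expect_equal(sum(fs2$points$kind == "HYD"), 0)
  # propanol: all three carbons, but C1 touches oxygen -> only 2 clean
  fs3 <- perceive_features(tiny_ensemble("CCCO"))
  expect_equal(sum(fs3$points$kind == "HYD"), 0)
})

test_that("typed matches are identical across conformers of one molecule", {
  ens <- tiny_ensemble("CCCO")
  expect_gte(length(ens$conformers), 2)
  fss <- lapply(seq_along(ens$conformers), function(i)
    perceive_features(ens, i))
  kinds <- lapply(fss, function(f) f$points$kind)
  srcs <- lapply(fss, function(f) f$points$source_atoms)
  for (i in seq_along(fss)[-1]) {
    expect_identical(kinds[[i]], kinds[[1]])
    expect_identical(srcs[[i]], srcs[[1]])
  }
})

test_that("feature distance matrices are exact Euclidean distances", {
  fs <- structure(list(molecule_id = "t", conformer_index = 1L,
                       points = data.frame(kind = c("HYD", "HYD", "ACC"),
                                           x = c(0, 3, 0),
                                           y = c(0, 4, 0),
                                           z = c(0, 0, 1))),
                  class = "FeatureSet")
  m <- feature_distance_matrix(fs, 1:2)
  expect_equal(m, matrix(c(0, 5, 5, 0), 2))
  expect_equal(feature_distance_matrix(fs, 1), matrix(0, 1, 1))
  expect_error(feature_distance_matrix(fs, c(1, 1)), "repeated")
  fx <- make_planted_feature_sets(k = 4, n_molecules = 3, n_noise = 0,
                                  jitter_sd = 0, seed = 3)
  fs1 <- fx$feature_sets[[1]][[1]]
  ord <- order(match(fs1$points$kind, fx$query$kinds))
  m1 <- feature_distance_matrix(fs1)
  expect_equal(sort(m1[upper.tri(m1)]),
               sort(fx$query$distance_matrix[
                 upper.tri(fx$query$distance_matrix)]),
               tolerance = 1e-9)
})
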