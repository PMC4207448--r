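# Query enumeration, subgraph matching, rigid superposition, overlap
# scoring and the elucidation search.

fake_fs <- function(kinds, coords, id = "t", conf = 1L) {
  structure(list(molecule_id = id, conformer_index = conf,
                 points = data.frame(kind = kinds, x = coords[, 1],
                                     y = coords[, 2], z = coords[, 3])),
            class = "FeatureSet")
}

rot_z90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)

test_that("candidate counts follow the subset combinatorics", {
  co4 <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
  fs4 <- fake_fs(c("ARO_RING", "HYD", "PROJ_DON", "PROJ_ACC"), co4)
  expect_length(enumerate_candidate_queries(list(fs4), k = 4), 1)
  set.seed(42)
  co6 <- matrix(runif(18, -6, 6), 6)
  while (min(dist(co6)) < 2) co6 <- matrix(runif(18, -6, 6), 6)
  fs6 <- fake_fs(c("ARO_RING", "HYD", "PROJ_DON", "PROJ_ACC", "DON",
                   "ACC"), co6)
  expect_length(enumerate_candidate_queries(list(fs6), k = 4), 15)
  # a close pair (< 1.5 A) excludes every subset containing both points
  co_close <- rbind(co4, c(0.5, 0, 0))
  fs5 <- fake_fs(c("ARO_RING", "HYD", "PROJ_DON", "PROJ_ACC", "DON"),
                 co_close)
  cands <- enumerate_candidate_queries(list(fs5), k = 4)
  expect_length(cands, 2)  # C(5,4)=5 minus the 3 subsets holding the pair
  expect_warning(enumerate_candidate_queries(list(fs4), k = 5), "fewer")
})

test_that("matching recovers rigid motions and the query's own source", {
  co <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(1, 1, 3))
  kinds <- c("ARO_RING", "HYD", "PROJ_DON", "PROJ_ACC")
  fs <- fake_fs(kinds, co)
  q <- enumerate_candidate_queries(list(fs), k = 4)[[1]]
  self <- match_and_place(q, fs, dist_tol = 1.0)
  expect_lt(self$rmsd, 1e-9)
  moved <- fake_fs(kinds, sweep(co %*% t(rot_z90), 2, c(5, 0, 0), "+"))
  pl <- match_and_place(q, moved, dist_tol = 1.0)
  expect_lt(pl$rmsd, 1e-9)
  # recovered transform inverts the motion
  back <- apply_transform(as.matrix(moved$points[, c("x", "y", "z")]),
                          pl$rotation, pl$translation)
  expect_equal(back, unname(as.matrix(q$coords)), tolerance = 1e-9)
})

test_that("matching equals brute-force minimum over same-kind assignments", {
  fx <- make_planted_feature_sets(k = 4, n_molecules = 2, n_noise = 4,
                                  jitter_sd = 0.2, seed = 8)
  q_fs <- fx$feature_sets[[1]][[1]]
  cands <- enumerate_candidate_queries(list(q_fs), k = 4)
  target <- fx$feature_sets[[2]][[1]]
  f_co <- as.matrix(target$points[, c("x", "y", "z")])
  for (q in cands[seq_len(min(5, length(cands)))]) {
    got <- match_and_place(q, target, dist_tol = 1.5)
    # independent oracle: enumerate every injective same-kind assignment
    # with plain permutation loops and superpose each one
    idx_by_kind <- lapply(q$kinds, function(k)
      which(target$points$kind == k))
    best <- Inf
    grid <- expand.grid(idx_by_kind)
    for (r in seq_len(nrow(grid))) {
      a <- as.integer(grid[r, ])
      if (anyDuplicated(a)) next
      qd <- as.matrix(dist(q$coords))
      fd <- as.matrix(dist(f_co[a, ]))
      if (max(abs(qd - fd)) > 1.5) next
      fit <- superpose(f_co[a, ], q$coords)
      best <- min(best, fit$rmsd)
    }
    if (is.null(got)) {
      expect_identical(best, Inf)
    } else {
      expect_equal(got$rmsd, best, tolerance = 1e-10)
    }
  }
})

test_that("superposition is optimal and recovers known motions", {
  set.seed(7)
  pts <- matrix(rnorm(15), 5)
  expect_lt(superpose(pts, pts)$rmsd, 1e-12)
  R0 <- rot_z90
  tgt <- sweep(pts %*% t(R0), 2, c(1, -2, 3), "+")
  fit <- superpose(pts, tgt)
  expect_equal(fit$rotation, R0, tolerance = 1e-9)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # degenerate input is refused
  line <- cbind(1:4, 2 * (1:4), -(1:4))
  expect_error(superpose(line, line), "collinear")
})

test_that("overlap scoring matches a direct double sum and its limits", {
  m1 <- tiny_ensemble("C")
  al <- list(query = list(label = "xx"),
             placements = list(
               a = list(conformer_index = 1L, rotation = diag(3),
                        translation = c(0, 0, 0), rmsd = 0),
               b = list(conformer_index = 1L, rotation = diag(3),
                        translation = c(0, 0, 0), rmsd = 0)))
  ens2 <- list(a = m1, b = m1)
  s_coincident <- overlap_score(al, ens2)
  # coincident copies score the self-overlap V_AA
  co <- m1$conformers[[1]]$coords
  vaa <- 0
  p <- 2.7; alpha <- 2 * log(2)
  rad <- c(H = 1.20, C = 1.70)
  for (i in seq_len(nrow(co))) for (j in seq_len(nrow(co))) {
    d2 <- sum((co[i, ] - co[j, ])^2)
    vaa <- vaa + p * exp(-alpha * d2 / (rad[[m1$elements[i]]]^2 +
                                          rad[[m1$elements[j]]]^2))
  }
  expect_equal(s_coincident, vaa, tolerance = 1e-10)
  al$placements$b$translation <- c(50, 0, 0)
  expect_lt(overlap_score(al, ens2), 1e-6)
  expect_error(overlap_score(list(placements = al$placements["a"]), ens2),
               "at least 2")
})

test_that("overlap is invariant under a common rigid motion", {
  fx <- make_planted_feature_sets(k = 4, n_molecules = 4, n_noise = 2,
                                  jitter_sd = 0.1, seed = 2)
  al <- elucidate(fx$dataset, fx$ensembles, fx$feature_sets,
                  run_config(dist_tol = 1.5))[[1]]
  s0 <- overlap_score(al, fx$ensembles)
  moved <- al
  for (id in names(moved$placements)) {
    pl <- moved$placements[[id]]
    moved$placements[[id]]$rotation <- rot_z90 %*% pl$rotation
    moved$placements[[id]]$translation <-
      as.numeric(rot_z90 %*% pl$translation) + c(3, -1, 2)
  }
  expect_equal(overlap_score(moved, fx$ensembles), s0, tolerance = 1e-9)
})

test_that("elucidation recovers a noiseless planted arrangement exactly", {
  fx <- make_planted_feature_sets(k = 4, n_molecules = 6, n_noise = 0,
                                  jitter_sd = 0, seed = 1)
  al <- elucidate(fx$dataset, fx$ensembles, fx$feature_sets, run_config())
  expect_lte(length(al), 10)
  top <- al[[1]]
  expect_equal(top$coverage, 1.0)
  expect_true(all(vapply(top$placements, `[[`, numeric(1), "rmsd") < 1e-6))
  qd <- as.matrix(dist(top$query$coords))
  pd <- fx$query$distance_matrix
  expect_equal(sort(qd[upper.tri(qd)]), sort(pd[upper.tri(pd)]),
               tolerance = 1e-6)
})

test_that("a molecule lacking the arrangement blocks full-coverage queries", {
  fx <- make_planted_feature_sets(k = 4, n_molecules = 5, n_noise = 0,
                                  jitter_sd = 0, seed = 4)
  # replace one molecule's features by far-away decoys of other kinds
  id <- names(fx$feature_sets)[5]
  pts <- fx$feature_sets[[id]][[1]]$points
  pts$kind <- rep("ANI", nrow(pts))
  fx$feature_sets[[id]][[1]]$points <- pts
  expect_error(
    elucidate(fx$dataset, fx$ensembles, fx$feature_sets,
              run_config(min_coverage = 1.0)),
    "lower k|covered")
})
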