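# Synthetic ground-truth fixtures: (i) labeled 3D feature point sets with a
# planted common pharmacophore, used to test elucidation and alignment in
# isolation, and (ii) a small congeneric molecule series whose activities
# are generated from a known linear function of designated field columns,
# used to test end-to-end signal recovery.

# Uniform random rotation matrix (via normalized quaternion).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

#' Planted-pharmacophore feature sets
#'
#' Plants one k-point typed arrangement (points mutually >= 2 Angstrom
#' apart), copies it into `n_molecules` "molecules" under random rigid
#' motions plus optional Gaussian jitter, and adds `n_noise` decoy features
#' per molecule, uniform in a 12 Angstrom box but at least 1.5 Angstrom from
#' every planted point.  Everything is deterministic given `seed`.
#'
#' @param k Number of planted points (3..7).
#' @param n_molecules Number of synthetic molecules.
#' @param n_noise Decoy features per molecule.
#' @param jitter_sd Per-coordinate Gaussian jitter of the planted points,
#'   Angstrom.
#' @param seed Integer seed.
#' @return List with `query` (planted `kinds`, `coords`,
#'   `distance_matrix`), `feature_sets` (named list: one single-conformer
#'   `FeatureSet` list per molecule), `ensembles` (pseudo-atom ensembles,
#'   one carbon-like atom per feature point, so overlap scoring and field
#'   computation work), `dataset` (a `Dataset` with synthetic activities in
#'   descending input order) and `seed`.
#' @export
make_planted_feature_sets <- function(k = 4, n_molecules = 6, n_noise = 0,
                                      jitter_sd = 0, seed = 1) {
  stopifnot(k >= 3, k <= 7, jitter_sd >= 0, n_molecules >= 2)
  set.seed(seed)
  kinds_pool <- c("ARO_RING", "HYD", "PROJ_DON", "PROJ_ACC")
  planted_kinds <- sample(kinds_pool, k, replace = TRUE)
  planted <- matrix(NA_real_, k, 3)
  planted[1, ] <- c(0, 0, 0)
  for (i in 2:k) {
    for (try in 1:2000) {
      p <- stats::runif(3, -4, 4)
      d <- sqrt(rowSums(sweep(planted[seq_len(i - 1), , drop = FALSE],
                              2, p)^2))
      if (all(d >= 2)) {
        planted[i, ] <- p
        break
      }
    }
    if (anyNA(planted[i, ])) {
      stop("could not place planted points >= 2 Angstrom apart")
    }
  }
  feature_sets <- list()
  ensembles <- list()
  records <- list()
  for (m in seq_len(n_molecules)) {
    id <- sprintf("mol%02d", m)
    R <- random_rotation()
    tr <- stats::runif(3, -5, 5)
    pts <- sweep(planted %*% t(R), 2, tr, "+")
    if (jitter_sd > 0) {
      pts <- pts + matrix(stats::rnorm(3 * k, 0, jitter_sd), k, 3)
    }
    kinds <- planted_kinds
    if (n_noise > 0) {
      decoys <- matrix(NA_real_, n_noise, 3)
      for (j in seq_len(n_noise)) {
        for (try in 1:2000) {
          p <- stats::runif(3, -6, 6) + tr
          d <- sqrt(rowSums(sweep(pts, 2, p)^2))
          if (all(d >= 1.5)) {
            decoys[j, ] <- p
            break
          }
        }
      }
      if (anyNA(decoys)) stop("could not place decoy features")
      pts <- rbind(pts, decoys)
      kinds <- c(kinds, sample(kinds_pool, n_noise, replace = TRUE))
    }
    points <- data.frame(kind = kinds, x = pts[, 1], y = pts[, 2],
                         z = pts[, 3])
    points$source_atoms <- as.list(seq_len(nrow(points)))
    ord <- order(kind_rank(points$kind), seq_len(nrow(points)))
    points <- points[ord, , drop = FALSE]
    rownames(points) <- NULL
    fs <- structure(list(molecule_id = id, conformer_index = 1L,
                         points = points),
                    class = "FeatureSet")
    feature_sets[[id]] <- list(fs)
    ensembles[[id]] <- structure(
      list(molecule_id = id,
           elements = rep("C", nrow(points)),
           sybyl = rep("C.3", nrow(points)),
           formal_charges = integer(nrow(points)),
           charges = numeric(nrow(points)),
           bonds = data.frame(origin = integer(0), target = integer(0),
                              order = integer(0), aromatic = logical(0)),
           hyb = rep(3L, nrow(points)),
           conformers = list(list(
             coords = as.matrix(points[, c("x", "y", "z")]),
             strain_energy = 0))),
      class = "ConformerEnsemble")
    records[[m]] <- list(id = id, smiles = NA_character_,
                         pIC50 = n_molecules - m + 1, is_active = TRUE,
                         role = "train")
  }
  list(query = list(kinds = planted_kinds, coords = planted,
                    distance_matrix = as.matrix(stats::dist(planted))),
       feature_sets = feature_sets,
       ensembles = ensembles,
       dataset = structure(list(records = records,
                                provenance = "planted fixture"),
                           class = "Dataset"),
       seed = seed)
}

# Fixed congeneric series: a rigid naphthol scaffold substituted at three
# spatially separated ring positions.  The scaffold (hydroxyl + two
# aromatic rings) supplies the common pharmacophore; the three sites vary
# independently under a Latin-square-style balanced design, so the field
# matrix carries three distinguishable regional signals.
.series_sites <- list(
  x = c("", "F", "Cl", "C", "OC"),
  y = c("", "C", "CC", "C(C)C", "Br"),
  z = c("", "F", "C#N", "N", "O"))

series_smiles <- function(n) {
  wrap <- function(s) if (s == "") "" else paste0("(", s, ")")
  vapply(seq_len(n) - 1L, function(i) {
    xi <- i %% 5L; yi <- (i + i %/% 5L) %% 5L; zi <- (i + 2L * (i %/% 5L)) %% 5L
    t <- "Oc1cc(X)c2cc(Y)cc(Z)c2c1"
    t <- sub("(X)", wrap(.series_sites$x[xi + 1]), t, fixed = TRUE)
    t <- sub("(Y)", wrap(.series_sites$y[yi + 1]), t, fixed = TRUE)
    sub("(Z)", wrap(.series_sites$z[zi + 1]), t, fixed = TRUE)
  }, character(1))
}

#' Congeneric molecule series with planted field-linear activities
#'
#' Emits a SMILES file and an activities CSV for `n` rigid congeneric
#' molecules (6-substituted 2-naphthols).  Activities are
#' `y = b0 + sum_j b_j z_j + eps`, where `z_j` are standardized values of
#' three designated field columns computed by running the pipeline's own
#' alignment + field stages on the series (with the conformer seed in
#' `config`), and `eps ~ N(0, noise_sd^2)` drawn under `seed`.  Roles are a
#' seeded 80/20 train/test split.  A JSON manifest stores everything needed
#' to verify recovery.
#'
#' @param n Number of molecules (>= 12; the substituent list recycles past
#'   20).
#' @param noise_sd Activity noise standard deviation in pIC50 units
#'   (default 0.1).
#' @param seed Seed for the noise draw and the role split.
#' @param dir Output directory (created if needed).
#' @param config A [run_config()]; its `seed` fixes the conformer stage.
#' @param internals Result of [series_internals()] for this `n`/`config`,
#'   to avoid recomputing the alignment and fields; computed when `NULL`.
#' @return Invisibly, a list with `path_structures`, `path_activities`,
#'   `path_manifest`, `manifest` and `internals`.
#' @export
make_congeneric_series <- function(n = 20, noise_sd = 0.1, seed = 1,
                                   dir = tempfile("series"),
                                   config = run_config(),
                                   internals = NULL) {
  stopifnot(n >= 12)
  if (is.null(internals)) internals <- series_internals(n, config)
  Z <- internals$designated_z
  beta <- .series_beta
  b0 <- 7.0
  set.seed(seed)
  eps <- stats::rnorm(n, 0, noise_sd)
  y <- b0 + as.numeric(Z %*% beta) + eps
  n_test <- max(1L, round(0.2 * n))
  test_idx <- sort(sample(n, n_test))
  roles <- rep("train", n)
  roles[test_idx] <- "test"
  ids <- internals$ids
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path_structures <- file.path(dir, "molecules.smi")
  writeLines(paste(internals$smiles, ids, sep = "\t"), path_structures)
  path_activities <- file.path(dir, "activities.csv")
  utils::write.csv(data.frame(id = ids, pIC50 = round(y, 6), active = TRUE,
                              role = roles),
                   path_activities, row.names = FALSE, quote = FALSE)
  manifest <- list(n = n, noise_sd = noise_sd, seed = seed,
                   conformer_seed = config$seed,
                   b0 = b0, beta = beta,
                   designated_columns = internals$designated_columns,
                   designated_means = internals$designated_means,
                   designated_sds = internals$designated_sds,
                   query_label = internals$alignment$query$label,
                   roles = roles, ids = ids)
  path_manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path_manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(path_structures = path_structures,
                 path_activities = path_activities,
                 path_manifest = path_manifest,
                 manifest = manifest, internals = internals))
}

# Fixed truth coefficients of the series, applied to standardized
# designated columns (pIC50 units per SD of the column).
.series_beta <- c(1.0, -0.8, 0.6)

# Choose three designated truth columns of a field matrix X.
#
# A CoMFA-style field matrix is strongly collinear (neighbouring grid
# points see the same substituents), so an arbitrary column is not
# individually attributable: a coefficient planted on it partly lands on
# correlated neighbours.  The generator therefore plants its truth on a
# *self-identifying triple*: a set of three columns such that a PLS fit of
# the noiseless response built on exactly those columns ranks exactly those
# columns as its three largest standardized coefficients — the operational
# definition of a recoverable planted signal.  The triple is found by
# fixed-point iteration of that probe from seeded starts, restricted to
# columns whose variation is spread over the series (>= 40% of molecules
# with |z| > 0.5, no molecule beyond 3 SD), and accepted only when stable
# across 3, 6 and 10 probe components.  Deterministic for a given X.
select_designated_columns <- function(X, n, beta = .series_beta) {
  Z <- scale(X)
  sds <- apply(X, 2, stats::sd)
  spread <- apply(Z, 2, function(z) sum(abs(z) > 0.5))
  peak <- apply(abs(Z), 2, max)
  okcol <- spread >= max(6, round(0.4 * n)) & peak <= 3
  base <- which(okcol)
  if (length(base) < 3) stop("too few informative field columns")
  top3 <- function(ch, noc) {
    y <- as.numeric(Z[, ch, drop = FALSE] %*% beta[seq_along(ch)])
    fit <- suppressWarnings(fit_pls(X, y, noc))
    order(-abs(fit$coefficients) * sds)[1:3]
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(99L)
  starts <- lapply(seq_len(24), function(k) sample(base, 3))
  for (st in starts) {
    ch <- st
    for (it in seq_len(15)) {
      t3 <- top3(ch, 6)
      if (!all(okcol[t3])) break
      if (setequal(t3, ch)) {
        if (setequal(top3(ch, 3), ch) && setequal(top3(ch, 10), ch)) {
          return(sort(ch))
        }
        break
      }
      ch <- t3
    }
  }
  stop("could not find a self-identifying designated column triple")
}

#' Standardized coefficient effects of a fitted model
#'
#' `|beta_j| * sd(x_j)`: the magnitude of each field column's contribution
#' to the predicted activity, in pIC50 units per standard deviation of the
#' column over the training molecules.  This is the scale-free ranking used
#' to read a coefficient map and to check recovery of planted signals.
#'
#' @param model An `AutoGPAModel` with its training `field` attached.
#' @return Named numeric vector over design-matrix columns, same order as
#'   the coefficient vector.
#' @export
coefficient_effects <- function(model) {
  X <- field_design_matrix(model$field)
  stats::setNames(abs(model$pls$coefficients) * apply(X, 2, stats::sd),
                  colnames(X))
}

#' Check recovery of designated truth columns in a trained model
#'
#' A grid column's linear index is only meaningful relative to the overlay
#' frame of its own alignment: two alignments of the same molecules that
#' differ by a rigid motion carry the same physical grid columns under
#' different indices.  Recovery is therefore checked frame-independently,
#' by value pattern: the model's `n_top` largest-effect columns (see
#' [coefficient_effects()]) must admit a perfect one-to-one matching with
#' the designated truth columns in which matched pairs correlate (in
#' absolute value, across the model's training molecules) at least
#' `min_cor`.  Identical physical columns correlate > 0.999 in practice
#' while distinct columns of this series stay below ~0.99.
#'
#' @param model An `AutoGPAModel` with its training `field`.
#' @param designated_z Matrix of standardized truth-column values, one row
#'   per series molecule (the generator's `designated_z`).
#' @param ids Molecule ids corresponding to the rows of `designated_z`.
#' @param n_top How many top-effect columns to inspect (default 3).
#' @param min_cor Correlation threshold identifying "the same column".
#' @return Number of designated columns recovered (0..ncol(designated_z));
#'   equals `ncol(designated_z)` iff a full matching exists.
#' @export
designated_recovery <- function(model, designated_z, ids, n_top = 3,
                                min_cor = 0.995) {
  X <- field_design_matrix(model$field)
  Zd <- designated_z[match(model$field$molecule_ids, ids), , drop = FALSE]
  eff <- abs(model$pls$coefficients) * apply(X, 2, stats::sd)
  top <- order(-eff)[seq_len(min(n_top, ncol(X)))]
  C <- abs(stats::cor(X[, top, drop = FALSE], Zd))
  k <- ncol(Zd)
  best <- 0L
  for (perm in all_permutations(seq_len(min(length(top), k)))) {
    hit <- sum(vapply(seq_along(perm), function(j)
      C[perm[j], j] >= min_cor, logical(1)))
    best <- max(best, hit)
  }
  best
}

all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_permutations(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

#' Alignment and field internals of the congeneric series
#'
#' Runs conformer generation, feature perception, elucidation and field
#' computation for the fixed series (these depend only on `n` and the
#' config, not on activities or the noise seed), and selects the three
#' designated truth columns as a self-identifying triple (see
#' [coefficient_effects()] and the package vignette): columns with
#' series-wide variation on which a planted linear signal provably
#' concentrates its own top-3 standardized coefficients.
#'
#' @param n Number of molecules.
#' @param config A [run_config()].
#' @return List with `ids`, `smiles`, `ensembles`, `feature_sets`,
#'   `alignment`, `field` (filtered `FieldMatrix` over all n molecules),
#'   `X`, `designated_columns` (column names), `designated_z`
#'   (standardized n x 3 truth matrix), `designated_means`,
#'   `designated_sds`.
#' @export
series_internals <- function(n = 20, config = run_config()) {
  smiles <- series_smiles(n)
  ids <- sprintf("cmpd%02d", seq_len(n))
  records <- lapply(seq_len(n), function(i)
    list(id = ids[i], smiles = smiles[i], pIC50 = 0, is_active = TRUE,
         role = "train"))
  dataset <- structure(list(records = records, provenance = "series"),
                       class = "Dataset")
  ensembles <- generate_ensembles(dataset, config)
  feature_sets <- perceive_all_features(ensembles)
  alignments <- elucidate(dataset, ensembles, feature_sets, config)
  # require full coverage so that the truth is defined for every molecule
  full <- Filter(function(a) a$coverage >= 1 - 1e-9, alignments)
  alignment <- if (length(full) > 0) full[[1]] else alignments[[1]]
  fm <- compute_field_matrix(alignment, ensembles,
                             probe = probe_params(config$probe_charge),
                             steric_cutoff = config$steric_cutoff,
                             spacing = config$spacing,
                             padding = config$padding)
  fm <- filter_columns(fm, min_sd = config$min_sd)
  X <- field_design_matrix(fm)
  X <- X[match(ids, fm$molecule_ids), , drop = FALSE]
  chosen <- select_designated_columns(X, n, beta = .series_beta)
  mu <- colMeans(X[, chosen, drop = FALSE])
  sd3 <- apply(X[, chosen, drop = FALSE], 2, stats::sd)
  Z <- sweep(sweep(X[, chosen, drop = FALSE], 2, mu), 2, sd3, "/")
  list(ids = ids, smiles = smiles, ensembles = ensembles,
       feature_sets = feature_sets, alignment = alignment, field = fm,
       X = X, designated_columns = colnames(X)[chosen],
       designated_z = Z, designated_means = mu, designated_sds = sd3)
}
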