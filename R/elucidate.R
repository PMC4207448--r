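# Common-pharmacophore search and alignment: enumerate candidate queries
# from reference molecules, match them against every training molecule's
# conformer feature sets, superpose matching conformers, and score the
# resulting overlays by Gaussian atomic volume overlap.

# Canonical single-letter codes for feature kinds, in canonical sort order.
.kind_order <- c(ARO_RING = "R", HYD = "H", PROJ_DON = "d", PROJ_ACC = "a",
                 DON = "D", ACC = "A", CAT = "C", ANI = "N")

kind_rank <- function(kind) match(kind, names(.kind_order))

query_label <- function(kinds) {
  paste(.kind_order[kinds[order(kind_rank(kinds))]], collapse = "")
}

# Kabsch core: optimal proper rotation + translation of `moving` onto
# `target`; no degeneracy checks (see superpose() for the user-facing
# contract).
kabsch <- function(moving, target) {
  cm <- colMeans(moving); ct <- colMeans(target)
  A <- sweep(moving, 2, cm); B <- sweep(target, 2, ct)
  H <- t(A) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  list(rotation = R, translation = as.numeric(ct - R %*% cm), rmsd = rmsd)
}

best_fit_rmsd <- function(a, b) kabsch(a, b)$rmsd

apply_transform <- function(coords, rotation, translation) {
  sweep(coords %*% t(rotation), 2, translation, "+")
}

#' Least-squares rigid superposition of two point sets
#'
#' Finds the proper rotation (no reflection) and translation minimizing the
#' sum of squared distances between corresponding points (Kabsch algorithm).
#'
#' @param moving,target Numeric n x 3 matrices, n >= 3, not collinear.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3)
#'   and `rmsd` (Angstrom).  `rotation %*% m + translation` maps moving
#'   points onto the target frame.
#' @export
superpose <- function(moving, target) {
  moving <- as.matrix(moving); target <- as.matrix(target)
  if (!all(dim(moving) == dim(target)) || ncol(moving) != 3) {
    stop("point sets must be equal-size n x 3 matrices")
  }
  if (nrow(moving) < 3) stop("at least 3 points are required")
  for (m in list(moving, target)) {
    sv <- svd(sweep(m, 2, colMeans(m)))$d
    if (sv[2] < 1e-8 * max(sv[1], 1)) {
      stop("degenerate (collinear) point set")
    }
  }
  kabsch(moving, target)
}

#' Enumerate candidate pharmacophore queries from a reference molecule
#'
#' All k-point subsets of every conformer's feature set become candidate
#' queries, excluding subsets with any inter-point distance below 1.5
#' Angstrom, then deduplicated: two candidates with the same kind multiset
#' whose sorted-correspondence distance matrices deviate by less than
#' `dedup_tol` anywhere collapse to the first.
#'
#' @param feature_sets List of `FeatureSet` (all conformers of the reference
#'   molecule).
#' @param k Query size, 3..7 (default 4).
#' @param dedup_tol Deduplication tolerance in Angstrom (default 0.5).
#' @param min_sep Minimum inter-point distance (default 1.5).
#' @return List of `PharmacophoreQuery`: lists with `kinds`, `coords`,
#'   `label`, `source` (molecule_id, conformer_index, feature indices).
#' @export
enumerate_candidate_queries <- function(feature_sets, k = 4, dedup_tol = 0.5,
                                        min_sep = 1.5) {
  stopifnot(k >= 3, k <= 7)
  out <- list()
  for (fs in feature_sets) {
    n <- nrow(fs$points)
    if (is.null(n) || n < k) next
    combs <- utils::combn(n, k)
    for (ci in seq_len(ncol(combs))) {
      idx <- combs[, ci]
      co <- as.matrix(fs$points[idx, c("x", "y", "z")])
      dm <- as.matrix(stats::dist(co))
      if (min(dm[upper.tri(dm)]) < min_sep) next
      kinds <- fs$points$kind[idx]
      ord <- order(kind_rank(kinds), idx)
      cand <- list(kinds = kinds[ord], coords = co[ord, , drop = FALSE],
                   label = query_label(kinds),
                   tolerance = NA_real_,
                   source = list(molecule_id = fs$molecule_id,
                                 conformer_index = fs$conformer_index,
                                 feature_indices = idx[ord]))
      dup <- FALSE
      for (prev in out) {
        if (!identical(paste(prev$kinds, collapse = ""),
                       paste(cand$kinds, collapse = ""))) next
        if (queries_equivalent(prev, cand, dedup_tol)) {
          dup <- TRUE
          break
        }
      }
      if (!dup) out[[length(out) + 1L]] <- cand
    }
  }
  if (length(out) == 0) {
    warning("reference molecule has fewer than k features in every conformer")
  }
  out
}

# Two same-kind-multiset queries are equivalent if some kind-preserving
# correspondence makes their distance matrices agree within tol everywhere.
queries_equivalent <- function(q1, q2, tol) {
  m <- match_assignments(q1$kinds, q1$coords, q2$kinds, q2$coords, tol)
  length(m) > 0
}

# Enumerate kind-preserving injective assignments of query points to
# features whose pairwise distances agree entrywise within tol.  Returns a
# list of integer vectors (feature index per query point); search is
# depth-first with distance pruning.
match_assignments <- function(q_kinds, q_coords, f_kinds, f_coords, tol,
                              max_assignments = Inf) {
  k <- length(q_kinds)
  qd <- as.matrix(stats::dist(q_coords))
  fd <- as.matrix(stats::dist(f_coords))
  domains <- lapply(q_kinds, function(kk) which(f_kinds == kk))
  if (any(lengths(domains) == 0)) return(list())
  res <- list()
  assign_rec <- function(pos, chosen) {
    if (length(res) >= max_assignments) return()
    if (pos > k) {
      res[[length(res) + 1L]] <<- chosen
      return()
    }
    for (f in domains[[pos]]) {
      if (f %in% chosen) next
      ok <- TRUE
      if (pos > 1) {
        for (p in seq_len(pos - 1)) {
          if (abs(qd[pos, p] - fd[f, chosen[p]]) > tol) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) assign_rec(pos + 1, c(chosen, f))
    }
  }
  assign_rec(1L, integer(0))
  res
}

#' Match a pharmacophore query against one conformer's feature set
#'
#' Searches for an injective assignment of query points to same-kind
#' features whose inter-feature distance matrix deviates from the query's by
#' at most `dist_tol` entrywise, then rigidly superposes the matched
#' features onto the query.  Among multiple consistent assignments the
#' minimum-RMSD one wins; ties break on lowest feature indices.
#'
#' @param query A `PharmacophoreQuery`.
#' @param fs A `FeatureSet`.
#' @param dist_tol Entrywise distance-matrix tolerance in Angstrom
#'   (default 1.0).
#' @return `NULL` if no assignment exists, else a placement: list with
#'   `conformer_index`, `rotation`, `translation` (conformer frame onto the
#'   query frame), `rmsd`, `feature_indices`.
#' @export
match_and_place <- function(query, fs, dist_tol = 1.0) {
  if (is.null(fs$points) || nrow(fs$points) < length(query$kinds)) {
    return(NULL)
  }
  f_co <- as.matrix(fs$points[, c("x", "y", "z")])
  asg <- match_assignments(query$kinds, query$coords, fs$points$kind, f_co,
                           dist_tol)
  if (length(asg) == 0) return(NULL)
  best <- NULL
  for (a in asg) {
    fit <- kabsch(f_co[a, , drop = FALSE], query$coords)
    if (is.null(best) || fit$rmsd < best$rmsd - 1e-12 ||
        (abs(fit$rmsd - best$rmsd) <= 1e-12 &&
         paste(a, collapse = ",") < paste(best$feature_indices,
                                          collapse = ","))) {
      best <- list(conformer_index = fs$conformer_index,
                   rotation = fit$rotation, translation = fit$translation,
                   rmsd = fit$rmsd, feature_indices = a)
    }
  }
  best
}

# Element van der Waals radii (Angstrom) for the Gaussian overlap volume.
.overlap_radius <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                     P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)

# Gaussian volume overlap between two placed molecules:
# V_AB = sum_ij p * exp(-alpha * d_ij^2 / (r_i^2 + r_j^2)),
# p = 2.7, alpha = 2 ln 2.
gaussian_overlap_pair <- function(coords_a, elem_a, coords_b, elem_b,
                                  p = 2.7, alpha = 2 * log(2)) {
  ra <- .overlap_radius[elem_a]; rb <- .overlap_radius[elem_b]
  ra[is.na(ra)] <- 1.7; rb[is.na(rb)] <- 1.7
  d2 <- outer(rowSums(coords_a^2), rowSums(coords_b^2), "+") -
    2 * coords_a %*% t(coords_b)
  d2[d2 < 0] <- 0
  denom <- outer(ra^2, rb^2, "+")
  sum(p * exp(-alpha * d2 / denom))
}

#' Atomic overlap score of an alignment
#'
#' Mean over unordered molecule pairs of the Gaussian atomic volume overlap
#' of the placed conformers.  Higher means a tighter overlay; the score is
#' invariant under a common rigid motion of all placed molecules.
#'
#' @param alignment An `Alignment` (see [elucidate()]).
#' @param ensembles Named list of `ConformerEnsemble`.
#' @return A single numeric score.
#' @export
overlap_score <- function(alignment, ensembles) {
  ids <- names(alignment$placements)
  if (length(ids) < 2) stop("need at least 2 placed molecules")
  placed <- lapply(ids, function(id) {
    pl <- alignment$placements[[id]]
    ens <- ensembles[[id]]
    co <- apply_transform(ens$conformers[[pl$conformer_index]]$coords,
                          pl$rotation, pl$translation)
    list(coords = co, elements = ens$elements)
  })
  total <- 0
  npair <- 0L
  for (i in seq_along(placed)) {
    for (j in seq_along(placed)) {
      if (j <= i) next
      total <- total + gaussian_overlap_pair(placed[[i]]$coords,
                                             placed[[i]]$elements,
                                             placed[[j]]$coords,
                                             placed[[j]]$elements)
      npair <- npair + 1L
    }
  }
  total / npair
}

#' Search for common pharmacophore queries and rank alignments
#'
#' Candidate queries are enumerated from the most active reference
#' molecules; each candidate is matched against every training molecule's
#' conformers (keeping the lowest-RMSD conformer per molecule), candidates
#' covering too few molecules are discarded, candidates matching too many
#' inactives are demoted, and survivors are ranked by atomic overlap score.
#'
#' @param dataset A `Dataset`.
#' @param ensembles Named list of `ConformerEnsemble` (training molecules).
#' @param feature_sets Named list (by molecule id) of lists of `FeatureSet`
#'   (one per conformer).
#' @param config A [run_config()]; uses `k`, `dist_tol`, `min_coverage`,
#'   `max_queries`, `n_reference`, `max_inactive_frac`, `dedup_tol`.
#' @return List of `Alignment`s sorted by decreasing overlap score, at most
#'   `config$max_queries` long.  Each has `query`, `placements` (per placed
#'   molecule id), `coverage`, `overlap` and `penalized`.
#' @export
elucidate <- function(dataset, ensembles, feature_sets,
                      config = run_config()) {
  train <- Filter(function(r) r$role == "train", dataset$records)
  train_ids <- vapply(train, `[[`, character(1), "id")
  act <- vapply(train, `[[`, numeric(1), "pIC50")
  has_flags <- all(vapply(train, function(r) !is.null(r$is_active),
                          logical(1))) &&
    any(vapply(train, function(r) isTRUE(!r$is_active), logical(1)))
  active_ids <- if (has_flags) {
    train_ids[vapply(train, function(r) isTRUE(r$is_active), logical(1))]
  } else {
    train_ids
  }
  inactive_ids <- setdiff(train_ids, active_ids)
  refs <- train_ids[order(-act)][seq_len(min(config$n_reference,
                                             length(train_ids)))]
  candidates <- list()
  for (rid in refs) {
    cands <- suppressWarnings(
      enumerate_candidate_queries(feature_sets[[rid]], k = config$k,
                                  dedup_tol = config$dedup_tol))
    candidates <- c(candidates, cands)
  }
  if (length(candidates) == 0) {
    stop("no candidate queries could be enumerated; lower k or check features")
  }
  alignments <- list()
  n_active <- length(active_ids)
  for (cand in candidates) {
    cand$tolerance <- config$dist_tol
    placements <- list()
    n_fail_active <- 0L
    feasible <- TRUE
    for (id in train_ids) {
      best <- NULL
      for (fs in feature_sets[[id]]) {
        pl <- match_and_place(cand, fs, dist_tol = config$dist_tol)
        if (!is.null(pl) && (is.null(best) || pl$rmsd < best$rmsd)) {
          best <- pl
        }
      }
      if (!is.null(best)) {
        placements[[id]] <- best
      } else if (id %in% active_ids) {
        n_fail_active <- n_fail_active + 1L
        if ((n_active - n_fail_active) / n_active <
            config$min_coverage - 1e-9) {
          feasible <- FALSE
          break
        }
      }
    }
    if (!feasible) next
    cov_active <- sum(names(placements) %in% active_ids) / n_active
    if (cov_active < config$min_coverage - 1e-9) next
    if (length(placements) < 2) next
    penal <- FALSE
    if (length(inactive_ids) > 0) {
      frac_inact <- sum(names(placements) %in% inactive_ids) /
        length(inactive_ids)
      penal <- frac_inact > config$max_inactive_frac
    }
    al <- list(query = cand, placements = placements,
               coverage = length(placements) / length(train_ids),
               penalized = penal)
    al$overlap <- overlap_score(al, ensembles)
    alignments[[length(alignments) + 1L]] <- al
  }
  if (length(alignments) == 0) {
    stop("no pharmacophore query covered enough training molecules; ",
         "lower k or raise dist_tol")
  }
  score <- vapply(alignments, function(a)
    a$overlap - if (a$penalized) 1e6 else 0, numeric(1))
  ord <- order(-score)
  alignments <- alignments[ord[seq_len(min(config$max_queries,
                                           length(ord)))]]
  alignments
}

#' Export an alignment's placed conformers as a multi-record SDF
#'
#' @param alignment An `Alignment`.
#' @param ensembles Named list of `ConformerEnsemble`.
#' @param path Output SDF path.
#' @export
write_alignment_sdf <- function(alignment, ensembles, path) {
  lines <- unlist(lapply(names(alignment$placements), function(id) {
    pl <- alignment$placements[[id]]
    ens <- ensembles[[id]]
    co <- apply_transform(ens$conformers[[pl$conformer_index]]$coords,
                          pl$rotation, pl$translation)
    sdf_with_coords(ens$sdf_template, round(co, 4), title = id,
                    tags = list(QUERY_LABEL = alignment$query$label,
                                MATCH_RMSD = sprintf("%.6f", pl$rmsd)))
  }))
  writeLines(lines, path)
  invisible(path)
}
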