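# Pharmacophore feature perception on 3D conformers.
#
# Feature classes and the typed-graph rules that define them (the bundled
# pattern table; matched on the SYBYL-typed molecular graph):
#   ARO_RING (R): centroid of each aromatic ring (cycle of aromatic bonds).
#   HYD      (H): centroid of each maximal group of >= 3 connected
#                 non-aromatic carbons none of which touches a heteroatom;
#                 halogens are not treated as hydrophobes.
#   DON      (D): N or O bearing at least one hydrogen.
#   ACC      (A): O with formal charge <= 0; N with formal charge <= 0 that
#                 is not an amide nitrogen (bonded to a carbonyl carbon),
#                 not an aromatic N-H, and has fewer than 4 connections.
#   PROJ_DON (d): virtual point 3.0 A from the donor heteroatom along each
#                 heteroatom -> H unit vector.
#   PROJ_ACC (a): virtual point 3.0 A from the acceptor along each
#                 idealized lone-pair axis (sp2 and sp3 O emit 2, nitrile
#                 and multi-substituted N emit 1).
#   CAT      (C): nitrogen with positive formal charge (protonated amine /
#                 amidinium / guanidinium).
#   ANI      (N): carboxylate / sulfonate / phosphate group centroid (over
#                 the O atoms) or any other formally negative heavy atom.

.proj_distance <- 3.0

#' Perceive pharmacophore feature points on one conformer
#'
#' Applies the bundled typed-graph pattern table (see the package vignette)
#' to a conformer with explicit hydrogens.  Pattern matches depend only on
#' the molecular graph, so every conformer of one molecule carries the same
#' typed features; only the coordinates differ.
#'
#' @param ensemble A `ConformerEnsemble`.
#' @param conformer_index Which conformer's coordinates to use (default 1).
#' @return A `FeatureSet`: list with `molecule_id`, `conformer_index` and
#'   `points`, a data.frame with columns `kind`, `x`, `y`, `z` and a list
#'   column `source_atoms`; rows sorted by canonical kind order then lowest
#'   source atom.
#' @export
perceive_features <- function(ensemble, conformer_index = 1) {
  co <- ensemble$conformers[[conformer_index]]$coords
  el <- ensemble$elements
  fc <- ensemble$formal_charges
  bonds <- ensemble$bonds
  n <- length(el)
  nbrs <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    o <- bonds$origin[i]; t <- bonds$target[i]
    nbrs[[o]] <- c(nbrs[[o]], t); nbrs[[t]] <- c(nbrs[[t]], o)
  }
  border <- function(i, j) {
    hit <- (bonds$origin == i & bonds$target == j) |
      (bonds$origin == j & bonds$target == i)
    bonds[which(hit)[1], ]
  }
  pts <- list()
  add <- function(kind, coords, src) {
    pts[[length(pts) + 1L]] <<- list(kind = kind, coords = coords,
                                     src = sort(as.integer(src)))
  }

  # aromatic rings
  ar_bonds <- bonds[bonds$aromatic, , drop = FALSE]
  if (nrow(ar_bonds) >= 3) {
    rings <- perceive_rings(n, ar_bonds)
    seen <- character(0)
    for (r in rings) {
      key <- paste(sort(r), collapse = ",")
      if (key %in% seen || length(r) < 5 || length(r) > 7) next
      seen <- c(seen, key)
      add("ARO_RING", colMeans(co[r, , drop = FALSE]), r)
    }
  }

  # hydrophobic carbon groups
  is_het <- !(el %in% c("C", "H"))
  plain_c <- which(el == "C" &
                     !vapply(seq_len(n), function(i)
                       any(is_het[nbrs[[i]]]), logical(1)))
  arom_atoms <- unique(c(ar_bonds$origin, ar_bonds$target))
  plain_c <- setdiff(plain_c, arom_atoms)
  if (length(plain_c) >= 3) {
    sub <- bonds[bonds$origin %in% plain_c & bonds$target %in% plain_c, ,
                 drop = FALSE]
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(sub$origin),
                 to = as.character(sub$target)),
      directed = FALSE,
      vertices = data.frame(name = as.character(plain_c)))
    comp <- igraph::components(g)$membership
    for (k in unique(comp)) {
      grp <- as.integer(names(comp)[comp == k])
      if (length(grp) >= 3) {
        add("HYD", colMeans(co[grp, , drop = FALSE]), grp)
      }
    }
  }

  donors <- integer(0)
  acceptors <- integer(0)
  for (i in which(el %in% c("N", "O"))) {
    hs <- nbrs[[i]][el[nbrs[[i]]] == "H"]
    if (length(hs) > 0) donors <- c(donors, i)
    if (el[i] == "O" && fc[i] <= 0) acceptors <- c(acceptors, i)
    if (el[i] == "N" && fc[i] <= 0) {
      amide <- any(vapply(nbrs[[i]], function(j) {
        el[j] == "C" && any(vapply(nbrs[[j]], function(m) {
          el[m] == "O" && border(j, m)$order == 2L
        }, logical(1)))
      }, logical(1)))
      aromatic_nh <- i %in% arom_atoms && length(hs) > 0
      if (!amide && !aromatic_nh && length(nbrs[[i]]) < 4) {
        acceptors <- c(acceptors, i)
      }
    }
  }
  for (i in donors) add("DON", co[i, ], i)
  for (i in acceptors) add("ACC", co[i, ], i)

  # projected donor points: 3 A along each D-H vector
  for (i in donors) {
    for (h in nbrs[[i]][el[nbrs[[i]]] == "H"]) {
      d <- unit(co[h, ] - co[i, ])
      add("PROJ_DON", co[i, ] + .proj_distance * d, c(i, h))
    }
  }

  # projected acceptor points: 3 A along idealized lone-pair axes
  for (i in acceptors) {
    nb <- nbrs[[i]]
    u <- lapply(nb, function(j) unit(co[j, ] - co[i, ]))
    axes <- lone_pair_axes(el[i], ensemble$hyb[i], nb, u,
                           if (length(nb) == 1) border(i, nb[1])$order else 1L,
                           co, nbrs)
    for (d in axes) add("PROJ_ACC", co[i, ] + .proj_distance * d, i)
  }

  # ionized groups
  for (i in which(fc > 0 & el == "N")) add("CAT", co[i, ], i)
  neg <- which(fc < 0)
  grouped <- integer(0)
  for (i in neg) {
    if (el[i] == "O") {
      x <- nbrs[[i]][el[nbrs[[i]]] %in% c("C", "S", "P")]
      if (length(x) == 1) {
        oxy <- nbrs[[x]][el[nbrs[[x]]] == "O"]
        if (length(oxy) >= 2) {
          add("ANI", colMeans(co[oxy, , drop = FALSE]), c(x, oxy))
          grouped <- c(grouped, i)
          next
        }
      }
    }
    add("ANI", co[i, ], i)
  }

  if (length(pts) == 0) {
    points <- data.frame(kind = character(0), x = numeric(0),
                         y = numeric(0), z = numeric(0))
    points$source_atoms <- list()
  } else {
    points <- data.frame(
      kind = vapply(pts, `[[`, character(1), "kind"),
      x = vapply(pts, function(p) p$coords[1], numeric(1)),
      y = vapply(pts, function(p) p$coords[2], numeric(1)),
      z = vapply(pts, function(p) p$coords[3], numeric(1)))
    points$source_atoms <- lapply(pts, `[[`, "src")
    ord <- order(kind_rank(points$kind),
                 vapply(points$source_atoms, min, numeric(1)))
    points <- points[ord, , drop = FALSE]
    rownames(points) <- NULL
  }
  structure(list(molecule_id = ensemble$molecule_id,
                 conformer_index = conformer_index, points = points),
            class = "FeatureSet")
}

# Idealized lone-pair direction(s) for an acceptor atom.
lone_pair_axes <- function(element, hyb, nb, u, order1, co, nbrs) {
  k <- length(nb)
  if (k == 0) return(list(c(1, 0, 0)))
  if (k == 1) {
    if (order1 >= 3L || hyb == 1L) return(list(-1 * u[[1]]))
    # terminal sp2 (carbonyl-like): two in-plane axes at 120 deg from the bond
    b <- nb[1]
    others <- setdiff(nbrs[[b]], integer(0))
    ref <- NULL
    for (j in others) {
      w <- unit(co[j, ] - co[b, ])
      t <- w - sum(w * u[[1]]) * u[[1]]
      if (sqrt(sum(t^2)) > 1e-6) { ref <- unit(t); break }
    }
    if (is.null(ref)) ref <- perp_vector(u[[1]])
    a <- -1 * u[[1]]
    return(list(unit(a * cos(pi / 3) + ref * sin(pi / 3)),
                unit(a * cos(pi / 3) - ref * sin(pi / 3))))
  }
  if (k == 2) {
    base <- -unit(u[[1]] + u[[2]])
    if (hyb == 3L) {
      nrm <- cross3(u[[1]], u[[2]])
      if (sqrt(sum(nrm^2)) < 1e-6) nrm <- perp_vector(u[[1]])
      nrm <- unit(nrm)
      phi <- 54.25 * pi / 180
      return(list(unit(base * cos(phi) + nrm * sin(phi)),
                  unit(base * cos(phi) - nrm * sin(phi))))
    }
    return(list(base))  # pyridine-like: single in-plane axis
  }
  list(-unit(Reduce(`+`, u)))
}

#' Distances between feature points
#'
#' @param fs A `FeatureSet`.
#' @param subset Integer indices of the points to use (distinct); default
#'   all points.
#' @return Symmetric matrix of Euclidean distances in Angstrom.
#' @export
feature_distance_matrix <- function(fs, subset = seq_len(nrow(fs$points))) {
  if (anyDuplicated(subset)) stop("repeated feature index")
  co <- as.matrix(fs$points[subset, c("x", "y", "z")])
  m <- as.matrix(stats::dist(co))
  dimnames(m) <- NULL
  m
}

#' Perceive features on every conformer of every ensemble
#'
#' @param ensembles Named list of `ConformerEnsemble`.
#' @return Named list (molecule id) of lists of `FeatureSet`, one per
#'   conformer.
#' @export
perceive_all_features <- function(ensembles) {
  lapply(ensembles, function(ens) {
    lapply(seq_along(ens$conformers), function(i)
      perceive_features(ens, i))
  })
}

#' @export
print.FeatureSet <- function(x, ...) {
  cat("FeatureSet:", x$molecule_id, "conformer", x$conformer_index, "-",
      nrow(x$points), "feature(s):",
      paste(x$points$kind, collapse = " "), "\n")
  invisible(x)
}
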