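# Deterministic, seeded construction of initial 3D coordinates from a
# molecular graph.  Ring systems are laid out as fused regular polygons,
# acyclic atoms are grown outward with ideal bond lengths and angles, and a
# small seeded jitter breaks planar/symmetric saddle points before the
# MMFF94 minimization that follows.  Replaces stochastic builder/rotor-search
# embeddings so that identical (structure, parameters, seed) always yields
# bit-identical conformers.

.covalent_radius <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                      P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39,
                      B = 0.84, Si = 1.11)

ideal_bond_length <- function(el1, el2, order = 1L, aromatic = FALSE) {
  r1 <- .covalent_radius[el1]; r2 <- .covalent_radius[el2]
  if (is.na(r1)) r1 <- 1.1
  if (is.na(r2)) r2 <- 1.1
  len <- unname(r1 + r2)
  if (aromatic) return(len * 0.93)
  if (order == 2L) return(len * 0.87)
  if (order >= 3L) return(len * 0.81)
  len
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(c(1, 0, 0))
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# A deterministic vector perpendicular to u.
perp_vector <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(cross3(u, ref))
}

rotate_about <- function(v, axis, theta) {
  a <- unit(axis)
  v * cos(theta) + cross3(a, v) * sin(theta) +
    a * sum(a * v) * (1 - cos(theta))
}

# Hybridization (1 = sp, 2 = sp2, 3 = sp3) from a SYBYL atom type string.
hyb_from_sybyl <- function(type) {
  if (grepl("\\.1$", type)) return(1L)
  if (grepl("\\.(ar|2|co2|am|pl3|cat)$", type) || grepl("\\.o2?$", type)) {
    return(2L)
  }
  3L
}

# Shortest-cycle basis of the molecular graph (approximate SSSR): one
# shortest cycle per non-tree edge.
perceive_rings <- function(natoms, bonds) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = bonds$origin, to = bonds$target),
    directed = FALSE, vertices = data.frame(name = seq_len(natoms)))
  tree_ids <- igraph::as_ids(igraph::E(igraph::mst(g)))
  extra <- setdiff(igraph::as_ids(igraph::E(g)), tree_ids)
  rings <- list()
  for (eid in extra) {
    uv <- strsplit(eid, "|", fixed = TRUE)[[1]]
    g2 <- igraph::delete_edges(g, eid)
    sp <- suppressWarnings(igraph::shortest_paths(
      g2, from = uv[1], to = uv[2]))$vpath[[1]]
    if (length(sp) >= 3) {
      rings[[length(rings) + 1L]] <- as.integer(igraph::as_ids(sp))
    }
  }
  rings[order(lengths(rings))]
}

# Cycle traversal of `ring` from atom a to atom b that avoids the direct
# a-b edge (a and b must be adjacent in the cycle ordering).
ring_long_path <- function(ring, a, b) {
  n <- length(ring)
  i <- match(a, ring)
  fwd <- ring[((i - 1 + 0:(n - 1)) %% n) + 1]
  if (fwd[2] == b) fwd <- ring[((i - 1 - 0:(n - 1)) %% n) + 1]
  fwd
}

# 2D layout (z = 0) of one fused ring system as regular polygons.  Returns a
# named list atom-id -> 3-vector.
layout_ring_system <- function(rings, bond_len = 1.45) {
  pos <- list()
  circum <- function(n) bond_len / (2 * sin(pi / n))
  apothem <- function(n) bond_len / (2 * tan(pi / n))

  place_first <- function(ring) {
    n <- length(ring)
    ang <- 2 * pi * (seq_len(n) - 1) / n
    for (i in seq_len(n)) {
      pos[[as.character(ring[i])]] <<- circum(n) * c(cos(ang[i]), sin(ang[i]), 0)
    }
  }
  place_fused <- function(ring, a, b) {
    n <- length(ring)
    pa <- pos[[as.character(a)]]; pb <- pos[[as.character(b)]]
    mid <- (pa + pb) / 2
    e <- unit(pb - pa)
    perp <- c(-e[2], e[1], 0)
    placed_pts <- do.call(rbind, pos)
    away <- mid - c(colMeans(placed_pts)[1:2], 0)
    if (sum(perp * away) < 0) perp <- -perp
    cen <- mid + perp * apothem(n)
    alpha <- atan2(pa[2] - cen[2], pa[1] - cen[1])
    beta <- atan2(pb[2] - cen[2], pb[1] - cen[1])
    dshort <- atan2(sin(beta - alpha), cos(beta - alpha))
    dir <- if (dshort >= 0) -1 else 1
    path <- ring_long_path(ring, a, b)
    inner <- path[2:(n - 1)]
    for (i in seq_along(inner)) {
      nm <- as.character(inner[i])
      if (is.null(pos[[nm]])) {
        ang <- alpha + dir * 2 * pi * i / n
        pos[[nm]] <<- cen + circum(n) * c(cos(ang), sin(ang), 0)
      }
    }
  }
  place_spiro <- function(ring, shared) {
    n <- length(ring)
    ang <- 2 * pi * (seq_len(n) - 1) / n
    local <- lapply(seq_len(n), function(i)
      circum(n) * c(cos(ang[i]), sin(ang[i]), 0))
    shift <- pos[[as.character(shared)]] - local[[match(shared, ring)]] +
      c(0, 0, 0.5)
    for (i in seq_len(n)) {
      nm <- as.character(ring[i])
      if (is.null(pos[[nm]])) pos[[nm]] <<- local[[i]] + shift
    }
  }

  done <- logical(length(rings))
  place_first(rings[[1]])
  done[1] <- TRUE
  repeat {
    progressed <- FALSE
    for (k in which(!done)) {
      ring <- rings[[k]]
      n <- length(ring)
      have <- ring %in% as.integer(names(pos))
      pair <- NULL
      for (i in which(have)) {
        nxt <- (i %% n) + 1
        if (have[nxt]) { pair <- c(ring[i], ring[nxt]); break }
      }
      if (!is.null(pair)) {
        place_fused(ring, pair[1], pair[2])
        done[k] <- TRUE; progressed <- TRUE
      } else if (sum(have) >= 1) {
        place_spiro(ring, ring[which(have)[1]])
        done[k] <- TRUE; progressed <- TRUE
      }
    }
    if (all(done) || !progressed) break
  }
  pos
}

# Ideal directions for new substituents given unit vectors to already-placed
# neighbours and the parent's hybridization.
ideal_directions <- function(udirs, hyb, n_new) {
  k <- length(udirs)
  if (k == 0) {
    return(rep(list(c(1, 0, 0)), max(1, n_new)))
  }
  if (k == 1) {
    u <- udirs[[1]]
    theta <- switch(hyb, pi, pi * 2 / 3, 109.47 * pi / 180)
    p <- perp_vector(u)
    step <- switch(hyb, 0, pi, 2 * pi / 3)
    return(lapply(seq_len(max(1, n_new)), function(i) {
      d0 <- rotate_about(-u, p, pi - theta)
      unit(rotate_about(d0, u, (i - 1) * step))
    }))
  }
  base <- -unit(Reduce(`+`, udirs))
  if (hyb == 3L && k == 2) {
    nrm <- unit(cross3(udirs[[1]], udirs[[2]]))
    if (n_new >= 2) {
      return(list(unit(base + 0.82 * nrm), unit(base - 0.82 * nrm)))
    }
    return(list(unit(base + 0.5 * nrm)))
  }
  rep(list(base), max(1, n_new))
}

# Initial 3D coordinates for a molecule.  `bonds` needs columns
# origin/target/order and logical `aromatic`; `hyb` is per-atom 1/2/3.
build_initial_coords <- function(elements, bonds, hyb, seed,
                                 jitter_sd = 0.02) {
  natoms <- length(elements)
  coords <- matrix(NA_real_, natoms, 3)
  placed <- logical(natoms)
  nbrs <- vector("list", natoms)
  border <- list()
  for (i in seq_len(nrow(bonds))) {
    o <- bonds$origin[i]; t <- bonds$target[i]
    nbrs[[o]] <- c(nbrs[[o]], t); nbrs[[t]] <- c(nbrs[[t]], o)
    border[[paste(min(o, t), max(o, t))]] <- bonds[i, ]
  }
  blen <- function(i, j) {
    b <- border[[paste(min(i, j), max(i, j))]]
    ideal_bond_length(elements[i], elements[j], b$order, isTRUE(b$aromatic))
  }

  rings <- if (nrow(bonds) >= natoms) perceive_rings(natoms, bonds) else list()
  systems <- list()
  if (length(rings) > 0) {
    rg <- igraph::make_empty_graph(n = length(rings), directed = FALSE)
    if (length(rings) > 1) {
      pairs <- utils::combn(length(rings), 2)
      share <- apply(pairs, 2, function(p)
        length(intersect(rings[[p[1]]], rings[[p[2]]])) > 0)
      if (any(share)) rg <- igraph::add_edges(rg, as.vector(pairs[, share]))
    }
    comp <- igraph::components(rg)$membership
    systems <- lapply(seq_len(max(comp)), function(k) rings[comp == k])
  }
  system_of_atom <- integer(natoms)
  for (k in seq_along(systems)) {
    system_of_atom[unique(unlist(systems[[k]]))] <- k
  }

  place_system <- function(k, attach_atom = NULL, attach_pos = NULL,
                           attach_dir = NULL) {
    sys_rings <- systems[[k]]
    atoms <- unique(unlist(sys_rings))
    aromatic_sys <- mean(hyb[atoms] == 2L) > 0.5
    lay <- layout_ring_system(sys_rings, bond_len = if (aromatic_sys) 1.42 else 1.52)
    ids <- as.integer(names(lay))
    pts <- do.call(rbind, lay)
    if (!is.null(attach_atom)) {
      a_local <- lay[[as.character(attach_atom)]]
      cen <- colMeans(pts)
      v <- unit(cen - a_local)
      axis <- cross3(v, attach_dir)
      s <- sqrt(sum(axis^2)); d <- sum(v * attach_dir)
      pts <- t(apply(pts, 1, function(p) {
        q <- p - a_local
        if (s > 1e-9) {
          rotate_about(q, axis, atan2(s, d))
        } else if (d < 0) -q else q
      }))
      pts <- sweep(pts, 2, attach_pos, "+")
    }
    for (i in seq_along(ids)) {
      if (!placed[ids[i]]) {
        coords[ids[i], ] <<- pts[i, ]
        placed[ids[i]] <<- TRUE
      }
    }
  }

  if (length(systems) > 0) {
    sizes <- vapply(systems, function(s) length(unique(unlist(s))), integer(1))
    place_system(which.max(sizes))
  } else {
    coords[1, ] <- c(0, 0, 0)
    placed[1] <- TRUE
  }

  queue <- which(placed)
  while (length(queue) > 0) {
    p <- queue[1]; queue <- queue[-1]
    todo <- sort(nbrs[[p]][!placed[nbrs[[p]]]])
    if (length(todo) == 0) next
    udirs <- lapply(nbrs[[p]][placed[nbrs[[p]]]],
                    function(j) unit(coords[j, ] - coords[p, ]))
    dirs <- ideal_directions(udirs, hyb[p], length(todo))
    for (i in seq_along(todo)) {
      a <- todo[i]
      if (placed[a]) next
      d <- dirs[[min(i, length(dirs))]]
      target <- coords[p, ] + d * blen(p, a)
      if (system_of_atom[a] > 0) {
        place_system(system_of_atom[a], attach_atom = a,
                     attach_pos = target, attach_dir = d)
        queue <- c(queue, setdiff(which(placed), queue))
      } else {
        coords[a, ] <- target
        placed[a] <- TRUE
        queue <- c(queue, a)
      }
    }
  }
  if (any(!placed)) {
    coords[!placed, ] <- 8 + matrix(seq_len(3 * sum(!placed)), ncol = 3)
  }
  set.seed(seed %% .Machine$integer.max)
  coords + matrix(stats::rnorm(3 * natoms, 0, jitter_sd), natoms, 3)
}
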