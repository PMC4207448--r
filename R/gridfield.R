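# CoMFA-style molecular interaction fields: a regular 3D grid around the
# aligned ensemble, probed at every point by an sp3 carbon of charge +1.0.
# Steric energies are Lennard-Jones 6-12 with R* radius combination; the
# electrostatic term is Coulombic with a distance-dependent dielectric
# eps(r) = r, giving E = 332.0637 q_i q_probe / r^2 per atom.

.coulomb_k <- 332.0637

# Tripos-style van der Waals parameters by element: R = radius (Angstrom),
# eps = well depth (kcal/mol).  The probe is an sp3 carbon, charge +1.0 e.
.vdw_table <- data.frame(
  element = c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
  R = c(1.50, 1.70, 1.55, 1.52, 1.47, 1.80, 1.80, 1.75, 1.85, 1.98),
  eps = c(0.042, 0.107, 0.095, 0.116, 0.109, 0.314, 0.314, 0.314, 0.434,
          0.623))

#' Probe-atom parameters
#'
#' @param charge Probe charge in elementary units (default +1.0).
#' @param vdw_radius Probe van der Waals radius in Angstrom (sp3 carbon).
#' @param vdw_epsilon Probe well depth in kcal/mol.
#' @return A `ProbeParams` list.
#' @export
probe_params <- function(charge = 1.0, vdw_radius = 1.70,
                         vdw_epsilon = 0.107) {
  structure(list(element = "C.3", charge = charge, vdw_radius = vdw_radius,
                 vdw_epsilon = vdw_epsilon), class = "ProbeParams")
}

vdw_params_for <- function(elements) {
  i <- match(elements, .vdw_table$element)
  R <- .vdw_table$R[i]; eps <- .vdw_table$eps[i]
  R[is.na(R)] <- 1.70; eps[is.na(eps)] <- 0.107
  list(R = R, eps = eps)
}

#' Build the regular grid enclosing an aligned ensemble
#'
#' Axis-aligned regular grid with the requested spacing; the origin is the
#' floor-to-spacing of (min coordinate - padding) and counts are minimal so
#' that (max + padding) is enclosed.
#'
#' @param aligned_coords Matrix (n x 3) of every placed atom, Angstrom.
#' @param spacing Grid separation in Angstrom (default 2.0).
#' @param padding Margin beyond the bounding box in Angstrom (default 4.0).
#' @return A `GridSpec`: list with `origin`, `spacing`, `counts`.
#' @export
build_grid <- function(aligned_coords, spacing = 2.0, padding = 4.0) {
  aligned_coords <- as.matrix(aligned_coords)
  stopifnot(nrow(aligned_coords) >= 1, spacing > 0)
  lo <- apply(aligned_coords, 2, min) - padding
  hi <- apply(aligned_coords, 2, max) + padding
  origin <- floor(lo / spacing) * spacing
  counts <- pmax(2L, as.integer(ceiling((hi - origin) / spacing)) + 1L)
  structure(list(origin = origin, spacing = spacing, counts = counts),
            class = "GridSpec")
}

#' Grid point coordinates
#'
#' @param grid A `GridSpec`.
#' @return Matrix (prod(counts) x 3) of grid point coordinates; x varies
#'   fastest (linear index = ix + nx*(iy + ny*iz), zero-based).
#' @export
grid_points <- function(grid) {
  n <- grid$counts
  g <- expand.grid(x = grid$origin[1] + grid$spacing * (seq_len(n[1]) - 1),
                   y = grid$origin[2] + grid$spacing * (seq_len(n[2]) - 1),
                   z = grid$origin[3] + grid$spacing * (seq_len(n[3]) - 1))
  as.matrix(g)
}

#' Steric and electrostatic probe energies at one grid point
#'
#' @param coords Molecule coordinates, n x 3 Angstrom.
#' @param elements Element symbols, length n.
#' @param charges Partial charges, length n (e).
#' @param grid_point Length-3 position of the probe.
#' @param probe A [probe_params()].
#' @param r_min Distance floor in Angstrom preventing singularities
#'   (default 0.05).
#' @return Named numeric `c(steric=, electrostatic=)` in kcal/mol.
#' @export
compute_field_point <- function(coords, elements, charges, grid_point,
                                probe = probe_params(), r_min = 0.05) {
  vp <- vdw_params_for(elements)
  d <- sqrt(rowSums(sweep(as.matrix(coords), 2, grid_point)^2))
  d <- pmax(d, r_min)
  Rstar <- vp$R + probe$vdw_radius
  epsstar <- sqrt(vp$eps * probe$vdw_epsilon)
  sr6 <- (Rstar / d)^6
  steric <- sum(epsstar * (sr6^2 - 2 * sr6))
  elec <- sum(.coulomb_k * charges * probe$charge / d^2)
  c(steric = steric, electrostatic = elec)
}

# Vectorized over all grid points for one molecule; returns a 2-column
# matrix (steric, electrostatic), one row per grid point.
field_for_molecule <- function(coords, elements, charges, gpts,
                               probe = probe_params(), r_min = 0.05) {
  vp <- vdw_params_for(elements)
  Rstar <- vp$R + probe$vdw_radius
  epsstar <- sqrt(vp$eps * probe$vdw_epsilon)
  d2 <- outer(rowSums(gpts^2), rowSums(coords^2), "+") -
    2 * gpts %*% t(as.matrix(coords))
  d2[d2 < 0] <- 0
  d <- pmax(sqrt(d2), r_min)
  sr6 <- sweep(1 / d, 2, Rstar, "*")^6
  steric <- (sr6^2 - 2 * sr6) %*% epsstar
  elec <- (1 / d^2) %*% (.coulomb_k * charges * probe$charge)
  cbind(steric = as.numeric(steric), electrostatic = as.numeric(elec))
}

#' Compute the field descriptor matrix for an aligned ensemble
#'
#' Evaluates the steric and electrostatic probe energies of every placed
#' molecule at every grid point, then discards any grid point where any
#' molecule's steric energy exceeds `steric_cutoff` (the point is removed
#' globally, for all molecules).
#'
#' @param alignment An `Alignment` from [elucidate()].
#' @param ensembles Named list of `ConformerEnsemble`.
#' @param grid A `GridSpec`, or `NULL` to build one from the placed atoms.
#' @param probe A [probe_params()].
#' @param steric_cutoff Steric discard threshold in kcal/mol (default +30);
#'   use `Inf` to keep every point.
#' @param spacing,padding Grid construction parameters used when
#'   `grid = NULL`.
#' @return A `FieldMatrix`: list with `molecule_ids`, `steric` and
#'   `electrostatic` (molecules x kept-points matrices, kcal/mol),
#'   `kept_point_indices` (1-based linear grid indices) and `grid`.
#' @export
compute_field_matrix <- function(alignment, ensembles, grid = NULL,
                                 probe = probe_params(),
                                 steric_cutoff = 30.0, spacing = 2.0,
                                 padding = 4.0) {
  ids <- names(alignment$placements)
  placed <- lapply(ids, function(id) {
    pl <- alignment$placements[[id]]
    ens <- ensembles[[id]]
    list(coords = apply_transform(
      ens$conformers[[pl$conformer_index]]$coords,
      pl$rotation, pl$translation),
      elements = ens$elements, charges = ens$charges)
  })
  names(placed) <- ids
  if (is.null(grid)) {
    allco <- do.call(rbind, lapply(placed, `[[`, "coords"))
    grid <- build_grid(allco, spacing = spacing, padding = padding)
  }
  gpts <- grid_points(grid)
  ng <- nrow(gpts)
  steric <- matrix(NA_real_, length(ids), ng)
  elec <- matrix(NA_real_, length(ids), ng)
  for (i in seq_along(ids)) {
    fm <- field_for_molecule(placed[[i]]$coords, placed[[i]]$elements,
                             placed[[i]]$charges, gpts, probe)
    steric[i, ] <- fm[, "steric"]
    elec[i, ] <- fm[, "electrostatic"]
  }
  max_steric <- apply(steric, 2, max)
  kept <- which(max_steric <= steric_cutoff)
  if (length(kept) == 0) stop("every grid point exceeded the steric cutoff")
  structure(list(molecule_ids = ids,
                 steric = steric[, kept, drop = FALSE],
                 electrostatic = elec[, kept, drop = FALSE],
                 kept_point_indices = kept,
                 grid = grid),
            class = "FieldMatrix")
}

#' @export
print.FieldMatrix <- function(x, ...) {
  cat("FieldMatrix:", length(x$molecule_ids), "molecules x",
      length(x$kept_point_indices), "kept grid points (of",
      prod(x$grid$counts), ")\n")
  invisible(x)
}
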