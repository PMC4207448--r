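#' Conformer ensemble generation
#'
#' Generates a pruned ensemble of low-strain-energy 3D conformers for one
#' molecule.  Initial coordinates come from a deterministic seeded builder,
#' conformers are enumerated by systematic torsion driving, every conformer
#' is MMFF94-minimized, strain energies are taken relative to the ensemble
#' minimum, and near-duplicate geometries (heavy-atom best-fit RMSD below
#' `rmsd_prune`) are removed keeping the lower-energy member.
#'
#' @param record A molecule record as returned by [read_dataset()] (a list
#'   with at least `id` and `smiles`).
#' @param max_confs Maximum ensemble size after pruning (default 250).
#' @param energy_window Strain-energy window in kcal/mol above the ensemble
#'   minimum; higher-strain conformers are discarded (default 7.0).
#' @param rmsd_prune Heavy-atom RMSD threshold in Angstrom below which two
#'   conformers are considered duplicates (default 0.5).
#' @param seed Integer seed controlling the initial embedding; required.
#' @param charge_model Partial-charge model, `"mmff94"` (MMFF94-family bond
#'   charge increments, the default) or `"gasteiger"`.
#' @return A `ConformerEnsemble`: list with `molecule_id`, `elements`,
#'   `sybyl` atom types, `formal_charges`, `charges` (per-atom partial
#'   charges, e), `bonds`, `hyb`, `conformers` (each a list with `coords`
#'   n x 3 matrix in Angstrom and `strain_energy` kcal/mol, sorted ascending
#'   by strain), and `sdf_template` used for SDF export.
#' @export
generate_conformers <- function(record, max_confs = 250, energy_window = 7.0,
                                rmsd_prune = 0.5, seed,
                                charge_model = c("mmff94", "gasteiger")) {
  if (missing(seed)) stop("seed is required for conformer generation")
  charge_model <- match.arg(charge_model)
  stopifnot(max_confs >= 1, energy_window >= 0, rmsd_prune >= 0)
  graph <- molecule_graph(record$smiles, record$id)
  coords0 <- build_initial_coords(graph$elements, graph$bonds, graph$hyb,
                                  seed = seed)
  sdf0 <- sdf_with_coords(graph$sdf_template, coords0)
  min0 <- obabel_minimize(sdf0)
  confs_sdf <- obabel_confab(min0)
  confs_min <- obabel_minimize(confs_sdf)
  recs <- parse_sdf_records(confs_min)
  energies <- obabel_energies(confs_min)
  if (length(energies) != length(recs)) {
    stop("conformer generation failed for molecule '", record$id,
         "': energy evaluation mismatch")
  }
  strain <- energies - min(energies)
  keep <- which(strain <= energy_window + 1e-9)
  ord <- keep[order(strain[keep])]
  heavy <- graph$elements != "H"
  kept <- list()
  for (i in ord) {
    co <- recs[[i]]$coords
    dup <- FALSE
    for (k in kept) {
      if (best_fit_rmsd(co[heavy, , drop = FALSE],
                        k$coords[heavy, , drop = FALSE]) < rmsd_prune) {
        dup <- TRUE
        break
      }
    }
    if (!dup) {
      kept[[length(kept) + 1L]] <- list(coords = round(co, 4),
                                        strain_energy = strain[i])
    }
    if (length(kept) >= max_confs) break
  }
  if (length(kept) == 0) {
    stop("no conformers survived for molecule '", record$id, "'")
  }
  base <- min(vapply(kept, `[[`, numeric(1), "strain_energy"))
  kept <- lapply(kept, function(k) {
    k$strain_energy <- k$strain_energy - base
    k
  })
  ens <- structure(list(molecule_id = record$id,
                        elements = graph$elements,
                        sybyl = graph$sybyl,
                        formal_charges = graph$formal_charges,
                        charges = NULL,
                        charge_model = NULL,
                        bonds = graph$bonds,
                        hyb = graph$hyb,
                        conformers = kept,
                        sdf_template = graph$sdf_template),
                   class = "ConformerEnsemble")
  assign_partial_charges(ens, method = if (charge_model == "mmff94")
    "mmff-like" else "gasteiger")
}

# Topology, SYBYL typing and formal charges for one SMILES.
molecule_graph <- function(smiles, id) {
  sdf <- smiles_to_sdf_text(smiles, id)
  rec <- parse_sdf_records(sdf)[[1]]
  if (sum(rec$elements != "H") < 1) {
    stop("molecule '", id, "' has no heavy atoms")
  }
  mol2 <- sdf_to_mol2(sdf)
  if (nrow(mol2$atom) != rec$natoms) {
    stop("atom count mismatch while typing molecule '", id, "'")
  }
  sybyl <- mol2$atom$elety
  bonds <- rec$bonds
  btype <- mol2$bond$type
  key <- paste(pmin(mol2$bond$origin, mol2$bond$target),
               pmax(mol2$bond$origin, mol2$bond$target))
  arom <- setNames(btype %in% c("ar"), key)
  bonds$aromatic <- unname(arom[paste(pmin(bonds$origin, bonds$target),
                                      pmax(bonds$origin, bonds$target))])
  bonds$aromatic[is.na(bonds$aromatic)] <- FALSE
  hyb <- vapply(sybyl, hyb_from_sybyl, integer(1))
  list(elements = rec$elements, bonds = bonds, hyb = unname(hyb),
       formal_charges = rec$formal_charges, sybyl = sybyl,
       sdf_template = rec$block)
}

#' Assign per-atom partial charges to an ensemble
#'
#' Charges are assigned topologically (bond charge increment schemes), so
#' they are identical across conformers of one molecule and sum to the total
#' formal charge.
#'
#' @param ensemble A `ConformerEnsemble`.
#' @param method `"mmff-like"` (MMFF94-family charges, default) or
#'   `"gasteiger"`.
#' @return The ensemble with `charges` and `charge_model` filled in.
#' @export
assign_partial_charges <- function(ensemble,
                                   method = c("mmff-like", "gasteiger")) {
  method <- match.arg(method)
  model <- if (method == "mmff-like") "mmff94" else "gasteiger"
  sdf <- sdf_with_coords(ensemble$sdf_template,
                         ensemble$conformers[[1]]$coords)
  mol2 <- sdf_to_mol2(sdf, charge_model = model)
  q <- mol2$atom$charge
  if (any(!is.finite(q))) {
    stop("charge model '", method, "' failed for molecule '",
         ensemble$molecule_id, "' (unsupported element?)")
  }
  total <- sum(ensemble$formal_charges)
  if (abs(sum(q) - total) > 1e-4) {
    # bond-charge-increment schemes conserve formal charge; a larger gap
    # means the backend could not type an atom
    stop("partial charges for '", ensemble$molecule_id,
         "' do not sum to the formal charge (", sum(q), " vs ", total, ")")
  }
  q <- q - (sum(q) - total) / length(q)
  ensemble$charges <- q
  ensemble$charge_model <- method
  ensemble
}

#' Generate conformer ensembles for a whole dataset
#'
#' @param dataset A `Dataset` from [read_dataset()].
#' @param config A [run_config()] list (uses `max_confs`, `energy_window`,
#'   `rmsd_prune`, `seed`, `charge_model`).
#' @param verbose Print one line per molecule.
#' @return Named list of `ConformerEnsemble`, in dataset order.
#' @export
generate_ensembles <- function(dataset, config = run_config(),
                               verbose = FALSE) {
  out <- list()
  for (rec in dataset$records) {
    if (verbose) message("conformers: ", rec$id)
    out[[rec$id]] <- generate_conformers(
      rec, max_confs = config$max_confs,
      energy_window = config$energy_window,
      rmsd_prune = config$rmsd_prune, seed = config$seed,
      charge_model = if (config$charge_model == "mmff-like") "mmff94"
      else "gasteiger")
  }
  out
}

#' @export
print.ConformerEnsemble <- function(x, ...) {
  cat("ConformerEnsemble:", x$molecule_id, "-", length(x$conformers),
      "conformer(s),", length(x$elements), "atoms\n")
  invisible(x)
}

#' Export an ensemble as a multi-record SDF
#'
#' One SDF record per conformer with the strain energy in an SD tag
#' `STRAIN_KCAL`.
#'
#' @param ensemble A `ConformerEnsemble`.
#' @param path Output file path.
#' @export
write_ensemble_sdf <- function(ensemble, path) {
  lines <- unlist(lapply(seq_along(ensemble$conformers), function(i) {
    cf <- ensemble$conformers[[i]]
    sdf_with_coords(ensemble$sdf_template, cf$coords,
                    title = paste0(ensemble$molecule_id, "_conf", i),
                    tags = list(STRAIN_KCAL = sprintf("%.4f",
                                                      cf$strain_energy)))
  }))
  writeLines(lines, path)
  invisible(path)
}
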