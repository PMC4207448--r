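# End-to-end orchestration: configuration, training runs, prediction for
# new molecules, external test-set evaluation, and the reproducibility
# manifest.

#' Run configuration
#'
#' Collects every tunable of the pipeline with its default.  All randomness
#' in a run is controlled by the single `seed`.
#'
#' @param seed Master seed (integer, required at run time; default 1).
#' @param max_confs,energy_window,rmsd_prune,charge_model Conformer stage;
#'   see [generate_conformers()].
#' @param k,dist_tol,dedup_tol,min_coverage,max_queries,n_reference,max_inactive_frac
#'   Pharmacophore elucidation; see [elucidate()].
#' @param spacing,padding,steric_cutoff,probe_charge Field grid; see
#'   [compute_field_matrix()].
#' @param min_sd,noc_max PLS stage; see [filter_columns()] and [loo_q2()].
#' @return A `RunConfig` list.
#' @export
run_config <- function(seed = 1L, max_confs = 250, energy_window = 7.0,
                       rmsd_prune = 0.5, charge_model = "mmff-like",
                       k = 4, dist_tol = 1.0, dedup_tol = 0.5,
                       min_coverage = 0.9, max_queries = 10,
                       n_reference = 3, max_inactive_frac = 0.5,
                       spacing = 2.0, padding = 4.0, steric_cutoff = 30.0,
                       probe_charge = 1.0, min_sd = 0.1, noc_max = 10) {
  structure(list(seed = as.integer(seed), max_confs = max_confs,
                 energy_window = energy_window, rmsd_prune = rmsd_prune,
                 charge_model = charge_model, k = k, dist_tol = dist_tol,
                 dedup_tol = dedup_tol, min_coverage = min_coverage,
                 max_queries = max_queries, n_reference = n_reference,
                 max_inactive_frac = max_inactive_frac, spacing = spacing,
                 padding = padding, steric_cutoff = steric_cutoff,
                 probe_charge = probe_charge, min_sd = min_sd,
                 noc_max = noc_max),
            class = "RunConfig")
}

#' Train ranked pharmacophore + field models
#'
#' Runs conformer generation, feature perception, common-pharmacophore
#' elucidation and PLS model building on the training records, returning at
#' most `config$max_queries` models ranked by leave-one-out q2.  The run is
#' deterministic given (dataset, config).
#'
#' @param dataset A `Dataset` from [read_dataset()].
#' @param config A [run_config()].
#' @param output_dir Optional directory; when given, writes `manifest.json`,
#'   `stats.csv`, `model_NN.json` per model, the best model's aligned
#'   ensemble SDF and its mean-field and coefficient OpenDX maps.
#' @param ensembles Optional precomputed ensembles (as returned by
#'   [generate_ensembles()] under the same config) to skip the conformer
#'   stage; conformer generation depends only on the structures and the
#'   config, not on the activities, so ensembles can be shared between runs
#'   that differ only in the response.
#' @param verbose Progress messages.
#' @return List with `models` (ranked `AutoGPAModel`s), `stats`
#'   (data.frame), `alignments`, `ensembles`, `feature_sets`, `config`.
#' @export
run_train <- function(dataset, config = run_config(), output_dir = NULL,
                      ensembles = NULL, verbose = FALSE) {
  train <- Filter(function(r) r$role == "train", dataset$records)
  if (length(train) < 4) {
    stop("model building needs at least 4 training records")
  }
  train_ids <- vapply(train, `[[`, character(1), "id")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  if (is.null(ensembles)) {
    tdat <- structure(list(records = train, provenance = dataset$provenance),
                      class = "Dataset")
    ensembles <- stage("conformers",
                       generate_ensembles(tdat, config, verbose = verbose))
  } else {
    ensembles <- ensembles[train_ids]
    if (any(vapply(ensembles, is.null, logical(1)))) {
      stop("precomputed ensembles are missing training molecules")
    }
  }
  feature_sets <- stage("features", perceive_all_features(ensembles))
  tdat <- structure(list(records = train, provenance = dataset$provenance),
                    class = "Dataset")
  alignments <- stage("elucidate",
                      elucidate(tdat, ensembles, feature_sets, config))
  models <- stage("plsqsar",
                  build_models(alignments, ensembles, tdat, config))
  models <- lapply(models, function(m) {
    m$probe_charge <- config$probe_charge
    m$dist_tol <- config$dist_tol
    m$steric_cutoff <- config$steric_cutoff
    m
  })
  stats <- model_stats_table(models)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_stats_csv(models, file.path(output_dir, "stats.csv"))
    for (i in seq_along(models)) {
      write_model(models[[i]],
                  file.path(output_dir, sprintf("model_%02d.json", i)))
    }
    best <- models[[1]]
    write_alignment_sdf(best$alignment, ensembles,
                        file.path(output_dir, "aligned_best.sdf"))
    write_model_maps(best, output_dir)
    manifest <- list(config = unclass(config),
                     package_version =
                       as.character(utils::packageVersion("autogpa")),
                     r_version = R.version.string,
                     n_train = length(train),
                     n_models = length(models),
                     created = "see file mtime")
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(models = models, stats = stats, alignments = alignments,
       ensembles = ensembles, feature_sets = feature_sets, config = config)
}

# Mean-over-molecules field maps and PLS coefficient maps (steric and
# electrostatic) for contour plotting, as OpenDX files.
write_model_maps <- function(model, output_dir) {
  grid <- model$grid
  ng <- prod(grid$counts)
  expand <- function(cols, vals) {
    full <- numeric(ng)
    full[cols] <- vals
    full
  }
  ns <- length(model$field$steric_cols)
  write_field_grid(expand(model$field$steric_cols,
                          colMeans(model$field$steric)),
                   grid, file.path(output_dir, "field_steric_mean.dx"))
  write_field_grid(expand(model$field$elec_cols,
                          colMeans(model$field$electrostatic)),
                   grid, file.path(output_dir, "field_electrostatic_mean.dx"))
  beta <- model$pls$coefficients
  write_field_grid(expand(model$field$steric_cols, beta[seq_len(ns)]),
                   grid, file.path(output_dir, "coef_steric.dx"))
  write_field_grid(expand(model$field$elec_cols, beta[-seq_len(ns)]),
                   grid, file.path(output_dir, "coef_electrostatic.dx"))
  invisible(NULL)
}

#' Predict the activity of one molecule with a trained model
#'
#' Generates conformers for the molecule and evaluates every conformer that
#' satisfies both the pharmacophore model and the grid potential model: the
#' conformer's feature set must match the model's query, and, once aligned,
#' the probe steric energy at every grid column the model uses must not
#' exceed the model's steric cutoff (a conformer protruding into regions
#' where no training molecule reached would otherwise be scored by wild
#' extrapolation).  Each surviving conformer's field vector goes through
#' the PLS regression and the maximum over conformers is adopted as the
#' predicted activity.  A molecule with no surviving conformer gets status
#' `no_match` and no numeric prediction.
#'
#' @param model An `AutoGPAModel` (from [build_models()] or [load_model()]).
#' @param record A molecule record (list with `id` and `smiles`).
#' @param config A [run_config()]; the conformer settings and `dist_tol`
#'   are used.
#' @param ensemble Optional precomputed `ConformerEnsemble` for the record.
#' @return A `Prediction`: list with `molecule_id`, `per_conformer`
#'   (one predicted pIC50 per matching conformer), `predicted` (their max,
#'   or `NA` when `no_match`), `n_matching_conformers` and `status`.
#' @export
predict_activity <- function(model, record, config = run_config(),
                             ensemble = NULL) {
  if (is.null(ensemble)) {
    ensemble <- generate_conformers(
      record, max_confs = config$max_confs,
      energy_window = config$energy_window,
      rmsd_prune = config$rmsd_prune, seed = config$seed,
      charge_model = if (config$charge_model == "mmff-like") "mmff94"
      else "gasteiger")
  }
  dist_tol <- model$dist_tol %||% config$dist_tol
  cutoff <- model$steric_cutoff %||% config$steric_cutoff
  gpts <- grid_points(model$grid)
  probe <- probe_params(model$probe_charge %||% config$probe_charge)
  gate_points <- sort(unique(c(model$field$steric_cols,
                               model$field$elec_cols)))
  per_conf <- numeric(0)
  for (ci in seq_along(ensemble$conformers)) {
    fs <- perceive_features(ensemble, ci)
    pl <- match_and_place(model$query, fs, dist_tol = dist_tol)
    if (is.null(pl)) next
    co <- apply_transform(ensemble$conformers[[ci]]$coords,
                          pl$rotation, pl$translation)
    fields <- field_for_molecule(co, ensemble$elements, ensemble$charges,
                                 gpts, probe)
    if (max(fields[gate_points, "steric"]) > cutoff) next
    x <- c(fields[model$field$steric_cols, "steric"],
           fields[model$field$elec_cols, "electrostatic"])
    per_conf <- c(per_conf, predict(model$pls, x))
  }
  status <- if (length(per_conf) > 0) "ok" else "no_match"
  structure(list(molecule_id = record$id,
                 per_conformer = per_conf,
                 predicted = if (status == "ok") max(per_conf) else NA_real_,
                 n_matching_conformers = length(per_conf),
                 status = status),
            class = "Prediction")
}

#' @export
print.Prediction <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("Prediction %s: %.3f (max over %d matching conformer(s))\n",
                x$molecule_id, x$predicted, x$n_matching_conformers))
  } else {
    cat("Prediction", x$molecule_id, ": no_match\n")
  }
  invisible(x)
}

#' Evaluate a model on an external test set
#'
#' Computes predictive r2 against the training-set mean:
#' `r2_pred = 1 - sum((y - yhat)^2) / sum((y - y_train_mean)^2)`.
#' Molecules with status `no_match` are reported but excluded from the
#' sums, never imputed.
#'
#' @param model An `AutoGPAModel`.
#' @param test_records List of molecule records with `pIC50`.
#' @param config A [run_config()].
#' @param ensembles Optional named list of precomputed ensembles.
#' @return List with `r2_pred` and `table` (data.frame: id, observed,
#'   predicted, n_matching_conformers, status).
#' @export
evaluate_test_set <- function(model, test_records, config = run_config(),
                              ensembles = NULL) {
  preds <- lapply(test_records, function(r)
    predict_activity(model, r, config,
                     ensemble = if (!is.null(ensembles))
                       ensembles[[r$id]] else NULL))
  tab <- data.frame(
    id = vapply(test_records, `[[`, character(1), "id"),
    observed = vapply(test_records, `[[`, numeric(1), "pIC50"),
    predicted = vapply(preds, `[[`, numeric(1), "predicted"),
    n_matching_conformers = vapply(preds, `[[`, numeric(1),
                                   "n_matching_conformers"),
    status = vapply(preds, `[[`, character(1), "status"))
  ok <- tab$status == "ok"
  if (sum(ok) < 3) {
    stop("need at least 3 test molecules with a prediction; got ", sum(ok))
  }
  list(r2_pred = r2_pred(tab$observed[ok], tab$predicted[ok],
                         model$pls$y_mean),
       table = tab)
}

#' Predictive r-squared against the training mean
#'
#' `1 - sum((y - yhat)^2) / sum((y - y_train_mean)^2)`: 1 for perfect
#' prediction, 0 for a model no better than always predicting the training
#' mean, negative for worse.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @param y_train_mean Mean activity of the training set.
#' @return A single number.
#' @export
r2_pred <- function(observed, predicted, y_train_mean) {
  1 - sum((observed - predicted)^2) / sum((observed - y_train_mean)^2)
}

#' Write a predictions table as CSV
#'
#' @param eval_result Result of [evaluate_test_set()].
#' @param path Output CSV path.
#' @export
write_predictions_csv <- function(eval_result, path) {
  utils::write.csv(eval_result$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
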