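# Partial least squares regression of activity on field columns, with
# leave-one-out selection of the number of components and CoMFA-style block
# scaling (the steric and electrostatic blocks are given equal total
# variance; columns are centered but not individually autoscaled, which
# preserves within-block spatial contrast).

# Variance-filter the two field blocks of a FieldMatrix.
#' Drop near-constant field columns
#'
#' Removes, independently in each block, columns whose standard deviation
#' across molecules is below `min_sd`.  A grid point can survive in one
#' block and be dropped from the other.
#'
#' @param fm A `FieldMatrix`.
#' @param min_sd Minimum column standard deviation in kcal/mol
#'   (default 0.1); `0` keeps everything.
#' @return The reduced `FieldMatrix`, with `steric_cols` / `elec_cols`
#'   recording the surviving grid-point indices per block.
#' @export
filter_columns <- function(fm, min_sd = 0.1) {
  stopifnot(min_sd >= 0)
  keep_block <- function(m) {
    if (min_sd == 0) return(seq_len(ncol(m)))
    which(apply(m, 2, stats::sd) >= min_sd)
  }
  ks <- keep_block(fm$steric)
  ke <- keep_block(fm$electrostatic)
  if (length(ks) + length(ke) == 0) {
    stop("variance filter dropped every field column")
  }
  fm$steric_cols <- fm$kept_point_indices[ks]
  fm$elec_cols <- fm$kept_point_indices[ke]
  fm$steric <- fm$steric[, ks, drop = FALSE]
  fm$electrostatic <- fm$electrostatic[, ke, drop = FALSE]
  fm
}

# Assemble the descriptor matrix [steric | electrostatic] from a (filtered)
# FieldMatrix, with per-block scale factors that equalize total variance.
field_design_matrix <- function(fm) {
  X <- cbind(fm$steric, fm$electrostatic)
  ns <- ncol(fm$steric)
  colnames(X) <- c(if (ns > 0) paste0("S", fm$steric_cols %||%
                                        fm$kept_point_indices),
                   if (ncol(fm$electrostatic) > 0)
                     paste0("E", fm$elec_cols %||% fm$kept_point_indices))
  attr(X, "block") <- rep(c("S", "E"), c(ns, ncol(fm$electrostatic)))
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-block scale factors giving each block unit total variance; a block
# with (near) zero variance is left unscaled.
block_scale_factors <- function(X, block) {
  vapply(unique(block), function(b) {
    tv <- sum(apply(X[, block == b, drop = FALSE], 2, stats::var))
    if (tv < 1e-12) 1 else 1 / sqrt(tv)
  }, numeric(1))
}

#' Fit a PLS regression (NIPALS)
#'
#' Centers y and the columns of X, applies CoMFA block scaling when a block
#' assignment is provided, extracts `noc` latent components by the NIPALS
#' algorithm with deflation, and back-transforms the regression vector to
#' original column units.
#'
#' @param X Descriptor matrix (n x p).
#' @param y Response vector (pIC50), length n.
#' @param noc Number of latent components requested.
#' @param block Optional character vector (length p) assigning columns to
#'   scaling blocks; `NULL` disables block scaling.
#' @return A `pls_fit`: list with `coefficients` (length p, original
#'   units), `intercept`, `x_mean`, `y_mean`, `scale`, `noc` (achieved),
#'   `fitted`, `r2`, `mse`.
#' @export
fit_pls <- function(X, y, noc, block = attr(X, "block")) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= 3)
  if (stats::var(y) < 1e-14) stop("response has zero variance")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  scale <- rep(1, p)
  if (!is.null(block)) {
    f <- block_scale_factors(X, block)
    scale <- unname(f[block])
  }
  Xc <- sweep(sweep(X, 2, x_mean), 2, scale, "*")
  yc <- y - y_mean
  W <- matrix(0, p, 0); P <- matrix(0, p, 0); Q <- numeric(0)
  Xd <- Xc; yd <- yc
  achieved <- 0L
  for (a in seq_len(noc)) {
    w <- as.numeric(t(Xd) %*% yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_score <- as.numeric(Xd %*% w)
    tt <- sum(t_score^2)
    if (tt < 1e-12) break
    p_load <- as.numeric(t(Xd) %*% t_score) / tt
    q_load <- sum(yd * t_score) / tt
    W <- cbind(W, w); P <- cbind(P, p_load); Q <- c(Q, q_load)
    Xd <- Xd - t_score %*% t(p_load)
    yd <- yd - t_score * q_load
    achieved <- a
  }
  if (achieved == 0L) stop("no PLS component could be extracted")
  if (achieved < noc) {
    warning("requested ", noc, " components but only ", achieved,
            " could be extracted")
  }
  # beta in centered/scaled space: W (P'W)^-1 Q
  beta_s <- W %*% solve(t(P) %*% W, Q)
  beta <- as.numeric(beta_s) * scale
  fitted <- y_mean + as.numeric(sweep(X, 2, x_mean) %*% beta)
  resid <- y - fitted
  mse <- mean(resid^2)
  r2 <- 1 - sum(resid^2) / sum((y - y_mean)^2)
  structure(list(coefficients = beta, intercept = y_mean,
                 x_mean = x_mean, y_mean = y_mean, scale = scale,
                 noc = achieved, fitted = fitted, r2 = r2, mse = mse),
            class = "pls_fit")
}

#' Predict from a PLS fit
#'
#' @param object A `pls_fit`.
#' @param newdata Matrix (m x p) on the same columns as the training X.
#' @param ... Ignored.
#' @return Numeric vector of predictions.
#' @export
predict.pls_fit <- function(object, newdata, ...) {
  newdata <- matrix(newdata, ncol = length(object$x_mean))
  object$y_mean +
    as.numeric(sweep(newdata, 2, object$x_mean) %*% object$coefficients)
}

#' Leave-one-out q-squared over component counts
#'
#' For each number of components up to `noc_max`, refits the PLS model n
#' times leaving each row out in turn (re-centering and re-scaling inside
#' every fold), predicts the held-out row, and computes
#' q2 = 1 - PRESS / sum((y - mean(y))^2) with the mean over all n rows.
#'
#' @param X Descriptor matrix.
#' @param y Response vector; n >= 4.
#' @param noc_max Maximum number of components (default 10); capped at
#'   n - 2.
#' @param block Optional column block assignment for scaling.
#' @return List with `best_noc` (argmax q2, ties to fewer components) and
#'   `q2` (named vector over component counts).
#' @export
loo_q2 <- function(X, y, noc_max = 10, block = attr(X, "block")) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("leave-one-out needs at least 4 rows")
  nocs <- seq_len(min(noc_max, n - 2))
  press <- numeric(length(nocs))
  for (i in seq_len(n)) {
    preds <- pls_path_predict(X[-i, , drop = FALSE], y[-i],
                              X[i, ], max(nocs), block)
    press <- press + (y[i] - preds)^2
  }
  ss <- sum((y - mean(y))^2)
  q2 <- 1 - press / ss
  names(q2) <- nocs
  list(best_noc = nocs[which.max(q2)], q2 = q2)
}

# One NIPALS pass extracting up to `A` components (they are nested: the
# first a components of a larger fit equal the a-component fit), returning
# the prediction of `xnew` at every component count 1..A.  If extraction
# stops early the last achievable prediction is carried forward, matching
# what a capped refit would produce.
pls_path_predict <- function(X, y, xnew, A, block = NULL) {
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  scale <- rep(1, ncol(X))
  if (!is.null(block)) {
    f <- block_scale_factors(X, block)
    scale <- unname(f[block])
  }
  Xd <- sweep(sweep(X, 2, x_mean), 2, scale, "*")
  yd <- y - y_mean
  xn <- (xnew - x_mean) * scale
  W <- matrix(0, ncol(X), 0); P <- matrix(0, ncol(X), 0); Q <- numeric(0)
  preds <- numeric(A)
  last <- y_mean
  for (a in seq_len(A)) {
    w <- as.numeric(t(Xd) %*% yd)
    nw <- sqrt(sum(w^2))
    ok <- nw >= 1e-12
    if (ok) {
      w <- w / nw
      t_score <- as.numeric(Xd %*% w)
      tt <- sum(t_score^2)
      ok <- tt >= 1e-12
      if (ok) {
        p_load <- as.numeric(t(Xd) %*% t_score) / tt
        q_load <- sum(yd * t_score) / tt
        W <- cbind(W, w); P <- cbind(P, p_load); Q <- c(Q, q_load)
        Xd <- Xd - t_score %*% t(p_load)
        yd <- yd - t_score * q_load
        beta_s <- W %*% solve(t(P) %*% W, Q)
        last <- y_mean + sum(xn * beta_s)
      }
    }
    preds[a] <- last
  }
  preds
}

#' Build and rank QSAR models over a set of alignments
#'
#' For every alignment: compute the field matrix, variance-filter the
#' columns, pick the number of PLS components by leave-one-out q2, fit the
#' final model, and collect the statistics.  Models are returned sorted by
#' decreasing q2 (ties: fewer components, then fewer grid columns).
#'
#' @param alignments List of `Alignment`s from [elucidate()].
#' @param ensembles Named list of `ConformerEnsemble`.
#' @param dataset The `Dataset` (training activities are taken from it).
#' @param config A [run_config()].
#' @return List of `AutoGPAModel`s sorted by decreasing q2.  Each has
#'   `query`, `alignment`, `grid`, `field` (filtered training
#'   `FieldMatrix`), `pls`, and `stats` (`noc`, `r2`, `q2`, `mse`,
#'   `n_grids`, `overlap`, `label`).
#' @export
build_models <- function(alignments, ensembles, dataset,
                         config = run_config()) {
  stopifnot(length(alignments) >= 1)
  acts <- stats::setNames(
    vapply(dataset$records, `[[`, numeric(1), "pIC50"),
    vapply(dataset$records, `[[`, character(1), "id"))
  models <- list()
  for (ai in seq_along(alignments)) {
    al <- alignments[[ai]]
    res <- try({
      fm <- compute_field_matrix(al, ensembles,
                                 probe = probe_params(config$probe_charge),
                                 steric_cutoff = config$steric_cutoff,
                                 spacing = config$spacing,
                                 padding = config$padding)
      fm <- filter_columns(fm, min_sd = config$min_sd)
      X <- field_design_matrix(fm)
      y <- unname(acts[fm$molecule_ids])
      cv <- loo_q2(X, y, noc_max = config$noc_max)
      fit <- suppressWarnings(fit_pls(X, y, cv$best_noc))
      stats <- list(noc = fit$noc, r2 = fit$r2,
                    q2 = unname(cv$q2[as.character(fit$noc)]),
                    mse = fit$mse, n_grids = ncol(X),
                    overlap = al$overlap, label = al$query$label)
      structure(list(query = al$query, alignment = al, grid = fm$grid,
                     field = fm, pls = fit, stats = stats,
                     q2_by_noc = cv$q2),
                class = "AutoGPAModel")
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      warning("alignment ", al$query$label, " (#", ai, ") failed: ",
              attr(res, "condition")$message)
    } else {
      models[[length(models) + 1L]] <- res
    }
  }
  if (length(models) == 0) stop("no alignment yielded a QSAR model")
  key <- vapply(models, function(m)
    c(-m$stats$q2, m$stats$noc, m$stats$n_grids), numeric(3))
  ord <- order(key[1, ], key[2, ], key[3, ])
  models[ord]
}

#' Statistics table for a ranked model list
#'
#' One row per model, mirroring the usual summary of ranked pharmacophore +
#' field models: overlap score, pharmacophore label, number of components,
#' number of grid columns, training MSE, r2 and leave-one-out q2.
#'
#' @param models List of `AutoGPAModel`.
#' @return A data.frame with columns Model, Overlap, PH4, NOC, Grids, MSE,
#'   r2, q2.
#' @export
model_stats_table <- function(models) {
  data.frame(
    Model = seq_along(models),
    Overlap = vapply(models, function(m) round(m$stats$overlap, 4),
                     numeric(1)),
    PH4 = vapply(models, function(m) m$stats$label, character(1)),
    NOC = vapply(models, function(m) m$stats$noc, integer(1)),
    Grids = vapply(models, function(m) m$stats$n_grids, numeric(1)),
    MSE = vapply(models, function(m) round(m$stats$mse, 6), numeric(1)),
    r2 = vapply(models, function(m) round(m$stats$r2, 6), numeric(1)),
    q2 = vapply(models, function(m) round(m$stats$q2, 6), numeric(1)))
}

#' @export
print.AutoGPAModel <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "AutoGPAModel [%s]: noc=%d grids=%d r2=%.3f q2=%.3f mse=%.4f\n",
    s$label, s$noc, s$n_grids, s$r2, s$q2, s$mse))
  invisible(x)
}
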