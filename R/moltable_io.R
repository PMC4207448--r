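# Reading molecule + activity tables and writing models, statistics tables
# and field grids.
#
# Structures come in as SMILES ("SMILES<tab>id", one per line) or SDF V2000;
# activities as a CSV with header id,pIC50[,active][,role].  Model files are
# versioned, checksummed JSON so that a saved model reproduces its
# predictions bit-identically; field grids go out as OpenDX regular grids.

#' Read a molecule + activity dataset
#'
#' Joins every activity row to a structure by id.  Salt fragments are
#' stripped keeping the largest component (activities refer to the parent
#' compound).  Activities must be numeric pIC50 values; qualified values
#' such as "<5" or ">8" are rejected, not imputed.
#'
#' @param path_structures SMILES file (`SMILES<tab>id` per line; extension
#'   `.smi`/`.smiles`/`.txt`) or an SDF file (`.sdf`/`.mol`).
#' @param path_activities CSV with columns `id`, `pIC50` and optionally
#'   `active` (logical/0-1) and `role` (`train`/`test`).
#' @return A `Dataset`: list with `records` (list of molecule records:
#'   `id`, `smiles`, `pIC50`, `is_active`, `role`) in activity-file order,
#'   and `provenance`.
#' @export
read_dataset <- function(path_structures, path_activities) {
  structures <- read_structures(path_structures)
  if (anyDuplicated(structures$id)) {
    stop("duplicate molecule id(s): ",
         paste(unique(structures$id[duplicated(structures$id)]),
               collapse = ", "))
  }
  act <- utils::read.csv(path_activities, stringsAsFactors = FALSE)
  need <- c("id", "pIC50")
  if (!all(need %in% names(act))) {
    stop("activities file must have columns id and pIC50")
  }
  if (anyDuplicated(act$id)) {
    stop("duplicate id(s) in activities: ",
         paste(unique(act$id[duplicated(act$id)]), collapse = ", "))
  }
  if (is.character(act$pIC50)) {
    qual <- grepl("[<>]", act$pIC50)
    if (any(qual)) {
      stop("qualified activity values are not supported: ",
           paste(act$id[qual], collapse = ", "))
    }
    act$pIC50 <- as.numeric(act$pIC50)
  }
  if (any(!is.finite(act$pIC50))) {
    stop("non-finite pIC50 for: ",
         paste(act$id[!is.finite(act$pIC50)], collapse = ", "))
  }
  missing_ids <- setdiff(act$id, structures$id)
  if (length(missing_ids) > 0) {
    stop("activity rows with no structure: ",
         paste(missing_ids, collapse = ", "))
  }
  unused <- setdiff(structures$id, act$id)
  if (length(unused) > 0) {
    message("structures without activity ignored: ",
            paste(unused, collapse = ", "))
  }
  records <- lapply(seq_len(nrow(act)), function(i) {
    id <- act$id[i]
    smiles <- strip_salts(structures$smiles[match(id, structures$id)])
    list(id = id, smiles = smiles, pIC50 = act$pIC50[i],
         is_active = if ("active" %in% names(act))
           as.logical(act$active[i]) else NULL,
         role = if ("role" %in% names(act)) {
           match.arg(act$role[i], c("train", "test"))
         } else "train")
  })
  structure(list(records = records,
                 provenance = paste0(path_structures, " + ",
                                     path_activities)),
            class = "Dataset")
}

read_structures <- function(path) {
  if (grepl("\\.(sdf|mol)$", path, ignore.case = TRUE)) {
    tmp <- tempfile(fileext = ".smi")
    on.exit(unlink(tmp), add = TRUE)
    run_obabel(c(shQuote(path), "-osmi", "-O", shQuote(tmp)))
    lines <- readLines(tmp)
  } else {
    lines <- readLines(path)
  }
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t ]+")
  bad <- which(lengths(parts) < 2)
  if (length(bad) > 0) {
    stop("structure line ", bad[1], " has no id: '", lines[bad[1]], "'")
  }
  smiles <- vapply(parts, `[[`, character(1), 1)
  for (i in seq_along(smiles)) {
    ok <- try(smiles_to_sdf_text(smiles[i], "check"), silent = TRUE)
    if (inherits(ok, "try-error")) {
      stop("unparsable structure at line ", i, ": '", smiles[i], "'")
    }
  }
  data.frame(smiles = smiles,
             id = vapply(parts, `[[`, character(1), 2),
             stringsAsFactors = FALSE)
}

#' @export
print.Dataset <- function(x, ...) {
  roles <- vapply(x$records, `[[`, character(1), "role")
  cat("Dataset:", length(x$records), "molecules (",
      sum(roles == "train"), "train /", sum(roles == "test"), "test )\n")
  invisible(x)
}

.model_schema_version <- "1.0"

# Doubles go through the file as %.17g strings: 17 significant digits
# round-trip IEEE-754 exactly, so a loaded model predicts bit-identically.
num_out <- function(x) sprintf("%.17g", as.numeric(x))
num_in <- function(x) as.numeric(x)

model_payload <- function(model) {
  list(schema = .model_schema_version,
       query = list(kinds = model$query$kinds,
                    coords = num_out(unname(as.matrix(model$query$coords))),
                    tolerance = model$query$tolerance,
                    label = model$query$label),
       grid = list(origin = num_out(model$grid$origin),
                   spacing = model$grid$spacing,
                   counts = unname(model$grid$counts)),
       columns = list(steric = as.integer(model$field$steric_cols),
                      electrostatic = as.integer(model$field$elec_cols)),
       probe = unclass(probe_params(model$probe_charge %||% 1.0)),
       steric_cutoff = model$steric_cutoff %||% 30.0,
       pls = list(coefficients = num_out(model$pls$coefficients),
                  x_mean = num_out(model$pls$x_mean),
                  y_mean = num_out(model$pls$y_mean),
                  scale = num_out(model$pls$scale),
                  noc = model$pls$noc),
       stats = model$stats)
}

payload_checksum <- function(payload) {
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Save a model to a structured text file
#'
#' The file is versioned JSON with an embedded checksum; [load_model()]
#' refuses a file whose payload no longer matches its checksum, and a
#' loaded model reproduces predictions bit-identically.
#'
#' @param model An `AutoGPAModel` from [build_models()].
#' @param path Output file path.
#' @export
write_model <- function(model, path) {
  if (is.null(model$query) || is.null(model$pls) || is.null(model$grid) ||
      is.null(model$stats) || is.null(model$field)) {
    stop("model is incomplete; expected query, grid, field, pls and stats")
  }
  payload <- model_payload(model)
  out <- list(payload = payload, checksum = payload_checksum(payload))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a model file
#'
#' @param path File written by [write_model()].
#' @return An `AutoGPAModel` sufficient for [predict_activity()].
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$payload) || is.null(obj$checksum)) {
    stop("not a model file: ", path)
  }
  # re-serialize through the same canonical form and compare checksums
  p <- obj$payload
  payload <- list(schema = p$schema,
                  query = list(kinds = p$query$kinds,
                               coords = as.character(p$query$coords),
                               tolerance = p$query$tolerance,
                               label = p$query$label),
                  grid = list(origin = as.character(p$grid$origin),
                              spacing = p$grid$spacing,
                              counts = p$grid$counts),
                  columns = list(steric = as.integer(p$columns$steric),
                                 electrostatic =
                                   as.integer(p$columns$electrostatic)),
                  probe = as.list(p$probe),
                  steric_cutoff = p$steric_cutoff,
                  pls = list(coefficients = as.character(p$pls$coefficients),
                             x_mean = as.character(p$pls$x_mean),
                             y_mean = as.character(p$pls$y_mean),
                             scale = as.character(p$pls$scale),
                             noc = p$pls$noc),
                  stats = as.list(p$stats))
  if (!identical(payload_checksum(payload), obj$checksum)) {
    stop("model file checksum mismatch; file was modified: ", path)
  }
  k <- length(payload$query$kinds)
  query <- list(kinds = payload$query$kinds,
                coords = matrix(num_in(payload$query$coords), k, 3),
                tolerance = payload$query$tolerance,
                label = payload$query$label)
  grid <- structure(list(origin = num_in(payload$grid$origin),
                         spacing = payload$grid$spacing,
                         counts = as.integer(payload$grid$counts)),
                    class = "GridSpec")
  pls <- structure(list(coefficients = num_in(payload$pls$coefficients),
                        x_mean = num_in(payload$pls$x_mean),
                        y_mean = num_in(payload$pls$y_mean),
                        scale = num_in(payload$pls$scale),
                        noc = payload$pls$noc),
                   class = "pls_fit")
  structure(list(query = query, grid = grid,
                 field = list(steric_cols = payload$columns$steric,
                              elec_cols = payload$columns$electrostatic),
                 probe_charge = payload$probe$charge,
                 steric_cutoff = payload$steric_cutoff,
                 pls = pls, stats = payload$stats),
            class = "AutoGPAModel")
}

#' Write per-grid-point values as an OpenDX regular grid
#'
#' @param values Numeric vector, one value (kcal/mol) per grid point in the
#'   package's linear order (x fastest; see [grid_points()]).
#' @param grid A `GridSpec`.
#' @param path Output `.dx` path.
#' @export
write_field_grid <- function(values, grid, path) {
  n <- grid$counts
  if (length(values) != prod(n)) {
    stop("value length ", length(values), " does not match grid size ",
         prod(n))
  }
  # DX convention: last index (z) varies fastest
  arr <- array(values, dim = n)
  vals <- as.numeric(aperm(arr, c(3, 2, 1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d",
            n[1], n[2], n[3]),
    sprintf("origin %.6f %.6f %.6f",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", grid$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", grid$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(n))), con)
  full <- seq_len(length(vals) %/% 3L * 3L)
  if (length(full) > 0) {
    m <- matrix(vals[full], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.6g %.6g %.6g", m[, 1], m[, 2], m[, 3]), con)
  }
  rest <- vals[setdiff(seq_along(vals), full)]
  if (length(rest) > 0) {
    writeLines(paste(sprintf("%.6g", rest), collapse = " "), con)
  }
  writeLines(c("attribute \"dep\" string \"positions\"",
               "object \"field\" class field",
               "component \"positions\" value 1",
               "component \"connections\" value 2",
               "component \"data\" value 3"), con)
  invisible(path)
}

#' Write the ranked-model statistics table as CSV
#'
#' @param models List of `AutoGPAModel`.
#' @param path Output CSV path.
#' @export
write_stats_csv <- function(models, path) {
  utils::write.csv(model_stats_table(models), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
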