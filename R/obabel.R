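# Internal wrappers around the OpenBabel command-line tools (obabel, obenergy).
# All structure interconversion, force-field minimization and force-field
# energy evaluation go through these helpers; everything they run is
# deterministic given the input bytes, which is what makes seeded runs of the
# whole pipeline reproducible.

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) stop("obabel not found on PATH; OpenBabel 3.x is required")
  p
}

run_obabel <- function(args, stdin_text = NULL) {
  infile <- NULL
  if (!is.null(stdin_text)) {
    infile <- tempfile(fileext = ".txt")
    writeLines(stdin_text, infile)
    on.exit(unlink(infile), add = TRUE)
  }
  out <- suppressWarnings(system2(obabel_path(), args = args,
                                  stdout = TRUE, stderr = TRUE,
                                  stdin = if (is.null(infile)) "" else infile))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("obabel failed (status ", status, "): ", paste(out, collapse = "\n"))
  }
  out
}

# Convert a SMILES string to an SDF block with explicit hydrogens and no
# coordinates (topology only).  Returns the raw SDF text lines.
smiles_to_sdf_text <- function(smiles, id) {
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp), add = TRUE)
  run_obabel(c(shQuote(paste0("-:", smiles)), "-osdf", "-h",
               "--title", shQuote(id), "-O", shQuote(tmp)))
  if (!file.exists(tmp) || file.info(tmp)$size == 0) {
    stop("could not parse SMILES for molecule '", id, "': ", smiles)
  }
  readLines(tmp)
}

# SYBYL atom typing + partial charges via a mol2 round trip.  Types and both
# supported charge models are topological in OpenBabel, so a zero-coordinate
# molecule types identically to any of its conformers.
sdf_to_mol2 <- function(sdf_lines, charge_model = c("mmff94", "gasteiger")) {
  charge_model <- match.arg(charge_model)
  fin <- tempfile(fileext = ".sdf"); fout <- tempfile(fileext = ".mol2")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(sdf_lines, fin)
  run_obabel(c(shQuote(fin), "-O", shQuote(fout),
               "--partialcharge", charge_model))
  mol2 <- bio3d::read.mol2(fout)
  if (inherits(mol2, "mol2")) mol2 else mol2[[1]]
}

# Parse the fields of a (possibly multi-record) V2000 SDF we care about:
# per-record element symbols, coordinates, bonds and formal charges.
parse_sdf_records <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0) ends <- length(lines) + 1L
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_along(starts), function(k) {
    rec <- lines[starts[k]:min(ends[k] - 1L, length(lines))]
    cl <- grep("V2000", rec)[1]
    if (is.na(cl)) stop("not a V2000 SDF record")
    natoms <- as.integer(substr(rec[cl], 1, 3))
    nbonds <- as.integer(substr(rec[cl], 4, 6))
    at <- rec[(cl + 1):(cl + natoms)]
    coords <- cbind(as.numeric(substr(at, 1, 10)),
                    as.numeric(substr(at, 11, 20)),
                    as.numeric(substr(at, 21, 30)))
    elements <- trimws(substr(at, 32, 34))
    bonds <- NULL
    if (nbonds > 0) {
      bl <- rec[(cl + natoms + 1):(cl + natoms + nbonds)]
      bonds <- data.frame(origin = as.integer(substr(bl, 1, 3)),
                          target = as.integer(substr(bl, 4, 6)),
                          order  = as.integer(substr(bl, 7, 9)))
    }
    fchg <- integer(natoms)
    for (ln in grep("^M  CHG", rec, value = TRUE)) {
      toks <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
      nent <- toks[1]
      for (i in seq_len(nent)) fchg[toks[2 * i]] <- toks[2 * i + 1]
    }
    list(title = rec[1], natoms = natoms, elements = elements,
         coords = coords, bonds = bonds, formal_charges = fchg,
         block = rec)
  })
}

# Rewrite the coordinate columns of a template SDF record, leaving every other
# byte (bond block, M CHG lines, properties) untouched.  Used to feed our own
# embeddings and transformed conformers back to OpenBabel and to disk.
sdf_with_coords <- function(template_block, coords, title = NULL,
                            tags = NULL) {
  rec <- template_block
  cl <- grep("V2000", rec)[1]
  natoms <- as.integer(substr(rec[cl], 1, 3))
  stopifnot(nrow(coords) == natoms)
  idx <- (cl + 1):(cl + natoms)
  rec[idx] <- paste0(sprintf("%10.4f%10.4f%10.4f", coords[, 1], coords[, 2],
                             coords[, 3]),
                     substr(rec[idx], 31, nchar(rec[idx])))
  rec[2] <- "  autogpa          3D"
  if (!is.null(title)) rec[1] <- title
  end <- grep("^M  END", rec)[1]
  body <- rec[1:end]
  if (!is.null(tags)) {
    for (nm in names(tags)) {
      body <- c(body, paste0("> <", nm, ">"), as.character(tags[[nm]]), "")
    }
  }
  c(body, "$$$$")
}

# Deterministic MMFF94 minimization of every record in an SDF file.
obabel_minimize <- function(sdf_lines, steps = 2500, crit = 1e-7,
                            ff = "MMFF94") {
  fin <- tempfile(fileext = ".sdf"); fout <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(sdf_lines, fin)
  run_obabel(c(shQuote(fin), "-O", shQuote(fout), "--minimize",
               "--ff", ff, "--steps", format(steps), "--crit",
               format(crit, scientific = FALSE)))
  readLines(fout)
}

# Systematic (torsion-driving) conformer enumeration; deterministic.
obabel_confab <- function(sdf_lines, ecutoff = 20, rcutoff = 0.3,
                          conf_limit = 10000) {
  fin <- tempfile(fileext = ".sdf"); fout <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(sdf_lines, fin)
  run_obabel(c(shQuote(fin), "-O", shQuote(fout), "--confab", "--original",
               "--ecutoff", format(ecutoff), "--rcutoff", format(rcutoff),
               "--conf", format(conf_limit)))
  readLines(fout)
}

# MMFF94 single-point energies (kcal/mol), one per SDF record, via obenergy.
obabel_energies <- function(sdf_lines, ff = "MMFF94") {
  p <- Sys.which("obenergy")
  if (!nzchar(p)) stop("obenergy not found on PATH")
  fin <- tempfile(fileext = ".sdf")
  on.exit(unlink(fin), add = TRUE)
  writeLines(sdf_lines, fin)
  out <- suppressWarnings(system2(p, c("-ff", ff, shQuote(fin)),
                                  stdout = TRUE, stderr = FALSE))
  e <- grep("^TOTAL ENERGY", out, value = TRUE)
  if (length(e) == 0) stop("obenergy returned no energies")
  as.numeric(sub("^TOTAL ENERGY\\s*=\\s*([-0-9.eE+]+).*", "\\1", e))
}

# Keep the largest connected fragment of a SMILES (salt stripping).
strip_salts <- function(smiles) {
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  if (length(frags) == 1) return(smiles)
  sizes <- vapply(frags, function(f) {
    sdf <- try(smiles_to_sdf_text(f, "frag"), silent = TRUE)
    if (inherits(sdf, "try-error")) return(-1L)
    rec <- parse_sdf_records(sdf)[[1]]
    sum(rec$elements != "H")
  }, integer(1))
  frags[which.max(sizes)]
}
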