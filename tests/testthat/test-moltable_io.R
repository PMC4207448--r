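# Dataset reading, model serialization and field-grid export.

write_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("read_dataset joins structures and activities by id", {
  smi <- write_tmp(c("CO\tm1", "CCO\tm2", "CCCO\tm3"), ".smi")
  act <- write_tmp(c("id,pIC50", "m1,5.1", "m2,6.2", "m3,7.3"), ".csv")
  ds <- read_dataset(smi, act)
  expect_length(ds$records, 3)
  expect_equal(vapply(ds$records, `[[`, character(1), "id"),
               c("m1", "m2", "m3"))
  expect_equal(vapply(ds$records, `[[`, numeric(1), "pIC50"),
               c(5.1, 6.2, 7.3))
  expect_true(all(vapply(ds$records, `[[`, character(1), "role") == "train"))
})

test_that("activity rows without a structure fail, naming the id", {
  smi <- write_tmp(c("CO\tm1"), ".smi")
  act <- write_tmp(c("id,pIC50", "m1,5.1", "m9,6.0"), ".csv")
  expect_error(read_dataset(smi, act), "m9")
})

test_that("duplicate ids and qualified activities are rejected", {
  smi <- write_tmp(c("CO\tm1", "CC\tm1"), ".smi")
  act <- write_tmp(c("id,pIC50", "m1,5.1"), ".csv")
  expect_error(read_dataset(smi, act), "duplicate")
  smi2 <- write_tmp(c("CO\tm1", "CC\tm2"), ".smi")
  act2 <- write_tmp(c("id,pIC50", "m1,<5", "m2,6"), ".csv")
  expect_error(read_dataset(smi2, act2), "qualified")
  act3 <- write_tmp(c("id,pIC50", "m1,5", "m2,NA"), ".csv")
  expect_error(read_dataset(smi2, act3), "non-finite")
})

test_that("salt fragments are stripped keeping the largest component", {
  smi <- write_tmp(c("c1ccccc1.CO\tm1"), ".smi")
  act <- write_tmp(c("id,pIC50", "m1,5.0"), ".csv")
  ds <- read_dataset(smi, act)
  expect_equal(ds$records[[1]]$smiles, "c1ccccc1")
})

test_that("generated series files load with the generator's roles", {
  tc <- trained_cache()
  ds <- tc$dataset
  expect_length(ds$records, 20)
  roles <- vapply(ds$records, `[[`, character(1), "role")
  expect_equal(sum(roles == "train"), 16)
  expect_equal(sum(roles == "test"), 4)
  expect_equal(roles, tc$series$manifest$roles)
})

test_that("dataset round trip preserves ids, activities and order", {
  tc <- trained_cache()
  ds <- tc$dataset
  smi <- tempfile(fileext = ".smi")
  act <- tempfile(fileext = ".csv")
  writeLines(vapply(ds$records, function(r)
    paste(r$smiles, r$id, sep = "\t"), character(1)), smi)
  utils::write.csv(data.frame(
    id = vapply(ds$records, `[[`, character(1), "id"),
    pIC50 = vapply(ds$records, `[[`, numeric(1), "pIC50")),
    act, row.names = FALSE, quote = FALSE)
  ds2 <- read_dataset(smi, act)
  expect_equal(vapply(ds2$records, `[[`, character(1), "id"),
               vapply(ds$records, `[[`, character(1), "id"))
  expect_equal(vapply(ds2$records, `[[`, numeric(1), "pIC50"),
               vapply(ds$records, `[[`, numeric(1), "pIC50"))
})

test_that("model files round-trip bit-identically and detect tampering", {
  tc <- trained_cache()
  best <- tc$result$models[[1]]
  path <- tempfile(fileext = ".json")
  write_model(best, path)
  loaded <- load_model(path)
  rec <- tc$dataset$records[[2]]
  ens <- tc$internals$ensembles[[rec$id]]
  p1 <- predict_activity(best, rec, tc$config, ensemble = ens)
  p2 <- predict_activity(loaded, rec, tc$config, ensemble = ens)
  expect_identical(p1$predicted, p2$predicted)
  expect_identical(p1$per_conformer, p2$per_conformer)
  # coefficient entries = steric + electrostatic surviving columns
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_length(obj$payload$pls$coefficients,
                length(best$field$steric_cols) +
                  length(best$field$elec_cols))
  # perturb one stored coefficient -> checksum error
  txt <- readLines(path)
  i <- grep("coefficients", txt)[1] + 1
  txt[i] <- sub("[1-8]", "9", txt[i])
  tam <- tempfile(fileext = ".json")
  writeLines(txt, tam)
  expect_error(load_model(tam), "checksum")
  # partial model -> error
  incomplete <- best
  incomplete$pls <- NULL
  expect_error(write_model(incomplete, tempfile()), "incomplete")
})

test_that("OpenDX export writes the grid spec and values faithfully", {
  grid <- structure(list(origin = c(-2, -2, -2), spacing = 2,
                         counts = c(3L, 3L, 3L)), class = "GridSpec")
  path <- tempfile(fileext = ".dx")
  write_field_grid(rep(0, 27), grid, path)
  txt <- readLines(path)
  expect_true(any(grepl("counts 3 3 3", txt)))
  expect_equal(sum(grepl("^delta", txt)), 3)
  deltas <- txt[grepl("^delta", txt)]
  expect_equal(vapply(strsplit(deltas, " "), function(p)
    sum(as.numeric(p[-1])), numeric(1)), rep(2, 3))
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(txt[grepl("^[-0-9]", txt)], " "))))
  expect_equal(sum(!is.na(vals)), 27)
  expect_true(all(vals[!is.na(vals)] == 0))
  expect_error(write_field_grid(rep(0, 5), grid, path), "does not match")
})

test_that("exported DX values equal direct probe energies", {
  ens <- tiny_ensemble("CO")
  grid <- structure(list(origin = c(-4, -4, -4), spacing = 4,
                         counts = c(2L, 2L, 2L)), class = "GridSpec")
  gpts <- grid_points(grid)
  co <- ens$conformers[[1]]$coords
  vals <- vapply(seq_len(nrow(gpts)), function(i)
    compute_field_point(co, ens$elements, ens$charges,
                        gpts[i, ])[["steric"]], numeric(1))
  path <- tempfile(fileext = ".dx")
  write_field_grid(vals, grid, path)
  txt <- readLines(path)
  lo <- grep("data follows", txt) + 1
  hi <- grep("^attribute", txt)[1] - 1
  written <- as.numeric(unlist(strsplit(txt[lo:hi], " ")))
  # DX order is z-fastest; our linear order is x-fastest
  arr <- array(vals, dim = grid$counts)
  expect_equal(written, as.numeric(aperm(arr, c(3, 2, 1))),
               tolerance = 1e-5)
})
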