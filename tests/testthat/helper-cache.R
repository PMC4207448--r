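# Expensive shared fixtures, built once per test run.  Everything here is
# deterministic: conformer generation is seeded and the congeneric series
# is a fixed design.

.test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .test_cache)) {
    assign(name, force(expr), envir = .test_cache)
  }
  get(name, envir = .test_cache)
}

# Small single-molecule ensembles used across feature / grid tests.
tiny_ensemble <- function(smiles, seed = 1) {
  cached(paste0("ens_", smiles, "_", seed),
         generate_conformers(list(id = smiles, smiles = smiles), seed = seed))
}

# The congeneric series: alignment + fields (activity-independent).
series_cache <- function() {
  cached("series", {
    cfg <- run_config(seed = 1)
    list(config = cfg, internals = series_internals(20, cfg))
  })
}

# One trained run on the series (noise seed 1), with outputs on disk.
trained_cache <- function() {
  cached("trained", {
    sc <- series_cache()
    dir <- file.path(tempdir(), "autogpa_trained")
    ser <- make_congeneric_series(20, 0.1, seed = 1, dir = dir,
                                  config = sc$config,
                                  internals = sc$internals)
    dataset <- read_dataset(ser$path_structures, ser$path_activities)
    out_dir <- file.path(dir, "out")
    res <- run_train(dataset, sc$config, output_dir = out_dir,
                     ensembles = sc$internals$ensembles)
    list(series = ser, dataset = dataset, result = res, out_dir = out_dir,
         config = sc$config, internals = sc$internals)
  })
}

# Independent brute-force probe energies (the oracle used by several
# tests): plain double loop, separately coded from the package's
# vectorized implementation.
oracle_field_point <- function(coords, elements, charges, gp,
                               probe_R = 1.70, probe_eps = 0.107,
                               probe_q = 1.0) {
  vdw_R <- c(H = 1.50, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
             S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)
  vdw_e <- c(H = 0.042, C = 0.107, N = 0.095, O = 0.116, F = 0.109,
             P = 0.314, S = 0.314, Cl = 0.314, Br = 0.434, I = 0.623)
  st <- 0; el <- 0
  for (i in seq_len(nrow(coords))) {
    r <- sqrt(sum((coords[i, ] - gp)^2))
    if (r < 0.05) r <- 0.05
    Rs <- vdw_R[[elements[i]]] + probe_R
    es <- sqrt(vdw_e[[elements[i]]] * probe_eps)
    st <- st + es * ((Rs / r)^12 - 2 * (Rs / r)^6)
    el <- el + 332.0637 * charges[i] * probe_q / r^2
  }
  c(steric = st, electrostatic = el)
}
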