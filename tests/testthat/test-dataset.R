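test_that("dataset round-trips through write and load unchanged", {
  ds <- tiny_dataset(n_species = 8L, ensemble = 5L)
  path <- withr::local_tempfile(fileext = ".csv")
  epath <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path, epath)
  ds2 <- load_dataset(path, epath, surface = ds$surface)
  expect_equal(ds2$species, ds$species)
  expect_equal(ds2$energies, ds$energies, tolerance = 1e-12)
  expect_equal(unname(ds2$ensemble), unname(ds$ensemble), tolerance = 1e-12)
  expect_equal(functionals(ds2), functionals(ds))
})

test_that("loader reports offending species and functional for missing cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species_id,smiles,E_A,E_B",
               "s1,C,0.1,0.2",
               "s2,[CH3],,0.4"), path)
  expect_error(load_dataset(path), "s2/A")
  writeLines(c("species_id,smiles,E_A", "s1,C,0.1", "s1,CC,0.2"), path)
  expect_error(load_dataset(path), "duplicated species")
  writeLines(c("species_id,smiles,E_A", "s1,CX,0.1"), path)
  expect_error(load_dataset(path), "unparseable SMILES.*s1")
})

test_that("single-carbon enumeration is exactly the four CHx species", {
  expect_setequal(enumerate_intermediates(1L), c("C", "[CH3]", "[CH2]", "[CH]"))
})

test_that("the C3 family contains the stable backbones and round-trips", {
  e3 <- enumerate_intermediates(3L)
  expect_true(all(c("CCC", "C=CC", "C#CC") %in% e3))
  expect_false(any(duplicated(e3)))
  for (s in e3) expect_silent(parse_smiles(s))
  # every pairwise distinct entry is a distinct graph (spot check a slice)
  slice <- e3[seq(1, length(e3), by = 13)]
  for (i in seq_along(slice)) for (j in seq_len(i - 1L))
    expect_false(graph_isomorphic(parse_smiles(slice[i]), parse_smiles(slice[j])))
})

test_that("synthetic generation is a deterministic function of the config", {
  cfg <- synthetic_config(n_species = 10L, ensemble_members = 8L, seed = 42L)
  d1 <- generate_synthetic_dataset(cfg)
  d2 <- generate_synthetic_dataset(cfg)
  expect_identical(d1$energies, d2$energies)
  expect_identical(d1$ensemble, d2$ensemble)
  expect_identical(d1$species, d2$species)
})

test_that("degenerate generator settings collapse all functional columns", {
  cfg <- synthetic_config(n_species = 8L, noise_sd = 0, distortion_scale = 0,
                          functional_scale = 1, functional_offset = 0,
                          ensemble_members = 0L, seed = 3L)
  ds <- generate_synthetic_dataset(cfg)
  for (f in functionals(ds)[-1])
    expect_equal(ds$energies[, f], ds$energies[, 1], tolerance = 1e-12)
})

test_that("functional columns track the latent energy under default settings", {
  for (seed in 1:10) {
    ds <- generate_synthetic_dataset(synthetic_config(
      n_species = 40L, ensemble_members = 0L, seed = seed))
    g <- attr(ds, "latent")
    expect_true(all(cor(ds$energies, g) > 0.8), info = paste("seed", seed))
    spread <- apply(ds$energies, 1L, function(r) diff(range(r)))
    expect_gt(stats::var(spread), 0)
  }
})

test_that("stronger functional distortion increases cross-functional disagreement", {
  disagreement <- function(ds) {
    fn <- functionals(ds)
    m <- 0; cnt <- 0
    for (i in seq_along(fn)) for (j in seq_len(i - 1L)) {
      m <- m + mean(abs(ds$energies[, i] - ds$energies[, j])); cnt <- cnt + 1
    }
    m / cnt
  }
  for (seed in 1:5) {
    lo <- disagreement(generate_synthetic_dataset(synthetic_config(
      n_species = 20L, distortion_scale = 0.05, ensemble_members = 0L, seed = seed)))
    hi <- disagreement(generate_synthetic_dataset(synthetic_config(
      n_species = 20L, distortion_scale = 0.3, ensemble_members = 0L, seed = seed)))
    expect_gt(hi, lo)
  }
})

test_that("ensemble pseudo-functionals are less diverse than the functionals", {
  ds <- tiny_dataset(n_species = 15L, ensemble = 40L, seed = 11L)
  ens_spread <- mean(apply(ds$ensemble, 1L, stats::sd))
  fn_spread <- mean(apply(ds$energies, 1L, stats::sd))
  expect_lt(ens_spread, fn_spread)
})

test_that("dataset statistics summarise counts and mean absolute energies", {
  ds <- tiny_dataset(n_species = 9L, ensemble = 6L)
  st <- dataset_statistics(ds)
  expect_equal(st$n_species, 9L)
  expect_equal(st$ensemble_members, 6L)
  expect_equal(unname(st$mean_abs_energy["PBE-D3"]),
               mean(abs(ds$energies[, "PBE-D3"])))
})
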