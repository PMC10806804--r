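test_that("integrated gradients are exact for linear and constant predictors", {
  w <- c(2, -1, 0.5, 0)
  lin <- function(M) drop(M %*% w + 3)
  x <- c(1, 2, -1, 4)
  ig <- integrated_gradients(lin, x, steps = 5L)
  expect_equal(ig, w * x, tolerance = 1e-8)

  expect_equal(integrated_gradients(function(M) rep(7, nrow(M)), x),
               rep(0, 4), tolerance = 1e-10)
})

test_that("the midpoint rule integrates quadratic predictors exactly", {
  sq <- function(M) drop(M[, 1]^2)
  ig <- integrated_gradients(sq, x = 2, baseline = 0, steps = 50L)
  expect_equal(unname(ig), 4, tolerance = 1e-6)
  # completeness: f(x) - f(baseline) = 4 - 0
  ig2 <- integrated_gradients(sq, x = 3, baseline = 1, steps = 50L)
  expect_equal(unname(ig2), 9 - 1, tolerance = 1e-6)
})

test_that("attribution satisfies completeness through fitted model chains", {
  ds <- tiny_dataset(n_species = 14L, ensemble = 0L, seed = 17L)
  tr <- run_trial(ds, "flat24", "ffm", "PBE-D3",
                  regressors = c("ridge", "krr"), seed = 2L,
                  control = fast_control(epochs = 80L))
  FP <- imrcat:::dataset_fingerprints(ds, "flat24")
  baseline <- numeric(ncol(FP))
  for (m in c("ridge", "krr")) {
    chain <- trial_chain(tr, "imr", m)
    f0 <- chain(matrix(baseline, 1L, dimnames = list(NULL, colnames(FP))))
    for (i in c(1L, 7L)) {
      ig <- integrated_gradients(chain, FP[i, ], baseline = baseline,
                                 steps = 200L)
      gap <- chain(FP[i, , drop = FALSE]) - f0
      expect_equal(sum(ig), gap, tolerance = max(1e-3 * abs(gap), 1e-6))
    }
  }
})

test_that("features the model ignores receive zero attribution", {
  w <- c(1.5, 0, -2)
  lin <- function(M) drop(M %*% w)
  X <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), c("f1", "f2", "f3")))
  rep <- mean_absolute_attribution(lin, X, steps = 20L)
  expect_equal(unname(rep$mean_abs["f2"]), 0, tolerance = 1e-8)
  expect_true("f2" %in% rep$negligible)
  expect_equal(rep$threshold, 0.5 * max(rep$mean_abs))
  expect_setequal(rep$top_features,
                  names(rep$mean_abs)[rep$mean_abs >= rep$threshold])
})

test_that("duplicate species rows get identical attribution rows", {
  lin <- function(M) drop(M %*% c(1, -1))
  X <- matrix(c(2, 3, 2, 3), 2, 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("u", "v")))
  rep <- mean_absolute_attribution(lin, X, steps = 10L)
  expect_equal(rep$per_species["s1", ], rep$per_species["s2", ])
})

test_that("top-feature agreement is the Jaccard overlap", {
  mk <- function(top) structure(list(
    mean_abs = stats::setNames(rep(1, 4), c("H", "C", "C0", "C1")),
    top_features = top), class = "attribution_report")
  expect_equal(strategy_agreement(mk(c("H", "C")), mk(c("H", "C"))), 1)
  expect_equal(strategy_agreement(mk("H"), mk("C")), 0)
  expect_equal(strategy_agreement(mk(c("H", "C", "C0")), mk(c("H", "C", "C1"))),
               0.5)
  empty <- strategy_agreement(mk(character(0)), mk(character(0)))
  expect_true(is.na(empty))
  expect_true(attr(empty, "empty_union"))
})

test_that("attribution recovers the generative drivers of the latent energy", {
  cfg <- synthetic_config(
    n_species = 16L,
    latent_coefficients = c("H" = -1.5, "C-C" = -2.5),
    distortion_scale = 0.02, noise_sd = 0.01,
    ensemble_members = 0L, seed = 9L)
  ds <- generate_synthetic_dataset(cfg)
  tr <- run_trial(ds, "flat24", "ffm", "PBE-D3", regressors = "ridge",
                  seed = 1L)
  FP <- imrcat:::dataset_fingerprints(ds, "flat24")
  rep <- mean_absolute_attribution(trial_chain(tr, "imr", "ridge"), FP,
                                   steps = 50L)
  expect_true(all(c("H", "C-C") %in% rep$top_features))
})
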