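test_that("pair building enumerates canonical within-functional pairs", {
  ds <- tiny_dataset(n_species = 10L, ensemble = 6L)
  fns <- functionals(ds)
  p2 <- build_pairs(ds, fns[1:2])
  expect_equal(nrow(p2), 2 * choose(10, 2))
  expect_true(all(p2$species_a < p2$species_b))
  expect_false(any(p2$species_a == p2$species_b))
  # targets are within-functional energy differences
  i <- 17L
  expect_equal(p2$delta_e[i],
               ds$energies[p2$species_a[i], p2$functional[i]] -
                 ds$energies[p2$species_b[i], p2$functional[i]])
  # the pair count formula |functionals| * n(n-1)/2
  expect_equal(nrow(build_pairs(ds, fns)), 4 * 45)
  expect_equal(3 * 46 * 45 / 2, 3105)  # the full-family FFM pair count
  ds1 <- imrcat:::subset_dataset(ds, ds$species$species_id[1])
  expect_error(build_pairs(ds1, fns[1]), "fewer than 2")
})

test_that("ensemble draws are seeded, distinct and bounded", {
  ds <- tiny_dataset(n_species = 8L, ensemble = 30L)
  lab <- sample_beef_ensemble(ds, count = 12L, seed = 5L)
  expect_length(lab, 12L)
  expect_false(any(duplicated(lab)))
  expect_identical(lab, sample_beef_ensemble(ds, count = 12L, seed = 5L))
  expect_false(identical(lab, sample_beef_ensemble(ds, count = 12L, seed = 6L)))
  expect_setequal(sample_beef_ensemble(ds, count = 30L, seed = 1L),
                  colnames(ds$ensemble))
  expect_error(sample_beef_ensemble(ds, count = 31L), "cannot sample")
  ds_no <- tiny_dataset(n_species = 8L, ensemble = 0L)
  expect_error(sample_beef_ensemble(ds_no, 5L), "no ensemble")
})

test_that("constant-energy pairs train to near-zero predictions", {
  ds <- tiny_dataset(n_species = 8L, ensemble = 0L)
  ds$energies[, 1] <- 1.5  # constant functional: all pair deltas are zero
  pairs <- build_pairs(ds, functionals(ds)[1])
  FP <- fingerprint_matrix(stats::setNames(ds$species$smiles,
                                           ds$species$species_id), "flat24")
  m <- train_siamese(pairs, FP, k = 3L, config = fast_control(epochs = 300L))
  expect_lt(m$train_mae, 0.01)
  preds <- predict_pair_delta(m, FP[pairs$species_a, ], FP[pairs$species_b, ])
  expect_lt(max(abs(preds)), 0.05)
})

test_that("pair predictions are exactly antisymmetric and zero on self", {
  ds <- tiny_dataset(n_species = 8L, ensemble = 0L)
  m <- train_strategy(ds, "flat24", "ffm", "PBE-D3",
                      config = fast_control(epochs = 60L))
  FP <- imrcat:::dataset_fingerprints(ds, "flat24")
  for (i in 1:4) {
    x <- FP[i, ]; y <- FP[9L - i, ]
    expect_identical(predict_pair_delta(m, x, x), 0)
    expect_equal(predict_pair_delta(m, x, y), -predict_pair_delta(m, y, x),
                 tolerance = 1e-14)
  }
})

test_that("training is invariant to the order of the input pair list", {
  ds <- tiny_dataset(n_species = 7L, ensemble = 0L)
  pairs <- build_pairs(ds, functionals(ds)[2:3])
  FP <- imrcat:::dataset_fingerprints(ds, "flat24")
  cfg <- fast_control(epochs = 40L)
  m1 <- train_siamese(pairs, FP, k = 3L, config = cfg)
  set.seed(99)
  m2 <- train_siamese(pairs[sample(nrow(pairs)), ], FP, k = 3L, config = cfg)
  expect_identical(m1$subnet$W, m2$subnet$W)
  expect_identical(m1$head$W, m2$head$W)
})

test_that("training reduces the pair MAE from initialisation", {
  ds <- tiny_dataset(n_species = 10L, ensemble = 0L, seed = 21L)
  m <- train_strategy(ds, "flat24", "ffm", "RPBE",
                      config = fast_control(epochs = 250L))
  expect_lt(m$final_train_mae, m$initial_train_mae)
  expect_lt(m$train_mae, 0.5 * m$initial_train_mae)
})

test_that("strategies route the pair sources as specified", {
  ds <- tiny_dataset(n_species = 9L, ensemble = 25L)
  ctl <- fast_control(epochs = 25L)
  ffm <- train_strategy(ds, "flat24", "ffm", "PBE-D3", config = ctl)
  expect_setequal(unique(ffm$pairs$functional),
                  setdiff(functionals(ds), "PBE-D3"))
  expect_equal(ffm$n_pairs, 3 * choose(9, 2))

  bem <- train_strategy(ds, "flat24", "bem", "PBE-D3",
                        config = { c <- ctl; c$bem_count <- 10L; c })
  expect_length(unique(bem$pairs$functional), 10L)
  expect_true(all(unique(bem$pairs$functional) %in% colnames(ds$ensemble)))
  expect_equal(bem$n_pairs, 10 * choose(9, 2))

  split <- ds$species$species_id[1:6]
  fsm <- train_strategy(ds, "flat24", "fsm", "PBE-D3", config = ctl,
                        train_species = split)
  expect_equal(unique(fsm$pairs$functional), "PBE-D3")
  expect_equal(fsm$n_pairs, choose(6, 2))
  expect_setequal(unique(c(fsm$pairs$species_a, fsm$pairs$species_b)), split)

  expect_error(train_strategy(ds, "flat24", "fsm", "PBE-D3", config = ctl),
               "training-split")
  ds2 <- ds
  ds2$energies <- ds2$energies[, 1:2]
  expect_error(train_strategy(ds2, "flat24", "ffm", "PBE-D3", config = ctl),
               "at least 2 functionals")
})

test_that("the representation is deterministic with the matched dimension", {
  ds <- tiny_dataset(n_species = 8L, ensemble = 0L)
  FP <- imrcat:::dataset_fingerprints(ds, "flat24")
  k_pca <- fit_pca(FP, 0.98)$k
  m <- train_strategy(ds, "flat24", "ffm", "RPBE", config = fast_control(epochs = 30L))
  expect_equal(m$k, k_pca)
  Z1 <- imr_embed(m, FP)
  expect_identical(Z1, imr_embed(m, FP))
  expect_equal(ncol(Z1), k_pca)
  # identical fingerprints map to identical representations
  expect_equal(imr_embed(m, FP[3, ]), imr_embed(m, FP[3, , drop = FALSE]),
               ignore_attr = TRUE)
  expect_error(imr_embed(m, FP[, 1:10]), "width")
})

test_that("scaling all pair targets scales the best constant-predictor loss", {
  ds <- tiny_dataset(n_species = 10L, ensemble = 0L)
  t0 <- build_pairs(ds, functionals(ds)[1])$delta_e
  const_loss <- function(t) mean(abs(t - stats::median(t)))
  for (c in c(0.5, 2, -3))
    expect_equal(const_loss(c * t0), abs(c) * const_loss(t0), tolerance = 1e-12)
})

test_that("training shrinks cross-functional residual spread for fixed pairs", {
  ds <- tiny_dataset(n_species = 10L, ensemble = 0L, seed = 13L)
  fns <- setdiff(functionals(ds), "PBE-D3")
  pairs <- build_pairs(ds, fns)
  FP <- imrcat:::dataset_fingerprints(ds, "flat24")
  trained <- train_siamese(pairs, FP, k = 4L, config = fast_control(epochs = 300L))
  untrained <- train_siamese(pairs, FP, k = 4L,
                             config = fast_control(epochs = 1L))
  resid_sq <- function(m) {
    key <- paste(pairs$species_a, pairs$species_b)
    pred <- predict_pair_delta(m, FP[pairs$species_a, ], FP[pairs$species_b, ])
    mean((pred - pairs$delta_e)^2)
  }
  expect_lt(resid_sq(trained), resid_sq(untrained))
})

test_that("imr() returns a full-featured model object", {
  ds <- tiny_dataset(n_species = 8L, ensemble = 0L)
  fit <- imr(ds, strategy = "ffm", test_functional = "RPBE",
             control = fast_control(epochs = 40L))
  expect_s3_class(fit, "imr")
  expect_output(print(fit), "strategy: FFM")
  expect_output(summary(fit), "bias-free")
  expect_type(coef(fit), "list")
  r <- residuals(fit)
  expect_length(r, fit$n_pairs)
  expect_equal(mean(abs(r)), fit$train_mae, tolerance = 1e-12)
  Z <- predict(fit, ds)
  expect_equal(dim(Z), c(8L, fit$k))
  d <- predict(fit, list(ds$species$smiles[1], ds$species$smiles[2]),
               type = "delta")
  expect_equal(d, -predict(fit, list(ds$species$smiles[2],
                                     ds$species$smiles[1]), type = "delta"),
               tolerance = 1e-12)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
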