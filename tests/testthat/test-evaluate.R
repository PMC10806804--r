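test_that("mean absolute error matches hand arithmetic", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(0, 2), c(1, 1)), 1.0)
  expect_equal(mae(c(0.43, -0.81, 0.37), c(0.5, -0.7, 0.3)), 0.25 / 3)
  expect_error(mae(1:3, 1:2), "equal-length")
})

test_that("D2 score is anchored at the null and perfect predictors", {
  y_tr <- c(0, 2, 4)
  expect_equal(d2_score(c(1, 3), c(1, 3), y_tr), 1)
  expect_equal(d2_score(c(1, 3), c(2, 2), y_tr), 0)      # worked example
  expect_equal(d2_score(c(1, 3), rep(stats::median(y_tr), 2), y_tr), 0)
  expect_lt(d2_score(c(1, 3), c(5, -5), y_tr), 0)
  s <- d2_score(c(2, 2), c(1, 1), c(2, 2, 2))            # zero null deviance
  expect_true(is.na(s))
  expect_true(attr(s, "undefined_null"))
  expect_lte(d2_score(rnorm(5), rnorm(5), rnorm(5)), 1)
})

test_that("representation comparison t-tests behave at the edges", {
  same <- c(0.3, 0.31, 0.29, 0.3)
  out <- compare_representations(same, same)
  expect_equal(out$p_value, 1, tolerance = 1e-12)
  expect_false(out$significant)

  a <- c(0.30, 0.31, 0.32, 0.33)
  b <- c(0.10, 0.11, 0.12, 0.13)
  out2 <- compare_representations(a, b)
  expect_lt(out2$p_value, 0.001)
  expect_true(out2$significant)
  # closed-form Welch statistic as an independent check
  tstat <- (mean(a) - mean(b)) / sqrt(var(a) / 4 + var(b) / 4)
  df <- (var(a) / 4 + var(b) / 4)^2 /
    ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  p_manual <- 2 * stats::pt(-abs(tstat), df)
  expect_equal(out2$p_value, p_manual, tolerance = 1e-10)

  expect_false(compare_representations(a, b, alpha = 0)$significant)
  expect_equal(compare_representations(rep(1, 3), rep(2, 3))$p_value, 0)
  paired <- compare_representations(a, a + 0.05, paired = TRUE)
  expect_lt(paired$p_value, 1e-6)
})

test_that("trials split species 2:1 with clean train/test hygiene", {
  ds <- tiny_dataset(n_species = 12L, ensemble = 0L)
  tr <- run_trial(ds, "flat24", "ffm", "PBE-D3", regressors = "ridge",
                  seed = 3L, control = fast_control(epochs = 60L))
  expect_length(tr$test_ids, round(12 / 3))
  expect_length(intersect(tr$train_ids, tr$test_ids), 0L)
  expect_setequal(c(tr$train_ids, tr$test_ids), ds$species$species_id)
  expect_equal(tr$results$representation, c("original", "pca", "imr"))
  expect_true(all(tr$results$mae >= 0))
  expect_true(all(tr$results$d2 <= 1))
  # FSM uses only training-split species for its pairs
  fsm <- run_trial(ds, "flat24", "fsm", "PBE-D3", regressors = "ridge",
                   seed = 3L, control = fast_control(epochs = 40L))
  expect_setequal(unique(c(fsm$imr_model$pairs$species_a,
                           fsm$imr_model$pairs$species_b)), fsm$train_ids)
  expect_error(run_trial(ds, "flat24", "ffm", "PBE-D3",
                         regressors = "lasso", seed = 1L),
               "unknown regressor")
})

test_that("a seeded trial is exactly reproducible", {
  ds <- tiny_dataset(n_species = 10L, ensemble = 0L)
  t1 <- run_trial(ds, "flat24", "ffm", "RPBE", regressors = c("ridge", "krr"),
                  seed = 8L, control = fast_control(epochs = 50L))
  t2 <- run_trial(ds, "flat24", "ffm", "RPBE", regressors = c("ridge", "krr"),
                  seed = 8L, control = fast_control(epochs = 50L))
  expect_identical(t1$results, t2$results)
  expect_identical(t1$test_ids, t2$test_ids)
})

test_that("a noiseless linear target is fit to near-zero error on raw features", {
  cfg <- synthetic_config(n_species = 30L, noise_sd = 0, distortion_scale = 0,
                          functional_scale = 1, functional_offset = 0,
                          ensemble_members = 0L, seed = 5L)
  ds <- generate_synthetic_dataset(cfg)
  tr <- run_trial(ds, "flat24", "ffm", "PBE-D3", regressors = "ridge",
                  seed = 2L, control = fast_control(epochs = 30L))
  row <- tr$results[tr$results$representation == "original", ]
  expect_lt(row$mae, 1e-3)
})

test_that("noise added to predictions cannot improve the expected MAE", {
  set.seed(31)
  y <- rnorm(40); pred <- y + rnorm(40, sd = 0.3)
  base <- mae(y, pred)
  for (sigma in c(0.1, 0.5, 1)) {
    noisy <- mean(replicate(300, mae(y, pred + rnorm(40, sd = sigma))))
    expect_gte(noisy, base)
  }
})

test_that("experiment aggregation has the promised shape", {
  ds <- tiny_dataset(n_species = 10L, ensemble = 0L)
  ex <- run_experiment(ds, "flat24", "ffm",
                       test_functionals = c("PBE-D3", "RPBE"),
                       regressors = c("ridge", "krr"), n_trials = 2L,
                       base_seed = 1L, control = fast_control(epochs = 40L))
  expect_equal(nrow(ex$table), 2L * 2L)
  expect_true(all(c("mae_original", "mae_pca", "mae_imr",
                    "p_imr_vs_pca", "sig_imr_vs_pca") %in% names(ex$table)))
  expect_output(print(ex), "three molecular representations")
  expect_s3_class(as.data.frame(ex), "data.frame")

  ex1 <- run_experiment(ds, "flat24", "ffm", test_functionals = "PBE-D3",
                        regressors = "ridge", n_trials = 1L, base_seed = 4L,
                        control = fast_control(epochs = 40L))
  expect_equal(ex1$table$sd_imr, 0)
  expect_true(is.na(ex1$table$p_imr_vs_pca))
})
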