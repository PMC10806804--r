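#' Mean absolute error
#'
#' @param y_true,y_pred Numeric vectors of equal length (eV).
#' @return Mean of absolute differences (eV).
#' @export
mae <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1L)
    stop("mae: inputs must be equal-length, non-empty vectors", call. = FALSE)
  mean(abs(y_true - y_pred))
}

#' D-squared goodness-of-fit score with a median null model
#'
#' `1 - sum|y - yhat| / sum|y - median(y_train)|`: the fraction of
#' absolute-error deviance explained relative to a null predictor that
#' always outputs the training median. 1 is a perfect fit, 0 matches the
#' null model, negative values are worse than the null.
#'
#' @param y_true_test,y_pred_test Test energies and predictions (eV).
#' @param y_train Training energies whose median defines the null model.
#' @return The score; if the null deviance is zero the score is undefined
#'   and `NA` is returned with attribute `undefined_null = TRUE`.
#' @export
d2_score <- function(y_true_test, y_pred_test, y_train) {
  if (length(y_true_test) != length(y_pred_test) || length(y_true_test) < 1L)
    stop("d2_score: test vectors must be equal-length and non-empty", call. = FALSE)
  if (length(y_train) < 1L)
    stop("d2_score: y_train must be non-empty", call. = FALSE)
  null_dev <- sum(abs(y_true_test - stats::median(y_train)))
  if (null_dev == 0)
    return(structure(NA_real_, undefined_null = TRUE))
  1 - sum(abs(y_true_test - y_pred_test)) / null_dev
}

#' Compare per-trial MAEs of two representations by t-test
#'
#' Two-sided Welch t-test by default; a paired t-test is available since
#' trials share train/test splits across representations. Two identical
#' zero-variance samples yield p = 1 by convention.
#'
#' @param mae_a,mae_b Per-trial MAE vectors of equal length (>= 2).
#' @param alpha Significance level (default 0.05).
#' @param paired Use a paired t-test.
#' @return List with `p_value` and `significant` (`p < alpha`).
#' @export
compare_representations <- function(mae_a, mae_b, alpha = 0.05,
                                    paired = FALSE) {
  stopifnot(length(mae_a) == length(mae_b), length(mae_a) >= 2L)
  degenerate <- if (paired) stats::var(mae_a - mae_b) == 0 else
    (stats::var(mae_a) == 0 && stats::var(mae_b) == 0)
  if (degenerate) {
    same <- if (paired) all(mae_a == mae_b) else mean(mae_a) == mean(mae_b)
    p <- if (same) 1 else 0
  } else {
    p <- stats::t.test(mae_a, mae_b, paired = paired,
                       var.equal = FALSE)$p.value
  }
  list(p_value = p, significant = p < alpha)
}

#' Run one evaluation trial
#'
#' One trial of the evaluation protocol: split the test functional's
#' species 2:1 into training and test sets (test size = round(n/3)); build
#' the three representation providers (PCA and all downstream fitting on
#' the training split only; the Siamese model per the strategy, with its
#' representation size matched to the PCA dimension); then for each
#' requested regressor, select hyperparameters by 5-fold CV MAE on the
#' training split, refit, and record test MAE and D2 score.
#'
#' @param dataset A `catalysis_dataset`.
#' @param fingerprint_kind `"flat24"`, `"morgan24"` or `"embedding"`.
#' @param strategy `"ffm"`, `"bem"` or `"fsm"`.
#' @param test_functional Functional to hold out and predict.
#' @param regressors Subset of `c("ridge", "elastic", "krr", "svr")`.
#' @param seed Trial seed (controls split, CV folds and Siamese training).
#' @param control A [siamese_control()].
#' @param variance_threshold PCA explained-variance threshold.
#' @param grids Hyperparameter grids, see [default_grids()].
#' @param embeddings Optional embedding map for
#'   `fingerprint_kind = "embedding"`.
#' @return Object of class `imr_trial`: split indices, representation
#'   dimension `k`, and a results table with one row per
#'   (representation, regressor) holding test MAE (eV) and D2 score.
#' @export
run_trial <- function(dataset, fingerprint_kind = "flat24",
                      strategy = c("ffm", "bem", "fsm"),
                      test_functional,
                      regressors = c("ridge", "elastic", "krr", "svr"),
                      seed = 1L, control = siamese_control(),
                      variance_threshold = 0.98, grids = default_grids(),
                      embeddings = NULL) {
  strategy <- match.arg(strategy)
  bad <- setdiff(regressors, c("ridge", "elastic", "krr", "svr"))
  if (length(bad) > 0L)
    stop(sprintf("unknown regressor label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  ids <- dataset$species$species_id
  n <- length(ids)
  y <- stats::setNames(dataset$energies[, test_functional], ids)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "trial-split"))
  test_ids <- c_sort(sample(ids, round(n / 3)))
  train_ids <- setdiff(ids, test_ids)

  FP <- dataset_fingerprints(dataset, fingerprint_kind, embeddings)
  pca <- fit_pca(FP[train_ids, , drop = FALSE], variance_threshold)
  imr_model <- train_strategy(dataset, fingerprint_kind, strategy,
                              test_functional, k = pca$k, config = control,
                              seed = derive_seed(seed, "trial-imr"),
                              train_species = train_ids,
                              embeddings = embeddings)
  providers <- list(
    original = representation_provider("original", d = ncol(FP)),
    pca = representation_provider("pca", pca),
    imr = representation_provider("imr", imr_model))

  set.seed(derive_seed(seed, "trial-folds"))
  folds <- sample(rep_len(1:5, length(train_ids)))

  rows <- list()
  fits <- list()
  for (rep_name in names(providers)) {
    R <- transform_representation(providers[[rep_name]], FP)
    rownames(R) <- rownames(FP)
    sc <- scaler_fit(R[train_ids, , drop = FALSE])
    Rz <- scaler_apply(R, sc)
    for (m in regressors) {
      fit <- fit_regressor(m, Rz[train_ids, , drop = FALSE], y[train_ids],
                           folds = folds, grid = grids[[m]])
      pred <- predict(fit, Rz[test_ids, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        representation = rep_name, regressor = m,
        mae = mae(y[test_ids], pred),
        d2 = as.numeric(d2_score(y[test_ids], pred, y[train_ids])),
        stringsAsFactors = FALSE)
      fits[[paste(rep_name, m, sep = ".")]] <-
        list(fit = fit, scaler = sc, provider = providers[[rep_name]],
             predictions = stats::setNames(pred, test_ids))
    }
  }
  structure(list(seed = seed, test_functional = test_functional,
                 strategy = strategy, fingerprint = fingerprint_kind,
                 train_ids = train_ids, test_ids = test_ids,
                 k = pca$k, results = do.call(rbind, rows),
                 fits = fits, imr_model = imr_model, pca = pca),
            class = "imr_trial")
}

#' @export
print.imr_trial <- function(x, ...) {
  cat(sprintf("trial (seed %s): %s / %s, test functional %s, k = %d\n",
              format(x$seed), toupper(x$strategy), x$fingerprint,
              x$test_functional, x$k))
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' End-to-end prediction chain of a fitted trial combination
#'
#' Returns `function(fingerprint_matrix) -> predicted energies (eV)`
#' composing representation transform, feature scaling and the fitted
#' regressor — the attribution target for [mean_absolute_attribution()].
#'
#' @param trial An `imr_trial`.
#' @param representation `"original"`, `"pca"` or `"imr"`.
#' @param regressor Regressor label fitted in the trial.
#' @return A vectorised prediction function over fingerprint rows.
#' @export
trial_chain <- function(trial, representation = "imr", regressor = "ridge") {
  key <- paste(representation, regressor, sep = ".")
  entry <- trial$fits[[key]]
  if (is.null(entry))
    stop(sprintf("combination %s not fitted in this trial", key), call. = FALSE)
  function(M) {
    R <- transform_representation(entry$provider, M)
    as.numeric(predict(entry$fit, scaler_apply(R, entry$scaler)))
  }
}

#' Run the full multi-trial evaluation experiment
#'
#' The evaluation protocol over `n_trials` seeded trials per test
#' functional: per (functional, regressor, representation) mean and
#' standard deviation of test MAE, Welch t-tests of IMR against the PCA
#' and Original baselines at `alpha`, and mean D2 scores.
#'
#' @inheritParams run_trial
#' @param test_functionals Functionals to evaluate (default: all).
#' @param n_trials Trials per functional (default 10).
#' @param base_seed Trials use seeds `base_seed + 0:(n_trials-1)`.
#' @param alpha Significance level for the t-tests.
#' @param paired Use paired t-tests (trials share splits).
#' @return Object of class `imr_experiment`: `table` (aggregated results),
#'   `trial_mae` (per-trial MAE array), and the resolved settings.
#' @export
run_experiment <- function(dataset, fingerprint_kind = "flat24",
                           strategy = c("ffm", "bem", "fsm"),
                           test_functionals = functionals(dataset),
                           regressors = c("ridge", "elastic", "krr", "svr"),
                           n_trials = 10L, base_seed = 0L,
                           control = siamese_control(),
                           variance_threshold = 0.98,
                           grids = default_grids(),
                           alpha = 0.05, paired = FALSE,
                           embeddings = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(n_trials >= 1L)
  reps <- c("original", "pca", "imr")
  seeds <- base_seed + seq_len(n_trials) - 1L

  trial_mae <- array(NA_real_,
                     dim = c(length(test_functionals), length(regressors),
                             length(reps), n_trials),
                     dimnames = list(test_functionals, regressors, reps, NULL))
  trial_d2 <- trial_mae
  trials <- list()
  for (fi in seq_along(test_functionals)) {
    for (ti in seq_len(n_trials)) {
      tr <- run_trial(dataset, fingerprint_kind, strategy,
                      test_functionals[fi], regressors, seed = seeds[ti],
                      control = control,
                      variance_threshold = variance_threshold,
                      grids = grids, embeddings = embeddings)
      trials[[sprintf("%s.%d", test_functionals[fi], seeds[ti])]] <- tr
      for (r in seq_len(nrow(tr$results))) {
        row <- tr$results[r, ]
        trial_mae[fi, row$regressor, row$representation, ti] <- row$mae
        trial_d2[fi, row$regressor, row$representation, ti] <- row$d2
      }
    }
  }

  rows <- list()
  for (fi in seq_along(test_functionals)) for (m in regressors) {
    stats_row <- list(functional = test_functionals[fi], regressor = m)
    for (rp in reps) {
      v <- trial_mae[fi, m, rp, ]
      stats_row[[paste0("mae_", rp)]] <- mean(v)
      stats_row[[paste0("sd_", rp)]] <- if (n_trials > 1L) stats::sd(v) else 0
      stats_row[[paste0("d2_", rp)]] <- mean(trial_d2[fi, m, rp, ], na.rm = TRUE)
    }
    if (n_trials >= 2L) {
      cmp_pca <- compare_representations(trial_mae[fi, m, "imr", ],
                                         trial_mae[fi, m, "pca", ],
                                         alpha = alpha, paired = paired)
      cmp_orig <- compare_representations(trial_mae[fi, m, "imr", ],
                                          trial_mae[fi, m, "original", ],
                                          alpha = alpha, paired = paired)
      stats_row$p_imr_vs_pca <- cmp_pca$p_value
      stats_row$sig_imr_vs_pca <- cmp_pca$significant
      stats_row$p_imr_vs_original <- cmp_orig$p_value
      stats_row$sig_imr_vs_original <- cmp_orig$significant
    } else {
      stats_row$p_imr_vs_pca <- NA_real_
      stats_row$sig_imr_vs_pca <- NA
      stats_row$p_imr_vs_original <- NA_real_
      stats_row$sig_imr_vs_original <- NA
    }
    rows[[length(rows) + 1L]] <- as.data.frame(stats_row,
                                               stringsAsFactors = FALSE)
  }

  structure(list(table = do.call(rbind, rows),
                 trial_mae = trial_mae, trial_d2 = trial_d2,
                 trials = trials,
                 settings = list(fingerprint = fingerprint_kind,
                                 strategy = strategy, n_trials = n_trials,
                                 base_seed = base_seed, alpha = alpha,
                                 paired = paired,
                                 variance_threshold = variance_threshold,
                                 regressors = regressors)),
            class = "imr_experiment")
}

#' @export
print.imr_experiment <- function(x, digits = 2, ...) {
  s <- x$settings
  cat(sprintf("Evaluation of three molecular representations (%s, %s fingerprints, %d trials)\n",
              toupper(s$strategy), s$fingerprint, s$n_trials))
  cat("Test MAE in eV (mean ± sd over trials); * marks IMR significantly different from PCA\n\n")
  fmt <- function(m, sd) sprintf(paste0("%.", digits, "f ± %.", digits, "f"), m, sd)
  tb <- x$table
  out <- data.frame(functional = tb$functional, regressor = tb$regressor,
                    original = fmt(tb$mae_original, tb$sd_original),
                    PCA = fmt(tb$mae_pca, tb$sd_pca),
                    IMR = paste0(fmt(tb$mae_imr, tb$sd_imr),
                                 ifelse(!is.na(tb$sig_imr_vs_pca) & tb$sig_imr_vs_pca,
                                        " *", "")))
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.imr_experiment <- function(x, ...) x$table

#' @export
summary.imr_experiment <- function(object, ...) {
  print(object)
  tb <- object$table
  cat(sprintf("\nIMR beats PCA in %d/%d rows (significant in %d); beats Original in %d/%d\n",
              sum(tb$mae_imr < tb$mae_pca), nrow(tb),
              sum(tb$sig_imr_vs_pca & tb$mae_imr < tb$mae_pca, na.rm = TRUE),
              sum(tb$mae_imr < tb$mae_original), nrow(tb)))
  invisible(object)
}
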