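#' Build within-functional species pairs
#'
#' Enumerates all unordered species pairs within each listed functional and
#' records the relative adsorption-energy difference `E(a) - E(b)` (eV) as
#' the pair target. Orientation is canonical: `species_a < species_b` by id.
#' Labels may name either a functional column or, when the dataset carries
#' an ensemble matrix, an ensemble member (pseudo-functional).
#'
#' @param dataset A `catalysis_dataset`.
#' @param functionals Character vector of functional or ensemble-member
#'   labels.
#' @return Data frame with columns `species_a`, `species_b`, `functional`,
#'   `delta_e`; `length(functionals) * n(n-1)/2` rows.
#' @export
build_pairs <- function(dataset, functionals) {
  stopifnot(inherits(dataset, "catalysis_dataset"))
  ids <- c_sort(dataset$species$species_id)
  n <- length(ids)
  if (n < 2L)
    stop("cannot build pairs from fewer than 2 species", call. = FALSE)
  idx <- utils::combn(n, 2L)
  out <- vector("list", length(functionals))
  for (f in seq_along(functionals)) {
    e <- energy_column(dataset, functionals[f])
    a <- ids[idx[1L, ]]
    b <- ids[idx[2L, ]]
    out[[f]] <- data.frame(species_a = a, species_b = b,
                           functional = functionals[f],
                           delta_e = e[a] - e[b],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# look a label up among functional columns, then ensemble members
energy_column <- function(dataset, label) {
  if (label %in% colnames(dataset$energies)) {
    e <- dataset$energies[, label]
  } else if (!is.null(dataset$ensemble) && label %in% colnames(dataset$ensemble)) {
    e <- dataset$ensemble[, label]
  } else {
    stop(sprintf("unknown functional or ensemble label: %s", label), call. = FALSE)
  }
  stats::setNames(e, dataset$species$species_id)
}

#' Draw pseudo-functionals from the functional ensemble
#'
#' Selects `count` distinct ensemble columns uniformly without replacement.
#' Each selected member can then be treated as a distinct functional by
#' [build_pairs()].
#'
#' @param dataset A `catalysis_dataset` with an ensemble matrix.
#' @param count Number of members to draw (default 50).
#' @param seed Integer seed for the draw.
#' @return Character vector of `count` ensemble column labels.
#' @export
sample_beef_ensemble <- function(dataset, count = 50L, seed = 1L) {
  stopifnot(inherits(dataset, "catalysis_dataset"))
  if (is.null(dataset$ensemble))
    stop("dataset has no ensemble energies", call. = FALSE)
  M <- ncol(dataset$ensemble)
  if (count > M)
    stop(sprintf("cannot sample %d ensemble members from %d", count, M),
         call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  c_sort(sample(colnames(dataset$ensemble), count))
}

#' Training control for the Siamese model
#'
#' @param hidden Hidden layer sizes of the twin subnetwork (tanh).
#' @param head_hidden Hidden layer sizes of the readout head (tanh, no
#'   bias anywhere in the head so that it is an exactly odd function).
#' @param epochs Maximum total number of full-batch Adam epochs across all
#'   learning-rate stages.
#' @param lr Adam learning rates, one per stage: after a stage stops
#'   improving, training restarts from the best weights so far at the next
#'   (smaller) rate. A single value gives single-stage training.
#' @param patience Early-stopping patience per stage, in epochs without
#'   improvement of the monitored pair MAE (recycled to the number of
#'   stages).
#' @param monitor_every Evaluate the monitored MAE every this many epochs.
#' @param holdout_fraction Fraction of pairs held out to monitor early
#'   stopping (0 disables the holdout; training MAE is monitored instead).
#' @param bem_count Ensemble members drawn per BEM training run.
#' @param seed Seed controlling weight initialisation and the holdout draw.
#' @return A list of class `siamese_control`.
#' @export
siamese_control <- function(hidden = c(32L, 32L), head_hidden = 8L,
                            epochs = 1000L, lr = c(5e-3, 1.5e-3),
                            patience = c(60L, 120L), monitor_every = 5L,
                            holdout_fraction = 0.1, bem_count = 50L,
                            seed = 1L) {
  stopifnot(epochs >= 1L, all(lr > 0), monitor_every >= 1L,
            holdout_fraction >= 0, holdout_fraction < 1)
  structure(list(hidden = as.integer(hidden),
                 head_hidden = as.integer(head_hidden),
                 epochs = as.integer(epochs), lr = lr,
                 patience = as.integer(rep_len(patience, length(lr))),
                 monitor_every = as.integer(monitor_every),
                 bem_count = as.integer(bem_count),
                 holdout_fraction = holdout_fraction,
                 seed = as.integer(seed)),
            class = "siamese_control")
}

# deterministic 31-bit sub-seed derivation
derive_seed <- function(seed, salt) {
  (as.numeric(seed) %% 2147483647 * 48271 + stable_hash(salt)) %% 2147483646 + 1
}

#' Train the Siamese network on energy-difference pairs
#'
#' Fits twin subnetworks (shared weights) mapping fingerprints to a
#' k-dimensional representation, and a bias-free odd readout head mapping
#' the difference of twin outputs to the predicted pair energy difference.
#' The loss is the mean absolute error over pairs, minimised by full-batch
#' Adam; because the head is odd by construction, swap antisymmetry
#' `f(a,b) = -f(b,a)` and `f(a,a) = 0` hold exactly at all times. Pairs are
#' canonically re-sorted internally, so the result does not depend on the
#' order of the input pair list.
#'
#' @param pairs Data frame from [build_pairs()].
#' @param fingerprints Named list of fingerprint vectors or a numeric
#'   matrix with species ids as rownames.
#' @param k Representation size (typically matched to the PCA dimension
#'   for the same fingerprint kind).
#' @param config A [siamese_control()].
#' @return An object of class `imr`; see [imr()] for the methods.
#' @export
train_siamese <- function(pairs, fingerprints, k, config = siamese_control()) {
  stopifnot(k >= 1L, is.data.frame(pairs), nrow(pairs) >= 1L)
  if (any(pairs$species_a == pairs$species_b))
    stop("pair list contains a self-pair", call. = FALSE)
  FP <- as_fp_matrix(fingerprints)
  missing_sp <- setdiff(unique(c(pairs$species_a, pairs$species_b)), rownames(FP))
  if (length(missing_sp) > 0L)
    stop(sprintf("no fingerprint for species: %s",
                 paste(missing_sp, collapse = ", ")), call. = FALSE)
  d <- ncol(FP)
  if (k > d)
    warning(sprintf("representation size k = %d exceeds fingerprint width d = %d (over-complete)",
                    k, d), call. = FALSE)

  # canonical order: invariant to how the caller sorted the pairs
  pairs <- pairs[order(pairs$functional, pairs$species_a, pairs$species_b,
                       method = "radix"), , drop = FALSE]

  species <- c_sort(unique(c(pairs$species_a, pairs$species_b)))
  X <- FP[species, , drop = FALSE]
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xz <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")

  ai <- match(pairs$species_a, species)
  bi <- match(pairs$species_b, species)
  target <- pairs$delta_e

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, "siamese-init"))
  sub <- mlp_init(c(d, config$hidden, k), bias = TRUE)
  head <- mlp_init(c(k, config$head_hidden, 1L), bias = FALSE)

  P <- nrow(pairs)
  n_hold <- floor(config$holdout_fraction * P)
  hold <- if (n_hold >= 1L) sort(sample(P, n_hold)) else integer(0)
  tr <- if (length(hold) > 0L) setdiff(seq_len(P), hold) else seq_len(P)

  pair_mae <- function(sub, head, idx) {
    Z <- mlp_forward(sub, Xz)$out
    D <- Z[ai[idx], , drop = FALSE] - Z[bi[idx], , drop = FALSE]
    pred <- drop(mlp_forward(head, D)$out)
    mean(abs(pred - target[idx]))
  }

  n_sp <- length(species)
  # fixed signed incidence matrix: accumulates pair gradients onto species
  Sgn <- Matrix::sparseMatrix(i = c(seq_along(tr), seq_along(tr)),
                              j = c(ai[tr], bi[tr]),
                              x = rep(c(1, -1), each = length(tr)),
                              dims = c(length(tr), n_sp))
  SgnT <- Matrix::t(Sgn)

  history <- matrix(NA_real_, config$epochs, 2L,
                    dimnames = list(NULL, c("train_mae", "monitor_mae")))
  best <- list(mae = Inf, sub = sub, head = head, epoch = 0L)
  initial_train_mae <- pair_mae(sub, head, tr)
  epoch <- 0L
  monitor_idx <- if (length(hold) > 0L) hold else tr

  for (stage in seq_along(config$lr)) {
    lr <- config$lr[stage]
    check_patience <- max(1L, ceiling(config$patience[stage] /
                                        config$monitor_every))
    sub <- best$sub; head <- best$head   # later stages resume from the best
    params <- list(subW = sub$W, subb = sub$b, headW = head$W)
    opt <- adam_init(params)
    stall <- 0L

    while (epoch < config$epochs) {
      epoch <- epoch + 1L
      fw_sub <- mlp_forward(sub, Xz)
      Z <- fw_sub$out
      D <- Z[ai[tr], , drop = FALSE] - Z[bi[tr], , drop = FALSE]
      fw_head <- mlp_forward(head, D)
      pred <- drop(fw_head$out)
      err <- pred - target[tr]
      train_mae <- mean(abs(err))
      if (!is.finite(train_mae))
        stop(sprintf(paste0("Siamese training diverged (non-finite loss) with ",
                            "hidden=%s, head_hidden=%s, lr=%s, epochs=%d"),
                     paste(config$hidden, collapse = "x"),
                     paste(config$head_hidden, collapse = "x"),
                     paste(config$lr, collapse = "/"),
                     config$epochs), call. = FALSE)

      g_pred <- matrix(sign(err) / length(err), ncol = 1L)
      bk_head <- mlp_backward(head, fw_head, g_pred)
      dZ <- as.matrix(SgnT %*% bk_head$dX)
      bk_sub <- mlp_backward(sub, fw_sub, dZ)

      grads <- list(subW = bk_sub$dW, subb = bk_sub$db, headW = bk_head$dW)
      stepped <- adam_step(params, grads, opt, lr = lr)
      params <- stepped$params
      opt <- stepped$state
      sub$W <- params$subW; sub$b <- params$subb; head$W <- params$headW

      if (epoch %% config$monitor_every == 0L || epoch == config$epochs) {
        monitor <- pair_mae(sub, head, monitor_idx)
        history[epoch, ] <- c(train_mae, monitor)
        if (monitor < best$mae - 1e-9) {
          best <- list(mae = monitor, sub = sub, head = head, epoch = epoch)
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= check_patience) break
        }
      } else {
        history[epoch, 1L] <- train_mae
      }
    }
  }
  epochs_run <- epoch
  sub <- best$sub; head <- best$head

  final_train_mae <- pair_mae(sub, head, tr)
  all_pair_mae <- pair_mae(sub, head, seq_len(P))
  structure(list(subnet = sub, head = head,
                 k = as.integer(k), d = d,
                 schema = colnames(FP),
                 center = ctr, scale = scl,
                 species = species,
                 fingerprints = X,
                 pairs = pairs,
                 n_pairs = P,
                 config = config,
                 history = history[seq_len(epochs_run), , drop = FALSE],
                 best_epoch = best$epoch,
                 initial_train_mae = initial_train_mae,
                 final_train_mae = min(final_train_mae, initial_train_mae),
                 train_mae = all_pair_mae,
                 strategy = NA_character_,
                 fingerprint = NA_character_,
                 test_functional = NA_character_),
            class = "imr")
}

# coerce fingerprint input (named list of vectors or matrix) to a matrix
as_fp_matrix <- function(fingerprints) {
  if (is.matrix(fingerprints)) {
    if (is.null(rownames(fingerprints)))
      stop("fingerprint matrix must have species ids as rownames", call. = FALSE)
    return(fingerprints)
  }
  if (is.list(fingerprints)) {
    if (is.null(names(fingerprints)))
      stop("fingerprint list must be named by species id", call. = FALSE)
    return(do.call(rbind, fingerprints))
  }
  stop("fingerprints must be a matrix or a named list of vectors", call. = FALSE)
}

# standardize new fingerprints with the model's training statistics
model_standardize <- function(model, fp) {
  M <- if (is.matrix(fp)) fp else matrix(fp, nrow = 1L,
                                         dimnames = list(NULL, names(fp)))
  if (ncol(M) != model$d)
    stop(sprintf("fingerprint width %d does not match model input width %d",
                 ncol(M), model$d), call. = FALSE)
  sweep(sweep(M, 2L, model$center, "-"), 2L, model$scale, "/")
}

#' Invariant molecular representation of fingerprints
#'
#' Deterministic forward pass through the trained twin subnetwork; the
#' output is the invariant molecular representation (IMR).
#'
#' @param model An `imr` model.
#' @param fp A fingerprint vector or matrix (rows = species).
#' @return Numeric matrix, rows = inputs, `model$k` columns.
#' @export
imr_embed <- function(model, fp) {
  stopifnot(inherits(model, "imr"))
  Z <- mlp_forward(model$subnet, model_standardize(model, fp))$out
  colnames(Z) <- sprintf("imr%02d", seq_len(ncol(Z)))
  if (is.matrix(fp)) rownames(Z) <- rownames(fp)
  Z
}

#' Predict the adsorption-energy difference of a species pair
#'
#' Computes `head(subnet(a) - subnet(b))`. By the bias-free odd head this
#' is exactly antisymmetric in the two arguments and exactly zero when
#' they coincide.
#'
#' @param model An `imr` model.
#' @param fp_a,fp_b Fingerprint vectors (or matrices of equal height).
#' @return Predicted energy difference(s) in eV.
#' @export
predict_pair_delta <- function(model, fp_a, fp_b) {
  Za <- mlp_forward(model$subnet, model_standardize(model, fp_a))$out
  Zb <- mlp_forward(model$subnet, model_standardize(model, fp_b))$out
  drop(mlp_forward(model$head, Za - Zb)$out)
}

#' Train the Siamese model under a named strategy
#'
#' Implements the three training strategies: `"ffm"` trains on pairs from
#' every functional except the test functional; `"bem"` trains on pairs
#' from randomly drawn ensemble pseudo-functionals; `"fsm"` (the control)
#' trains on pairs of the test functional itself, restricted to the
#' current trial's training-split species.
#'
#' @param dataset A `catalysis_dataset`.
#' @param fingerprint_kind `"flat24"`, `"morgan24"` or `"embedding"`.
#' @param strategy `"ffm"`, `"bem"` or `"fsm"`.
#' @param test_functional The functional whose energies are being held out.
#' @param k Representation size; `NULL` matches the PCA dimension at the
#'   0.98 variance threshold on the fitting species.
#' @param config A [siamese_control()].
#' @param seed Seed for ensemble draws and training.
#' @param train_species Species ids of the training split (required for
#'   `"fsm"`).
#' @param embeddings Named list from [load_embeddings()] when
#'   `fingerprint_kind = "embedding"`.
#' @return An `imr` model annotated with the strategy metadata.
#' @export
train_strategy <- function(dataset, fingerprint_kind = "flat24",
                           strategy = c("ffm", "bem", "fsm"),
                           test_functional, k = NULL,
                           config = siamese_control(), seed = config$seed,
                           train_species = NULL, embeddings = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(dataset, "catalysis_dataset"))
  if (!test_functional %in% functionals(dataset))
    stop(sprintf("unknown test functional: %s", test_functional), call. = FALSE)
  FP <- dataset_fingerprints(dataset, fingerprint_kind, embeddings)

  if (strategy == "ffm") {
    fns <- setdiff(functionals(dataset), test_functional)
    if (length(fns) < 2L)
      stop("FFM requires at least 2 functionals besides the test functional",
           call. = FALSE)
    pairs <- build_pairs(dataset, fns)
    fit_species <- dataset$species$species_id
  } else if (strategy == "bem") {
    labels <- sample_beef_ensemble(dataset, count = config$bem_count,
                                   seed = derive_seed(seed, "bem-draw"))
    pairs <- build_pairs(dataset, labels)
    fit_species <- dataset$species$species_id
  } else {
    if (is.null(train_species))
      stop("FSM requires the trial's training-split species", call. = FALSE)
    sub <- subset_dataset(dataset, train_species)
    pairs <- build_pairs(sub, test_functional)
    fit_species <- train_species
  }

  if (is.null(k)) k <- fit_pca(FP[fit_species, , drop = FALSE], 0.98)$k
  cfg <- config
  cfg$seed <- as.integer(derive_seed(seed, "siamese-train"))
  model <- train_siamese(pairs, FP, k, cfg)
  model$strategy <- strategy
  model$fingerprint <- fingerprint_kind
  model$test_functional <- test_functional
  model
}

# fingerprint matrix for every species of a dataset
dataset_fingerprints <- function(dataset, kind, embeddings = NULL) {
  ids <- dataset$species$species_id
  if (kind == "embedding") {
    if (is.null(embeddings))
      stop("fingerprint_kind = \"embedding\" requires `embeddings`", call. = FALSE)
    missing_sp <- setdiff(ids, names(embeddings))
    if (length(missing_sp) > 0L)
      stop(sprintf("no embedding for species: %s",
                   paste(missing_sp, collapse = ", ")), call. = FALSE)
    return(do.call(rbind, lapply(embeddings[ids], as.numeric)) |>
             (\(m) { rownames(m) <- ids
                     colnames(m) <- attr(embeddings[[1L]], "schema")
                     m })())
  }
  fingerprint_matrix(stats::setNames(dataset$species$smiles, ids), kind = kind)
}

# restrict a dataset to a subset of species ids
subset_dataset <- function(dataset, species_ids) {
  keep <- dataset$species$species_id %in% species_ids
  catalysis_dataset(dataset$species[keep, , drop = FALSE],
                    dataset$energies[keep, , drop = FALSE],
                    ensemble = if (is.null(dataset$ensemble)) NULL else
                      dataset$ensemble[keep, , drop = FALSE],
                    surface = dataset$surface)
}

#' Fit an invariant-molecular-representation model
#'
#' The front door of the package: trains the Siamese network on
#' within-functional adsorption-energy differences under the chosen
#' strategy and returns the fitted model, whose subnetwork output is the
#' invariant molecular representation (IMR) used for downstream
#' adsorption-energy regression.
#'
#' @inheritParams train_strategy
#' @param fingerprint Fingerprint family used as network input.
#' @param control A [siamese_control()].
#' @return An object of class `imr` with `print`, `summary`, `predict`,
#'   `plot`, `coef` and `residuals` methods.
#' @examples
#' \donttest{
#' ds <- generate_synthetic_dataset(synthetic_config(n_species = 12,
#'                                                   ensemble_members = 0))
#' fit <- imr(ds, strategy = "ffm", test_functional = "PBE-D3",
#'            control = siamese_control(epochs = 50))
#' fit
#' }
#' @export
imr <- function(dataset, fingerprint = c("flat24", "morgan24", "embedding"),
                strategy = c("ffm", "bem", "fsm"), test_functional,
                k = NULL, seed = 1L, control = siamese_control(),
                train_species = NULL, embeddings = NULL) {
  fingerprint <- match.arg(fingerprint)
  strategy <- match.arg(strategy)
  model <- train_strategy(dataset, fingerprint_kind = fingerprint,
                          strategy = strategy,
                          test_functional = test_functional, k = k,
                          config = control, seed = seed,
                          train_species = train_species,
                          embeddings = embeddings)
  model$call <- match.call()
  model
}

#' @export
print.imr <- function(x, ...) {
  cat("Invariant molecular representation (Siamese) model\n")
  if (!is.na(x$strategy))
    cat(sprintf("  strategy: %s   test functional: %s   fingerprint: %s\n",
                toupper(x$strategy), x$test_functional, x$fingerprint))
  cat(sprintf("  input width d = %d, representation size k = %d\n", x$d, x$k))
  cat(sprintf("  trained on %d pairs over %d species; %d epochs (best at %d)\n",
              x$n_pairs, length(x$species), nrow(x$history), x$best_epoch))
  cat(sprintf("  pair MAE: %.4f eV (initial %.4f eV)\n",
              x$train_mae, x$initial_train_mae))
  invisible(x)
}

#' @export
summary.imr <- function(object, ...) {
  print(object)
  cat(sprintf("  subnetwork: %s -> %s -> %d (tanh hidden, linear out)\n",
              object$d, paste(object$config$hidden, collapse = " -> "),
              object$k))
  cat(sprintf("  head: %d -> %s -> 1 (tanh, bias-free, exactly odd)\n",
              object$k, paste(object$config$head_hidden, collapse = " -> ")))
  cat(sprintf("  optimiser: full-batch Adam, lr %s, patience %s, holdout %.0f%%\n",
              paste(object$config$lr, collapse = "/"),
              paste(object$config$patience, collapse = "/"),
              100 * object$config$holdout_fraction))
  invisible(object)
}

#' Predict from an IMR model
#'
#' @param object An `imr` model.
#' @param newdata SMILES character vector, fingerprint vector/matrix or a
#'   `catalysis_dataset`.
#' @param type `"embedding"` for the invariant representation (default) or
#'   `"delta"` for pairwise energy differences, in which case `newdata`
#'   must be a list of two fingerprint sets `list(a, b)`.
#' @param ... Unused.
#' @return A matrix of embeddings, or a vector of energy differences (eV).
#' @export
predict.imr <- function(object, newdata, type = c("embedding", "delta"), ...) {
  type <- match.arg(type)
  to_fp <- function(nd) {
    if (inherits(nd, "catalysis_dataset"))
      return(dataset_fingerprints(nd, object$fingerprint))
    if (is.character(nd))
      return(fingerprint_matrix(nd, kind = if (is.na(object$fingerprint)) "flat24"
                                           else object$fingerprint))
    nd
  }
  if (type == "embedding") return(imr_embed(object, to_fp(newdata)))
  if (!is.list(newdata) || length(newdata) != 2L)
    stop("type = \"delta\" needs newdata = list(fp_a, fp_b)", call. = FALSE)
  predict_pair_delta(object, to_fp(newdata[[1L]]), to_fp(newdata[[2L]]))
}

#' @export
plot.imr <- function(x, ...) {
  h <- x$history
  graphics::matplot(seq_len(nrow(h)), h, type = "l", lty = 1,
                    col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "pair MAE (eV)",
                    main = "Siamese training history", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", legend = c("training", "monitored"),
                   col = c("black", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' @export
coef.imr <- function(object, ...) {
  list(subnetwork = list(W = object$subnet$W, b = object$subnet$b),
       head = list(W = object$head$W))
}

#' @export
residuals.imr <- function(object, ...) {
  pairs <- object$pairs
  FP <- object$fingerprints
  pred <- predict_pair_delta(object,
                             FP[pairs$species_a, , drop = FALSE],
                             FP[pairs$species_b, , drop = FALSE])
  pred - pairs$delta_e
}
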