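# Downstream adsorption-energy regressors: ridge and elastic net (glmnet),
# kernel ridge (closed form, RBF) and support vector regression (e1071).
# All operate on feature matrices already z-scored with training statistics;
# hyperparameters are chosen by seeded k-fold cross-validation on the
# training split with mean validation MAE as the objective.

#' Default hyperparameter grids for the downstream regressors
#'
#' Ridge/elastic-net penalties span 1e-4..1e2 (7 log-spaced values) with
#' elastic mixing in {0.1, 0.5, 0.9}; kernel ridge uses an RBF kernel with
#' penalty 1e-4..1e1 and bandwidth at {0.5, 1, 2} times the median
#' pairwise distance; SVR (RBF) searches cost {0.1, 1, 10, 100} and
#' epsilon {0.01, 0.05, 0.1}.
#'
#' @return Named list of per-method parameter grids.
#' @export
default_grids <- function() {
  list(ridge = expand.grid(lambda = 10^seq(-4, 2, length.out = 7)),
       elastic = expand.grid(lambda = 10^seq(-4, 2, length.out = 7),
                             alpha = c(0.1, 0.5, 0.9)),
       krr = expand.grid(lambda = 10^seq(-4, 1, length.out = 6),
                         gamma_mult = c(0.5, 1, 2)),
       svr = expand.grid(cost = c(0.1, 1, 10, 100),
                         epsilon = c(0.01, 0.05, 0.1)))
}

rbf_kernel <- function(X1, X2, sigma) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

median_bandwidth <- function(X) {
  d <- as.numeric(stats::dist(X))
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

# glmnet needs >= 2 columns; pad 1-column inputs with a zero column
pad2 <- function(X) if (ncol(X) >= 2L) X else cbind(X, .pad = 0)

fit_one <- function(method, X, y, par) {
  switch(method,
    ridge = ,
    elastic = {
      alpha <- if (method == "ridge") 0 else par$alpha
      fit <- glmnet::glmnet(pad2(X), y, alpha = alpha,
                            lambda = sort(unique(c(par$lambda,
                                                   10^seq(-4, 2, length.out = 7))),
                                          decreasing = TRUE),
                            standardize = FALSE,
                            thresh = 1e-12, maxit = 1e6)
      list(fit = fit, lambda = par$lambda, alpha = alpha)
    },
    krr = {
      sigma <- par$gamma_mult * median_bandwidth(X)
      K <- rbf_kernel(X, X, sigma)
      ybar <- mean(y)
      a <- solve(K + par$lambda * diag(nrow(X)), y - ybar)
      list(alpha_coef = a, Xtrain = X, sigma = sigma, ybar = ybar)
    },
    svr = {
      fit <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                        cost = par$cost, epsilon = par$epsilon, scale = FALSE)
      list(fit = fit)
    },
    stop(sprintf("unknown regressor: %s", method), call. = FALSE))
}

predict_one <- function(method, model, X) {
  switch(method,
    ridge = ,
    elastic = as.numeric(stats::predict(model$fit, newx = pad2(X),
                                        s = model$lambda)),
    krr = as.numeric(rbf_kernel(X, model$Xtrain, model$sigma) %*%
                       model$alpha_coef + model$ybar),
    svr = as.numeric(stats::predict(model$fit, X)))
}

#' Fit a downstream regressor with cross-validated hyperparameters
#'
#' @param method One of `"ridge"`, `"elastic"`, `"krr"`, `"svr"`.
#' @param X Training feature matrix (already scaled).
#' @param y Training energies (eV).
#' @param folds Integer fold assignment per training row (seeded by the
#'   caller); `NULL` draws 5 folds from the current RNG state.
#' @param grid Data frame of candidate hyperparameters; defaults to
#'   [default_grids()] for the method.
#' @return Object of class `imr_regressor`.
#' @export
fit_regressor <- function(method, X, y, folds = NULL, grid = NULL) {
  method <- match.arg(method, c("ridge", "elastic", "krr", "svr"))
  X <- as.matrix(X)
  if (is.null(grid)) grid <- default_grids()[[method]]
  if (is.null(folds)) folds <- sample(rep_len(1:5, nrow(X)))
  nf <- length(unique(folds))
  cv_mae <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    par <- grid[gi, , drop = FALSE]
    errs <- numeric(nf)
    for (f in seq_len(nf)) {
      hold <- folds == sort(unique(folds))[f]
      m <- fit_one(method, X[!hold, , drop = FALSE], y[!hold], par)
      errs[f] <- mean(abs(predict_one(method, m, X[hold, , drop = FALSE]) -
                            y[hold]))
    }
    cv_mae[gi] <- mean(errs)
  }
  best <- which.min(cv_mae)  # deterministic: first minimum in grid order
  model <- fit_one(method, X, y, grid[best, , drop = FALSE])
  structure(list(method = method, model = model,
                 params = as.list(grid[best, , drop = FALSE]),
                 cv_mae = cv_mae[best]),
            class = "imr_regressor")
}

#' @export
predict.imr_regressor <- function(object, newdata, ...) {
  predict_one(object$method, object$model, as.matrix(newdata))
}

#' @export
print.imr_regressor <- function(x, ...) {
  cat(sprintf("%s regressor (CV MAE %.4f eV); params: %s\n", x$method,
              x$cv_mae,
              paste(names(x$params), signif(unlist(x$params), 3),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# column z-scoring with training statistics
scaler_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}
scaler_apply <- function(X, s) sweep(sweep(X, 2L, s$center, "-"), 2L, s$scale, "/")
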