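#' Fit a PCA transform choosing the dimension by explained variance
#'
#' Centred principal component analysis (via [stats::prcomp()]); the
#' representation size `k` is the smallest number of leading components
#' whose cumulative explained-variance ratio reaches `variance_threshold`.
#'
#' @param fingerprints Numeric matrix, rows = species.
#' @param variance_threshold Fraction of variance to retain (default 0.98,
#'   the threshold used for 24-length fingerprints; 0.90 is typical for
#'   wide learned embeddings).
#' @return Object of class `pca_transform` with fields `mean`, `components`
#'   (k x d, orthonormal rows), `explained_variance_ratio`, `k`.
#' @export
fit_pca <- function(fingerprints, variance_threshold = 0.98) {
  X <- as.matrix(fingerprints)
  stopifnot(nrow(X) >= 2L, variance_threshold > 0, variance_threshold <= 1)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  var_tot <- sum(pc$sdev^2)
  if (var_tot <= 0)
    stop("degenerate input: fingerprint matrix has zero variance", call. = FALSE)
  evr <- pc$sdev^2 / var_tot
  k <- which(cumsum(evr) >= variance_threshold - 1e-12)[1L]
  structure(list(mean = pc$center,
                 components = t(pc$rotation[, seq_len(k), drop = FALSE]),
                 explained_variance_ratio = evr,
                 k = as.integer(k),
                 variance_threshold = variance_threshold),
            class = "pca_transform")
}

#' @export
print.pca_transform <- function(x, ...) {
  cat(sprintf("PCA transform: d = %d -> k = %d (>= %.0f%% variance)\n",
              ncol(x$components), x$k, 100 * x$variance_threshold))
  invisible(x)
}

#' @export
predict.pca_transform <- function(object, newdata, ...) {
  M <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1L)
  if (ncol(M) != ncol(object$components))
    stop(sprintf("input width %d does not match fitted width %d",
                 ncol(M), ncol(object$components)), call. = FALSE)
  out <- sweep(M, 2L, object$mean, "-") %*% t(object$components)
  colnames(out) <- sprintf("pc%02d", seq_len(object$k))
  rownames(out) <- rownames(M)
  out
}

#' Build a representation provider
#'
#' Wraps the three representation routes compared throughout the package
#' behind one transform contract: `"original"` (identity on the raw
#' fingerprints), `"pca"` (a fitted [fit_pca()] transform) and `"imr"`
#' (the trained Siamese subnetwork).
#'
#' @param kind `"original"`, `"pca"` or `"imr"`.
#' @param state `NULL` for `"original"` (pass `d` instead), a
#'   `pca_transform`, or an `imr` model.
#' @param d Input width, required for `"original"`.
#' @return Object of class `representation_provider` with an `output_dim`
#'   field.
#' @export
representation_provider <- function(kind = c("original", "pca", "imr"),
                                    state = NULL, d = NULL) {
  kind <- match.arg(kind)
  output_dim <- switch(kind,
    original = { stopifnot(!is.null(d)); as.integer(d) },
    pca = { stopifnot(inherits(state, "pca_transform")); state$k },
    imr = { stopifnot(inherits(state, "imr")); state$k })
  structure(list(kind = kind, state = state, output_dim = output_dim,
                 input_dim = switch(kind, original = as.integer(d),
                                    pca = ncol(state$components),
                                    imr = state$d)),
            class = "representation_provider")
}

#' Transform fingerprints through a representation provider
#'
#' @param provider A [representation_provider()].
#' @param fingerprints Numeric vector or matrix (rows = species).
#' @return Numeric matrix with `provider$output_dim` columns.
#' @export
transform_representation <- function(provider, fingerprints) {
  stopifnot(inherits(provider, "representation_provider"))
  M <- if (is.matrix(fingerprints)) fingerprints else
    matrix(fingerprints, nrow = 1L, dimnames = list(NULL, names(fingerprints)))
  if (ncol(M) != provider$input_dim)
    stop(sprintf("input width %d does not match provider width %d",
                 ncol(M), provider$input_dim), call. = FALSE)
  switch(provider$kind,
         original = M,
         pca = predict(provider$state, M),
         imr = imr_embed(provider$state, M))
}

#' @export
print.representation_provider <- function(x, ...) {
  cat(sprintf("representation provider: %s (output_dim = %d)\n",
              x$kind, x$output_dim))
  invisible(x)
}
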