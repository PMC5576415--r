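# PCA feature reduction followed by Fisher linear discriminant projection.

#' Fit a PCA model
#'
#' Principal components of a subjects x features matrix, computed from the
#' singular value decomposition of the centered data — equivalent to an
#' eigendecomposition of the sample covariance but numerically stable in the
#' many-features/few-samples regime this pipeline lives in (p of order 5e4,
#' n of order 1e2; at most `n - 1` components carry variance).
#'
#' Component signs are fixed by forcing each component's largest-magnitude
#' entry positive, so fits are reproducible.
#'
#' @param x Numeric matrix, one row per sample.
#' @param n_components Number of components to retain; at most
#'   `min(nrow(x) - 1, ncol(x))`.
#' @return Object of class `"wave_pca"`: `mean` (per-feature means),
#'   `components` (features x `n_components` orthonormal basis),
#'   `eigenvalues` (all `min(n - 1, p)` covariance eigenvalues, descending),
#'   `n_components`.
#' @seealso [pca_transform()], [fisher_lda()]
#' @export
pca_fit <- function(x, n_components) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 2L) stop("PCA needs at least 2 samples", call. = FALSE)
  kmax <- min(n - 1L, p)
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > kmax)
    stop(sprintf("n_components must be in [1, %d] (= min(n_samples - 1, n_features))",
                 kmax), call. = FALSE)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  sv <- svd(xc, nu = 0L, nv = kmax)
  eig <- sv$d[seq_len(kmax)]^2 / (n - 1L)
  comp <- sv$v[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(comp))) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  structure(list(mean = mu, components = comp, eigenvalues = eig,
                 n_components = n_components),
            class = "wave_pca")
}

#' Project data onto a fitted PCA basis
#'
#' @param model A `"wave_pca"` from [pca_fit()].
#' @param x Matrix with the same feature count the model was fitted on.
#' @return Scores matrix (`nrow(x)` x `n_components`).
#' @export
pca_transform <- function(model, x) {
  stopifnot(inherits(model, "wave_pca"))
  x <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(x) != length(model$mean))
    stop(sprintf("feature count mismatch: model has %d, data has %d",
                 length(model$mean), ncol(x)), call. = FALSE)
  sweep(x, 2L, model$mean) %*% model$components
}

#' @export
predict.wave_pca <- function(object, newdata, ...) pca_transform(object, newdata)

#' @export
print.wave_pca <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  kept <- sum(x$eigenvalues[seq_len(x$n_components)])
  cat(sprintf("PCA model: %d feature(s) -> %d component(s) (%.1f%% variance)\n",
              length(x$mean), x$n_components,
              if (tot > 0) 100 * kept / tot else 100))
  invisible(x)
}

#' Fit a Fisher linear discriminant projection
#'
#' Maximizes the generalized Rayleigh quotient
#' \eqn{J(w) = w^T S_B w / w^T S_w w} of between-class to within-class
#' scatter.  The between-class scatter is the average over classes of
#' \eqn{(m_j - m)(m_j - m)^T}; the within-class scatter is the unnormalized
#' sum of squared deviations from class means.  The discriminant axes solve
#' \eqn{S_B W = \lambda S_w W}, computed as the eigenvectors of
#' \eqn{S_w^{-1} S_B} after adding a small ridge to \eqn{S_w}
#' (`ridge * trace(S_w) / d`), the standard small-sample safeguard; the
#' intended input is PCA scores with `n_components <= n - c`, for which
#' \eqn{S_w} is well conditioned.  At most `c - 1` axes carry signal (one for
#' two classes).
#'
#' @param x Numeric matrix of (projected) features, one row per sample.
#' @param labels Class labels, one per row; every class needs >= 2 samples.
#' @param l Number of discriminant axes to retain (default `c - 1`).
#' @param ridge Relative ridge added to the within-class scatter.
#' @return Object of class `"wave_lda"`: `S_B`, `S_w`, `class_means`,
#'   `grand_mean`, `axes` (d x l, unit length, sign-fixed), `eigenvalues`,
#'   `classes`, `l`.
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 2), 20))
#' f <- fisher_lda(x, rep(c("a", "b"), each = 20))
#' dim(lda_transform(f, x))  # 40 x 1
#' @export
fisher_lda <- function(x, labels, l = NULL, ridge = 1e-6) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  classes <- sort(unique(labels))
  c_ <- length(classes)
  if (c_ < 2L) stop("need at least 2 classes", call. = FALSE)
  cnt <- table(labels)
  if (any(cnt < 2L))
    stop("every class needs at least 2 samples; short: ",
         paste(names(cnt)[cnt < 2], collapse = ", "), call. = FALSE)
  d <- ncol(x)
  m <- colMeans(x)
  means <- t(vapply(classes, function(cl) colMeans(x[labels == cl, , drop = FALSE]),
                    numeric(d)))
  SB <- matrix(0, d, d)
  for (j in seq_len(c_)) {
    dv <- means[j, ] - m
    SB <- SB + tcrossprod(dv)
  }
  SB <- SB / c_
  SW <- matrix(0, d, d)
  for (j in seq_len(c_)) {
    xc <- sweep(x[labels == classes[j], , drop = FALSE], 2L, means[j, ])
    SW <- SW + crossprod(xc)
  }
  eps <- ridge * sum(diag(SW)) / d
  SWr <- SW + diag(eps, d)
  M <- tryCatch(solve(SWr, SB), error = function(e)
    stop("within-class scatter is numerically singular even after ",
         "regularization: ", conditionMessage(e), call. = FALSE))
  ei <- eigen(M)
  ord <- order(Re(ei$values), decreasing = TRUE)
  vals <- Re(ei$values)[ord]
  vecs <- Re(ei$vectors)[, ord, drop = FALSE]
  if (is.null(l)) l <- c_ - 1L
  l <- as.integer(l)
  stopifnot(l >= 1L, l <= d)
  W <- vecs[, seq_len(l), drop = FALSE]
  for (j in seq_len(l)) {
    W[, j] <- W[, j] / sqrt(sum(W[, j]^2))
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  structure(list(S_B = SB, S_w = SW, class_means = means, grand_mean = m,
                 axes = W, eigenvalues = vals[seq_len(l)],
                 classes = classes, l = l),
            class = "wave_lda")
}

#' Project features onto the discriminant axes
#'
#' Centers by the grand mean and projects onto the retained axes, giving the
#' final feature matrix with `l` columns (one column for two classes).
#'
#' @param model A `"wave_lda"` from [fisher_lda()].
#' @param x Matrix with matching feature count.
#' @return `nrow(x)` x `l` matrix.
#' @export
lda_transform <- function(model, x) {
  stopifnot(inherits(model, "wave_lda"))
  x <- as.matrix(x)
  if (ncol(x) != length(model$grand_mean))
    stop(sprintf("feature count mismatch: model has %d, data has %d",
                 length(model$grand_mean), ncol(x)), call. = FALSE)
  sweep(x, 2L, model$grand_mean) %*% model$axes
}

#' @export
predict.wave_lda <- function(object, newdata, ...) lda_transform(object, newdata)

#' @export
print.wave_lda <- function(x, ...) {
  cat(sprintf("Fisher LDA: %d class(es), %d axis/axes retained\n",
              length(x$classes), x$l))
  cat("  leading generalized eigenvalue:", format(x$eigenvalues[1]), "\n")
  invisible(x)
}

# Fisher ratio J(w) = (w' S_B w) / (w' S_w w) for a direction w.
.fisher_ratio <- function(model, w) {
  as.numeric((crossprod(w, model$S_B) %*% w) /
             (crossprod(w, model$S_w) %*% w))
}
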