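# The full feature -> PCA -> (LDA) -> twin SVM pipeline as one fitted model.

#' Fit the wavelet-feature classification pipeline
#'
#' Chains the stages applied to a cohort's wavelet feature matrix: PCA to
#' `n_components` scores, optionally a Fisher discriminant projection to
#' `c - 1` axes, then a linear twin SVM on the projected features.  This is
#' the model fitted inside every cross-validation fold of [cv_evaluate()].
#'
#' `n_components` is capped at `n - 2` when `use_lda = TRUE` (two classes;
#' keeps the within-class scatter invertible) and at `n - 1` otherwise.
#'
#' @param x Feature matrix (e.g. from [cohort_features()]), or any numeric
#'   samples x features matrix.
#' @param labels Class labels: `+1`/`-1` or `"patient"`/`"control"`; taken
#'   from `attr(x, "labels")` when omitted.
#' @param n_components Principal components to retain (default 20, the tuned
#'   operating point of the published pipeline).
#' @param use_lda Project PCA scores onto the Fisher discriminant axis
#'   before classification?
#' @param C1,C2,epsilon,tol Twin SVM parameters, see [twinsvm()].
#' @return Object of class `"wave_classifier"` holding the fitted `pca`,
#'   `lda` (or `NULL`), `tsvm`, and the `variant` label (e.g.
#'   `"DTCWT+PCA+LDA+TSVM"` when `x` carries a feature layout).
#' @examples
#' spec <- phantom_spec(image_size = 64, n_slices = 2, seed = 1)
#' coh <- phantom_cohort(spec, n_patients = 6, n_controls = 6)
#' X <- cohort_features(coh)
#' fit <- wave_classifier(X, n_components = 5)
#' table(predict(fit, X), attr(X, "labels"))
#' @export
wave_classifier <- function(x, labels = attr(x, "labels"), n_components = 20L,
                            use_lda = TRUE, C1 = 1, C2 = 1, epsilon = 1e-6,
                            tol = 1e-6) {
  if (is.null(labels))
    stop("`labels` missing and `x` carries no \"labels\" attribute",
         call. = FALSE)
  X <- unclass(x)
  attr(X, "labels") <- NULL
  X <- as.matrix(X)
  yy <- if (is.numeric(labels)) ifelse(labels > 0, 1, -1)
        else ifelse(as.character(labels) == "patient", 1, -1)
  n <- nrow(X)
  c_ <- length(unique(yy))
  kcap <- if (use_lda) n - c_ else n - 1L
  k <- min(as.integer(n_components), kcap, ncol(X))
  if (k < 1L) stop("too few samples to fit the pipeline", call. = FALSE)
  pca <- pca_fit(X, n_components = k)
  Z <- pca_transform(pca, X)
  lda <- NULL
  if (use_lda) {
    lda <- fisher_lda(Z, ifelse(yy > 0, "patient", "control"))
    Z <- lda_transform(lda, Z)
  }
  tsvm <- twinsvm(Z, yy, C1 = C1, C2 = C2, epsilon = epsilon, tol = tol)
  layout <- attr(x, "layout")
  variant <- paste0(
    if (!is.null(layout)) toupper(layout$transform) else "WAVE",
    "+PCA", if (use_lda) "+LDA", "+TSVM")
  structure(list(pca = pca, lda = lda, tsvm = tsvm, variant = variant,
                 n_components = k, use_lda = use_lda),
            class = "wave_classifier")
}

#' @export
predict.wave_classifier <- function(object, newdata, ...) {
  Z <- pca_transform(object$pca, as.matrix(unclass(newdata)))
  if (!is.null(object$lda)) Z <- lda_transform(object$lda, Z)
  predict(object$tsvm, Z, ...)
}

#' @export
print.wave_classifier <- function(x, ...) {
  cat(sprintf("Pipeline classifier [%s]\n", x$variant))
  cat(sprintf("  PCA components: %d%s\n", x$n_components,
              if (x$use_lda) "; Fisher LDA projection to 1 axis" else ""))
  cat(sprintf("  twin SVM: C1 = %g, C2 = %g (KKT %.1e)\n", x$tsvm$C1,
              x$tsvm$C2, x$tsvm$kkt_residual))
  invisible(x)
}
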