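# Repeated stratified k-fold cross-validation and confusion-matrix
# statistics.

#' Build a repeated stratified k-fold plan
#'
#' For each run, subjects are partitioned into `k` folds preserving the class
#' proportions: per-class counts are spread so that every fold's count of
#' each class differs from perfect proportionality by at most one, and fold
#' totals are balanced by assigning each class's remainders to the currently
#' smallest folds.  Distinct runs draw from one RNG stream seeded by `seed`,
#' so a plan is reproducible as a whole.
#'
#' @param labels Class label per subject (any coding).
#' @param k Fold count; must not exceed the smaller class size.
#' @param runs Number of repeated runs.
#' @param seed Integer seed.
#' @return Object of class `"cv_plan"`: `k`, `runs`, `seed`, and `folds`, a
#'   list of integer vectors (fold id per subject) per run.
#' @examples
#' pl <- make_cv_plan(rep(c("patient", "control"), c(51, 44)), k = 5, runs = 2)
#' table(pl$folds[[1]])  # five folds of 19
#' @export
make_cv_plan <- function(labels, k, runs = 10L, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  k <- as.integer(k); runs <- as.integer(runs)
  cnt <- table(labels)
  if (k < 2L || k > min(cnt))
    stop(sprintf("k = %d invalid: must be in [2, %d] (smaller class size)",
                 k, min(cnt)), call. = FALSE)
  set.seed(as.integer(seed))
  folds <- vector("list", runs)
  for (r in seq_len(runs)) {
    fold <- integer(n)
    totals <- integer(k)
    for (cl in names(sort(cnt, decreasing = TRUE))) {
      idx <- sample(which(labels == cl))
      m <- length(idx)
      base <- m %/% k
      extra <- m %% k
      sizes <- rep(base, k)
      if (extra > 0L) {
        # remainders go to the currently smallest folds (random tie-break)
        ord <- order(totals + stats::runif(k) * 1e-9)
        sizes[ord[seq_len(extra)]] <- base + 1L
      }
      stop_at <- cumsum(sizes)
      start_at <- c(1L, head(stop_at, -1L) + 1L)
      for (f in seq_len(k))
        if (sizes[f] > 0L) fold[idx[start_at[f]:stop_at[f]]] <- f
      totals <- totals + sizes
    }
    folds[[r]] <- fold
  }
  structure(list(k = k, runs = runs, seed = as.integer(seed), folds = folds),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("Stratified CV plan: %d-fold x %d run(s), seed %d, %d subject(s)\n",
              x$k, x$runs, x$seed, length(x$folds[[1]])))
  invisible(x)
}

#' Confusion-matrix statistics
#'
#' The seven statistics reported by the pipeline, computed from the four
#' confusion counts: accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision `TP/(TP+FP)`, recall
#' (identical to sensitivity), F-measure
#' `2*precision*recall/(precision+recall)` and g-mean
#' `sqrt(sensitivity * specificity)`.  A ratio with a zero denominator is
#' reported as `NA` (undefined), never an error.
#'
#' @param tp,fn,fp,tn Confusion counts: true positives (patients classified
#'   as patients), false negatives, false positives, true negatives.
#' @return Named numeric vector of the seven statistics, values in `[0, 1]`.
#' @examples
#' classification_metrics(tp = 50, fn = 5, fp = 5, tn = 40)["accuracy"]  # 0.9
#' @export
classification_metrics <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  total <- tp + fn + fp + tn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  div <- function(a, b) if (b > 0) a / b else NA_real_
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  prec <- div(tp, tp + fp)
  fmeas <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  gmean <- if (!is.na(sens) && !is.na(spec)) sqrt(sens * spec) else NA_real_
  c(accuracy = (tp + tn) / total, sensitivity = sens, specificity = spec,
    precision = prec, recall = sens, f_measure = fmeas, gmean = gmean)
}

#' Cross-validated evaluation of the pipeline
#'
#' Runs repeated stratified k-fold cross-validation of the full pipeline on
#' a precomputed feature matrix.  Within every fold the entire model — PCA,
#' optional Fisher LDA, twin SVM — is refitted on the training folds only,
#' so no held-out subject influences any fitted component (a leak-free
#' protocol).  Per run, confusion counts are pooled over folds and the seven
#' statistics computed from the pooled counts; the report gives their mean
#' and standard deviation over runs, plus the run x fold accuracy table.
#'
#' @param x Feature matrix (subjects x features), e.g. [cohort_features()].
#' @param labels Labels (`+1`/`-1` or `"patient"`/`"control"`); default from
#'   `attr(x, "labels")`.
#' @param k Folds per run.
#' @param runs Repeat count (default 10).
#' @param seed Master seed for the fold plan.
#' @inheritParams wave_classifier
#' @return Object of class `"wave_cv"`: `summary` (7 x 2 matrix of mean and
#'   sd over runs), `run_metrics` (runs x 7), `fold_accuracy` (runs x k),
#'   `predictions` (runs x subjects, `+1`/`-1`), `plan`, `variant`, and the
#'   configuration used.
#' @examples
#' spec <- phantom_spec(image_size = 64, n_slices = 2, seed = 3)
#' X <- cohort_features(phantom_cohort(spec, 8, 8))
#' cv <- cv_evaluate(X, k = 4, runs = 2, seed = 1, n_components = 5)
#' cv$summary["accuracy", ]
#' @export
cv_evaluate <- function(x, labels = attr(x, "labels"), k = 5L, runs = 10L,
                        seed = 1L, n_components = 20L, use_lda = TRUE,
                        C1 = 1, C2 = 1, epsilon = 1e-6, tol = 1e-6) {
  if (is.null(labels))
    stop("`labels` missing and `x` carries no \"labels\" attribute",
         call. = FALSE)
  X <- as.matrix(unclass(x))
  yy <- if (is.numeric(labels)) ifelse(labels > 0, 1, -1)
        else ifelse(as.character(labels) == "patient", 1, -1)
  if (length(unique(yy)) != 2L)
    stop("cohort must contain both classes", call. = FALSE)
  plan <- make_cv_plan(ifelse(yy > 0, "patient", "control"), k = k,
                       runs = runs, seed = seed)
  n <- nrow(X)
  fold_acc <- matrix(NA_real_, runs, k,
                     dimnames = list(paste0("run", seq_len(runs)),
                                     paste0("fold", seq_len(k))))
  run_metrics <- matrix(NA_real_, runs, 7L)
  preds <- matrix(NA_real_, runs, n)
  variant <- NULL
  for (r in seq_len(runs)) {
    fold <- plan$folds[[r]]
    counts <- c(tp = 0L, fn = 0L, fp = 0L, tn = 0L)
    for (f in seq_len(k)) {
      tr <- fold != f
      fit <- wave_classifier(X[tr, , drop = FALSE], labels = yy[tr],
                             n_components = n_components, use_lda = use_lda,
                             C1 = C1, C2 = C2, epsilon = epsilon, tol = tol)
      if (is.null(variant)) {
        variant <- sub("^WAVE", {
          lay <- attr(x, "layout")
          if (!is.null(lay)) toupper(lay$transform) else "WAVE"
        }, fit$variant)
      }
      p <- predict(fit, X[!tr, , drop = FALSE])
      truth <- yy[!tr]
      preds[r, !tr] <- p
      fold_acc[r, f] <- mean(p == truth)
      counts <- counts + c(tp = sum(p > 0 & truth > 0),
                           fn = sum(p < 0 & truth > 0),
                           fp = sum(p > 0 & truth < 0),
                           tn = sum(p < 0 & truth < 0))
    }
    run_metrics[r, ] <- classification_metrics(counts["tp"], counts["fn"],
                                               counts["fp"], counts["tn"])
  }
  colnames(run_metrics) <- c("accuracy", "sensitivity", "specificity",
                             "precision", "recall", "f_measure", "gmean")
  summ <- cbind(mean = colMeans(run_metrics, na.rm = TRUE),
                sd = apply(run_metrics, 2L, stats::sd, na.rm = TRUE))
  structure(list(summary = summ, run_metrics = run_metrics,
                 fold_accuracy = fold_acc, predictions = preds, plan = plan,
                 variant = variant,
                 config = list(k = k, runs = runs, seed = seed,
                               n_components = n_components, use_lda = use_lda,
                               C1 = C1, C2 = C2, epsilon = epsilon)),
            class = "wave_cv")
}

#' @export
print.wave_cv <- function(x, ...) {
  cat(sprintf("Cross-validated pipeline evaluation [%s]\n", x$variant))
  cat(sprintf("  %d-fold x %d run(s), seed %d\n", x$plan$k, x$plan$runs,
              x$plan$seed))
  s <- x$summary
  cat(sprintf("  accuracy %.2f +/- %.2f %%\n", 100 * s["accuracy", "mean"],
              100 * s["accuracy", "sd"]))
  invisible(x)
}

#' @export
summary.wave_cv <- function(object, ...) {
  cat(sprintf("Cross-validated pipeline evaluation [%s]\n", object$variant))
  cat(sprintf("  %d-fold stratified CV, %d run(s), seed %d\n\n",
              object$plan$k, object$plan$runs, object$plan$seed))
  s <- object$summary
  for (m in rownames(s))
    cat(sprintf("  %-12s %6.2f +/- %.2f %%\n", m, 100 * s[m, "mean"],
                100 * s[m, "sd"]))
  invisible(object$summary)
}

#' Write cross-validation results to disk
#'
#' Writes (a) the run x fold accuracy table as a TSV (runs in rows, folds in
#' columns, with per-run and per-fold averages appended) and (b) a JSON
#' summary of the seven statistics as mean and sd over runs.
#'
#' @param cv A `"wave_cv"` object.
#' @param dir Output directory (created if absent).
#' @param prefix File name prefix, default the variant label.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_cv_results <- function(cv, dir, prefix = NULL) {
  stopifnot(inherits(cv, "wave_cv"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(prefix)) prefix <- gsub("[^A-Za-z0-9]+", "_", cv$variant)
  tab <- cv$fold_accuracy
  tab <- cbind(tab, run_mean = rowMeans(tab))
  tab <- rbind(tab, fold_mean = colMeans(tab))
  tsv <- file.path(dir, paste0(prefix, "_fold_accuracy.tsv"))
  utils::write.table(round(100 * tab, 3), tsv, sep = "\t", quote = FALSE,
                     col.names = NA)
  js <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(
    list(variant = cv$variant, config = cv$config,
         metrics_percent = apply(cv$summary, 1L, function(v)
           list(mean = 100 * v[["mean"]], sd = 100 * v[["sd"]]))),
    js, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(tsv, js))
}
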