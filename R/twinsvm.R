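# Linear Twin Support Vector Machine.
#
# The classifier fits two nonparallel hyperplanes, each solving a small
# quadratic program: plane 1 stays close to the patient-class points while
# keeping the control class at (soft) distance >= 1, and symmetrically for
# plane 2.  With H = [X1 1], G = [X2 1] and u1 = [w1; b1], plane 1 solves
#
#   min_{u1, xi}  1/2 ||H u1||^2 + C1 1' xi
#   s.t.          -(G u1) + xi >= 1,  xi >= 0,
#
# whose Lagrange dual is the box-constrained QP
#
#   max_alpha  1' alpha - 1/2 alpha' G (H'H + eps I)^{-1} G' alpha,
#   0 <= alpha <= C1,        u1 = -(H'H + eps I)^{-1} G' alpha.
#
# Plane 2 is identical with the class roles swapped.  The small ridge eps is
# required whenever features >= samples (H'H rank deficient).  A sample is
# assigned to the class whose plane is nearer in perpendicular distance.

# Box-constrained QP solver for: max 1'a - 1/2 a' Q a, 0 <= a <= C,
# by a primal-dual interior-point method with a final active-set polish.
# The barrier term regularizes the Newton systems, so the severely
# ill-conditioned duals arising from a small ridge eps (features >= samples)
# converge in a few dozen iterations regardless of kappa(Q).  The returned
# KKT residual is the projected-gradient residual on the multiplier scale
# (divided by max(1, C)).
.boxqp <- function(Q, C, tol = 1e-8, max_iter = 150L) {
  n <- nrow(Q)
  kkt_of <- function(v) {
    g <- 1 - as.vector(Q %*% v)
    max(abs(v - pmin(pmax(v + g, 0), C))) / max(1, C)
  }
  polish <- function(a, lam, mu) {
    free <- lam <= a & mu <= (C - a)
    if (!any(free)) return(NULL)
    hi <- which(!free & mu > C - a)
    rhs <- rep(1, sum(free))
    if (length(hi))
      rhs <- rhs - Q[free, hi, drop = FALSE] %*% rep(C, length(hi))
    af <- tryCatch(solve(Q[free, free, drop = FALSE], rhs),
                   error = function(e) NULL)
    if (is.null(af)) return(NULL)
    a2 <- numeric(n)
    a2[hi] <- C
    a2[free] <- pmin(pmax(af, 0), C)
    a2
  }
  a <- rep(C / 2, n); lam <- rep(1, n); mu <- rep(1, n)
  best <- a; best_kkt <- kkt_of(a)
  for (it in seq_len(max_iter)) {
    r1 <- as.vector(Q %*% a) - 1 - lam + mu
    nu <- (sum(a * lam) + sum((C - a) * mu)) / (2 * n)
    if (it >= 3L) {
      a2 <- polish(a, lam, mu)
      if (!is.null(a2)) {
        k2 <- kkt_of(a2)
        if (k2 < best_kkt) { best <- a2; best_kkt <- k2 }
        if (k2 <= tol)
          return(list(alpha = a2, kkt = k2, iters = it))
      }
    }
    k0 <- kkt_of(a)
    if (k0 < best_kkt) { best <- a; best_kkt <- k0 }
    if (k0 <= tol) return(list(alpha = a, kkt = k0, iters = it))
    sig <- 0.2
    D <- lam / a + mu / (C - a)
    rhs <- -r1 + (sig * nu - a * lam) / a - (sig * nu - (C - a) * mu) / (C - a)
    da <- tryCatch(solve(Q + diag(D, n), rhs), error = function(e) NULL)
    if (is.null(da)) break
    dlam <- (sig * nu - a * lam - lam * da) / a
    dmu <- (sig * nu - (C - a) * mu + mu * da) / (C - a)
    stepmax <- function(x, dx) {
      i <- dx < 0
      if (!any(i)) 1 else min(1, 0.995 * min(-x[i] / dx[i]))
    }
    st <- min(stepmax(a, da), stepmax(C - a, -da),
              stepmax(lam, dlam), stepmax(mu, dmu))
    if (st <= 1e-14) break
    a <- a + st * da; lam <- lam + st * dlam; mu <- mu + st * dmu
  }
  if (best_kkt > tol * 100)
    stop(sprintf(
      "twin SVM dual solver did not reach tolerance (KKT residual %.2e)",
      best_kkt), call. = FALSE)
  list(alpha = best, kkt = best_kkt, iters = max_iter)
}

# Solve one plane: minimize ||A u||-type objective keeping `other` at
# distance 1.  Returns w, b, duals and KKT residual.
.tsvm_plane <- function(own, other, C, epsilon, tol) {
  H <- cbind(own, 1)
  G <- cbind(other, 1)
  M <- crossprod(H)
  eps <- epsilon * sum(diag(M)) / ncol(M)
  M <- M + diag(eps, ncol(M))
  R <- chol(M)
  PGt <- backsolve(R, forwardsolve(t(R), t(G)))   # M^{-1} G'
  Q <- G %*% PGt
  Q <- (Q + t(Q)) / 2
  sol <- .boxqp(Q, C, tol = min(tol, 1e-8))
  u <- -as.vector(PGt %*% sol$alpha)
  d <- length(u)
  list(w = u[-d], b = u[d], alpha = sol$alpha, kkt = sol$kkt)
}

#' Twin support vector machine
#'
#' Fits the two nonparallel hyperplanes of a linear twin SVM by solving the
#' two dual box-constrained quadratic programs with a primal-dual
#' interior-point method plus active-set polish; the fit records the achieved
#' projected-gradient KKT residual (on the multiplier scale, i.e. divided by
#' `max(1, C)`), which must come out below `tol`.  Prediction assigns each
#' sample to the class whose hyperplane is nearer (see [predict.twinsvm()]).
#'
#' `twinsvm` is generic with a default matrix method and a formula method.
#'
#' @param x Numeric matrix of features (samples in rows), or a formula.
#' @param y Class labels: a factor with two levels, or numeric `+1`/`-1`.
#'   The positive class (`+1`, or the `"patient"` level if present, else the
#'   first factor level) is class 1.
#' @param C1,C2 Positive penalty parameters of the two quadratic programs.
#' @param epsilon Relative ridge added to the Gram matrices before inversion
#'   (scaled by `trace/dim`); must be positive.
#' @param tol KKT residual tolerance for the dual solver.
#' @param ... Passed between methods.
#' @return Object of class `"twinsvm"` with elements `w1`, `b1`, `w2`, `b2`,
#'   `duals` (the two multiplier vectors), `kkt_residual`, `C1`, `C2`,
#'   `epsilon` and `classes` (labels of class 1 and class 2).
#' @examples
#' x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 3), 20))
#' y <- rep(c(1, -1), each = 20)
#' fit <- twinsvm(x, y)
#' mean(predict(fit, x) == y)
#' @export
twinsvm <- function(x, ...) UseMethod("twinsvm")

#' @rdname twinsvm
#' @export
twinsvm.default <- function(x, y, C1 = 1, C2 = 1, epsilon = 1e-6,
                            tol = 1e-6, ...) {
  if (!is.numeric(C1) || !is.numeric(C2) || C1 <= 0 || C2 <= 0)
    stop("penalties C1 and C2 must be positive", call. = FALSE)
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("`epsilon` must be positive", call. = FALSE)
  x <- as.matrix(x)
  if (is.factor(y) || is.character(y)) {
    y <- as.factor(y)
    if (nlevels(y) != 2L) stop("`y` must have exactly 2 classes", call. = FALSE)
    lv <- levels(y)
    pos <- if ("patient" %in% lv) "patient" else lv[1]
    classes <- c(pos, setdiff(lv, pos))
    yy <- ifelse(as.character(y) == pos, 1, -1)
  } else {
    if (!all(y %in% c(-1, 1)))
      stop("numeric `y` must be coded +1 / -1", call. = FALSE)
    classes <- c("1", "-1")
    yy <- y
  }
  X1 <- x[yy > 0, , drop = FALSE]
  X2 <- x[yy < 0, , drop = FALSE]
  if (nrow(X1) == 0L || nrow(X2) == 0L)
    stop("both classes must be nonempty", call. = FALSE)
  p1 <- .tsvm_plane(X1, X2, C1, epsilon, tol)
  p2 <- .tsvm_plane(X2, X1, C2, epsilon, tol)
  structure(list(w1 = p1$w, b1 = p1$b, w2 = p2$w, b2 = p2$b,
                 duals = list(alpha = p1$alpha, gamma = p2$alpha),
                 kkt_residual = max(p1$kkt, p2$kkt),
                 C1 = C1, C2 = C2, epsilon = epsilon, classes = classes,
                 n_features = ncol(x)),
            class = "twinsvm")
}

#' @rdname twinsvm
#' @param data Data frame for the formula interface.
#' @export
twinsvm.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  mm <- stats::model.matrix(attr(mf, "terms"), mf)
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  fit <- twinsvm.default(mm, y, ...)
  fit$terms <- attr(mf, "terms")
  fit
}

#' Predict method for twin SVM fits
#'
#' Each sample is assigned to the class whose hyperplane has the smaller
#' perpendicular distance `|w_k . x + b_k| / ||w_k||`; exact ties go to
#' class 1.
#'
#' @param object A `"twinsvm"` fit.
#' @param newdata Matrix (or data frame for formula fits) of samples.
#' @param type `"class"` for labels, `"distance"` for the two plane
#'   distances.
#' @param ... Unused.
#' @return Labels in the coding the model was fitted with, or an `n x 2`
#'   matrix of distances.
#' @export
predict.twinsvm <- function(object, newdata, type = c("class", "distance"),
                            ...) {
  type <- match.arg(type)
  if (!is.null(object$terms) && is.data.frame(newdata)) {
    mm <- stats::model.matrix(stats::delete.response(object$terms), newdata)
    newdata <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  }
  x <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L)
       else as.matrix(newdata)
  if (ncol(x) != object$n_features)
    stop(sprintf("feature count mismatch: model has %d, data has %d",
                 object$n_features, ncol(x)), call. = FALSE)
  n1 <- sqrt(sum(object$w1^2)); n2 <- sqrt(sum(object$w2^2))
  if (n1 == 0 || n2 == 0)
    stop("degenerate twin SVM model: a plane has zero normal vector",
         call. = FALSE)
  d1 <- abs(x %*% object$w1 + object$b1) / n1
  d2 <- abs(x %*% object$w2 + object$b2) / n2
  if (type == "distance")
    return(cbind(class1 = as.vector(d1), class2 = as.vector(d2)))
  lab <- ifelse(d1 <= d2, object$classes[1], object$classes[2])
  if (all(object$classes == c("1", "-1"))) as.numeric(lab) else lab
}

#' @export
print.twinsvm <- function(x, ...) {
  cat("Linear twin SVM\n")
  cat(sprintf("  features: %d   C1 = %g, C2 = %g, epsilon = %g\n",
              x$n_features, x$C1, x$C2, x$epsilon))
  cat(sprintf("  KKT residual: %.2e\n", x$kkt_residual))
  invisible(x)
}

#' @export
summary.twinsvm <- function(object, ...) {
  cat("Linear twin SVM\n")
  cat(sprintf("  plane 1: ||w1|| = %.4g, b1 = %.4g, %d active multiplier(s)\n",
              sqrt(sum(object$w1^2)), object$b1,
              sum(object$duals$alpha > 1e-8)))
  cat(sprintf("  plane 2: ||w2|| = %.4g, b2 = %.4g, %d active multiplier(s)\n",
              sqrt(sum(object$w2^2)), object$b2,
              sum(object$duals$gamma > 1e-8)))
  cat(sprintf("  KKT residual %.2e (tolerance met: %s)\n",
              object$kkt_residual, object$kkt_residual <= 1e-6))
  invisible(object)
}

#' @export
coef.twinsvm <- function(object, ...) {
  list(plane1 = c(object$w1, b = object$b1),
       plane2 = c(object$w2, b = object$b2))
}

#' Select twin SVM penalties by inner cross-validation
#'
#' Exhaustively evaluates every `(C1, C2)` pair from the grid by stratified
#' inner cross-validation and returns the pair with the highest mean
#' accuracy; ties are broken toward smaller penalties (smaller `max(C1,C2)`,
#' then smaller `C1 + C2`, then smaller `C1`).
#'
#' @param x Feature matrix.
#' @param y Labels (as in [twinsvm()]).
#' @param C_grid Vector of positive candidate penalties.
#' @param k Inner fold count (default 3).
#' @param seed Seed for the inner fold assignment.
#' @param epsilon,tol Passed to [twinsvm()].
#' @return Named numeric vector `c(C1, C2)` with attribute `"accuracy"` (the
#'   full grid of inner-CV accuracies).
#' @export
twinsvm_grid_search <- function(x, y, C_grid, k = 3L, seed = 1L,
                                epsilon = 1e-6, tol = 1e-6) {
  stopifnot(length(C_grid) >= 1L, all(C_grid > 0))
  x <- as.matrix(x)
  yy <- if (is.numeric(y)) ifelse(y > 0, "pos", "neg") else as.character(y)
  plan <- make_cv_plan(yy, k = k, runs = 1L, seed = seed)
  folds <- plan$folds[[1]]
  grid <- expand.grid(C1 = sort(C_grid), C2 = sort(C_grid))
  grid <- grid[order(pmax(grid$C1, grid$C2), grid$C1 + grid$C2, grid$C1), ]
  acc <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ok <- 0L; tot <- 0L
    for (f in seq_len(k)) {
      tr <- folds != f; te <- !tr
      fit <- twinsvm(x[tr, , drop = FALSE], y[tr], C1 = grid$C1[i],
                     C2 = grid$C2[i], epsilon = epsilon, tol = tol)
      pred <- predict(fit, x[te, , drop = FALSE])
      truth <- y[te]
      ok <- ok + sum(as.character(pred) == as.character(truth))
      tot <- tot + sum(te)
    }
    acc[i] <- ok / tot
  }
  best <- which.max(acc)   # first maximum = smallest C by the ordering above
  out <- c(C1 = grid$C1[best], C2 = grid$C2[best])
  attr(out, "accuracy") <- cbind(grid, accuracy = acc)
  out
}
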