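# Shared fixtures, generated in code (no stored data).

# random test image with reproducible content
rand_image <- function(n, m = n, seed = 1) {
  set.seed(seed)
  matrix(stats::rnorm(n * m), n, m)
}

# step-edge image with structure off the dyadic grid (shift-invariance
# fixtures); a diagonal edge plus an axis-aligned step
edge_image <- function(n = 64) {
  img <- outer(seq_len(n), seq_len(n), function(i, j) as.numeric(i + j > n))
  img[, seq.int(ceiling(0.45 * n), n)] <- img[, seq.int(ceiling(0.45 * n), n)] + 0.5
  img
}

# small phantom cohort reused across tests (memoised per options)
.fixture_env <- new.env()
tiny_cohort <- function(n_per_class = 8, image_size = 64, n_slices = 2,
                        effect_size = 1, noise_sd = 0.05, seed = 101) {
  key <- paste(n_per_class, image_size, n_slices, effect_size, noise_sd, seed,
               sep = "_")
  if (is.null(.fixture_env[[key]])) {
    spec <- phantom_spec(image_size = image_size, n_slices = n_slices,
                         effect_size = effect_size, noise_sd = noise_sd,
                         seed = seed)
    .fixture_env[[key]] <- phantom_cohort(spec, n_per_class, n_per_class)
  }
  .fixture_env[[key]]
}

# canonical twin SVM fixture: two parallel rows of points
tsvm_fixture <- function() {
  list(X1 = rbind(c(0, 0), c(1, 0), c(2, 0)),
       X2 = rbind(c(0, 2), c(1, 2), c(2, 2)),
       y = rep(c(1, -1), each = 3))
}

# independent generic-QP oracle for the twin SVM primal (Eqs of the model):
# minimize 0.5 u'(H'H + eps I)u + C 1'xi  s.t.  G u - xi <= -1, xi >= 0,
# solved over x = (u, xi) with pracma's active-set QP.  The tiny ridge on the
# xi block makes the Hessian positive definite without materially moving the
# solution.
tsvm_primal_oracle <- function(own, other, C, epsilon = 1e-6) {
  H <- cbind(own, 1)
  G <- cbind(other, 1)
  M <- crossprod(H)
  eps <- epsilon * sum(diag(M)) / ncol(M)
  d <- ncol(H)
  m2 <- nrow(G)
  Cmat <- rbind(cbind(M + diag(eps, d), matrix(0, d, m2)),
                cbind(matrix(0, m2, d), diag(1e-10, m2)))
  dvec <- c(rep(0, d), rep(C, m2))
  A <- cbind(G, -diag(m2))
  b <- rep(-1, m2)
  lb <- c(rep(-1e6, d), rep(0, m2))
  ub <- rep(1e6, d + m2)
  sol <- pracma::quadprog(Cmat, dvec, A = A, b = b, lb = lb, ub = ub)
  list(w = sol$xmin[seq_len(d - 1)], b = sol$xmin[d],
       xi = sol$xmin[-seq_len(d)], value = sol$fval)
}

# dual objective value reached by a fitted plane
tsvm_dual_value <- function(alpha, own, other, epsilon = 1e-6) {
  H <- cbind(own, 1)
  G <- cbind(other, 1)
  M <- crossprod(H)
  eps <- epsilon * sum(diag(M)) / ncol(M)
  Q <- G %*% solve(M + diag(eps, ncol(M)), t(G))
  sum(alpha) - 0.5 * sum(alpha * (Q %*% alpha))
}
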