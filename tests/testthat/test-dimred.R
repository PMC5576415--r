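# PCA and Fisher LDA: oracles, invariants, degenerate cases.

test_that("PCA eigenvalues match a direct covariance eigendecomposition", {
  set.seed(21)
  x <- matrix(rnorm(40), 10, 4)
  m <- pca_fit(x, 3)
  oracle <- eigen(stats::cov(x), symmetric = TRUE)$values
  expect_equal(m$eigenvalues[1:4], oracle, tolerance = 1e-10)
})

test_that("components are orthonormal and variance is conserved", {
  set.seed(22)
  x <- matrix(rnorm(30 * 12), 30, 12)
  m <- pca_fit(x, 8)
  G <- crossprod(m$components)
  expect_lt(max(abs(G - diag(8))), 1e-8)
  z <- pca_transform(m, x)
  expect_equal(sum(apply(z, 2, stats::var)), sum(m$eigenvalues[1:8]),
               tolerance = 1e-8)
})

test_that("the fitted mean projects to zero and reconstruction is lossless", {
  set.seed(23)
  x <- matrix(rnorm(15 * 6), 15, 6)
  m <- pca_fit(x, 6)   # all components (n - 1 > p here)
  expect_lt(max(abs(pca_transform(m, m$mean))), 1e-10)
  xr <- pca_transform(m, x) %*% t(m$components)
  xr <- sweep(xr, 2, m$mean, `+`)
  expect_lt(max(abs(xr - x)), 1e-8)
})

test_that("reconstruction error is nonincreasing in the component count", {
  set.seed(24)
  x <- matrix(rnorm(20 * 10), 20, 10)
  errs <- vapply(1:9, function(k) {
    m <- pca_fit(x, k)
    xr <- sweep(pca_transform(m, x) %*% t(m$components), 2, m$mean, `+`)
    sum((xr - x)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("rank limits: n samples give at most n-1 nonzero eigenvalues", {
  set.seed(25)
  for (n in c(7, 12)) {
    x <- matrix(rnorm(n * 40), n, 40)
    m <- pca_fit(x, n - 1)
    expect_length(m$eigenvalues, n - 1)
    expect_true(all(m$eigenvalues > 0))
  }
  # collinear points in 2-D: exactly one nonzero eigenvalue
  x <- cbind(1:3, 2 * (1:3))
  m <- pca_fit(x, 1)
  expect_gt(m$eigenvalues[1], 0)
  expect_lt(m$eigenvalues[2] / m$eigenvalues[1], 1e-12)
  expect_error(pca_fit(x, 5), "n_components")
  expect_error(pca_transform(m, matrix(0, 2, 5)), "mismatch")
})

test_that("LDA recovers the analytic Fisher axis for isotropic classes", {
  base <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))  # isotropic scatter
  x <- rbind(base, sweep(base, 2, c(1, 0), `+`))
  lab <- rep(c("control", "patient"), each = 4)
  f <- fisher_lda(x, lab)
  expect_equal(abs(f$axes[, 1]), c(1, 0), tolerance = 1e-8)
  expect_equal(f$l, 1L)
  # exactly one nonzero generalized eigenvalue for 2 classes
  ev <- f$eigenvalues
  expect_gt(ev[1], 0)
})

test_that("scatter matrices are symmetric PSD with rank(S_B) <= c-1", {
  set.seed(26)
  x <- matrix(rnorm(30 * 5), 30, 5)
  lab <- rep(c("a", "b", "c"), each = 10)
  f <- fisher_lda(x, lab, l = 2)
  expect_equal(f$S_B, t(f$S_B))
  expect_equal(f$S_w, t(f$S_w))
  expect_true(all(eigen(f$S_B, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-10))
  expect_true(all(eigen(f$S_w, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-10))
  expect_equal(sum(eigen(f$S_B, symmetric = TRUE,
                         only.values = TRUE)$values > 1e-10), 2L)
})

test_that("the fitted axis dominates 1000 random directions in Fisher ratio", {
  set.seed(27)
  x <- rbind(matrix(rnorm(40 * 4), 40, 4),
             sweep(matrix(rnorm(40 * 4), 40, 4), 2, c(1.5, 0.5, 0, -1), `+`))
  lab <- rep(c("control", "patient"), each = 40)
  f <- fisher_lda(x, lab)
  j_fit <- twinwave:::.fisher_ratio(f, f$axes[, 1])
  dirs <- matrix(rnorm(1000 * 4), 4)
  j_rand <- apply(dirs, 2, function(w)
    twinwave:::.fisher_ratio(f, w / sqrt(sum(w^2))))
  expect_true(all(j_fit >= j_rand))
})

test_that("LDA parameter recovery on Gaussian classes with known axis", {
  set.seed(1)
  n <- 200
  x0 <- matrix(rnorm(n * 2), n, 2)          # identity within-class covariance
  delta <- c(1.5, 1)
  x <- rbind(x0[1:(n / 2), ], sweep(x0[(n / 2 + 1):n, ], 2, delta, `+`))
  lab <- rep(c("control", "patient"), each = n / 2)
  f <- fisher_lda(x, lab)
  # sharp oracle: the closed-form sample Fisher direction S_w^{-1}(m2 - m1)
  m1 <- colMeans(x[lab == "control", ]); m2 <- colMeans(x[lab == "patient", ])
  Sw <- crossprod(sweep(x[lab == "control", ], 2, m1)) +
        crossprod(sweep(x[lab == "patient", ], 2, m2))
  w_samp <- solve(Sw, m2 - m1); w_samp <- w_samp / sqrt(sum(w_samp^2))
  expect_gt(abs(sum(f$axes[, 1] * w_samp)), 1 - 1e-8)
  # and the population direction is recovered at this sample size
  w_pop <- delta / sqrt(sum(delta^2))
  expect_gt(abs(sum(f$axes[, 1] * w_pop)), 0.99)
})

test_that("projection separates class means and respects dimensions", {
  set.seed(29)
  x <- rbind(matrix(rnorm(20), 10, 2), matrix(rnorm(20, 2), 10, 2))
  lab <- rep(c("patient", "control"), each = 10)
  f <- fisher_lda(x, lab)
  z <- lda_transform(f, x)
  expect_equal(ncol(z), 1L)
  expect_gt(abs(mean(z[lab == "patient", ]) - mean(z[lab == "control", ])), 0)
  expect_error(lda_transform(f, matrix(0, 3, 7)), "mismatch")
  expect_error(fisher_lda(x[1:11, ], lab[1:11]), "at least 2 samples")
})

test_that("LDA is invariant (up to sign) to invertible re-parameterization", {
  set.seed(30)
  x <- rbind(matrix(rnorm(60), 20, 3), matrix(rnorm(60, 1), 20, 3))
  lab <- rep(c("a", "b"), each = 20)
  A <- matrix(rnorm(9), 3) + diag(3)
  z1 <- lda_transform(fisher_lda(x, lab), x)
  z2 <- lda_transform(fisher_lda(x %*% A, lab), x %*% A)
  cors <- abs(stats::cor(z1, z2))
  # the small within-class ridge breaks exact invariance, hence the tolerance
  expect_gt(cors[1, 1], 0.999)
})
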