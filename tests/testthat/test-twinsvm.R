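# Twin SVM: geometry fixtures, QP oracle equivalence, duality, symmetry,
# prediction rules, grid search.

test_that("parallel-row fixture yields the two obvious planes", {
  fx <- tsvm_fixture()
  fit <- twinsvm(rbind(fx$X1, fx$X2), fx$y)
  # plane 1 hugs class 1 (y = 0), plane 2 hugs class 2 (y = 2)
  expect_lt(max(abs(fx$X1 %*% fit$w1 + fit$b1)), 1e-4)
  expect_lt(max(abs(fx$X2 %*% fit$w2 + fit$b2)), 1e-4)
  expect_lte(fit$kkt_residual, 1e-6)
  # multipliers live in the box
  expect_true(all(fit$duals$alpha >= -1e-8 & fit$duals$alpha <= 1 + 1e-8))
  # training points classified perfectly
  expect_equal(predict(fit, rbind(fx$X1, fx$X2)), fx$y)
})

test_that("dual solution matches a generic primal QP solve on small instances", {
  skip_if_not_installed("pracma")
  fx <- tsvm_fixture()
  cases <- list(list(X1 = fx$X1, X2 = fx$X2, C = 1))
  set.seed(31)
  for (i in 1:5) {
    n1 <- sample(4:10, 1); n2 <- sample(4:10, 1); d <- sample(2:3, 1)
    cases[[i + 1]] <- list(
      X1 = matrix(rnorm(n1 * d), n1),
      X2 = matrix(rnorm(n2 * d), n2) + 1.5,
      C = sample(c(0.5, 1, 4), 1))
  }
  for (cs in cases) {
    fit <- twinsvm(rbind(cs$X1, cs$X2), rep(c(1, -1), c(nrow(cs$X1), nrow(cs$X2))),
                   C1 = cs$C, C2 = cs$C)
    ora <- tsvm_primal_oracle(cs$X1, cs$X2, cs$C)
    scale <- max(1, sqrt(sum(c(ora$w, ora$b)^2)))
    expect_lt(max(abs(c(fit$w1, fit$b1) - c(ora$w, ora$b))) / scale, 1e-4)
    # plane 2 is the same program with the class roles swapped
    ora2 <- tsvm_primal_oracle(cs$X2, cs$X1, cs$C)
    scale2 <- max(1, sqrt(sum(c(ora2$w, ora2$b)^2)))
    expect_lt(max(abs(c(fit$w2, fit$b2) - c(ora2$w, ora2$b))) / scale2, 1e-4)
  }
})

test_that("dual and primal objective values agree (strong duality)", {
  set.seed(32)
  for (i in 1:4) {
    X1 <- matrix(rnorm(12), 6, 2); X2 <- matrix(rnorm(12), 6, 2) + 2
    C <- c(0.5, 2)[i %% 2 + 1]
    fit <- twinsvm(rbind(X1, X2), rep(c(1, -1), each = 6), C1 = C, C2 = C)
    dual_val <- tsvm_dual_value(fit$duals$alpha, X1, X2)
    # primal value of the recovered plane, xi implied by the constraints
    H <- cbind(X1, 1); G <- cbind(X2, 1)
    M <- crossprod(H); eps <- 1e-6 * sum(diag(M)) / ncol(M)
    u <- c(fit$w1, fit$b1)
    xi <- pmax(0, 1 + as.vector(G %*% u))
    primal_val <- 0.5 * sum(u * ((M + diag(eps, 3)) %*% u)) + C * sum(xi)
    # dual maximum equals (negated) primal minimum at the optimum:
    # primal = -dual + const 0 here since strong duality holds exactly
    expect_equal(primal_val, -(-dual_val), tolerance = 1e-5 * max(1, abs(dual_val)))
  }
})

test_that("swapping class labels swaps the two planes", {
  set.seed(33)
  X1 <- matrix(rnorm(10), 5, 2); X2 <- matrix(rnorm(10), 5, 2) + 1
  y <- rep(c(1, -1), each = 5)
  f1 <- twinsvm(rbind(X1, X2), y, C1 = 2, C2 = 0.7)
  f2 <- twinsvm(rbind(X1, X2), -y, C1 = 0.7, C2 = 2)
  expect_equal(c(f1$w1, f1$b1), c(f2$w2, f2$b2), tolerance = 1e-8)
  expect_equal(c(f1$w2, f1$b2), c(f2$w1, f2$b1), tolerance = 1e-8)
})

test_that("duplicating points of one class leaves its plane unchanged", {
  fx <- tsvm_fixture()
  f1 <- twinsvm(rbind(fx$X1, fx$X2), fx$y)
  f2 <- twinsvm(rbind(fx$X1, fx$X1, fx$X2),
                rep(c(1, -1), c(6, 3)))
  dir1 <- c(f1$w1, f1$b1) / sqrt(sum(c(f1$w1, f1$b1)^2))
  dir2 <- c(f2$w1, f2$b1) / sqrt(sum(c(f2$w1, f2$b1)^2))
  expect_lt(min(max(abs(dir1 - dir2)), max(abs(dir1 + dir2))), 1e-6)
})

test_that("prediction follows nearest-plane geometry with ties to class 1", {
  fx <- tsvm_fixture()
  fit <- twinsvm(rbind(fx$X1, fx$X2), fx$y)
  expect_equal(predict(fit, c(1, -0.5)), 1)       # distance 0.5 vs 2.5
  expect_equal(predict(fit, c(1, 1)), 1)          # equidistant -> class 1
  d <- predict(fit, c(1, -0.5), type = "distance")
  expect_equal(as.vector(d), c(0.5, 2.5), tolerance = 1e-4)
  expect_error(predict(fit, matrix(0, 1, 5)), "mismatch")
})

test_that("scaling the inputs scales distances but not predictions", {
  set.seed(34)
  X <- rbind(matrix(rnorm(16), 8, 2), matrix(rnorm(16), 8, 2) + 2)
  y <- rep(c(1, -1), each = 8)
  f1 <- twinsvm(X, y)
  f5 <- twinsvm(5 * X, y)
  te <- matrix(rnorm(20), 10, 2) + 1
  expect_equal(predict(f1, te), predict(f5, 5 * te))
  d1 <- predict(f1, te, type = "distance")
  d5 <- predict(f5, 5 * te, type = "distance")
  expect_equal(unname(d5 / d1), matrix(5, 10, 2), tolerance = 1e-4)
})

test_that("factor labels work and 'patient' is the positive class", {
  set.seed(35)
  X <- rbind(matrix(rnorm(16, 3), 8, 2), matrix(rnorm(16), 8, 2))
  y <- rep(c("patient", "control"), each = 8)
  fit <- twinsvm(X, y)
  expect_equal(fit$classes[1], "patient")
  expect_true(all(predict(fit, X[1:2, ]) %in% c("patient", "control")))
})

test_that("the formula interface matches the matrix interface", {
  set.seed(36)
  df <- data.frame(a = rnorm(20), b = rnorm(20),
                   y = factor(rep(c("patient", "control"), each = 10)))
  df$a[df$y == "patient"] <- df$a[df$y == "patient"] + 2
  f1 <- twinsvm(y ~ a + b, data = df)
  f2 <- twinsvm(as.matrix(df[, c("a", "b")]), df$y)
  expect_equal(c(f1$w1, f1$b1), c(f2$w1, f2$b1), tolerance = 1e-10)
  expect_length(predict(f1, df), 20L)
})

test_that("invalid parameters and degenerate inputs raise errors", {
  fx <- tsvm_fixture()
  X <- rbind(fx$X1, fx$X2)
  expect_error(twinsvm(X, fx$y, C1 = 0), "positive")
  expect_error(twinsvm(X, fx$y, epsilon = -1), "positive")
  expect_error(twinsvm(X, rep(1, 6)), "nonempty")
  expect_error(twinsvm(X, c(1, 2, 1, -1, -1, -1)), "\\+1 / -1")
})

test_that("grid search honours exhaustiveness and the smaller-C tie rule", {
  set.seed(37)
  X <- rbind(matrix(rnorm(24), 12, 2), matrix(rnorm(24), 12, 2) + 4)
  y <- rep(c(1, -1), each = 12)
  # single-value grid returns that value
  g1 <- twinsvm_grid_search(X, y, C_grid = 2.5)
  expect_equal(unname(g1), c(2.5, 2.5), ignore_attr = TRUE)
  # separable data: every pair perfect, smallest C returned
  g2 <- twinsvm_grid_search(X, y, C_grid = c(0.25, 1, 4))
  expect_equal(unname(g2), c(0.25, 0.25), ignore_attr = TRUE)
  # selected pair attains the maximum of the recorded accuracy grid
  Xn <- X + matrix(rnorm(48, sd = 2.5), 24, 2)
  g3 <- twinsvm_grid_search(Xn, y, C_grid = c(0.1, 1))
  tab <- attr(g3, "accuracy")
  best_rows <- tab[tab$accuracy == max(tab$accuracy), ]
  expect_true(any(best_rows$C1 == g3["C1"] & best_rows$C2 == g3["C2"]))
})
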