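test_that("one_hot builds indicator columns in the stated class order", {
  Y <- one_hot(c("EOPE", "nPTB", "EOPE"), c("EOPE", "nPTB"))
  expect_equal(unname(Y), rbind(c(1, 0), c(0, 1), c(1, 0)))
  expect_equal(unname(colSums(Y)), c(2, 1))
  expect_error(one_hot(c("EOPE", "EOPE"), c("EOPE", "nPTB")),
               "Both classes", class = "methylpls_validation_error")
  expect_error(one_hot(c("EOPE", "other"), c("EOPE", "nPTB")),
               "Unseen", class = "methylpls_validation_error")
})

# independent oracle: literal soft-thresholding at the (keepX+1)-th largest
# absolute weight, then unit normalization
soft_threshold_oracle <- function(w, keepX) {
  lambda <- if (keepX < length(w)) sort(abs(w), decreasing = TRUE)[keepX + 1] else 0
  out <- sign(w) * pmax(abs(w) - lambda, 0)
  out / sqrt(sum(out^2))
}

test_that("select_features equals the soft-threshold oracle on enumerated fixtures", {
  w <- c(3, -2, 1, 0.5)
  expect_equal(select_features(w, 2), c(2, -1, 0, 0) / sqrt(5), tolerance = 1e-12)

  cases <- list(
    list(w = c(0.3, -1.4, 2.2, 0.1, -0.6), k = 3),
    list(w = c(-5, 4, -3, 2, -1), k = 1),
    list(w = rnorm(20), k = 7),
    list(w = c(2, -2.5), k = 2))
  withr::with_seed(3, for (cs in cases) {
    expect_equal(select_features(cs$w, cs$k),
                 soft_threshold_oracle(cs$w, cs$k), tolerance = 1e-12)
  })
  # keepX = length leaves the direction unchanged
  w2 <- c(1.5, -0.2, 0.7)
  expect_equal(select_features(w2, 3), w2 / sqrt(sum(w2^2)), tolerance = 1e-12)
})

test_that("select_features breaks complete ties toward the lowest indices", {
  out <- select_features(c(1, 1, 1), 2)
  expect_equal(out, c(1, 1, 0) / sqrt(2), tolerance = 1e-12)
  expect_error(select_features(c(1, 2), 3), class = "methylpls_validation_error")
  expect_error(select_features(c(1, 2), 0), class = "methylpls_validation_error")
})

test_that("with two separated classes, keepX = k recovers the signature and a 0 training OER", {
  withr::local_seed(5)
  n <- 20; p <- 30; k <- 4
  X <- matrix(rnorm(n * p, 0.5, 0.05), n, p,
              dimnames = list(NULL, paste0("f", 1:p)))
  y <- rep(c("case", "ctrl"), each = n / 2)
  X[y == "case", 1:k] <- X[y == "case", 1:k] + 0.5
  m <- fit_splsda(X, y, keepX = k)
  expect_setequal(selected_features(m), paste0("f", 1:k))
  p_hat <- predict(m, X)
  expect_equal(compute_oer(p_hat$class_max, y)$overall, 0)
})

test_that("the dense one-component loading matches the SVD of the scaled cross-product", {
  withr::local_seed(11)
  X <- matrix(runif(6 * 4, 0.2, 0.8), 6, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- c("a", "a", "a", "b", "b", "b")
  m <- fit_splsda(X, y, n_components = 1, keepX = 4)
  # independent oracle: full SVD of the scaled X'Y
  Xs <- scale(X)
  Ys <- scale(one_hot(y, c("a", "b")))
  u_oracle <- svd(crossprod(Xs, Ys))$u[, 1]
  cos <- abs(sum(m$loadings[, 1] * u_oracle))
  expect_gt(cos, 1 - 1e-9)
  # component-1 scores correlate with the oracle projection
  t_oracle <- Xs %*% u_oracle
  t_mine <- Xs %*% m$loadings[, 1]
  expect_gt(abs(cor(t_mine, t_oracle)), 0.999)
})

test_that("two-component score vectors are orthogonal after deflation", {
  co <- small_cohort(n_probes = 245, seed = 61)
  X <- t(co$beta)
  m <- fit_splsda(X, co$sheet$condition, n_components = 2, keepX = c(20, 20))
  Xs <- apply_scaling_for_test(X, m)
  t1 <- Xs %*% m$loadings[, 1]
  Xs2 <- Xs - t1 %*% t(m$x_regression_coefs[, 1])
  t2 <- Xs2 %*% m$loadings[, 2]
  cosangle <- abs(sum(t1 * t2)) / sqrt(sum(t1^2) * sum(t2^2))
  expect_lt(cosangle, 1e-6)
})

test_that("zero-variance features are rejected by name", {
  X <- make_beta(4, 10, seed = 71)
  X <- t(X)
  X[, 2] <- 0.4
  expect_error(fit_splsda(X, rep(c("a", "b"), 5)), "cg00002",
               class = "methylpls_data_error")
})

test_that("softmax probabilities follow the closed form and the threshold rule", {
  co <- small_cohort(n_probes = 245, seed = 81)
  m <- fit_splsda(t(co$beta), co$sheet$condition, keepX = 45)
  # arithmetic oracle for dummy scores (2, 1)
  expect_equal(exp(2) / (exp(2) + exp(1)), 0.7311, tolerance = 1e-4)
  pr <- predict(m, t(co$beta))
  expect_true(all(abs(pr$prob_EOPE + pr$prob_nPTB - 1) < 1e-9))
  # max-distance call agrees with the larger dummy score; thresholded call
  # flips exactly at the stated probability threshold
  expect_identical(pr$class_max,
                   ifelse(pr$score_EOPE >= pr$score_nPTB, "EOPE", "nPTB"))
  p54 <- which.min(abs(pr$prob_EOPE - 0.55))
  thr_high <- predict(m, t(co$beta), threshold = pr$prob_EOPE[p54] + 1e-6)
  thr_low <- predict(m, t(co$beta), threshold = pr$prob_EOPE[p54] - 1e-6)
  expect_identical(thr_high$class_threshold[p54], "nPTB")
  expect_identical(thr_low$class_threshold[p54], "EOPE")
})

test_that("prediction is invariant to feature order and errors on missing features", {
  co <- small_cohort(n_probes = 245, seed = 91)
  X <- t(co$beta)
  m <- fit_splsda(X, co$sheet$condition, keepX = 10)
  perm <- withr::with_seed(1, sample(ncol(X)))
  expect_equal(predict(m, X[, perm])$prob_EOPE, predict(m, X)$prob_EOPE,
               tolerance = 1e-12)
  expect_error(predict(m, X[, -1]), "missing", class = "methylpls_data_error")
})

test_that("the keepX budget bounds the nonzero loadings of every component", {
  co <- small_cohort(n_probes = 245, seed = 101)
  for (kx in c(5, 20, 45)) {
    m <- fit_splsda(t(co$beta), co$sheet$condition, n_components = 2,
                    keepX = c(kx, kx))
    expect_true(all(colSums(m$loadings != 0) <= kx))
    expect_equal(unname(apply(m$loadings, 2, function(u) sum(u^2))), c(1, 1),
                 tolerance = 1e-9)
  }
})
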