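make_blobs <- function(n = 15, sep = 3, sd = 0.3, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n, 0, sd), n),
             matrix(rnorm(2 * n, sep, sd), n),
             cbind(rnorm(n, 0, sd), rnorm(n, sep, sd)))
  list(X = X, y = rep(c("I", "II", "III"), each = n))
}

test_that("RBF kernel: unit self-similarity, symmetry, known value, PSD Gram", {
  expect_error(rbf_kernel(1:3, 1:3, 0), "sigma")
  expect_error(rbf_kernel(1:3, 1:2, 1), "equal length")
  set.seed(2)
  for (i in 1:5) {
    u <- rnorm(4); v <- rnorm(4); s <- runif(1, 0.5, 3)
    expect_equal(rbf_kernel(u, u, s), 1)
    expect_equal(rbf_kernel(u, v, s), rbf_kernel(v, u, s))
  }
  u <- c(0, 0); v <- c(2, 0)  # ||u-v|| = sigma * sqrt(2) with sigma = sqrt(2)
  expect_equal(rbf_kernel(u, v, sqrt(2)), exp(-1))
  X <- matrix(rnorm(40), 10, 4)
  K <- outer(1:10, 1:10, Vectorize(function(i, j) rbf_kernel(X[i, ], X[j, ], 1.3)))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("training solves the dual within KKT tolerances and separates blobs", {
  b <- make_blobs()
  m <- svm_train(b$X, b$y, C = 50)
  expect_equal(svm_predict(m, b$X)$class, b$y)  # 100% training accuracy
  for (sm in m$sub_models) {
    expect_lt(abs(sum(sm$alpha_all * sm$y_all)), 1e-6)
    expect_true(all(sm$alpha_all >= 0 & sm$alpha_all <= 50 + 1e-12))
  }
  expect_error(svm_train(b$X, rep("I", nrow(b$X))), "single-class")
  # conflicting duplicate labels: finite C absorbs, training completes
  Xd <- rbind(b$X, b$X[1:5, ])
  yd <- c(b$y, rep("II", 5))
  md <- svm_train(Xd, yd, C = 50)
  expect_lt(mean(svm_predict(md, Xd)$class == yd), 1)
  # degenerate constant dimension is dropped with a warning
  expect_warning(svm_train(cbind(b$X, 7), b$y), "zero-spread")
})

test_that("prediction: support vectors self-classify, centroids resolve, order-invariant", {
  b <- make_blobs(seed = 4)
  m <- svm_train(b$X, b$y)
  pr <- svm_predict(m, rbind(c(0, 0), c(3, 3), c(0, 3)))
  expect_equal(pr$class, c("I", "II", "III"))
  expect_equal(dim(pr$votes), c(3L, 3L))
  expect_error(svm_predict(m, matrix(0, 1, 5)), "dimension mismatch")
  # shuffling the training rows leaves predictions unchanged
  set.seed(9)
  perm <- sample(length(b$y))
  m2 <- svm_train(b$X[perm, ], b$y[perm])
  probe <- matrix(rnorm(20), 10, 2)
  expect_equal(svm_predict(m, probe)$class, svm_predict(m2, probe)$class)
})

test_that("our decision function agrees with an independent SVM on separable data", {
  skip_if_not_installed("e1071")
  b <- make_blobs(n = 20, seed = 11)
  m <- svm_train(b$X, b$y, C = 50)
  probe <- make_blobs(n = 10, seed = 12)$X
  ours <- svm_predict(m, probe)$class
  ref <- e1071::svm(x = b$X, y = factor(b$y), cost = 50, scale = TRUE)
  theirs <- as.character(predict(ref, probe))
  expect_gte(mean(ours == theirs), 0.95)
})

test_that("feature vector assembly mirrors the min/max-over-segments layout", {
  tex <- matrix(rep(1:10, 5), 10, 5,
                dimnames = list(NULL, c("contrast", "correlation", "entropy",
                                        "uniformity", "energy")))
  fv <- build_feature_vector(tex, 0.25)
  expect_length(fv, 11L)
  expect_equal(unname(fv[["contrast_min"]]), 1)
  expect_equal(unname(fv[["contrast_max"]]), 10)
  expect_equal(unname(fv[["area_fraction"]]), 0.25)
  const <- matrix(5, 10, 5, dimnames = dimnames(tex))
  fvc <- build_feature_vector(const, 0)
  expect_true(all(fvc[1:10] == 5))
  expect_error(build_feature_vector(tex[1:9, ], 0.1), "10 x 5")
  expect_error(build_feature_vector(tex, 1.5), "area fraction")
})

test_that("evaluation reports per-class recognition rates on the printed scale", {
  b <- make_blobs(n = 22, seed = 21)
  m <- svm_train(b$X[c(1:2, 23:24, 45:46), ], b$y[c(1:2, 23:24, 45:46)])
  test_idx <- setdiff(seq_along(b$y), c(1:2, 23:24, 45:46))
  tab <- svm_evaluate(m, b$X[test_idx, ], b$y[test_idx])
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$rate_pct >= 0 & tab$rate_pct <= 100))
  expect_equal(tab$rate_pct, 100 * tab$n_recognized / tab$n_test)
  expect_error(svm_evaluate(m, b$X[0, ], character(0)), "empty")
  # arithmetic of a 17/18/19-out-of-20 outcome
  fake_rates <- 100 * c(17, 18, 19) / 20
  expect_equal(fake_rates, c(85, 90, 95))
})

test_that("model serialization round-trips through the JSON archive", {
  b <- make_blobs(seed = 31)
  m <- svm_train(b$X, b$y)
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(svm_predict(m2, b$X)$class, svm_predict(m, b$X)$class)
  expect_equal(m2$sigma, m$sigma)
  expect_equal(m2$C, m$C)
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "other"), bad, auto_unbox = TRUE)
  expect_error(load_model(bad), "not a dermatex")
})

test_that("test accuracy does not degrade as class separation grows", {
  accs <- vapply(c(1.5, 3, 6), function(sep) {
    tr <- make_blobs(n = 12, sep = sep, seed = 41)
    te <- make_blobs(n = 12, sep = sep, seed = 42)
    m <- svm_train(tr$X, tr$y)
    mean(svm_predict(m, te$X)$class == te$y)
  }, 1)
  expect_true(all(diff(accs) >= 0))
  expect_equal(accs[3], 1)
})
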