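test_that("the scaler standardizes training features and drops constants", {
  x <- cbind(a = c(1, 3), b = c(5, 5))
  sc <- fit_scaler(x)
  z <- apply_scaler(sc, x)
  expect_equal(unname(z[, 1]), c(-1, 1))
  expect_equal(ncol(z), 1)  # constant feature dropped
  expect_equal(sc$n_dropped, 1)
  withr::with_seed(1, x2 <- matrix(rnorm(200), 20))
  sc2 <- fit_scaler(x2)
  z2 <- apply_scaler(sc2, x2)
  expect_lt(max(abs(colMeans(z2))), 1e-9)
  expect_lt(max(abs(sqrt(colMeans(sweep(z2, 2, colMeans(z2))^2)) - 1)), 1e-9)
  # the same drop is applied to new data
  expect_equal(ncol(apply_scaler(sc, cbind(c(0, 1, 2), c(9, 9, 9)))), 1)
  expect_error(fit_scaler(x[1, , drop = FALSE]),
               class = "ramancell_scaler_error")
})

test_that("PCA ratios match analytic eigenstructure", {
  withr::with_seed(2, {
    r1 <- outer(rnorm(30), rnorm(5))
    p1 <- fit_spectra_pca(r1, n_components = 2)
    expect_equal(p1$variance_ratio[1], 1, tolerance = 1e-9)
    # covariance [[2,1],[1,2]] has eigenvalues 3 and 1
    ch <- chol(matrix(c(2, 1, 1, 2), 2))
    g <- matrix(rnorm(20000), ncol = 2) %*% ch
    p2 <- fit_spectra_pca(g, n_components = 2)
    expect_equal(p2$variance_ratio, c(0.75, 0.25), tolerance = 0.02)
    x <- matrix(rnorm(50 * 8), 50)
    p3 <- fit_spectra_pca(x, n_components = 8)
    expect_true(all(diff(p3$variance_ratio) <= 1e-12))
    expect_true(all(p3$variance_ratio >= 0))
    expect_lte(sum(p3$variance_ratio), 1 + 1e-9)
  })
  expect_error(fit_spectra_pca(matrix(rnorm(20), 4), n_components = 4),
               class = "ramancell_pca_error")
})

test_that("PCA agrees with a direct eigendecomposition oracle", {
  withr::with_seed(3, x <- matrix(rnorm(40 * 12), 40) %*%
                     diag(seq(3, 0.5, length.out = 12)))
  p <- fit_spectra_pca(x, n_components = 12)
  xc <- sweep(x, 2, colMeans(x))
  eg <- eigen(stats::cov(x), symmetric = TRUE)
  expect_equal(p$variance_ratio, eg$values / sum(eg$values), tolerance = 1e-6)
  s_pkg <- apply_pca(p, x)
  s_ora <- xc %*% eg$vectors
  for (k in 1:12) {  # eigenvector sign is arbitrary per component
    expect_equal(abs(s_pkg[, k]), abs(s_ora[, k]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  g <- p$rotation
  expect_equal(crossprod(g), diag(12), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("train-fitted transforms are identical with or without test data", {
  withr::with_seed(4, all_x <- matrix(rnorm(60 * 10), 60))
  train_rows <- 1:40
  sc_a <- fit_scaler(all_x[train_rows, ])
  pc_a <- fit_spectra_pca(apply_scaler(sc_a, all_x[train_rows, ]), 5)
  # same training rows, test rows absent from the object entirely
  train_only <- all_x[train_rows, ]
  sc_b <- fit_scaler(train_only)
  pc_b <- fit_spectra_pca(apply_scaler(sc_b, train_only), 5)
  expect_identical(sc_a, sc_b)
  expect_identical(pc_a, pc_b)
})

test_that("the MLP separates well-separated classes and is deterministic", {
  d <- separable_scores(n_per_class = 100, d = 4, sep = 6, seed = 5)
  # monitor the training loss here: a 20-sample validation split makes
  # the early-stopping snapshot, not the optimizer, the tested quantity
  m1 <- fit_mlp(d$x, d$y, seed = 11, validation_fraction = 0)
  m2 <- fit_mlp(d$x, d$y, seed = 11, validation_fraction = 0)
  expect_identical(m1$weights, m2$weights)
  p <- predict(m1, d$x, type = "prob")
  cl <- predict(m1, d$x, type = "class")
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(cl, ifelse(p >= 0.5, "pediatric", "adult"))
  expect_gte(mean(cl == d$y), 0.98)
  m3 <- fit_mlp(d$x, d$y, seed = 12, validation_fraction = 0)
  expect_false(identical(m1$weights, m3$weights))
})

test_that("MLP input validation", {
  d <- separable_scores(20, seed = 6)
  bad <- d$x
  bad[1, 1] <- NA
  expect_error(fit_mlp(bad, d$y), class = "ramancell_mlp_error")
  expect_error(fit_mlp(d$x, d$y, hidden = rep(5, 11)),
               class = "ramancell_mlp_error")
  expect_error(fit_mlp(d$x, rep("adult", nrow(d$x))),
               class = "ramancell_mlp_error")
})

test_that("the architecture grid covers the search space of the study", {
  grid <- mlp_architectures()
  expect_equal(nrow(grid), 60)
  expect_true(any(grid$depth == 5 & grid$width == 5))
  five <- grid$layout[grid$depth == 5 & grid$width == 5][[1]]
  expect_equal(five, rep(5L, 5))
  expect_true(all(grid$depth %in% 1:10))
  expect_true(all(grid$width >= 2 & grid$width <= 100))
  expect_error(mlp_architectures(depths = 0:3))
  expect_error(mlp_architectures(widths = c(1, 5)))
})

test_that("grouped CV scores every architecture high on separable data", {
  d <- separable_scores(n_per_class = 60, d = 3, sep = 7, seed = 7)
  archs <- mlp_architectures(depths = c(1, 5), widths = c(5, 10))
  cv <- crossvalidate_mlp(d$x, d$y, d$meta, architectures = archs, k = 3,
                          seed = 2, max_epochs = 200,
                          validation_fraction = 0)
  expect_true(all(cv$results$mean_accuracy >= 0.95))
  expect_true(all(cv$results$mean_accuracy <= 1))
  # tie-break prefers fewer parameters: with all accuracies ~equal the
  # chosen architecture cannot have more parameters at equal accuracy
  top <- max(cv$results$mean_accuracy)
  cands <- cv$results[cv$results$mean_accuracy == top, ]
  expect_equal(cv$chosen$n_params, min(cands$n_params))
})

test_that("permuted labels drive CV accuracy to chance", {
  d <- separable_scores(n_per_class = 60, d = 3, sep = 7, seed = 8)
  y_perm <- withr::with_seed(9, sample(d$y))
  archs <- mlp_architectures(depths = 1, widths = c(5, 10))
  cv <- crossvalidate_mlp(d$x, y_perm, d$meta, architectures = archs, k = 3,
                          seed = 3, max_epochs = 200,
                          validation_fraction = 0)
  expect_gte(cv$chosen$mean_accuracy, 0.35)
  expect_lte(cv$chosen$mean_accuracy, 0.65)
})

test_that("CV refuses fold counts the cell structure cannot support", {
  d <- separable_scores(n_per_class = 8, d = 2, sep = 6, seed = 10)
  expect_error(
    crossvalidate_mlp(d$x, d$y, d$meta,
                      architectures = mlp_architectures(1, 5), k = 10),
    class = "ramancell_cv_error")
})
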