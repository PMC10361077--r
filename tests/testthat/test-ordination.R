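# PCA + varimax: closed-form eigenstructure oracles, rotation invariants,
# and the brute-force rotation-angle sweep.

test_that("two correlated traits give the closed-form eigenvalue split (1 +/- r)", {
  set.seed(11)
  n <- 400L
  z <- rnorm(n)
  r_target <- 0.6
  x <- cbind(a = z, b = r_target * z + sqrt(1 - r_target^2) * rnorm(n))
  r_obs <- cor(x)[1, 2]
  ord <- fit_pca(x, k = 2L)
  expect_equal(ord$variance_explained,
               100 * c(1 + r_obs, 1 - r_obs) / 2, tolerance = 1e-8)
})

test_that("a duplicated column loads everything on PC1", {
  set.seed(12)
  z <- rnorm(50)
  x <- cbind(a = z, b = z)
  ord <- fit_pca(x, k = 2L)
  expect_equal(ord$variance_explained[1], 100, tolerance = 1e-8)
  expect_equal(ord$variance_explained[2], 0, tolerance = 1e-8)
})

test_that("uncorrelated equal-variance traits share variance isotropically", {
  set.seed(13)
  x <- matrix(rnorm(4000 * 6), ncol = 6)
  ord <- fit_pca(x, k = 6L)
  expect_true(all(abs(ord$variance_explained - 100 / 6) < 3))
})

test_that("correlation PCA accounting is exact over all components", {
  tab <- toy_table(30L)
  ord <- fit_pca(tab, k = 6L)
  expect_equal(sum(ord$variance_explained), 100, tolerance = 1e-10)
  expect_true(all(diff(ord$variance_explained) <= 1e-12))  # non-increasing
  ## scores are centred and reconstruct the standardized data exactly
  expect_true(all(abs(colMeans(ord$scores)) < 1e-10))
  mat <- as.matrix(as.data.frame(tab)[, trait_names()])
  xs <- scale(mat)
  recon <- ord$scores %*% t(ord$eigenvectors)
  expect_lt(max(abs(recon - xs)), 1e-8)
})

test_that("degenerate ordination inputs raise informative errors", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(fit_pca(x[1, , drop = FALSE], k = 1L), "at least 2")
  x_const <- cbind(a = rnorm(10), b = rep(2, 10))
  expect_error(fit_pca(x_const, k = 2L), "zero-variance.*b")
  expect_error(fit_pca(x, k = 3L), "k must be")
})

test_that("sign convention makes the largest loading per column positive", {
  tab <- toy_table(40L)
  ord <- varimax_rotate(fit_pca(tab, 4L))
  for (j in seq_len(4L)) {
    expect_gt(ord$loadings[which.max(abs(ord$loadings[, j])), j], 0)
  }
})

test_that("varimax rotation preserves communalities and total variance", {
  tab <- generate_traits(default_design())
  ord0 <- fit_pca(tab, 4L)
  ord1 <- varimax_rotate(ord0)
  expect_lt(max(abs(rowSums(ord1$loadings^2) - rowSums(ord0$loadings^2))), 1e-8)
  expect_equal(sum(ord1$variance_explained_rotated),
               ord0$total_variance_explained, tolerance = 1e-8)
  ## the rotation is orthogonal and carries the scores with it
  rt <- ord1$rotation_matrix
  expect_lt(max(abs(t(rt) %*% rt - diag(4))), 1e-10)
  expect_lt(max(abs(ord0$scores %*% rt - ord1$scores)), 1e-10)
})

test_that("rotated solution beats a brute-force sweep of planar angles", {
  set.seed(14)
  for (rep in 1:3) {
    loadings <- matrix(rnorm(8), 4, 2)
    ord <- structure(list(loadings = loadings, scores = matrix(rnorm(40), 20, 2),
                          eigenvalues = c(1, 1), rotation_matrix = diag(2),
                          variance_explained = c(50, 50), k = 2L,
                          pca_matrix = "correlation",
                          traits = paste0("t", 1:4), rotated = FALSE),
                     class = "ordination")
    rotated <- varimax_rotate(ord)
    angles <- seq(0, pi / 2, by = 0.1 * pi / 180)
    sweep_best <- max(vapply(angles, function(a) {
      rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
      varimax_criterion(loadings %*% rot)
    }, numeric(1)))
    expect_gte(varimax_criterion(rotated$loadings) + 1e-9, sweep_best)
  }
})

test_that("perfectly simple loadings are a varimax fixed point", {
  loadings <- rbind(c(0.9, 0), c(0.8, 0), c(0, 0.7), c(0, 0.6))
  ord <- structure(list(loadings = loadings, scores = matrix(0, 5, 2),
                        eigenvalues = c(1.45, 0.85), rotation_matrix = diag(2),
                        variance_explained = c(60, 40), k = 2L,
                        pca_matrix = "correlation",
                        traits = paste0("t", 1:4), rotated = FALSE),
                   class = "ordination")
  rotated <- varimax_rotate(ord)
  ## identity up to column permutation and sign
  expect_equal(sort(abs(as.vector(rotated$loadings))),
               sort(c(0, 0, 0, 0, 0.6, 0.7, 0.8, 0.9)), tolerance = 1e-6)
})

test_that("k < 2 rotation is a warning no-op", {
  tab <- toy_table(20L)
  ord <- fit_pca(tab, k = 1L)
  expect_warning(out <- varimax_rotate(ord), "at least 2")
  expect_identical(out$loadings, ord$loadings)
})

test_that("predict reproduces training scores and handles new data", {
  tab <- toy_table(25L)
  ord <- varimax_rotate(fit_pca(tab, 4L))
  expect_lt(max(abs(predict(ord, tab) - ord$scores)), 1e-10)
  newx <- as.data.frame(tab)[1:3, trait_names()]
  expect_equal(dim(predict(ord, as.matrix(newx))), c(3L, 4L))
})

test_that("covariance-matrix ordination is available as a switch", {
  tab <- toy_table(30L)
  ord <- fit_pca(tab, k = 4L, pca_matrix = "covariance")
  expect_equal(ord$pca_matrix, "covariance")
  full <- fit_pca(tab, k = 6L, pca_matrix = "covariance")
  expect_equal(sum(full$variance_explained), 100, tolerance = 1e-8)
})
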