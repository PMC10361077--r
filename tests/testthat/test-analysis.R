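# Resampling engine: sub-sampled distributions, the pooled null,
# Mann-Whitney comparisons, and the dissimilarity decomposition.

scores_fixture <- function(n = 60L, k = 4L, seed = 41L, shift = 0) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n * k), 2 * n, k)
  x[(n + 1):(2 * n), ] <- x[(n + 1):(2 * n), ] + shift
  list(scores = x, population = rep(c("A", "B"), each = n))
}

test_that("a population of exactly subsample_size gives a constant distribution", {
  fx <- scores_fixture(n = 10L)
  cfg <- morphospace_config(subsample_size = 10L, n_subsamples = 15L,
                            n_null = 20L, seed = 3L)
  dists <- subsampled_hulls(fx$scores, fx$population, cfg)
  expect_equal(length(dists$A$volumes), 15L)
  expect_equal(diff(range(dists$A$volumes)), 0)
  expect_equal(diff(range(dists$A$centroid_distances)), 0)
})

test_that("sub-sampling is reproducible and keyed by population label", {
  fx <- scores_fixture()
  cfg <- morphospace_config(n_subsamples = 10L, n_null = 20L, seed = 5L)
  d1 <- subsampled_hulls(fx$scores, fx$population, cfg)
  d2 <- subsampled_hulls(fx$scores, fx$population, cfg)
  expect_identical(d1$A$volumes, d2$A$volumes)
  ## reordering rows within the other population leaves A's stream untouched;
  ## reordering whole population blocks changes nothing at all
  ord <- c(61:120, 1:60)
  d3 <- subsampled_hulls(fx$scores[ord, ], fx$population[ord], cfg)
  expect_identical(d3$A$volumes, d1$A$volumes)
  expect_identical(d3$B$volumes, d1$B$volumes)
})

test_that("undersized populations are excluded with a warning", {
  fx <- scores_fixture(n = 30L)
  scores <- rbind(fx$scores, matrix(rnorm(4 * 9), 9, 4))
  pop <- c(fx$population, rep("C", 9))  # C has 9 < subsample_size = 10
  cfg <- morphospace_config(n_subsamples = 5L, n_null = 10L, seed = 1L)
  expect_warning(dists <- subsampled_hulls(scores, pop, cfg), "C")
  expect_named(dists, c("A", "B"))
})

test_that("the null distribution draws from the pooled individuals", {
  fx <- scores_fixture(n = 40L)
  cfg <- morphospace_config(n_subsamples = 30L, n_null = 60L, seed = 7L)
  nd <- null_distribution(fx$scores, cfg)
  expect_equal(nd$label, "null")
  expect_length(nd$volumes, 60L)
  expect_error(null_distribution(fx$scores[1:5, ], cfg), "smaller than subsample_size")
  ## self-null: one homogeneous group is indistinguishable from the null
  one <- matrix(rnorm(50 * 4), 50, 4)
  d_one <- subsampled_hulls(one, rep("A", 50), cfg)
  n_one <- null_distribution(one, cfg)
  res <- compare_to_null(d_one$A, n_one, "volume", alpha = 0.001)
  expect_gt(res$p_value, 0.001)
})

test_that("compare_to_null handles identity and complete separation", {
  d <- structure(
    list(label = "x", volumes = c(1, 2, 3), centroid_distances = c(1, 1, 1),
         median_volume = 2, median_distance = 1), class = "volume_distribution")
  expect_message(res <- compare_to_null(d, d, "centroid_distance"), "identical")
  expect_equal(res$p_value, 1)
  same <- compare_to_null(d, d, "volume")
  expect_equal(same$direction, 0)
  expect_gt(same$p_value, 0.99)

  nul <- structure(list(label = "null", volumes = c(10, 11, 12),
                        centroid_distances = c(2, 2, 2),
                        median_volume = 11, median_distance = 2),
                   class = "volume_distribution")
  sep <- compare_to_null(d, nul, "volume")
  expect_equal(sep$direction, -1)
  ## independent oracle: U = 0 at complete separation (brute-force over all
  ## 3-subsets), and the tie-free normal approximation gives
  ## z = (0 - 4.5) / sqrt(3 * 3 * 7 / 12)
  combos <- utils::combn(6, 3)
  ranksums <- apply(combos, 2, sum)
  u_all <- ranksums - 6  # rank sum minus min rank sum for n = 3
  expect_equal(min(u_all), 0)
  z <- (0 - 4.5) / sqrt(3 * 3 * 7 / 12)
  expect_equal(sep$p_value, 2 * pnorm(z), tolerance = 1e-10)
})

test_that("dissimilarity decomposition: identical populations share all volume", {
  set.seed(43)
  x <- matrix(rnorm(30 * 4), 30, 4)
  scores <- rbind(x, x)
  pop <- rep(c("A", "B"), each = 30)
  cfg <- morphospace_config(mc_points = 20000L, n_perm = 9L,
                            perm_mc_points = 2000L, seed = 9L)
  md <- md_decomposition(scores, pop, cfg)
  expect_equal(md$md_total, 0)
  expect_equal(md$md_per_population$unique_pct, c(0, 0))
  expect_equal(unname(md$turnover_matrix["A", "B"]), 0)
})

test_that("dissimilarity decomposition: disjoint populations are fully unique", {
  ## 2-D, moderate separation: rejection sampling in the joint bounding box
  ## still lands enough points inside each hull
  set.seed(44)
  x <- matrix(rnorm(25 * 2), 25, 2)
  scores <- rbind(x, x + 10)
  pop <- rep(c("A", "B"), each = 25)
  cfg <- morphospace_config(k_dims = 2L, mc_points = 20000L, n_perm = 9L,
                            perm_mc_points = 2000L, seed = 10L)
  md <- md_decomposition(scores, pop, cfg)
  expect_equal(md$md_total, 100)
  expect_equal(unname(md$turnover_matrix["A", "B"]), 100)
  ## per-population uniques sum to the total exactly (shared MC point set)
  expect_equal(sum(md$md_per_population$unique_pct), md$md_total, tolerance = 1e-12)
  expect_true(all(md$md_per_population$p_value >= 0 &
                    md$md_per_population$p_value <= 1))
})

test_that("dissimilarity errors name a degenerate population", {
  scores <- rbind(matrix(rnorm(20 * 4), 20, 4), matrix(rnorm(12), 3, 4))
  pop <- c(rep("A", 20), rep("B", 3))
  cfg <- morphospace_config(seed = 1L)
  expect_error(md_decomposition(scores, pop, cfg), "B")
})

test_that("subsampled-mean dissimilarity mode runs and stays in range", {
  fx <- scores_fixture(n = 20L, shift = 3)
  cfg <- morphospace_config(n_subsamples = 4L, mc_points = 5000L,
                            perm_mc_points = 2000L, md_mode = "subsampled_mean",
                            seed = 11L)
  md <- md_decomposition(fx$scores, fx$population, cfg)
  expect_true(md$md_total >= 0 && md$md_total <= 100)
  expect_true(all(is.na(diag(md$turnover_matrix))))
})
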