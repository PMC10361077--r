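# End-to-end fit: parameter recovery on the designed synthetic world,
# invariances, interfaces, methods, and report output.

test_that("the fit recovers the designed clustered and displaced populations", {
  tab <- generate_traits(default_design(), seed = 2L)
  roles <- attr(tab, "design")$roles
  fit <- morphospace(tab, config = fast_config(seed = 2L))

  vt <- fit$volume_tests
  clustered <- vt[vt$population == roles[["clustered"]], ]
  expect_true(clustered$significant)
  expect_equal(clustered$direction, -1)

  ct <- fit$centroid_tests
  displaced <- ct[ct$population == roles[["displaced"]], ]
  expect_true(displaced$significant)
  expect_equal(displaced$direction, 1)
})

test_that("rotated and unrotated scores give identical hull statistics", {
  ## the rotation is orthogonal, so volumes and centroid distances cannot change
  tab <- generate_traits(default_design(), seed = 3L)
  cfg_r <- fast_config(seed = 4L)
  cfg_u <- fast_config(seed = 4L, scores = "unrotated")
  fit_r <- morphospace(tab, config = cfg_r, md = FALSE)
  fit_u <- morphospace(tab, config = cfg_u, md = FALSE)
  expect_equal(fit_r$volume_tests$median, fit_u$volume_tests$median, tolerance = 1e-8)
  expect_equal(fit_r$centroid_tests$median, fit_u$centroid_tests$median, tolerance = 1e-8)
})

test_that("the report is invariant to population input order", {
  ## population blocks re-ordered, keeping each block's internal row order
  ## (per-population RNG substreams are keyed by label, not position)
  tab <- generate_traits(default_design(), seed = 5L)
  df <- as.data.frame(tab)
  blocks <- split(seq_len(nrow(df)), df$population)
  shuffled <- as_trait_table(df[unlist(rev(blocks)), ])
  cfg <- fast_config(seed = 6L)
  f1 <- morphospace(tab, config = cfg)
  f2 <- morphospace(shuffled, config = cfg)
  expect_equal(f1$volume_tests, f2$volume_tests, tolerance = 1e-12)
  expect_equal(f1$md$md_total, f2$md$md_total, tolerance = 1e-12)
  expect_equal(f1$turnover_matrix, f2$turnover_matrix, tolerance = 1e-12)
})

test_that("equal seeds reproduce the fit exactly", {
  tab <- generate_traits(default_design(), seed = 7L)
  cfg <- fast_config(seed = 8L)
  f1 <- morphospace(tab, config = cfg, md = FALSE)
  f2 <- morphospace(tab, config = cfg, md = FALSE)
  expect_identical(f1$volume_tests, f2$volume_tests)
  expect_identical(f1$null$volumes, f2$null$volumes)
})

test_that("detection of a contracted population strengthens as the filter tightens", {
  ## power property: flag probability increases as cov_scale decreases
  rates <- vapply(c(0.8, 0.5, 0.3), function(s) {
    flags <- vapply(1:12, function(r) {
      d <- homogeneous_design()
      d$populations[[2]] <- population_spec("P2", 15L, cov_scale = s)
      tab <- generate_traits(d, seed = 1000L + r)
      ord <- varimax_rotate(fit_pca(tab, 4L))
      cfg <- morphospace_config(n_subsamples = 25L, n_null = 120L,
                                seed = 2000L + r)
      pop <- ifelse(tab$population == "P2", "P2", "rest")
      dists <- subsampled_hulls(ord$scores, pop, cfg)
      nul <- null_distribution(ord$scores, cfg)
      res <- compare_to_null(dists$P2, nul, "volume", alpha = 0.001)
      res$significant && res$direction < 0
    }, logical(1))
    mean(flags)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0) || (rates[3] > rates[1]))
  expect_gt(rates[3], 0.8)
})

test_that("formula and data.frame interfaces match the trait_table interface", {
  tab <- generate_traits(default_design(), seed = 9L)
  cfg <- fast_config(seed = 10L)
  f1 <- morphospace(tab, config = cfg, md = FALSE)
  df <- as.data.frame(tab)
  f2 <- morphospace(df, config = cfg, md = FALSE)
  f3 <- morphospace(. ~ population, data = df, config = cfg, md = FALSE)
  expect_equal(f1$volume_tests, f2$volume_tests, tolerance = 1e-12)
  expect_equal(f1$volume_tests, f3$volume_tests, tolerance = 1e-12)
})

test_that("undersized populations are excluded but kept in the ordination", {
  d <- homogeneous_design()
  d$populations[[3]] <- population_spec("P3", 9L)  # below subsample_size = 10
  tab <- generate_traits(d, seed = 11L)
  cfg <- fast_config(seed = 12L)
  expect_warning(fit <- morphospace(tab, config = cfg), "P3")
  expect_false("P3" %in% fit$volume_tests$population)
  expect_true("P3" %in% fit$excluded)
  ## ordination and grand centroid cover all individuals, including P3's
  expect_equal(nrow(fit$scores), nrow(tab))
  expect_equal(fit$grand_centroid, colMeans(fit$scores))
  expect_false("P3" %in% fit$md$md_per_population$population)
})

test_that("print, summary, plot and predict methods work", {
  tab <- generate_traits(default_design(), seed = 13L)
  fit <- morphospace(tab, config = fast_config(seed = 14L))
  expect_output(print(fit), "Morphospace analysis")
  s <- summary(fit)
  expect_s3_class(s, "summary.morphospace")
  expect_output(print(s), "Convex hull volume vs pooled null")
  expect_true(all(s$volume_tests$status %in% c("clustered", "expanded", "ns")))
  expect_true(all(s$centroid_tests$status %in% c("displaced", "converged", "ns")))
  grDevices::pdf(NULL)
  expect_invisible(plot(fit))
  grDevices::dev.off()
  sc <- predict(fit, tab[1:5, ])
  expect_equal(dim(sc), c(5L, 4L))
})

test_that("write_report emits the expected files and respects omissions", {
  tab <- toy_table(n_per_pop = 12L)
  cfg <- fast_config(seed = 15L)
  fit <- morphospace(tab, config = cfg)
  dir <- withr::local_tempdir()
  write_report(fit, dir)
  expect_true(all(file.exists(file.path(dir,
    c("volume_tests.csv", "centroid_tests.csv", "unique_volume.csv",
      "turnover.csv", "loadings.csv", "summary.json")))))
  uv <- utils::read.csv(file.path(dir, "unique_volume.csv"))
  expect_equal(nrow(uv), 2L)
  tm <- utils::read.csv(file.path(dir, "turnover.csv"))
  expect_equal(dim(tm), c(2L, 3L))           # population column + 2 pair columns
  expect_true(all(is.na(c(tm[1, 2], tm[2, 3]))))  # empty diagonal
  js <- jsonlite::read_json(file.path(dir, "summary.json"), simplifyVector = TRUE)
  expect_equal(js$n_individuals, nrow(tab))
  expect_equal(js$config$seed, 15L)

  ## no dissimilarity section requested: that file is omitted, others remain
  fit2 <- morphospace(tab, config = cfg, md = FALSE)
  dir2 <- withr::local_tempdir()
  write_report(fit2, dir2)
  expect_false(file.exists(file.path(dir2, "unique_volume.csv")))
  expect_true(file.exists(file.path(dir2, "volume_tests.csv")))
})
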