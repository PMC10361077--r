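#' Write a morphospace report to disk
#'
#' Emits machine-readable tables from a fitted [morphospace()] object into a
#' directory, with deterministic field order:
#' * `unique_volume.csv` — population, uniquely occupied % of the pooled
#'   morphospace, permutation p-value;
#' * `turnover.csv` — pairwise matrix with turnover percentages below the
#'   diagonal and volume-difference Mann-Whitney p-values above it;
#' * `volume_tests.csv`, `centroid_tests.csv` — per-population medians of
#'   the sub-sampled distributions, null medians, p-values, directions;
#' * `loadings.csv` — rotated component loadings (traits by components);
#' * `summary.json` — every statistic plus the full configuration
#'   (including the RNG seed) for provenance.
#' Sections whose statistics are absent from the fit (e.g. the
#' dissimilarity decomposition when `morphospace(..., md = FALSE)`) are
#' omitted; the other files are unchanged.
#'
#' @param report a `morphospace` fit.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "morphospace"))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory: %s", path))
  }
  wcsv <- function(x, file, ...) {
    utils::write.csv(x, file.path(path, file), row.names = FALSE, ...)
  }

  wcsv(report$volume_tests, "volume_tests.csv")
  wcsv(report$centroid_tests, "centroid_tests.csv")

  load_df <- data.frame(trait = rownames(report$ordination$loadings),
                        round(report$ordination$loadings, 6L),
                        stringsAsFactors = FALSE, check.names = FALSE)
  wcsv(load_df, "loadings.csv")

  if (!is.null(report$md)) {
    wcsv(report$md$md_per_population, "unique_volume.csv")
    comb <- combined_pair_matrix(report$turnover_matrix, report$pairwise_volume_p)
    comb_df <- data.frame(population = rownames(comb), round(comb, 6L),
                          stringsAsFactors = FALSE, check.names = FALSE)
    utils::write.csv(comb_df, file.path(path, "turnover.csv"),
                     row.names = FALSE, na = "")
  }

  summary_list <- list(
    n_individuals = nrow(report$table),
    populations = as.list(population_counts(report$table)),
    analysed = report$populations,
    excluded = report$excluded,
    variance_explained = report$ordination$variance_explained,
    total_variance_explained = report$ordination$total_variance_explained,
    variance_explained_rotated = report$ordination$variance_explained_rotated,
    volume_tests = report$volume_tests,
    centroid_tests = report$centroid_tests,
    md_total = if (!is.null(report$md)) report$md$md_total else NULL,
    md_per_population = if (!is.null(report$md)) report$md$md_per_population else NULL,
    turnover_matrix = report$turnover_matrix,
    pairwise_volume_p = report$pairwise_volume_p,
    config = unclass(report$config)
  )
  jsonlite::write_json(summary_list, file.path(path, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}
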