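#' Analysis configuration
#'
#' All tunable constants of the morphospace pipeline in one validated
#' object.  The defaults follow the study design the pipeline implements:
#' four retained components, sub-samples of 10 workers per population
#' repeated 100 times, a pooled-draw null of 1000 repetitions, and
#' significance at 0.001.
#'
#' @param k_dims retained ordination dimensionality (hull dimension).
#' @param subsample_size individuals drawn per sub-sample (must be at least
#'   `k_dims + 1` so a hull can be built).
#' @param n_subsamples sub-sampling repetitions per population.
#' @param n_null pooled-draw null repetitions.
#' @param n_perm label permutations for the unique-volume significance test.
#' @param alpha significance level.
#' @param mc_points Monte Carlo points for hull set operations.
#' @param perm_mc_points Monte Carlo points per permutation replicate (a
#'   lighter sample keeps the permutation null affordable).
#' @param seed master RNG seed; all stage substreams derive from it.
#' @param pca_matrix `"correlation"` or `"covariance"` ordination (see
#'   [fit_pca()]).
#' @param varimax_normalize Kaiser row normalization in [varimax_rotate()].
#' @param scores use `"rotated"` (default) or `"unrotated"` component scores
#'   for hull analyses.
#' @param md_mode build dissimilarity hulls from each population's full
#'   sample (`"full"`, default) or average over sub-sampled replicate hull
#'   sets (`"subsampled_mean"`).
#' @return a validated `morphospace_config` list.
#' @export
morphospace_config <- function(k_dims = 4L, subsample_size = 10L,
                               n_subsamples = 100L, n_null = 1000L,
                               n_perm = 999L, alpha = 0.001,
                               mc_points = 100000L, perm_mc_points = 20000L,
                               seed = 1L,
                               pca_matrix = c("correlation", "covariance"),
                               varimax_normalize = FALSE,
                               scores = c("rotated", "unrotated"),
                               md_mode = c("full", "subsampled_mean")) {
  cfg <- list(
    k_dims = as.integer(k_dims),
    subsample_size = as.integer(subsample_size),
    n_subsamples = as.integer(n_subsamples),
    n_null = as.integer(n_null),
    n_perm = as.integer(n_perm),
    alpha = as.numeric(alpha),
    mc_points = as.integer(mc_points),
    perm_mc_points = as.integer(perm_mc_points),
    seed = as.integer(seed),
    pca_matrix = match.arg(pca_matrix),
    varimax_normalize = isTRUE(varimax_normalize),
    scores = match.arg(scores),
    md_mode = match.arg(md_mode)
  )
  class(cfg) <- "morphospace_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop(sprintf("invalid config: %s", msg))
  chk(!is.na(cfg$k_dims) && cfg$k_dims >= 1L && cfg$k_dims <= 6L,
      "k_dims must be in [1, 6]")
  chk(!is.na(cfg$subsample_size) && cfg$subsample_size >= cfg$k_dims + 1L,
      sprintf("subsample_size must be >= k_dims + 1 = %d", cfg$k_dims + 1L))
  for (fld in c("n_subsamples", "n_null", "n_perm", "mc_points", "perm_mc_points")) {
    chk(!is.na(cfg[[fld]]) && cfg[[fld]] >= 1L, sprintf("%s must be >= 1", fld))
  }
  chk(is.finite(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 1,
      "alpha must be in (0, 1)")
  chk(!is.na(cfg$seed), "seed must be an integer")
  invisible(cfg)
}

#' Read an analysis configuration from a JSON or YAML file
#'
#' Fields mirror the arguments of [morphospace_config()]; absent fields keep
#' their defaults.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return a validated `morphospace_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(morphospace_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop(sprintf("invalid config: unknown field(s) %s", paste(unknown, collapse = ", ")))
  }
  do.call(morphospace_config, vals)
}

#' @export
print.morphospace_config <- function(x, ...) {
  cat("Morphospace analysis configuration:\n")
  for (nm in names(unclass(x))) cat(sprintf("  %s: %s\n", nm, x[[nm]]))
  invisible(x)
}
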