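#' Fit a morphospace analysis
#'
#' The full pipeline for testing how labelled populations occupy a shared
#' trait space.  The six traits are reduced by principal component analysis
#' with a varimax rotation (four components retained by default); each
#' population's occupied morphospace is measured as the volume of the
#' convex hull of repeated sub-samples of its individuals, and its position
#' as the distance of each sub-sample's centroid from the grand centroid of
#' all individuals pooled.  Both statistics are compared to a pooled
#' random-draw null model with two-sided Mann-Whitney U tests:
#' significantly smaller volumes indicate trait clustering (a strong
#' environmental filter), significantly larger centroid displacement
#' indicates a shifted phenotypic optimum.  The pooled morphospace is also
#' decomposed into per-population uniquely occupied volumes (morphological
#' dissimilarity) and pairwise turnover.
#'
#' @param x a `trait_table` (see [read_trait_table()], [as_trait_table()],
#'   [generate_traits()]), a data.frame convertible to one, or a formula of
#'   the form `. ~ population_column` (all six canonical traits) or
#'   `cbind(t1, t2, ...) ~ population_column`.
#' @param config a [morphospace_config()].
#' @param md compute the morphological-dissimilarity decomposition (can be
#'   disabled for speed; default `TRUE`).
#' @param ... method-specific arguments; for the data.frame method,
#'   `schema` is passed to [as_trait_table()]; for the formula method,
#'   `data`.
#' @return an object of class `morphospace`; see [summary.morphospace()].
#'   Main elements: `ordination`, `distributions` (per-population replicate
#'   volumes and centroid distances), `null` (the pooled-draw reference),
#'   `volume_tests` and `centroid_tests` (per-population medians, p-values,
#'   directions), `pairwise_volume_p`, `md` (unique-volume decomposition),
#'   `turnover_matrix`, `excluded`, `config`, `timings`.
#' @examples
#' tab <- generate_traits(default_design())
#' cfg <- morphospace_config(n_subsamples = 20, n_null = 50, n_perm = 19,
#'                           mc_points = 5000, perm_mc_points = 2000)
#' fit <- morphospace(tab, config = cfg)
#' print(fit)
#' @export
morphospace <- function(x, ...) UseMethod("morphospace")

#' @rdname morphospace
#' @export
morphospace.trait_table <- function(x, config = morphospace_config(),
                                    md = TRUE, ...) {
  fit_morphospace(x, config = config, md = md)
}

#' @rdname morphospace
#' @param schema column-name mapping for data.frame input (see
#'   [as_trait_table()]).
#' @export
morphospace.data.frame <- function(x, config = morphospace_config(),
                                   md = TRUE, schema = NULL, ...) {
  fit_morphospace(as_trait_table(x, schema = schema), config = config, md = md)
}

#' @rdname morphospace
#' @param data data.frame holding the formula's variables.
#' @export
morphospace.formula <- function(x, data, config = morphospace_config(),
                                md = TRUE, ...) {
  rhs <- all.vars(x[[3L]])
  if (length(rhs) != 1L) stop("formula must have a single grouping variable on the right")
  lhs_vars <- all.vars(x[[2L]])
  traits <- if (identical(lhs_vars, character(0)) || identical(deparse(x[[2L]]), ".")) {
    trait_names()
  } else {
    lhs_vars
  }
  if (length(traits) != 6L) {
    stop("the trait-table pipeline requires the six canonical traits; map columns via schema instead")
  }
  schema <- stats::setNames(c(traits, rhs), c(trait_names(), "population"))
  fit_morphospace(as_trait_table(data, schema = schema), config = config, md = md)
}

fit_morphospace <- function(table, config, md) {
  stopifnot(inherits(table, "trait_table"))
  validate_config(config)
  cl <- match.call(morphospace, sys.call(-1L))
  warnings_log <- character(0)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  note_warning <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    warning(w)
    invokeRestart("muffleWarning")
  }

  ## ordination on ALL individuals (populations too small for hulls still
  ## contribute to the component space and the grand centroid)
  t0 <- tic()
  ord <- fit_pca(table, k = config$k_dims, pca_matrix = config$pca_matrix)
  if (config$k_dims >= 2L) ord <- varimax_rotate(ord, normalize = config$varimax_normalize)
  scores <- if (config$scores == "unrotated" && config$k_dims >= 2L) {
    ## undo the (orthogonal) rotation to recover the unrotated scores
    s <- ord$scores %*% t(ord$rotation_matrix)
    colnames(s) <- paste0("PC", seq_len(config$k_dims))
    s
  } else {
    ord$scores
  }
  timings["ordination"] <- tic() - t0

  ## analysis stages see a canonical (stable label-sorted) ordering so that
  ## results do not depend on the order population blocks appear in the input
  canon <- order(table$population, method = "radix")
  scores_c <- scores[canon, , drop = FALSE]
  population <- table$population[canon]
  counts <- population_counts(table)
  excluded <- names(counts)[counts < config$subsample_size]
  included <- setdiff(sort(names(counts)), excluded)
  if (length(included) < 1L) stop("no population has enough individuals to sub-sample")

  t0 <- tic()
  dists <- withCallingHandlers(
    subsampled_hulls(scores_c, population, config),
    warning = note_warning)
  timings["subsampled_hulls"] <- tic() - t0

  t0 <- tic()
  null <- null_distribution(scores_c, config)
  timings["null_distribution"] <- tic() - t0

  t0 <- tic()
  volume_tests <- test_table(dists, null, "volume", config$alpha)
  centroid_tests <- test_table(dists, null, "centroid_distance", config$alpha)
  pairwise_volume_p <- pairwise_volume_tests(dists)
  timings["null_tests"] <- tic() - t0

  md_res <- NULL
  if (isTRUE(md)) {
    t0 <- tic()
    keep <- population %in% included
    md_res <- withCallingHandlers(
      md_decomposition(scores_c[keep, , drop = FALSE], population[keep], config),
      warning = note_warning)
    timings["md_decomposition"] <- tic() - t0
  }

  structure(list(
    call = cl,
    table = table,
    ordination = ord,
    scores = scores,
    grand_centroid = colMeans(scores),
    populations = included,
    excluded = excluded,
    distributions = dists,
    null = null,
    volume_tests = volume_tests,
    centroid_tests = centroid_tests,
    pairwise_volume_p = pairwise_volume_p,
    md = md_res,
    turnover_matrix = if (!is.null(md_res)) md_res$turnover_matrix else NULL,
    config = config,
    timings = timings,
    warnings = warnings_log
  ), class = "morphospace")
}

test_table <- function(dists, null, statistic, alpha) {
  rows <- lapply(dists, function(d) {
    res <- compare_to_null(d, null, statistic = statistic, alpha = alpha)
    data.frame(population = d$label,
               median = res$median_observed,
               null_median = res$median_null,
               p_value = res$p_value,
               direction = res$direction,
               significant = res$significant,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

## pairwise Mann-Whitney tests between the sub-sampled volume lists of each
## population pair (upper-triangle p-values of the turnover table)
pairwise_volume_tests <- function(dists) {
  labels <- names(dists)
  k <- length(labels)
  m <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  if (k < 2L) return(m)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      x <- dists[[i]]$volumes
      y <- dists[[j]]$volumes
      p <- if (length(unique(c(x, y))) == 1L) 1 else {
        stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
      }
      m[i, j] <- m[j, i] <- if (is.na(p)) 1 else p
    }
  }
  m
}

#' @export
print.morphospace <- function(x, ...) {
  cat("Morphospace analysis\n")
  cat(sprintf("  %d individuals, %d populations analysed (k = %d components, %.1f%% of variance)\n",
              nrow(x$table), length(x$populations), x$config$k_dims,
              x$ordination$total_variance_explained))
  if (length(x$excluded) > 0L) {
    cat(sprintf("  excluded (n < %d): %s\n", x$config$subsample_size,
                paste(x$excluded, collapse = ", ")))
  }
  if (!is.null(x$md)) {
    cat(sprintf("  morphological dissimilarity: %.1f%% of pooled morphospace uniquely occupied\n",
                x$md$md_total))
  }
  nv <- sum(x$volume_tests$significant)
  nc <- sum(x$centroid_tests$significant)
  cat(sprintf("  populations departing from the pooled null at alpha = %g: %d (volume), %d (centroid)\n",
              x$config$alpha, nv, nc))
  cat("  use summary() for per-population tables\n")
  invisible(x)
}

#' Summarize a morphospace fit
#'
#' @param object a `morphospace` fit.
#' @param digits significant digits for printing.
#' @param ... unused.
#' @return a `summary.morphospace` list with the per-population test tables,
#'   unique-volume decomposition, turnover matrix and variance accounting.
#' @export
summary.morphospace <- function(object, digits = 3L, ...) {
  status <- function(tests, smaller, larger) {
    ifelse(!tests$significant, "ns",
           ifelse(tests$direction < 0, smaller, larger))
  }
  vt <- object$volume_tests
  vt$status <- status(vt, "clustered", "expanded")
  ct <- object$centroid_tests
  ct$status <- status(ct, "converged", "displaced")
  structure(list(
    call = object$call,
    n = nrow(object$table),
    populations = object$populations,
    excluded = object$excluded,
    variance_explained = object$ordination$variance_explained,
    total_variance_explained = object$ordination$total_variance_explained,
    loadings = object$ordination$loadings,
    volume_tests = vt,
    centroid_tests = ct,
    md_total = if (!is.null(object$md)) object$md$md_total else NULL,
    md_per_population = if (!is.null(object$md)) object$md$md_per_population else NULL,
    turnover_matrix = object$turnover_matrix,
    pairwise_volume_p = object$pairwise_volume_p,
    config = object$config,
    digits = digits
  ), class = "summary.morphospace")
}

#' @export
print.summary.morphospace <- function(x, ...) {
  d <- x$digits
  cat("Morphospace analysis summary\n\n")
  cat(sprintf("Individuals: %d   populations analysed: %s\n", x$n,
              paste(x$populations, collapse = ", ")))
  if (length(x$excluded) > 0L) {
    cat(sprintf("Excluded populations: %s\n", paste(x$excluded, collapse = ", ")))
  }
  cat(sprintf("\nVariance explained by retained components (pre-rotation): %s  (total %.2f%%)\n",
              paste(sprintf("%.2f%%", x$variance_explained), collapse = " "),
              x$total_variance_explained))
  cat("\nConvex hull volume vs pooled null:\n")
  print(format_tests(x$volume_tests, d), row.names = FALSE)
  cat("\nCentroid displacement vs pooled null:\n")
  print(format_tests(x$centroid_tests, d), row.names = FALSE)
  if (!is.null(x$md_total)) {
    cat(sprintf("\nUniquely occupied morphospace (total %.1f%% of the pooled volume):\n",
                x$md_total))
    md <- x$md_per_population
    md$unique_pct <- round(md$unique_pct, 1L)
    md$p_value <- signif(md$p_value, d)
    print(md[, c("population", "unique_pct", "p_value")], row.names = FALSE)
    cat("\nPairwise turnover (% non-overlap, lower triangle) / volume-difference p (upper):\n")
    print(round(combined_pair_matrix(x$turnover_matrix, x$pairwise_volume_p), 3L))
  }
  invisible(x)
}

format_tests <- function(tab, d) {
  out <- tab
  out$median <- signif(out$median, d)
  out$null_median <- signif(out$null_median, d)
  out$p_value <- signif(out$p_value, d)
  out[, c("population", "median", "null_median", "p_value", "status")]
}

## lower triangle from `lower`, upper triangle from `upper`, NA diagonal
combined_pair_matrix <- function(lower, upper) {
  if (is.null(lower)) return(NULL)
  m <- lower
  if (!is.null(upper)) {
    common <- intersect(rownames(lower), rownames(upper))
    m[common, common][upper.tri(m[common, common])] <-
      upper[common, common][upper.tri(upper[common, common])]
  }
  diag(m) <- NA_real_
  m
}

#' Plot a morphospace fit
#'
#' Two panels: per-population sub-sampled convex hull volumes, and per-
#' population centroid displacements, each as boxplots against the pooled
#' null distribution (grey).  Populations departing from the null at the
#' configured significance level are marked with an asterisk.
#'
#' @param x a `morphospace` fit.
#' @param which `"both"`, `"volume"` or `"centroid"`.
#' @param ... passed to [graphics::boxplot()].
#' @return `x`, invisibly.
#' @export
plot.morphospace <- function(x, which = c("both", "volume", "centroid"), ...) {
  which <- match.arg(which)
  panels <- if (which == "both") c("volume", "centroid") else which
  if (length(panels) == 2L) {
    old <- graphics::par(mfrow = c(1L, 2L))
    on.exit(graphics::par(old))
  }
  for (panel in panels) {
    fld <- if (panel == "volume") "volumes" else "centroid_distances"
    tests <- if (panel == "volume") x$volume_tests else x$centroid_tests
    values <- c(list(null = x$null[[fld]]),
                lapply(x$distributions, `[[`, fld))
    labs <- names(values)
    star <- c("", ifelse(tests$significant[match(labs[-1L], tests$population)], "*", ""))
    graphics::boxplot(values,
                      names = paste0(labs, star),
                      col = c("grey80", rep("white", length(values) - 1L)),
                      ylab = if (panel == "volume") "convex hull volume" else "centroid displacement",
                      main = if (panel == "volume") "Hull volume vs null" else "Centroid displacement vs null",
                      las = 2L, ...)
  }
  invisible(x)
}

#' @export
predict.morphospace <- function(object, newdata, ...) {
  predict(object$ordination, newdata, ...)
}
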