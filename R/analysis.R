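# Resampling engine: sub-sampled hull distributions per population, the
# pooled random-draw null model, Mann-Whitney comparisons, and the
# morphological-dissimilarity decomposition.

#' Sub-sampled hull volume and centroid-distance distributions
#'
#' For each population with at least `subsample_size` individuals, draws
#' `n_subsamples` sub-samples of `subsample_size` individuals without
#' replacement (within a draw), builds the convex hull of each draw in
#' component space, and records its volume and the Euclidean distance from
#' the draw's centroid to the grand centroid (the mean score over all
#' individuals of all populations, including any excluded ones).
#' Sub-sampling equalizes sampling effort across populations of unequal
#' size.  Populations below `subsample_size` are excluded with a warning.
#' Each population has its own RNG substream keyed by its label, so results
#' do not depend on population ordering.
#'
#' @param scores numeric matrix of component scores (individuals by
#'   `k_dims`).
#' @param population character/factor vector of population labels, one per
#'   row of `scores`.
#' @param config a [morphospace_config()].
#' @return named list of `volume_distribution` objects (fields `label`,
#'   `volumes`, `centroid_distances`, `median_volume`, `median_distance`),
#'   ordered by population label.
#' @export
subsampled_hulls <- function(scores, population, config = morphospace_config()) {
  scores <- as.matrix(scores)
  population <- as.character(population)
  stopifnot(nrow(scores) == length(population))
  grand <- colMeans(scores)

  labels <- sort(unique(population))
  counts <- table(population)
  small <- labels[counts[labels] < config$subsample_size]
  if (length(small) > 0L) {
    warning(sprintf(
      "excluding population(s) with fewer than subsample_size = %d individuals: %s",
      config$subsample_size, paste(small, collapse = ", ")))
    labels <- setdiff(labels, small)
  }
  if (length(labels) == 0L) stop("no population has enough individuals to sub-sample")

  out <- lapply(labels, function(lab) {
    xs <- scores[population == lab, , drop = FALSE]
    with_seed(substream_seed(config$seed, paste0("subsample:", lab)), {
      vols <- numeric(config$n_subsamples)
      dists <- numeric(config$n_subsamples)
      for (r in seq_len(config$n_subsamples)) {
        idx <- sample.int(nrow(xs), config$subsample_size)
        draw <- xs[idx, , drop = FALSE]
        vols[r] <- convex_hull(draw)$volume
        dists[r] <- centroid_distance(centroid(draw), grand)
      }
      volume_distribution(lab, vols, dists)
    })
  })
  stats::setNames(out, labels)
}

#' Pooled random-draw null distribution
#'
#' Draws `n_null` sub-samples of `subsample_size` individuals from all
#' individuals pooled across populations (without replacement within a
#' draw, with replacement across draws) and records hull volumes and
#' centroid distances exactly as [subsampled_hulls()] does.  This is the
#' reference distribution under no population structure.
#'
#' @inheritParams subsampled_hulls
#' @return a `volume_distribution` labelled `"null"`.
#' @export
null_distribution <- function(scores, config = morphospace_config()) {
  scores <- as.matrix(scores)
  if (nrow(scores) < config$subsample_size) {
    stop(sprintf("pooled n = %d is smaller than subsample_size = %d",
                 nrow(scores), config$subsample_size))
  }
  grand <- colMeans(scores)
  with_seed(substream_seed(config$seed, "null"), {
    vols <- numeric(config$n_null)
    dists <- numeric(config$n_null)
    for (r in seq_len(config$n_null)) {
      idx <- sample.int(nrow(scores), config$subsample_size)
      draw <- scores[idx, , drop = FALSE]
      vols[r] <- convex_hull(draw)$volume
      dists[r] <- centroid_distance(centroid(draw), grand)
    }
    volume_distribution("null", vols, dists)
  })
}

volume_distribution <- function(label, volumes, centroid_distances) {
  structure(list(
    label = label,
    volumes = volumes,
    centroid_distances = centroid_distances,
    median_volume = stats::median(volumes),
    median_distance = stats::median(centroid_distances)
  ), class = "volume_distribution")
}

#' @export
print.volume_distribution <- function(x, ...) {
  cat(sprintf("Distribution '%s': %d replicates, median volume %.4g, median centroid distance %.4g\n",
              x$label, length(x$volumes), x$median_volume, x$median_distance))
  invisible(x)
}

#' Mann-Whitney comparison of an observed distribution to the null
#'
#' Two-sided Mann-Whitney U test (normal approximation with tie correction)
#' between the observed replicate list and the null replicate list of the
#' chosen statistic.  The direction is the sign of the observed median minus
#' the null median.  If both lists are constant and identical the test is
#' undefined and `p = 1` is returned by convention (with a message).
#'
#' @param observed,null `volume_distribution` objects.
#' @param statistic `"volume"` or `"centroid_distance"`.
#' @param alpha significance level used for the `significant` flag.
#' @return list with `p_value`, `direction` (-1, 0, 1), `significant`,
#'   `median_observed`, `median_null`, and `statistic`.
#' @export
compare_to_null <- function(observed, null,
                            statistic = c("volume", "centroid_distance"),
                            alpha = 0.001) {
  statistic <- match.arg(statistic)
  fld <- if (statistic == "volume") "volumes" else "centroid_distances"
  x <- observed[[fld]]
  y <- null[[fld]]
  if (length(x) == 0L || length(y) == 0L) stop("empty replicate list")

  med_x <- stats::median(x)
  med_y <- stats::median(y)
  if (length(unique(c(x, y))) == 1L) {
    message("compare_to_null: all replicate values identical; p = 1 by convention")
    p <- 1
  } else {
    p <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
    if (is.na(p)) {
      message("compare_to_null: degenerate Mann-Whitney statistic; p = 1 by convention")
      p <- 1
    }
  }
  list(p_value = p,
       direction = sign(med_x - med_y),
       significant = p < alpha,
       median_observed = med_x,
       median_null = med_y,
       statistic = statistic)
}

#' Morphological-dissimilarity decomposition
#'
#' Builds one convex hull per population (from all of its individuals under
#' `md_mode = "full"`), estimates how the pooled (union) morphospace volume
#' decomposes into uniquely and jointly occupied regions, and computes the
#' full pairwise turnover matrix.  Per-population unique percentages and
#' their total (`md_total`) share one Monte Carlo point set, so the uniques
#' sum to the total exactly.  Significance of each population's unique
#' volume is assessed against a label-permutation null: population labels
#' are shuffled over individuals `n_perm` times (preserving group sizes),
#' the unique percentages are recomputed with a lighter Monte Carlo sample,
#' and a two-sided rank p-value is reported.  The permutation construction
#' is this package's own; it is not part of the original sub-sampling
#' scheme.
#'
#' Under `md_mode = "subsampled_mean"` the decomposition is instead averaged
#' over `n_subsamples` replicate hull sets, each built from a random
#' sub-sample of `subsample_size` individuals per population (no permutation
#' p-values in this mode).
#'
#' @inheritParams subsampled_hulls
#' @return list with `md_total` (percent of union volume occupied uniquely
#'   by any single population), `md_per_population` (data.frame: population,
#'   `unique_pct`, `se`, `p_value`), `turnover_matrix` (symmetric, empty
#'   diagonal), and `occupancy` (the full [estimate_occupancy()] object; for
#'   `"full"` mode only).
#' @export
md_decomposition <- function(scores, population, config = morphospace_config()) {
  scores <- as.matrix(scores)
  population <- as.character(population)
  stopifnot(nrow(scores) == length(population))
  labels <- sort(unique(population))
  counts <- table(population)
  too_small <- labels[counts[labels] < config$k_dims + 1L]
  if (length(too_small) > 0L) {
    stop(sprintf("population(s) too small for a %d-dimensional hull: %s",
                 config$k_dims, paste(too_small, collapse = ", ")))
  }

  if (config$md_mode == "subsampled_mean") {
    return(md_subsampled_mean(scores, population, labels, config))
  }

  hulls <- build_population_hulls(scores, population, labels)
  occ <- estimate_occupancy(hulls, n_points = config$mc_points,
                            seed = substream_seed(config$seed, "md:occupancy"))
  unique_pct <- 100 * occ$unique_fractions
  md_total <- sum(unique_pct)

  ## label-permutation null for the unique percentages
  n_perm <- config$n_perm
  perm_mc <- min(config$perm_mc_points, config$mc_points)
  perm_uniques <- matrix(NA_real_, n_perm, length(labels),
                         dimnames = list(NULL, labels))
  with_seed(substream_seed(config$seed, "md:permutation"), {
    for (b in seq_len(n_perm)) {
      shuffled <- sample(population)
      occ_b <- tryCatch({
        hulls_b <- build_population_hulls(scores, shuffled, labels)
        estimate_occupancy(hulls_b, n_points = perm_mc,
                           seed = sample.int(.Machine$integer.max - 1L, 1L))
      }, error = function(e) NULL)  # degenerate shuffled hull: drop replicate
      if (!is.null(occ_b)) perm_uniques[b, ] <- 100 * occ_b$unique_fractions
    }
  })
  p_perm <- vapply(labels, function(lab) {
    perm <- perm_uniques[, lab]
    perm <- perm[!is.na(perm)]
    if (length(perm) == 0L) return(NA_real_)
    n_ok <- length(perm)
    p_ge <- (1 + sum(perm >= unique_pct[[lab]])) / (n_ok + 1)
    p_le <- (1 + sum(perm <= unique_pct[[lab]])) / (n_ok + 1)
    min(1, 2 * min(p_ge, p_le))
  }, numeric(1))

  turnover <- turnover_matrix(hulls, config)

  list(
    md_total = md_total,
    md_per_population = data.frame(
      population = labels,
      unique_pct = as.numeric(unique_pct[labels]),
      se = as.numeric(100 * sqrt(occ$unique_fractions[labels] *
                                   (1 - occ$unique_fractions[labels]) / occ$n_points)),
      p_value = as.numeric(p_perm[labels]),
      row.names = NULL, stringsAsFactors = FALSE),
    turnover_matrix = turnover,
    occupancy = occ
  )
}

md_subsampled_mean <- function(scores, population, labels, config) {
  counts <- table(population)
  size <- min(config$subsample_size, min(counts[labels]))
  acc_unique <- matrix(0, config$n_subsamples, length(labels),
                       dimnames = list(NULL, labels))
  acc_turn <- array(0, c(length(labels), length(labels), config$n_subsamples))
  with_seed(substream_seed(config$seed, "md:subsampled"), {
    for (r in seq_len(config$n_subsamples)) {
      idx <- unlist(lapply(labels, function(lab) {
        pool <- which(population == lab)
        pool[sample.int(length(pool), size)]
      }))
      hulls_r <- build_population_hulls(scores[idx, , drop = FALSE],
                                        population[idx], labels)
      occ_r <- estimate_occupancy(hulls_r, n_points = config$perm_mc_points,
                                  seed = sample.int(.Machine$integer.max - 1L, 1L))
      acc_unique[r, ] <- 100 * occ_r$unique_fractions[labels]
      acc_turn[, , r] <- turnover_matrix(hulls_r, config,
                                         n_points = config$perm_mc_points)
    }
  })
  turnover <- apply(acc_turn, c(1L, 2L), mean)
  dimnames(turnover) <- list(labels, labels)
  diag(turnover) <- NA_real_
  unique_pct <- colMeans(acc_unique)
  list(
    md_total = sum(unique_pct),
    md_per_population = data.frame(
      population = labels, unique_pct = as.numeric(unique_pct),
      se = as.numeric(apply(acc_unique, 2L, stats::sd) / sqrt(config$n_subsamples)),
      p_value = NA_real_, row.names = NULL, stringsAsFactors = FALSE),
    turnover_matrix = turnover,
    occupancy = NULL
  )
}

build_population_hulls <- function(scores, population, labels) {
  hulls <- vector("list", length(labels))
  names(hulls) <- labels
  for (lab in labels) {
    hulls[[lab]] <- tryCatch(
      convex_hull(scores[population == lab, , drop = FALSE]),
      error = function(e) {
        stop(sprintf("population '%s': %s", lab, conditionMessage(e)), call. = FALSE)
      })
  }
  hulls
}

turnover_matrix <- function(hulls, config, n_points = config$mc_points) {
  labels <- names(hulls)
  k <- length(labels)
  turnover <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  if (k < 2L) return(turnover)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      seed_ij <- substream_seed(config$seed,
                                paste0("md:turnover:", labels[i], "|", labels[j]))
      t_ij <- pairwise_turnover(hulls[[i]], hulls[[j]], n_points = n_points,
                                seed = seed_ij)
      turnover[i, j] <- t_ij
      turnover[j, i] <- t_ij
    }
  }
  turnover
}
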