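#' Monte Carlo occupancy decomposition of a set of hulls
#'
#' Samples points uniformly in the axis-aligned bounding box of all hull
#' vertices, classifies each point by the subset of hulls containing it, and
#' estimates the union volume and the fraction of the union occupied by
#' exactly each subset.  The fraction inside exactly one hull is that
#' population's uniquely occupied share of the pooled morphospace
#' (morphological dissimilarity); fractions over all non-empty subsets sum
#' to 1.  Exact polytope boolean algebra in four dimensions is
#' disproportionate; rejection sampling in the bounding box is simple,
#' unbiased, and its binomial standard errors are reported.
#'
#' @param hulls named list of [convex_hull()] objects, all of the same
#'   dimension.
#' @param n_points number of Monte Carlo points (default 1e5).
#' @param seed RNG seed for the point sample.
#' @return an `occupancy_estimate`: `union_volume`, `box_volume`,
#'   `region_fractions` (named by `+`-joined label subsets, fractions of the
#'   union), `unique_fractions` (per label), `standard_error` (binomial SE
#'   per region fraction), `n_points`, `n_in_union`, `seed`.
#' @export
estimate_occupancy <- function(hulls, n_points = 1e5, seed = 1L) {
  if (length(hulls) == 0L) stop("estimate_occupancy needs at least one hull")
  if (is.null(names(hulls)) || any(!nzchar(names(hulls)))) {
    names(hulls) <- paste0("hull_", seq_along(hulls))
  }
  dims <- vapply(hulls, `[[`, integer(1), "dim")
  if (length(unique(dims)) != 1L) stop("all hulls must have the same dimension")
  d <- dims[[1L]]
  n_points <- as.integer(n_points)
  if (n_points < 1L) stop("n_points must be >= 1")

  verts <- do.call(rbind, lapply(hulls, `[[`, "vertices"))
  lo <- apply(verts, 2L, min)
  hi <- apply(verts, 2L, max)
  box_volume <- prod(hi - lo)

  labels <- names(hulls)
  k <- length(hulls)
  membership_counts <- new.env(parent = emptyenv())
  n_in_union <- 0L

  with_seed(seed, {
    chunk <- 200000L
    done <- 0L
    while (done < n_points) {
      m <- min(chunk, n_points - done)
      u <- matrix(stats::runif(m * d), m, d)
      u <- sweep(u, 2L, hi - lo, "*")
      u <- sweep(u, 2L, lo, "+")
      member <- matrix(FALSE, m, k)
      for (j in seq_len(k)) member[, j] <- hull_contains(hulls[[j]], u)
      code <- drop(member %*% 2^(seq_len(k) - 1L))
      inside <- code > 0
      n_in_union <- n_in_union + sum(inside)
      if (any(inside)) {
        tab <- table(code[inside])
        for (nm in names(tab)) {
          prev <- if (exists(nm, envir = membership_counts)) get(nm, envir = membership_counts) else 0L
          assign(nm, prev + as.integer(tab[[nm]]), envir = membership_counts)
        }
      }
      done <- done + m
    }
  })

  codes <- as.numeric(ls(membership_counts))
  counts <- vapply(as.character(codes), get, numeric(1), envir = membership_counts)
  region_names <- vapply(codes, function(code) {
    members <- labels[bitwAnd(as.integer(code), 2^(seq_len(k) - 1L)) > 0]
    paste(members, collapse = "+")
  }, character(1))
  ord <- order(region_names)
  region_fractions <- stats::setNames(
    if (n_in_union > 0L) as.numeric(counts[ord]) / n_in_union else numeric(length(counts)),
    region_names[ord])

  unique_fractions <- stats::setNames(numeric(k), labels)
  for (lab in labels) {
    if (lab %in% names(region_fractions)) unique_fractions[[lab]] <- region_fractions[[lab]]
  }

  structure(list(
    union_volume = box_volume * n_in_union / n_points,
    box_volume = box_volume,
    region_fractions = region_fractions,
    unique_fractions = unique_fractions,
    standard_error = sqrt(region_fractions * (1 - region_fractions) / n_points),
    n_points = n_points,
    n_in_union = n_in_union,
    seed = as.integer(seed),
    labels = labels
  ), class = "occupancy_estimate")
}

#' @export
print.occupancy_estimate <- function(x, ...) {
  cat(sprintf("Occupancy estimate over %d hulls (%d MC points): union volume %.4g\n",
              length(x$labels), x$n_points, x$union_volume))
  cat("  unique fractions: ",
      paste(sprintf("%s=%.3f", names(x$unique_fractions), x$unique_fractions),
            collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise morphological turnover between two hulls
#'
#' The percentage of the pair's combined morphospace that the two
#' populations do not share: `100 * (V(a u b) - V(a n b)) / V(a u b)`,
#' Monte Carlo estimated by sampling in the pair's bounding box.  Identical
#' hulls give 0; disjoint hulls give 100.
#'
#' @param a,b [convex_hull()] objects of the same dimension.
#' @param n_points Monte Carlo points.
#' @param seed RNG seed.
#' @return turnover percentage in `[0, 100]`.
#' @export
pairwise_turnover <- function(a, b, n_points = 1e5, seed = 1L) {
  occ <- estimate_occupancy(list(a = a, b = b), n_points = n_points, seed = seed)
  shared <- if ("a+b" %in% names(occ$region_fractions)) occ$region_fractions[["a+b"]] else 0
  100 * (1 - shared)
}
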