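#' d-dimensional convex hull with facet inequalities and exact volume
#'
#' Builds the convex hull of a point cloud in `d` dimensions using an
#' incremental (beneath-beyond) algorithm.  The hull is returned as a set of
#' extreme points together with the half-space inequalities
#' \eqn{u \cdot x \le b} (unit outward normals `u`) whose intersection is the
#' hull, and its exact volume computed by simplicial decomposition of the
#' facet fan around an interior point.  Volumes are exact (facet-based), not
#' sampled; only hull set operations (see [estimate_occupancy()]) are
#' estimated by Monte Carlo.
#'
#' Affinely degenerate inputs (points spanning fewer than `d` dimensions)
#' raise an error reporting the observed affine rank rather than silently
#' returning a flat, zero-volume hull: silent dimension loss would corrupt
#' downstream volume comparisons between populations.
#'
#' @param points numeric matrix (rows = points, columns = coordinates) or an
#'   object coercible to one; at least `d + 1` rows are required for a
#'   `d`-column input.
#' @return An object of class `convex_hull`: a list with elements
#'   `dim`, `vertices` (matrix of extreme points), `vertex_indices` (rows of
#'   the input that are extreme), `normals` (facets-by-`d` matrix of unit
#'   outward normals), `offsets` (facet offsets `b`), `facets` (integer matrix
#'   of vertex indices per simplicial facet), `volume`, and `tol`.
#' @examples
#' sq <- convex_hull(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
#' sq$volume           # 1
#' hull_contains(sq, c(0.5, 0.5))
#' @seealso [hull_contains()], [estimate_occupancy()], [pairwise_turnover()]
#' @export
convex_hull <- function(points) {
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  dimnames(pts) <- NULL
  if (any(!is.finite(pts))) stop("points contain non-finite values")
  n <- nrow(pts)
  d <- ncol(pts)
  if (d < 1L) stop("points must have at least one coordinate column")
  if (n < d + 1L) {
    stop(sprintf("insufficient points: need at least %d points in %d dimensions, got %d",
                 d + 1L, d, n))
  }

  scale <- max(abs(pts), 1)
  tol <- 1e-9 * scale

  if (d == 1L) return(hull_1d(pts, tol))

  ctr <- colMeans(pts)
  centred <- pts - rep(ctr, each = n)
  sv <- svd(centred, nu = 0L, nv = 0L)$d
  arank <- sum(sv > max(sv[1L], .Machine$double.eps) * 1e-10 * sqrt(n))
  if (arank < d) {
    stop(sprintf("degenerate point configuration: affine rank %d < dimension %d",
                 arank, d))
  }

  init <- initial_simplex(pts, tol)
  interior <- colMeans(pts[init, , drop = FALSE])

  ## facets: rows of sorted vertex indices, with unit outward normals/offsets
  fv <- t(utils::combn(sort.int(init), d))
  m0 <- nrow(fv)
  fn <- matrix(0, m0, d)
  fo <- numeric(m0)
  for (i in seq_len(m0)) {
    pl <- facet_plane(pts[fv[i, ], , drop = FALSE], interior)
    fn[i, ] <- pl$u
    fo[i] <- pl$b
  }

  remaining <- setdiff(seq_len(n), init)
  if (length(remaining) > 1L) {
    rem <- pts[remaining, , drop = FALSE] - rep(interior, each = length(remaining))
    remaining <- remaining[order(rowSums(rem^2), decreasing = TRUE)]
  }

  ## ridge keys: a sorted (d-1)-subset of vertex indices encoded in base n+1
  base_pow <- as.numeric(n + 1L)^(0:(d - 2L))

  for (p_idx in remaining) {
    p <- pts[p_idx, ]
    height <- fn %*% p - fo
    visible <- which(height > tol)
    if (length(visible) == 0L) next

    vis_fv <- fv[visible, , drop = FALSE]
    nvis <- nrow(vis_fv)
    ## all (d-1)-ridges of the visible facets (facet rows are sorted, so
    ## dropping the j-th column keeps each ridge sorted)
    ridges <- matrix(0L, nvis * d, d - 1L)
    for (j in seq_len(d)) {
      ridges[((j - 1L) * nvis + 1L):(j * nvis), ] <- vis_fv[, -j, drop = FALSE]
    }
    ## horizon ridges are those whose key occurs exactly once among visible facets
    keys <- ridges %*% base_pow
    first <- match(keys, keys)
    cnt <- tabulate(first)
    horizon <- ridges[cnt[first] == 1L, , drop = FALSE]
    if (nrow(horizon) == 0L) {
      stop("convex hull construction failed: no horizon ridge (degenerate geometry)")
    }

    nh <- nrow(horizon)
    new_fv <- matrix(0L, nh, d)
    new_fn <- matrix(0, nh, d)
    new_fo <- numeric(nh)
    for (i in seq_len(nh)) {
      fvert <- insert_sorted(horizon[i, ], p_idx)
      pl <- facet_plane(pts[fvert, , drop = FALSE], interior)
      if (is.null(pl)) {
        stop("convex hull construction failed: degenerate facet (nearly affinely dependent points)")
      }
      new_fv[i, ] <- fvert
      new_fn[i, ] <- pl$u
      new_fo[i] <- pl$b
    }
    keep <- seq_len(nrow(fv))[-visible]
    fv <- rbind(fv[keep, , drop = FALSE], new_fv)
    fn <- rbind(fn[keep, , drop = FALSE], new_fn)
    fo <- c(fo[keep], new_fo)
  }

  vidx <- sort.int(unique(as.vector(fv)))
  vol <- 0
  dfac <- factorial(d)
  for (i in seq_len(nrow(fv))) {
    w <- pts[fv[i, ], , drop = FALSE] - rep(interior, each = d)
    vol <- vol + abs(fast_det(w)) / dfac
  }

  structure(list(
    dim = d,
    vertices = pts[vidx, , drop = FALSE],
    vertex_indices = vidx,
    normals = fn,
    offsets = fo,
    facets = fv,
    volume = vol,
    interior_point = interior,
    tol = tol
  ), class = "convex_hull")
}

## 1-D hull: an interval
hull_1d <- function(pts, tol) {
  lo <- min(pts)
  hi <- max(pts)
  if (hi - lo <= tol) stop("degenerate point configuration: affine rank 0 < dimension 1")
  structure(list(
    dim = 1L,
    vertices = matrix(c(lo, hi), ncol = 1L),
    vertex_indices = c(which.min(pts[, 1L]), which.max(pts[, 1L])),
    normals = matrix(c(1, -1), ncol = 1L),
    offsets = c(hi, -lo),
    facets = matrix(c(which.max(pts[, 1L]), which.min(pts[, 1L])), ncol = 1L),
    volume = hi - lo,
    interior_point = matrix((lo + hi) / 2, 1L, 1L)[1L, ],
    tol = tol
  ), class = "convex_hull")
}

## insert value v into sorted integer vector x, keeping order
insert_sorted <- function(x, v) {
  pos <- sum(x < v)
  if (pos == 0L) c(v, x) else if (pos == length(x)) c(x, v) else c(x[1:pos], v, x[(pos + 1L):length(x)])
}

## Greedy affinely-independent seed simplex: start from an extreme point and
## repeatedly take the point farthest from the affine span of those chosen.
initial_simplex <- function(pts, tol) {
  n <- nrow(pts)
  d <- ncol(pts)
  chosen <- which.min(pts[, 1L])
  for (step in seq_len(d)) {
    base <- pts[chosen[1L], ]
    resid <- pts - rep(base, each = n)
    if (length(chosen) > 1L) {
      q <- qr.Q(qr(t(pts[chosen[-1L], , drop = FALSE]) - base))
      resid <- resid - resid %*% q %*% t(q)
    }
    dist <- sqrt(rowSums(resid^2))
    cand <- which.max(dist)
    if (dist[cand] <= tol) {
      stop(sprintf("degenerate point configuration: affine rank %d < dimension %d",
                   length(chosen) - 1L, d))
    }
    chosen <- c(chosen, cand)
  }
  chosen
}

## Oriented supporting hyperplane through the d rows of `w` (unit normal,
## pointing away from `interior`).  NULL if the rows are affinely dependent.
## The normal is the generalized cross product of the d-1 edge vectors,
## closed-form for d <= 4, QR null space otherwise.
facet_plane <- function(w, interior) {
  d <- ncol(w)
  e <- w[-1L, , drop = FALSE] - rep(w[1L, ], each = d - 1L)  # (d-1) x d edges
  u <- if (d == 2L) {
    c(e[1L, 2L], -e[1L, 1L])
  } else if (d == 3L) {
    c(e[1L, 2L] * e[2L, 3L] - e[1L, 3L] * e[2L, 2L],
      e[1L, 3L] * e[2L, 1L] - e[1L, 1L] * e[2L, 3L],
      e[1L, 1L] * e[2L, 2L] - e[1L, 2L] * e[2L, 1L])
  } else if (d == 4L) {
    cross4(e)
  } else {
    qr_m <- qr(t(e))
    if (qr_m$rank < d - 1L) return(NULL)
    qr.Q(qr_m, complete = TRUE)[, d]
  }
  nu <- sqrt(sum(u^2))
  edge_scale <- max(abs(e))
  if (nu <= (edge_scale^(d - 1L)) * 1e-12) return(NULL)
  u <- u / nu
  b <- sum(u * w[1L, ])
  if (sum(u * interior) > b) {
    u <- -u
    b <- -b
  }
  list(u = u, b = b)
}

## generalized cross product of the 3 rows of a 3x4 matrix: u_j is the signed
## 3x3 minor obtained by deleting column j
cross4 <- function(e) {
  d3 <- function(a1, a2, a3, b1, b2, b3, c1, c2, c3) {
    a1 * (b2 * c3 - b3 * c2) - a2 * (b1 * c3 - b3 * c1) + a3 * (b1 * c2 - b2 * c1)
  }
  c( d3(e[1, 2], e[1, 3], e[1, 4], e[2, 2], e[2, 3], e[2, 4], e[3, 2], e[3, 3], e[3, 4]),
    -d3(e[1, 1], e[1, 3], e[1, 4], e[2, 1], e[2, 3], e[2, 4], e[3, 1], e[3, 3], e[3, 4]),
     d3(e[1, 1], e[1, 2], e[1, 4], e[2, 1], e[2, 2], e[2, 4], e[3, 1], e[3, 2], e[3, 4]),
    -d3(e[1, 1], e[1, 2], e[1, 3], e[2, 1], e[2, 2], e[2, 3], e[3, 1], e[3, 2], e[3, 3]))
}

## determinant of a small d x d matrix, closed-form for d <= 3
fast_det <- function(w) {
  d <- ncol(w)
  if (d == 2L) return(w[1L, 1L] * w[2L, 2L] - w[1L, 2L] * w[2L, 1L])
  if (d == 3L) {
    return(w[1L, 1L] * (w[2L, 2L] * w[3L, 3L] - w[2L, 3L] * w[3L, 2L]) -
           w[1L, 2L] * (w[2L, 1L] * w[3L, 3L] - w[2L, 3L] * w[3L, 1L]) +
           w[1L, 3L] * (w[2L, 1L] * w[3L, 2L] - w[2L, 2L] * w[3L, 1L]))
  }
  if (d == 4L) {
    ## Laplace expansion along the first row using 3x3 minors
    m <- w[-1L, , drop = FALSE]
    d3 <- function(cols) {
      a <- m[, cols]
      a[1L, 1L] * (a[2L, 2L] * a[3L, 3L] - a[2L, 3L] * a[3L, 2L]) -
        a[1L, 2L] * (a[2L, 1L] * a[3L, 3L] - a[2L, 3L] * a[3L, 1L]) +
        a[1L, 3L] * (a[2L, 1L] * a[3L, 2L] - a[2L, 2L] * a[3L, 1L])
    }
    return(w[1L, 1L] * d3(c(2L, 3L, 4L)) - w[1L, 2L] * d3(c(1L, 3L, 4L)) +
           w[1L, 3L] * d3(c(1L, 2L, 4L)) - w[1L, 4L] * d3(c(1L, 2L, 3L)))
  }
  det(w)
}

#' Test whether points lie inside a convex hull
#'
#' A point is inside when every facet inequality \eqn{u \cdot x \le b} holds
#' up to the hull's tolerance, so boundary points count as inside.
#'
#' @param hull a [convex_hull()] object.
#' @param x a single point (numeric vector of length `hull$dim`) or a matrix
#'   with `hull$dim` columns, one point per row.
#' @return logical vector, one entry per point.
#' @export
hull_contains <- function(hull, x) {
  stopifnot(inherits(hull, "convex_hull"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != hull$dim) {
    stop(sprintf("dimension mismatch: hull is %d-dimensional, points have %d coordinates",
                 hull$dim, ncol(x)))
  }
  h <- x %*% t(hull$normals)
  lim <- hull$offsets + hull$tol
  out <- h > rep(lim, each = nrow(x))
  rowSums(out) == 0L
}

#' @export
print.convex_hull <- function(x, ...) {
  cat(sprintf("Convex hull in %d dimensions: %d vertices, %d facets, volume %.6g\n",
              x$dim, nrow(x$vertices), nrow(x$facets), x$volume))
  invisible(x)
}

#' Centroid of a point cloud
#'
#' The arithmetic mean of the points (the population's mean position in
#' morphospace), not the mass centroid of the hull solid.
#'
#' @param points numeric matrix, one point per row (a vector is treated as a
#'   single point).
#' @return numeric vector of column means.
#' @export
centroid <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("centroid of an empty point set is undefined")
  colMeans(points)
}

#' Euclidean distance between two centroids
#'
#' @param a,b numeric vectors of equal length.
#' @return non-negative scalar.
#' @export
centroid_distance <- function(a, b) {
  if (length(a) != length(b)) stop("dimension mismatch between centroids")
  sqrt(sum((a - b)^2))
}
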