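# Small 2D polygon kernel used by the tessellation simulator and the
# quantification stages. All polygons are plain n x 2 numeric matrices of
# vertices in order; areas are in the square of the coordinate unit (µm²).

#' Signed polygon area (shoelace formula)
#'
#' Positive for counterclockwise vertex order.
#'
#' @param xy numeric matrix (n x 2) of polygon vertices in order.
#' @return signed area, in squared coordinate units.
#' @export
poly_area_signed <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Absolute polygon area
#' @inheritParams poly_area_signed
#' @return area >= 0.
#' @export
poly_area <- function(xy) abs(poly_area_signed(xy))

#' Polygon centroid (area-weighted)
#' @inheritParams poly_area_signed
#' @return length-2 numeric vector.
#' @export
poly_centroid <- function(xy) {
  n <- nrow(xy)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(xy))  # degenerate: fall back to mean
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

# Ensure counterclockwise orientation.
ensure_ccw <- function(xy) {
  if (poly_area_signed(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

# Clip polygon to half-plane {p : a . p <= b} (Sutherland-Hodgman, one plane).
# Returns a matrix possibly with 0 rows.
clip_halfplane <- function(xy, a, b) {
  n <- nrow(xy)
  if (n == 0L) return(xy)
  d <- xy %*% a - b
  inside <- d <= 1e-12
  if (all(inside)) return(xy)
  if (!any(inside)) return(xy[0, , drop = FALSE])
  out <- matrix(0, n + 4L, 2L)
  k <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) { k <- k + 1L; out[k, ] <- xy[i, ] }
    if (inside[i] != inside[j]) {
      t <- d[i] / (d[i] - d[j])
      k <- k + 1L
      out[k, ] <- xy[i, ] + t * (xy[j, ] - xy[i, ])
    }
  }
  out[seq_len(k), , drop = FALSE]
}

# Remove consecutive duplicate vertices (closing duplicate included).
dedupe_poly <- function(xy, tol = 1e-9) {
  n <- nrow(xy)
  if (n < 2L) return(xy)
  j <- c(2:n, 1L)
  keep <- sqrt((xy[, 1] - xy[j, 1])^2 + (xy[, 2] - xy[j, 2])^2) > tol
  # keep[i] FALSE means vertex i duplicates its successor; drop i
  xy[c(keep[n], keep[-n]), , drop = FALSE]
}

# Proper + improper segment intersection test for simplicity checking.
.segs_cross <- function(p1, p2, q1, q2) {
  d1 <- (q2[1] - q1[1]) * (p1[2] - q1[2]) - (q2[2] - q1[2]) * (p1[1] - q1[1])
  d2 <- (q2[1] - q1[1]) * (p2[2] - q1[2]) - (q2[2] - q1[2]) * (p2[1] - q1[1])
  d3 <- (p2[1] - p1[1]) * (q1[2] - p1[2]) - (p2[2] - p1[2]) * (q1[1] - p1[1])
  d4 <- (p2[1] - p1[1]) * (q2[2] - p1[2]) - (p2[2] - p1[2]) * (q2[1] - p1[1])
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

#' Test whether a polygon is simple (non-self-intersecting)
#'
#' O(n^2) pairwise segment test; adequate for cell outlines (n ~ 10).
#'
#' @inheritParams poly_area_signed
#' @return logical.
#' @export
is_simple_polygon <- function(xy) {
  xy <- dedupe_poly(xy)
  n <- nrow(xy)
  if (n < 3L) return(FALSE)
  nxt <- c(2:n, 1L)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (j == i || nxt[j] == i) next
      if (.segs_cross(xy[i, ], xy[nxt[i], ], xy[j, ], xy[nxt[j], ])) return(FALSE)
    }
  }
  TRUE
}

# Voronoi cell of seed i: clip `domain` by the bisector half-plane against
# every other seed. O(n) clips per cell; only used on the initial tissue.
.voronoi_cell <- function(i, seeds, domain) {
  p <- seeds[i, ]
  cell <- domain
  ord <- order((seeds[, 1] - p[1])^2 + (seeds[, 2] - p[2])^2)
  for (k in ord) {
    if (k == i) next
    q <- seeds[k, ]
    a <- q - p                      # keep  a . x <= a . (p+q)/2
    b <- sum(a * (p + q) / 2)
    cell <- clip_halfplane(cell, a, b)
    if (nrow(cell) < 3L) break
  }
  dedupe_poly(cell)
}

#' Clipped Voronoi tessellation of a polygonal domain
#'
#' @param seeds n x 2 matrix of generator points inside `domain`.
#' @param domain simple polygon (matrix), counterclockwise.
#' @return list of polygons (matrices), one per seed, tiling the domain.
#' @export
voronoi_tessellation <- function(seeds, domain) {
  domain <- ensure_ccw(domain)
  lapply(seq_len(nrow(seeds)), .voronoi_cell, seeds = seeds, domain = domain)
}

#' Lloyd (centroidal Voronoi) relaxation
#'
#' @inheritParams voronoi_tessellation
#' @param iters number of relaxation sweeps.
#' @return relaxed seed matrix.
#' @export
lloyd_relax <- function(seeds, domain, iters = 3L) {
  for (it in seq_len(iters)) {
    cells <- voronoi_tessellation(seeds, domain)
    seeds <- t(vapply(cells, poly_centroid, numeric(2)))
  }
  seeds
}

# Split a polygon by the line through `point` with unit normal `nrm`:
# returns list(neg =, pos =) polygons on each side, each inheriting the
# two new cut vertices. Used by the cell-division rule.
split_polygon <- function(xy, point, nrm) {
  b <- sum(nrm * point)
  list(neg = dedupe_poly(clip_halfplane(xy, nrm, b)),
       pos = dedupe_poly(clip_halfplane(xy, -nrm, -b)))
}

# Principal axis of a polygon via second moments of area about the centroid.
# Returns unit vector of the LONGEST axis.
poly_long_axis <- function(xy) {
  c0 <- poly_centroid(xy)
  p <- sweep(xy, 2, c0)
  n <- nrow(p)
  j <- c(2:n, 1L)
  cr <- p[, 1] * p[j, 2] - p[j, 1] * p[, 2]
  ixx <- sum(cr * (p[, 2]^2 + p[, 2] * p[j, 2] + p[j, 2]^2)) / 12
  iyy <- sum(cr * (p[, 1]^2 + p[, 1] * p[j, 1] + p[j, 1]^2)) / 12
  ixy <- sum(cr * (p[, 1] * p[j, 2] + 2 * p[, 1] * p[, 2] +
                     2 * p[j, 1] * p[j, 2] + p[j, 1] * p[, 2])) / 24
  if (poly_area_signed(xy) < 0) { ixx <- -ixx; iyy <- -iyy; ixy <- -ixy }
  # covariance-like tensor: large eigenvalue of [[iyy,ixy],[ixy,ixx]] points
  # along the long axis
  m <- matrix(c(iyy, ixy, ixy, ixx), 2, 2)
  ev <- eigen(m, symmetric = TRUE)
  v <- ev$vectors[, 1]
  # tie-break: prefer lower angle to the x-axis (positive x component,
  # then positive y)
  if (abs(ev$values[1] - ev$values[2]) < 1e-12 * max(abs(ev$values), 1)) {
    v <- c(1, 0)
  }
  if (v[1] < 0 || (abs(v[1]) < 1e-12 && v[2] < 0)) v <- -v
  v
}
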