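# Organ axis parameterization via Bezier curves and geodesic cell-distance
# fields on the cell adjacency graph.
#
# Axis conventions: u is the normalized arclength along the longitudinal
# curve (0 at the organ base, 1 at the tip); v is the signed perpendicular
# offset rescaled by the local organ width, so that v = 0.5 on the curve,
# v = 0 on one margin and v = 1 on the other. Mediolateral positions
# relative to a medial reference (replum) are normally measured with
# cell_distance() instead, which follows the tissue itself.

.bezier_point <- function(cp, t) {
  n <- nrow(cp) - 1L
  out <- matrix(0, length(t), 2)
  for (i in 0:n) {
    b <- choose(n, i) * t^i * (1 - t)^(n - i)
    out <- out + b %o% cp[i + 1L, ]
  }
  out
}

.bezier_tangent <- function(cp, t) {
  n <- nrow(cp) - 1L
  d <- n * (cp[-1L, , drop = FALSE] - cp[-(n + 1L), , drop = FALSE])
  if (nrow(d) == 1L) return(matrix(d, length(t), 2, byrow = TRUE))
  .bezier_point(d, t)
}

#' Fit an organ axis grid
#'
#' Builds the (u, v) surface-point parameterization from a longitudinal
#' Bezier curve: u by normalized arclength of the nearest-parameter
#' projection, v by signed perpendicular offset rescaled by the local organ
#' width (estimated from the snapshot's cell vertices per arclength
#' station). The mediolateral control points only orient the sign of v
#' (v grows toward their far endpoint).
#'
#' @param snapshot a [tissue_snapshot()] whose cells define the organ
#'   footprint (used for the local width table).
#' @param longitudinal_control_points k x 2 matrix (µm), k >= 2, base first.
#' @param mediolateral_control_points optional k x 2 matrix fixing the sign
#'   of v.
#' @param n_samples dense samples along the curve (default 1024).
#' @return object of class `axis_grid`.
#' @export
fit_axis_grid <- function(snapshot, longitudinal_control_points,
                          mediolateral_control_points = NULL,
                          n_samples = 1024L) {
  cp <- as.matrix(longitudinal_control_points)
  if (nrow(cp) < 2L) stop("need >= 2 longitudinal control points")
  if (max(dist(cp)) < 1e-9) stop("control points coincide: zero-extent axis")
  ts <- seq(0, 1, length.out = n_samples)
  pts <- .bezier_point(cp, ts)
  seg <- sqrt(rowSums(diff(pts)^2))
  arc <- c(0, cumsum(seg))
  L <- arc[length(arc)]
  if (L < 1e-9) stop("zero-length axis curve")
  tg <- .bezier_tangent(cp, ts)
  tg <- tg / sqrt(rowSums(tg^2))
  nrm <- cbind(tg[, 2], -tg[, 1])          # rotate -90 deg: right side positive
  grid <- structure(list(cp = cp, med_cp = mediolateral_control_points,
                         ts = ts, pts = pts, arc = arc, arclength = L,
                         tangents = tg, normals = nrm,
                         hw_u = NULL, hw = NULL),
                    class = "axis_grid")
  # orient v toward the mediolateral curve's far endpoint
  if (!is.null(mediolateral_control_points)) {
    mp <- as.matrix(mediolateral_control_points)
    far <- mp[nrow(mp), ]
    uvo <- .project_to_curve(grid, matrix(far, 1))
    if (uvo$offset[1] < 0) grid$normals <- -grid$normals
  }
  # local half-width table from the snapshot's vertices
  V <- do.call(rbind, lapply(snapshot$cells, `[[`, "vertices"))
  pr <- .project_to_curve(grid, V)
  nb <- 32L
  bins <- pmin(pmax(floor(pr$u * nb) + 1L, 1L), nb)
  hw0 <- vapply(seq_len(nb), function(b) {
    o <- abs(pr$offset[bins == b])
    if (length(o)) max(o) else NA_real_
  }, numeric(1))
  # running max over +-2 bins: single cells under-sample the margin
  hw <- vapply(seq_len(nb), function(b) {
    w <- hw0[max(1L, b - 2L):min(nb, b + 2L)]
    if (all(is.na(w))) NA_real_ else max(w, na.rm = TRUE)
  }, numeric(1))
  mid <- (seq_len(nb) - 0.5) / nb
  ok <- !is.na(hw) & hw > 1e-9
  if (sum(ok) < 2L) stop("cannot estimate organ width from snapshot")
  grid$hw_u <- mid[ok]
  grid$hw <- hw[ok]
  # projection residual of cell centroids (diagnostic)
  ctr <- snapshot_centroids(snapshot)
  prc <- .project_to_curve(grid, ctr)
  grid$projection_residual_rms <- sqrt(mean(prc$dist2))
  grid
}

.grid_halfwidth <- function(grid, u)
  stats::approx(grid$hw_u, grid$hw, xout = pmin(pmax(u, 0), 1),
                rule = 2)$y

# Nearest-parameter projection of points onto the curve: coarse argmin over
# dense samples, then a few ternary refinement steps. Vectorized over rows.
.project_to_curve <- function(grid, P) {
  P <- as.matrix(P)
  d2 <- outer(rowSums(grid$pts^2), rep(1, nrow(P))) -
    2 * grid$pts %*% t(P) +
    outer(rep(1, nrow(grid$pts)), rowSums(P^2))
  i0 <- max.col(-t(d2), ties.method = "first")  # nearest sample per point
  n <- length(grid$ts)
  lo <- grid$ts[pmax(i0 - 2L, 1L)]
  hi <- grid$ts[pmin(i0 + 2L, n)]
  f <- function(t) rowSums((.bezier_point(grid$cp, t) - P)^2)
  for (it in 1:40) {
    m1 <- lo + (hi - lo) / 3
    m2 <- hi - (hi - lo) / 3
    take <- f(m1) < f(m2)
    hi <- ifelse(take, m2, hi)
    lo <- ifelse(take, lo, m1)
  }
  t_star <- (lo + hi) / 2
  C <- .bezier_point(grid$cp, t_star)
  Tg <- .bezier_tangent(grid$cp, t_star)
  Tg <- Tg / sqrt(rowSums(Tg^2))
  Nm <- cbind(Tg[, 2], -Tg[, 1])
  if (!is.null(grid$normals)) {
    # keep the grid's chosen sign
    sgn <- sign(rowSums(Nm * grid$normals[pmin(pmax(i0, 1L), n), ,
                                          drop = FALSE]))
    sgn[sgn == 0] <- 1
    Nm <- Nm * sgn
  }
  diffp <- P - C
  offset <- rowSums(diffp * Nm)
  u <- stats::approx(grid$ts, grid$arc, xout = t_star)$y / grid$arclength
  list(u = u, offset = offset, t = t_star, dist2 = rowSums(diffp^2))
}

#' Map surface points to axis coordinates (u, v)
#'
#' @param grid an [axis_grid()].
#' @param points n x 2 matrix (µm).
#' @return n x 2 matrix of (u, v), both clipped to `[0, 1]`.
#' @export
axis_coords <- function(grid, points) {
  pr <- .project_to_curve(grid, points)
  hw <- .grid_halfwidth(grid, pr$u)
  v <- pr$offset / (2 * hw) + 0.5
  cbind(u = pmin(pmax(pr$u, 0), 1), v = pmin(pmax(v, 0), 1))
}

#' Map axis coordinates (u, v) back to a surface point
#'
#' @param grid an [axis_grid()].
#' @param uv n x 2 matrix of (u, v) coordinates.
#' @return n x 2 matrix of points (µm).
#' @export
axis_point <- function(grid, uv) {
  uv <- matrix(uv, ncol = 2)
  t_star <- stats::approx(grid$arc / grid$arclength, grid$ts,
                          xout = pmin(pmax(uv[, 1], 0), 1))$y
  C <- .bezier_point(grid$cp, t_star)
  Tg <- .bezier_tangent(grid$cp, t_star)
  Tg <- Tg / sqrt(rowSums(Tg^2))
  Nm <- cbind(Tg[, 2], -Tg[, 1])
  i0 <- pmin(pmax(findInterval(t_star, grid$ts), 1L), nrow(grid$normals))
  sgn <- sign(rowSums(Nm * grid$normals[i0, , drop = FALSE]))
  sgn[sgn == 0] <- 1
  Nm <- Nm * sgn
  hw <- .grid_halfwidth(grid, uv[, 1])
  C + Nm * ((uv[, 2] - 0.5) * 2 * hw)
}

#' Geodesic cell-distance field on the adjacency graph
#'
#' Shortest-path distance from a source cell set, following the tissue:
#' cells are graph nodes, adjacent cells are connected with edge weight
#' equal to their centroid-to-centroid Euclidean distance, and the distance
#' to a cell is the minimum over sources. Source cells are at 0.
#'
#' @param snapshot a [tissue_snapshot()] with adjacency.
#' @param source_labels integer labels of the source set.
#' @return object of class `distance_field`: list with `source_labels`,
#'   `distance` (named, µm; `Inf` = unreachable, flagged in `unreachable`),
#'   and `normalized` (`NULL` until [normalize_distance()]).
#' @export
cell_distance <- function(snapshot, source_labels) {
  labs <- snapshot_labels(snapshot)
  source_labels <- as.integer(source_labels)
  if (!length(source_labels)) stop("empty source set")
  missing <- setdiff(source_labels, labs)
  if (length(missing)) stop("source labels not in snapshot: ",
                            paste(missing, collapse = ", "))
  ctr <- snapshot_centroids(snapshot)
  adj <- snapshot$adjacency
  g <- igraph::make_empty_graph(n = 0, directed = FALSE) +
    igraph::vertices(as.character(labs))
  if (nrow(adj)) {
    w <- sqrt(rowSums((ctr[as.character(adj[, 1]), , drop = FALSE] -
                         ctr[as.character(adj[, 2]), , drop = FALSE])^2))
    g <- igraph::add_edges(g, rbind(as.character(adj[, 1]),
                                    as.character(adj[, 2])))
    igraph::E(g)$weight <- w
  }
  D <- igraph::distances(g, v = as.character(source_labels),
                         to = as.character(labs), algorithm = "dijkstra")
  d <- apply(D, 2, min)
  names(d) <- as.character(labs)
  structure(list(source_labels = source_labels, distance = d,
                 normalized = NULL,
                 unreachable = as.integer(labs[is.infinite(d)])),
            class = "distance_field")
}

#' Normalize a distance field over a stated domain
#'
#' Divides by the maximum distance over `domain_labels` and clips to
#' `[0, 1]`. The normalization domain is an explicit, recorded parameter
#' (e.g. valve cells only, or the whole organ): there is no silent default
#' beyond "all finite cells".
#'
#' @param field a [cell_distance()] result.
#' @param domain_labels labels over which the maximum is taken (default:
#'   all cells with finite distance).
#' @return the field with `normalized` filled in (cells outside the domain
#'   get `NA`) and `domain_labels` recorded.
#' @export
normalize_distance <- function(field, domain_labels = NULL) {
  if (is.null(domain_labels)) {
    domain_labels <- as.integer(names(field$distance)[
      is.finite(field$distance)])
  }
  dd <- field$distance[as.character(domain_labels)]
  dd <- dd[is.finite(dd)]
  if (!length(dd)) stop("degenerate domain: no finite distances")
  mx <- max(dd)
  if (mx <= 0) stop("degenerate domain: all distances zero")
  nrm <- rep(NA_real_, length(field$distance))
  names(nrm) <- names(field$distance)
  nrm[names(dd)] <- pmin(pmax(dd / mx, 0), 1)
  field$normalized <- nrm
  field$domain_labels <- as.integer(names(dd))
  field$max_distance <- mx
  field
}
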