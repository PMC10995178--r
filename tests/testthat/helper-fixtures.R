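# Shared fixtures. Everything is generated in code; the expensive gynoecium
# scenario is simulated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# Full gynoecium preset series (DAI 3 -> 11, seed 1): the stated world for
# the recovery-based acceptance criteria.
gyn_series <- function() {
  if (is.null(.fixture_cache$gyn)) .fixture_cache$gyn <- scenario("gynoecium", seed = 1)
  .fixture_cache$gyn
}

# Small uniform-field world for cheap simulator tests.
unit_square <- function(side = 10) {
  matrix(c(0, 0, side, 0, side, side, 0, side), ncol = 2, byrow = TRUE)
}

rect_domain <- function(w, h, x0 = -w / 2, y0 = 0) {
  matrix(c(x0, y0, x0 + w, y0, x0 + w, y0 + h, x0, y0 + h),
         ncol = 2, byrow = TRUE)
}

uniform_spec <- function(domain, rate = 0.2, log_anis = 0,
                         division_area_threshold = 1e9, tau = 1e6, ...) {
  growth_field_spec(
    domain = domain,
    areal_rate = function(x, y, t) rep(rate, length(x)),
    log_anisotropy = function(x, y, t) rep(log_anis, length(x)),
    division_area_threshold = division_area_threshold,
    differentiation_onset = function(x, y) rep(tau, length(x)), ...)
}

# Hand-built 2x2 grid of unit squares with shared vertex ids:
#   7--8--9      cells: 1 = (1,2,5,4), 2 = (2,3,6,5),
#   4--5--6             3 = (4,5,8,7), 4 = (5,6,9,8)
#   1--2--3
grid4_snapshot <- function(time_dai = 0) {
  vid <- function(i, j) (j - 1L) * 3L + i          # i = col, j = row
  coords <- function(ids) cbind((ids - 1L) %% 3L, (ids - 1L) %/% 3L)
  mk <- function(lab, ids, region = "none", state = "proliferative")
    cell_polygon(lab, coords(ids), region = region, state = state,
                 vertex_ids = ids)
  tissue_snapshot(time_dai, list(
    mk(1L, c(vid(1, 1), vid(2, 1), vid(2, 2), vid(1, 2))),
    mk(2L, c(vid(2, 1), vid(3, 1), vid(3, 2), vid(2, 2))),
    mk(3L, c(vid(1, 2), vid(2, 2), vid(2, 3), vid(1, 3))),
    mk(4L, c(vid(2, 2), vid(3, 2), vid(3, 3), vid(2, 3)))))
}

# A chain of n unit-width cells along x, centroids `pitch` apart.
chain_snapshot <- function(n = 5, pitch = 10, time_dai = 0) {
  cells <- lapply(seq_len(n), function(i) {
    x0 <- (i - 1) * pitch
    cell_polygon(i, rbind(c(x0, 0), c(x0 + pitch, 0),
                          c(x0 + pitch, 5), c(x0, 5)))
  })
  adj <- if (n > 1) cbind(seq_len(n - 1), 2:n) else NULL
  tissue_snapshot(time_dai, cells, adjacency = adj)
}

# Independent shortest-path oracle: Bellman-Ford relaxation on the cell
# adjacency graph with centroid-distance weights, min over sources.
bellman_ford_distances <- function(snapshot, sources) {
  labs <- snapshot_labels(snapshot)
  ctr <- snapshot_centroids(snapshot)
  adj <- snapshot$adjacency
  w <- sqrt(rowSums((ctr[as.character(adj[, 1]), , drop = FALSE] -
                       ctr[as.character(adj[, 2]), , drop = FALSE])^2))
  d <- stats::setNames(rep(Inf, length(labs)), as.character(labs))
  d[as.character(sources)] <- 0
  for (iter in seq_len(length(labs))) {
    changed <- FALSE
    for (e in seq_len(nrow(adj))) {
      a <- as.character(adj[e, 1]); b <- as.character(adj[e, 2])
      if (d[[a]] + w[e] < d[[b]] - 1e-12) { d[[b]] <- d[[a]] + w[e]; changed <- TRUE }
      if (d[[b]] + w[e] < d[[a]] - 1e-12) { d[[a]] <- d[[b]] + w[e]; changed <- TRUE }
    }
    if (!changed) break
  }
  d
}

# Region tags of a snapshot as a named character vector.
regions_of <- function(snapshot)
  vapply(snapshot$cells, `[[`, character(1), "region")

states_of <- function(snapshot)
  vapply(snapshot$cells, `[[`, character(1), "state")

# Per-interval growth values + distance fields for one region group of the
# gynoecium series, as used by the acceptance recovery criterion.
gyn_axis_call <- function(k, group_region, seed = 42) {
  sim <- gyn_series()
  s1 <- sim$snapshots[[k + 1L]]
  gm <- compute_growth_map(sim$snapshots[[k]], s1, sim$lineages[[k]])
  rg <- regions_of(s1)
  grp <- as.integer(names(rg)[rg == group_region])
  vals <- stats::setNames(gm$heat_map$area_expansion_pct,
                          gm$heat_map$label)[as.character(grp)]
  if (group_region == "valve") {
    src_u <- select_labels(s1, "ymin:0.05")
    src_v <- as.integer(names(rg)[rg == "replum"])
  } else {                                  # style: distance from organ tip
    src_u <- select_labels(s1, "ymax:0.97")
    src_v <- intersect(select_labels(s1, "xband:0.12"), grp)
  }
  uf <- normalize_distance(cell_distance(s1, src_u), grp)
  vf <- normalize_distance(cell_distance(s1, src_v), grp)
  dominant_axis(vals, uf, vf, seed = seed)
}
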