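# Synthetic growing-tissue generator. Emulates a time-lapse of a growing,
# dividing, differentiating epidermal cell layer with prescribed spatially
# varying areal growth rate, anisotropy, differentiation-onset and stomata
# fields, and records exact per-lineage ground truth for recovery tests.
#
# Growth model: a diagonal strain-rate field E(x,y,t) = diag(ex, ey) is
# prescribed; vertices move with the velocity field
#   v(x, y) = ( \int_0^x ex(s, y, t) ds , \int_0^y ey(x, s, t) ds )
# whose divergence is exactly ex + ey everywhere, so local area growth
# matches the prescription even when the field varies in space (the price
# is a small compatible shear where the field has cross-gradients).
# Ground truth per cell: the areal factor is the analytic field's
# exp(h*div), averaged over the cell's vertices and centroid and composed
# across sub-steps; stretches/direction come from composing the motion
# Jacobian along the centroid trajectory.

#' Prescribed growth/differentiation field specification
#'
#' The strain-rate field is diagonal in the organ frame (x = mediolateral,
#' y = longitudinal). `areal_rate(x, y, t)` is the relative area growth per
#' day; `log_anisotropy(x, y, t)` is the signed log of the per-day stretch
#' ratio (positive = longitudinal-dominant, negative = mediolateral); both
#' must be vectorized over positions. `differentiation_onset(x, y)` returns
#' the local onset time tau (days): past tau a cell stops dividing, its
#' local rate is multiplied by `enlargement` (ramped in over ~1 day), and
#' it may convert to a stoma with probability `stomata_prob` per day,
#' honouring the no-two-adjacent-stomata spacing rule.
#'
#' Exactly one of `log_anisotropy` and `longitudinal_rate` must be given.
#' With `longitudinal_rate(y, t)` (a function of the longitudinal
#' coordinate and time only) the longitudinal strain rate is ey =
#' longitudinal_rate and ex = areal_rate - ey: because ey then has no
#' transverse gradient, the velocity field carries no shear that grows
#' with y, which keeps strongly patterned organs (distinct regions side by
#' side) well-behaved. With `log_anisotropy(x, y, t)` the split is
#' symmetric, ex = (r - la)/2, ey = (r + la)/2; use it for spatially
#' uniform or gently varying fields.
#'
#' @param domain organ outline polygon (matrix, µm) at the initial time.
#' @param areal_rate function(x, y, t) -> rate/day, vectorized, >= 0.
#' @param log_anisotropy function(x, y, t) -> signed log stretch ratio.
#' @param longitudinal_rate function(y, t) -> longitudinal strain rate/day.
#' @param division_area_threshold µm²; proliferative cells above it divide.
#' @param differentiation_onset function(x, y) -> tau (days), vectorized.
#' @param stomata_prob probability/day for a differentiated cell to become
#'   a stoma (subject to spacing).
#' @param stomata_regions region tags in which stomata may form.
#' @param enlargement rate multiplier for differentiated cells (>= 1).
#' @param seed integer seed recorded with the spec.
#' @param update_geom optional function(verts) called before each sub-step;
#'   lets field closures track the current organ extent (normalized
#'   coordinates) through a shared environment.
#' @return object of class `growth_field_spec`.
#' @export
growth_field_spec <- function(domain, areal_rate, log_anisotropy = NULL,
                              longitudinal_rate = NULL,
                              division_area_threshold,
                              differentiation_onset,
                              stomata_prob = 0, stomata_regions = REGION_TAGS,
                              enlargement = 1.25, seed = 1L,
                              update_geom = NULL) {
  stopifnot(is.function(areal_rate),
            is.function(differentiation_onset),
            division_area_threshold > 0, enlargement >= 1,
            stomata_prob >= 0, stomata_prob <= 1)
  if (is.null(log_anisotropy) == is.null(longitudinal_rate))
    stop("give exactly one of log_anisotropy and longitudinal_rate")
  structure(list(domain = domain, areal_rate = areal_rate,
                 log_anisotropy = log_anisotropy,
                 longitudinal_rate = longitudinal_rate,
                 division_area_threshold = division_area_threshold,
                 differentiation_onset = differentiation_onset,
                 stomata_prob = stomata_prob,
                 stomata_regions = stomata_regions,
                 enlargement = enlargement, seed = as.integer(seed),
                 update_geom = update_geom),
            class = "growth_field_spec")
}

# smoothstep on [0, 1]
sstep <- function(z) {
  z <- pmin(pmax(z, 0), 1)
  z * z * (3 - 2 * z)
}

# effective strain rates including the differentiation enlargement factor
# (the enlargement multiplies the areal rate; with a prescribed
# longitudinal_rate the extra growth goes into ex so that ey keeps no
# transverse gradient)
.field_exey <- function(spec, x, y, t) {
  r <- spec$areal_rate(x, y, t)
  r <- r * (1 + (spec$enlargement - 1) *
              sstep((t - spec$differentiation_onset(x, y)) / 1.0))
  if (!is.null(spec$longitudinal_rate)) {
    ey <- spec$longitudinal_rate(y, t)
    if (length(ey) == 1L) ey <- rep(ey, length(x))
    list(ex = r - ey, ey = ey)
  } else {
    la <- spec$log_anisotropy(x, y, t)
    list(ex = (r - la) / 2, ey = (r + la) / 2)
  }
}

# velocity field at points P (k x 2) by m-point midpoint quadrature
.field_velocity <- function(spec, P, t, m = 32L) {
  x <- P[, 1]; y <- P[, 2]
  w <- (seq_len(m) - 0.5) / m
  sx <- x %o% w
  ex <- .field_exey(spec, as.vector(sx), rep(y, times = m), t)$ex
  vx <- (x / m) * rowSums(matrix(ex, length(x), m))
  sy <- y %o% w
  ey <- .field_exey(spec, rep(x, times = m), as.vector(sy), t)$ey
  vy <- (y / m) * rowSums(matrix(ey, length(y), m))
  cbind(vx, vy)
}

# point-in-polygon (ray casting), vectorized over points
points_in_poly <- function(P, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(P))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > P[, 2]) != (yj > P[, 2])) &
      (P[, 1] < (xj - xi) * (P[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Generate an initial cell tessellation
#'
#' Centroidally relaxed (Lloyd) Voronoi tessellation of a polygonal organ
#' outline: the cells tile the domain without gaps or overlaps.
#'
#' @param n_cells number of cells (>= 4).
#' @param domain simple polygon matrix (µm).
#' @param seed integer seed; identical seeds give identical snapshots.
#' @param time_dai time stamp of the snapshot (days), default 0.
#' @param lloyd_iters relaxation sweeps (default 4).
#' @return a [tissue_snapshot()] whose cells carry vertex ids.
#' @export
make_initial_tissue <- function(n_cells, domain, seed, time_dai = 0,
                                lloyd_iters = 4L) {
  n_cells <- as.integer(n_cells)
  if (n_cells < 4L) stop("n_cells must be >= 4")
  domain <- ensure_ccw(as.matrix(domain))
  if (nrow(domain) < 3L || poly_area(domain) <= 0 ||
      !is_simple_polygon(domain))
    stop("degenerate domain polygon")
  set.seed(seed)
  bb <- apply(domain, 2, range)
  seeds <- matrix(0, 0, 2)
  while (nrow(seeds) < n_cells) {
    cand <- cbind(stats::runif(2 * n_cells, bb[1, 1], bb[2, 1]),
                  stats::runif(2 * n_cells, bb[1, 2], bb[2, 2]))
    cand <- cand[points_in_poly(cand, domain), , drop = FALSE]
    seeds <- rbind(seeds, cand)
  }
  seeds <- seeds[seq_len(n_cells), , drop = FALSE]
  seeds <- lloyd_relax(seeds, domain, iters = lloyd_iters)
  polys <- voronoi_tessellation(seeds, domain)
  as_snapshot(tissue_from_polys(polys, time = time_dai))
}

#' Advance a tissue by one time interval under a growth field
#'
#' Applies the prescribed growth to all shared vertices with sub-stepping,
#' switches cells past their local differentiation onset to the
#' differentiated state, divides proliferative cells above the area
#' threshold (shortest wall through the centroid, perpendicular to the
#' cell's longest axis), converts differentiated cells to stomata under the
#' spacing rule, and returns the new snapshot, the child-to-parent lineage
#' map, and a ground-truth table of the imposed per-parent deformation.
#'
#' @param snapshot a [tissue_snapshot()] with vertex ids.
#' @param spec a [growth_field_spec()].
#' @param dt interval length (days), > 0.
#' @param seed integer seed for division/stomata randomness.
#' @param n_substeps sub-steps per interval (default 10).
#' @return list with `snapshot` (t1), `lineage` ([lineage_map()]), and
#'   `ground_truth` (data.frame: parent_label, t0, t1, area_factor,
#'   lambda_max, lambda_min, angle_deg).
#' @export
step_tissue <- function(snapshot, spec, dt, seed = 1L, n_substeps = 10L) {
  stopifnot(dt > 0)
  tissue0 <- snapshot_to_tissue(snapshot)
  res <- .step_geometry(tissue0, spec, dt, n_substeps)
  if (!res$ok) {
    res <- .step_geometry(tissue0, spec, dt, 2L * n_substeps)
    if (!res$ok) stop("growth step produced a self-intersecting polygon ",
                      "even with halved sub-steps")
  }
  tissue <- res$tissue
  t1 <- tissue$time
  set.seed(seed)
  if (!is.null(spec$update_geom)) spec$update_geom(tissue$verts)

  # differentiation: proliferative cells past their local onset switch
  ctr <- tissue_centroids(tissue)
  tau <- spec$differentiation_onset(ctr[, 1], ctr[, 2])
  prolif <- names(tissue$cells)[tissue$state == "proliferative"]
  flip <- prolif[t1 >= tau[match(prolif, rownames(ctr))]]
  tissue$state[flip] <- "differentiated"

  # division of proliferative cells above the area threshold; lineage is
  # tracked back to the labels present at step start
  parent_of_lab <- stats::setNames(as.integer(names(tissue$cells)),
                                   names(tissue$cells))
  for (round in 1:4) {
    areas <- tissue_areas(tissue)
    big <- names(areas)[areas > spec$division_area_threshold &
                          tissue$state[names(areas)] == "proliferative"]
    if (!length(big)) break
    em <- tissue_edge_map(tissue)
    for (lab in big) {
      out <- divide_one(tissue, lab, em)
      if (is.null(out)) next
      tissue <- out$tissue
      anc <- parent_of_lab[[lab]]
      parent_of_lab <- parent_of_lab[names(parent_of_lab) != lab]
      for (dl in out$daughters) parent_of_lab[[as.character(dl)]] <- anc
    }
  }

  # stomata: differentiated cells in permitted regions convert with
  # probability stomata_prob * dt, never adjacent to an existing stoma
  if (spec$stomata_prob > 0) {
    adj <- tissue_adjacency(tissue)
    nbrs <- function(lab) {
      l <- as.integer(lab)
      c(adj[adj[, 1] == l, 2], adj[adj[, 2] == l, 1])
    }
    cand <- names(tissue$cells)[tissue$state == "differentiated" &
                                  tissue$region %in% spec$stomata_regions]
    cand <- sample(cand)
    p <- min(1, spec$stomata_prob * dt)
    for (lab in cand) {
      if (stats::runif(1) > p) next
      if (any(tissue$state[as.character(nbrs(lab))] == "stoma")) next
      tissue$state[lab] <- "stoma"
    }
  }

  snap1 <- as_snapshot(tissue)
  lin <- lineage_map(snapshot$time_dai, t1, parent_of_lab)
  gt <- res$ground_truth
  list(snapshot = snap1, lineage = lin, ground_truth = gt)
}

# geometric part of a step: vertex displacement + per-cell ground truth.
# Returns ok = FALSE if any polygon went non-simple (caller retries with
# more sub-steps).
.step_geometry <- function(tissue, spec, dt, n_substeps) {
  t0 <- tissue$time
  h <- dt / n_substeps
  ncell <- length(tissue$cells)
  C <- tissue_centroids(tissue)
  Fs <- array(0, c(2, 2, ncell))
  Fs[1, 1, ] <- 1; Fs[2, 2, ] <- 1
  # cell-membership index of vertices, for cell-averaged field sampling
  cyc_all <- unlist(tissue$cells, use.names = FALSE)
  cyc_len <- lengths(tissue$cells)
  cyc_cell <- rep(seq_len(ncell), times = cyc_len)
  area_fac <- rep(1, ncell)
  eps <- 0.05  # µm, finite-difference step for the motion Jacobian
  for (s in seq_len(n_substeps)) {
    tt <- t0 + (s - 0.5) * h
    if (!is.null(spec$update_geom)) spec$update_geom(tissue$verts)
    # ground truth first (field evaluated before vertices move is the same
    # field the vertices see in this sub-step)
    P5 <- rbind(C,
                C + matrix(c(eps, 0), ncell, 2, byrow = TRUE),
                C - matrix(c(eps, 0), ncell, 2, byrow = TRUE),
                C + matrix(c(0, eps), ncell, 2, byrow = TRUE),
                C - matrix(c(0, eps), ncell, 2, byrow = TRUE))
    V5 <- .field_velocity(spec, P5, tt)
    i0 <- seq_len(ncell)
    dvdx <- (V5[i0 + ncell, ] - V5[i0 + 2L * ncell, ]) / (2 * eps)
    dvdy <- (V5[i0 + 3L * ncell, ] - V5[i0 + 4L * ncell, ]) / (2 * eps)
    for (k in i0) {
      J <- matrix(c(dvdx[k, 1], dvdy[k, 1], dvdx[k, 2], dvdy[k, 2]),
                  2, 2, byrow = TRUE)
      Fs[, , k] <- (diag(2) + h * J) %*% Fs[, , k]
    }
    # ground-truth area factor: exp(h * div) of the imposed strain field,
    # averaged over each cell's vertices and centroid (evaluates the
    # analytic field, not the numerical motion, so it stays an independent
    # prescription; exp matches the continuum flow that the RK2 vertex
    # update approximates)
    ee_v <- .field_exey(spec, tissue$verts[, 1], tissue$verts[, 2], tt)
    fac_v <- exp(h * (ee_v$ex + ee_v$ey))
    ee_c <- .field_exey(spec, C[, 1], C[, 2], tt)
    fac_c <- exp(h * (ee_c$ex + ee_c$ey))
    fac_cell <- (rowsum(fac_v[cyc_all], cyc_cell)[, 1] + fac_c) /
      (cyc_len + 1)
    area_fac <- area_fac * fac_cell
    # midpoint (RK2) update for centroid paths and vertices
    Cmid <- C + (h / 2) * V5[i0, , drop = FALSE]
    C <- C + h * .field_velocity(spec, Cmid, tt)
    Vm <- tissue$verts + (h / 2) * .field_velocity(spec, tissue$verts, tt)
    tissue$verts <- tissue$verts + h * .field_velocity(spec, Vm, tt)
  }
  tissue$time <- t0 + dt
  # validity: polygons must remain simple with positive area
  for (ids in tissue$cells) {
    xy <- cell_xy(tissue, ids)
    if (poly_area_signed(xy) <= 0 || !is_simple_polygon(xy))
      return(list(ok = FALSE))
  }
  labs <- names(tissue$cells)
  gt <- data.frame(parent_label = as.integer(labs), t0 = t0, t1 = t0 + dt,
                   area_factor = NA_real_, lambda_max = NA_real_,
                   lambda_min = NA_real_, angle_deg = NA_real_)
  for (k in seq_len(ncell)) {
    Fk <- Fs[, , k]
    sv <- svd(Fk)
    gt$area_factor[k] <- area_fac[k]
    gt$lambda_max[k] <- sv$d[1]
    gt$lambda_min[k] <- sv$d[2]
    gt$angle_deg[k] <- atan2(sv$u[2, 1], sv$u[1, 1]) * 180 / pi
  }
  list(ok = TRUE, tissue = tissue, ground_truth = gt)
}
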