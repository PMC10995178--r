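# Per-lineage growth quantification: area expansion, principal stretches
# and anisotropy from junction correspondence (least-squares affine fit +
# SVD), directional growth along organ axes, and interval growth maps
# displayed on the second time point.

#' Area expansion between a mother cell and its daughters
#'
#' `(total daughter area at T1 / mother area at T0 - 1) x 100`, in percent;
#' negative values indicate shrinkage.
#'
#' @param area_t0 mother area (µm²), > 0.
#' @param total_daughter_area_t1 summed daughter area (µm²), >= 0.
#' @return percent area expansion (vectorized).
#' @export
area_expansion <- function(area_t0, total_daughter_area_t1) {
  if (any(area_t0 <= 0)) stop("area_t0 must be > 0")
  if (any(total_daughter_area_t1 < 0)) stop("daughter area must be >= 0")
  (total_daughter_area_t1 / area_t0 - 1) * 100
}

#' Growth anisotropy ratio
#'
#' Ratio of expansion in the maximal and minimal principal directions of
#' growth.
#'
#' @param lambda_max,lambda_min principal stretches, `lambda_min > 0`.
#' @return `lambda_max / lambda_min` (>= 1 for ordered stretches).
#' @export
anisotropy <- function(lambda_max, lambda_min) {
  if (any(lambda_min <= 0)) stop("lambda_min must be > 0")
  lambda_max / lambda_min
}

#' Principal growth stretches from junction correspondence
#'
#' Fits the least-squares linear map `A` (2 x 2, translation removed by
#' centering both point sets) sending the mother cell's junctions at T0 to
#' their positions at T1; the singular values of `A` are the principal
#' stretches and the left singular vector of the largest one the principal
#' growth direction.
#'
#' @param junctions_t0,junctions_t1 n x 2 matrices of matched junction
#'   coordinates (n >= 3, non-collinear).
#' @return list: `lambda_max`, `lambda_min`, `anisotropy`,
#'   `principal_direction` (unit vector; `NA` and `direction_defined =
#'   FALSE` when anisotropy < 1 + 1e-6), `A` (fitted map), `residual_rms`.
#' @export
growth_tensor <- function(junctions_t0, junctions_t1) {
  X0 <- as.matrix(junctions_t0); X1 <- as.matrix(junctions_t1)
  if (nrow(X0) != nrow(X1)) stop("junction sets differ in size")
  if (nrow(X0) < 3L) stop("under-determined deformation: need >= 3 junction pairs")
  X0c <- sweep(X0, 2, colMeans(X0))
  X1c <- sweep(X1, 2, colMeans(X1))
  M <- crossprod(X0c)                      # 2x2
  if (abs(det(M)) < 1e-10 * (sum(X0c^2) / nrow(X0c))^2 || sum(X0c^2) == 0)
    stop("under-determined deformation: junctions are collinear")
  # A minimizing ||X1c - X0c A^T||: A = (X1c' X0c) (X0c' X0c)^{-1}
  A <- crossprod(X1c, X0c) %*% solve(M)
  sv <- svd(A)
  res <- X1c - X0c %*% t(A)
  lmax <- sv$d[1]; lmin <- sv$d[2]
  defined <- (lmax / lmin) >= 1 + 1e-6
  dir <- if (defined) sv$u[, 1] else c(NA_real_, NA_real_)
  if (defined && (dir[1] < 0 || (dir[1] == 0 && dir[2] < 0))) dir <- -dir
  list(lambda_max = lmax, lambda_min = lmin,
       anisotropy = lmax / lmin,
       principal_direction = dir, direction_defined = defined,
       A = A, residual_rms = sqrt(mean(res^2)))
}

# Outer boundary of a set of cells sharing vertex ids: edges used exactly
# once, chained into a cycle. Returns list(ids, xy) or NULL if the union is
# not a single simple cycle.
daughters_union_boundary <- function(cells) {
  dir_a <- integer(0); dir_b <- integer(0)
  for (c in cells) {
    ids <- c$vertex_ids
    n <- length(ids)
    j <- c(2:n, 1L)
    dir_a <- c(dir_a, ids); dir_b <- c(dir_b, ids[j])
  }
  keys <- paste0(dir_a, ">", dir_b)
  rev_in <- paste0(dir_b, ">", dir_a) %in% keys
  ba <- dir_a[!rev_in]; bb <- dir_b[!rev_in]
  if (!length(ba)) return(NULL)
  nxt <- stats::setNames(bb, as.character(ba))
  start <- ba[1]
  cyc <- start; cur <- start
  repeat {
    cur <- nxt[[as.character(cur)]]
    if (is.null(cur)) return(NULL)
    if (cur == start) break
    cyc <- c(cyc, cur)
    if (length(cyc) > length(ba)) return(NULL)
  }
  if (length(cyc) != length(ba)) return(NULL)  # multiple loops / holes
  # coordinates: look up from whichever cell holds each id
  coord <- new.env(parent = emptyenv())
  for (c in cells)
    for (k in seq_along(c$vertex_ids))
      coord[[as.character(c$vertex_ids[k])]] <- c$vertices[k, ]
  xy <- t(vapply(as.character(cyc), function(id) coord[[id]], numeric(2)))
  list(ids = as.integer(cyc), xy = ensure_ccw(xy))
}

#' Directional growth along an organ axis
#'
#' Cell "length" along an axis is the extent of the cell footprint in the
#' grid coordinate of that axis, converted to arclength µm; the return is
#' the length-ratio percentage `(L1 / L0 - 1) x 100`.
#'
#' @param parent_xy mother outline at T0 (matrix, µm).
#' @param daughters_xy union outline of the daughters at T1.
#' @param grid an [axis_grid()] (fitted on a frame covering both outlines).
#' @param axis `"longitudinal"` (u) or `"mediolateral"` (v).
#' @return percent length increase along the axis.
#' @export
directional_expansion <- function(parent_xy, daughters_xy, grid,
                                  axis = c("longitudinal", "mediolateral")) {
  axis <- match.arg(axis)
  l0 <- .axis_length(grid, parent_xy, axis)
  l1 <- .axis_length(grid, daughters_xy, axis)
  if (l0 <= 0) stop("degenerate mother extent along ", axis)
  (l1 / l0 - 1) * 100
}

.axis_length <- function(grid, xy, axis) {
  uv <- axis_coords(grid, xy)
  if (anyNA(uv)) stop("cell outside the axis-grid domain")
  if (axis == "longitudinal") {
    diff(range(uv[, 1])) * grid$arclength
  } else {
    # local organ width at the cell's mean longitudinal station
    diff(range(uv[, 2])) * 2 * .grid_halfwidth(grid, mean(uv[, 1]))
  }
}

#' Per-interval growth map between two snapshots
#'
#' One growth record per non-vanished parent: area expansion from the
#' daughters' summed area, principal stretches/anisotropy from the
#' junctions of the parent that persist to T1 (vertex ids shared by both
#' snapshots; >= 3 required, otherwise the tensor fields are `NA`), and
#' optionally directional expansion along the axes of `grid`. The heat-map
#' table repeats each parent's values on every daughter label, i.e. the
#' interval quantities are displayed on the second time point.
#'
#' @param s0,s1 consecutive [tissue_snapshot()]s.
#' @param lineage [lineage_map()] from `s0` to `s1`.
#' @param grid optional [axis_grid()] for directional components.
#' @return list: `records` (data.frame keyed by `parent_label`) and
#'   `heat_map` (data.frame keyed by t1 `label`).
#' @export
compute_growth_map <- function(s0, s1, lineage, grid = NULL) {
  a0 <- snapshot_areas(s0)
  a1 <- snapshot_areas(s1)
  kids_by_parent <- split(names(lineage$parent_of), lineage$parent_of)
  parents <- names(kids_by_parent)
  n <- length(parents)
  rec <- data.frame(parent_label = as.integer(parents),
                    t0 = lineage$t0, t1 = lineage$t1,
                    area_expansion_pct = NA_real_,
                    lambda_max = NA_real_, lambda_min = NA_real_,
                    anisotropy = NA_real_, direction_angle_deg = NA_real_,
                    n_daughters = NA_integer_, residual_rms = NA_real_,
                    longitudinal_pct = NA_real_, mediolateral_pct = NA_real_)
  has_ids1 <- all(vapply(s1$cells, function(c) !is.null(c$vertex_ids),
                         logical(1)))
  for (i in seq_len(n)) {
    par <- parents[i]
    kids <- kids_by_parent[[i]]
    rec$n_daughters[i] <- length(kids)
    rec$area_expansion_pct[i] <- area_expansion(a0[[par]],
                                                sum(a1[kids]))
    pc <- s0$cells[[par]]
    if (is.null(pc$vertex_ids) || !has_ids1) next
    # junctions of the parent still present at t1 (ids persist)
    id_pos1 <- new.env(parent = emptyenv())
    for (kc in s1$cells[kids])
      for (q in seq_along(kc$vertex_ids))
        id_pos1[[as.character(kc$vertex_ids[q])]] <- kc$vertices[q, ]
    keep <- vapply(as.character(pc$vertex_ids),
                   function(id) !is.null(id_pos1[[id]]), logical(1))
    if (sum(keep) < 3L) next
    X0 <- pc$vertices[keep, , drop = FALSE]
    X1 <- t(vapply(as.character(pc$vertex_ids[keep]),
                   function(id) id_pos1[[id]], numeric(2)))
    gt <- tryCatch(growth_tensor(X0, X1), error = function(e) NULL)
    if (is.null(gt)) next
    rec$lambda_max[i] <- gt$lambda_max
    rec$lambda_min[i] <- gt$lambda_min
    rec$anisotropy[i] <- gt$anisotropy
    rec$residual_rms[i] <- gt$residual_rms
    if (gt$direction_defined)
      rec$direction_angle_deg[i] <- atan2(gt$principal_direction[2],
                                          gt$principal_direction[1]) * 180 / pi
    if (!is.null(grid)) {
      ub <- daughters_union_boundary(s1$cells[kids])
      if (!is.null(ub)) {
        rec$longitudinal_pct[i] <- tryCatch(
          directional_expansion(pc$vertices, ub$xy, grid, "longitudinal"),
          error = function(e) NA_real_)
        rec$mediolateral_pct[i] <- tryCatch(
          directional_expansion(pc$vertices, ub$xy, grid, "mediolateral"),
          error = function(e) NA_real_)
      }
    }
  }
  # heat map: values keyed by the t1 labels, daughters inherit the parent's
  child <- names(lineage$parent_of)
  idx <- match(as.character(lineage$parent_of), parents)
  hm <- rec[idx, setdiff(names(rec), c("parent_label", "n_daughters")),
            drop = FALSE]
  hm <- cbind(label = as.integer(child),
              parent_label = as.integer(as.character(lineage$parent_of)), hm)
  rownames(hm) <- NULL
  list(records = rec, heat_map = hm)
}
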