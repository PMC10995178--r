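# Internal shared-vertex tessellation. Cells are stored as cycles of vertex
# ids into one coordinate table, so that growth displaces every shared wall
# vertex exactly once and divisions stay conformal (a new wall endpoint is
# inserted into the neighbouring cell's boundary too). Vertex ids persist
# across time steps; they are the junction correspondence used downstream.

ot_tissue <- function(time, verts, cells, region, state, next_label) {
  structure(list(time = time, verts = verts, cells = cells,
                 region = region, state = state, next_label = next_label),
            class = "ot_tissue")
}

# Build an ot_tissue from loose polygons by pooling vertices on rounded
# coordinates (tol ~ 1e-7 of a µm).
tissue_from_polys <- function(polys, time = 0) {
  key_env <- new.env(hash = TRUE, parent = emptyenv())
  verts <- matrix(0, 0, 2)
  nv <- 0L
  coords <- list()
  cells <- vector("list", length(polys))
  for (ci in seq_along(polys)) {
    xy <- ensure_ccw(dedupe_poly(polys[[ci]]))
    ids <- integer(nrow(xy))
    for (k in seq_len(nrow(xy))) {
      key <- paste(sprintf("%.7f", xy[k, 1]), sprintf("%.7f", xy[k, 2]))
      id <- key_env[[key]]
      if (is.null(id)) {
        nv <- nv + 1L
        id <- nv
        key_env[[key]] <- id
        coords[[nv]] <- xy[k, ]
      }
      ids[k] <- id
    }
    cells[[ci]] <- ids
  }
  verts <- do.call(rbind, coords)
  names(cells) <- as.character(seq_along(polys))
  n <- length(polys)
  ot_tissue(time, verts, cells,
            region = stats::setNames(rep("none", n), names(cells)),
            state = stats::setNames(rep("proliferative", n), names(cells)),
            next_label = n + 1L)
}

cell_xy <- function(tissue, ids) tissue$verts[ids, , drop = FALSE]

tissue_areas <- function(tissue)
  vapply(tissue$cells, function(ids) poly_area(cell_xy(tissue, ids)),
         numeric(1))

tissue_centroids <- function(tissue) {
  m <- t(vapply(tissue$cells,
                function(ids) poly_centroid(cell_xy(tissue, ids)),
                numeric(2)))
  rownames(m) <- names(tissue$cells)
  m
}

# edge key helpers (vertex ids fit comfortably in doubles)
.ek <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))

.cell_edges <- function(ids) {
  n <- length(ids)
  j <- c(2:n, 1L)
  cbind(ids, ids[j])
}

# map edge key -> integer vector of owning cell labels (1 boundary, 2 inner)
tissue_edge_map <- function(tissue) {
  em <- new.env(hash = TRUE, parent = emptyenv())
  for (lab in names(tissue$cells)) {
    e <- .cell_edges(tissue$cells[[lab]])
    keys <- .ek(e[, 1], e[, 2])
    labn <- as.integer(lab)
    for (k in keys) em[[k]] <- c(em[[k]], labn)
  }
  em
}

tissue_adjacency <- function(tissue) {
  em <- tissue_edge_map(tissue)
  prs <- eapply(em, identity)
  prs <- prs[lengths(prs) == 2L]
  if (!length(prs)) return(matrix(integer(0), 0, 2))
  .canon_adjacency(do.call(rbind, prs))
}

# Convert to the public snapshot type (cells carry vertex ids).
as_snapshot <- function(tissue) {
  cells <- lapply(names(tissue$cells), function(lab) {
    ids <- tissue$cells[[lab]]
    cell_polygon(as.integer(lab), cell_xy(tissue, ids),
                 region = tissue$region[[lab]], state = tissue$state[[lab]],
                 vertex_ids = ids)
  })
  tissue_snapshot(tissue$time, cells, adjacency = tissue_adjacency(tissue))
}

# Rebuild the internal structure from a snapshot whose cells carry
# vertex ids (simulator output or files that preserve them).
snapshot_to_tissue <- function(snapshot) {
  cells <- snapshot$cells
  if (!all(vapply(cells, function(c) !is.null(c$vertex_ids), logical(1))))
    stop("snapshot cells lack vertex ids; cannot rebuild tessellation")
  maxid <- max(vapply(cells, function(c) max(c$vertex_ids), integer(1)))
  verts <- matrix(NA_real_, maxid, 2)
  cl <- list(); region <- character(0); state <- character(0)
  for (c in cells) {
    verts[c$vertex_ids, ] <- c$vertices
    lab <- as.character(c$label)
    cl[[lab]] <- c$vertex_ids
    region[lab] <- c$region
    state[lab] <- c$state
  }
  ot_tissue(snapshot$time_dai, verts, cl, region, state,
            next_label = max(vapply(cells, `[[`, integer(1), "label")) + 1L)
}

# Structural soundness of a tessellation: every cell simple/ccw/positive,
# every directed edge used at most once, and the union of cells is gap- and
# overlap-free (sum of cell areas equals the area enclosed by the assembled
# outer boundary, within rel_tol).
tessellation_check <- function(tissue, rel_tol = 1e-6, check_simple = TRUE) {
  msgs <- character(0)
  dir_keys <- character(0)
  total <- 0
  for (lab in names(tissue$cells)) {
    ids <- tissue$cells[[lab]]
    xy <- cell_xy(tissue, ids)
    a <- poly_area_signed(xy)
    if (a <= 0) msgs <- c(msgs, paste0("cell ", lab, ": non-positive/clockwise area"))
    if (check_simple && !is_simple_polygon(xy))
      msgs <- c(msgs, paste0("cell ", lab, ": self-intersecting"))
    total <- total + abs(a)
    e <- .cell_edges(ids)
    dir_keys <- c(dir_keys, paste0(e[, 1], ">", e[, 2]))
  }
  if (anyDuplicated(dir_keys))
    msgs <- c(msgs, "directed edge reused: overlapping cells")
  # assemble boundary cycles from directed edges with no reverse partner
  pieces <- strsplit(dir_keys, ">", fixed = TRUE)
  a_ <- vapply(pieces, `[`, character(1), 1L)
  b_ <- vapply(pieces, `[`, character(1), 2L)
  rev_present <- paste0(b_, ">", a_) %in% dir_keys
  ba <- as.integer(a_[!rev_present]); bb <- as.integer(b_[!rev_present])
  nxt <- stats::setNames(bb, ba)
  visited <- stats::setNames(rep(FALSE, length(ba)), ba)
  barea <- 0
  for (s in ba) {
    if (visited[[as.character(s)]]) next
    cyc <- s; cur <- s
    repeat {
      visited[[as.character(cur)]] <- TRUE
      cur <- nxt[[as.character(cur)]]
      if (is.null(cur) || cur == s) break
      cyc <- c(cyc, cur)
    }
    barea <- barea + poly_area_signed(tissue$verts[cyc, , drop = FALSE])
  }
  if (abs(barea - total) > rel_tol * max(total, 1))
    msgs <- c(msgs, sprintf("gap/overlap: boundary area %.6f vs cell sum %.6f",
                            barea, total))
  list(ok = length(msgs) == 0L, messages = msgs,
       total_area = total, boundary_area = barea)
}

# --- cell division ------------------------------------------------------

# Split cell `lab` by the wall through its centroid perpendicular to its
# longest principal axis. Inserts the two wall endpoints into the
# neighbouring cells' boundaries (via the live edge map `em`). Returns the
# updated tissue plus the two daughter labels, or NULL if the cut is
# degenerate (skipped this round).
divide_one <- function(tissue, lab, em) {
  ids <- tissue$cells[[lab]]
  xy <- cell_xy(tissue, ids)
  nrm <- poly_long_axis(xy)          # wall runs perpendicular to long axis
  ctr <- poly_centroid(xy)
  b <- sum(nrm * ctr)
  d <- as.vector(xy %*% nrm) - b
  n <- length(ids)
  j <- c(2:n, 1L)
  crossing <- which((d < 0 & d[j] >= 0) | (d >= 0 & d[j] < 0))
  if (length(crossing) != 2L) return(NULL)
  newids <- integer(2)
  newpts <- matrix(0, 2, 2)
  for (k in 1:2) {
    i <- crossing[k]
    t <- d[i] / (d[i] - d[j][i])
    t <- min(max(t, 0.02), 0.98)     # keep wall endpoints off junctions
    newpts[k, ] <- xy[i, ] + t * (xy[j[i], ] - xy[i, ])
  }
  nv <- nrow(tissue$verts)
  tissue$verts <- rbind(tissue$verts, newpts)
  newids <- c(nv + 1L, nv + 2L)
  # insert new vertex into this cycle after position crossing[k], and into
  # the neighbour sharing that edge
  ins <- function(cyc, after_id, before_id, wid) {
    # insert wid between consecutive occurrence of after_id -> before_id
    m <- length(cyc)
    jj <- c(2:m, 1L)
    pos <- which(cyc == after_id & cyc[jj] == before_id)
    if (!length(pos)) {
      pos <- which(cyc == before_id & cyc[jj] == after_id)
      if (!length(pos)) return(NULL)
    }
    append(cyc, wid, after = pos[1])
  }
  labn <- as.integer(lab)
  for (k in 1:2) {
    i <- crossing[k]
    a_id <- ids[i]; b_id <- ids[j[i]]
    key <- .ek(a_id, b_id)
    owners <- em[[key]]
    for (ow in setdiff(owners, labn)) {
      owl <- as.character(ow)
      upd <- ins(tissue$cells[[owl]], a_id, b_id, newids[k])
      if (!is.null(upd)) tissue$cells[[owl]] <- upd
    }
    # update edge map: key -> two halves, same owners
    em[[.ek(a_id, newids[k])]] <- owners
    em[[.ek(newids[k], b_id)]] <- owners
    if (!is.null(em[[key]])) rm(list = key, envir = em)
  }
  # rebuild this cell's cycle with the wall vertices in place
  cyc <- ids
  for (k in 1:2) cyc <- ins(cyc, ids[crossing[k]], ids[j[crossing[k]]], newids[k])
  p1 <- which(cyc == newids[1]); p2 <- which(cyc == newids[2])
  if (p1 > p2) { tmp <- p1; p1 <- p2; p2 <- tmp }
  d1 <- cyc[p1:p2]
  d2 <- c(cyc[p2:length(cyc)], cyc[seq_len(p1)])
  if (length(d1) < 3L || length(d2) < 3L) return(NULL)
  la <- tissue$next_label; lb <- la + 1L
  tissue$next_label <- lb + 1L
  laa <- as.character(la); lbb <- as.character(lb)
  tissue$cells[[laa]] <- d1
  tissue$cells[[lbb]] <- d2
  tissue$region[laa] <- tissue$region[lbb] <- tissue$region[[lab]]
  tissue$state[laa] <- tissue$state[lbb] <- tissue$state[[lab]]
  tissue$cells[[lab]] <- NULL
  tissue$region <- tissue$region[names(tissue$region) != lab]
  tissue$state <- tissue$state[names(tissue$state) != lab]
  # reassign edges of the divided cell to its daughters
  for (dl in c(laa, lbb)) {
    e <- .cell_edges(tissue$cells[[dl]])
    for (q in seq_len(nrow(e))) {
      key <- .ek(e[q, 1], e[q, 2])
      own <- em[[key]]
      own <- own[own != labn]
      em[[key]] <- unique(c(own, as.integer(dl)))
    }
  }
  list(tissue = tissue, daughters = c(la, lb))
}
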