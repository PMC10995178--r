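# Core domain types: CellPolygon, TissueSnapshot, LineageMap, DistanceField,
# GradientProfile, plus series validation. Units are fixed package-wide:
# µm for coordinates, µm² for areas, days for time, percentages on 0-100.

REGION_TAGS <- c("style", "valve", "replum", "medial", "base", "none")
STATE_TAGS  <- c("proliferative", "differentiated", "stoma")

#' Construct a labeled epidermal cell footprint
#'
#' A cell is a simple, counterclockwise planar polygon with a region identity
#' tag and a cell-state tag. Vertex ids, when supplied, identify shared
#' tessellation vertices across cells and time points and enable
#' junction-correspondence growth tensors.
#'
#' @param label positive integer cell label, unique within a snapshot.
#' @param vertices n x 2 numeric matrix of ordered vertex coordinates (µm).
#' @param region one of `"style"`, `"valve"`, `"replum"`, `"medial"`,
#'   `"base"`, `"none"`.
#' @param state one of `"proliferative"`, `"differentiated"`, `"stoma"`.
#' @param vertex_ids optional integer vector of shared-vertex ids, one per
#'   vertex row.
#' @return object of class `cell_polygon` with an `area` field (µm²,
#'   shoelace).
#' @export
cell_polygon <- function(label, vertices, region = "none",
                         state = "proliferative", vertex_ids = NULL) {
  label <- as.integer(label)
  stopifnot(length(label) == 1L, !is.na(label), label > 0L)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("cell ", label, ": vertices must be an n x 2 matrix with n >= 3")
  region <- match.arg(region, REGION_TAGS)
  state <- match.arg(state, STATE_TAGS)
  if (poly_area_signed(vertices) < 0) {
    vertices <- vertices[rev(seq_len(nrow(vertices))), , drop = FALSE]
    if (!is.null(vertex_ids)) vertex_ids <- rev(vertex_ids)
  }
  if (!is_simple_polygon(vertices))
    stop("cell ", label, ": polygon is self-intersecting")
  a <- poly_area(vertices)
  if (a <= 0) stop("cell ", label, ": zero area")
  if (!is.null(vertex_ids)) {
    vertex_ids <- as.integer(vertex_ids)
    stopifnot(length(vertex_ids) == nrow(vertices))
  }
  structure(list(label = label, vertices = vertices, region = region,
                 state = state, area = a, vertex_ids = vertex_ids),
            class = "cell_polygon")
}

#' @export
print.cell_polygon <- function(x, ...) {
  cat(sprintf("<cell %d: %s/%s, %d vertices, %.2f um^2>\n",
              x$label, x$region, x$state, nrow(x$vertices), x$area))
  invisible(x)
}

#' Construct a tissue snapshot (all cells at one time point)
#'
#' @param time_dai time in days after organ initiation.
#' @param cells list of [cell_polygon()] objects with unique labels.
#' @param adjacency two-column integer matrix of unordered adjacent label
#'   pairs; derived from shared vertex ids when `NULL` and ids are present.
#' @return object of class `tissue_snapshot`.
#' @export
tissue_snapshot <- function(time_dai, cells, adjacency = NULL) {
  stopifnot(is.numeric(time_dai), length(time_dai) == 1L)
  if (length(cells) == 0L) stop("empty snapshot")
  labs <- vapply(cells, function(c) c$label, integer(1))
  if (anyDuplicated(labs)) stop("duplicate cell labels: ",
                                paste(unique(labs[duplicated(labs)]), collapse = ", "))
  names(cells) <- as.character(labs)
  if (is.null(adjacency)) {
    if (all(vapply(cells, function(c) !is.null(c$vertex_ids), logical(1)))) {
      adjacency <- .adjacency_from_ids(cells)
    } else {
      adjacency <- matrix(integer(0), 0, 2)
    }
  } else {
    adjacency <- .canon_adjacency(adjacency)
    bad <- setdiff(unique(as.vector(adjacency)), labs)
    if (length(bad)) stop("adjacency references unknown labels: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(time_dai = as.numeric(time_dai), cells = cells,
                 adjacency = adjacency),
            class = "tissue_snapshot")
}

# canonical form: each pair (min,max), sorted, unique
.canon_adjacency <- function(adj) {
  adj <- matrix(as.integer(as.matrix(adj)), ncol = 2)
  adj <- adj[adj[, 1] != adj[, 2], , drop = FALSE]
  adj <- cbind(pmin(adj[, 1], adj[, 2]), pmax(adj[, 1], adj[, 2]))
  adj <- unique(adj)
  adj[order(adj[, 1], adj[, 2]), , drop = FALSE]
}

# adjacency from shared edges: two cells are adjacent iff they share an
# edge (two vertex ids consecutive in at least one of the two boundaries)
.adjacency_from_ids <- function(cells) {
  ekeys <- character(0); ecell <- integer(0)
  for (cl in cells) {
    ids <- cl$vertex_ids
    n <- length(ids)
    j <- c(2:n, 1L)
    ekeys <- c(ekeys, paste(pmin(ids, ids[j]), pmax(ids, ids[j])))
    ecell <- c(ecell, rep(cl$label, n))
  }
  sp <- split(ecell, ekeys)
  prs <- sp[lengths(sp) == 2L]
  if (!length(prs)) return(matrix(integer(0), 0, 2))
  m <- do.call(rbind, prs)
  .canon_adjacency(m)
}

#' @export
print.tissue_snapshot <- function(x, ...) {
  cat(sprintf("<tissue snapshot: t = %g DAI, %d cells, %d adjacencies>\n",
              x$time_dai, length(x$cells), nrow(x$adjacency)))
  invisible(x)
}

#' Cell labels of a snapshot
#' @param snapshot a [tissue_snapshot()].
#' @return integer vector.
#' @export
snapshot_labels <- function(snapshot)
  as.integer(vapply(snapshot$cells, `[[`, integer(1), "label"))

#' Per-cell areas of a snapshot
#' @param snapshot a [tissue_snapshot()].
#' @return named numeric vector (µm²), names are labels.
#' @export
snapshot_areas <- function(snapshot) {
  a <- vapply(snapshot$cells, `[[`, numeric(1), "area")
  names(a) <- names(snapshot$cells)
  a
}

#' Per-cell centroids of a snapshot
#' @param snapshot a [tissue_snapshot()].
#' @return n x 2 matrix with labels as rownames.
#' @export
snapshot_centroids <- function(snapshot) {
  m <- t(vapply(snapshot$cells, function(c) poly_centroid(c$vertices),
                numeric(2)))
  rownames(m) <- names(snapshot$cells)
  m
}

#' Construct a child-to-parent lineage map between two time points
#'
#' @param t0,t1 interval endpoints in days, `t1 > t0`.
#' @param parent_of named integer vector: names are child labels at `t1`,
#'   values are parent labels at `t0`.
#' @return object of class `lineage_map`.
#' @export
lineage_map <- function(t0, t1, parent_of) {
  stopifnot(is.numeric(t0), is.numeric(t1))
  if (!(t1 > t0)) stop("lineage interval must have t1 > t0")
  parent_of <- stats::setNames(as.integer(parent_of), names(parent_of))
  if (is.null(names(parent_of)) || any(names(parent_of) == ""))
    stop("parent_of must be a named vector (names = child labels)")
  if (anyDuplicated(names(parent_of)))
    stop("child labels must be unique in a lineage map")
  structure(list(t0 = as.numeric(t0), t1 = as.numeric(t1),
                 parent_of = parent_of),
            class = "lineage_map")
}

#' @export
print.lineage_map <- function(x, ...) {
  cat(sprintf("<lineage map %g -> %g DAI: %d children, %d parents>\n",
              x$t0, x$t1, length(x$parent_of), length(unique(x$parent_of))))
  invisible(x)
}

#' Validate a snapshot/lineage series
#'
#' Checks label uniqueness, adjacency symmetry and label coverage,
#' per-region connectivity (warning only), interval alignment, orphan
#' children (parent label absent at t0) and vanished parents (t0 cells with
#' no children, i.e. cells that left the imaged region; non-fatal, they are
#' excluded from growth maps downstream).
#'
#' @param snapshots list of [tissue_snapshot()] sorted by time.
#' @param lineages list of [lineage_map()], one per consecutive snapshot pair.
#' @return object of class `validation_report`: list with `fatal`,
#'   `warnings`, `vanished` (per-interval label lists) and `accepted`.
#' @export
validate_series <- function(snapshots, lineages) {
  fatal <- character(0); warns <- character(0)
  vanished <- vector("list", length(lineages))
  if (length(snapshots) == 0L) fatal <- c(fatal, "empty series")
  times <- vapply(snapshots, `[[`, numeric(1), "time_dai")
  if (is.unsorted(times, strictly = TRUE))
    fatal <- c(fatal, "snapshots not strictly sorted by time")
  if (length(lineages) != max(length(snapshots) - 1L, 0L))
    fatal <- c(fatal, sprintf("expected %d lineage maps, got %d",
                              max(length(snapshots) - 1L, 0L), length(lineages)))
  for (s in snapshots) {
    if (length(s$cells) == 0L)
      fatal <- c(fatal, sprintf("empty snapshot at t=%g", s$time_dai))
    labs <- snapshot_labels(s)
    if (nrow(s$adjacency)) {
      bad <- setdiff(unique(as.vector(s$adjacency)), labs)
      if (length(bad))
        fatal <- c(fatal, sprintf("t=%g: adjacency references unknown labels %s",
                                  s$time_dai, paste(bad, collapse = ",")))
    }
    # region-restricted connectivity: disconnection is only a warning
    for (rg in setdiff(unique(vapply(s$cells, `[[`, character(1), "region")),
                       "none")) {
      rl <- labs[vapply(s$cells, `[[`, character(1), "region") == rg]
      if (length(rl) < 2L || !nrow(s$adjacency)) next
      keep <- s$adjacency[, 1] %in% rl & s$adjacency[, 2] %in% rl
      g <- igraph::graph_from_edgelist(
        matrix(as.character(s$adjacency[keep, , drop = FALSE]), ncol = 2),
        directed = FALSE)
      g <- g + igraph::vertices(setdiff(as.character(rl),
                                        igraph::V(g)$name))
      if (igraph::components(g)$no > 1L)
        warns <- c(warns, sprintf("t=%g: region '%s' is disconnected",
                                  s$time_dai, rg))
    }
  }
  if (!length(fatal)) {
    for (i in seq_along(lineages)) {
      lm <- lineages[[i]]
      s0 <- snapshots[[i]]; s1 <- snapshots[[i + 1L]]
      if (abs(lm$t0 - s0$time_dai) > 1e-9 || abs(lm$t1 - s1$time_dai) > 1e-9) {
        fatal <- c(fatal, sprintf(
          "lineage %d interval (%g,%g) does not match snapshots (%g,%g)",
          i, lm$t0, lm$t1, s0$time_dai, s1$time_dai))
        next
      }
      l0 <- snapshot_labels(s0); l1 <- snapshot_labels(s1)
      kids <- as.integer(names(lm$parent_of))
      unknown_child <- setdiff(kids, l1)
      if (length(unknown_child))
        fatal <- c(fatal, sprintf("interval %g-%g: unknown child %s",
                                  lm$t0, lm$t1,
                                  paste(unknown_child, collapse = ",")))
      orphan <- setdiff(l1, kids)
      if (length(orphan))
        warns <- c(warns, sprintf("interval %g-%g: orphan children (no parent): %s",
                                  lm$t0, lm$t1, paste(orphan, collapse = ",")))
      unknown_parent <- setdiff(unique(lm$parent_of), l0)
      if (length(unknown_parent))
        fatal <- c(fatal, sprintf("interval %g-%g: parent %s not in t0 snapshot",
                                  lm$t0, lm$t1,
                                  paste(unknown_parent, collapse = ",")))
      van <- setdiff(l0, unique(lm$parent_of))
      vanished[[i]] <- van
      if (length(van))
        warns <- c(warns, sprintf("interval %g-%g: vanished parents (no children): %s",
                                  lm$t0, lm$t1, paste(van, collapse = ",")))
    }
  }
  structure(list(fatal = fatal, warnings = warns, vanished = vanished,
                 accepted = length(fatal) == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation: %s; %d fatal, %d warnings>\n",
              if (x$accepted) "ACCEPTED" else "REJECTED",
              length(x$fatal), length(x$warnings)))
  for (f in x$fatal) cat("  FATAL:", f, "\n")
  for (w in x$warnings) cat("  warn :", w, "\n")
  invisible(x)
}
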