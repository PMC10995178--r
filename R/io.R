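# File formats: JSON cell-outline snapshots, PLY with a per-face integer
# cell_label attribute, lineage CSV with an interval header comment, and
# JSON configs. All round-trips are lossless (coordinates written with 17
# significant digits).

#' Write a tissue snapshot to a JSON cell-outline file
#'
#' One record per cell: label, vertex list (µm), region, state, and vertex
#' ids when present; adjacency stored as label pairs.
#'
#' @param snapshot a [tissue_snapshot()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(snapshot, path) {
  cells <- lapply(snapshot$cells, function(c) {
    rec <- list(label = c$label, vertices = c$vertices,
                region = c$region, state = c$state)
    if (!is.null(c$vertex_ids)) rec$vertex_ids <- c$vertex_ids
    rec
  })
  obj <- list(format = "organtrace-snapshot", version = 1L,
              time_dai = snapshot$time_dai,
              cells = unname(cells),
              adjacency = snapshot$adjacency)
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                           matrix = "rowmajor")
  writeLines(json, path)
  invisible(path)
}

#' Read a tissue snapshot from a JSON cell-outline file
#'
#' @param path file produced by [write_snapshot()] (schema
#'   `organtrace-snapshot`).
#' @return a [tissue_snapshot()].
#' @export
read_snapshot <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  if (is.null(obj$format) || obj$format != "organtrace-snapshot")
    stop("not an organtrace snapshot file: ", path)
  cells <- lapply(seq_along(obj$cells), function(i) {
    rec <- obj$cells[[i]]
    if (is.null(rec$label) || is.null(rec$vertices))
      stop("malformed cell record #", i, " in ", path)
    cell_polygon(rec$label, matrix(unlist(rec$vertices), ncol = 2,
                                   byrow = !is.matrix(rec$vertices)),
                 region = rec$region %||% "none",
                 state = rec$state %||% "proliferative",
                 vertex_ids = rec$vertex_ids)
  })
  adj <- obj$adjacency
  if (!is.null(adj) && length(adj))
    adj <- matrix(as.integer(unlist(adj)), ncol = 2,
                  byrow = !is.matrix(adj))
  else adj <- NULL
  tissue_snapshot(obj$time_dai, cells, adjacency = adj)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a lineage map to CSV
#'
#' Two columns (child, parent) preceded by `# t0=` / `# t1=` header
#' comments.
#'
#' @param lineage a [lineage_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lineage <- function(lineage, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# t0=%.10g", lineage$t0),
               sprintf("# t1=%.10g", lineage$t1),
               "child,parent"), con)
  writeLines(sprintf("%s,%d", names(lineage$parent_of),
                     unname(lineage$parent_of)), con)
  invisible(path)
}

#' Read a lineage map from CSV
#' @param path file produced by [write_lineage()].
#' @return a [lineage_map()].
#' @export
read_lineage <- function(path) {
  hdr <- readLines(path, n = 2L)
  t0 <- as.numeric(sub("# t0=", "", hdr[1], fixed = TRUE))
  t1 <- as.numeric(sub("# t1=", "", hdr[2], fixed = TRUE))
  if (is.na(t0) || is.na(t1)) stop("missing t0/t1 header comments in ", path)
  df <- utils::read.csv(path, comment.char = "#")
  lineage_map(t0, t1, stats::setNames(as.integer(df$parent),
                                      as.character(df$child)))
}

# --- PLY ----------------------------------------------------------------

#' Write a snapshot as ASCII PLY with per-face cell labels
#'
#' Each cell polygon becomes one face; faces carry an integer `cell_label`
#' property. Vertex ids become PLY vertex indices, so shared walls stay
#' shared.
#'
#' @param snapshot a [tissue_snapshot()] whose cells carry vertex ids.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ply_snapshot <- function(snapshot, path) {
  cells <- snapshot$cells
  if (!all(vapply(cells, function(c) !is.null(c$vertex_ids), logical(1))))
    stop("PLY export needs vertex ids on every cell")
  ids <- sort(unique(unlist(lapply(cells, `[[`, "vertex_ids"))))
  remap <- stats::setNames(seq_along(ids) - 1L, as.character(ids))
  V <- matrix(NA_real_, length(ids), 2)
  for (c in cells) V[remap[as.character(c$vertex_ids)] + 1L, ] <- c$vertices
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("comment time_dai %.10g", snapshot$time_dai),
               sprintf("element vertex %d", nrow(V)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", length(cells)),
               "property list uchar int vertex_indices",
               "property int cell_label",
               "end_header"), con)
  writeLines(sprintf("%.17g %.17g 0", V[, 1], V[, 2]), con)
  for (c in cells) {
    idx <- remap[as.character(c$vertex_ids)]
    writeLines(paste(length(idx), paste(idx, collapse = " "), c$label), con)
  }
  invisible(path)
}

#' Read a snapshot from ASCII PLY with per-face cell labels
#'
#' Faces sharing a `cell_label` are merged: the cell outline is the outer
#' boundary of their union (edges used exactly once).
#'
#' @param path ASCII PLY file with a face property `cell_label`.
#' @param time_dai snapshot time override; default taken from a
#'   `comment time_dai` header line, else 0.
#' @return a [tissue_snapshot()].
#' @export
read_ply_snapshot <- function(path, time_dai = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3L || lines[1] != "ply") stop("not a PLY file: ", path)
  endh <- match("end_header", lines)
  if (is.na(endh)) stop("PLY header not terminated")
  hdr <- lines[seq_len(endh)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", hdr,
                                                   value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", hdr,
                                                 value = TRUE)))
  if (!length(nv) || !length(nf)) stop("PLY lacks vertex/face elements")
  face_props <- hdr[seq(match(sprintf("element face %d", nf), hdr) + 1L,
                        endh - 1L)]
  if (!any(grepl("cell_label", face_props)))
    stop("PLY face element lacks the cell_label property")
  if (is.null(time_dai)) {
    tl <- grep("^comment time_dai ", hdr, value = TRUE)
    time_dai <- if (length(tl)) as.numeric(sub("comment time_dai ", "",
                                               tl[1])) else 0
  }
  vlines <- lines[endh + seq_len(nv)]
  V <- do.call(rbind, lapply(strsplit(vlines, " +"),
                             function(z) as.numeric(z[1:2])))
  flines <- lines[endh + nv + seq_len(nf)]
  faces <- lapply(strsplit(flines, " +"), as.numeric)
  labs <- vapply(faces, function(f) as.integer(f[length(f)]), integer(1))
  polys <- lapply(faces, function(f) as.integer(f[2:(1 + f[1])]) + 1L)
  cells <- lapply(unique(labs), function(lb) {
    fs <- polys[labs == lb]
    fake <- lapply(fs, function(idx)
      list(vertex_ids = idx, vertices = V[idx, , drop = FALSE]))
    ub <- daughters_union_boundary(fake)
    if (is.null(ub)) stop("faces of cell_label ", lb,
                          " do not merge into a simple outline")
    cell_polygon(lb, ub$xy, vertex_ids = ub$ids)
  })
  tissue_snapshot(time_dai, cells)
}

# --- config -------------------------------------------------------------

#' Read / write a pipeline configuration (JSON)
#'
#' @param path JSON file.
#' @return named list.
#' @export
read_config <- function(path)
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)

#' @rdname read_config
#' @param config named list (must round-trip losslessly).
#' @export
write_config <- function(config, path) {
  writeLines(jsonlite::toJSON(config, digits = I(17), auto_unbox = TRUE,
                              null = "null", pretty = TRUE), path)
  invisible(path)
}

# md5 of the serialized config (tools::md5sum; no extra dependency)
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_config(config, tf)
  unname(tools::md5sum(tf))
}

# CSV with provenance header comments
write_csv_commented <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste("#", cm), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
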