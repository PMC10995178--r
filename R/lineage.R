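# Lineage algebra: composition of child->parent maps across consecutive
# intervals, reverse lineage tracing of late region identities back to
# early sectors, and per-parent proliferation counts.

#' Compose consecutive lineage maps
#'
#' Chains child-to-parent relations across intervals so that each cell at
#' the final time maps to its ancestor at the initial time. Children whose
#' chain breaks (a missing parent at some intermediate time) are omitted
#' and reported in the `broken` attribute.
#'
#' @param lineages list of [lineage_map()] whose intervals chain
#'   (each `t1` equals the next map's `t0`).
#' @return a [lineage_map()] spanning (first `t0`, last `t1`), with
#'   attribute `broken`: child labels dropped because their chain broke.
#' @export
compose_lineages <- function(lineages) {
  if (!length(lineages)) stop("no lineage maps to compose")
  if (length(lineages) == 1L) {
    out <- lineages[[1L]]
    attr(out, "broken") <- integer(0)
    return(out)
  }
  for (i in seq_len(length(lineages) - 1L)) {
    if (abs(lineages[[i]]$t1 - lineages[[i + 1L]]$t0) > 1e-9)
      stop(sprintf("lineage maps do not chain: map %d ends at %g, map %d starts at %g",
                   i, lineages[[i]]$t1, i + 1L, lineages[[i + 1L]]$t0))
  }
  acc <- lineages[[1L]]$parent_of          # child at t_k -> ancestor at t_0
  for (i in 2L:length(lineages)) {
    nxt <- lineages[[i]]$parent_of         # child at t_{k+1} -> parent at t_k
    anc <- acc[as.character(nxt)]          # ancestor (NA where chain breaks)
    names(anc) <- names(nxt)
    acc <- anc[!is.na(anc)]
  }
  out <- lineage_map(lineages[[1L]]$t0, lineages[[length(lineages)]]$t1, acc)
  # broken = children of the last interval that did not survive composition
  attr(out, "broken") <- as.integer(setdiff(
    names(lineages[[length(lineages)]]$parent_of), names(acc)))
  out
}

#' Reverse lineage tracing: late regions to early sectors
#'
#' Assigns to every ancestor cell at the first time the region identity of
#' its descendants at the late time. Ancestors whose descendants disagree
#' are tagged `"mixed"` and reported: exclusive sectors are the expected
#' outcome, so mixing is surfaced as a QC signal rather than resolved
#' silently.
#'
#' @param late_assignment named character vector: late-time cell label ->
#'   region tag.
#' @param lineages list of [lineage_map()] chaining from the early to the
#'   late time (or an already-composed single map).
#' @param late_snapshot optional [tissue_snapshot()] at the late time; when
#'   supplied, labels in `late_assignment` must exist in it.
#' @return named character vector: early-time label -> region (or
#'   `"mixed"`), with attribute `mixed` listing the mixed ancestors.
#' @export
reverse_trace <- function(late_assignment, lineages, late_snapshot = NULL) {
  if (inherits(lineages, "lineage_map")) lineages <- list(lineages)
  comp <- compose_lineages(lineages)
  if (!is.null(late_snapshot)) {
    bad <- setdiff(names(late_assignment),
                   as.character(snapshot_labels(late_snapshot)))
    if (length(bad))
      stop("late_assignment labels absent from late snapshot: ",
           paste(bad, collapse = ", "))
  }
  kids <- intersect(names(late_assignment), names(comp$parent_of))
  anc <- comp$parent_of[kids]
  by_anc <- split(unname(late_assignment[kids]), anc)
  out <- vapply(by_anc, function(rs) {
    rs <- unique(rs)
    if (length(rs) == 1L) rs else "mixed"
  }, character(1))
  attr(out, "mixed") <- names(out)[out == "mixed"]
  out
}

#' Forward-propagate an ancestor sector map to descendants
#'
#' Inverse of [reverse_trace()] for non-mixed sectors: each late cell takes
#' its ancestor's tag.
#'
#' @param sectors named character vector: early label -> tag.
#' @param lineages list of [lineage_map()] (or one composed map).
#' @return named character vector: late label -> tag (cells with ancestors
#'   outside `sectors` are omitted).
#' @export
forward_propagate <- function(sectors, lineages) {
  if (inherits(lineages, "lineage_map")) lineages <- list(lineages)
  comp <- compose_lineages(lineages)
  anc <- as.character(comp$parent_of)
  keep <- anc %in% names(sectors)
  stats::setNames(unname(sectors[anc[keep]]), names(comp$parent_of)[keep])
}

#' Daughter count of a parent cell
#'
#' @param lineage a [lineage_map()].
#' @param parent parent label at `t0`.
#' @return integer daughter count; 0 with attribute `vanished = TRUE` for a
#'   parent absent from the map's image (cell left the imaged region).
#' @export
proliferation <- function(lineage, parent) {
  n <- sum(lineage$parent_of == as.integer(parent))
  if (n == 0L) attr(n, "vanished") <- TRUE
  n
}
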