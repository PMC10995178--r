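# Gradient readouts: binned profiles versus normalized distance, rank
# correlation + permutation statistics for gradient presence, dominant-axis
# classification, onset-time detection, stomata distributions and
# cell-size profiles.

#' Binned profile of a per-cell measure versus normalized distance
#'
#' Equal-width bins on `[0, 1]`; per bin the mean, SD and n of the values.
#' Cells without a defined normalized distance are excluded and counted.
#'
#' @param values named numeric vector of per-cell values (names = labels).
#' @param field a normalized [cell_distance()] field.
#' @param n_bins number of bins (>= 2).
#' @return object of class `gradient_profile`: data.frame with `bin_lo`,
#'   `bin_hi`, `mean`, `sd`, `n`, `single` (flag for n = 1 bins, where SD
#'   is reported as 0); attributes `n_cells` (admitted) and `n_excluded`.
#' @export
profile_gradient <- function(values, field, n_bins = 10L) {
  if (is.null(field$normalized)) stop("field is not normalized; call normalize_distance() first")
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 2L)
  common <- intersect(names(values), names(field$normalized))
  common <- common[!is.na(field$normalized[common]) & !is.na(values[common])]
  if (!length(common)) stop("no overlapping labels between values and field")
  x <- field$normalized[common]
  y <- values[common]
  bin <- pmin(pmax(findInterval(x, seq(0, 1, length.out = n_bins + 1L),
                                rightmost.closed = TRUE), 1L), n_bins)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  out <- data.frame(bin_lo = edges[-(n_bins + 1L)], bin_hi = edges[-1L],
                    mean = NA_real_, sd = NA_real_, n = 0L, single = FALSE)
  for (b in seq_len(n_bins)) {
    yy <- y[bin == b]
    out$n[b] <- length(yy)
    if (length(yy)) {
      out$mean[b] <- mean(yy)
      out$sd[b] <- if (length(yy) > 1L) stats::sd(yy) else 0
      out$single[b] <- length(yy) == 1L
    }
  }
  structure(out, class = c("gradient_profile", "data.frame"),
            n_cells = length(common),
            n_excluded = length(values) - length(common))
}

#' Gradient presence statistic: slope, rank correlation, permutation p
#'
#' Ordinary-least-squares slope of value versus normalized distance,
#' Spearman rank correlation, and a label-shuffling permutation p-value
#' `(1 + #\{|rho_perm| >= |rho_obs|\}) / (n_permutations + 1)`.
#'
#' @param values named numeric per-cell values.
#' @param field a normalized [cell_distance()] field.
#' @param n_permutations number of shuffles (default 999).
#' @param seed integer seed for the shuffles.
#' @return object of class `gradient_stat`: list with `slope`,
#'   `rank_correlation`, `permutation_p`, `n_cells`, `flag`.
#' @export
gradient_stat <- function(values, field, n_permutations = 999L, seed = 1L) {
  if (is.null(field$normalized)) stop("field is not normalized")
  common <- intersect(names(values), names(field$normalized))
  common <- common[!is.na(field$normalized[common]) & !is.na(values[common])]
  n <- length(common)
  if (n < 10L) stop("need >= 10 cells for a gradient statistic")
  x <- unname(field$normalized[common])
  y <- unname(values[common])
  if (stats::sd(y) == 0 || stats::sd(x) == 0) {
    return(structure(list(slope = 0, rank_correlation = 0,
                          permutation_p = 1, n_cells = n,
                          flag = "zero-variance"),
                     class = "gradient_stat"))
  }
  slope <- stats::cov(x, y) / stats::var(x)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  set.seed(seed)
  perm <- matrix(0, n, n_permutations)
  for (k in seq_len(n_permutations)) perm[, k] <- sample(ry)
  rho_perm <- as.vector(stats::cor(rx, perm))
  p <- (1 + sum(abs(rho_perm) >= abs(rho))) / (n_permutations + 1)
  structure(list(slope = slope, rank_correlation = rho,
                 permutation_p = p, n_cells = n, flag = NULL),
            class = "gradient_stat")
}

#' @export
print.gradient_stat <- function(x, ...) {
  cat(sprintf("<gradient stat: slope %.4g, rho %.3f, p %.4g, n %d%s>\n",
              x$slope, x$rank_correlation, x$permutation_p, x$n_cells,
              if (!is.null(x$flag)) paste0(", ", x$flag) else ""))
  invisible(x)
}

#' Dominant gradient axis of a per-cell measure
#'
#' Compares the gradient statistic along the longitudinal (u) and
#' mediolateral (v) distance fields: the axis with the larger absolute rank
#' correlation wins if its permutation p is below `alpha` and its |rho|
#' exceeds the other's by at least `delta`; otherwise `"none"`.
#'
#' @param values named numeric per-cell values.
#' @param u_field,v_field normalized [cell_distance()] fields along the two
#'   axes.
#' @param alpha significance level (default 0.05).
#' @param delta required |rho| margin (default 0.1).
#' @param n_permutations,seed passed to [gradient_stat()].
#' @return list: `axis` (`"longitudinal"`, `"mediolateral"`, `"none"`),
#'   `longitudinal`, `mediolateral` (the two [gradient_stat()]s).
#' @export
dominant_axis <- function(values, u_field, v_field, alpha = 0.05,
                          delta = 0.1, n_permutations = 999L, seed = 1L) {
  su <- gradient_stat(values, u_field, n_permutations, seed)
  sv <- gradient_stat(values, v_field, n_permutations, seed + 1L)
  au <- abs(su$rank_correlation); av <- abs(sv$rank_correlation)
  axis <- "none"
  if (au >= av && su$permutation_p < alpha && au - av >= delta)
    axis <- "longitudinal"
  if (av > au && sv$permutation_p < alpha && av - au >= delta)
    axis <- "mediolateral"
  list(axis = axis, longitudinal = su, mediolateral = sv)
}

#' Onset interval of a sustained gradient
#'
#' First interval at which the permutation p stays below `alpha` for
#' `min_consecutive` consecutive intervals with a consistent sign of the
#' rank correlation.
#'
#' @param stats_by_interval list of [gradient_stat()]s in interval order.
#' @param alpha significance level (default 0.05).
#' @param min_consecutive required run length (default 2).
#' @return 1-based index of the onset interval, or `NA` if no sustained
#'   gradient is found (or the series is empty).
#' @export
onset_time <- function(stats_by_interval, alpha = 0.05,
                       min_consecutive = 2L) {
  m <- length(stats_by_interval)
  if (!m) return(NA_integer_)
  sig <- vapply(stats_by_interval,
                function(s) s$permutation_p < alpha, logical(1))
  sgn <- vapply(stats_by_interval,
                function(s) sign(s$rank_correlation), numeric(1))
  for (i in seq_len(m - min_consecutive + 1L)) {
    idx <- i:(i + min_consecutive - 1L)
    if (all(sig[idx]) && length(unique(sgn[idx])) == 1L && sgn[i] != 0)
      return(i)
  }
  NA_integer_
}

#' Stomata distribution versus normalized distance
#'
#' Counts stoma-state cells per normalized-distance bin, once from a basal
#' reference set and once from a medial reference set.
#'
#' @param snapshot a [tissue_snapshot()] with state tags.
#' @param base_reference labels of the basal reference cells.
#' @param medial_reference labels of the medial reference cells.
#' @param n_bins number of bins (default 10).
#' @param domain_labels optional normalization domain (default: all cells).
#' @return list: `from_base`, `from_medial` (data.frames `bin_lo`,
#'   `bin_hi`, `count`), `n_stomata`, `flag` (`"no stomata"` when empty).
#' @export
stomata_distribution <- function(snapshot, base_reference, medial_reference,
                                 n_bins = 10L, domain_labels = NULL) {
  states <- vapply(snapshot$cells, `[[`, character(1), "state")
  stoma <- names(states)[states == "stoma"]
  hist1 <- function(ref) {
    f <- normalize_distance(cell_distance(snapshot, ref), domain_labels)
    edges <- seq(0, 1, length.out = n_bins + 1L)
    cnt <- integer(n_bins)
    if (length(stoma)) {
      x <- f$normalized[stoma]
      x <- x[!is.na(x)]
      b <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
                n_bins)
      tb <- table(factor(b, levels = seq_len(n_bins)))
      cnt <- as.integer(tb)
    }
    data.frame(bin_lo = edges[-(n_bins + 1L)], bin_hi = edges[-1L],
               count = cnt)
  }
  list(from_base = hist1(base_reference),
       from_medial = hist1(medial_reference),
       n_stomata = length(stoma),
       flag = if (!length(stoma)) "no stomata" else NULL)
}

#' Cell-size profile versus normalized distance
#'
#' [profile_gradient()] with values = cell areas (µm²); cell size is the
#' differentiation readout (differentiated cells stop dividing and keep
#' enlarging).
#'
#' @param snapshot a [tissue_snapshot()].
#' @param field a normalized [cell_distance()] field.
#' @param n_bins number of bins (default 10).
#' @return a `gradient_profile`.
#' @export
cell_size_profile <- function(snapshot, field, n_bins = 10L)
  profile_gradient(snapshot_areas(snapshot), field, n_bins)
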