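# End-to-end pipeline driver: simulate (or load) -> validate -> compose
# lineages -> growth maps -> distance fields -> gradient statistics and
# onsets -> stomata distributions, with every output CSV carrying the
# config hash and the seed.

#' Select cell labels of a snapshot by a config selector
#'
#' Selectors: `"all"`; `"region:<tag>"`; `"state:<tag>"`;
#' `"ymin:<q>"` / `"ymax:<q>"` (cells whose centroid y is below/above the
#' q-quantile of the organ's y extent); `"xband:<f>"` (cells within
#' fraction f of the medial line x = 0); or an integer vector of labels.
#'
#' @param snapshot a [tissue_snapshot()].
#' @param selector selector string or integer labels.
#' @return integer label vector.
#' @export
select_labels <- function(snapshot, selector) {
  if (is.numeric(selector)) return(as.integer(selector))
  labs <- snapshot_labels(snapshot)
  ctr <- snapshot_centroids(snapshot)
  if (identical(selector, "all")) return(labs)
  if (startsWith(selector, "region:")) {
    tag <- sub("region:", "", selector, fixed = TRUE)
    rg <- vapply(snapshot$cells, `[[`, character(1), "region")
    return(labs[rg == tag])
  }
  if (startsWith(selector, "state:")) {
    tag <- sub("state:", "", selector, fixed = TRUE)
    st <- vapply(snapshot$cells, `[[`, character(1), "state")
    return(labs[st == tag])
  }
  if (startsWith(selector, "ymin:")) {
    q <- as.numeric(sub("ymin:", "", selector, fixed = TRUE))
    yr <- range(ctr[, 2])
    return(labs[ctr[, 2] <= yr[1] + q * diff(yr)])
  }
  if (startsWith(selector, "ymax:")) {
    q <- as.numeric(sub("ymax:", "", selector, fixed = TRUE))
    yr <- range(ctr[, 2])
    return(labs[ctr[, 2] >= yr[1] + q * diff(yr)])
  }
  if (startsWith(selector, "xband:")) {
    f <- as.numeric(sub("xband:", "", selector, fixed = TRUE))
    xmax <- max(abs(ctr[, 1]))
    return(labs[abs(ctr[, 1]) <= f * xmax])
  }
  stop("unknown selector: ", selector)
}

#' Default pipeline configuration
#'
#' @param scenario_name preset for the simulation stage.
#' @param seed master seed.
#' @param out_dir output directory.
#' @return named config list (see [run_pipeline()]).
#' @export
default_config <- function(scenario_name = "gynoecium", seed = 1L,
                           out_dir = tempfile("organtrace_run_")) {
  list(scenario = scenario_name, overrides = list(), seed = as.integer(seed),
       out_dir = out_dir,
       group = "all",                 # cells admitted to gradient stats
       base_source = "ymin:0.05",     # longitudinal distance sources
       tip_source = "ymax:0.95",
       medial_source = "xband:0.15",  # mediolateral distance sources
       longitudinal_from = "base",    # "base" or "tip"
       n_bins = 10L, n_permutations = 999L,
       alpha = 0.05, delta = 0.1, min_consecutive = 2L,
       write_png = FALSE)
}

#' Run the full analysis pipeline
#'
#' Simulates the configured scenario (or loads `snapshot_paths` /
#' `lineage_paths`), validates the series, composes lineages, computes
#' growth maps per interval, builds longitudinal and mediolateral distance
#' fields, runs gradient statistics, dominant-axis classification and
#' onset detection, and computes the final stomata distribution. All
#' tables are written to `config$out_dir` as CSV with the config hash and
#' seed in header comments, together with a JSON run manifest.
#'
#' @param config list as produced by [default_config()].
#' @return the output bundle, invisibly: list with `snapshots`,
#'   `lineages`, `growth`, `axis_calls`, `onsets`, `stomata`, `manifest`.
#' @export
run_pipeline <- function(config) {
  t_start <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(fmt, ...))
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    logf("stage %s ...", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  # the hash identifies the analysis, not the output location
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  hdr <- c(paste("config_hash:", hash), paste("seed:", config$seed))

  # --- simulate or load -------------------------------------------------
  if (!is.null(config$snapshot_paths)) {
    sim <- stage("load", {
      snaps <- lapply(config$snapshot_paths, read_snapshot)
      lins <- lapply(config$lineage_paths, read_lineage)
      list(snapshots = snaps, lineages = lins, ground_truth = NULL,
           config = config)
    })
  } else {
    sim <- stage("simulate",
                 scenario(config$scenario, config$overrides %||% list(),
                          seed = config$seed))
  }
  snaps <- sim$snapshots; lins <- sim$lineages
  logf("series: %d snapshots, %d..%d cells",
       length(snaps), length(snaps[[1]]$cells),
       length(snaps[[length(snaps)]]$cells))

  rep <- stage("validate", validate_series(snaps, lins))
  if (!rep$accepted)
    stop("pipeline stage 'validate' failed: ",
         paste(rep$fatal, collapse = "; "), call. = FALSE)

  composed <- stage("compose", compose_lineages(lins))

  # --- per-interval growth + gradients ---------------------------------
  growth <- list(); axis_calls <- list()
  ustats <- list(); vstats <- list()
  for (k in seq_along(lins)) {
    s0 <- snaps[[k]]; s1 <- snaps[[k + 1L]]
    gm <- stage(sprintf("growth %g-%g", lins[[k]]$t0, lins[[k]]$t1),
                compute_growth_map(s0, s1, lins[[k]]))
    growth[[k]] <- gm
    grp <- intersect(select_labels(s1, config$group),
                     gm$heat_map$label)
    vals <- stats::setNames(gm$heat_map$area_expansion_pct,
                            as.character(gm$heat_map$label))[as.character(grp)]
    src_long <- select_labels(
      s1, if (identical(config$longitudinal_from, "tip"))
        config$tip_source else config$base_source)
    src_med <- select_labels(s1, config$medial_source)
    ac <- stage(sprintf("gradients %g-%g", lins[[k]]$t0, lins[[k]]$t1), {
      uf <- normalize_distance(cell_distance(s1, src_long), grp)
      vf <- normalize_distance(cell_distance(s1, src_med), grp)
      dominant_axis(vals, uf, vf, alpha = config$alpha,
                    delta = config$delta,
                    n_permutations = config$n_permutations,
                    seed = config$seed + 101L * k)
    })
    axis_calls[[k]] <- ac
    ustats[[k]] <- ac$longitudinal
    vstats[[k]] <- ac$mediolateral
  }

  onsets <- list(
    longitudinal = onset_time(ustats, config$alpha, config$min_consecutive),
    mediolateral = onset_time(vstats, config$alpha, config$min_consecutive))

  sN <- snaps[[length(snaps)]]
  stomata <- stage("stomata", stomata_distribution(
    sN, select_labels(sN, config$base_source),
    select_labels(sN, config$medial_source), n_bins = config$n_bins))

  # --- outputs ----------------------------------------------------------
  stage("write", {
    recs <- do.call(rbind, lapply(growth, `[[`, "records"))
    write_csv_commented(recs, file.path(config$out_dir, "growth_records.csv"),
                        hdr)
    hms <- do.call(rbind, lapply(seq_along(growth), function(k)
      cbind(interval = k, growth[[k]]$heat_map)))
    write_csv_commented(hms, file.path(config$out_dir, "heat_maps.csv"), hdr)
    stat_row <- function(s, axis, k)
      data.frame(interval = k, axis = axis, slope = s$slope,
                 rank_correlation = s$rank_correlation,
                 permutation_p = s$permutation_p, n_cells = s$n_cells)
    stats_df <- do.call(rbind, c(
      lapply(seq_along(ustats), function(k)
        stat_row(ustats[[k]], "longitudinal", k)),
      lapply(seq_along(vstats), function(k)
        stat_row(vstats[[k]], "mediolateral", k))))
    stats_df$dominant <- vapply(axis_calls, `[[`, character(1),
                                "axis")[stats_df$interval]
    write_csv_commented(stats_df,
                        file.path(config$out_dir, "gradient_stats.csv"), hdr)
    write_csv_commented(
      cbind(reference = "base", stomata$from_base),
      file.path(config$out_dir, "stomata_from_base.csv"), hdr)
    write_csv_commented(
      cbind(reference = "medial", stomata$from_medial),
      file.path(config$out_dir, "stomata_from_medial.csv"), hdr)
    comp_df <- data.frame(label = names(composed$parent_of),
                          ancestor = unname(composed$parent_of))
    write_csv_commented(comp_df,
                        file.path(config$out_dir, "composed_lineage.csv"),
                        hdr)
    if (!is.null(sim$ground_truth))
      write_csv_commented(sim$ground_truth,
                          file.path(config$out_dir, "ground_truth.csv"), hdr)
    if (isTRUE(config$write_png)) {
      for (k in seq_along(growth)) {
        vals <- stats::setNames(growth[[k]]$heat_map$area_expansion_pct,
                                growth[[k]]$heat_map$label)
        png_path <- file.path(config$out_dir,
                              sprintf("heatmap_interval_%02d.png", k))
        plot_heat_map(snaps[[k + 1L]], vals, png_path)
      }
    }
  })

  manifest <- list(config = config, config_hash = hash,
                   seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("organtrace")),
                   r_version = R.version.string,
                   n_snapshots = length(snaps),
                   onsets = onsets,
                   dominant_axis = vapply(axis_calls, `[[`, character(1),
                                          "axis"))
  write_config(manifest, file.path(config$out_dir, "manifest.json"))
  logf("done in %.1f s", as.numeric(difftime(Sys.time(), t_start, "secs")))
  invisible(list(snapshots = snaps, lineages = lins, growth = growth,
                 axis_calls = axis_calls, onsets = onsets,
                 stomata = stomata, ground_truth = sim$ground_truth,
                 manifest = manifest))
}

#' Render a per-cell heat map to a PNG
#'
#' Fills each cell polygon with a color mapped from `values` (labels must
#' match); the interval convention is the caller's (pass the T1 snapshot
#' for interval quantities).
#'
#' @param snapshot a [tissue_snapshot()].
#' @param values named numeric vector keyed by cell label.
#' @param path output PNG path.
#' @param palette color ramp (default viridis-like).
#' @return `path`, invisibly.
#' @export
plot_heat_map <- function(snapshot, values, path,
                          palette = grDevices::hcl.colors(64, "viridis")) {
  rng <- range(values, na.rm = TRUE)
  if (!is.finite(rng[1])) rng <- c(0, 1)
  grDevices::png(path, width = 800, height = 1000)
  on.exit(grDevices::dev.off())
  allv <- do.call(rbind, lapply(snapshot$cells, `[[`, "vertices"))
  plot(NA, xlim = range(allv[, 1]), ylim = range(allv[, 2]), asp = 1,
       xlab = "x (um)", ylab = "y (um)",
       main = sprintf("t = %g DAI", snapshot$time_dai))
  for (c in snapshot$cells) {
    v <- values[[as.character(c$label)]]
    col <- if (is.null(v) || is.na(v)) "grey90" else
      palette[1 + floor(63 * (v - rng[1]) / max(rng[2] - rng[1], 1e-12))]
    graphics::polygon(c$vertices[, 1], c$vertices[, 2], col = col,
                      border = "grey30", lwd = 0.3)
  }
  invisible(path)
}
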