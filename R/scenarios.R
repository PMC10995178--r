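# Scenario presets for the synthetic generator. Each preset states a world:
# an organ outline, a region layout, and spatially varying areal-rate,
# anisotropy and differentiation-onset fields in normalized organ
# coordinates (xn = x / current half-width in [-1, 1], mediolateral, 0 at
# the medial line; yn = y / current length in [0, 1], longitudinal, 0 at
# the base). Timings follow the gynoecium literature (mediolateral valve
# gradient active ~4-8 DAI, longitudinal style gradient from 9 DAI,
# valve differentiation from ~6 DAI laterally, style from 9 DAI at the
# tip); gradient magnitudes are free parameters of the generator and are
# reported in the returned config, not presented as measurements.

SCENARIO_NAMES <- c("gynoecium", "valveless", "sepal", "carpelized_sepal",
                    "split_mutant")

.preset_params <- function(name) {
  base <- list(
    r0 = 0.40,                # baseline areal rate, /day
    division_area_threshold = 240,  # µm²
    stomata_prob = 0.25,      # /day per differentiated cell
    enlargement = 1.10,       # rate multiplier past differentiation onset
    n_substeps = 10L)
  p <- switch(name,
    gynoecium = list(
      width = 60, length = 140, n_init = 70L,
      t_start = 3, t_end = 11,
      ey0 = 0.20,                     # longitudinal strain rate, /day
      replum_rate = 0.18, replum_halfwidth = 0.15,
      base_rate = 0.32, style_from = 0.82, base_to = 0.05,
      valve_ml_boost = 0.18,          # extra rate near the replum
      valve_ml_window = c(4, 8),      # DAI window of the mediolateral gradient
      style_tip_factor = 0.45,        # tip rate fraction once gradient active
      style_gradient_from = 9,        # DAI
      tau_valve = c(lateral = 6, medial = 10),  # onset, margin -> replum
      tau_style = c(tip = 9, base = 11.5),
      stomata_regions = "valve"),
    valveless = list(
      width = 50, length = 160, n_init = 80L,
      t_start = 4, t_end = 10,
      ey0 = 0.22,
      tau_long = c(tip = 7, base = 12),   # organ-wide basipetal onset
      tip_slow = 0.5, tip_slow_from = 7,
      stomata_regions = c("valve", "none")),
    sepal = list(
      width = 60, length = 120, n_init = 60L,
      t_start = 3, t_end = 8,
      ey0 = 0.22,
      tau_long = c(tip = 4, base = 9),
      tip_boost = 0.45,                  # growth declines away from the tip
      stomata_regions = c("valve", "none")),
    carpelized_sepal = list(
      width = 60, length = 120, n_init = 60L,
      t_start = 3, t_end = 9,
      ey0 = 0.18,
      medial_halfwidth = 0.2,
      tau_ml = c(center = 5, margin = 9),  # onset increases toward margin
      stomata_regions = c("valve", "none")),
    split_mutant = list(
      width = 60, length = 150, n_init = 70L,
      t_start = 4, t_end = 9,
      ey0 = 0.22,
      replum_halfwidth = 0.15,
      tau_distal = c(tip = 5, mid = 8),    # leaf-like basipetal, distal half
      tau_basal = c(lateral = 8, medial = 11),  # mediolateral, basal half
      stomata_regions = c("valve", "none")),
    stop("unknown scenario '", name, "'; presets: ",
         paste(SCENARIO_NAMES, collapse = ", "))
  )
  utils::modifyList(base, p)
}

# linear interpolation helper on a normalized coordinate in [0, 1]
.lerp <- function(z, from, to) from + (to - from) * pmin(pmax(z, 0), 1)

# Build the growth_field_spec + region assignment for a preset.
.preset_spec <- function(name, p) {
  geom <- new.env(parent = emptyenv())
  geom$W2 <- p$width / 2
  geom$L <- p$length
  update_geom <- function(verts) {
    geom$W2 <- max(abs(verts[, 1]))
    geom$L <- max(verts[, 2])
  }
  xn <- function(x) x / geom$W2
  yn <- function(y) pmin(pmax(y / geom$L, 0), 1)

  if (name == "gynoecium") {
    # rate blend zones sit INSIDE the replum/base strips and BELOW the
    # style boundary, so cells tagged "valve" always feel the pure valve
    # rate; the replum/base/style tagged cells absorb the transition
    ws <- function(v) sstep((v - (p$style_from - 0.08)) / 0.08)
    wb <- function(v) 1 - sstep((v - (p$base_to - 0.05)) / 0.05)
    wrep_raw <- function(u)
      1 - sstep((abs(u) - (p$replum_halfwidth - 0.12)) / 0.12)
    xhat <- function(u)                      # normalized distance from replum
      pmin(pmax((abs(u) - p$replum_halfwidth) /
                  (1 - p$replum_halfwidth), 0), 1)
    tipness <- function(v) pmin(pmax((v - p$style_from) / (1 - p$style_from),
                                     0), 1)
    style_slow <- function(v, t)
      1 - (1 - p$style_tip_factor) * tipness(v) *
        sstep((t - p$style_gradient_from) / 0.5)
    areal_rate <- function(x, y, t) {
      u <- xn(x); v <- yn(y)
      s <- ws(v); b <- wb(v) * (1 - s)
      rp <- wrep_raw(u) * (1 - s) * (1 - b)
      vv <- (1 - s) * (1 - b) * (1 - wrep_raw(u))
      wt <- sstep((t - p$valve_ml_window[1]) / 0.5) *
        (1 - sstep((t - p$valve_ml_window[2]) / 0.5))
      # taper the boost below the style so style cells never feel it
      wy <- 1 - sstep((v - 0.70) / 0.06)
      r_valve <- p$r0 + p$valve_ml_boost * (1 - xhat(u)) * wt * wy
      r_style <- p$r0 * style_slow(v, t)
      # replum growth only drops after the regions diverge (~4 DAI)
      r_rep <- p$r0 + (p$replum_rate - p$r0) * sstep((t - 4) / 1)
      s * r_style + b * p$base_rate + rp * r_rep + vv * r_valve
    }
    longitudinal_rate <- function(y, t) {
      v <- yn(y)
      s <- ws(v)
      (1 - s) * p$ey0 + s * p$ey0 * style_slow(v, t)
    }
    differentiation_onset <- function(x, y) {
      u <- xn(x); v <- yn(y)
      s <- ws(v); b <- wb(v) * (1 - s)
      rp <- wrep_raw(u) * (1 - s) * (1 - b)
      vv <- (1 - s) * (1 - b) * (1 - wrep_raw(u))
      tv <- .lerp(1 - xhat(u), p$tau_valve["lateral"], p$tau_valve["medial"])
      ts <- .lerp(1 - tipness(v), p$tau_style["tip"], p$tau_style["base"])
      s * ts + vv * tv + (rp + b) * 99
    }
    region_assign <- function(u, v) {
      out <- rep("valve", length(u))
      out[abs(u) < p$replum_halfwidth] <- "replum"
      out[v > p$style_from] <- "style"
      out[v < p$base_to] <- "base"
      out
    }
  } else if (name == "valveless") {
    slow <- function(v, t) 1 - p$tip_slow * v * sstep((t - p$tip_slow_from) / 0.5)
    areal_rate <- function(x, y, t) p$r0 * slow(yn(y), t)
    longitudinal_rate <- function(y, t) p$ey0 * slow(yn(y), t)
    differentiation_onset <- function(x, y)
      .lerp(1 - yn(y), p$tau_long["tip"], p$tau_long["base"])
    region_assign <- function(u, v) rep("none", length(u))
  } else if (name == "sepal") {
    shape <- function(v) 1 - p$tip_boost * (1 - v)
    areal_rate <- function(x, y, t) p$r0 * shape(yn(y))
    longitudinal_rate <- function(y, t) p$ey0 * shape(yn(y))
    differentiation_onset <- function(x, y)
      .lerp(1 - yn(y), p$tau_long["tip"], p$tau_long["base"])
    region_assign <- function(u, v) rep("none", length(u))
  } else if (name == "carpelized_sepal") {
    areal_rate <- function(x, y, t) rep(p$r0, length(x))
    longitudinal_rate <- function(y, t) p$ey0
    differentiation_onset <- function(x, y)
      .lerp(abs(xn(x)), p$tau_ml["center"], p$tau_ml["margin"])
    region_assign <- function(u, v)
      ifelse(abs(u) < p$medial_halfwidth, "medial", "valve")
  } else if (name == "split_mutant") {
    xhat <- function(u)
      pmin(pmax((abs(u) - p$replum_halfwidth) / (1 - p$replum_halfwidth),
                0), 1)
    areal_rate <- function(x, y, t) rep(p$r0, length(x))
    longitudinal_rate <- function(y, t) p$ey0
    differentiation_onset <- function(x, y) {
      u <- xn(x); v <- yn(y)
      distal <- .lerp((1 - v) / 0.5, p$tau_distal["tip"], p$tau_distal["mid"])
      basal <- .lerp(1 - xhat(u), p$tau_basal["lateral"], p$tau_basal["medial"])
      ifelse(v > 0.5, distal, basal)
    }
    region_assign <- function(u, v) {
      out <- rep("valve", length(u))
      out[abs(u) < p$replum_halfwidth & v <= 0.5] <- "replum"
      out[v > 0.5] <- "none"
      out
    }
  }

  domain <- matrix(c(-p$width / 2, 0, p$width / 2, 0,
                     p$width / 2, p$length, -p$width / 2, p$length),
                   ncol = 2, byrow = TRUE)
  spec <- growth_field_spec(
    domain = domain, areal_rate = areal_rate,
    longitudinal_rate = longitudinal_rate,
    division_area_threshold = p$division_area_threshold,
    differentiation_onset = differentiation_onset,
    stomata_prob = p$stomata_prob, stomata_regions = p$stomata_regions,
    enlargement = p$enlargement, update_geom = update_geom)
  list(spec = spec, region_assign = region_assign, geom = geom,
       domain = domain)
}

#' Simulate a preset organ scenario
#'
#' Generates a daily time series (snapshots, lineage maps, ground truth)
#' for one of the preset organ worlds: `"gynoecium"` (mediolateral valve
#' gradient active 4-8 DAI, longitudinal style gradient from 9 DAI,
#' differentiation first in the lateral valves), `"valveless"` (organ-wide
#' basipetal onset gradient, as after polar-auxin-transport inhibition),
#' `"sepal"` (basipetal gradient from 4 DAI), `"carpelized_sepal"` (onset
#' increasing toward the organ margin), and `"split_mutant"` (leaf-like
#' basipetal gradient in the distal half, mediolateral gradient in the
#' basal half).
#'
#' @param name preset name.
#' @param overrides named list merged over the preset parameters (e.g.
#'   `list(t_end = 6, n_init = 40)` to scale a test down).
#' @param seed integer master seed; all per-step randomness derives from it.
#' @return list with `snapshots`, `lineages`, `ground_truth` (one
#'   data.frame over all intervals), `config` (all parameter values and the
#'   seed), and `name`.
#' @export
scenario <- function(name, overrides = list(), seed = 1L) {
  name <- match.arg(name, SCENARIO_NAMES)
  p <- utils::modifyList(.preset_params(name), overrides)
  built <- .preset_spec(name, p)
  snap <- make_initial_tissue(p$n_init, built$domain, seed = seed,
                              time_dai = p$t_start)
  # region identities assigned once on the initial tissue, inherited by
  # daughters ever after (regions are identities, not positions)
  ctr <- snapshot_centroids(snap)
  u <- ctr[, 1] / built$geom$W2
  v <- ctr[, 2] / built$geom$L
  regions <- built$region_assign(u, v)
  tis <- snapshot_to_tissue(snap)
  tis$region[] <- regions[match(names(tis$region), rownames(ctr))]
  snap <- as_snapshot(tis)

  snapshots <- list(snap)
  lineages <- list()
  gts <- list()
  t <- p$t_start
  k <- 0L
  while (t < p$t_end - 1e-9) {
    k <- k + 1L
    st <- step_tissue(snapshots[[k]], built$spec, dt = 1,
                      seed = (seed + 7919L * k) %% .Machine$integer.max,
                      n_substeps = p$n_substeps)
    snapshots[[k + 1L]] <- st$snapshot
    lineages[[k]] <- st$lineage
    gts[[k]] <- st$ground_truth
    t <- t + 1
  }
  list(snapshots = snapshots, lineages = lineages,
       ground_truth = do.call(rbind, gts),
       config = list(scenario = name, params = p, seed = seed),
       name = name)
}
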