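# organtrace

Lineage-based quantification of cellular growth and differentiation
gradients in plant organ epidermis, with a synthetic growing-tissue
generator for fully reproducible testing.

## The problem

Time-lapse confocal imaging of a developing plant organ (the *Arabidopsis*
gynoecium is the motivating system, but sepals, leaves and mutant organs
fit the same mold) yields, after segmentation, a series of labeled
epidermal cell polygons with parent relations between consecutive days.
From these one wants the classic morphometric readouts:

- **Area expansion** per cell lineage over one interval:
  `(Σ daughter areas at T1 / mother area at T0 − 1) × 100` (percent).
- **Growth anisotropy**: the best-fit linear map `A` sending the mother
  cell's tracked junctions (shared tri-cell vertices) at T0 to their T1
  positions is estimated by least squares after removing translation; its
  singular values `λ_max ≥ λ_min` are the principal stretches,
  anisotropy = `λ_max / λ_min`, and the left singular vector of `λ_max`
  is the principal growth direction.
- **Directional growth** along organ axes: cell length along the
  longitudinal (u) or mediolateral (v) coordinate of a Bezier grid
  fitted to the organ, as `(L1 / L0 − 1) × 100`.
- **Cell distance**: geodesic distance on the cell adjacency graph
  (cells as nodes, centroid-to-centroid edge weights), normalized per
  time point over a stated domain.
- **Gradient statistics**: binned mean ± SD profiles versus normalized
  distance; gradient presence via Spearman rank correlation with a
  label-shuffling permutation p-value
  `p = (1 + #{|ρ_perm| ≥ |ρ_obs|}) / (n_perm + 1)`; dominant-axis
  classification (longitudinal vs mediolateral); onset-time detection as
  the first sustained run of significant intervals; stomata distributions
  versus distance from basal and medial references.
- **Lineage algebra**: composition of child→parent maps across days,
  reverse lineage tracing of late region identities back to early
  sectors (with an exclusivity check), proliferation counts.

Because raw organ meshes are large and external, the package ships a
seeded simulator (`scenario()`, `make_initial_tissue()`, `step_tissue()`)
that grows, divides and differentiates a cell tessellation under
prescribed areal-rate, anisotropy and differentiation-onset fields and
records exact per-lineage ground truth — so every stage of the pipeline
is tested against an imposed, recoverable world. Presets encode the
biological scenarios: `gynoecium` (mediolateral valve gradient active
4–8 DAI, longitudinal style gradient from 9 DAI, stomata appearing
laterally first), `valveless` (organ-wide basipetal gradient), `sepal`,
`carpelized_sepal`, and `split_mutant`.

## Worked example

Simulate the gynoecium world, quantify the 5→6 DAI interval, and ask
whether valve growth is graded from the replum outward:

```r
library(organtrace)

sim <- scenario("gynoecium", seed = 1)          # DAI 3 -> 11, 70 -> ~600 cells
s0 <- sim$snapshots[[3]]; s1 <- sim$snapshots[[4]]
gm <- compute_growth_map(s0, s1, sim$lineages[[3]])
head(gm$records[, c("parent_label", "area_expansion_pct",
                    "anisotropy", "n_daughters")], 3)
#>   parent_label area_expansion_pct anisotropy n_daughters
#> 1            3           52.74338   1.046442           2
#> 2            4           53.64689   1.030429           2
#> 3            5           52.18744   1.146357           2

rg     <- sapply(s1$cells, `[[`, "region")
valves <- as.integer(names(rg)[rg == "valve"])
repl   <- as.integer(names(rg)[rg == "replum"])
vals <- setNames(gm$heat_map$area_expansion_pct,
                 gm$heat_map$label)[as.character(valves)]
vf <- normalize_distance(cell_distance(s1, repl), valves)
gradient_stat(vals, vf, n_permutations = 999, seed = 42)
#> <gradient stat: slope -20.59, rho -0.603, p 0.001, n 121>
```

The negative slope (−20.6 percentage points of area expansion per unit
normalized distance from the replum) and significant rank correlation
(ρ = −0.60, permutation p = 0.001 over 121 valve cells) recover the
mediolateral growth gradient the simulator imposed: valve cells adjacent
to the replum grow fastest. The binned profile shows the same trend as
mean ± SD (62.5 ± 8.6 % in the bin nearest the replum, falling to
53.6 ± 1.5 % at the lateral margin). Running `dominant_axis()` per
interval and `onset_time()` over the series recovers the imposed onsets:
mediolateral in the valves from DAI 4, longitudinal in the style from
DAI 9.

The end-to-end driver writes all tables (growth records, heat-map values
keyed by the second time point, gradient statistics, stomata histograms,
composed lineages, ground truth, manifest) to an output directory:

```r
run_pipeline(default_config("gynoecium", seed = 1, out_dir = "out"))
```

A command-line wrapper with `simulate` / `validate` / `quantify` /
`gradients` / `run` subcommands is installed at
`system.file("cli/organtrace.R", package = "organtrace")`.

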