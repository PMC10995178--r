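---
title: "organtrace: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{organtrace: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, numerical choices and design decisions
behind the package, in the spirit of a methods section. It states no
empirical result that the test suite does not itself compute.

## 1. The quantification model

All quantities operate on 2D planar-projected cell outlines. The organ
surfaces this pipeline targets are near-planar or gently curved single
epidermal layers; projecting curved inputs to the plane is a
pre-processing contract of the caller, not part of the math here. Units
are fixed package-wide: µm, µm², days, percentages on the 0–100 scale.

**Area expansion** is the printed lineage formula,
`(Σ daughter areas at T1 / mother area at T0 − 1) × 100`. It can be
negative (shrinkage) and is only defined for mothers with positive area.

**Principal stretches** come from junction correspondence. A cell's
junctions are its boundary vertices shared with neighbouring cells;
because the simulator (and the file formats) carry persistent vertex
ids, the T0→T1 correspondence is exact. We fit the 2×2 linear map `A`
minimizing `‖X1 − X0 Aᵀ‖` after centering both junction sets (translation
removed), and take the SVD `A = U Σ Vᵀ`: the singular values are the
stretches, the first left singular vector the principal direction, and
the RMS residual is reported. Three non-collinear pairs are the hard
minimum; when neighbour divisions add vertices, only junctions present at
both times are used. Below anisotropy `1 + 1e-6` the direction is
reported as undefined rather than an arbitrary vector. This
affine-least-squares/SVD construction is this package's explicit choice;
upstream mesh software computes principal growth directions by its own
(unpublished) method, so equivalence cannot be asserted — only internal
consistency, which the tests check via `det(A) ≈ 1 + expansion/100`.

**Directional growth** uses a Bezier axis grid. The longitudinal
coordinate u of a point is the normalized arclength of its
nearest-parameter projection onto the longitudinal Bezier curve; v is the
signed perpendicular offset rescaled by the local organ width, so v = 0.5
on the curve and v spans [0, 1] across the organ. The width table is
estimated from the snapshot's cell vertices in 32 arclength bins with a
±2-bin running maximum (single cells under-sample the margin). Cell
"length" along u is the u-extent times total arclength; along v it is the
v-extent times twice the local half-width. With both lengths in µm, the
directional formula is the same length-ratio percentage as area
expansion, and under diagonal growth the two axis factors multiply to the
area factor (tested at 2%).

**Cell distance** is the shortest path on the cell adjacency graph with
centroid-to-centroid Euclidean edge weights (Dijkstra via igraph; an
independent Bellman–Ford oracle backs the tests). This matches the
cell-granular semantics of interactive "cell distance" tools rather than
exact geodesics on a triangulated surface, which are out of scope.
Normalization divides by the maximum distance over an explicitly stated
domain (e.g. valve cells only, or the whole organ) per time point; the
domain is a required parameter because published figures do not state it,
and the choice changes the profiles.

**Gradient statistics.** Binned profiles report mean, SD and n per
equal-width bin on [0, 1]; single-cell bins are flagged and their SD
reported as 0. Gradient presence is operationalized as Spearman rank
correlation plus a label-shuffling permutation p-value
`(1 + #{|ρ_perm| ≥ |ρ_obs|})/(n_perm + 1)` — the add-one form keeps p in
(0, 1] and super-uniform under the null (calibration is tested by KS).
Dominant-axis classification compares |ρ| along the longitudinal and
mediolateral fields: the larger wins if its p < α and its |ρ| exceeds the
other's by a margin δ; defaults α = 0.05, δ = 0.1, n_perm = 999. Onset
detection takes the first run of `min_consecutive` (default 2)
consecutive significant intervals with a consistent sign of ρ. These
thresholds formalize gradients that the source imagery literature asserts
visually; all are config-exposed.

**Heat-map convention.** Interval quantities are displayed on the second
time point: every daughter inherits its parent's value, keyed by T1
labels. No additional spatial smoothing is applied (the averaging used in
published heat maps is unstated; per-cell display is this package's
choice).

**Vanished parents** (T0 cells with no children — cells that left the
imaged region) are flagged by `validate_series()` and excluded from
growth maps; how such cells were treated in published averages is not
stated, so flag-and-exclude is this package's documented choice.

## 2. The synthetic growing tissue

The generator's role is to stand in for segmented time-lapse data with a
*known* imposed world, so the pipeline's recovery can be tested.

**Tessellation.** The initial tissue is a centroidally relaxed (4 Lloyd
sweeps) Voronoi tessellation of the organ outline, clipped by half-plane
bisectors — cells tile the domain exactly. Cells are stored as cycles of
shared vertex ids; growth displaces each shared vertex once, so the
tessellation can never tear.

**Growth.** A diagonal strain-rate field `E = diag(ex, ey)` in the organ
frame (x mediolateral, y longitudinal) is prescribed; vertices move with

    v(x, y) = ( ∫₀ˣ ex(s, y, t) ds ,  ∫₀ʸ ey(x, s, t) ds )

whose divergence is exactly `ex + ey` everywhere, so the local areal
growth rate matches the prescription even for spatially varying fields.
The price is a compatible shear where the field has cross-gradients:
`∂v_y/∂x = ∫ ∂ey/∂x ds` grows linearly with y, which destroys strongly
patterned organs if `ey` varies across x. The presets therefore prescribe
`longitudinal_rate(y, t)` (x-independent `ey`) and absorb all transverse
variation into `ex = r − ey`; the symmetric split
`ex, ey = (r ∓ log a)/2` remains available for uniform or gently varying
anisotropy fields. Integration uses 10 sub-steps/day with a midpoint
(RK2) update; the velocity integrals use 32-point midpoint quadrature
(node spacing well below the narrowest field transition).

**Ground truth.** Per parent cell and step the generator records (i) an
areal factor: the product over sub-steps of `exp(h·(ex+ey))` averaged
over the cell's vertices and centroid — the analytic field integrated by
dense sub-stepping, never the measured polygon areas — and (ii) principal
stretches and direction from composing the motion Jacobian (evaluated by
central differences of the velocity) along the centroid trajectory.

**Resolvability limit.** A straight-edged polygon can only realize the
continuum flow to ~1% per cell if the field is smooth at cell scale.
Presets with region contrasts narrower than a cell diameter (the
gynoecium's replum strip) violate this near region boundaries: cells
straddling the transition average two rates, and their measured area
factor deviates from the pointwise prescription by several percent. The
per-cell 1% conservation property is therefore asserted on the
cell-scale-smooth preset (valveless), while the gynoecium world is held
to total-area conservation within 1%, gap/overlap-freeness, and stomata
spacing. This is a property of any vertex-displacement tessellation, not
of the implementation.

**Division.** Proliferative cells exceeding the area threshold are split
by the shortest wall through the centroid perpendicular to the cell's
longest principal axis (second moments of area; ties broken toward the
x-axis). Wall endpoints are inserted into the neighbouring cells'
boundaries, keeping the tessellation conformal; endpoints are kept at
least 2% of an edge away from existing junctions to avoid slivers.
Daughters receive fresh labels and parent links. The source literature
does not model division; this is a standard geometric rule that keeps
cell shapes realistic.

**Differentiation and stomata.** A cell whose local onset time
τ(position) has passed stops dividing; its local areal rate is multiplied
by an enlargement factor (preset 1.10, ramped over ~1 day — with the
prescribed-`ey` split the extra growth goes into the mediolateral rate so
`ey` keeps no transverse gradient). Differentiated cells are larger
mainly because they stop dividing while growth continues, matching the
use of cell size as the differentiation readout. Differentiated cells in
permitted regions convert to stomata with a per-day probability (preset
0.25), never adjacent to an existing stoma.

## 3. The preset worlds

Timings follow the developmental literature for each organ; gradient
*magnitudes* are free parameters of the generator (no quantitative
magnitudes are published), recorded in the returned `config`, and must
not be read as measurements.

- `gynoecium` (DAI 3→11, 70 initial cells on a 60×140 µm outline,
  baseline rate 0.40/day, ey 0.20/day, division threshold 240 µm²):
  valves carry a mediolateral rate boost of up to +0.18/day toward the
  replum, active DAI 4–8; replum growth ramps down to 0.18/day from DAI 4
  (regions diverge between 4 and 5 DAI); the style slows toward its tip
  (factor 0.45) from DAI 9; valve differentiation onset runs 6 (lateral
  margin) → 10 (replum-adjacent), style onset 9 (tip) → 11.5 (base);
  stomata form in valves only. Rate-blend zones are placed inside the
  replum/base strips and below the style boundary so that valve-tagged
  cells feel pure valve rates; the boost is tapered below the style so
  style cells never feel it.
- `valveless`: one organ-wide basipetal onset gradient (tip 7 → base 12)
  with growth slowing toward the tip from DAI 7 — the
  radially-symmetric, valve-less organ after polar-auxin-transport
  inhibition, flattened to a sheet.
- `sepal`: growth and onset graded from the tip from DAI 4 (tip 4 →
  base 9).
- `carpelized_sepal`: onset increasing toward the organ margin
  (center 5 → margin 9), the mediolateral reorientation produced by
  carpel identity in the margin.
- `split_mutant`: leaf-like basipetal onset in the distal half (tip 5 →
  mid 8), mediolateral onset in the basal half (lateral 8 → medial 11).

Initial cell counts and windows are scaled to desk size: the real organ
grows from ~70 to ~11,000 cells; the presets reach several hundred to a
couple thousand, which preserves every gradient readout while keeping the
full suite under a minute. Tests that need a preset repeatedly simulate
it once and cache it.

**What the generator does not emulate:** mechanical force balance or
vertex-model energy minimization; 3D organ shape and surface curvature;
hormone transport; segmentation and tracking errors (parent relations are
exact); cells leaving the field of view (every lineage is complete —
vanished-parent handling is exercised with hand-built fixtures instead).
A green recovery test therefore establishes that the pipeline recovers
gradients from ideal segmented data of a growing, dividing, patterned
tissue — not that it is robust to imaging artifacts.

## 4. Numerical choices and degenerate inputs

- Polygon areas: shoelace; orientation normalized to counterclockwise at
  construction; self-intersection is rejected (O(n²) segment test — cell
  outlines are small).
- Vertex pooling on file import rounds coordinates to 1e-7 µm; snapshot
  round-trips write 17 significant digits and are byte-lossless.
- Bezier projection: 1024 dense samples, deterministic nearest-sample
  pick (`ties.method = "first"`), ±2-sample bracket, 40 ternary-search
  iterations; the (u,v) round-trip is tested to 1e-3 and achieves ~1e-9
  on gentle curvature. Strongly curved axes whose curvature radius
  approaches the organ half-width leave the tubular neighbourhood where
  the projection is invertible; that is a usage limit, not an error the
  code can detect cheaply.
- `growth_tensor` refuses under-determined input (<3 pairs, collinear
  junctions). Zero-variance values yield a flagged null gradient stat
  (ρ = 0, p = 1) rather than an error.
- Degenerate normalization domains (no finite distances, all-zero field)
  are errors, as is an empty source set; unreachable cells get `Inf` and
  are listed.
- All randomness flows from explicit integer seeds; per-step simulator
  seeds derive from the master seed as `seed + 7919·k` (kept below 2³¹).
  Identical seeds give byte-identical series and output files.

## 5. Known limitations

- 2D only; curvature-corrected tensors on strongly curved surfaces are
  out of scope.
- The affine-SVD growth tensor matches upstream mesh software only in
  spirit; no claim of numerical equivalence is made.
- Per-cell conservation at 1% requires fields smooth at cell scale (see
  §2); sharper prescriptions remain usable but their ground truth is
  honest only in aggregate.
- The permutation test assumes exchangeability of cell values under the
  null; spatial autocorrelation in real tissues (not modelled by the
  generator's iid null) would make it anti-conservative.
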