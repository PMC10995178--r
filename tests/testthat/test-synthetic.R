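test_that("make_initial_tissue tiles the domain with the requested cells", {
  dom <- rect_domain(60, 140)
  s <- make_initial_tissue(70, dom, seed = 1)
  expect_length(s$cells, 70)
  expect_equal(sum(snapshot_areas(s)), poly_area(dom), tolerance = 1e-9)

  s4 <- make_initial_tissue(4, unit_square(1), seed = 3)
  expect_length(s4$cells, 4)
  g <- igraph::graph_from_edgelist(matrix(as.character(s4$adjacency),
                                          ncol = 2), directed = FALSE)
  expect_equal(igraph::components(g)$no, 1)

  expect_error(make_initial_tissue(3, unit_square(1), seed = 1), ">= 4")
  expect_error(make_initial_tissue(5, rbind(c(0, 0), c(1, 1)), seed = 1),
               "degenerate")
})

test_that("same seed gives byte-identical snapshots", {
  dom <- rect_domain(20, 20)
  a <- make_initial_tissue(12, dom, seed = 9)
  b <- make_initial_tissue(12, dom, seed = 9)
  expect_identical(a, b)
  c <- make_initial_tissue(12, dom, seed = 10)
  expect_false(identical(a, c))
})

test_that("uniform areal rate multiplies every area by ~exp(r)", {
  dom <- rect_domain(40, 40)
  s <- make_initial_tissue(20, dom, seed = 2)
  spec <- uniform_spec(dom, rate = 0.2)
  st <- step_tissue(s, spec, dt = 1, seed = 1)
  ratio <- snapshot_areas(st$snapshot)[names(s$cells)] / snapshot_areas(s)
  expect_equal(unname(ratio), rep(exp(0.2), 20), tolerance = 2e-3)
  # tessellation remains gap-free
  chk <- organtrace:::tessellation_check(
    organtrace:::snapshot_to_tissue(st$snapshot))
  expect_true(chk$ok)
})

test_that("pure anisotropy elongates in x and shrinks in y", {
  dom <- rect_domain(40, 40, y0 = -20)
  s <- make_initial_tissue(16, dom, seed = 4)
  # ratio 2 along x per day, zero net area change: la = -log(2)
  spec <- uniform_spec(dom, rate = 0, log_anis = -log(2))
  st <- step_tissue(s, spec, dt = 1, seed = 1)
  bb0 <- apply(do.call(rbind, lapply(s$cells, `[[`, "vertices")), 2, range)
  bb1 <- apply(do.call(rbind, lapply(st$snapshot$cells, `[[`, "vertices")),
               2, range)
  expect_gt(diff(bb1[, 1]), diff(bb0[, 1]))          # wider
  expect_lt(diff(bb1[, 2]), diff(bb0[, 2]))          # shorter
  expect_equal(diff(bb1[, 1]) / diff(bb0[, 1]) /
                 (diff(bb1[, 2]) / diff(bb0[, 2])), 2, tolerance = 0.01)
  expect_equal(sum(snapshot_areas(st$snapshot)), sum(snapshot_areas(s)),
               tolerance = 1e-3)
})

test_that("daughter-area sums match the imposed ground truth per cell", {
  # spatially varying but cell-scale-smooth field; oracle = the imposed
  # field integrated by dense sub-stepping (the ground-truth table)
  dom <- rect_domain(60, 120)
  s <- make_initial_tissue(40, dom, seed = 5)
  spec <- growth_field_spec(
    domain = dom,
    areal_rate = function(x, y, t) 0.3 + 0.002 * y,
    longitudinal_rate = function(y, t) 0.15 + 0.001 * y,
    division_area_threshold = 250,
    differentiation_onset = function(x, y) rep(99, length(x)))
  st <- step_tissue(s, spec, dt = 1, seed = 2)
  a0 <- snapshot_areas(s)
  a1 <- snapshot_areas(st$snapshot)
  dsum <- tapply(a1[names(st$lineage$parent_of)], st$lineage$parent_of, sum)
  gt <- st$ground_truth
  fac <- dsum[as.character(gt$parent_label)] / a0[as.character(gt$parent_label)]
  expect_true(all(abs(fac / gt$area_factor - 1) < 0.01))
})

test_that("division splits big cells and keeps the tessellation conformal", {
  dom <- rect_domain(40, 40)
  s <- make_initial_tissue(16, dom, seed = 6)
  spec <- uniform_spec(dom, rate = 0.5, division_area_threshold = 120)
  st <- step_tissue(s, spec, dt = 1, seed = 3)
  expect_gt(length(st$snapshot$cells), length(s$cells))
  expect_true(all(snapshot_areas(st$snapshot) <= 1.05 * 120 * exp(0.5)))
  chk <- organtrace:::tessellation_check(
    organtrace:::snapshot_to_tissue(st$snapshot))
  expect_true(chk$ok)
  # every daughter has a parent in the lineage, lineage covers all t1 cells
  expect_setequal(names(st$lineage$parent_of), names(st$snapshot$cells))
  expect_true(all(st$lineage$parent_of %in%
                    as.integer(names(s$cells))))
})

test_that("scenario presets run, are deterministic, and list their names", {
  expect_error(scenario("nonesuch"), "gynoecium")
  a <- scenario("sepal", list(t_end = 5, n_init = 30L), seed = 11)
  b <- scenario("sepal", list(t_end = 5, n_init = 30L), seed = 11)
  expect_identical(a$snapshots, b$snapshots)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_equal(a$config$seed, 11)
  expect_true(is.list(a$config$params))      # magnitudes are reported
})

test_that("stomata are never adjacent, in any gynoecium snapshot", {
  sim <- gyn_series()
  for (s in sim$snapshots) {
    st <- states_of(s)
    stoma <- as.integer(names(st)[st == "stoma"])
    if (length(stoma) < 2) next
    adj <- s$adjacency
    both <- adj[, 1] %in% stoma & adj[, 2] %in% stoma
    expect_false(any(both))
  }
})

test_that("gynoecium series grows from ~70 cells and stays structurally valid", {
  sim <- gyn_series()
  n <- vapply(sim$snapshots, function(s) length(s$cells), integer(1))
  expect_equal(n[1], 70)
  expect_true(all(diff(n) >= 0))
  expect_gt(n[length(n)], 500)
  last <- organtrace:::snapshot_to_tissue(sim$snapshots[[length(n)]])
  expect_true(organtrace:::tessellation_check(last)$ok)
})

test_that("differentiation appears first in the lateral valves", {
  sim <- gyn_series()
  s <- sim$snapshots[[5]]                    # 7 DAI: lateral onset (tau 6) passed
  rg <- regions_of(s); st <- states_of(s)
  valve <- names(rg)[rg == "valve"]
  diffed <- valve[st[valve] != "proliferative"]
  expect_gt(length(diffed), 0)
  ctr <- snapshot_centroids(s)
  xmax <- max(abs(ctr[valve, 1]))
  expect_gt(mean(abs(ctr[diffed, 1])) / xmax, 0.6)
})
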