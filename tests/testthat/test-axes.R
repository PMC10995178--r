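test_that("rectilinear limit: u is normalized y, v is normalized x", {
  dom <- rect_domain(40, 100)
  s <- make_initial_tissue(40, dom, seed = 5)
  grid <- fit_axis_grid(s, rbind(c(0, 0), c(0, 100)),
                        rbind(c(0, 50), c(20, 50)))
  set.seed(2)
  P <- cbind(runif(100, -19, 19), runif(100, 2, 98))
  uv <- axis_coords(grid, P)
  expect_equal(uv[, 1], P[, 2] / 100, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(uv[, 2], (P[, 1] + 20) / 40, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("points on a bent axis have v = 0.5 and strictly increasing u", {
  cp <- rbind(c(0, 0), c(8, 40), c(-6, 80), c(2, 120))
  dom <- rect_domain(60, 124, y0 = -2)
  s <- make_initial_tissue(60, dom, seed = 6)
  grid <- fit_axis_grid(s, cp)
  tt <- seq(0.05, 0.95, length.out = 25)
  uv <- axis_coords(grid, organtrace:::.bezier_point(cp, tt))
  expect_true(all(abs(uv[, 2] - 0.5) < 1e-4))
  expect_true(all(diff(uv[, 1]) > 0))
})

test_that("(u,v) -> point -> (u,v) round-trips within 1e-3", {
  cp <- rbind(c(0, 0), c(8, 40), c(-6, 80), c(2, 120))
  dom <- rect_domain(60, 124, y0 = -2)
  s <- make_initial_tissue(60, dom, seed = 6)
  grid <- fit_axis_grid(s, cp)
  set.seed(1)
  Q <- cbind(runif(1000, -18, 18), runif(1000, 3, 117))
  uv <- axis_coords(grid, Q)
  uv2 <- axis_coords(grid, axis_point(grid, uv))
  expect_lt(max(abs(uv2 - uv)), 1e-3)
})

test_that("degenerate control points are rejected", {
  s <- make_initial_tissue(9, unit_square(10), seed = 1)
  expect_error(fit_axis_grid(s, rbind(c(1, 1), c(1, 1))), "zero-extent")
  expect_error(fit_axis_grid(s, rbind(c(1, 1))), ">= 2")
})

test_that("chain fixture yields distances 0, 10, 20, 30, 40", {
  s <- chain_snapshot(5, pitch = 10)
  f <- cell_distance(s, 1)
  expect_equal(unname(f$distance), c(0, 10, 20, 30, 40))
  all_src <- cell_distance(s, 1:5)
  expect_equal(unname(all_src$distance), rep(0, 5))
})

test_that("cell_distance equals the exhaustive Bellman-Ford oracle", {
  dom <- rect_domain(50, 50)
  s <- make_initial_tissue(50, dom, seed = 21)
  labs <- snapshot_labels(s)
  set.seed(3)
  for (rep in 1:5) {
    src <- sample(labs, sample(1:3, 1))
    got <- cell_distance(s, src)$distance
    want <- bellman_ford_distances(s, src)
    expect_equal(got, want[names(got)], tolerance = 1e-9)
  }
})

test_that("unreachable cells get infinite distance and a flag", {
  cells <- list(cell_polygon(1, unit_square(1)),
                cell_polygon(2, unit_square(1) + 5),
                cell_polygon(3, unit_square(1) + 10))
  s <- tissue_snapshot(0, cells, adjacency = rbind(c(1L, 2L)))
  f <- cell_distance(s, 1)
  expect_true(is.infinite(f$distance[["3"]]))
  expect_equal(f$unreachable, 3L)
})

test_that("triangle inequality holds on simulated tessellations", {
  dom <- rect_domain(40, 40)
  s <- make_initial_tissue(30, dom, seed = 22)
  labs <- snapshot_labels(s)
  d_all <- sapply(labs, function(l) cell_distance(s, l)$distance)
  set.seed(4)
  for (rep in 1:200) {
    ijk <- sample(seq_along(labs), 3)
    expect_lte(d_all[ijk[1], ijk[3]],
               d_all[ijk[1], ijk[2]] + d_all[ijk[2], ijk[3]] + 1e-9)
  }
})

test_that("normalize_distance scales to [0,1] over the stated domain", {
  s <- chain_snapshot(3, pitch = 10)
  f <- normalize_distance(cell_distance(s, 1))
  expect_equal(unname(f$normalized), c(0, 0.5, 1))
  expect_equal(f$max_distance, 20)
  # degenerate domain: single source cell only
  s1 <- tissue_snapshot(0, list(cell_polygon(1, unit_square(1))),
                        adjacency = NULL)
  expect_error(normalize_distance(cell_distance(s1, 1)), "degenerate")
  # restricted domain: max over the domain labels, clipped elsewhere
  f2 <- normalize_distance(cell_distance(s, 1), domain_labels = c(1, 2))
  expect_equal(f2$normalized[["2"]], 1)
  expect_true(is.na(f2$normalized[["3"]]))
})

test_that("normalization is per time point on a growing series", {
  sim <- gyn_series()
  for (k in c(1, 4, 8)) {
    s <- sim$snapshots[[k + 1]]
    rg <- regions_of(s)
    valve <- as.integer(names(rg)[rg == "valve"])
    repl <- as.integer(names(rg)[rg == "replum"])
    f <- normalize_distance(cell_distance(s, repl), valve)
    expect_equal(max(f$normalized, na.rm = TRUE), 1)
    expect_true(all(f$normalized >= 0 & f$normalized <= 1, na.rm = TRUE))
  }
})
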