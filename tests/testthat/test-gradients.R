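test_that("profile_gradient: constant, linear and oracle cases", {
  s <- chain_snapshot(9, pitch = 10)
  f <- normalize_distance(cell_distance(s, 1))
  vals <- stats::setNames(rep(5, 9), 1:9)
  pr <- profile_gradient(vals, f, n_bins = 4)
  expect_equal(pr$mean[pr$n > 0], rep(5, sum(pr$n > 0)))
  expect_equal(pr$sd[pr$n > 0], rep(0, sum(pr$n > 0)))
  expect_equal(sum(pr$n), attr(pr, "n_cells"))

  # value = normalized distance, 4 bins -> means near bin centers
  vals2 <- f$normalized
  pr2 <- profile_gradient(vals2, f, n_bins = 4)
  expect_lt(max(abs(pr2$mean - c(0.125, 0.375, 0.625, 0.875))), 0.07)

  # random values: direct group-by-bin recomputation oracle
  set.seed(9)
  vals3 <- stats::setNames(rnorm(9), 1:9)
  pr3 <- profile_gradient(vals3, f, n_bins = 3)
  bin <- pmin(pmax(findInterval(f$normalized, seq(0, 1, by = 1 / 3),
                                rightmost.closed = TRUE), 1), 3)
  for (b in 1:3) {
    expect_equal(pr3$mean[b], mean(vals3[bin == b]))
    expect_equal(pr3$n[b], sum(bin == b))
  }
  expect_error(profile_gradient(c(x = 1), f), "no overlapping")
})

test_that("weighted recombination of bin means recovers the global mean", {
  dom <- rect_domain(40, 40)
  s <- make_initial_tissue(40, dom, seed = 30)
  f <- normalize_distance(cell_distance(s, 1))
  set.seed(10)
  vals <- stats::setNames(rnorm(40, 50, 10), snapshot_labels(s))
  pr <- profile_gradient(vals, f, n_bins = 6)
  expect_equal(sum(pr$mean * pr$n, na.rm = TRUE) / sum(pr$n),
               mean(vals))
  expect_true(all(pr$single == (pr$n == 1)))
})

test_that("gradient_stat: perfect monotone and zero-variance cases", {
  s <- chain_snapshot(12, pitch = 10)
  f <- normalize_distance(cell_distance(s, 1))
  inc <- f$normalized * 3 + 2
  gs <- gradient_stat(inc, f, n_permutations = 499, seed = 1)
  expect_equal(gs$rank_correlation, 1)
  expect_equal(gs$permutation_p, 1 / 500)
  expect_equal(gs$slope, 3, tolerance = 1e-9)

  flat <- stats::setNames(rep(2, 12), names(f$normalized))
  gz <- gradient_stat(flat, f, n_permutations = 99, seed = 1)
  expect_equal(gz$rank_correlation, 0)
  expect_equal(gz$permutation_p, 1)
  expect_equal(gz$flag, "zero-variance")
  expect_error(gradient_stat(inc[1:5], f), ">= 10")
})

test_that("p-values behave under the null (n = 500 Monte Carlo)", {
  s <- chain_snapshot(500, pitch = 2)
  f <- normalize_distance(cell_distance(s, 1))
  labs <- names(f$normalized)
  set.seed(11)
  hits <- 0L
  for (r in 1:40) {
    vals <- stats::setNames(rnorm(length(labs)), labs)
    gs <- gradient_stat(vals, f, n_permutations = 199, seed = 1000 + r)
    if (abs(gs$rank_correlation) < 0.1 && gs$permutation_p > 0.05)
      hits <- hits + 1L
  }
  expect_gte(hits, 36)                       # >= 90% of seeds
})

test_that("dominant_axis picks the axis the values depend on, and swaps", {
  dom <- rect_domain(40, 100)
  s <- make_initial_tissue(80, dom, seed = 32)
  base <- select_labels(s, "ymin:0.05")
  med <- select_labels(s, "xband:0.2")
  uf <- normalize_distance(cell_distance(s, base))
  vf <- normalize_distance(cell_distance(s, med))
  vals_u <- 10 + 5 * uf$normalized
  vals_v <- 10 + 5 * vf$normalized
  du <- dominant_axis(vals_u, uf, vf, seed = 2)
  expect_equal(du$axis, "longitudinal")
  dv <- dominant_axis(vals_v, uf, vf, seed = 2)
  expect_equal(dv$axis, "mediolateral")
  # swapping the fields swaps the verdict
  sw <- dominant_axis(vals_u, vf, uf, seed = 2)
  expect_equal(sw$axis, "mediolateral")
})

test_that("onset_time finds the first sustained significant run", {
  mk <- function(p, rho) structure(list(slope = rho, rank_correlation = rho,
                                        permutation_p = p, n_cells = 50,
                                        flag = NULL),
                                   class = "gradient_stat")
  ser <- list(mk(0.8, 0.1), mk(0.6, 0.1), mk(0.01, 0.5), mk(0.02, 0.6),
              mk(0.01, 0.5))
  expect_equal(onset_time(ser, min_consecutive = 2), 3L)
  none <- list(mk(0.8, 0.1), mk(0.6, -0.1))
  expect_true(is.na(onset_time(none)))
  expect_true(is.na(onset_time(list())))
  # sign must be consistent across the run
  flip <- list(mk(0.01, 0.5), mk(0.01, -0.5), mk(0.01, 0.5))
  expect_true(is.na(onset_time(flip, min_consecutive = 3)))
})

test_that("stomata_distribution: empty and concentrated cases", {
  s <- chain_snapshot(10, pitch = 10)
  sd0 <- stomata_distribution(s, 1, 10, n_bins = 5)
  expect_equal(sd0$n_stomata, 0)
  expect_equal(sd0$flag, "no stomata")
  expect_true(all(sd0$from_base$count == 0))

  # stomata only at maximal distance from the medial reference (cell 10)
  cells <- lapply(s$cells, function(c)
    cell_polygon(c$label, c$vertices,
                 state = if (c$label %in% c(1, 2)) "stoma" else "proliferative"))
  s2 <- tissue_snapshot(0, cells, adjacency = s$adjacency)
  sd2 <- stomata_distribution(s2, 1, 10, n_bins = 5)
  expect_equal(sd2$n_stomata, 2)
  expect_equal(sd2$from_medial$count[5], 2)  # all mass in the last bin
  expect_equal(sum(sd2$from_medial$count), 2)
})

test_that("cell_size_profile: flat areas and differentiated enlargement", {
  s <- chain_snapshot(10, pitch = 10)
  f <- normalize_distance(cell_distance(s, 1))
  pr <- cell_size_profile(s, f, n_bins = 5)
  expect_true(all(abs(pr$mean[pr$n > 0] - 50) < 1e-9))

  # on the gynoecium world, differentiated cells are bigger than
  # proliferative ones (they stopped dividing but kept growing)
  sim <- gyn_series()
  s9 <- sim$snapshots[[7]]
  st <- states_of(s9); ar <- snapshot_areas(s9)
  rg <- regions_of(s9)
  valve <- rg == "valve"
  expect_gt(mean(ar[valve & st != "proliferative"]),
            mean(ar[valve & st == "proliferative"]))
})
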