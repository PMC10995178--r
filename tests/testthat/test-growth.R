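test_that("area_expansion reproduces the printed-formula cases", {
  expect_equal(area_expansion(100, 100), 0)
  expect_equal(area_expansion(50, 100), 100)
  expect_equal(area_expansion(80, 60), -25)
  expect_equal(area_expansion(c(100, 50, 80), c(100, 100, 60)),
               c(0, 100, -25))
  expect_error(area_expansion(0, 10), "> 0")
  expect_error(area_expansion(10, -1), ">= 0")
})

test_that("anisotropy is the stretch ratio with guarded input", {
  expect_equal(anisotropy(1.2, 1.2), 1)
  expect_equal(anisotropy(2, 1), 2)
  expect_error(anisotropy(1, 0), "> 0")
})

test_that("growth_tensor: identity, isotropic and axis-aligned cases", {
  sq <- unit_square(1)
  gt <- growth_tensor(sq, sq)
  expect_equal(gt$lambda_max, 1, tolerance = 1e-12)
  expect_equal(gt$anisotropy, 1, tolerance = 1e-12)
  expect_false(gt$direction_defined)

  gt2 <- growth_tensor(sq, sq * 1.2)
  expect_equal(c(gt2$lambda_max, gt2$lambda_min), c(1.2, 1.2),
               tolerance = 1e-12)
  expect_equal(gt2$anisotropy, 1, tolerance = 1e-12)

  gt3 <- growth_tensor(sq, sq %*% diag(c(2, 1)))
  expect_equal(c(gt3$lambda_max, gt3$lambda_min), c(2, 1),
               tolerance = 1e-12)
  expect_equal(abs(gt3$principal_direction), c(1, 0), tolerance = 1e-12)
  expect_lt(gt3$residual_rms, 1e-12)
})

test_that("growth_tensor recovers singular values of random maps to 1e-9", {
  set.seed(31)
  for (rep in 1:20) {
    A <- matrix(rnorm(4, sd = 1), 2, 2)
    while (abs(det(A)) < 0.05) A <- matrix(rnorm(4), 2, 2)
    X0 <- cbind(rnorm(6), rnorm(6))
    X1 <- X0 %*% t(A) + matrix(c(3, -1), 6, 2, byrow = TRUE)  # + translation
    gt <- growth_tensor(X0, X1)
    sv <- svd(A)$d                          # independent singular-value oracle
    expect_equal(gt$lambda_max, sv[1], tolerance = 1e-9)
    expect_equal(gt$lambda_min, sv[2], tolerance = 1e-9)
    expect_lt(gt$residual_rms, 1e-9)
  }
})

test_that("growth_tensor is rotation-equivariant at machine precision", {
  set.seed(5)
  X0 <- cbind(rnorm(8), rnorm(8))
  A <- matrix(c(1.7, 0.3, -0.2, 0.9), 2, 2)
  X1 <- X0 %*% t(A)
  base <- growth_tensor(X0, X1)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- growth_tensor(X0 %*% t(R), X1 %*% t(R))
  expect_equal(rot$lambda_max, base$lambda_max, tolerance = 1e-12)
  expect_equal(rot$lambda_min, base$lambda_min, tolerance = 1e-12)
  d_rot <- rot$principal_direction
  d_exp <- as.vector(R %*% base$principal_direction)
  if (sum(d_rot * d_exp) < 0) d_exp <- -d_exp      # sign convention
  expect_equal(d_rot, d_exp, tolerance = 1e-9)
})

test_that("growth_tensor rejects under-determined input", {
  expect_error(growth_tensor(cbind(0:1, 0:1), cbind(0:1, 0:1)),
               "under-determined")
  coll <- cbind(1:5, 2 * (1:5))
  expect_error(growth_tensor(coll, coll), "collinear")
})

test_that("directional_expansion: axis-aligned stretch and identity", {
  dom <- rect_domain(40, 100)
  s <- make_initial_tissue(40, dom, seed = 5)
  grid <- fit_axis_grid(s, rbind(c(0, 0), c(0, 100)),
                        rbind(c(0, 50), c(20, 50)))
  p0 <- rbind(c(-5, 40), c(5, 40), c(5, 50), c(-5, 50))     # 10 x 10
  p1y <- rbind(c(-5, 40), c(5, 40), c(5, 60), c(-5, 60))    # 10 x 20
  expect_equal(directional_expansion(p0, p1y, grid, "longitudinal"), 100,
               tolerance = 1e-6)
  expect_equal(directional_expansion(p0, p1y, grid, "mediolateral"), 0,
               tolerance = 1e-6)
  expect_equal(directional_expansion(p0, p0, grid, "longitudinal"), 0,
               tolerance = 1e-9)
  expect_equal(directional_expansion(p0, p0, grid, "mediolateral"), 0,
               tolerance = 1e-9)
})

test_that("axis factors multiply to the area factor under diagonal growth", {
  dom <- rect_domain(40, 100)
  s <- make_initial_tissue(40, dom, seed = 5)
  grid <- fit_axis_grid(s, rbind(c(0, 0), c(0, 100)),
                        rbind(c(0, 50), c(20, 50)))
  set.seed(8)
  for (rep in 1:10) {
    fx <- runif(1, 0.8, 1.6); fy <- runif(1, 0.8, 1.6)
    p0 <- rbind(c(-4, 40), c(4, 40), c(4, 48), c(-4, 48))
    ctr <- poly_centroid(p0)
    p1 <- sweep(sweep(p0, 2, ctr) %*% diag(c(fx, fy)), 2, ctr, `+`)
    u <- directional_expansion(p0, p1, grid, "longitudinal")
    v <- directional_expansion(p0, p1, grid, "mediolateral")
    a <- area_expansion(poly_area(p0), poly_area(p1))
    expect_equal((1 + u / 100) * (1 + v / 100), 1 + a / 100,
                 tolerance = 0.02)
  }
})

test_that("compute_growth_map keys heat values by t1 labels (display at T1)", {
  s0 <- grid4_snapshot(0)
  # cell 1 divides into 5 and 6; the others persist with the same outline
  co <- function(m) matrix(m, ncol = 2, byrow = TRUE)
  s1 <- tissue_snapshot(1, list(
    cell_polygon(5, co(c(0, 0, 1, 0, 1, 0.5, 0, 0.5)),
                 vertex_ids = c(1L, 2L, 20L, 21L)),
    cell_polygon(6, co(c(0, 0.5, 1, 0.5, 1, 1, 0, 1)),
                 vertex_ids = c(21L, 20L, 5L, 4L)),
    cell_polygon(2, co(c(1, 0, 2, 0, 2, 1, 1, 1)),
                 vertex_ids = c(2L, 3L, 6L, 5L, 20L)[c(1, 2, 3, 4)]),
    cell_polygon(3, co(c(0, 1, 1, 1, 1, 2, 0, 2)),
                 vertex_ids = c(4L, 5L, 8L, 7L)),
    cell_polygon(4, co(c(1, 1, 2, 1, 2, 2, 1, 2)),
                 vertex_ids = c(5L, 6L, 9L, 8L))))
  lin <- lineage_map(0, 1, c("5" = 1, "6" = 1, "2" = 2, "3" = 3, "4" = 4))
  gm <- compute_growth_map(s0, s1, lin)
  rec <- gm$records
  expect_equal(nrow(rec), 4)
  r1 <- rec[rec$parent_label == 1, ]
  expect_equal(r1$n_daughters, 2L)
  expect_equal(r1$area_expansion_pct, 0)     # two half-cells: same total
  hm <- gm$heat_map
  expect_setequal(hm$label, c(5L, 6L, 2L, 3L, 4L))
  expect_equal(hm$area_expansion_pct[hm$label == 5],
               hm$area_expansion_pct[hm$label == 6])
})

test_that("junction-based and area-based growth agree on simulated tissue", {
  dom <- rect_domain(50, 50)
  s <- make_initial_tissue(25, dom, seed = 12)
  spec <- uniform_spec(dom, rate = 0.25, log_anis = log(1.5))
  st <- step_tissue(s, spec, dt = 1, seed = 4)
  gm <- compute_growth_map(s, st$snapshot, st$lineage)
  rec <- gm$records[!is.na(gm$records$lambda_max), ]
  expect_gt(nrow(rec), 15)
  # det(A) consistency within 5%
  expect_true(all(abs(rec$lambda_max * rec$lambda_min /
                        (1 + rec$area_expansion_pct / 100) - 1) < 0.05))
  # imposed uniform anisotropy ratio 1.5 recovered in the median
  expect_gt(median(rec$anisotropy), 1.45)
  expect_lt(median(rec$anisotropy), 1.55)
})
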