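test_that("compose: two-map chain and single-map identity", {
  l1 <- lineage_map(0, 1, c("2" = 1))          # c -> b
  l2 <- lineage_map(1, 2, c("3" = 2))          # b -> a
  comp <- compose_lineages(list(l1, l2))
  expect_equal(comp$parent_of, c("3" = 1L))
  expect_equal(c(comp$t0, comp$t1), c(0, 2))
  solo <- compose_lineages(list(l1))
  expect_equal(solo$parent_of, l1$parent_of)
  expect_error(compose_lineages(list(l2, l1)), "do not chain")
})

test_that("compose matches a step-by-step dictionary walk on random chains", {
  set.seed(42)
  n_lab <- 100L
  maps <- list()
  labels <- seq_len(n_lab)
  for (k in 1:5) {
    # each label maps to a random parent from the previous generation;
    # a few children are orphaned (missing parent) to exercise reporting
    parents <- sample(labels, n_lab, replace = TRUE)
    kids <- labels + k * 1000L
    keep <- runif(n_lab) > 0.05
    maps[[k]] <- lineage_map(k - 1, k,
                             stats::setNames(parents[keep], kids[keep]))
    labels <- kids
  }
  comp <- compose_lineages(maps)
  # oracle: walk each final child back through the chain by lookup
  walk <- function(child) {
    cur <- child
    for (k in 5:1) {
      cur <- maps[[k]]$parent_of[as.character(cur)]
      if (is.na(cur)) return(NA_integer_)
      cur <- unname(cur)
    }
    cur
  }
  finals <- names(maps[[5]]$parent_of)
  oracle <- vapply(finals, walk, integer(1))
  oracle <- oracle[!is.na(oracle)]
  expect_identical(comp$parent_of[names(oracle)], oracle)
  expect_setequal(names(comp$parent_of), names(oracle))
})

test_that("composition is associative", {
  set.seed(7)
  mk <- function(t0, t1, off) {
    kids <- seq_len(40) + off
    lineage_map(t0, t1, stats::setNames(sample(seq_len(40) + off - 100,
                                               40, replace = TRUE), kids))
  }
  l1 <- mk(0, 1, 100); l2 <- mk(1, 2, 200); l3 <- mk(2, 3, 300)
  left <- compose_lineages(list(compose_lineages(list(l1, l2)), l3))
  right <- compose_lineages(list(l1, compose_lineages(list(l2, l3))))
  expect_equal(left$parent_of, right$parent_of)
})

test_that("reverse_trace assigns descendants' region, flags disagreement", {
  l <- lineage_map(0, 1, c("10" = 7, "11" = 7, "12" = 8, "13" = 8))
  sect <- reverse_trace(c("10" = "valve", "11" = "valve",
                          "12" = "style", "13" = "valve"), l)
  expect_equal(sect[["7"]], "valve")
  expect_equal(sect[["8"]], "mixed")
  expect_equal(attr(sect, "mixed"), "8")
})

test_that("reverse then forward propagation is the identity on non-mixed lineages", {
  sim <- gyn_series()
  last <- sim$snapshots[[length(sim$snapshots)]]
  late <- regions_of(last)
  sect <- reverse_trace(late, sim$lineages, late_snapshot = last)
  expect_length(attr(sect, "mixed"), 0)      # regions are inherited: exclusive
  fwd <- forward_propagate(sect, sim$lineages)
  expect_identical(fwd[names(fwd)], late[names(fwd)])
  # early sectors match the t0 region tags
  t0reg <- regions_of(sim$snapshots[[1]])
  expect_identical(unname(sect[names(sect)]),
                   unname(t0reg[names(sect)]))
})

test_that("reverse_trace checks late labels against the snapshot", {
  l <- lineage_map(0, 1, c("10" = 7))
  s1 <- grid4_snapshot(1)
  expect_error(reverse_trace(c("77" = "valve"), l, late_snapshot = s1),
               "absent")
})

test_that("proliferation counts daughters; vanished parents flagged", {
  l <- lineage_map(0, 1, c("4" = 1, "5" = 1, "6" = 2))
  expect_equal(as.integer(proliferation(l, 1)), 2L)
  expect_equal(as.integer(proliferation(l, 2)), 1L)
  v <- proliferation(l, 3)
  expect_equal(as.integer(v), 0L)
  expect_true(attr(v, "vanished"))
})

test_that("per-interval daughter totals equal persisting + divided cells", {
  sim <- gyn_series()
  for (k in seq_along(sim$lineages)) {
    lm <- sim$lineages[[k]]
    n1 <- length(sim$snapshots[[k + 1]]$cells)
    expect_equal(length(lm$parent_of), n1)   # the simulator loses no cells
    counts <- table(lm$parent_of)
    expect_equal(sum(counts), n1)
    expect_true(all(counts >= 1))
  }
})
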