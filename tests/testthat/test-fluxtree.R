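test_that("build: root equals the sum of the values", {
  expect_equal(flux_tree_root(flux_tree(c(1, 2, 3, 4))), 10)
  expect_equal(flux_tree_root(flux_tree(numeric())), 0)
  set.seed(5)
  v <- runif(1000) * 10
  t <- flux_tree(v)
  expect_equal(flux_tree_root(t), sum(v), tolerance = 1e-12)
  expect_error(flux_tree(c(1, -2)), "negative")
})

test_that("update touches only the leaf-to-root path and restores exactly", {
  v <- c(0.5, 1.5, 2.5, 3.5, 4.5)
  t <- flux_tree(v)
  r0 <- flux_tree_root(t)
  flux_tree_update(t, 3, 0)
  flux_tree_update(t, 3, 2.5)
  expect_identical(flux_tree_root(t), r0)
  nodes <- flux_tree_update(t, 2, 9)
  expect_lte(nodes, ceiling(log2(rnakinetics:::rk_ftree_capacity(t$ptr))) + 1)
  expect_equal(flux_tree_root(t), sum(v) - 1.5 + 9, tolerance = 1e-12)
  expect_error(flux_tree_update(t, 6, 1), "dead or invalid")
  expect_error(flux_tree_update(t, 0, 1), "dead or invalid")
})

test_that("selection: worked examples and boundary conventions", {
  t <- flux_tree(c(1, 2, 3))
  s <- flux_tree_select(t, 4.5)
  expect_equal(s$slot, 3)
  expect_equal(s$remainder, 1.5)
  # target 0 -> first non-empty slot with remainder 0
  t2 <- flux_tree(c(0, 0, 2, 1))
  s2 <- flux_tree_select(t2, 0)
  expect_equal(s2$slot, 3)
  expect_equal(s2$remainder, 0)
  expect_error(flux_tree_select(t, 6), "outside")
  expect_error(flux_tree_select(t, -1), "outside")
})

test_that("selection matches the linear-scan oracle on random tables", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(2:200, 1)
    v <- round(runif(n, 0, 5), 3)
    v[sample(n, n %/% 3)] <- 0
    if (sum(v) == 0) v[1] <- 1
    t <- flux_tree(v)
    cum <- cumsum(v)
    for (x in c(seq(0, sum(v) - 1e-9, length.out = 41))) {
      s <- flux_tree_select(t, x)
      slot_ref <- which(cum > x)[1]
      expect_identical(s$slot, as.integer(slot_ref))
      expect_equal(s$remainder, x - c(0, cum)[slot_ref], tolerance = 1e-9)
      expect_lt(s$remainder, v[s$slot] + 1e-12)
      expect_gte(s$remainder, 0)
    }
  }
})

test_that("selection frequencies match flux weights", {
  v <- c(0.2, 1.3, 0, 2.5, 1.0)
  t <- flux_tree(v)
  set.seed(23)
  n <- 1e5
  draws <- vapply(runif(n) * sum(v),
                  function(x) flux_tree_select(t, x)$slot, 1L)
  obs <- tabulate(draws, nbins = 5)
  p <- v / sum(v)
  for (k in which(v > 0)) {
    sg <- sqrt(n * p[k] * (1 - p[k]))
    expect_lt(abs(obs[k] - n * p[k]), 4 * sg + 1)
  }
  expect_equal(obs[3], 0L)
})

test_that("root stays equal to the leaf sum under arbitrary updates", {
  set.seed(31)
  n <- 300
  v <- runif(n)
  t <- flux_tree(v)
  for (k in 1:2000) {
    i <- sample(n, 1)
    v[i] <- if (runif(1) < 0.3) 0 else runif(1) * 10
    flux_tree_update(t, i, v[i])
  }
  expect_equal(flux_tree_root(t), sum(v),
               tolerance = 1e-12 * max(1, sum(v)))
  expect_equal(flux_tree_leaves(t), v)
})
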