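test_that("population kinetics: fractions normalise and start denatured", {
  trs <- lapply(1:20, function(k)
    simulate_folding(HP20, t_max = 10, seed = k, par = PAR,
                     record = "events"))
  grid <- seq(0, 10, length.out = 21)
  open <- strrep(".", 20)
  pk <- population_kinetics(trs, grid, tracked = open)
  expect_equal(pk$S1[1], 1)                       # all start open
  expect_equal(pk$S1 + pk$other, rep(1, 21), tolerance = 1e-12)
  # no tracked structures: everything is "other"
  pk0 <- population_kinetics(trs, grid)
  expect_equal(pk0$other, rep(1, 21))
  expect_error(population_kinetics(list(), grid), "empty")
})

test_that("piecewise-constant sampling is right-continuous", {
  tr <- simulate_folding(HP20, t_max = 5, seed = 3, par = PAR,
                         record = "events")
  # at exactly an event time the new state holds
  t_evt <- tr$time[2]
  pk <- population_kinetics(list(tr), t_evt, tracked = tr$db[2])
  expect_equal(pk$S1, 1)
})

test_that("ensemble kinetics agrees with trajectory-level bookkeeping", {
  grid <- c(0, 1, 5, 20)
  ek <- ensemble_kinetics(HP20, grid, tracked = strrep(".", 20),
                          n_traj = 50, seed = 9, par = PAR)
  expect_equal(ek$S1[1], 1)
  expect_equal(ek$S1 + ek$other, rep(1, 4), tolerance = 1e-12)
})

test_that("FPT histogram conserves counts and handles censoring", {
  times <- c(10^runif(200, -2, 2), NA, NA)
  h <- fpt_histogram(times, n_bins = 25)
  expect_equal(sum(h$count), 200)
  expect_equal(attr(h, "censored"), 2)
  expect_equal(sum(h$count) + attr(h, "censored"), length(times))
  # identical times occupy a single bin
  h1 <- fpt_histogram(rep(3.5, 40), n_bins = 10)
  expect_equal(sum(h1$count > 0), 1L)
  expect_equal(sum(h1$count), 40)
  expect_error(fpt_histogram(c(NA_real_, NA_real_)), "no uncensored")
  expect_error(fpt_histogram(c(-1, 2)), "positive")
})

test_that("2-state FPT histogram is consistent with the exponential law", {
  s <- "GAAAC"
  kf <- enumerate_loop_moves(open_chain(s), PAR, RATES)$rate[1]
  fp <- first_passage_times(s, "(...)", t_cap = Inf, n_traj = 1000,
                            seed = 6, par = PAR)
  h <- fpt_histogram(fp$time, n_bins = 12)
  # expected counts from the exponential law on the log10 bins
  p <- stats::pexp(10^h$upper, kf) - stats::pexp(10^h$lower, kf)
  expd <- 1000 * p / sum(p)
  keep <- expd >= 5
  chi <- sum((h$count[keep] - expd[keep])^2 / expd[keep])
  expect_lt(chi, stats::qchisq(0.999, df = sum(keep) - 1))
})
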