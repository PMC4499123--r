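test_that("trajectories are bit-reproducible for a fixed seed", {
  a <- simulate_folding(HP20, t_max = 30, seed = 77, par = PAR,
                        record = "events")
  b <- simulate_folding(HP20, t_max = 30, seed = 77, par = PAR,
                        record = "events")
  expect_identical(a$time, b$time)
  expect_identical(a$db, b$db)
  c <- simulate_folding(HP20, t_max = 30, seed = 78, par = PAR,
                        record = "events")
  expect_false(identical(a$time, c$time))
})

test_that("a zero horizon returns only the initial state", {
  tr <- simulate_folding(HP20, t_max = 0, seed = 1, par = PAR)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$time, 0)
  expect_equal(tr$db, strrep(".", 20))
})

test_that("a state with a single available move fires it with certainty", {
  # GAAAC admits exactly one pair (1,5): the first event is forced
  for (seed in 1:5) {
    tr <- simulate_folding("GAAAC", t_max = Inf, seed = seed,
                           record = "events", max_steps = 1)
    expect_equal(tr$db[2], "(...)")
  }
})

test_that("waiting times: tau * Phi is Exp(1)", {
  tr <- simulate_folding(HP20, t_max = Inf, seed = 13, par = PAR,
                         record = "ends", max_steps = 2e4,
                         collect_tau = TRUE)
  tp <- attr(tr, "tau_phi")
  expect_equal(length(tp), 2e4)
  ks <- suppressWarnings(stats::ks.test(tp, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("two-state toy: folded fraction matches the Boltzmann ratio", {
  # GAAAC has exactly two structures; long-run occupancy of the folded
  # state must equal its Boltzmann weight
  s <- "GAAAC"
  expect_equal(length(enumerate_structures(s)), 2L)
  bd <- boltzmann_distribution(s, par = PAR)
  p_fold <- bd$prob[bd$db == "(...)"]
  tr <- simulate_folding(s, t_max = Inf, seed = 4, par = PAR,
                         record = "events", max_steps = 4e4)
  w <- diff(c(tr$time, attr(tr, "t_final")))
  occ <- sum(w[tr$db == "(...)"]) / sum(w)
  # Monte Carlo error: ~2e4 folding/unfolding cycles
  expect_lt(abs(occ - p_fold), 0.02)
})

test_that("long-run state occupancies match Boltzmann on a 10-nt toy", {
  toy <- "GGAGUUCUCC"
  bd <- boltzmann_distribution(toy, par = PAR)
  tr <- simulate_folding(toy, t_max = Inf, seed = 3, par = PAR,
                         record = "events", max_steps = 2e5)
  w <- diff(c(tr$time, attr(tr, "t_final")))
  occ <- tapply(w, factor(tr$db, levels = bd$db), sum)
  occ[is.na(occ)] <- 0
  occ <- occ / sum(w)
  expect_lt(max(abs(occ - bd$prob)), 0.01)
  # chi-square over all visited states
  keep <- bd$prob > 5e-4
  chi <- sum((occ[keep] - bd$prob[keep])^2 / bd$prob[keep])
  expect_lt(chi, 0.01)
})

test_that("the ensemble sampler preserves the equilibrium distribution", {
  toy <- "GGAGUUCUCC"
  bd <- boltzmann_distribution(toy, par = PAR)
  set.seed(8)
  inits <- sample(bd$db, 3000, replace = TRUE, prob = bd$prob)
  fin <- simulate_ensemble(toy, t_max = 40, n_traj = 3000, seed = 99,
                           initial = inits, par = PAR)
  occ <- as.numeric(table(factor(fin, levels = bd$db))) / 3000
  tv <- 0.5 * sum(abs(occ - bd$prob))
  expect_lt(tv, 0.035)
})

test_that("first-passage times behave as expected", {
  # target = initial open chain: passage time 0
  fp0 <- first_passage_times(HP20, strrep(".", 20), t_cap = 10,
                             n_traj = 3, seed = 1, par = PAR)
  expect_equal(fp0$time, c(0, 0, 0))
  expect_false(any(fp0$censored))
  # 2-state toy: FPT to the folded state is Exp(k_forward)
  s <- "GAAAC"
  mv <- enumerate_loop_moves(open_chain(s), PAR, RATES)
  kf <- mv$rate[1]
  fp <- first_passage_times(s, "(...)", t_cap = Inf, n_traj = 600,
                            seed = 21, par = PAR)
  expect_false(any(fp$censored))
  ks <- suppressWarnings(stats::ks.test(fp$time, "pexp", kf))
  expect_gt(ks$p.value, 0.01)
  # reproducible under a fixed seed
  fp2 <- first_passage_times(s, "(...)", t_cap = Inf, n_traj = 600,
                             seed = 21, par = PAR)
  expect_identical(fp$time, fp2$time)
})

test_that("lockstep: incremental and naive engines agree event by event", {
  res <- lockstep_check("GGAGUUCUCCAAGGCUAAGC", 2000, seed = 5,
                        par = PAR, verify_cache = TRUE, verify_every = 10)
  expect_true(res$ok)
  expect_equal(res$steps, 2000)
  expect_equal(res$max_flux_reldiff, 0)
})

test_that("trajectory times are strictly increasing", {
  tr <- simulate_folding(HP20, t_max = 20, seed = 41, par = PAR,
                         record = "events")
  expect_true(all(diff(tr$time) > 0))
  expect_true(attr(tr, "reason") %in%
                c("max_time", "target_reached", "no_moves", "max_steps"))
})

test_that("no-move sequences terminate cleanly", {
  tr <- simulate_folding("AAAA", t_max = 5, seed = 1, par = PAR)
  expect_equal(attr(tr, "reason"), "no_moves")
  expect_equal(tr$db[nrow(tr)], "....")
})
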