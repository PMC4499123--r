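test_that("trivial energies: open chain and a single stack step", {
  expect_equal(structure_energy("AAAAAAAA", "........", PAR), 0)
  # adding one stacked pair on a hairpin contributes exactly the
  # tabulated 5'GG/3'CC stack step (-3.30 kcal/mol): the enclosed hairpin
  # face (loop sequence GAAAAC) is identical in both structures
  e_stacked <- structure_energy("GGAAAACC", "((....))", PAR)
  e_hairpin <- structure_energy("GAAAAC", "(....)", PAR)
  expect_equal(e_stacked - e_hairpin, -3.30)
})

test_that("per-loop energies are additive to the structure energy", {
  for (x in random_states(20, seed0 = 8000)) {
    le <- loop_energies(x, PAR)
    expect_equal(sum(le$energy), structure_energy(x, par = PAR),
                 tolerance = 1e-12)
  }
})

test_that("move delta G equals full recomputation", {
  for (x in random_states(15, n_range = 12:40, seed0 = 8100)) {
    mv <- enumerate_loop_moves(x, PAR, RATES)
    if (nrow(mv) == 0) next
    e0 <- structure_energy(x, par = PAR)
    for (i in sample(nrow(mv), min(12, nrow(mv)))) {
      y <- apply_move(x, mv[i, ])
      expect_equal(mv$dG[i], structure_energy(y, par = PAR) - e0,
                   tolerance = 1e-9)
      expect_equal(move_delta_g(x, mv[i, ], PAR), mv$dG[i],
                   tolerance = 1e-12)
    }
  }
})

test_that("energies telescope along a trajectory", {
  tr <- simulate_folding(HP20, t_max = 50, seed = 2, par = PAR,
                         record = "events")
  recomputed <- structure_energies(HP20, tr$db, PAR)
  expect_equal(tr$energy, recomputed, tolerance = 1e-6)
})

test_that("evaluator agrees with an independent Turner-99 implementation", {
  # cross-check against the pre-installed reference evaluator (RNAeval,
  # single-base dangle convention, linear multiloops) on the hairpin
  # benchmark ensemble and on random folds of a longer sequence
  dbs <- enumerate_structures(HP20)
  set.seed(3)
  dbs <- dbs[sample(length(dbs), 400)]
  mine <- structure_energies(HP20, dbs, PAR_LIN)
  ref <- rnaeval_d1(HP20, dbs)
  expect_lt(max(abs(mine - ref)), 0.011)

  s <- random_rna_sequence(70, 0.55, seed = 99)
  dbs2 <- vapply(1:25, function(k)
    random_structure(s, seed = k, walk_steps = 300)$db, "")
  mine2 <- structure_energies(s, dbs2, PAR_LIN)
  ref2 <- rnaeval_d1(s, dbs2)
  expect_lt(max(abs(mine2 - ref2)), 0.011)
})

test_that("temperature only rescales beta, not the tables", {
  p2 <- energy_parameters(temperature = 330)
  expect_equal(structure_energy("GGGGAAACCCC", "((((...))))", p2),
               structure_energy("GGGGAAACCCC", "((((...))))", PAR))
  expect_equal(p2$rt, 0.0019872 * 330)
})

test_that("logarithmic and linear multiloop modes differ only for large loops", {
  # multiloop with few unpaired nucleotides: identical energies
  db <- "((((...))((...))))"
  sq <- "GGGGAAACCGGAAACCCC"
  expect_equal(structure_energy(sq, db, PAR), structure_energy(sq, db, PAR_LIN))
  # many unpaired nucleotides: the logarithmic growth term kicks in
  db2 <- "(((....((...))....((...))....)))"
  sq2 <- "GGGAAAAGGAAACCAAAAGGAAACCAAAACCC"
  e_log <- structure_energy(sq2, db2, PAR)
  e_lin <- structure_energy(sq2, db2, PAR_LIN)
  expect_false(isTRUE(all.equal(e_log, e_lin)))
})
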