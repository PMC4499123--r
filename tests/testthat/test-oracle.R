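test_that("enumeration base cases", {
  expect_equal(enumerate_structures("AAAA"), "....")
  expect_equal(count_structures("AAAA"), 1)
  # two-state sequence
  expect_setequal(enumerate_structures("GAAAC"), c(".....", "(...)"))
})

test_that("two independent enumerators agree on random sequences", {
  set.seed(12)
  for (k in 1:12) {
    s <- random_rna_sequence(sample(6:16, 1), runif(1, 0.2, 0.8),
                             seed = 600 + k)
    dbs <- enumerate_structures(s)
    expect_equal(length(dbs), count_structures(s))
    expect_equal(anyDuplicated(dbs), 0L)
  }
  expect_equal(length(enumerate_structures("GGGAAAACCC")),
               count_structures("GGGAAAACCC"))
})

test_that("enumeration refuses long sequences", {
  expect_error(enumerate_structures(strrep("GACU", 10)), "too long")
})

test_that("the ensemble is closed under the move set and connected", {
  s <- "GGAGUUCUCC"
  dbs <- enumerate_structures(s)
  idx <- stats::setNames(seq_along(dbs), dbs)
  # closure: every move from every structure lands inside the ensemble;
  # connectivity: BFS from the open chain reaches every structure
  adj <- vector("list", length(dbs))
  for (i in seq_along(dbs)) {
    x <- parse_dot_bracket(dbs[i], s)
    mv <- enumerate_loop_moves(x, PAR, RATES)
    if (nrow(mv) == 0) { adj[[i]] <- integer(); next }
    nbr <- vapply(seq_len(nrow(mv)),
                  function(r) apply_move(x, mv[r, ])$db, "")
    expect_true(all(nbr %in% dbs))
    adj[[i]] <- unname(idx[nbr])
  }
  seen <- rep(FALSE, length(dbs))
  queue <- idx[[strrep(".", nchar(s))]]
  seen[queue] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    nxt <- adj[[cur]][!seen[adj[[cur]]]]
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  expect_true(all(seen))
})

test_that("Boltzmann distribution limits", {
  one <- boltzmann_distribution("AAAA", par = PAR)
  expect_equal(one$prob, 1)
  # equal energies -> uniform (use explicit ensemble of open chains)
  bd <- boltzmann_distribution("AAAAAA", dbs = c("......"), par = PAR)
  expect_equal(bd$prob, 1)
  bd2 <- boltzmann_distribution(HP20, par = PAR)
  expect_equal(sum(bd2$prob), 1, tolerance = 1e-12)
  expect_true(!is.unsorted(bd2$energy))
})

test_that("brute-force neighbourhood size is bounded by N^2", {
  for (x in random_states(6, n_range = 20:40, seed0 = 9600)) {
    b <- bruteforce_neighbors(x, PAR, RATES)
    expect_lte(nrow(b), nchar(x$seq)^2)
  }
})
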