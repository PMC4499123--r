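test_that("Kawasaki rate closed forms", {
  expect_equal(kawasaki_rate(0, k0 = 1, beta = 1), 1)
  expect_equal(kawasaki_rate(0, k0 = 3.7, beta = 2), 3.7)
  # beta dG = 2 ln 2  ->  rate k0 / 2
  expect_equal(kawasaki_rate(2 * log(2), k0 = 1, beta = 1), 0.5)
  # forward/backward ratio is exp(-beta dG) for any dG
  for (dG in c(-3.2, -0.1, 0.7, 5)) {
    r <- kawasaki_rate(dG, 1, BETA) / kawasaki_rate(-dG, 1, BETA)
    expect_equal(r, exp(-BETA * dG), tolerance = 1e-12)
  }
})

test_that("nucleation rates follow loop-closure scaling and balance", {
  x <- open_chain("GGGAAAAAAACCC")
  mv <- enumerate_loop_moves(x, PAR, RATES)
  expect_true(all(mv$kind == "nucleation"))
  # forward rate = k0_nuc * n^(-alpha), non-increasing in n
  expect_equal(mv$rate, mv$nucn^(-RATES$alpha), tolerance = 1e-12)
  ord <- order(mv$nucn)
  expect_true(all(diff(mv$rate[ord]) <= 1e-12))
  # nucleation_rate() agrees and satisfies detailed balance
  nr <- nucleation_rate(x, mv$ai[1], mv$aj[1], RATES, PAR)
  expect_equal(nr$forward, mv$rate[1])
  y <- apply_move(x, mv[1, ])
  mv2 <- enumerate_loop_moves(y, PAR, RATES)
  inv <- mv2[mv2$ri == mv$ai[1] & mv2$rj == mv$aj[1] &
             mv2$ai == 0 & mv2$aj == 0, ]
  expect_equal(nr$backward, inv$rate, tolerance = 1e-12)
  expect_equal(inv$rate / nr$forward, exp(BETA * mv$dG[1]),
               tolerance = 1e-9)
})

test_that("a two-loop hairpin state has 5 moves partitioned 2 and 3", {
  x <- parse_dot_bracket("((.....)).", "GGUACAAUUC")
  lp <- decompose_loops(x)
  expect_equal(nrow(lp), 2L)
  mv <- enumerate_loop_moves(x, PAR, RATES)
  expect_equal(nrow(mv), 5L)
  counts <- table(paste(mv$owner_i, mv$owner_j))
  expect_setequal(as.integer(counts), c(2L, 3L))
  # partial fluxes per loop sum to the total flux
  fluxes <- tapply(mv$rate, paste(mv$owner_i, mv$owner_j), sum)
  expect_equal(sum(fluxes), loop_flux(mv))
})

test_that("open chain produces only nucleation moves with correct count", {
  s <- "GGAGUUCUCC"
  x <- open_chain(s)
  mv <- enumerate_loop_moves(x, PAR, RATES)
  expect_true(all(mv$kind == "nucleation"))
  # count = valid canonical pairs at distance >= 4
  cnt <- 0
  b <- strsplit(s, "")[[1]]
  canon <- c("GC", "CG", "AU", "UA", "GU", "UG")
  for (i in 1:(nchar(s) - 4)) for (j in (i + 4):nchar(s))
    if (paste0(b[i], b[j]) %in% canon) cnt <- cnt + 1
  expect_equal(nrow(mv), cnt)
})

test_that("loop_flux sums rates and is 0 for an empty list", {
  expect_equal(loop_flux(data.frame(rate = c(1, 2))), 3)
  expect_equal(loop_flux(data.frame(rate = numeric())), 0)
})

test_that("per-loop partition equals the brute-force neighbourhood", {
  for (x in random_states(25, n_range = 10:45, seed0 = 9000)) {
    a <- enumerate_loop_moves(x, PAR, RATES)
    b <- bruteforce_neighbors(x, PAR, RATES)
    expect_identical(move_key(a), move_key(b))
    ao <- a[order(a$ri, a$rj, a$ai, a$aj), ]
    bo <- b[order(b$ri, b$rj, b$ai, b$aj), ]
    expect_equal(ao$rate, bo$rate, tolerance = 1e-12)
    expect_equal(ao$dG, bo$dG, tolerance = 1e-12)
    # ownership is unique: no move owned by two loops
    expect_equal(anyDuplicated(move_key(a)), 0L)
    # total move count bounded by N^2
    expect_lte(nrow(a), nchar(x$seq)^2)
  }
})

test_that("every move is reversible with detailed-balance rates", {
  for (x in random_states(10, n_range = 10:30, seed0 = 9100)) {
    mv <- enumerate_loop_moves(x, PAR, RATES)
    if (nrow(mv) == 0) next
    for (i in sample(nrow(mv), min(8, nrow(mv)))) {
      y <- apply_move(x, mv[i, ])
      mv2 <- enumerate_loop_moves(y, PAR, RATES)
      inv <- mv2[mv2$ri == mv$ai[i] & mv2$rj == mv$aj[i] &
                 mv2$ai == mv$ri[i] & mv2$aj == mv$rj[i], ]
      expect_equal(nrow(inv), 1L)
      expect_equal(mv$rate[i] / inv$rate, exp(-BETA * mv$dG[i]),
                   tolerance = 1e-9)
      expect_equal(inv$dG, -mv$dG[i], tolerance = 1e-9)
    }
  }
})

test_that("shift moves remove one pair and add one sharing an endpoint", {
  for (x in random_states(8, n_range = 15:35, seed0 = 9200)) {
    mv <- enumerate_loop_moves(x, PAR, RATES)
    sh <- mv[mv$kind %in% c("morph", "defect_diffusion"), ]
    if (nrow(sh) == 0) next
    shared <- (sh$ai == sh$ri) + (sh$ai == sh$rj) +
      (sh$aj == sh$ri) + (sh$aj == sh$rj)
    expect_true(all(shared == 1))
    dd <- sh[sh$kind == "defect_diffusion", ]
    if (nrow(dd)) {
      moved_from <- ifelse(dd$ai == dd$ri | dd$aj == dd$ri, dd$rj, dd$ri)
      moved_to <- ifelse(dd$ai == dd$ri | dd$ai == dd$rj, dd$aj, dd$ai)
      expect_true(all(abs(moved_to - moved_from) == 1))
    }
  }
})
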