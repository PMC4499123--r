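test_that("dot-bracket parsing handles the basic cases and round-trips", {
  x <- parse_dot_bracket("....................", HP20)
  expect_equal(sum(x$pt), 0)

  x <- parse_dot_bracket("((((...))))", "GGGGAAACCCC")
  expect_equal(x$pt[1:4], c(11L, 10L, 9L, 8L))
  expect_equal(write_dot_bracket(x), "((((...))))")

  expect_equal(write_dot_bracket(open_chain("AAAAA")), ".....")

  # round-trip on random valid structures
  for (x in random_states(15, seed0 = 7000)) {
    expect_identical(parse_dot_bracket(x$db, x$seq)$pt, x$pt)
  }
})

test_that("invalid structures are rejected with position reports", {
  expect_error(parse_dot_bracket("((..))", "GGAACC"), "fewer than 3")
  expect_error(parse_dot_bracket("(....", "GAAAC"), "unbalanced")
  expect_error(parse_dot_bracket("....)", "GAAAC"), "unbalanced")
  expect_error(parse_dot_bracket("(...)", "GAAAG"), "non-canonical")
  expect_error(parse_dot_bracket("...", "GAAAC"), "length")
  expect_error(parse_dot_bracket("..x..", "GAAAC"), "invalid character")
})

test_that("T is converted to U and bad letters rejected", {
  x <- open_chain("GATTACA")
  expect_equal(x$seq, "GAUUACA")
  expect_error(open_chain("GANNAC"), "invalid RNA letter")
})

test_that("loop decomposition reproduces the canonical 45-nt example", {
  # three helices pairing 2-5 with 40-37, 8-11 with 19-16, 23-26 with 34-31:
  # a multibranch loop closed by (5,37) carrying two hairpins, plus the
  # external loop labelled (45,1) with members {1, 41..45}
  db <- paste0(".((((..((((....))))...((((....))))..))))",
               ".....")
  seq <- paste0("A", "GGGG", "AA", "GGGG", "AAAA", "CCCC", "AAA",
                "GGGG", "AAAA", "CCCC", "AA", "CCCC", "AAAAA")
  x <- parse_dot_bracket(db, seq)
  lp <- decompose_loops(x)
  labs <- sprintf("(%d,%d)", lp$i, lp$j)
  expect_setequal(labs, c("(5,37)", "(11,16)", "(26,31)", "(45,1)"))
  expect_equal(attr(lp, "n_loops"), 4L)
  ext <- lp[lp$external, ]
  expect_equal(sort(ext$members[[1]]), c(1L, 41L, 42L, 43L, 44L, 45L))
  expect_equal(lp$degree[match("(5,37)", labs)], 3L)
  expect_equal(lp$degree[match("(11,16)", labs)], 1L)
})

test_that("open chain decomposes into a single external loop", {
  for (n in c(1, 5, 12)) {
    x <- open_chain(strrep("A", n))
    lp <- decompose_loops(x)
    expect_equal(nrow(lp), 1L)
    expect_true(lp$external)
    expect_equal(lp$degree, 0L)
    expect_equal(lp$members[[1]], seq_len(n))
  }
})

test_that("a 5'-3' closing pair yields both an internal and external loop", {
  # pair (1,N): the external loop (N,1) coexists with element (1,N)
  x <- parse_dot_bracket("(......)", "GAAAAAAC")
  lp <- decompose_loops(x)
  expect_equal(nrow(lp), 2L)
  expect_true(any(lp$external))
  int <- lp[!lp$external, ]
  expect_equal(c(int$i, int$j), c(1L, 8L))
  expect_equal(length(lp$members[[which(lp$external)]]), 0L)
})

test_that("every nucleotide belongs to a loop; pairs border two loops", {
  for (x in random_states(10, seed0 = 7100)) {
    lp <- decompose_loops(x)
    n <- nchar(x$seq)
    ss <- sort(unlist(lp$members))
    expect_equal(ss, which(x$pt == 0))  # unpaired members partition
    # each branch pair appears in exactly one parent loop
    brs <- do.call(rbind, lp$branches)
    if (!is.null(brs) && nrow(brs)) {
      expect_equal(anyDuplicated(paste(brs[, 1], brs[, 2])), 0L)
    }
  }
})

test_that("incremental update equals re-decomposition for every move", {
  # apply each available move to random states; the new structure must be
  # valid and its decomposition consistent with the incremental claim
  for (x in random_states(12, n_range = 12:35, seed0 = 7200)) {
    mv <- enumerate_loop_moves(x, PAR, RATES)
    if (nrow(mv) == 0) next
    for (i in sample(nrow(mv), min(10, nrow(mv)))) {
      y <- apply_move(x, mv[i, ])     # re-validates internally
      expect_s3_class(y, "rna_structure")
      # inverse restores the original structure exactly
      mv2 <- enumerate_loop_moves(y, PAR, RATES)
      inv <- mv2[mv2$ri == mv$ai[i] & mv2$rj == mv$aj[i] &
                 mv2$ai == mv$ri[i] & mv2$aj == mv$rj[i], ]
      expect_equal(nrow(inv), 1L)
      z <- apply_move(y, inv)
      expect_identical(z$pt, x$pt)
    }
  }
})

test_that("loop count grows at most linearly with sequence length", {
  set.seed(11)
  for (n in c(30, 60, 120)) {
    s <- random_rna_sequence(n, 0.5, seed = n + 3)
    x <- random_structure(s, seed = n, walk_steps = 400)
    expect_lte(nrow(decompose_loops(x)), n)
  }
})
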