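test_that("bundled fixtures are valid", {
  expect_equal(nchar(HP20), 20L)
  expect_equal(HP20, "UUGCUAAGCAACCAUUGGUU")
  sl <- example_rna("sl56")
  expect_equal(nchar(sl), 56L)
  sts <- attr(sl, "structures")
  expect_equal(length(sts), 2L)
  for (d in sts) expect_s3_class(parse_dot_bracket(d, sl), "rna_structure")
})

test_that("FASTA reading uses the first record and converts T to U", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "GGATT", "ACA", ">b", "CCCC"), f)
  expect_equal(read_rna_fasta(f), "GGAUUACA")
})

test_that("random sequences are reproducible with stated composition", {
  a <- random_rna_sequence(30, 0.5, seed = 4)
  b <- random_rna_sequence(30, 0.5, seed = 4)
  expect_identical(a, b)
  expect_equal(nchar(random_rna_sequence(1, 0.5, seed = 1)), 1L)
  # composition within 4 sigma
  s <- random_rna_sequence(20000, 0.3, seed = 10)
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 6000), 4 * sqrt(20000 * 0.3 * 0.7))
  # gc_bias 0: no G or C at all
  expect_false(grepl("[GC]", random_rna_sequence(500, 0, seed = 2)))
})

test_that("random structures always satisfy the invariants", {
  for (k in 1:40) {
    n <- sample(6:40, 1)
    s <- random_rna_sequence(n, 0.5, seed = 100 + k)
    x <- random_structure(s, seed = k, walk_steps = 150)
    # parse_dot_bracket re-validates; reaching here means valid
    expect_s3_class(x, "rna_structure")
    expect_equal(nchar(x$db), n)
  }
  expect_equal(random_structure("AAAA", seed = 1)$db, "....")
})

test_that("short-sequence draws are uniform over the ensemble", {
  s <- "GGAGUUCUCC"
  dbs <- enumerate_structures(s)
  draws <- vapply(1:2000, function(k) random_structure(s, seed = k)$db, "")
  obs <- table(factor(draws, levels = dbs))
  expd <- 2000 / length(dbs)
  chi <- sum((obs - expd)^2 / expd)
  expect_lt(chi, stats::qchisq(0.999, df = length(dbs) - 1))
})
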