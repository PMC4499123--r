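# Shared model objects: parameter loading reads the bundled tables once.
PAR <- energy_parameters()
PAR_LIN <- energy_parameters(multiloop = "linear")
RATES <- rate_parameters()
BETA <- 1 / PAR$rt

HP20 <- example_rna("hp20")

# a small battery of random (sequence, structure) states
random_states <- function(n_cases, n_range = 15:50, seed0 = 1000,
                          walk_range = 0:250) {
  lapply(seq_len(n_cases), function(k) {
    set.seed(seed0 + k)
    n <- sample(n_range, 1)
    s <- random_rna_sequence(n, 0.5, seed = seed0 + k)
    random_structure(s, seed = seed0 + 500 + k,
                     walk_steps = sample(walk_range, 1), par = PAR,
                     rates = RATES)
  })
}

move_key <- function(df) {
  d <- df[order(df$ri, df$rj, df$ai, df$aj), ]
  paste(d$kind, d$ri, d$rj, d$ai, d$aj, d$nucn, sep = ":")
}

rnaeval_d1 <- function(seq, dbs) {
  # independent Turner-99 evaluator (single-base dangle convention);
  # pre-installed command-line tool used for cross-validation only
  bin <- Sys.which("RNAeval")
  parfile <- normalizePath(file.path(dirname(bin), "..", "share",
                                     "ViennaRNA", "rna_turner1999.par"),
                           mustWork = TRUE)
  input <- tempfile()
  writeLines(as.vector(rbind(seq, dbs)), input)
  out <- system2("RNAeval", c("-P", parfile, "-d1"), stdin = input,
                 stdout = TRUE, stderr = FALSE)
  out <- out[seq(2, length(out), by = 2)]
  as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)$", "\\1", out))
}
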