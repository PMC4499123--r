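#' Bundled example RNAs
#'
#' `"hp20"` is the 20-nt benchmark sequence whose complete ensemble
#' (4127 structures) is small enough for exhaustive enumeration and
#' equilibrium cross-checks.  `"sl56"` is a 56-nt spliced-leader RNA
#' (Leptomonas collosoma) bundled for demonstration of bistable folding;
#' its sequence is entered from the kinetic-folding literature and its
#' two reference stem-loops (attribute `structures`) were pre-computed
#' with an external Turner-99 minimum-free-energy folder, so treat both
#' as illustrative fixtures rather than measured data.
#'
#' @param name `"hp20"` or `"sl56"`.
#' @return the sequence (character scalar); for `"sl56"`, reference
#'   structures in attribute `structures`.
#' @export
example_rna <- function(name = c("hp20", "sl56")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".fasta"),
                      package = "rnakinetics", mustWork = TRUE)
  lines <- readLines(path)
  seq <- paste(lines[!startsWith(lines, ">")], collapse = "")
  seq <- rk_canonical_seq(seq)
  if (name == "sl56") {
    sp <- system.file("extdata", "sl56_structures.txt",
                      package = "rnakinetics", mustWork = TRUE)
    st <- readLines(sp)
    st <- st[!startsWith(st, "#") & nzchar(st)]
    attr(seq, "structures") <- st
  }
  seq
}

#' Read an RNA sequence from a FASTA file
#'
#' Uses Biostrings when available; the first record is used and T is
#' converted to U.
#'
#' @param path FASTA file.
#' @return character sequence.
#' @export
read_rna_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    if (length(ss) == 0) stop("no records in ", path)
    return(rk_canonical_seq(as.character(ss[[1]])))
  }
  lines <- readLines(path)
  seqs <- lines[!startsWith(lines, ">")]
  if (length(seqs) == 0) stop("no records in ", path)
  rk_canonical_seq(paste(seqs, collapse = ""))
}

#' Random RNA sequence
#'
#' I.i.d. letters with a given G+C fraction (G and C equiprobable within
#' it, likewise A and U).
#'
#' @param n length.
#' @param gc_bias target G+C fraction in `[0, 1]`.
#' @param seed RNG seed.
#' @return character sequence of length `n`.
#' @export
random_rna_sequence <- function(n, gc_bias = 0.5, seed = NULL) {
  stopifnot(n >= 1, gc_bias >= 0, gc_bias <= 1)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  p <- c(A = (1 - gc_bias) / 2, C = gc_bias / 2, G = gc_bias / 2,
         U = (1 - gc_bias) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Random secondary structure of a sequence
#'
#' For short sequences (N <= 20) samples uniformly from the exhaustively
#' enumerated ensemble; for longer sequences, performs a random walk of
#' valid elementary moves from the open chain.  Every draw satisfies the
#' structural invariants.
#'
#' @param seq RNA sequence.
#' @param seed RNG seed.
#' @param walk_steps walk length used for long sequences.
#' @param par,rates model parameters used for the long-sequence walk.
#' @return an `rna_structure`.
#' @export
random_structure <- function(seq, seed = NULL, walk_steps = 200,
                             par = energy_parameters(),
                             rates = rate_parameters()) {
  seq <- rk_canonical_seq(seq)
  if (nchar(seq) <= 20) {
    dbs <- enumerate_structures(seq)
    if (!is.null(seed)) {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old))
      set.seed(seed)
    }
    return(parse_dot_bracket(sample(dbs, 1), seq))
  }
  tr <- simulate_folding(seq, t_max = Inf, seed = if (is.null(seed)) 1 else
    seed, par = par, rates = rates, record = "ends",
    max_steps = walk_steps)
  parse_dot_bracket(attr(tr, "final_db"), seq)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
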