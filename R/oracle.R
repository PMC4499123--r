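#' Exhaustively enumerate all secondary structures
#'
#' Generates every pseudoknot-free structure over canonical pairs
#' (G-C, A-U, G-U) with a minimum hairpin of 3 unpaired nucleotides;
#' lonely pairs are allowed and the open chain is included.  Guarded to
#' short sequences (combinatorial growth).
#'
#' @param seq RNA sequence.
#' @param max_n refuse sequences longer than this (default 30).
#' @return character vector of dot-bracket structures, each exactly once.
#' @examples
#' enumerate_structures("GGGAAAACCC")
#' @export
enumerate_structures <- function(seq, max_n = 30) {
  rk_enumerate(rk_canonical_seq(seq), as.integer(max_n))
}

#' Count secondary structures by an independent recursion
#'
#' Memoised interval recursion on the first position, distinct from the
#' last-position recursion used by [enumerate_structures()]; the two must
#' agree, which the test suite asserts.
#'
#' @param seq RNA sequence.
#' @return the number of structures (as a double).
#' @export
count_structures <- function(seq) {
  rk_count_structures(rk_canonical_seq(seq))
}
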