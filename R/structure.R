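#' Parse a dot-bracket secondary structure
#'
#' Validates and converts Vienna dot-bracket notation into a pair table.
#' The structure must be balanced, use only canonical pairs
#' (G-C, A-U, G-U), keep at least 3 unpaired nucleotides in every hairpin
#' loop (`|j - i| >= 4`) and contain no pseudoknots.  Violations raise an
#' error with a position report.
#'
#' @param db dot-bracket string.
#' @param seq RNA sequence (A/C/G/U; T is silently converted to U).
#' @return an `rna_structure`: a list with `seq`, `db` and the integer
#'   pair table `pt` (0 = unpaired, 1-based partners).
#' @examples
#' parse_dot_bracket("((((...))))", "GGGGAAACCCC")
#' @export
parse_dot_bracket <- function(db, seq) {
  seq <- rk_canonical_seq(seq)
  pt <- rk_parse_db(seq, db)
  structure(list(seq = seq, db = db, pt = pt), class = "rna_structure")
}

#' Write a structure as a dot-bracket string
#'
#' Round-trips with [parse_dot_bracket()].
#'
#' @param x an `rna_structure` or an integer pair table.
#' @return dot-bracket string.
#' @export
write_dot_bracket <- function(x) {
  if (inherits(x, "rna_structure")) return(rk_write_db(x$pt))
  rk_write_db(as.integer(x))
}

#' Open-chain structure for a sequence
#' @param seq RNA sequence.
#' @return an `rna_structure` with no pairs.
#' @export
open_chain <- function(seq) {
  seq <- rk_canonical_seq(seq)
  parse_dot_bracket(strrep(".", nchar(seq)), seq)
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(x$seq, "\n", x$db, "\n", sep = "")
  cat(sprintf("N = %d, %d base pairs\n", nchar(x$seq), sum(x$pt > 0) / 2))
  invisible(x)
}

#' Decompose a structure into loop elements
#'
#' Every pseudoknot-free structure decomposes uniquely into loop elements:
#' a loop of unpaired nucleotides and branch closing pairs together with
#' the continuous helix that closes the loop.  Internal elements are
#' labelled by the innermost pair `(i, j)` of their closing helix; the
#' external loop is labelled `(N, 1)`.  The degree `d` counts the base
#' pairs bordering the loop (1 = hairpin, 2 = bulge/interior,
#' >2 = multibranch; the external loop counts only its branches).
#'
#' @param x an `rna_structure`.
#' @return a tibble with one row per loop element (label, degree, member
#'   nucleotides, branches, closing helix extent) and attribute `n_loops`.
#' @examples
#' s <- parse_dot_bracket("((((...))))", "GGGGAAACCCC")
#' decompose_loops(s)
#' @export
decompose_loops <- function(x) {
  stopifnot(inherits(x, "rna_structure"))
  raw <- rk_decompose(x$seq, x$db)
  out <- tibble::tibble(
    i = vapply(raw, `[[`, integer(1), "i"),
    j = vapply(raw, `[[`, integer(1), "j"),
    external = vapply(raw, `[[`, logical(1), "external"),
    degree = vapply(raw, `[[`, integer(1), "degree"),
    helix_length = vapply(raw, `[[`, integer(1), "helix_length"),
    helix_outer_i = vapply(raw, `[[`, integer(1), "helix_outer_i"),
    helix_outer_j = vapply(raw, `[[`, integer(1), "helix_outer_j"),
    members = lapply(raw, `[[`, "members"),
    branches = lapply(raw, `[[`, "branches")
  )
  attr(out, "n_loops") <- nrow(out)
  out
}

#' Apply an elementary move to a structure
#'
#' Applies one move (at most one pair removed and one added) and returns
#' the resulting structure; the result is re-validated, so applying a
#' stale move to the wrong state errors out.
#'
#' @param x an `rna_structure`.
#' @param move a one-row data frame or list with `ri`, `rj`, `ai`, `aj`
#'   (0 where no pair is removed/added), as produced by
#'   [enumerate_loop_moves()].
#' @return the new `rna_structure`.
#' @export
apply_move <- function(x, move) {
  stopifnot(inherits(x, "rna_structure"))
  mv <- as.list(move)[c("ri", "rj", "ai", "aj")]
  mv$kind <- 0L
  res <- rk_apply_move(x$seq, x$db, lapply(mv, as.integer))
  parse_dot_bracket(res$db, x$seq)
}
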