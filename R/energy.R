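#' Free energy of a secondary structure
#'
#' Standard nearest-neighbour evaluation: the energy is the sum over all
#' loops of the structure (stacks, hairpins, bulges, interior loops,
#' multiloops and the exterior loop) under the bundled Turner-99 tables.
#'
#' @param seq RNA sequence.
#' @param db dot-bracket structure (or an `rna_structure` in place of
#'   `seq`, in which case `db` is ignored).
#' @param par parameters from [energy_parameters()].
#' @return free energy in kcal/mol.
#' @examples
#' structure_energy("GGGGAAACCCC", "((((...))))", energy_parameters())
#' @export
structure_energy <- function(seq, db = NULL, par = energy_parameters()) {
  if (inherits(seq, "rna_structure")) {
    db <- seq$db
    seq <- seq$seq
  }
  rk_structure_energy(rk_canonical_seq(seq), db, par_ptr(par))
}

#' Free energies of many structures of one sequence
#' @param seq RNA sequence.
#' @param dbs character vector of dot-bracket structures.
#' @param par parameters from [energy_parameters()].
#' @return numeric vector, kcal/mol.
#' @export
structure_energies <- function(seq, dbs, par = energy_parameters()) {
  rk_structure_energies(rk_canonical_seq(seq), dbs, par_ptr(par))
}

#' Per-loop-element free energies
#'
#' Each loop element contributes the nearest-neighbour energy of the face
#' its label pair closes plus the stacking energies inside its closing
#' helix; these contributions sum exactly to [structure_energy()].
#'
#' @inheritParams decompose_loops
#' @param par parameters from [energy_parameters()].
#' @return tibble with loop labels and `energy` (kcal/mol).
#' @export
loop_energies <- function(x, par = energy_parameters()) {
  stopifnot(inherits(x, "rna_structure"))
  raw <- rk_loop_energies(x$seq, x$db, par_ptr(par))
  tibble::tibble(i = raw$i, j = raw$j, external = raw$external,
                 degree = raw$degree, energy = raw$energy)
}

#' Free-energy difference of a single move
#'
#' Computed locally from the affected loops only (O(1) in the sequence
#' length); equals the full-recompute difference
#' `structure_energy(after) - structure_energy(before)` exactly.
#'
#' @param x an `rna_structure`.
#' @param move move specification (row of [enumerate_loop_moves()]).
#' @param par parameters from [energy_parameters()].
#' @return delta G in kcal/mol.
#' @export
move_delta_g <- function(x, move, par = energy_parameters()) {
  stopifnot(inherits(x, "rna_structure"))
  mv <- as.list(move)[c("ri", "rj", "ai", "aj")]
  mv$kind <- 0L
  rk_move_dG(x$seq, x$db, lapply(mv, as.integer), par_ptr(par))
}

#' Boltzmann equilibrium distribution over an ensemble
#'
#' Scores every structure and converts to probabilities
#' `p_i = exp(-beta G_i) / Z`.
#'
#' @param seq RNA sequence; the ensemble is produced by
#'   [enumerate_structures()] unless `dbs` is given.
#' @param dbs optional character vector of structures to use as ensemble.
#' @param par parameters from [energy_parameters()].
#' @return tibble with `db`, `energy` (kcal/mol) and `prob`, sorted by
#'   increasing energy; the partition function is in attribute `Z`
#'   (relative to the minimum energy).
#' @export
boltzmann_distribution <- function(seq, dbs = NULL,
                                   par = energy_parameters()) {
  seq <- rk_canonical_seq(seq)
  if (is.null(dbs)) dbs <- enumerate_structures(seq)
  en <- structure_energies(seq, dbs, par)
  beta <- 1 / par$rt
  w <- exp(-beta * (en - min(en)))
  p <- w / sum(w)
  ord <- order(en, dbs)
  out <- tibble::tibble(db = dbs[ord], energy = en[ord], prob = p[ord])
  attr(out, "Z") <- sum(w)
  out
}
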