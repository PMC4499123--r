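#' Kawasaki transition rate
#'
#' `k = k0 exp(-beta dG / 2)`: the symmetric rate rule whose
#' forward/backward ratio `exp(-beta dG)` satisfies detailed balance.
#'
#' @param dG free-energy difference of the move, kcal/mol.
#' @param k0 rate prefactor (1/time).
#' @param beta inverse temperature 1/RT in mol/kcal.
#' @return transition rate (1/time).
#' @examples
#' kawasaki_rate(0, k0 = 1, beta = 1)      # = k0
#' @export
kawasaki_rate <- function(dG, k0 = 1, beta = 1 / (0.0019872 * 310.15)) {
  k0 * exp(-beta * dG / 2)
}

#' Nucleation rates for closing a new base pair
#'
#' Forward rate from polymer loop-closure scaling,
#' `k_f = k0_nuc n^(-alpha)`, where `n` is the number of loop elements
#' (unpaired nucleotides and branch pairs) along the enclosed side of the
#' ring between `i` and `j`.  The backward (lone-pair removal) rate is
#' `k_b = k_f exp(+beta dG)` so that detailed balance holds.
#'
#' @param x an `rna_structure` in which `i` and `j` are unpaired members
#'   of the same loop.
#' @param i,j positions of the nucleating pair.
#' @param rates from [rate_parameters()].
#' @param par parameters from [energy_parameters()].
#' @return list with `forward`, `backward`, `n` and `dG` (kcal/mol).
#' @export
nucleation_rate <- function(x, i, j, rates = rate_parameters(),
                            par = energy_parameters()) {
  mv <- enumerate_loop_moves(x, par = par, rates = rates)
  row <- mv[mv$kind == "nucleation" & mv$ai == i & mv$aj == j, ]
  if (nrow(row) != 1)
    stop("positions ", i, ",", j, " are not a nucleation site of this state")
  list(forward = rates$k0_nuc * row$nucn^(-rates$alpha),
       backward = rates$k0_nuc * row$nucn^(-rates$alpha) *
         exp(row$dG / par$rt),
       n = row$nucn, dG = row$dG)
}

move_df_finish <- function(df) {
  out <- tibble::as_tibble(df)
  out$kind <- kind_label(out$kind)
  out
}

#' Enumerate the cached move list of every loop element
#'
#' The six elementary moves of each loop: helix nucleation, extension,
#' retraction (including lone-pair removal), opening of a pair inside the
#' closing helix, helix morphing and defect diffusion.  Each move is owned
#' by exactly one loop element; the union over elements is the complete
#' single-move neighbourhood of the structure.
#'
#' @param x an `rna_structure`.
#' @param par parameters from [energy_parameters()].
#' @param rates from [rate_parameters()].
#' @return tibble of moves with owner labels, `dG` (kcal/mol) and rates.
#' @export
enumerate_loop_moves <- function(x, par = energy_parameters(),
                                 rates = rate_parameters()) {
  stopifnot(inherits(x, "rna_structure"))
  move_df_finish(rk_loop_moves(x$seq, x$db, par_ptr(par), rates_list(rates)))
}

#' Brute-force single-move neighbourhood (oracle)
#'
#' Recomputes the complete neighbourhood by scanning all candidate pair
#' additions, removals and shifts globally with a crossing test, without
#' the loop-element partition.  Used to validate [enumerate_loop_moves()].
#'
#' @inheritParams enumerate_loop_moves
#' @return tibble of moves.
#' @export
bruteforce_neighbors <- function(x, par = energy_parameters(),
                                 rates = rate_parameters()) {
  stopifnot(inherits(x, "rna_structure"))
  move_df_finish(rk_bruteforce_moves(x$seq, x$db, par_ptr(par),
                                     rates_list(rates)))
}

#' Partial flux of a move list
#'
#' The flux of a loop element is the sum of the rates of the moves it
#' owns; the total flux is the sum over elements.
#'
#' @param moves tibble with a `rate` column (possibly empty).
#' @return numeric scalar.
#' @export
loop_flux <- function(moves) {
  if (is.null(moves) || nrow(moves) == 0) return(0)
  sum(moves$rate)
}
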