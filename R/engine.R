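#' Simulate a stochastic folding trajectory
#'
#' Runs the Gillespie algorithm from an initial structure (default: the
#' open chain) until `t_max`, a target structure, or move exhaustion.
#' Per step, two uniform draws are consumed in a fixed order: `r1`
#' selects the loop element through the partial-sum tree and then the
#' move within the element by a cumulative scan; `r2` sets the waiting
#' time `tau = -log(r2) / Phi`.  Trajectories are bit-reproducible for a
#' given seed.
#'
#' Time is measured in `1/k0` units of [rate_parameters()]; supplying a
#' physical `k0` in 1/s makes the times seconds (the absolute calibration
#' of the prefactors is approximate).
#'
#' @param seq RNA sequence (character) or an `rna_structure` used as the
#'   initial state.
#' @param t_max simulated time horizon.
#' @param initial optional initial dot-bracket (default open chain).
#' @param target optional target dot-bracket: the run stops at the first
#'   visit (exact pair-table match) and records the first-passage time.
#' @param seed RNG seed (integer).
#' @param par parameters from [energy_parameters()].
#' @param rates from [rate_parameters()].
#' @param record `"events"` records every visited state; `"ends"` only
#'   the initial and final states.
#' @param max_steps hard cap on the number of Gillespie steps.
#' @param collect_tau if `TRUE`, returns the per-step `tau * Phi`
#'   products in attribute `tau_phi` (Exp(1) under the model).
#' @return a tibble (`time`, `db`, `energy`) of class `rk_trajectory`
#'   with attributes `seq`, `reason` (`max_time`, `target_reached`,
#'   `no_moves` or `max_steps`), `fpt`, `t_final` and engine statistics
#'   in `stats`.
#' @examples
#' tr <- simulate_folding("GGGGAAAACCCC", t_max = 5, seed = 1)
#' attr(tr, "reason")
#' @export
simulate_folding <- function(seq, t_max, initial = NULL, target = NULL,
                             seed = 1, par = energy_parameters(),
                             rates = rate_parameters(),
                             record = c("events", "ends"),
                             max_steps = 1e9, collect_tau = FALSE) {
  record <- match.arg(record)
  if (inherits(seq, "rna_structure")) {
    if (is.null(initial)) initial <- seq$db
    seq <- seq$seq
  }
  seq <- rk_canonical_seq(seq)
  if (is.null(initial)) initial <- strrep(".", nchar(seq))
  res <- rk_simulate(seq, initial, par_ptr(par), rates_list(rates),
                     t_max, if (is.null(target)) "" else target,
                     as.numeric(seed), as.numeric(max_steps),
                     record == "events", collect_tau)
  out <- tibble::tibble(time = res$time, db = res$db, energy = res$energy)
  attr(out, "seq") <- seq
  attr(out, "reason") <- res$reason
  attr(out, "fpt") <- res$fpt
  attr(out, "t_final") <- res$t_final
  attr(out, "final_db") <- res$final_db
  attr(out, "stats") <- res$stats
  if (collect_tau) attr(out, "tau_phi") <- res$tau_phi
  class(out) <- c("rk_trajectory", class(out))
  out
}

#' Final states of an ensemble of trajectories
#'
#' Runs `n_traj` independent trajectories (seeded from one master seed)
#' and returns the structure occupied at `t_max` by each — the
#' occupancies estimate the time-point populations of the ensemble.
#'
#' @inheritParams simulate_folding
#' @param n_traj number of trajectories.
#' @param initial initial dot-bracket, or a vector of them assigned to
#'   trajectories in rotation (e.g. an equilibrium sample); default the
#'   open chain.
#' @return character vector of final dot-brackets, length `n_traj`.
#' @export
simulate_ensemble <- function(seq, t_max, n_traj, seed = 1,
                              initial = NULL, par = energy_parameters(),
                              rates = rate_parameters(), max_steps = 1e9) {
  seq <- rk_canonical_seq(seq)
  if (is.null(initial)) initial <- strrep(".", nchar(seq))
  res <- rk_ensemble_final(seq, initial, par_ptr(par), rates_list(rates),
                           t_max, as.integer(n_traj), as.numeric(seed),
                           as.numeric(max_steps))
  res$final_db
}

#' First-passage times to a target structure
#'
#' Simulates from the open chain until the first visit to `target`
#' (exact match), up to `t_cap`; runs that never arrive are flagged
#' censored, never imputed.
#'
#' @inheritParams simulate_folding
#' @param target target dot-bracket (e.g. the minimum-free-energy fold).
#' @param t_cap time cap per trajectory.
#' @param n_traj number of trajectories.
#' @return tibble with `time` (NA when censored) and `censored`.
#' @export
first_passage_times <- function(seq, target, t_cap, n_traj = 1, seed = 1,
                                par = energy_parameters(),
                                rates = rate_parameters(),
                                max_steps = 1e9) {
  seq <- rk_canonical_seq(seq)
  res <- rk_first_passage(seq, target, par_ptr(par), rates_list(rates),
                          t_cap, as.integer(n_traj), as.numeric(seed),
                          as.numeric(max_steps))
  tibble::tibble(time = res$time, censored = res$censored)
}

#' Lockstep comparison of the incremental and naive engines
#'
#' Drives the incremental loop/flux-tree engine and a naive engine that
#' recomputes the complete neighbourhood, all rates and the total flux
#' from scratch each step, feeding both the same RNG stream, and compares
#' the fired move, the visited structure, the total flux and the waiting
#' time at every step.  Optionally also verifies the cached move lists of
#' untouched loops against the brute-force oracle.
#'
#' @inheritParams simulate_folding
#' @param n_steps number of Gillespie steps to compare.
#' @param verify_cache if `TRUE`, additionally cross-check the cached
#'   per-loop move lists every `verify_every` steps.
#' @param verify_every cache-check stride.
#' @return list with `ok`, `steps`, `mismatch`, `max_flux_reldiff` and
#'   the incremental engine's instrumentation `stats`.
#' @export
lockstep_check <- function(seq, n_steps, seed = 1, initial = NULL,
                           par = energy_parameters(),
                           rates = rate_parameters(),
                           verify_cache = TRUE, verify_every = 1) {
  seq <- rk_canonical_seq(seq)
  if (is.null(initial)) initial <- strrep(".", nchar(seq))
  rk_lockstep(seq, initial, par_ptr(par), rates_list(rates),
              as.numeric(n_steps), as.numeric(seed), verify_cache,
              as.integer(verify_every))
}

#' Ensemble population counts on a time grid
#'
#' Runs `n_traj` trajectories and counts, at every grid time, how many
#' occupy each tracked structure (piecewise-constant, right-continuous
#' sampling); remaining mass is "other".  This is the memory-flat
#' work-horse behind population-kinetics figures.
#'
#' @inheritParams simulate_folding
#' @param grid increasing vector of sampling times.
#' @param tracked character vector of dot-brackets to track.
#' @param n_traj number of trajectories.
#' @return tibble with `time`, one fraction column per tracked structure
#'   (`S1`, `S2`, ...) and `other`.
#' @export
ensemble_kinetics <- function(seq, grid, tracked, n_traj, seed = 1,
                              initial = NULL, par = energy_parameters(),
                              rates = rate_parameters(), max_steps = 1e9) {
  seq <- rk_canonical_seq(seq)
  if (is.null(initial)) initial <- strrep(".", nchar(seq))
  cnt <- rk_population_counts(seq, initial, par_ptr(par),
                              rates_list(rates), as.numeric(grid), tracked,
                              as.integer(n_traj), as.numeric(seed),
                              as.numeric(max_steps))
  fr <- cnt / n_traj
  nm <- c(paste0("S", seq_along(tracked)), "other")
  out <- tibble::as_tibble(stats::setNames(as.data.frame(fr), nm))
  out <- tibble::add_column(out, time = as.numeric(grid), .before = 1)
  attr(out, "tracked") <- tracked
  attr(out, "n_traj") <- n_traj
  out
}
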