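#' Nearest-neighbour energy parameters
#'
#' Loads the bundled Turner-99 free-energy tables (37 degrees C) and fixes
#' the thermodynamic temperature used for Boltzmann factors.  The tables
#' cover base-pair stacks, hairpin/bulge/interior loop lengths with
#' Jacobson-Stockmayer extrapolation beyond 30 nucleotides, terminal
#' mismatches, 5'/3' dangles, the special 1x1/2x1/2x2 interior loops,
#' tabulated tetraloops, the terminal-AU penalty and multiloop
#' coefficients.
#'
#' Dangling ends follow the per-base convention: an unpaired base adjacent
#' to a single helix end in the exterior or a multiloop contributes its
#' dangle energy, and a base shared between two helix ends contributes the
#' more favourable of its two options.
#'
#' The multiloop closing penalty is linear in the branch count; with
#' `multiloop = "logarithmic"` (the default) loops with more than six
#' unpaired nucleotides grow as `1.75 RT log(u/6)` instead of linearly,
#' the standard polymer-theory form.  `"linear"` reproduces the plain
#' linear model used by common reference evaluators.
#'
#' Temperature only rescales the Boltzmann factor beta = 1/RT; the free
#' energy tables themselves are 37 C values (no enthalpy tables are
#' bundled).
#'
#' @param temperature temperature in Kelvin (default 310.15, i.e. 37 C).
#' @param multiloop `"logarithmic"` or `"linear"` multiloop size penalty.
#' @return an object of class `rk_energy_parameters`.
#' @examples
#' par <- energy_parameters()
#' structure_energy("GGGGAAACCCC", "((((...))))", par)
#' @export
energy_parameters <- function(temperature = 310.15,
                              multiloop = c("logarithmic", "linear")) {
  multiloop <- match.arg(multiloop)
  loops <- system.file("extdata", "turner1999_loops.txt",
                       package = "rnakinetics", mustWork = TRUE)
  i22 <- system.file("extdata", "turner1999_int22.txt",
                     package = "rnakinetics", mustWork = TRUE)
  ptr <- rk_params_load(loops, i22, temperature, multiloop == "logarithmic")
  out <- list(ptr = ptr, temperature = temperature, multiloop = multiloop,
              rt = 0.0019872 * temperature)
  class(out) <- "rk_energy_parameters"
  out
}

#' @export
print.rk_energy_parameters <- function(x, ...) {
  cat("Turner-99 nearest-neighbour parameters\n")
  cat(sprintf("  temperature: %.2f K (RT = %.5f kcal/mol)\n",
              x$temperature, x$rt))
  cat(sprintf("  multiloop size penalty: %s\n", x$multiloop))
  invisible(x)
}

par_ptr <- function(par) {
  if (!inherits(par, "rk_energy_parameters"))
    stop("`par` must come from energy_parameters()")
  par$ptr
}

#' Kinetic rate parameters
#'
#' Prefactors and the loop-closure exponent of the transition rates.
#' `k0` scales all Kawasaki rates `k0 * exp(-beta dG / 2)`; `k0_nuc` and
#' `alpha` set the nucleation forward rate `k0_nuc * n^(-alpha)` over the
#' ring distance `n`.  Both prefactors are pure time scales (time is
#' reported in `1/k0` units by default), so equilibrium properties do not
#' depend on them.
#'
#' @param k0 Kawasaki prefactor (1/time), default 1.
#' @param k0_nuc nucleation prefactor (1/time), default 1.
#' @param alpha loop-closure exponent, default 1.5 (Jacobson-Stockmayer).
#' @return a list of class `rk_rate_parameters`.
#' @export
rate_parameters <- function(k0 = 1, k0_nuc = 1, alpha = 1.5) {
  stopifnot(k0 > 0, k0_nuc > 0, alpha > 0)
  structure(list(k0 = k0, k0_nuc = k0_nuc, alpha = alpha),
            class = "rk_rate_parameters")
}

rates_list <- function(rates) {
  if (is.null(rates)) rates <- rate_parameters()
  if (!inherits(rates, "rk_rate_parameters"))
    stop("`rates` must come from rate_parameters()")
  unclass(rates)
}
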