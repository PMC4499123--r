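#' Population kinetics from recorded trajectories
#'
#' For a set of event-recorded trajectories of one sequence, computes at
#' each grid time the fraction occupying each tracked structure, with
#' piecewise-constant (right-continuous) interpolation between events:
#' a state holds until the next event.  Untracked mass is "other".
#'
#' @param trajectories list of `rk_trajectory` objects recorded with
#'   `record = "events"`.
#' @param grid increasing vector of times within the simulated span.
#' @param tracked character vector of dot-brackets to track (possibly
#'   empty, in which case "other" is 1 everywhere).
#' @return tibble with `time`, `S1..Sk` fractions and `other`; fractions
#'   sum to 1 at every grid time.
#' @export
population_kinetics <- function(trajectories, grid, tracked = character()) {
  if (length(trajectories) == 0) stop("empty trajectory set")
  sq <- unique(vapply(trajectories, function(t) attr(t, "seq"), ""))
  if (length(sq) != 1) stop("trajectories do not share one sequence")
  k <- length(tracked)
  counts <- matrix(0, nrow = length(grid), ncol = k + 1)
  for (tr in trajectories) {
    # state index at grid times: last event with time <= t
    idx <- findInterval(grid, tr$time)
    idx[idx < 1] <- 1
    st <- tr$db[idx]
    m <- match(st, tracked)
    m[is.na(m)] <- k + 1
    for (g in seq_along(grid))
      counts[g, m[g]] <- counts[g, m[g]] + 1
  }
  fr <- counts / length(trajectories)
  nm <- c(if (k) paste0("S", seq_len(k)), "other")
  out <- tibble::as_tibble(stats::setNames(as.data.frame(fr), nm))
  tibble::add_column(out, time = as.numeric(grid), .before = 1)
}

#' First-passage-time histogram on a log10 time axis
#'
#' Uniform bins in log10(time) spanning the observed range; censored
#' passages are counted separately, never imputed.
#'
#' @param times positive first-passage times; `NA` entries are treated
#'   as censored.
#' @param n_bins number of bins.
#' @param censored optional logical vector marking censored runs.
#' @return tibble with `log10_mid`, `lower`, `upper`, `count`;
#'   attributes `censored` (count) and `n` (total runs).
#' @export
fpt_histogram <- function(times, n_bins = 30, censored = NULL) {
  if (is.null(censored)) censored <- is.na(times)
  obs <- times[!censored]
  if (length(obs) == 0) stop("no uncensored first-passage times")
  if (any(obs <= 0)) stop("first-passage times must be positive")
  lt <- log10(obs)
  lo <- min(lt)
  hi <- max(lt)
  if (hi - lo < 1e-12) { lo <- lo - 0.5; hi <- hi + 0.5 }
  edges <- seq(lo, hi, length.out = n_bins + 1)
  bin <- findInterval(lt, edges, rightmost.closed = TRUE)
  bin[bin < 1] <- 1
  bin[bin > n_bins] <- n_bins
  cnt <- tabulate(bin, nbins = n_bins)
  out <- tibble::tibble(
    log10_mid = (edges[-1] + edges[-(n_bins + 1)]) / 2,
    lower = edges[-(n_bins + 1)], upper = edges[-1], count = cnt)
  attr(out, "censored") <- sum(censored)
  attr(out, "n") <- length(times)
  out
}
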