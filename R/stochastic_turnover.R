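#' Parameters of the stochastic turnover simulation
#'
#' Counts of unmodified (C) and methylated (M) cytosines in a genomic
#' region evolve by autocatalytic methylation (propensity
#' \eqn{\alpha C M}) and demethylation initiation (propensity
#' \eqn{\beta M}); each initiated demethylation removes one M immediately
#' and schedules the reappearance of a C after a fixed delay
#' \eqn{\Delta t}, during which the molecule is inert ("in transit").
#'
#' @param alpha Autocatalytic methylation rate per (C, M) pair.
#' @param beta Demethylation initiation rate per M.
#' @param delta_t Delay between 5mC removal and C reappearance.
#' @param C0,M0 Initial integer counts.
#' @param t_end Simulated time span.
#' @param seed Optional RNG seed applied by the simulator.
#' @return An object of class \code{"turnover_params"}.
#' @export
turnover_params <- function(alpha, beta, delta_t, C0, M0, t_end, seed = NULL) {
  if (alpha < 0 || beta < 0 || delta_t < 0) stop("rates and delay must be >= 0")
  if (C0 < 0 || M0 < 0 || C0 != round(C0) || M0 != round(M0))
    stop("C0 and M0 must be non-negative integers")
  if (t_end < 0) stop("t_end must be >= 0")
  structure(list(alpha = alpha, beta = beta, delta_t = delta_t,
                 C0 = as.integer(C0), M0 = as.integer(M0),
                 t_end = t_end, seed = seed),
            class = "turnover_params")
}

#' Read-noise model for (single-cell) bisulfite sequencing
#'
#' Coverage per element follows a discretised exponential distribution
#' (mean \code{coverage_mean}) truncated below \code{min_coverage}
#' (elements with fewer informative reads are discarded upstream);
#' positive reads are binomial at the true methylation rate.
#'
#' @param coverage_mean Mean of the exponential coverage distribution.
#' @param min_coverage Lower truncation of the coverage.
#' @param seed Optional RNG seed.
#' @return An object of class \code{"read_noise_model"}.
#' @export
read_noise_model <- function(coverage_mean = 14.3, min_coverage = 5,
                             seed = NULL) {
  stopifnot(coverage_mean > 0, min_coverage >= 1)
  structure(list(coverage_mean = coverage_mean,
                 min_coverage = as.integer(min_coverage), seed = seed),
            class = "read_noise_model")
}

#' Mean coverage of the truncated discretised exponential
#'
#' @param noise A \code{\link{read_noise_model}}.
#' @return Expected coverage \eqn{(m_c - 1) + 1 / (1 - e^{-1/\mu})}.
#' @export
expected_coverage <- function(noise) {
  noise$min_coverage - 1 + 1 / (1 - exp(-1 / noise$coverage_mean))
}

#' Simulate the time-delayed turnover master equation
#'
#' Exact delayed-Gillespie sample path (direct method with a queue of
#' scheduled delayed completions). With \code{delta_t = 0} the simulator
#' reduces to the standard two-reaction direct method.
#'
#' @param params A \code{\link{turnover_params}} object.
#' @param record_times Times at which to record the state (defaults to 201
#'   equally spaced points on \code{[0, t_end]}).
#' @param keep_events If \code{TRUE}, also return the full event history.
#' @param seed_history If \code{TRUE}, seed the demethylation pipeline as
#'   if \code{M} had been constant at \code{M0} for the preceding delay
#'   window (a Poisson stream of pending completions on
#'   \code{(0, delta_t]}), matching the constant pre-history of the
#'   deterministic delay model. The default (\code{FALSE}) starts with an
#'   empty pipeline, so \code{C + M + in_transit = C0 + M0} exactly.
#' @return A list with vectors \code{time}, \code{C}, \code{M},
#'   \code{in_transit} and (optionally) \code{events}.
#' @export
simulate_delayed_turnover <- function(params, record_times = NULL,
                                      keep_events = FALSE,
                                      seed_history = FALSE) {
  stopifnot(inherits(params, "turnover_params"))
  if (params$t_end < 0) stop("t_end must be >= 0")
  if (is.null(record_times))
    record_times <- seq(0, params$t_end, length.out = 201)
  if (any(record_times < 0 | record_times > params$t_end))
    stop("record_times must lie in [0, t_end]")
  if (!is.null(params$seed)) set.seed(params$seed)
  r <- turnover_gillespie_cpp(params$alpha, params$beta, params$delta_t,
                              params$C0, params$M0, params$t_end,
                              sort(record_times), keep_events, seed_history)
  list(time = sort(record_times), C = r$C, M = r$M,
       in_transit = r$in_transit, events = r$events)
}

#' Draw sequencing reads at a true methylation rate
#'
#' @param true_rate Vector of true methylation rates in [0, 1] (one read
#'   pair \code{(k, s)} is drawn per element).
#' @param noise A \code{\link{read_noise_model}}.
#' @return A data frame with positive reads \code{k} and coverage \code{s}.
#' @export
sample_reads <- function(true_rate, noise = read_noise_model()) {
  if (any(true_rate < 0 | true_rate > 1)) stop("true_rate must be in [0, 1]")
  if (!is.null(noise$seed)) set.seed(noise$seed)
  r <- sample_reads_cpp(as.numeric(true_rate), noise$coverage_mean,
                        noise$min_coverage)
  data.frame(k = r$k, s = r$s)
}

#' Distribution of observed methylation rates over an ensemble of regions
#'
#' Runs \code{n_sims} independent turnover simulations; at each requested
#' timepoint the true rate \eqn{r = M / (C + M)} of every simulation is
#' pushed through the read-noise model, giving one observed rate
#' \eqn{k/s} per simulation per timepoint. Histograms are normalised to
#' probabilities.
#'
#' @param params A \code{\link{turnover_params}} object.
#' @param noise A \code{\link{read_noise_model}}.
#' @param n_sims Number of independent simulations.
#' @param timepoints Times (within \code{[0, t_end]}) to sample.
#' @param breaks Histogram break points on [0, 1].
#' @return A list with \code{histogram} (data frame: timepoint, bin_left,
#'   bin_right, probability) and \code{rates} (matrix n_sims x timepoints
#'   of observed rates).
#' @export
rate_distribution <- function(params, noise = read_noise_model(),
                              n_sims = 48000, timepoints,
                              breaks = seq(0, 1, by = 0.05),
                              seed_history = FALSE) {
  stopifnot(n_sims >= 1)
  if (any(timepoints > params$t_end))
    stop("timepoints must not exceed t_end")
  if (!is.null(params$seed)) set.seed(params$seed)
  nt <- length(timepoints)
  obs <- matrix(NA_real_, n_sims, nt)
  for (i in seq_len(n_sims)) {
    r <- turnover_gillespie_cpp(params$alpha, params$beta, params$delta_t,
                                params$C0, params$M0, params$t_end,
                                as.numeric(timepoints), FALSE, seed_history)
    tot <- r$C + r$M
    true_rate <- ifelse(tot > 0, r$M / tot, 0)
    rd <- sample_reads_cpp(true_rate, noise$coverage_mean, noise$min_coverage)
    obs[i, ] <- rd$k / rd$s
  }
  hh <- do.call(rbind, lapply(seq_len(nt), function(j) {
    h <- hist(obs[, j], breaks = breaks, plot = FALSE)
    data.frame(timepoint = timepoints[j], bin_left = h$breaks[-length(h$breaks)],
               bin_right = h$breaks[-1], probability = h$counts / sum(h$counts))
  }))
  list(histogram = hh, rates = obs)
}
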