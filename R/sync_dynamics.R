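#' Discrete-phase CpG lattice model
#'
#' Each CpG cycles stochastically through \code{n_states} chemical states,
#' represented as a discrete phase on \eqn{[0, 2\pi)}. Phases advance at
#' intrinsic rates \eqn{\omega_i} and are biased toward agreement with
#' genomic neighbours (kernel-weighted, emulating processive DNMT3A/B/L
#' action) and with the genome-wide mean field (emulating global feedback
#' through DNMT3A/B abundance).
#'
#' @param positions Genomic coordinates of the CpGs (increasing).
#' @param n_states Number of discrete phase states (\eqn{\ge 3}).
#' @param omega Intrinsic cycling rates (recycled to the number of sites).
#' @param xi Decay scale of the local interaction kernel
#'   \eqn{l(d) = e^{-d/\xi}}.
#' @param lambda Overall local coupling strength; the kernel is normalised
#'   so that its entries sum to one across all ordered pairs.
#' @param kappa Response of each site to the global field (\eqn{\ge 0}).
#' @param sigma Contribution of each site to the global field (\eqn{\ge 0}).
#' @param eps_coupling Sharpness of the phase-difference bias
#'   \eqn{(1 + \sin(\epsilon\,\Delta\phi))/2}.
#' @param phases Optional integer initial phases in \code{[0, n_states)};
#'   uniform random by default.
#' @param seed Optional RNG seed (used for default phases and simulation).
#' @return An object of class \code{"lattice_model"}.
#' @export
lattice_model <- function(positions, n_states = 20, omega = 1, xi = 10,
                          lambda = 0, kappa = 0, sigma = 1,
                          eps_coupling = 0.5, phases = NULL, seed = NULL) {
  n <- length(positions)
  stopifnot(n >= 1, n_states >= 3, lambda >= 0, xi > 0)
  if (is.unsorted(positions)) stop("positions must be increasing")
  omega <- rep_len(omega, n)
  kappa <- rep_len(kappa, n)
  sigma <- rep_len(sigma, n)
  if (any(kappa < 0) || any(sigma < 0)) stop("kappa and sigma must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(phases)) phases <- sample.int(n_states, n, replace = TRUE) - 1L
  stopifnot(length(phases) == n, all(phases >= 0), all(phases < n_states))
  d <- abs(outer(positions, positions, "-"))
  l <- exp(-d / xi)
  diag(l) <- 0
  K <- if (sum(l) > 0) l / sum(l) else l  # normalised kernel, sum_ij K = 1
  structure(list(positions = positions, n_states = as.integer(n_states),
                 omega = omega, xi = xi, lambda = lambda, kappa = kappa,
                 sigma = sigma, eps_coupling = eps_coupling,
                 phases = as.integer(phases), K = K, seed = seed),
            class = "lattice_model")
}

#' Simulate the coupled CpG phase lattice
#'
#' Exact continuous-time Markov simulation (direct method) of the
#' discrete-phase lattice; records the weighted order parameter
#' \eqn{r(t) e^{i\Psi(t)} = \sum_j \sigma_j e^{i\phi_j} / \sum_j \sigma_j}
#' (normalised by the total contribution so that \eqn{r \in [0, 1]}).
#'
#' @param model A \code{\link{lattice_model}}.
#' @param t_end Simulation time.
#' @param record_every Spacing of the recorded order-parameter series.
#' @return A list with \code{sync} (data frame t, r, psi), final integer
#'   \code{phases}, per-site forward/backward step counts and the event
#'   count.
#' @export
simulate_lattice <- function(model, t_end, record_every = 0.5) {
  stopifnot(inherits(model, "lattice_model"), t_end > 0)
  W <- model$lambda * model$K
  if (any(!is.finite(W))) stop("non-normalizable kernel")
  if (!is.null(model$seed)) set.seed(model$seed)
  r <- lattice_sim_cpp(model$phases, model$n_states, model$omega, W,
                       model$kappa, model$sigma, model$eps_coupling,
                       t_end, record_every)
  list(sync = data.frame(t = r$t, r = r$r, psi = r$psi),
       phases = r$phases, steps_fwd = r$steps_fwd, steps_bwd = r$steps_bwd,
       n_events = r$n_events)
}

#' Construct a coarse-grained oscillator ensemble
#'
#' @param omega Effective block frequencies.
#' @param kappa Response couplings to the global field.
#' @param sigma Contributions to the global field.
#' @param n Block weights (number of CpGs per block).
#' @param positions Optional block positions.
#' @return An object of class \code{"oscillator_ensemble"}.
#' @export
oscillator_ensemble <- function(omega, kappa = 1, sigma = kappa, n = 1,
                                positions = NULL) {
  N <- length(omega)
  kappa <- rep_len(kappa, N); sigma <- rep_len(sigma, N)
  n <- rep_len(n, N)
  stopifnot(all(n >= 1))
  structure(list(omega = omega, kappa = kappa, sigma = sigma,
                 n = as.integer(round(n)), positions = positions),
            class = "oscillator_ensemble")
}

#' Strong-disorder coarse-graining of the CpG lattice
#'
#' Repeatedly phase-averages the pair of neighbouring blocks with the
#' strongest mutual coupling (ties broken by lowest index). A merge of
#' blocks with weights \eqn{n_i, n_{i+1}} produces
#' \eqn{\tilde\omega = (n_i \omega_i + n_{i+1}\omega_{i+1})/(n_i+n_{i+1})},
#' rescales the local coupling as \eqn{\tilde\lambda = \lambda/(n_i+n_{i+1})}
#' and leaves the global terms invariant through
#' \eqn{\tilde\kappa_i = \kappa_i / n_i}, \eqn{\tilde\sigma_i = n_i \sigma_i}.
#' Merging stops when the local coupling scale drops to or below the
#' smaller of the typical block frequency and response coupling.
#'
#' @param model A \code{\link{lattice_model}} with at least 2 sites.
#' @return An \code{\link{oscillator_ensemble}} of coarse-grained blocks.
#' @export
coarse_grain <- function(model) {
  stopifnot(inherits(model, "lattice_model"))
  n_sites <- length(model$positions)
  if (n_sites < 2) stop("need at least 2 sites")
  pos <- model$positions
  w_base <- model$omega            # per-CpG intrinsic frequency (block mean)
  k_base <- model$kappa            # per-CpG response (block mean)
  s_base <- model$sigma            # per-CpG contribution (block mean)
  nb <- rep(1L, n_sites)
  kern <- function(d) exp(-d / model$xi)
  # kernel normalisation matching the lattice master equation (sum over
  # ordered pairs equals one before scaling by lambda)
  kscale <- sum(kern(abs(outer(pos, pos, "-")))) - n_sites
  lam0 <- if (kscale > 0) model$lambda / kscale else 0
  repeat {
    K <- length(pos)
    if (K < 2) break
    # coarse-grained coupling of each neighbouring block pair
    cpl <- lam0 * kern(diff(pos)) / (nb[-K] + nb[-1])
    i <- which.max(cpl)            # ties: which.max takes the lowest index
    j <- i + 1L
    # local coupling is irrelevant once it drops to the smaller of the
    # blocks' frequency and global-response scales
    if (cpl[i] <= min(abs(w_base[c(i, j)]), k_base[c(i, j)] / nb[c(i, j)]))
      break
    ntot <- nb[i] + nb[j]
    w_base[i] <- (nb[i] * w_base[i] + nb[j] * w_base[j]) / ntot
    k_base[i] <- (nb[i] * k_base[i] + nb[j] * k_base[j]) / ntot
    s_base[i] <- (nb[i] * s_base[i] + nb[j] * s_base[j]) / ntot
    pos[i] <- (nb[i] * pos[i] + nb[j] * pos[j]) / ntot
    nb[i] <- ntot
    keep <- setdiff(seq_len(K), j)
    pos <- pos[keep]; w_base <- w_base[keep]
    k_base <- k_base[keep]; s_base <- s_base[keep]; nb <- nb[keep]
  }
  oscillator_ensemble(omega = w_base, kappa = k_base / nb,
                      sigma = nb * s_base, n = nb, positions = pos)
}

#' Prepare a coarse-grained ensemble for mean-field simulation
#'
#' The renormalised response couplings \eqn{\tilde\kappa = \kappa / n}
#' are defined together with the growing state count of the block phase
#' variables; for direct integration of the continuous mean-field
#' equations (with the \eqn{N^{-1}}-normalised field of
#' \code{\link{simulate_kuramoto}}) the response must be rescaled by the
#' number of microscopic sites and by the linearised slope
#' \eqn{\epsilon} of the coupling bias \eqn{\sin(\epsilon\,\Delta\phi)}.
#'
#' @param ens An \code{\link{oscillator_ensemble}} from
#'   \code{\link{coarse_grain}}.
#' @param n_sites Number of microscopic lattice sites.
#' @param eps_coupling Coupling sharpness of the source lattice.
#' @return An \code{\link{oscillator_ensemble}} with rescaled responses.
#' @export
rescale_for_meanfield <- function(ens, n_sites, eps_coupling = 0.5) {
  oscillator_ensemble(ens$omega,
                      kappa = ens$kappa * n_sites * eps_coupling,
                      sigma = ens$sigma, n = ens$n,
                      positions = ens$positions)
}

#' Simulate the heterogeneous mean-field Kuramoto ensemble
#'
#' Deterministic midpoint integration of
#' \eqn{\dot\phi_i = \tilde\omega_i + \tilde\kappa_i r \sin(\Psi - \phi_i)}
#' with the self-consistent field
#' \eqn{r e^{i\Psi} = N^{-1} \sum_j \tilde\sigma_j e^{i\phi_j}}.
#' The reported order parameter is normalised by the mean contribution so
#' that it lies in [0, 1].
#'
#' @param ens An \code{\link{oscillator_ensemble}}.
#' @param t_end Integration time.
#' @param dt Time step; defaults to \code{0.1 / max(|omega|, kappa)}.
#' @param phases0 Initial phases (radians); uniform random by default.
#' @param record_every Spacing of recorded order-parameter values.
#' @param seed Optional RNG seed for the default initial phases.
#' @return A list with \code{sync} (data frame t, r, psi), final
#'   \code{phases}, and \code{r_asymptotic} (mean r over the last quarter
#'   of the run).
#' @export
simulate_kuramoto <- function(ens, t_end, dt = NULL, phases0 = NULL,
                              record_every = NULL, seed = NULL) {
  stopifnot(inherits(ens, "oscillator_ensemble"))
  N <- length(ens$omega)
  if (N == 0) stop("empty ensemble")
  # default step resolves the bulk of the frequency distribution (99.5%
  # quantile); heavy-tailed outliers never phase-lock, so aliasing their
  # rotation does not affect the order parameter
  scale <- max(stats::quantile(abs(ens$omega), 0.995), max(ens$kappa), 1e-8)
  if (is.null(dt)) dt <- 0.1 / scale
  if (dt * stats::quantile(abs(ens$omega), 0.995) >= 0.5)
    stop("dt does not resolve the fastest (bulk) frequency")
  if (is.null(record_every)) record_every <- max(dt, t_end / 400)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(phases0)) phases0 <- stats::runif(N, 0, 2 * pi)
  r <- kuramoto_sim_cpp(phases0, ens$omega, ens$kappa, ens$sigma,
                        t_end, dt, record_every)
  sync <- data.frame(t = r$t, r = r$r, psi = r$psi)
  tail_idx <- sync$t >= 0.75 * t_end
  list(sync = sync, phases = r$phases,
       r_asymptotic = mean(sync$r[tail_idx]))
}

#' Synchronization threshold of the coarse-grained ensemble
#'
#' With factorising frequency/coupling distributions and contributions
#' proportional to responses (\eqn{\tilde\sigma = a \tilde\kappa}), global
#' synchronization requires
#' \eqn{\langle\tilde\kappa\rangle^2 +
#'      \langle(\tilde\kappa - \langle\tilde\kappa\rangle)^2\rangle \ge
#'      2 / (\pi a\, g(\tilde\omega_0))};
#' for homogeneous coupling the critical value is
#' \eqn{\tilde\kappa_c = 2 / (\pi a\, g(\tilde\omega_0))}.
#'
#' @param g_at_mode Value of the frequency density at its mode
#'   (\eqn{> 0}).
#' @param a Proportionality between contribution and response couplings.
#' @param kappa_sample Optional sample (or two-element list
#'   \code{list(mean =, var =)}) of heterogeneous couplings used to
#'   evaluate the second-moment condition.
#' @return A list with \code{kappa_c} and, when couplings are supplied,
#'   \code{condition_met} and \code{kappa_sq_mean}.
#' @export
synchronization_threshold <- function(g_at_mode, a = 1, kappa_sample = NULL) {
  if (g_at_mode <= 0) stop("threshold undefined: g at the mode must be > 0")
  stopifnot(a > 0)
  kappa_c <- 2 / (pi * a * g_at_mode)
  out <- list(kappa_c = kappa_c)
  if (!is.null(kappa_sample)) {
    m2 <- if (is.list(kappa_sample)) kappa_sample$mean^2 + kappa_sample$var
          else mean(kappa_sample^2)
    out$kappa_sq_mean <- m2
    out$condition_met <- m2 >= 2 / (pi * a * g_at_mode)
  }
  out
}

#' Estimate the critical coupling from simulations
#'
#' Simulates homogeneously coupled ensembles across a grid of couplings
#' and extrapolates the synchronization onset by a linear fit of
#' \eqn{r^2} against \eqn{1/\kappa} (exact for Lorentzian frequencies,
#' where \eqn{r^2 = 1 - \kappa_c/\kappa}).
#'
#' @param freqs Sampled intrinsic frequencies.
#' @param kappa_grid Super-critical couplings to simulate.
#' @param t_end,dt,seed Passed to \code{\link{simulate_kuramoto}}.
#' @return A list with \code{kappa_c_hat} and the per-coupling data frame.
#' @export
estimate_critical_coupling <- function(freqs, kappa_grid, t_end = 150,
                                       dt = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(kappa_grid, function(k) {
    ens <- oscillator_ensemble(freqs, kappa = k, sigma = 1)
    data.frame(kappa = k,
               r = simulate_kuramoto(ens, t_end, dt = dt)$r_asymptotic)
  })
  tab <- do.call(rbind, rows)
  fit <- stats::lm(I(r^2) ~ I(1 / kappa), data = tab)
  list(kappa_c_hat = -stats::coef(fit)[[2]] / stats::coef(fit)[[1]],
       table = tab)
}

#' Near-critical scaling of the order parameter
#'
#' For homogeneous coupling slightly above threshold the order parameter
#' follows \eqn{r \approx \sqrt{16 \mu / (\pi \tilde\kappa_c^3
#' (-g''(\tilde\omega_0)))}} with
#' \eqn{\mu = (\tilde\kappa_0 - \tilde\kappa_c)/\tilde\kappa_c}.
#' Simulates Gaussian-frequency ensembles across a grid of relative
#' distances \eqn{\mu} above threshold and fits the scaling exponent by
#' log-log regression.
#'
#' @param mu_grid Relative distances above the critical coupling, in
#'   (0, 0.3]; the scaling law is asymptotic, so the default grid stays
#'   within the near-critical regime \eqn{\mu \le 0.1}.
#' @param n_osc Ensemble size.
#' @param freq_sd Standard deviation of the Gaussian frequency
#'   distribution.
#' @param n_seeds Independent frequency/phase draws averaged per grid
#'   point.
#' @param t_end Integration time per simulation; defaults to
#'   \code{max(150, 8 / min(mu_grid))} to outlast the critical slowing
#'   down near threshold.
#' @param seed Base RNG seed.
#' @return A list with \code{exponent}, \code{prefactor} (fitted
#'   \eqn{r / \sqrt\mu} at small \eqn{\mu}), \code{prefactor_theory},
#'   \code{kappa_c} and the fitted table.
#' @export
critical_scaling <- function(mu_grid = c(0.02, 0.04, 0.07, 0.10),
                             n_osc = 2000, freq_sd = 1,
                             n_seeds = 5, t_end = NULL, seed = 1) {
  if (any(mu_grid <= 0)) stop("mu grid must be strictly super-critical")
  if (any(mu_grid > 0.3)) stop("mu grid must stay within (0, 0.3]")
  if (is.null(t_end)) t_end <- max(150, 8 / min(mu_grid))
  g0 <- stats::dnorm(0, sd = freq_sd)
  kappa_c <- 2 / (pi * g0)
  # stratified (quantile-matched) frequency sample: removes the
  # sample-to-sample variability of the realised frequency density, which
  # otherwise dominates r near threshold; seeds vary the initial phases
  freqs <- stats::qnorm((seq_len(n_osc) - 0.5) / n_osc, sd = freq_sd)
  rows <- lapply(mu_grid, function(mu) {
    ens <- oscillator_ensemble(freqs, kappa = kappa_c * (1 + mu), sigma = 1)
    rr <- vapply(seq_len(n_seeds), function(s)
      simulate_kuramoto(ens, t_end, seed = seed + 7919L * s)$r_asymptotic,
      numeric(1))
    data.frame(mu = mu, r = mean(rr), r_sd = stats::sd(rr))
  })
  tab <- do.call(rbind, rows)
  fit <- stats::lm(log(r) ~ log(mu), data = tab)
  gpp <- -stats::dnorm(0, sd = freq_sd) / freq_sd^2  # g''(0), Gaussian
  pref_theory <- sqrt(16 / (pi * kappa_c^3 * (-gpp)))
  list(exponent = stats::coef(fit)[[2]],
       prefactor = mean(tab$r / sqrt(tab$mu)),
       prefactor_theory = pref_theory,
       kappa_c = kappa_c, table = tab)
}
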