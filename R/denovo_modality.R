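#' Generative model of cross-cell methylation distributions in vivo
#'
#' During global de novo methylation, the mean methylation of a cell
#' follows the sigmoid \eqn{\bar m(\Delta\tau) = 1/(1 + e^{-\Delta\tau})}
#' in the signed dimensionless time \eqn{\Delta\tau} measured from the
#' cell's half-methylation point (cells far from onset have
#' \eqn{\Delta\tau \ll 0} and \eqn{\bar m \approx e^{\Delta\tau}}, the
#' early asymptotic branch). The population distribution of methylation
#' levels at observation time \eqn{\tau} is the mixture
#' \eqn{p(m, \tau) = \int f(m; \bar m(\Delta\tau))\,
#' g(\Delta\tau; \tau)\, d\Delta\tau},
#' where \eqn{g} is the distribution of elapsed times (onset
#' variability) and \eqn{f} is the steady-state conditional distribution
#' of cell methylation around \eqn{\bar m}. Three scenarios are
#' distinguished: \code{unimodal_onset} (Gaussian \eqn{g}, Gaussian
#' \eqn{f}), \code{bimodal_onset} (two-component \eqn{g}, early lineage
#' segregation) and \code{oscillatory} (Gaussian \eqn{g}, bimodal
#' \eqn{f}: an equal two-Gaussian mixture at \eqn{\bar m \pm A/2}
#' reflecting oversampling of the oscillation extremes).
#'
#' @param scenario One of \code{"unimodal_onset"}, \code{"bimodal_onset"},
#'   \code{"oscillatory"}.
#' @param A Oscillation amplitude (mode separation of \eqn{f}), in [0,1].
#' @param sigma,sigma1 Widths of the two components of the oscillatory
#'   \eqn{f} (lower/upper extreme).
#' @param f_width Width of the Gaussian \eqn{f} for non-oscillatory
#'   scenarios.
#' @param onset_mean,onset_sd Mean and SD of the Gaussian onset-time
#'   distribution (calendar time of de novo methylation onset).
#' @param onset_mix For \code{bimodal_onset}: list with \code{means},
#'   \code{sds}, \code{weights} of the onset mixture.
#' @param m_grid Grid on [0, 1] for the methylation level.
#' @return An object of class \code{"modality_model"}.
#' @export
modality_model <- function(scenario = c("unimodal_onset", "bimodal_onset",
                                        "oscillatory"),
                           A = 0.3, sigma = 0.05, sigma1 = sigma,
                           f_width = 0.05, onset_mean = 6, onset_sd = 1.2,
                           onset_mix = NULL,
                           m_grid = seq(0, 1, length.out = 1001)) {
  scenario <- match.arg(scenario)
  stopifnot(A >= 0, A <= 1, sigma > 0, sigma1 > 0, f_width > 0)
  if (scenario == "bimodal_onset" && is.null(onset_mix))
    onset_mix <- list(means = c(onset_mean - 2.5, onset_mean + 2.5),
                      sds = c(onset_sd, onset_sd) / 2, weights = c(0.5, 0.5))
  structure(list(scenario = scenario, A = A, sigma = sigma, sigma1 = sigma1,
                 f_width = f_width, onset_mean = onset_mean,
                 onset_sd = onset_sd, onset_mix = onset_mix,
                 m_grid = m_grid),
            class = "modality_model")
}

#' Sigmoid mean methylation trajectory
#'
#' @param delta_tau Elapsed dimensionless time since onset of de novo
#'   methylation.
#' @return \eqn{\bar m = 1 / (1 + e^{-\Delta\tau})}.
#' @export
mean_trajectory <- function(delta_tau) stats::plogis(delta_tau)

# conditional density f(m; mbar) on the m grid (not yet normalized).
# The methylation scale saturates at 0 and 1, so the oscillation
# midpoint is clamped to [A/2, 1 - A/2]: near saturation the
# oscillation carves excursions away from the boundary, with modes at
# 1 - A and 1 (and at 0 and A near the hypomethylated floor).
.f_cond <- function(model, m, mbar) {
  if (model$scenario == "oscillatory") {
    ctr <- min(max(mbar, model$A / 2), 1 - model$A / 2)
    0.5 * stats::dnorm(m, ctr - model$A / 2, model$sigma) +
      0.5 * stats::dnorm(m, ctr + model$A / 2, model$sigma1)
  } else {
    stats::dnorm(m, mbar, model$f_width)
  }
}

# onset density of the signed elapsed time dtau (time from the cell's
# half-methylation point) at observation time tau; unbounded support, so
# cells that have not yet started (dtau << 0) sit at low methylation
.g_onset <- function(model, dtau, tau) {
  if (model$scenario == "bimodal_onset") {
    mix <- model$onset_mix
    rowSums(vapply(seq_along(mix$means), function(k)
      mix$weights[k] * stats::dnorm(dtau, tau - mix$means[k], mix$sds[k]),
      numeric(length(dtau))))
  } else {
    stats::dnorm(dtau, tau - model$onset_mean, model$onset_sd)
  }
}

# composite Simpson weights for an odd-length uniform grid
.simpson_w <- function(n, h) {
  w <- rep(c(4, 2), length.out = n - 2)
  h / 3 * c(1, w[-(n - 1)], 4, 1)[seq_len(n)]
}

#' Population density of methylation levels at an observation time
#'
#' Numerical quadrature (composite Simpson over 2001 elapsed-time nodes
#' spanning six onset standard deviations) of the onset-mixture integral;
#' the result is renormalised to unit mass on the methylation grid.
#'
#' @param model A \code{\link{modality_model}}.
#' @param tau Observation time (\eqn{> 0}).
#' @param n_quad Number of quadrature nodes (odd).
#' @return A data frame with \code{m} and density \code{p}.
#' @export
population_density <- function(model, tau, n_quad = 2001) {
  stopifnot(inherits(model, "modality_model"), tau > 0)
  if (n_quad %% 2 == 0) n_quad <- n_quad + 1
  centers <- tau - if (model$scenario == "bimodal_onset")
    model$onset_mix$means else model$onset_mean
  sds <- if (model$scenario == "bimodal_onset") model$onset_mix$sds
         else model$onset_sd
  dtau <- seq(min(centers - 6 * sds), max(centers + 6 * sds),
              length.out = n_quad)
  h <- dtau[2] - dtau[1]
  g <- .g_onset(model, dtau, tau)
  gsum <- sum(g) * h
  if (!is.finite(gsum) || gsum <= 0)
    stop("quadrature failure: onset density has no mass on [0, tau]; ",
         "tau = ", tau, ", grid step = ", signif(h, 3))
  g <- g / gsum
  # Simpson weights: 1,4,2,4,...,4,1 times h/3
  simp <- c(1, rep(c(4, 2), (n_quad - 3) / 2), 4, 1) * h / 3
  mbar <- mean_trajectory(dtau)
  m <- model$m_grid
  F <- vapply(seq_len(n_quad), function(i) .f_cond(model, m, mbar[i]),
              numeric(length(m)))
  p <- as.vector(F %*% (simp * g))
  dm <- diff(m)
  mass <- sum((p[-1] + p[-length(p)]) / 2 * dm)
  if (!is.finite(mass) || mass <= 0)
    stop("quadrature failure: population density has no mass")
  data.frame(m = m, p = p / mass)
}

#' Count modes of a density and classify modality
#'
#' Local maxima are retained when their topographic prominence is at
#' least 5\% of the global maximum; the density is classified as
#' \code{"unimodal"} or \code{"bimodal"} (two or more retained modes).
#'
#' @param p Density values on a grid (must integrate to 1 within 1e-3 on
#'   the grid supplied via \code{m}).
#' @param m Grid (defaults to a unit grid).
#' @param prominence_frac Minimum relative prominence of a retained mode.
#' @return A list with \code{n_modes}, \code{modes} (grid locations) and
#'   \code{modality}.
#' @export
classify_modality <- function(p, m = seq(0, 1, length.out = length(p)),
                              prominence_frac = 0.05) {
  dm <- diff(m)
  mass <- sum((p[-1] + p[-length(p)]) / 2 * dm)
  if (abs(mass - 1) > 1e-3) stop("density is not normalized (mass = ",
                                 signif(mass, 4), ")")
  n <- length(p)
  is_max <- which(diff(sign(diff(p))) < 0) + 1L
  if (p[1] > p[2]) is_max <- c(1L, is_max)
  if (p[n] > p[n - 1]) is_max <- c(is_max, n)
  if (!length(is_max)) is_max <- which.max(p)
  keep <- logical(length(is_max))
  gmax <- max(p)
  for (k in seq_along(is_max)) {
    i <- is_max[k]
    higher <- is_max[p[is_max] > p[i]]
    if (!length(higher)) { keep[k] <- TRUE; next }  # global max
    # prominence: height minus the highest saddle toward a higher peak
    saddles <- vapply(higher, function(j) {
      rng <- if (j < i) j:i else i:j
      min(p[rng])
    }, numeric(1))
    keep[k] <- (p[i] - max(saddles)) >= prominence_frac * gmax
  }
  modes <- m[is_max[keep]]
  list(n_modes = sum(keep), modes = modes,
       modality = if (sum(keep) >= 2) "bimodal" else "unimodal")
}

#' Modality signature of a scenario across time
#'
#' Classifies the population density at each observation time and
#' collapses the per-time classifications into an ordered signature of
#' runs (e.g. \code{"bimodal-unimodal-bimodal"} for the oscillatory
#' scenario).
#'
#' @param model A \code{\link{modality_model}}.
#' @param tau_grid Observation times; defaults to the characteristic
#'   early, intermediate and late stages of the de novo methylation
#'   sweep (\code{onset_mean + c(-4, 0, 5)}).
#' @return A list with per-time \code{modality} and the collapsed
#'   \code{signature} string.
#' @export
scenario_signature <- function(model,
                               tau_grid = model$onset_mean + c(-4, 0, 5)) {
  cls <- vapply(tau_grid, function(tau)
    classify_modality(population_density(model, tau)$p,
                      model$m_grid)$modality, character(1))
  runs <- rle(cls)$values
  list(modality = data.frame(tau = tau_grid, modality = cls),
       signature = paste(runs, collapse = "-"))
}

#' Early/late variance asymptotics of the mean methylation level
#'
#' With Gaussian onset variability (\eqn{\Delta\tau \sim N(\mu,
#' \sigma^2)}) and \eqn{u = e^{-\Delta\tau}}, the across-cell variance of
#' \eqn{\bar m} follows the lognormal closed forms
#' \eqn{u(\mu)^{-2} e^{\sigma^2}(e^{\sigma^2} - 1)} early (where
#' \eqn{\bar m \approx u^{-1}}) and
#' \eqn{u(\mu)^{2} e^{\sigma^2}(e^{\sigma^2} - 1)} late (where
#' \eqn{\bar m \approx 1 - u}). A Monte-Carlo estimate over \code{n_mc}
#' draws is returned alongside.
#'
#' @param mu Mean elapsed time.
#' @param sigma2 Onset variance (\eqn{> 0}).
#' @param regime \code{"early"} or \code{"late"}.
#' @param n_mc Monte-Carlo draws.
#' @param seed RNG seed.
#' @return A list with \code{closed_form}, \code{mc}, and
#'   \code{in_validity} (whether \eqn{\bar m(\mu)} lies within 0.1 of the
#'   relevant boundary; a warning is attached otherwise).
#' @export
variance_asymptotics <- function(mu, sigma2, regime = c("early", "late"),
                                 n_mc = 1e5, seed = 1) {
  regime <- match.arg(regime)
  stopifnot(sigma2 > 0)
  u_mu <- exp(-mu)
  cf <- if (regime == "early") u_mu^-2 * exp(sigma2) * (exp(sigma2) - 1)
        else u_mu^2 * exp(sigma2) * (exp(sigma2) - 1)
  set.seed(seed)
  dtau <- stats::rnorm(n_mc, mu, sqrt(sigma2))
  mc <- if (regime == "early") stats::var(exp(dtau)) else stats::var(exp(-dtau))
  mbar <- mean_trajectory(mu)
  in_validity <- if (regime == "early") mbar < 0.1 else mbar > 0.9
  if (!in_validity)
    warning("mean level ", signif(mbar, 3),
            " is outside the asymptotic regime of validity")
  list(closed_form = cf, mc = mc, in_validity = in_validity)
}

#' Across-cell variance of the mean methylation over a time sweep
#'
#' Monte-Carlo variance of \eqn{\bar m(\Delta\tau)} (full sigmoid, no
#' asymptotic expansion) across cells with Gaussian onset variability,
#' evaluated on a grid of observation times.
#'
#' @param model A \code{\link{modality_model}}.
#' @param tau_grid Observation times.
#' @param n_mc Draws per time point.
#' @param seed RNG seed.
#' @return A data frame with \code{tau} and \code{var_mbar}.
#' @export
variance_sweep <- function(model, tau_grid, n_mc = 2e4, seed = 1) {
  set.seed(seed)
  z <- stats::rnorm(n_mc)
  out <- vapply(tau_grid, function(tau) {
    dtau <- tau - (model$onset_mean + model$onset_sd * z)
    stats::var(mean_trajectory(dtau))
  }, numeric(1))
  data.frame(tau = tau_grid, var_mbar = out)
}
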