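#' Parameters of the dimensionless delayed turnover model
#'
#' The genome-averaged turnover of unmodified (C) and methylated (5mC)
#' cytosines is modelled by the dimensionless delay system
#' \deqn{\dot u(\tau) = v(\tau - \Delta\tau) - u(\tau) v(\tau), \qquad
#'       \dot v(\tau) = u(\tau) v(\tau) - v(\tau),}
#' where \eqn{u} and \eqn{v} are the unmethylated and methylated
#' concentrations (in units of the ratio of conversion rates), time is
#' measured in units of the inverse demethylation rate, and
#' \eqn{\Delta\tau} is the dimensionless delay between removal of the
#' methyl mark and reappearance of an unmodified cytosine.
#'
#' @param delta_tau Dimensionless delay (\eqn{\ge 0}).
#' @param u0,v0 Constant pre-history values of \eqn{u} and \eqn{v} on
#'   \eqn{[-\Delta\tau, 0]} (\eqn{\ge 0}).
#' @param epsilon Relative strength of non-autocatalytic de novo
#'   methylation (used by the \code{linear_denovo} variant).
#' @param hill Optional list with elements \code{A}, \code{B} (threshold
#'   concentrations) and integer Hill exponents \code{m}, \code{n} for the
#'   strongly nonlinear variant.
#' @param t_max Total integration time; must be at least
#'   \code{10 * delta_tau}.
#' @param dt Integrator step; defaults to \code{min(delta_tau / 200, 0.005)}
#'   (0.005 when \code{delta_tau} is 0). Must satisfy
#'   \code{dt <= delta_tau / 10} when \code{delta_tau > 0}.
#' @return An object of class \code{"delay_model_params"}.
#' @export
delay_model_params <- function(delta_tau, u0, v0, epsilon = 0, hill = NULL,
                               t_max = 1000, dt = NULL) {
  if (delta_tau < 0) stop("delta_tau must be >= 0")
  if (u0 < 0 || v0 < 0) stop("initial history values must be >= 0")
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (is.null(dt)) {
    dt <- if (delta_tau > 0) min(delta_tau / 200, 0.005) else 0.005
  }
  if (dt <= 0) stop("dt must be > 0")
  if (delta_tau > 0 && dt > delta_tau / 10)
    stop("dt too coarse relative to the delay (need dt <= delta_tau / 10)")
  if (t_max < 10 * delta_tau) stop("t_max must be at least 10 * delta_tau")
  if (!is.null(hill)) {
    stopifnot(all(c("A", "B", "m", "n") %in% names(hill)),
              hill$A > 0, hill$B > 0, hill$m >= 1, hill$n >= 1)
  }
  structure(list(delta_tau = delta_tau, u0 = u0, v0 = v0, epsilon = epsilon,
                 hill = hill, t_max = t_max, dt = dt),
            class = "delay_model_params")
}

#' Integrate the delayed turnover equations
#'
#' Fixed-step RK4 method of steps with linear interpolation of the stored
#' history. Four structural variants are supported: the \code{baseline}
#' autocatalytic system, \code{linear_denovo} adding a term
#' \eqn{\epsilon u} for methylation-independent de novo activity,
#' \code{hill} replacing the conversion terms by Hill functions, and
#' \code{time_dependent_rates} applying multiplicative schedules to the
#' methylation and demethylation channels (emulating time-dependent enzyme
#' levels).
#'
#' @param params A \code{\link{delay_model_params}} object.
#' @param variant One of \code{"baseline"}, \code{"linear_denovo"},
#'   \code{"hill"}, \code{"time_dependent_rates"}.
#' @param schedules For \code{time_dependent_rates}: a list with functions
#'   \code{cm(tau)} and \code{mc(tau)} multiplying the methylation (C to
#'   5mC) and demethylation (5mC to C) channels. The delayed completion
#'   term uses the demethylation schedule evaluated at the initiation time
#'   \eqn{\tau - \Delta\tau}. Defaults to a logistic ramp
#'   \code{1 / (1 + exp(-(tau - t_max/10) / (t_max/50)))} on both channels.
#' @return A data frame of class \code{"meth_trajectory"} with columns
#'   \code{tau}, \code{u}, \code{v}.
#' @export
integrate_dde <- function(params,
                          variant = c("baseline", "linear_denovo", "hill",
                                      "time_dependent_rates"),
                          schedules = NULL) {
  stopifnot(inherits(params, "delay_model_params"))
  variant <- match.arg(variant)
  vcode <- match(variant, c("baseline", "linear_denovo", "hill",
                            "time_dependent_rates")) - 1L
  hl <- params$hill
  if (variant == "hill" && is.null(hl))
    stop("variant 'hill' requires a hill parameter record")
  if (is.null(hl)) hl <- list(A = 1, B = 1, m = 1, n = 1)
  s_cm <- s_mc <- s_mc_del <- numeric(0)
  if (variant == "time_dependent_rates") {
    if (is.null(schedules)) {
      t0 <- params$t_max / 10
      w <- params$t_max / 50
      ramp <- function(tau) 1 / (1 + exp(-(tau - t0) / w))
      schedules <- list(cm = ramp, mc = ramp)
    }
    nstep <- round(params$t_max / params$dt)
    th <- seq(0, params$t_max, by = params$dt / 2)
    stopifnot(length(th) == 2 * nstep + 1)
    s_cm <- schedules$cm(th)
    s_mc <- schedules$mc(th)
    s_mc_del <- schedules$mc(pmax(th - params$delta_tau, 0))
  }
  m <- dde_rk4_cpp(params$u0, params$v0, params$delta_tau, params$t_max,
                   params$dt, vcode, params$epsilon, hl$A, hl$B, hl$m, hl$n,
                   s_cm, s_mc, s_mc_del)
  out <- data.frame(tau = m[, 1], u = m[, 2], v = m[, 3])
  attr(out, "params") <- params
  attr(out, "variant") <- variant
  class(out) <- c("meth_trajectory", "data.frame")
  out
}

#' Maximum defect of the delayed conservation law
#'
#' For the baseline variant the quantity
#' \eqn{u(\tau) + v(\tau) + \int_{\tau-\Delta\tau}^{\tau} v(s)\,ds}
#' is conserved (it counts all cytosines including those in transit through
#' the demethylation pipeline). Returns the maximum absolute deviation from
#' its initial value \eqn{u_0 + v_0 + \Delta\tau\, v_0} along the
#' trajectory.
#'
#' @param traj A \code{meth_trajectory} from \code{\link{integrate_dde}}.
#' @return Maximum absolute conservation defect (scalar).
#' @export
conservation_defect <- function(traj) {
  p <- attr(traj, "params")
  dt <- p$dt
  dtau <- p$delta_tau
  v <- traj$v
  # cumulative trapezoid of v from 0
  cumint <- c(0, cumsum((v[-1] + v[-length(v)]) / 2 * dt))
  tau <- traj$tau
  lower <- tau - dtau
  # integral over [tau - dtau, tau]; history contributes v0 * max(0, -lower)
  int_lo <- ifelse(lower <= 0, 0, stats::approx(tau, cumint, xout = pmax(lower, 0))$y)
  hist_part <- pmax(0, -lower) * p$v0
  total <- traj$u + v + (cumint - int_lo) + hist_part
  max(abs(total - (p$u0 + p$v0 + dtau * p$v0)))
}

#' Summarise oscillations in a trajectory
#'
#' Locates the roots of \eqn{dv/d\tau} (extrema of the methylated
#' concentration). The period is the mean spacing between next-nearest
#' roots over the last \code{n_last_cycles} cycles; the amplitude is the
#' mean absolute difference between consecutive extremal values
#' (peak-to-trough). A trajectory counts as oscillating only if the
#' amplitude exceeds \code{amp_tol} and is sustained, i.e. drifts by less
#' than 5\% between the last two \code{n_last_cycles}-cycle windows.
#'
#' @param traj A \code{meth_trajectory} (or any data frame with
#'   \code{tau}, \code{u}, \code{v}).
#' @param n_last_cycles Number of trailing cycles to average over.
#' @param amp_tol Amplitude below which the trajectory is classified as
#'   non-oscillating.
#' @return A list with \code{oscillating}, \code{period},
#'   \code{amplitude_u}, \code{amplitude_v}, \code{n_cycles_used}.
#' @export
oscillation_summary <- function(traj, n_last_cycles = 10, amp_tol = 1e-3) {
  if (nrow(traj) < 5 || anyNA(traj$v)) stop("trajectory is empty or contains NaN")
  ext_v <- .extrema(traj$tau, traj$v)
  ext_u <- .extrema(traj$tau, traj$u)
  need <- 2 * (2 * n_last_cycles) + 1   # two windows of n cycles
  no <- list(oscillating = FALSE, period = NA_real_, amplitude_u = 0,
             amplitude_v = 0, n_cycles_used = 0L)
  if (length(ext_v$t) < need) return(no)
  k <- 2 * n_last_cycles
  tt <- ext_v$t
  vv <- ext_v$v
  last <- seq(length(tt) - k + 1, length(tt))
  prev <- last - k
  amp_last <- mean(abs(diff(vv[last])))
  amp_prev <- mean(abs(diff(vv[prev])))
  if (amp_last < amp_tol) return(no)
  sustained <- abs(amp_last - amp_prev) / amp_last < 0.05
  if (!sustained) return(no)
  period <- mean(diff(tt[last], lag = 2)) # next-nearest roots
  nu <- length(ext_u$t)
  amp_u <- if (nu >= k + 1)
    mean(abs(diff(ext_u$v[seq(nu - k, nu)]))) else 0
  list(oscillating = TRUE, period = period, amplitude_u = amp_u,
       amplitude_v = amp_last, n_cycles_used = as.integer(n_last_cycles))
}

# extrema via sign changes of the finite-difference derivative
.extrema <- function(t, y) {
  dy <- diff(y)
  s <- sign(dy)
  nz <- which(s != 0)
  if (length(nz) < 2) return(list(t = numeric(0), v = numeric(0)))
  idx <- nz[which(diff(s[nz]) != 0)] + 1L
  list(t = t[idx], v = y[idx])
}

#' Scan the delay for the onset of sustained oscillations
#'
#' Integrates the model across a grid of dimensionless delays and reports
#' the smallest delay whose asymptotic oscillation amplitude exceeds
#' \code{amp_tol} (the Hopf threshold of the turnover model).
#'
#' @param params A \code{\link{delay_model_params}} object supplying
#'   \code{u0}, \code{v0}, \code{t_max}; its \code{delta_tau} is ignored.
#' @param delta_tau_grid Increasing grid of delays to scan.
#' @param amp_tol Oscillation amplitude tolerance.
#' @param variant,schedules Passed to \code{\link{integrate_dde}}.
#' @return A list with \code{threshold} (\code{NA} if the grid is entirely
#'   sub-critical) and a data frame \code{amplitudes} with columns
#'   \code{delta_tau}, \code{amplitude}, \code{period}.
#' @export
hopf_threshold_scan <- function(params, delta_tau_grid, amp_tol = 1e-3,
                                variant = "baseline", schedules = NULL) {
  stopifnot(inherits(params, "delay_model_params"))
  res <- lapply(delta_tau_grid, function(dtau) {
    p <- delay_model_params(dtau, params$u0, params$v0, params$epsilon,
                            params$hill, params$t_max)
    s <- oscillation_summary(integrate_dde(p, variant, schedules),
                             amp_tol = amp_tol)
    data.frame(delta_tau = dtau,
               amplitude = if (s$oscillating) s$amplitude_v else 0,
               period = s$period)
  })
  tab <- do.call(rbind, res)
  sup <- which(tab$amplitude > amp_tol)
  list(threshold = if (length(sup)) tab$delta_tau[min(sup)] else NA_real_,
       amplitudes = tab)
}

#' Linear stability of the balanced stationary state
#'
#' The balanced fixed point \eqn{(u, v) = (1, \bar v)} of the baseline
#' system has the characteristic equation
#' \eqn{\lambda^2 + \bar v \lambda + \bar v (1 - e^{-\lambda \Delta\tau}) = 0.}
#' The rightmost root is located numerically by damped Newton iteration
#' from a grid of complex starting points; the state is classified as
#' unstable when its real part is positive. Serves as a brute-force
#' cross-check of \code{\link{hopf_threshold_scan}}.
#'
#' @param v_bar Stationary methylated level (\eqn{> 0}).
#' @param delta_tau Dimensionless delay.
#' @return A list with \code{classification} ("stable"/"unstable"),
#'   \code{leading_re} and the leading complex \code{root}.
#' @export
linearized_threshold <- function(v_bar, delta_tau) {
  stopifnot(v_bar > 0, delta_tau >= 0)
  f <- function(z) z^2 + v_bar * z + v_bar * (1 - exp(-z * delta_tau))
  fp <- function(z) 2 * z + v_bar + v_bar * delta_tau * exp(-z * delta_tau)
  re0 <- seq(-2, 1, length.out = 9) * max(1, 1 / max(delta_tau, 0.5))
  im0 <- seq(0, 3 * pi / max(delta_tau, 0.5) + 3, length.out = 17)
  z <- outer(re0, im0, function(a, b) complex(real = a, imaginary = b))
  z <- as.vector(z)
  for (it in 1:60) {
    step <- f(z) / fp(z)
    step[!is.finite(step)] <- 0
    z <- z - step
  }
  ok <- abs(f(z)) < 1e-9
  if (!any(ok))
    stop("root search failed to converge; residuals: ",
         paste(signif(range(abs(f(z))), 3), collapse = " .. "))
  z <- z[ok]
  # drop the trivial root at 0 (neutral direction along the conserved family)
  z <- z[abs(z) > 1e-8]
  if (!length(z)) {
    return(list(classification = "stable", leading_re = 0, root = 0 + 0i))
  }
  lead <- z[which.max(Re(z))]
  list(classification = if (Re(lead) > 1e-8) "unstable" else "stable",
       leading_re = Re(lead), root = lead)
}

#' Closed-form Hopf crossing of the linearised balanced state
#'
#' Solving the characteristic equation for a purely imaginary root gives
#' \eqn{\omega = \sqrt{\bar v (2 - \bar v)}} and the critical delay
#' \eqn{\Delta\tau_c = (2\pi - \arccos(\bar v - 1)) / \omega}
#' (valid for \eqn{0 < \bar v < 2}).
#'
#' @param v_bar Stationary methylated level in (0, 2).
#' @return Critical dimensionless delay.
#' @export
hopf_delay_critical <- function(v_bar) {
  stopifnot(v_bar > 0, v_bar < 2)
  omega <- sqrt(v_bar * (2 - v_bar))
  (2 * pi - acos(v_bar - 1)) / omega
}

#' Asymptotic methylated level of the balanced branch
#'
#' From the delayed conservation law, a trajectory attracted to the
#' balanced state \eqn{u = 1} settles at
#' \eqn{\bar v = (u_0 + v_0 + \Delta\tau v_0 - 1) / (1 + \Delta\tau)}.
#'
#' @param params A \code{\link{delay_model_params}} object.
#' @return Stationary \eqn{\bar v} implied by the conserved quantity.
#' @export
stationary_v <- function(params) {
  with(params, (u0 + v0 + delta_tau * v0 - 1) / (1 + delta_tau))
}
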