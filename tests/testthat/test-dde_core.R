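test_that("stationary branches are held fixed by the integrator", {
  # balanced branch u = 1: any constant v is stationary
  tr <- integrate_dde(delay_model_params(3, u0 = 1, v0 = 0.7, t_max = 100))
  expect_true(all(tr$u == 1))
  expect_true(all(tr$v == 0.7))
  # fully unmethylated branch v = 0
  tr2 <- integrate_dde(delay_model_params(3, u0 = 2, v0 = 0, t_max = 100))
  expect_true(all(tr2$u == 2))
  expect_true(all(tr2$v == 0))
})

test_that("parameter validation rejects bad inputs", {
  expect_error(delay_model_params(-1, 1, 1), "delta_tau")
  expect_error(delay_model_params(3, -1, 1), ">= 0")
  expect_error(delay_model_params(3, 1, 1, dt = 0.5), "coarse")
  expect_error(delay_model_params(3, 1, 1, t_max = 20), "t_max")
  expect_error(integrate_dde(delay_model_params(3, 1, 1, t_max = 100),
                             variant = "hill"), "hill")
  expect_error(oscillation_summary(data.frame(tau = 1, u = 1, v = NaN)),
               "NaN")
})

test_that("super-critical delay yields a sustained limit cycle", {
  s1 <- oscillation_summary(
    integrate_dde(delay_model_params(8, 1.6, 0.4, t_max = 1000)))
  expect_true(s1$oscillating)
  # amplitude independent of further integration time
  s2 <- oscillation_summary(
    integrate_dde(delay_model_params(8, 1.6, 0.4, t_max = 2000)))
  expect_lt(abs(s1$amplitude_v - s2$amplitude_v) / s1$amplitude_v, 0.02)
  # sub-critical delay decays
  s3 <- oscillation_summary(
    integrate_dde(delay_model_params(3, 1.6, 0.4, t_max = 1000)))
  expect_false(s3$oscillating)
})

test_that("baseline variant conserves the delayed cytosine count", {
  tr <- integrate_dde(delay_model_params(8, 1.6, 0.4, t_max = 1000))
  expect_lt(conservation_defect(tr), 1e-4)
})

test_that("oscillation summary recovers a closed-form sinusoid", {
  tau <- seq(0, 200, by = 0.01)
  v <- 1 + 0.3 * sin(2 * pi * tau / 5)
  s <- oscillation_summary(data.frame(tau = tau, u = v, v = v))
  expect_true(s$oscillating)
  expect_lt(abs(s$period - 5) / 5, 0.01)
  expect_lt(abs(s$amplitude_v - 0.6) / 0.6, 0.01)
  # constant trajectory: not oscillating, zero amplitude
  s0 <- oscillation_summary(data.frame(tau = tau, u = 1, v = 0.7))
  expect_false(s0$oscillating)
  expect_equal(s0$amplitude_v, 0)
})

test_that("period grows linearly with the delay above threshold", {
  dts <- seq(6, 12, by = 1)
  per <- vapply(dts, function(d)
    oscillation_summary(
      integrate_dde(delay_model_params(d, 1.6, 0.4, t_max = 1000)))$period,
    numeric(1))
  expect_gt(summary(stats::lm(per ~ dts))$r.squared, 0.95)
})

test_that("Hopf scan finds the onset and the linearised oracle agrees", {
  p <- delay_model_params(1, 1.6, 0.4, t_max = 1000)
  sc <- hopf_threshold_scan(p, seq(3, 7, by = 0.25))
  expect_false(is.na(sc$threshold))
  # oracle: closed-form crossing with the self-consistent stationary level
  root <- uniroot(function(d) hopf_delay_critical(stationary_v(
    delay_model_params(d, 1.6, 0.4))) - d, c(2, 9))$root
  expect_lt(abs(sc$threshold - root), 0.25 + 1e-9) # within one grid step
  # amplitudes are 0 below and positive above the detected onset
  amp <- sc$amplitudes
  expect_true(all(amp$amplitude[amp$delta_tau < sc$threshold] == 0))
  expect_true(all(amp$amplitude[amp$delta_tau >= sc$threshold] > 0))
  # numeric rightmost-root classification brackets the crossing
  vb <- stationary_v(delay_model_params(root, 1.6, 0.4))
  expect_equal(linearized_threshold(vb, root - 0.5)$classification, "stable")
  expect_equal(linearized_threshold(vb, root + 0.5)$classification, "unstable")
  expect_equal(linearized_threshold(0.4, 0)$classification, "stable")
  expect_equal(linearized_threshold(0.4, 20)$classification, "unstable")
  # entirely sub-critical grid: absent threshold, no error
  sc0 <- hopf_threshold_scan(delay_model_params(1, 1.6, 0.4, t_max = 300),
                             seq(0, 1, by = 0.5))
  expect_true(is.na(sc0$threshold))
  expect_true(all(sc0$amplitudes$amplitude < 1e-3))
})

test_that("linear de novo methylation raises the oscillation threshold", {
  base <- hopf_threshold_scan(delay_model_params(1, 1.6, 0.4, t_max = 600),
                              seq(3, 9, by = 0.5))
  eps <- hopf_threshold_scan(
    delay_model_params(1, 1.6, 0.4, epsilon = 0.2, t_max = 600),
    seq(3, 9, by = 0.5), variant = "linear_denovo")
  expect_gt(eps$threshold, base$threshold)
})

test_that("structural variants stay non-negative and bounded", {
  ph <- delay_model_params(6, 1.6, 0.4, t_max = 300,
                           hill = list(A = 1, B = 1, m = 1, n = 1))
  trh <- integrate_dde(ph, variant = "hill")
  expect_true(all(trh$u >= 0) && all(trh$v >= 0))
  expect_true(all(trh$u < 50) && all(trh$v < 50))
  # Hill with unit thresholds/exponents is not the baseline system
  trb <- integrate_dde(delay_model_params(6, 1.6, 0.4, t_max = 300))
  expect_gt(max(abs(trh$v - trb$v)), 0.01)
  # time-dependent rates with the default logistic ramp
  trt <- integrate_dde(delay_model_params(6, 1.6, 0.4, t_max = 300),
                       variant = "time_dependent_rates")
  expect_true(all(trt$u >= 0) && all(trt$v >= 0))
})

test_that("trajectories agree with an independent DDE solver", {
  skip_if_not_installed("deSolve")
  p <- delay_model_params(3, 1.6, 0.4, t_max = 60)
  mine <- integrate_dde(p)
  f <- function(t, y, parms) {
    vlag <- if (t < 3) 0.4 else deSolve::lagvalue(t - 3, 2)
    list(c(vlag - y[1] * y[2], y[1] * y[2] - y[2]))
  }
  ref <- deSolve::dede(c(u = 1.6, v = 0.4), seq(0, 60, by = 0.1), f, NULL)
  got <- approx(mine$tau, mine$v, xout = ref[, "time"])$y
  expect_lt(max(abs(got - ref[, "v"])), 1e-3)
})
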