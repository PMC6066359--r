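test_that("an uncoupled site steps as a Poisson process", {
  set.seed(1)
  cnt <- replicate(300, {
    m <- lattice_model(positions = 1, n_states = 12, omega = 2,
                       lambda = 0, kappa = 0)
    simulate_lattice(m, t_end = 10)$steps_fwd
  })
  lam <- 2 * 10 * 12 / (2 * pi)   # omega * t * n / (2 pi)
  expect_lt(abs(mean(cnt) - lam) / lam, 0.05)
  expect_lt(abs(stats::var(as.numeric(cnt)) / mean(cnt) - 1), 0.25)
})

test_that("independent oscillators stay incoherent, coupled ones lock", {
  pos <- seq(1, by = 1000, length.out = 200)
  m0 <- lattice_model(pos, n_states = 20, omega = 1, lambda = 0,
                      kappa = 0, sigma = 1, seed = 3)
  r0 <- simulate_lattice(m0, t_end = 30)
  expect_lt(mean(tail(r0$sync$r, 20)), 3 / sqrt(200))
  m1 <- lattice_model(pos, n_states = 20, omega = 1, lambda = 0,
                      kappa = 6 / 200, sigma = 1, seed = 4)
  r1 <- simulate_lattice(m1, t_end = 60)
  expect_gt(mean(tail(r1$sync$r, 20)), 0.8)
  expect_true(all(r0$sync$r >= 0 & r0$sync$r <= 1))
})

test_that("coarse-graining bookkeeping is exact", {
  set.seed(5)
  pos <- as.vector(vapply(0:19, function(b) b * 500 + (1:10) * 2,
                          numeric(10)))
  om <- stats::rnorm(200, 1, 0.2)
  m <- lattice_model(pos, n_states = 20, omega = om, xi = 5,
                     lambda = 2000, kappa = 0.02, sigma = 1.5, seed = 6)
  ens <- coarse_grain(m)
  # weighted frequency sum is conserved
  expect_equal(sum(ens$n * ens$omega), sum(om), tolerance = 1e-12)
  # response scales as kappa / n, contribution as n * sigma
  expect_equal(ens$kappa, 0.02 / ens$n, tolerance = 1e-12)
  expect_equal(ens$sigma, 1.5 * ens$n, tolerance = 1e-12)
  expect_lt(length(ens$omega), 200)
  # merging two identical unit blocks keeps the shared frequency
  m2 <- lattice_model(c(1, 3), n_states = 12, omega = 1.3, xi = 10,
                      lambda = 50, kappa = 0.01, sigma = 1)
  e2 <- coarse_grain(m2)
  expect_equal(e2$omega, 1.3)
  expect_equal(e2$n, 2L)
})

test_that("mean-field ensemble reproduces classic Kuramoto behaviour", {
  # identical phases stay fully ordered
  ens <- oscillator_ensemble(rep(1.3, 100), kappa = 0.5, sigma = 1)
  k1 <- simulate_kuramoto(ens, 50, phases0 = rep(0.7, 100))
  expect_true(all(abs(k1$sync$r - 1) < 1e-9))
  # relaxation accelerates with coupling
  relax <- function(kap) {
    e <- oscillator_ensemble(rep(1, 300), kappa = kap, sigma = 1)
    s <- simulate_kuramoto(e, 40, seed = 7)$sync
    s$t[min(which(s$r > 0.9))]
  }
  tt <- c(relax(0.5), relax(1), relax(2))
  expect_true(all(diff(tt) < 0))
  # Lorentzian frequencies: closed form r = sqrt(1 - Kc/K), Kc = 2*gamma
  set.seed(5)
  fr <- stats::rcauchy(2000); fr <- fr[abs(fr) < 50]
  k2 <- simulate_kuramoto(oscillator_ensemble(fr, kappa = 3, sigma = 1),
                          150, dt = 0.01, seed = 6)
  expect_lt(abs(k2$r_asymptotic - sqrt(1 - 2 / 3)), 0.05)
  expect_error(simulate_kuramoto(oscillator_ensemble(numeric(0)), 10),
               "empty")
})

test_that("order parameter is rotation invariant", {
  set.seed(8)
  ph <- stats::runif(50, 0, 2 * pi)
  ens <- oscillator_ensemble(rep(0, 50), kappa = 0, sigma = runif(50))
  r1 <- simulate_kuramoto(ens, 1, dt = 0.5, phases0 = ph)$sync$r[1]
  r2 <- simulate_kuramoto(ens, 1, dt = 0.5, phases0 = ph + 1.234)$sync$r[1]
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("threshold formulas match plug-in values", {
  # standard normal frequencies: kc = 2 / (pi / sqrt(2 pi)) ~ 1.596
  expect_equal(synchronization_threshold(stats::dnorm(0))$kappa_c,
               2 * sqrt(2 * pi) / pi, tolerance = 1e-12)
  # Lorentzian half-width gamma: g(0) = 1/(pi gamma) so kc = 2 gamma
  gam <- 0.7
  expect_equal(synchronization_threshold(1 / (pi * gam))$kappa_c, 2 * gam,
               tolerance = 1e-12)
  # delta-distributed frequencies: kc -> 0, any coupling synchronizes
  s <- synchronization_threshold(1e12, kappa_sample = rep(1e-3, 5))
  expect_lt(s$kappa_c, 1e-10)
  expect_true(s$condition_met)
  expect_error(synchronization_threshold(0), "undefined")
  # heterogeneous condition uses the second moment
  h <- synchronization_threshold(stats::dnorm(0),
                                 kappa_sample = list(mean = 1, var = 2))
  expect_equal(h$kappa_sq_mean, 3)
})

test_that("near-critical scaling follows the square-root law", {
  cs <- critical_scaling(mu_grid = c(0.02, 0.05, 0.1), n_osc = 1000,
                         n_seeds = 2, seed = 1)
  expect_gt(cs$exponent, 0.4)
  expect_lt(cs$exponent, 0.6)
  expect_lt(abs(cs$prefactor - cs$prefactor_theory) / cs$prefactor_theory,
            0.2)
  expect_error(critical_scaling(mu_grid = c(-0.1, 0.1)), "super-critical")
})

test_that("coarse-grained ensemble tracks the full lattice when ordered", {
  set.seed(10)
  pos <- as.vector(vapply(0:29, function(b) b * 500 + (1:10) * 2,
                          numeric(10)))
  om <- stats::rnorm(300, 1, 0.1)
  m <- lattice_model(pos, n_states = 40, omega = om, xi = 5,
                     lambda = 2000, kappa = 8 / 300, sigma = 1, seed = 11)
  r_lat <- mean(tail(simulate_lattice(m, t_end = 20)$sync$r, 15))
  ens <- rescale_for_meanfield(coarse_grain(m), 300, m$eps_coupling)
  r_cg <- simulate_kuramoto(ens, 60, seed = 12)$r_asymptotic
  expect_lt(abs(r_lat - r_cg), 0.1)
})
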