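library(data.table)

test_that("informative-CpG tiling partitions chromosomes correctly", {
  calls <- constant_calls(n_cells = 2, n_pos = 50)
  tl <- tile_by_informative_cpgs(calls, window = 50)
  expect_equal(nrow(tl$tiles), 1L)
  expect_equal(tl$tiles$n_informative, 50L)
  # 173 informative CpGs, window 50: 3 tiles, 23 dropped
  calls2 <- constant_calls(n_cells = 1, n_pos = 173)
  tl2 <- tile_by_informative_cpgs(calls2, window = 50)
  expect_equal(nrow(tl2$tiles), 3L)
  expect_true(all(tl2$tiles$n_informative == 50L))
  # tiles are disjoint and ordered
  expect_true(all(tl2$tiles$start[-1] > tl2$tiles$end[-3]))
  expect_error(tile_by_informative_cpgs(calls, window = 1), "window")
  # unsorted input rejected
  bad <- data.table(sample_id = "a", chrom = "chr1", pos = c(10L, 5L),
                    meth = 1L, unmeth = 1L)
  expect_error(tile_by_informative_cpgs(bad, window = 2), "sorted")
})

test_that("tile densities recover the generator's block truth", {
  g <- genome_spec(densities = c(0.01, 0.025, 0.1), blocks_per_density = 2,
                   cpgs_per_block = 100)
  ds <- generate_single_cell_dataset(g, n_cells = 20, dropout = 0,
                                     seed = 5)
  tl <- tile_by_informative_cpgs(ds$calls, window = 50, all_positions = g)
  # with zero dropout tiles align to blocks: density within 10% of truth
  truth <- rep(sort(unique(g$density_real)), each = 4)
  got <- sort(tl$tiles$cpg_density)
  expect_equal(length(got), length(truth))
  expect_true(all(abs(got - sort(truth)) / sort(truth) < 0.1))
})

test_that("excess variance calibrates to 1 on technical noise only", {
  # identical rates in every sample: zero variance
  tl0 <- tile_by_informative_cpgs(constant_calls(), window = 50)
  ev0 <- excess_variance(tl0)
  expect_true(all(ev0$excess_var == 0))
  # binomial-only data: mean statistic 1.0 +- 0.1
  g <- genome_spec()
  ds <- generate_single_cell_dataset(g, n_cells = 50, amplitude_scale = 0,
                                     dropout = 0.3, seed = 6)
  ev <- excess_variance(tile_by_informative_cpgs(ds$calls, window = 50,
                                                 all_positions = g))
  expect_gt(nrow(ev), 80)
  expect_lt(abs(mean(ev$excess_var) - 1), 0.1)
  # oscillatory data: statistic peaks in the 2-3% density bin
  dso <- generate_single_cell_dataset(g, n_cells = 50, seed = 7)
  evo <- excess_variance(tile_by_informative_cpgs(dso$calls, window = 50,
                                                  all_positions = g))
  evo[, bin := cut(cpg_density, c(0, 0.01, 0.02, 0.03, 0.05, 0.1, 1))]
  prof <- evo[, .(m = mean(excess_var)), by = bin][order(bin)]
  expect_equal(which.max(prof$m), 3L)  # (0.02, 0.03]
})

test_that("binomial null bounds shrink with coverage and match the SE", {
  expect_equal(technical_null_bounds(0, c(10, 20)), c(0, 0))
  set.seed(1)
  w_small <- diff(technical_null_bounds(0.5, rep(20, 10)))
  w_large <- diff(technical_null_bounds(0.5, rep(2000, 10)))
  expect_lt(w_large, w_small / 5)
  # closed-form: sd of the weighted mean is sqrt(p q / sum s)
  width_theory <- 2 * qnorm(0.975) * sqrt(0.25 / 200)
  expect_lt(abs(w_small - width_theory) / width_theory, 0.15)
  expect_error(technical_null_bounds(0.5, c(0, 0)), "coverage")
})

test_that("quadratic detrending removes trends and keeps signal", {
  t <- seq(0, 100, by = 1)
  expect_equal(detrend_poly2(t, 2 + 0.3 * t - 0.01 * t^2), rep(0, 101),
               tolerance = 1e-8)
  expect_equal(detrend_poly2(t, rep(3, 101)), rep(0, 101),
               tolerance = 1e-10)
  y <- 1 + 0.05 * t + 0.001 * t^2 + 0.4 * sin(2 * pi * t / 8)
  r <- detrend_poly2(t, y)
  fit <- stats::lm(r ~ sin(2 * pi * t / 8) + cos(2 * pi * t / 8))
  amp <- sqrt(sum(stats::coef(fit)[2:3]^2))
  expect_lt(abs(amp - 0.4) / 0.4, 0.05)
  expect_error(detrend_poly2(1:3, 1:3), "4 points")
})

test_that("Lomb-Scargle locates pure tones and ignores time origin", {
  t <- seq(0, 3390, length.out = 31)
  periods <- seq(90, 300, by = 10)
  y <- sin(2 * pi * t / 150 + 0.3)
  p <- lomb_scargle(t, y, periods)
  expect_equal(periods[which.max(p)], 150)
  # invariance under a shift of the time origin (same samples)
  p2 <- lomb_scargle(t + 777, y, periods)
  expect_equal(p, p2, tolerance = 1e-8)
})

test_that("spectral enrichment is calibrated and detects shared tones", {
  t <- seq(0, 3390, length.out = 31)
  periods <- seq(90, 300, by = 10)
  set.seed(2)
  # pooled type-I over independent white-noise cohorts
  fr <- vapply(1:20, function(i) {
    sp <- spectral_enrichment(t, matrix(rnorm(300 * 31), 300, 31),
                              periods, n_null = 3000,
                              seed = 1000 + i)
    mean(sp$table$significant)
  }, numeric(1))
  expect_gt(mean(fr), 0.005)
  expect_lt(mean(fr), 0.12)
  # injected common 150-min tone at SNR 0.5
  Y <- matrix(rnorm(200 * 31), 200, 31) +
    outer(rep(0.5 * sqrt(2), 200), sin(2 * pi * t / 150))
  sp2 <- spectral_enrichment(t, Y, periods, n_null = 3000, seed = 9)
  expect_lt(sp2$table$p[sp2$table$period == 150], 0.05)
  # short series are excluded with a message
  Y2 <- rbind(Y[1:3, ], c(rnorm(5), rep(NA, 26)))
  expect_message(spectral_enrichment(t, Y2, periods, n_null = 500,
                                     seed = 1), "excluded")
})

test_that("amplicon scan filters, discards boundary peaks, tests enrichment", {
  tp <- seq(0, 920, by = 20)
  # locus with only 19 deep points is excluded
  few <- data.table(locus = "x", group = "treatment", time_min = tp,
                    meth = 50L, total = c(rep(300L, 19), rep(50L, 28)))
  expect_equal(nrow(amplicon_scan(few, n_null = 50)$loci), 0L)
  # exact 90-min tone peaks at the scan boundary and is discarded
  set.seed(3)
  rate90 <- 0.5 + 0.2 * sin(2 * pi * tp / 90)
  b <- data.table(locus = "b", group = "treatment", time_min = tp,
                  meth = as.integer(round(400 * rate90)), total = 400L)
  resb <- amplicon_scan(b, n_null = 200, seed = 4)$loci
  expect_true(resb$boundary)
  expect_false(resb$significant)
  # generator cohort: oscillating loci recovered, Fisher enrichment < 0.05
  amp <- generate_amplicon_timecourse(seed = 5)
  sc <- amplicon_scan(amp$series, n_null = 400, seed = 6)
  tr <- merge(sc$loci[group == "treatment"], amp$truth, by = "locus")
  expect_gte(sum(tr$significant & tr$oscillating), 3)
  expect_lt(sc$fisher$p, 0.05)
  # one-sided Fisher oracle: 4/14 vs 0/14 gives p just under 0.05,
  # frozen from the hypergeometric tail P(X >= 4)
  expect_equal(stats::fisher.test(matrix(c(4, 10, 0, 14), 2, byrow = TRUE),
                                  alternative = "greater")$p.value,
               choose(24, 10) / choose(28, 14), tolerance = 1e-12)
})

test_that("dip statistic matches hand-derived exact values", {
  ds <- function(x) methosc:::dip_stat_cpp(sort(x))
  expect_equal(ds(c(0, 1)), 0.25)
  expect_equal(ds((1:10) / 11), 1 / 20)        # equally spaced: 1/(2n)
  expect_equal(ds(c(0, 0, 1, 1)), 0.25)        # two half atoms
  expect_equal(ds(c(0, 0, 0, 1)), 0.125)       # atom absorbed at the mode
  expect_equal(ds(c(0, 0.5, 1)), 1 / 6)        # three equal atoms
  expect_true(ds(c(0.2, 0.2, 0.2)) == 0)
})

test_that("dip test is calibrated on unimodal nulls and powered when far", {
  set.seed(4)
  pnull <- replicate(400, dip_test(stats::runif(80))$p)
  expect_lte(mean(pnull < 0.05), 0.075)
  pgauss <- replicate(200, dip_test(stats::rnorm(80))$p)
  expect_lte(mean(pgauss < 0.05), 0.075)
  # 5-sigma separation: high power; 4-sigma: moderate power
  p5 <- replicate(200, dip_test(c(rnorm(40, -2.5), rnorm(40, 2.5)))$p)
  expect_gte(mean(p5 < 0.05), 0.72)
  p4 <- replicate(200, dip_test(c(rnorm(40, -2), rnorm(40, 2)))$p)
  expect_gte(mean(p4 < 0.05), 0.3)
  ct <- dip_test(rep(0.4, 50))
  expect_equal(ct$dip, 0)
  expect_equal(ct$p, 1, tolerance = 1e-3)
  expect_null(dip_test(runif(9)))
})

test_that("bimodality scans localise oscillatory density bins", {
  g <- genome_spec()
  # technical-noise-only data: near-nominal fractions everywhere
  ds0 <- generate_single_cell_dataset(g, n_cells = 40, amplitude_scale = 0,
                                      seed = 8)
  tl0 <- tile_by_informative_cpgs(ds0$calls, window = 50,
                                  all_positions = g)
  bs0 <- bimodality_scan(tl0, "cpg_density", n_mc = 500, n_boot = 200,
                         seed = 9)
  expect_true(all(bs0$bins$fraction <= 0.1))
  # oscillatory cells: fraction peaks in the 2-3% density bin
  ds1 <- generate_single_cell_dataset(g, n_cells = 80, coherence = 0.9,
                                      seed = 10)
  tl1 <- tile_by_informative_cpgs(ds1$calls, window = 50,
                                  all_positions = g)
  bs1 <- bimodality_scan(tl1, "cpg_density",
                         bins = c(0, 0.01, 0.02, 0.03, 0.05, 0.10, 0.30),
                         n_mc = 1000, n_boot = 200, seed = 11)
  peak <- bs1$bins$fraction[3]                 # (0.02, 0.03]
  expect_equal(peak, max(bs1$bins$fraction))
  expect_gt(peak, bs1$bins$fraction[1])        # above the 0-1% bin
  expect_gt(peak, bs1$bins$fraction[6])        # above the CpG-rich bin
})

test_that("pseudo-time orders cells and reveals the injected oscillation", {
  # fully methylated qualifying tiles give pt = 1
  g <- genome_spec(densities = 0.125, blocks_per_density = 6,
                   cpgs_per_block = 100)
  lst <- lapply(1:3, function(i)
    data.table(chrom = g$chrom, pos = g$pos, meth = 10L, unmeth = 0L))
  names(lst) <- paste0("c", 1:3)
  tlf <- tile_by_informative_cpgs(meth_call_table(lst), window = 100,
                                  all_positions = g)
  ptf <- pseudo_time(tlf)
  expect_true(all(ptf$pt == 1))
  # epiblast-like cohort: pseudo-time tracks developmental age
  gg <- genome_spec()
  ep <- generate_epiblast_dataset(gg, n_cells = 80, seed = 17)
  tl <- tile_by_informative_cpgs(ep$calls, window = 100,
                                 all_positions = gg)
  pt <- pseudo_time(tl)
  m <- merge(pt, ep$truth_cells, by = "sample_id")
  expect_gte(stats::cor(m$pt, m$age, method = "spearman"), 0.9)
  # invariance under cell relabeling
  calls2 <- data.table::copy(as.data.table(ep$calls))
  calls2[, sample_id := paste0("z_", sample_id)]
  pt2 <- pseudo_time(tile_by_informative_cpgs(calls2, window = 100,
                                              all_positions = gg))
  expect_equal(sort(pt2$pt), sort(pt$pt))
  # spectral enrichment over pseudo-time finds the age-locked rhythm
  ser <- pseudo_time_series(tl, pt)
  sp <- spectral_enrichment(ser$cells$pt, ser$tile_matrix,
                            periods = seq(0.15, 0.9, by = 0.05),
                            n_null = 2000, seed = 5)
  expect_lt(sp$table$p[sp$table$period == 0.35], 0.05) # truth 1/3
})

test_that("expression normalization anchors on long-lived transcripts", {
  set.seed(12)
  cts <- matrix(rpois(400, 60), 100, 4,
                dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:4)))
  lt <- rlnorm(100, log(7), 0.5)
  # identical samples: equal size factors, identical output
  n1 <- normalize_expression(cbind(cts[, 1], cts[, 1]), lt)
  expect_equal(n1$size_factors[1], n1$size_factors[2])
  expect_equal(n1$log_norm[, 1], n1$log_norm[, 2])
  # doubling long-lived genes doubles the factor, preserves short-lived FCs
  ctsB <- cts
  long <- lt > median(lt)
  ctsB[long, 3:4] <- ctsB[long, 3:4] * 2L
  n2 <- normalize_expression(ctsB, lt)
  expect_equal(mean(n2$size_factors[3:4]) / mean(n2$size_factors[1:2]), 2,
               tolerance = 0.05)
  short_fc <- n2$log_norm[!long, 3] - n2$log_norm[!long, 1]
  expect_lt(abs(median(short_fc) - (log(1 / 2) + 0)), 0.8)
  # all-zero gene stays at log(1) = 0
  cts0 <- cts; cts0[5, ] <- 0L
  expect_true(all(normalize_expression(cts0, lt)$log_norm[5, ] == 0))
  expect_error(normalize_expression(cts, rep(NA_real_, 100)), "50%")
  ctsZ <- cts; ctsZ[long, 2] <- 0L
  expect_error(normalize_expression(ctsZ, lt), "zero long-lived")
})

test_that("weighted feature correlations behave like correlations", {
  set.seed(13)
  X <- matrix(rnorm(100 * 5), 100, 5)
  X <- cbind(X, X[, 1])                       # duplicated feature
  w <- runif(100, 1, 10)
  cc <- feature_correlation(X, w)
  expect_equal(cc[1, 6], 1, tolerance = 1e-12)
  expect_true(all(diag(cc)[1:6] == 1))
  expect_true(isSymmetric(cc))
  off <- cc[1:5, 1:5][upper.tri(diag(5))]
  expect_gte(mean(abs(off) < 0.25), 0.9)      # independent features
  # constant feature reported missing
  Xc <- cbind(X[, 1:3], rep(0.5, 100))
  ccc <- feature_correlation(Xc, w)
  expect_true(all(is.na(ccc[4, ])))
  expect_error(feature_correlation(X[1:2, ]), "3 cells")
})
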