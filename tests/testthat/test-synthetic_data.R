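library(data.table)

test_that("genome blocks realise their target densities and amplitudes", {
  g <- genome_spec()
  expect_true(all(abs(g$density_real - g$density_target) /
                    g$density_target < 0.1))
  expect_true(all(diff(g$pos) > 0))
  blocks <- unique(g[, c("density_real", "amplitude")])
  # amplitude maximal in the 2-3% density band, negligible at >= 10%
  peak <- blocks$density_real[which.max(blocks$amplitude)]
  expect_gte(peak, 0.02)
  expect_lte(peak, 0.03)
  expect_true(all(blocks$amplitude[blocks$density_real >= 0.10] < 0.01))
})

test_that("generated files round-trip bit-identically through the readers", {
  g <- small_genome()
  ds <- generate_single_cell_dataset(g, n_cells = 12, seed = 99)
  d <- withr::local_tempdir()
  write_dataset(ds, d, params = list(seed = 99))
  expect_true(file.exists(file.path(d, "manifest.yaml")))
  back <- read_dataset(d)
  cols <- c("sample_id", "chrom", "pos", "meth", "unmeth")
  orig <- as.data.table(ds$calls)[order(sample_id, chrom, pos), ..cols]
  got <- as.data.table(back)[order(sample_id, chrom, pos), ..cols]
  expect_identical(orig, got)
})

test_that("generators are deterministic under a fixed seed", {
  g <- small_genome()
  a <- generate_single_cell_dataset(g, n_cells = 10, seed = 42)
  b <- generate_single_cell_dataset(g, n_cells = 10, seed = 42)
  expect_identical(as.data.table(a$calls), as.data.table(b$calls))
  expect_identical(a$truth_cells, b$truth_cells)
  e1 <- generate_amplicon_timecourse(seed = 7)
  e2 <- generate_amplicon_timecourse(seed = 7)
  expect_identical(e1$series, e2$series)
  x1 <- generate_expression_matrix(n_cells = 50, seed = 3)
  x2 <- generate_expression_matrix(n_cells = 50, seed = 3)
  expect_identical(x1$counts, x2$counts)
})

test_that("coherent cells move their density blocks together", {
  g <- genome_spec()
  ds <- generate_single_cell_dataset(g, n_cells = 60, coherence = 1,
                                     seed = 21)
  tl <- tile_by_informative_cpgs(ds$calls, window = 50, all_positions = g)
  cnt <- merge(tl$counts, tl$tiles[, c("tile_id", "cpg_density")],
               by = "tile_id")
  cnt <- cnt[cpg_density > 0.012 & cpg_density < 0.05]
  cnt[, dbin := cut(cpg_density, c(0.012, 0.022, 0.033, 0.05))]
  fm <- dcast(cnt[, .(m = sum(meth) / sum(coverage)),
                  by = c("sample_id", "dbin")],
              sample_id ~ dbin, value.var = "m")
  w <- cnt[, .(w = sum(coverage)), by = "sample_id"]$w
  cc <- feature_correlation(as.matrix(fm[, -1]), w)
  expect_true(all(cc[upper.tri(cc)] > 0.6))
  # and the 2-3% block means span a wide range while dense blocks are tight
  cnt2 <- merge(tl$counts, tl$tiles[, c("tile_id", "cpg_density")],
                by = "tile_id")
  spread <- function(lo, hi) {
    x <- cnt2[cpg_density >= lo & cpg_density <= hi,
              .(m = sum(meth) / sum(coverage)), by = "sample_id"]$m
    diff(range(x))
  }
  expect_gt(spread(0.02, 0.03), 3 * spread(0.10, 0.15))
})

test_that("amplicon generator respects filters and null cohorts", {
  a0 <- generate_amplicon_timecourse(oscillating_fraction = 0, seed = 8)
  sc0 <- amplicon_scan(a0$series, n_null = 300, seed = 9)
  expect_gt(sc0$fisher$p, 0.05)
  # a locus losing coverage at most points is excluded
  aa <- generate_amplicon_timecourse(seed = 10)
  drop <- aa$series$locus == "t_L01" &
    aa$series$time_min <= aa$series$time_min[30]
  aa$series$total[drop] <- 40L
  sc <- amplicon_scan(aa$series, n_null = 100, seed = 11)
  expect_false("t_L01" %in% sc$loci$locus)
})

test_that("bulk time course carries trend plus detectable oscillation", {
  g <- genome_spec()
  bk <- generate_bulk_timecourse(g, seed = 13)
  tl <- tile_by_informative_cpgs(bk$calls, window = 50, all_positions = g)
  cnt <- merge(tl$counts, bk$metadata, by = "sample_id")
  cnt <- merge(cnt, tl$tiles[, c("tile_id", "cpg_density")], by = "tile_id")
  el <- cnt[cpg_density > 0.015 & cpg_density < 0.04]
  ser <- dcast(el[, .(rate = sum(meth) / sum(coverage)),
                  by = c("tile_id", "time_min")],
               tile_id ~ time_min, value.var = "rate")
  tgrid <- as.numeric(colnames(ser)[-1])
  Y <- as.matrix(ser[, -1])
  Yd <- t(apply(Y, 1, function(y) detrend_poly2(tgrid, y)))
  periods <- seq(90, 300, by = 10)
  sp <- spectral_enrichment(tgrid, Yd, periods, n_null = 3000, seed = 7)
  tab <- sp$table
  expect_true(tab$significant[tab$period == 150])
  # strongest enrichment within one grid step of the truth
  best <- tab$period[which.max(tab$obs_mean)]
  expect_lte(abs(best - 150), 10)
  # trend-only data: residual variance at technical scale, no 150-min tone
  bk0 <- generate_bulk_timecourse(g, amplitude_scale = 0, seed = 14)
  tl0 <- tile_by_informative_cpgs(bk0$calls, window = 50,
                                  all_positions = g)
  cnt0 <- merge(tl0$counts, bk0$metadata, by = "sample_id")
  cnt0 <- merge(cnt0, tl0$tiles[, c("tile_id", "cpg_density")],
                by = "tile_id")
  el0 <- cnt0[cpg_density > 0.015 & cpg_density < 0.04]
  ser0 <- dcast(el0[, .(rate = sum(meth) / sum(coverage)),
                    by = c("tile_id", "time_min")],
                tile_id ~ time_min, value.var = "rate")
  Y0 <- as.matrix(ser0[, -1])
  Yd0 <- t(apply(Y0, 1, function(y) detrend_poly2(tgrid, y)))
  sp0 <- spectral_enrichment(tgrid, Yd0, periods, n_null = 3000, seed = 8)
  expect_lte(mean(sp0$table$significant), 0.15)
})

test_that("expression generator hits the weak-coupling design point", {
  ex <- generate_expression_matrix(seed = 4)
  nr <- normalize_expression(ex$counts, ex$lifetimes)
  ratio <- dnmt_tet_ratio(nr$log_norm, ex$enzyme_genes)
  r2 <- summary(stats::lm(ratio ~ ex$truth$global_meth))$r.squared
  expect_gte(r2, 0.01); expect_lte(r2, 0.15)
  ex0 <- generate_expression_matrix(target_r2 = 0, seed = 5)
  nr0 <- normalize_expression(ex0$counts, ex0$lifetimes)
  r20 <- summary(stats::lm(dnmt_tet_ratio(nr0$log_norm, ex0$enzyme_genes) ~
                             ex0$truth$global_meth))$r.squared
  expect_lt(r20, 0.05)
  expect_lt(abs(median(ex$lifetimes) - 7) / 7, 0.1)
})
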