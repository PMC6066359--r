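#' @importFrom data.table data.table as.data.table := .N .SD setorder rbindlist fread fwrite setnames
NULL

#' Read a Bismark-coverage methylation call file
#'
#' Expects the tab-separated Bismark coverage dialect: chromosome,
#' position, position, percent methylation, methylated count,
#' unmethylated count (1-based inclusive coordinates).
#'
#' @param file Path to the coverage file.
#' @param sample_id Sample identifier attached to the calls.
#' @return A \code{data.table} with columns \code{sample_id},
#'   \code{chrom}, \code{pos}, \code{meth}, \code{unmeth}.
#' @export
read_bismark_cov <- function(file, sample_id = basename(file)) {
  dt <- fread(file, header = FALSE,
              col.names = c("chrom", "start", "end", "pmeth", "meth", "unmeth"))
  data.table(sample_id = sample_id, chrom = as.character(dt$chrom),
             pos = as.integer(dt$start), meth = as.integer(dt$meth),
             unmeth = as.integer(dt$unmeth))
}

#' Write methylation calls in Bismark-coverage format
#'
#' @param calls A call table with columns \code{chrom}, \code{pos},
#'   \code{meth}, \code{unmeth} (a single sample).
#' @param file Output path.
#' @export
write_bismark_cov <- function(calls, file) {
  calls <- as.data.table(calls)
  tot <- calls$meth + calls$unmeth
  out <- data.table(calls$chrom, calls$pos, calls$pos,
                    ifelse(tot > 0, 100 * calls$meth / tot, 0),
                    calls$meth, calls$unmeth)
  fwrite(out, file, sep = "\t", col.names = FALSE)
  invisible(file)
}

#' Assemble a multi-sample methylation call table
#'
#' @param call_list Named list of per-sample call tables (columns
#'   \code{chrom}, \code{pos}, \code{meth}, \code{unmeth}).
#' @param metadata Optional sample metadata (data frame with
#'   \code{sample_id} plus e.g. \code{time_point} or \code{cell_id}).
#' @return A \code{data.table} of class \code{"meth_calls"}.
#' @export
meth_call_table <- function(call_list, metadata = NULL) {
  dt <- rbindlist(lapply(names(call_list), function(s) {
    x <- as.data.table(call_list[[s]])
    if (is.null(x$sample_id)) x[, sample_id := s]
    x
  }))
  if (any(dt$meth < 0 | dt$unmeth < 0)) stop("negative counts")
  setorder(dt, sample_id, chrom, pos)
  if (anyDuplicated(dt[, c("sample_id", "chrom", "pos")]))
    stop("duplicated positions within a sample")
  attr(dt, "metadata") <- metadata
  class(dt) <- c("meth_calls", class(dt))
  dt
}

#' Tile the genome into windows of a fixed number of informative CpGs
#'
#' A CpG is informative when it carries at least one read (pooled over
#' samples). Each chromosome is segmented greedily into consecutive
#' blocks of exactly \code{window} informative CpGs ("unbiased probes");
#' the trailing partial block is dropped. The CpG density of a tile is
#' the number of CpGs in its genomic span (from the full CpG map when
#' supplied, otherwise all CpGs present in the call table) divided by the
#' span length in base pairs.
#'
#' @param calls A \code{\link{meth_call_table}} (or equivalent
#'   data.table).
#' @param window Number of informative CpGs per tile (commonly 50 or
#'   100).
#' @param all_positions Optional full CpG map: data frame with
#'   \code{chrom}, \code{pos} for every CpG, covered or not.
#' @return A list of class \code{"meth_tiles"} with \code{tiles}
#'   (tile_id, chrom, start, end, n_informative, cpg_density) and
#'   \code{counts} (tile_id, sample_id, meth, unmeth, coverage, rate).
#' @export
tile_by_informative_cpgs <- function(calls, window = 50,
                                     all_positions = NULL) {
  stopifnot(window >= 2)
  dt <- as.data.table(calls)
  if (is.unsorted(dt[, .I[order(sample_id, chrom, pos)]]) &&
      any(dt[, is.unsorted(pos), by = c("sample_id", "chrom")]$V1))
    stop("calls must be sorted by position within chromosome")
  cov_pos <- dt[, .(tot = sum(meth + unmeth)), by = c("chrom", "pos")]
  setorder(cov_pos, chrom, pos)
  inf <- cov_pos[tot >= 1]
  inf[, tile_idx := ceiling(seq_len(.N) / window), by = "chrom"]
  inf[, n_in_tile := .N, by = c("chrom", "tile_idx")]
  inf <- inf[n_in_tile == window]      # drop trailing partial tiles
  if (nrow(inf) == 0)
    return(structure(list(tiles = data.table(), counts = data.table()),
                     class = "meth_tiles"))
  tiles <- inf[, .(start = min(pos), end = max(pos), n_informative = .N),
               by = c("chrom", "tile_idx")]
  allp <- if (is.null(all_positions)) cov_pos[, c("chrom", "pos")]
          else as.data.table(all_positions)[, c("chrom", "pos")]
  setorder(allp, chrom, pos)
  tiles[, n_cpg := {
    ap <- allp[chrom == .BY$chrom, pos]
    findInterval(end, ap) - findInterval(start - 1L, ap)
  }, by = "chrom"]
  tiles[, cpg_density := n_cpg / (end - start + 1)]
  tiles[, tile_id := paste0(chrom, ":", start, "-", end)]
  key <- inf[, c("chrom", "pos", "tile_idx")]
  counts <- merge(dt, key, by = c("chrom", "pos"))
  counts <- counts[, .(meth = sum(meth), unmeth = sum(unmeth)),
                   by = c("chrom", "tile_idx", "sample_id")]
  counts[, coverage := meth + unmeth]
  counts[, rate := ifelse(coverage > 0, meth / coverage, NA_real_)]
  counts <- merge(counts, tiles[, c("chrom", "tile_idx", "tile_id")],
                  by = c("chrom", "tile_idx"))
  structure(list(tiles = tiles[, c("tile_id", "chrom", "start", "end",
                                   "n_informative", "n_cpg", "cpg_density")],
                 counts = counts[, c("tile_id", "sample_id", "meth",
                                     "unmeth", "coverage", "rate")]),
            class = "meth_tiles")
}

#' Excess variance of methylation rates over binomial technical noise
#'
#' For each tile, the coverage-weighted variance of per-sample methylation
#' rates is rescaled by the variance expected from a Bernoulli trial at
#' the weighted mean rate \eqn{\bar m} and mean coverage \eqn{\bar c}:
#' \eqn{\mathrm{Var}(m) / [\bar m (1 - \bar m) / \bar c]}. Values near 1
#' indicate purely technical variability; values above 1 indicate
#' biological cell-to-cell (or time-point) variability such as
#' oscillation amplitude.
#'
#' @param tiles A \code{\link{tile_by_informative_cpgs}} result.
#' @param min_samples Minimum number of covered samples per tile.
#' @return A \code{data.table} with per-tile \code{mean_meth},
#'   \code{mean_coverage}, \code{n_samples}, \code{excess_var} and
#'   \code{cpg_density}. Tiles with \eqn{\bar m \in \{0, 1\}} or too few
#'   samples are omitted.
#' @export
excess_variance <- function(tiles, min_samples = 3) {
  cnt <- tiles$counts[coverage > 0]
  ev <- cnt[, {
    if (.N < min_samples) NULL else {
      w <- coverage / sum(coverage)
      mbar <- sum(w * rate)
      if (mbar <= 0 || mbar >= 1) NULL else {
        v <- sum(w * (rate - mbar)^2)
        cbar <- mean(coverage)
        list(mean_meth = mbar, mean_coverage = cbar, n_samples = .N,
             excess_var = v / (mbar * (1 - mbar) / cbar))
      }
    }
  }, by = "tile_id"]
  merge(ev, tiles$tiles[, c("tile_id", "cpg_density")], by = "tile_id")
}

#' Binomial null band for a tile's weighted mean methylation
#'
#' Resamples per-sample methylated counts binomially at the tile's
#' weighted mean rate and observed coverages, and returns the 2.5/97.5
#' percentiles of the resampled weighted means.
#'
#' @param mbar Weighted mean methylation rate of the tile.
#' @param coverages Per-sample coverages.
#' @param n_rep Number of binomial resamples.
#' @return Numeric vector \code{c(lo, hi)}.
#' @export
technical_null_bounds <- function(mbar, coverages, n_rep = 1000) {
  coverages <- coverages[coverages > 0]
  if (!length(coverages)) stop("all-zero coverage")
  if (mbar <= 0) return(c(0, 0))
  if (mbar >= 1) return(c(1, 1))
  w <- coverages / sum(coverages)
  means <- vapply(seq_len(n_rep), function(i) {
    sum(w * stats::rbinom(length(coverages), coverages, mbar) / coverages)
  }, numeric(1))
  unname(stats::quantile(means, c(0.025, 0.975)))
}

#' Remove slow trends by quadratic regression
#'
#' @param t Time stamps.
#' @param y Values.
#' @return Residuals of the least-squares second-order polynomial fit.
#' @export
detrend_poly2 <- function(t, y) {
  ok <- is.finite(y) & is.finite(t)
  if (sum(ok) < 4) stop("need at least 4 points for quadratic detrending")
  res <- rep(NA_real_, length(y))
  res[ok] <- stats::residuals(stats::lm(y[ok] ~ t[ok] + I(t[ok]^2)))
  res
}

#' Lomb-Scargle periodogram on an arbitrary time grid
#'
#' Classic normalised periodogram (invariant under time shift via the
#' per-frequency phase offset), suitable for unevenly sampled series.
#'
#' @param t Time stamps.
#' @param y Values (a vector, or a matrix with one series per row sharing
#'   the time grid).
#' @param periods Periods at which to evaluate the power.
#' @return A vector (or matrix, series x periods) of normalised powers.
#' @export
lomb_scargle <- function(t, y, periods) {
  Y <- if (is.matrix(y)) y else matrix(y, nrow = 1)
  stopifnot(ncol(Y) == length(t))
  Yc <- Y - rowMeans(Y)
  v <- apply(Y, 1, stats::var)
  P <- matrix(NA_real_, nrow(Y), length(periods))
  for (j in seq_along(periods)) {
    w <- 2 * pi / periods[j]
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    cc <- sum(ct^2); ss <- sum(st^2)
    P[, j] <- ((Yc %*% ct)^2 / cc + (Yc %*% st)^2 / ss) / (2 * v)
  }
  if (is.matrix(y)) P else P[1, ]
}

#' Spectral enrichment of parallel oscillations across genomic elements
#'
#' Computes Lomb-Scargle powers for every element on the shared
#' (possibly non-uniform) time grid and compares the element powers, per
#' scanned period, with the powers of Gaussian white-noise series
#' simulated on the identical grid. Enrichment per period is assessed by
#' a one-sided Welch t test (observed vs null powers).
#'
#' @param t Shared time stamps.
#' @param series_set Matrix (elements x time points) of detrended series;
#'   rows with fewer than \code{min_points} finite values are excluded.
#' @param periods Period grid to scan.
#' @param n_null Number of white-noise null series.
#' @param seed RNG seed for the null.
#' @param min_points Minimum finite points per element.
#' @return A list of class \code{"spectrum_result"} with \code{table}
#'   (period, obs_mean, null_mean, null_sd, p, significant),
#'   \code{n_elements} and \code{n_excluded}.
#' @export
spectral_enrichment <- function(t, series_set, periods, n_null = 1e4,
                                seed = 1, min_points = 8) {
  Y <- if (is.matrix(series_set)) series_set else matrix(series_set, nrow = 1)
  nfin <- rowSums(is.finite(Y))
  excl <- nfin < min_points
  if (any(excl))
    message(sum(excl), " element(s) excluded (<", min_points, " valid points)")
  Y <- Y[!excl, , drop = FALSE]
  if (nrow(Y) < 2)
    stop("need at least 2 elements with enough valid time points")
  has_na <- anyNA(Y)
  obs <- if (!has_na) lomb_scargle(t, Y, periods) else {
    t(apply(Y, 1, function(y) {
      ok <- is.finite(y)
      lomb_scargle(t[ok], y[ok], periods)
    }))
  }
  set.seed(seed)
  nullY <- matrix(stats::rnorm(n_null * length(t)), n_null, length(t))
  nullP <- lomb_scargle(t, nullY, periods)
  tab <- do.call(rbind, lapply(seq_along(periods), function(j) {
    tt <- stats::t.test(obs[, j], nullP[, j], alternative = "greater")
    data.frame(period = periods[j], obs_mean = mean(obs[, j]),
               null_mean = mean(nullP[, j]), null_sd = stats::sd(nullP[, j]),
               p = tt$p.value)
  }))
  tab$significant <- tab$p < 0.05
  structure(list(table = tab, powers = obs, n_elements = nrow(Y),
                 n_excluded = sum(excl)),
            class = "spectrum_result")
}

#' Per-locus oscillation scan for amplicon time courses
#'
#' Filters data points to those with more than \code{read_min} reads and
#' loci with more than \code{min_points} valid time points, detrends each
#' locus quadratically, scans Lomb-Scargle power over
#' \code{period_range}, and calls a locus significant when its spectral
#' peak lies strictly inside the scanned interval (boundary peaks are
#' discarded as artifacts) and exceeds the Monte-Carlo null of the peak
#' power at level 0.05. Treatment vs control significant-locus counts are
#' compared by a one-sided Fisher exact test.
#'
#' @param loci_series Data frame with columns \code{locus}, \code{group}
#'   ("treatment"/"control"), \code{time_min}, \code{meth}, \code{total}.
#' @param read_min Minimum read depth per retained point (exclusive).
#' @param min_points Minimum number of valid time points (exclusive).
#' @param period_range Scanned period interval in minutes.
#' @param period_step Spacing of the scanned period grid.
#' @param n_null Monte-Carlo null size for the peak-power distribution.
#' @param seed RNG seed for the null.
#' @return A list with \code{loci} (per-locus peak period, p, significant)
#'   and \code{fisher} (p-value, table); empty result when no locus
#'   survives the filters.
#' @export
amplicon_scan <- function(loci_series, read_min = 100, min_points = 20,
                          period_range = c(90, 180), period_step = 5,
                          n_null = 1000, seed = 1) {
  dt <- as.data.table(loci_series)
  if (is.null(dt$group)) dt[, group := "treatment"]
  dt <- dt[total > read_min]
  dt[, rate := meth / total]
  valid <- dt[, .N, by = c("locus", "group")][N > min_points]
  if (nrow(valid) == 0)
    return(list(loci = data.table(), fisher = NULL))
  periods <- seq(period_range[1], period_range[2], by = period_step)
  set.seed(seed)
  res <- rbindlist(lapply(seq_len(nrow(valid)), function(i) {
    li <- dt[locus == valid$locus[i] & group == valid$group[i]]
    setorder(li, time_min)
    y <- detrend_poly2(li$time_min, li$rate)
    pw <- lomb_scargle(li$time_min, y, periods)
    pk <- which.max(pw)
    nullmax <- vapply(seq_len(n_null), function(b) {
      max(lomb_scargle(li$time_min, stats::rnorm(nrow(li)), periods))
    }, numeric(1))
    p <- (1 + sum(nullmax >= pw[pk])) / (n_null + 1)
    boundary <- pk == 1L || pk == length(periods)
    data.table(locus = valid$locus[i], group = valid$group[i],
               n_points = nrow(li), peak_period = periods[pk],
               peak_power = pw[pk], p = p, boundary = boundary,
               significant = (p < 0.05) && !boundary)
  }))
  fisher <- NULL
  if (all(c("treatment", "control") %in% res$group)) {
    tab <- table(factor(res$group, c("treatment", "control")),
                 factor(res$significant, c(TRUE, FALSE)))
    ft <- stats::fisher.test(tab, alternative = "greater")
    fisher <- list(p = ft$p.value, table = tab)
  }
  list(loci = res, fisher = fisher)
}

# cache of Monte-Carlo dip null tables, keyed by "n|n_mc"
.dip_null_cache <- new.env(parent = emptyenv())

#' Hartigan dip test of unimodality
#'
#' Computes the dip statistic (smallest sup-norm distance between the
#' empirical cdf and the class of unimodal cdfs) and a Monte-Carlo
#' p-value against the uniform null (the least-favourable unimodal
#' distribution). Null tables are cached per sample size.
#'
#' @param values Sample of methylation rates (\eqn{n \ge 10}).
#' @param n_mc Number of Monte-Carlo null samples.
#' @param null_seed Seed used when generating a cached null table.
#' @return A list with \code{dip} and \code{p}; \code{NULL} when
#'   \code{n < 10}.
#' @export
dip_test <- function(values, n_mc = 2000, null_seed = 424242L) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 10) return(NULL)
  d <- dip_stat_cpp(sort(values))
  key <- paste0(n, "|", n_mc)
  if (is.null(.dip_null_cache[[key]])) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(null_seed)
    .dip_null_cache[[key]] <- vapply(seq_len(n_mc), function(i)
      dip_stat_cpp(sort(stats::runif(n))), numeric(1))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  nulls <- .dip_null_cache[[key]]
  list(dip = d, p = (1 + sum(nulls >= d)) / (n_mc + 1))
}

#' Bimodality scan across coverage-based tiles
#'
#' Applies the dip test to the across-cell distribution of tile
#' methylation rates, bins tiles by CpG density or mean methylation, and
#' reports the fraction of significantly bimodal tiles per bin with a
#' bootstrap confidence interval (resampling tiles within bins).
#'
#' @param tiles A \code{\link{tile_by_informative_cpgs}} result over
#'   cells.
#' @param group_by \code{"cpg_density"} or \code{"mean_methylation"}.
#' @param bins Bin boundaries on the grouping variable.
#' @param min_cells Minimum number of covered cells per tile.
#' @param n_boot Bootstrap replicates for the 95\% CI.
#' @param p_thresh Dip-test significance level.
#' @param n_mc Monte-Carlo null size per dip test.
#' @param seed RNG seed for the bootstrap.
#' @return A list with \code{per_tile} (tile_id, dip, p, mean_meth,
#'   cpg_density) and \code{bins} (bin, fraction, ci_lo, ci_hi,
#'   n_tiles).
#' @export
bimodality_scan <- function(tiles, group_by = c("cpg_density",
                                                "mean_methylation"),
                            bins = NULL, min_cells = 10, n_boot = 1000,
                            p_thresh = 0.05, n_mc = 2000, seed = 1) {
  group_by <- match.arg(group_by)
  cnt <- tiles$counts[coverage > 0]
  per_tile <- cnt[, {
    if (.N < min_cells) NULL else {
      dtst <- dip_test(rate, n_mc = n_mc)
      if (is.null(dtst)) NULL else
        list(dip = dtst$dip, p = dtst$p,
             mean_meth = sum(coverage * rate) / sum(coverage))
    }
  }, by = "tile_id"]
  per_tile <- merge(per_tile, tiles$tiles[, c("tile_id", "cpg_density")],
                    by = "tile_id")
  gvar <- if (group_by == "cpg_density") per_tile$cpg_density else per_tile$mean_meth
  if (is.null(bins)) {
    bins <- if (group_by == "cpg_density")
      c(0, 0.01, 0.02, 0.03, 0.05, 0.10, 0.20, 1)
    else seq(0, 1, by = 0.2)
  }
  per_tile[, bin := cut(gvar, bins, include.lowest = TRUE)]
  set.seed(seed)
  bin_tab <- per_tile[!is.na(bin), {
    sig <- p < p_thresh
    frac <- mean(sig)
    bs <- vapply(seq_len(n_boot), function(b)
      mean(sample(sig, .N, replace = TRUE)), numeric(1))
    ci <- stats::quantile(bs, c(0.025, 0.975))
    list(fraction = frac, ci_lo = ci[[1]], ci_hi = ci[[2]], n_tiles = .N)
  }, by = "bin"]
  list(per_tile = per_tile, bins = bin_tab[order(bin)])
}

#' Methylation pseudo-time from CpG-dense regions
#'
#' CpG-dense regions gain methylation monotonically during exit from
#' pluripotency and carry little oscillation, so their average
#' methylation orders cells by developmental age. Pseudo-time is the
#' unweighted mean methylation rate over qualifying tiles (CpG density
#' within \code{density_range}) per cell.
#'
#' @param tiles A \code{\link{tile_by_informative_cpgs}} result (window
#'   commonly 100).
#' @param density_range CpG density interval selecting qualifying tiles.
#' @param min_tiles Minimum number of qualifying covered tiles per cell.
#' @return A \code{data.table} with \code{sample_id}, \code{pt},
#'   \code{n_tiles}; cells with too few qualifying tiles are excluded.
#' @export
pseudo_time <- function(tiles, density_range = c(0.10, 0.15),
                        min_tiles = 5) {
  qual <- tiles$tiles[cpg_density >= density_range[1] &
                      cpg_density <= density_range[2], tile_id]
  cnt <- tiles$counts[tile_id %in% qual & coverage > 0]
  pt <- cnt[, .(pt = mean(rate), n_tiles = .N), by = "sample_id"]
  dropped <- pt[n_tiles < min_tiles]
  if (nrow(dropped))
    message(nrow(dropped), " cell(s) excluded (fewer than ", min_tiles,
            " qualifying tiles)")
  pt[n_tiles >= min_tiles]
}

#' Pseudo-time-ordered, detrended and noise-rescaled methylation series
#'
#' Orders cells by pseudo-time, extracts the mean methylation of tiles in
#' a target CpG-density band per cell, removes the linear trend in
#' pseudo-time and rescales by the expected technical variance
#' \eqn{\bar m (1 - \bar m) / \bar c}.
#'
#' @param tiles A \code{\link{tile_by_informative_cpgs}} result.
#' @param pt Pseudo-time table from \code{\link{pseudo_time}}.
#' @param target_density Density band of the tiles to chart (the band
#'   where oscillations are most pronounced, typically 2--3\%).
#' @return A list with \code{cells} (a \code{data.table} ordered by
#'   \code{pt} with the cross-tile mean series: \code{sample_id},
#'   \code{pt}, \code{raw}, \code{value} detrended and rescaled) and
#'   \code{tile_matrix} (tiles x cells, per-tile detrended and rescaled
#'   series on the same pseudo-time grid; \code{NA} where a tile lacks
#'   coverage in a cell).
#' @export
pseudo_time_series <- function(tiles, pt, target_density = c(0.02, 0.03)) {
  tgt <- tiles$tiles[cpg_density >= target_density[1] &
                     cpg_density <= target_density[2], tile_id]
  cnt <- tiles$counts[tile_id %in% tgt & coverage > 0]
  cnt <- merge(cnt, pt[, c("sample_id", "pt")], by = "sample_id")
  per_cell <- cnt[, .(raw = mean(rate), cbar = mean(coverage),
                      pt = pt[1]), by = "sample_id"]
  setorder(per_cell, pt)
  fit <- stats::lm(raw ~ pt, data = per_cell)
  mbar <- mean(per_cell$raw)
  tech_var <- mbar * (1 - mbar) / mean(per_cell$cbar)
  per_cell[, value := stats::residuals(fit) / tech_var]
  # per-tile series on the common pseudo-time grid
  wide <- data.table::dcast(cnt, tile_id ~ sample_id, value.var = "rate")
  M <- as.matrix(wide, rownames = "tile_id")
  M <- M[, per_cell$sample_id, drop = FALSE]
  for (i in seq_len(nrow(M))) {
    y <- M[i, ]
    ok <- is.finite(y)
    if (sum(ok) >= 4) {
      res <- stats::residuals(stats::lm(y ~ per_cell$pt, subset = ok))
      mb <- mean(y[ok])
      cb <- mean(cnt[tile_id == rownames(M)[i], coverage])
      tv <- mb * (1 - mb) / cb
      y[ok] <- res / max(tv, 1e-12)
      M[i, ] <- y
    } else M[i, ] <- NA_real_
  }
  list(cells = per_cell[, c("sample_id", "pt", "raw", "value")],
       tile_matrix = M)
}

#' Normalise expression counts using long-lived transcripts
#'
#' Rapid methylation oscillations should not move transcripts whose
#' lifetime far exceeds the oscillation period, so size factors
#' (median-of-ratios) are computed on the long-lived subset only (lifetime
#' above the median, roughly 7 h) and applied to all genes. Output is
#' natural-log transformed after adding an offset of 1.
#'
#' @param counts Gene-by-sample count matrix.
#' @param lifetimes Per-gene mean transcript lifetimes in hours (NA
#'   allowed for up to half of the genes).
#' @param lifetime_min Lifetime cutoff; defaults to the median lifetime.
#' @return A list with \code{log_norm} (matrix), \code{size_factors} and
#'   \code{lifetime_min}.
#' @export
normalize_expression <- function(counts, lifetimes, lifetime_min = NULL) {
  counts <- as.matrix(counts)
  stopifnot(length(lifetimes) == nrow(counts))
  if (mean(is.finite(lifetimes)) < 0.5)
    stop("lifetimes available for fewer than 50% of genes")
  if (is.null(lifetime_min))
    lifetime_min <- stats::median(lifetimes, na.rm = TRUE)
  long <- which(is.finite(lifetimes) & lifetimes > lifetime_min)
  if (length(long) < 2) stop("too few long-lived genes")
  sub <- counts[long, , drop = FALSE]
  if (any(colSums(sub) == 0)) stop("sample with zero long-lived counts")
  if (!requireNamespace("DESeq2", quietly = TRUE))
    stop("normalize_expression requires the DESeq2 package")
  sf <- DESeq2::estimateSizeFactorsForMatrix(sub)
  norm <- sweep(counts, 2, sf, "/")
  list(log_norm = log(norm + 1), size_factors = sf,
       lifetime_min = lifetime_min)
}

#' Coverage-weighted Pearson correlation between genomic features
#'
#' @param feature_means Cell-by-feature matrix of average methylation
#'   rates.
#' @param weights Per-cell weights (overall methylation coverage depth).
#' @return Symmetric weighted correlation matrix with unit diagonal;
#'   constant features yield \code{NA} rows/columns.
#' @export
feature_correlation <- function(feature_means, weights = NULL) {
  X <- as.matrix(feature_means)
  if (nrow(X) < 3) stop("need at least 3 cells")
  if (is.null(weights)) weights <- rep(1, nrow(X))
  cw <- stats::cov.wt(X, wt = weights / sum(weights), cor = TRUE)
  cc <- cw$cor
  const <- apply(X, 2, function(x) stats::var(x) == 0)
  cc[const, ] <- NA_real_
  cc[, const] <- NA_real_
  diag(cc) <- ifelse(const, NA_real_, 1)
  cc
}
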