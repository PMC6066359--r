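#' Oscillation amplitude as a function of CpG density
#'
#' Smooth stand-in for the observed density dependence of the
#' oscillation amplitude: log-Gaussian in density, peaking at
#' \code{d_star} (default 2.5\%), multiplied by a soft cutoff that
#' suppresses oscillations at CpG-rich regions (density above ~10\%).
#'
#' @param density CpG density (CpGs per base pair).
#' @param A0 Peak amplitude.
#' @param d_star Density of maximal amplitude.
#' @param log_width Width of the log-Gaussian in log-density units.
#' @param cutoff Density above which oscillations are suppressed.
#' @return Amplitude values.
#' @export
amplitude_density <- function(density, A0 = 0.22, d_star = 0.025,
                              log_width = 0.55, cutoff = 0.10) {
  A0 * exp(-(log(density) - log(d_star))^2 / (2 * log_width^2)) /
    (1 + exp((density - cutoff) / 0.01))
}

#' Synthetic genome of CpG-density blocks
#'
#' One synthetic chromosome built from contiguous blocks of CpGs placed
#' at regular spacing, each block targeting one CpG density between
#' 0.5\% and 20\%. Each block carries a ground-truth oscillation
#' amplitude (peaking near 2.5\% density) and methylation midpoint.
#'
#' @param densities Target block densities.
#' @param blocks_per_density Number of blocks per density.
#' @param cpgs_per_block CpGs per block.
#' @param gap_bp Gap between blocks (no CpGs).
#' @param A0 Peak oscillation amplitude passed to
#'   \code{\link{amplitude_density}}.
#' @return A \code{data.table} of class \code{"genome_spec"} with one row
#'   per CpG: \code{chrom}, \code{pos}, \code{block_id},
#'   \code{density_target}, \code{density_real}, \code{amplitude},
#'   \code{midpoint}.
#' @export
genome_spec <- function(densities = c(0.005, 0.01, 0.015, 0.02, 0.025,
                                      0.03, 0.04, 0.06, 0.10, 1 / 9,
                                      0.125, 0.18),
                        blocks_per_density = 4, cpgs_per_block = 100,
                        gap_bp = 1000, A0 = 0.22) {
  stopifnot(all(densities > 0), all(densities <= 0.5))
  blocks <- data.table::CJ(density_target = densities,
                           rep = seq_len(blocks_per_density))
  pos0 <- 1L
  rows <- vector("list", nrow(blocks))
  for (b in seq_len(nrow(blocks))) {
    d <- blocks$density_target[b]
    spacing <- max(2L, as.integer(round(1 / d)))
    p <- pos0 + spacing * (seq_len(cpgs_per_block) - 1L)
    d_real <- cpgs_per_block / (p[cpgs_per_block] - p[1] + spacing)
    rows[[b]] <- data.table(
      chrom = "chrS", pos = as.integer(p),
      block_id = sprintf("b%02.1f_%d", 100 * d, blocks$rep[b]),
      density_target = d, density_real = d_real)
    pos0 <- p[cpgs_per_block] + as.integer(gap_bp)
  }
  g <- rbindlist(rows)
  g[, amplitude := amplitude_density(density_real, A0 = A0)]
  g[, midpoint := pmin(0.3 + 2.8 * pmin(density_real, 0.2), 0.85)]
  class(g) <- c("genome_spec", class(g))
  g
}

.clamp01 <- function(x, lo = 0.005, hi = 0.995) pmin(pmax(x, lo), hi)

#' Generate a synthetic single-cell methylome cohort
#'
#' Each cell carries one oscillator phase; the true methylation rate of a
#' density block is \code{midpoint + amplitude(density) * sin(phase)},
#' with the per-block phase mixing the cell phase and independent block
#' jitter weighted by \code{coherence}. When \code{age_span > 0}, a
#' per-cell developmental age additionally drives the methylation of
#' CpG-dense blocks (density at or above 10\%) monotonically, emulating
#' progressive de novo methylation. Reads are drawn per covered CpG from
#' the bisulfite read-noise model; a fraction \code{dropout} of CpGs per
#' cell receives no reads.
#'
#' @param genome A \code{\link{genome_spec}}.
#' @param n_cells Number of cells (\eqn{\ge 10}).
#' @param noise A \code{\link{read_noise_model}} for per-CpG coverage.
#' @param coherence Weight in [0, 1] of the shared per-cell phase
#'   relative to block-level phase jitter.
#' @param amplitude_scale Global multiplier on block amplitudes (0 gives
#'   technical-noise-only data).
#' @param age_span Slope of the developmental-age effect on dense-block
#'   methylation (0 disables it).
#' @param dropout Fraction of CpGs without reads per cell.
#' @param seed RNG seed.
#' @return A list with \code{calls} (a \code{\link{meth_call_table}}),
#'   \code{truth_cells} (cell, phase, age), \code{truth_blocks} (block,
#'   density, amplitude, midpoint) and \code{genome}.
#' @export
generate_single_cell_dataset <- function(genome, n_cells = 50,
                                         noise = read_noise_model(),
                                         coherence = 0.8,
                                         amplitude_scale = 1,
                                         age_span = 0, dropout = 0.3,
                                         seed = 1) {
  stopifnot(n_cells >= 10, coherence >= 0, coherence <= 1)
  set.seed(seed)
  cells <- sprintf("cell%03d", seq_len(n_cells))
  phase <- stats::runif(n_cells, 0, 2 * pi)
  age <- stats::runif(n_cells)
  blocks <- unique(genome[, c("block_id", "density_real", "amplitude",
                              "midpoint")])
  nb <- nrow(blocks)
  call_list <- vector("list", n_cells)
  names(call_list) <- cells
  for (ci in seq_len(n_cells)) {
    blk_phase <- phase[ci] + (1 - coherence) * stats::runif(nb, -pi, pi)
    rate_blk <- .clamp01(blocks$midpoint +
                           amplitude_scale * blocks$amplitude * sin(blk_phase) +
                           (blocks$density_real >= 0.10) * age_span *
                             (age[ci] - 0.5))
    g <- data.table::copy(genome)
    g[, rate := rate_blk[match(block_id, blocks$block_id)]]
    keep <- stats::runif(nrow(g)) >= dropout
    g <- g[keep]
    rd <- sample_reads_cpp(g$rate, noise$coverage_mean, noise$min_coverage)
    call_list[[ci]] <- data.table(chrom = g$chrom, pos = g$pos,
                                  meth = rd$k, unmeth = rd$s - rd$k)
  }
  calls <- meth_call_table(call_list,
                           metadata = data.frame(sample_id = cells,
                                                 cell_id = cells))
  list(calls = calls,
       truth_cells = data.table(sample_id = cells, phase = phase, age = age),
       truth_blocks = blocks, genome = genome)
}

#' Generate a synthetic epiblast-like single-cell cohort
#'
#' Emulates an in vivo single-cell methylome snapshot during global de
#' novo methylation: cells carry a developmental age; every CpG-poor
#' block follows a sigmoidal de novo trajectory with a block-specific
#' onset midpoint (regions methylate at different developmental times),
#' and a density-dependent oscillation rides on top, with the
#' oscillator phase advancing with age (so oscillations are visible
#' along a methylation pseudo-time). CpG-dense blocks (density at or
#' above 10\%) share a common midpoint and carry essentially no
#' oscillation; their monotone rise anchors pseudo-time. Blocks whose
#' onset midpoint is far from the observation window sit saturated low
#' or high, where the oscillation bimodality is visible; blocks in
#' transit show onset-dominated (unimodal) cross-cell variability.
#'
#' @param genome A \code{\link{genome_spec}}.
#' @param n_cells Number of cells.
#' @param noise A \code{\link{read_noise_model}}.
#' @param coherence Weight of the age-locked phase relative to block
#'   jitter.
#' @param age_cycles Number of oscillation cycles completed across the
#'   developmental-age span; 0 draws one random phase per cell,
#'   independent of age.
#' @param amplitude_scale Multiplier on block amplitudes.
#' @param dropout Fraction of CpGs without reads per cell.
#' @param rate_floor,rate_ceiling Methylation levels before/after the de
#'   novo sweep.
#' @param onset_spread Half-range of the uniform distribution of
#'   block onset midpoints on the age axis (centred at 0.5).
#' @param transition_width Width of the sigmoidal de novo transition on
#'   the age axis.
#' @param seed RNG seed.
#' @return A list with \code{calls}, \code{truth_cells} (sample_id, age,
#'   phase at age), \code{truth_blocks} (incl. onset midpoints) and
#'   \code{genome}.
#' @export
generate_epiblast_dataset <- function(genome, n_cells = 80,
                                      noise = read_noise_model(),
                                      coherence = 0.5, age_cycles = 3,
                                      amplitude_scale = 1, dropout = 0.3,
                                      rate_floor = 0.05,
                                      rate_ceiling = 0.95,
                                      onset_spread = 3,
                                      transition_width = 0.5, seed = 1) {
  stopifnot(n_cells >= 10)
  set.seed(seed)
  cells <- sprintf("cell%03d", seq_len(n_cells))
  age <- stats::runif(n_cells)
  blocks <- unique(genome[, c("block_id", "density_real", "amplitude",
                              "midpoint")])
  nb <- nrow(blocks)
  dense <- blocks$density_real >= 0.10
  onset_mid <- stats::runif(nb, 0.5 - onset_spread, 0.5 + onset_spread)
  onset_mid[dense] <- 0.5
  # age_cycles > 0 locks the oscillator phase to developmental age (the
  # regime probed by pseudo-time spectra); age_cycles = 0 draws one
  # random phase per cell, independent of age (the regime assumed by the
  # onset-overshadowing argument for modality patterns)
  cell_phase <- if (age_cycles > 0) 2 * pi * age_cycles * age
                else stats::runif(n_cells, 0, 2 * pi)
  call_list <- vector("list", n_cells)
  names(call_list) <- cells
  for (ci in seq_len(n_cells)) {
    ph <- cell_phase[ci] +
      (1 - coherence) * stats::runif(nb, -pi, pi)
    base <- rate_floor + (rate_ceiling - rate_floor) *
      stats::plogis((age[ci] - onset_mid) / transition_width)
    rate_blk <- .clamp01(base +
                           amplitude_scale * blocks$amplitude * sin(ph))
    g <- data.table::copy(genome)
    g[, rate := rate_blk[match(block_id, blocks$block_id)]]
    g <- g[stats::runif(.N) >= dropout]
    rd <- sample_reads_cpp(g$rate, noise$coverage_mean, noise$min_coverage)
    call_list[[ci]] <- data.table(chrom = g$chrom, pos = g$pos,
                                  meth = rd$k, unmeth = rd$s - rd$k)
  }
  calls <- meth_call_table(call_list,
                           metadata = data.frame(sample_id = cells,
                                                 cell_id = cells))
  tb <- data.table::copy(blocks)
  tb[, onset_mid := onset_mid]
  list(calls = calls,
       truth_cells = data.table(sample_id = cells, age = age,
                                phase = cell_phase),
       truth_blocks = tb, genome = genome)
}

#' Generate a synthetic bulk 2i-release time course
#'
#' Emulates a release experiment in which bulk samples are collected at
#' 31 time points (0 to 56.5 h) in triplicate: every density block
#' follows a rising logistic trend plus a density-dependent oscillation
#' (default period 150 min), with small replicate jitter; reads are
#' binomial at deep bulk coverage.
#'
#' @param genome A \code{\link{genome_spec}}.
#' @param timepoints Collection times in minutes.
#' @param n_rep Replicates per time point.
#' @param period_min Oscillation period in minutes.
#' @param trend List with \code{lo}, \code{hi}, \code{mid} (minutes),
#'   \code{width} (minutes) defining the logistic rise.
#' @param amplitude_scale Multiplier on block amplitudes.
#' @param coverage Per-CpG read depth.
#' @param rep_sd SD of replicate-level rate jitter.
#' @param seed RNG seed.
#' @return A list with \code{calls}, \code{metadata} (sample_id,
#'   time_min, replicate), \code{truth} (period, trend) and
#'   \code{genome}.
#' @export
generate_bulk_timecourse <- function(genome,
                                     timepoints = seq(0, 3390, length.out = 31),
                                     n_rep = 3, period_min = 150,
                                     trend = list(lo = 0.15, hi = 0.6,
                                                  mid = 900, width = 400),
                                     amplitude_scale = 1, coverage = 200,
                                     rep_sd = 0.01, seed = 1) {
  set.seed(seed)
  blocks <- unique(genome[, c("block_id", "density_real", "amplitude",
                              "midpoint")])
  samples <- data.table::CJ(time_min = timepoints, replicate = seq_len(n_rep))
  samples[, sample_id := sprintf("t%04d_r%d", as.integer(round(time_min)),
                                 replicate)]
  call_list <- vector("list", nrow(samples))
  names(call_list) <- samples$sample_id
  for (si in seq_len(nrow(samples))) {
    tm <- samples$time_min[si]
    base <- trend$lo + (trend$hi - trend$lo) *
      stats::plogis((tm - trend$mid) / trend$width)
    rate_blk <- .clamp01(base +
                           amplitude_scale * blocks$amplitude *
                             sin(2 * pi * tm / period_min) +
                           stats::rnorm(nrow(blocks), 0, rep_sd))
    g <- data.table::copy(genome)
    g[, rate := rate_blk[match(block_id, blocks$block_id)]]
    k <- stats::rbinom(nrow(g), coverage, g$rate)
    call_list[[si]] <- data.table(chrom = g$chrom, pos = g$pos,
                                  meth = k, unmeth = coverage - k)
  }
  calls <- meth_call_table(call_list, metadata = as.data.frame(samples))
  list(calls = calls, metadata = samples,
       truth = list(period_min = period_min, trend = trend,
                    blocks = blocks),
       genome = genome)
}

#' Generate a synthetic amplicon bisulfite time course
#'
#' Deeply sequenced target loci sampled every 20 minutes (47 points by
#' default). A fraction of the treatment loci oscillates at
#' \code{period_min}; control loci (fresh-2i arm) never oscillate.
#'
#' @param n_loci Number of target loci per arm.
#' @param timepoints Collection times in minutes.
#' @param oscillating_fraction Fraction of treatment loci that oscillate.
#' @param period_min Oscillation period (minutes).
#' @param amplitude Oscillation amplitude on the methylation-rate scale.
#' @param midpoint Mean methylation level of the loci.
#' @param coverage_mean Mean read depth per point (Poisson).
#' @param seed RNG seed.
#' @return A list with \code{series} (locus, group, time_min, meth,
#'   total) and \code{truth} (oscillating locus flags).
#' @export
generate_amplicon_timecourse <- function(n_loci = 14,
                                         timepoints = seq(0, 920, by = 20),
                                         oscillating_fraction = 4 / 14,
                                         period_min = 150,
                                         amplitude = 0.08, midpoint = 0.5,
                                         coverage_mean = 400, seed = 1) {
  stopifnot(oscillating_fraction >= 0, oscillating_fraction <= 1)
  set.seed(seed)
  n_osc <- round(oscillating_fraction * n_loci)
  osc <- rep(c(TRUE, FALSE), c(n_osc, n_loci - n_osc))
  rows <- list()
  for (grp in c("treatment", "control")) {
    for (li in seq_len(n_loci)) {
      oscillates <- (grp == "treatment") && osc[li]
      ph <- stats::runif(1, 0, 2 * pi)
      rate <- .clamp01(midpoint +
                         if (oscillates)
                           amplitude * sin(2 * pi * timepoints / period_min + ph)
                         else 0)
      tot <- stats::rpois(length(timepoints), coverage_mean)
      k <- stats::rbinom(length(timepoints), tot, rate)
      rows[[length(rows) + 1]] <-
        data.table(locus = sprintf("%s_L%02d", substr(grp, 1, 1), li),
                   group = grp, time_min = timepoints, meth = k, total = tot)
    }
  }
  series <- rbindlist(rows)
  truth <- data.table(locus = sprintf("t_L%02d", seq_len(n_loci)),
                      oscillating = osc)
  list(series = series, truth = truth)
}

#' Generate a synthetic expression matrix with enzyme genes and lifetimes
#'
#' Builds a gene-by-cell count matrix including the DNA-methylation
#' enzyme genes (Dnmt3a/b/l, Dnmt1, Tet1/2/3, Tdg) whose Dnmt/Tet
#' log-expression summary correlates only weakly with the ground-truth
#' global methylation level of each cell (squared correlation near
#' \code{target_r2}), emulating the observed near-independence of
#' methylation and enzyme expression. Transcript lifetimes are
#' log-normal with median near 7 hours.
#'
#' @param n_cells Number of cells.
#' @param n_genes Total number of genes (including the 8 enzyme genes).
#' @param target_r2 Target squared correlation between the Dnmt/Tet
#'   summary and global methylation, in [0, 0.5].
#' @param global_meth Optional per-cell true global methylation levels
#'   (default uniform on [0.2, 0.8]).
#' @param base_mean Mean expression scale of the enzyme genes.
#' @param seed RNG seed.
#' @return A list with \code{counts} (genes x cells), \code{lifetimes}
#'   (hours), \code{truth} (cell, global_meth, ratio) and
#'   \code{enzyme_genes}.
#' @export
generate_expression_matrix <- function(n_cells = 200, n_genes = 200,
                                       target_r2 = 0.06,
                                       global_meth = NULL,
                                       base_mean = 300, seed = 1) {
  stopifnot(target_r2 >= 0, target_r2 <= 0.5, n_genes >= 20)
  set.seed(seed)
  if (is.null(global_meth)) global_meth <- stats::runif(n_cells, 0.2, 0.8)
  z <- as.vector(scale(global_meth))
  ratio <- sqrt(target_r2) * z + sqrt(1 - target_r2) * stats::rnorm(n_cells)
  dnmt <- c("Dnmt3a", "Dnmt3b", "Dnmt3l", "Dnmt1")
  tet <- c("Tet1", "Tet2", "Tet3", "Tdg")
  others <- sprintf("gene%04d", seq_len(n_genes - 8))
  genes <- c(dnmt, tet, others)
  log_base <- c(rep(log(base_mean), 8),
                stats::rnorm(n_genes - 8, log(50), 1))
  counts <- matrix(0L, n_genes, n_cells,
                   dimnames = list(genes, sprintf("cell%03d", seq_len(n_cells))))
  shift <- outer(c(rep(+1, 4), rep(-1, 4), rep(0, n_genes - 8)) * 0.125,
                 ratio)
  mu <- exp(log_base + shift)
  counts[] <- stats::rpois(length(mu), as.vector(mu))
  lifetimes <- stats::rlnorm(n_genes, log(7), 0.6)
  list(counts = counts, lifetimes = lifetimes,
       truth = data.table(sample_id = colnames(counts),
                          global_meth = global_meth, ratio = ratio),
       enzyme_genes = list(dnmt = dnmt, tet = tet))
}

#' Dnmt/Tet log-expression summary per cell
#'
#' Sum of log-normalised expression of the methylation-promoting genes
#' (Dnmt3a/b/l, Dnmt1) minus the sum over the demethylation genes
#' (Tet1/2/3, Tdg), computed from a \code{\link{normalize_expression}}
#' result.
#'
#' @param log_norm Log-normalised expression matrix (genes x cells).
#' @param enzyme_genes List with character vectors \code{dnmt} and
#'   \code{tet}.
#' @return Named per-cell summary vector.
#' @export
dnmt_tet_ratio <- function(log_norm, enzyme_genes) {
  colSums(log_norm[enzyme_genes$dnmt, , drop = FALSE]) -
    colSums(log_norm[enzyme_genes$tet, , drop = FALSE])
}

#' Write a synthetic methylome dataset to disk
#'
#' Writes one Bismark-coverage file per sample, a sample sheet, truth
#' tables and a YAML manifest recording the seed and parameters, so a
#' generated cohort round-trips through the package readers.
#'
#' @param dataset Result of \code{\link{generate_single_cell_dataset}} or
#'   \code{\link{generate_bulk_timecourse}}.
#' @param dir Output directory (created if needed).
#' @param params Named list stored in the manifest.
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir, params = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  calls <- as.data.table(dataset$calls)
  ids <- unique(calls$sample_id)
  for (s in ids)
    write_bismark_cov(calls[sample_id == s],
                      file.path(dir, paste0(s, ".cov")))
  meta <- attr(dataset$calls, "metadata")
  if (!is.null(meta))
    fwrite(meta, file.path(dir, "sample_sheet.tsv"), sep = "\t")
  if (!is.null(dataset$truth_cells))
    fwrite(dataset$truth_cells, file.path(dir, "truth_cells.tsv"), sep = "\t")
  if (!is.null(dataset$truth_blocks))
    fwrite(dataset$truth_blocks, file.path(dir, "truth_blocks.tsv"), sep = "\t")
  manifest <- c(list(n_samples = length(ids)), params)
  writeLines(paste0(names(manifest), ": ", vapply(manifest, format, "")),
             file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a dataset written by \code{\link{write_dataset}}
#'
#' @param dir Dataset directory.
#' @return A \code{\link{meth_call_table}} with the sample sheet as
#'   metadata.
#' @export
read_dataset <- function(dir) {
  files <- list.files(dir, pattern = "\\.cov$", full.names = TRUE)
  if (!length(files)) stop("no coverage files in ", dir)
  lst <- lapply(files, function(f)
    read_bismark_cov(f, sub("\\.cov$", "", basename(f))))
  names(lst) <- sub("\\.cov$", "", basename(files))
  meta_file <- file.path(dir, "sample_sheet.tsv")
  meta <- if (file.exists(meta_file)) as.data.frame(fread(meta_file)) else NULL
  meth_call_table(lst, metadata = meta)
}
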