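#!/usr/bin/env Rscript

# Generate the synthetic study cohorts with ground truth and write them in
# Bismark-coverage form under results/datasets/.

suppressPackageStartupMessages({library(methosc); library(data.table)})
dir.create("results/datasets", showWarnings = FALSE, recursive = TRUE)

g <- genome_spec()
fwrite(g, "results/datasets/genome_cpgs.tsv", sep = "\t")
cat("Synthetic genome:", nrow(g), "CpGs in",
    length(unique(g$block_id)), "density blocks (0.5% - 18%)\n")

sc <- generate_single_cell_dataset(g, n_cells = 50, coherence = 0.9,
                                   seed = 40)
write_dataset(sc, "results/datasets/single_cell",
              params = list(seed = 40, n_cells = 50, coherence = 0.9))
cat("Single-cell cohort: 50 cells,",
    nrow(sc$calls), "methylation calls written\n")

ep <- generate_epiblast_dataset(g, n_cells = 80, seed = 41)
write_dataset(ep, "results/datasets/epiblast",
              params = list(seed = 41, n_cells = 80, age_cycles = 3))
cat("Epiblast-like cohort: 80 cells with developmental ages,",
    "age-locked oscillator phase\n")

ep0 <- generate_epiblast_dataset(g, n_cells = 80, age_cycles = 0,
                                 seed = 45)
write_dataset(ep0, "results/datasets/epiblast_static",
              params = list(seed = 45, n_cells = 80, age_cycles = 0))
cat("Epiblast-like cohort (random phases): 80 cells, phase independent",
    "of developmental stage\n")

bk <- generate_bulk_timecourse(g, seed = 42)
write_dataset(bk, "results/datasets/bulk_release",
              params = list(seed = 42, period_min = 150))
cat("Bulk release time course: 31 time points x 3 replicates,",
    "150-min oscillation over a rising trend\n")

amp <- generate_amplicon_timecourse(seed = 43)
fwrite(amp$series, "results/datasets/amplicon_series.tsv", sep = "\t")
fwrite(amp$truth, "results/datasets/amplicon_truth.tsv", sep = "\t")
cat("Amplicon panel: 14 + 14 loci, 47 points at 20-min spacing,",
    sum(amp$truth$oscillating), "oscillating loci\n")

ex <- generate_expression_matrix(seed = 44)
fwrite(as.data.table(ex$counts, keep.rownames = "gene"),
       "results/datasets/expression_counts.tsv", sep = "\t")
fwrite(data.table(gene = rownames(ex$counts), lifetime_h = ex$lifetimes),
       "results/datasets/expression_lifetimes.tsv", sep = "\t")
fwrite(ex$truth, "results/datasets/expression_truth.tsv", sep = "\t")
cat("Expression matrix:", nrow(ex$counts), "genes x", ncol(ex$counts),
    "cells; transcript lifetime median",
    round(median(ex$lifetimes), 1), "h\n")
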