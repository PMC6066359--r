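# small shared fixtures, built in code

small_genome <- function() {
  genome_spec(densities = c(0.01, 0.025, 0.125), blocks_per_density = 2,
              cpgs_per_block = 60)
}

# plain two-reaction Gillespie in R: independent oracle for the
# delayed simulator at delta_t = 0
plain_gillespie_M <- function(alpha, beta, C0, M0, t_end) {
  C <- C0; M <- M0; t <- 0
  repeat {
    a1 <- alpha * C * M; a2 <- beta * M; a0 <- a1 + a2
    if (a0 <= 0) break
    t <- t + stats::rexp(1, a0)
    if (t > t_end) break
    if (stats::runif(1) * a0 < a1) { C <- C - 1; M <- M + 1 }
    else { M <- M - 1; C <- C + 1 }
  }
  M
}

# calls table where every cell has identical counts at every position
constant_calls <- function(n_cells = 12, n_pos = 120, k = 4, s = 10) {
  lst <- lapply(seq_len(n_cells), function(i)
    data.table::data.table(chrom = "chr1", pos = seq_len(n_pos) * 37L,
                           meth = k, unmeth = s - k))
  names(lst) <- sprintf("c%02d", seq_len(n_cells))
  meth_call_table(lst)
}
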