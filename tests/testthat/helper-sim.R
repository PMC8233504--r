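# shared fixtures: small simulated experiments and toy count matrices

# a quick neutral experiment at the default 6+6 design
quick_sim <- function(n_loci = 200, t = 50, ne = 150, seed = 1, ...) {
  simulate_experiment(sim_config(n_loci = n_loci, t = t, ne_selected = ne,
                                 ne_control = ne, seed = seed, ...))
}

# count matrix built directly from a frequency matrix at fixed depth
counts_from_freqs <- function(freqs, depth = 30, chrom = "2L",
                              pos = 1000L * seq_len(nrow(freqs))) {
  alt <- round(freqs * depth)
  ref <- depth - alt
  count_matrix(chrom = rep(chrom, nrow(freqs)), pos = pos,
               ref_allele = "A", alt_allele = "T",
               ref = ref, alt = alt,
               pops = c(paste0("S", 1:6), paste0("C", 1:6)))
}

# textbook Tajima's D implementation, kept deliberately separate from the
# package's own formulas (independent oracle)
oracle_tajima <- function(alt_counts, m) {
  seg <- alt_counts > 0 & alt_counts < m
  S <- sum(seg)
  pi_sum <- sum(2 * alt_counts * (m - alt_counts) / (m * (m - 1)))
  a1 <- sum(1 / seq_len(m - 1)); a2 <- sum(1 / seq_len(m - 1)^2)
  b1 <- (m + 1) / (3 * (m - 1)); b2 <- 2 * (m * m + m + 3) / (9 * m * (m - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (m + 2) / (a1 * m) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1 * a1 + a2)
  theta <- S / a1
  list(pi = pi_sum, theta = theta, S = S,
       D = if (S >= 1) (pi_sum - theta) / sqrt(e1 * S + e2 * S * (S - 1)) else NA)
}

default_design <- function() regime_design()
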