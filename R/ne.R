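#' Pool-seq sampling correction factor C
#'
#' For each population `j`, `C_j = 1/(2S) + 1/R_j + 1/(S R_j)` where `S` is
#' the pool size (diploid individuals) and `R_j` the read depth used to
#' estimate the allele frequency; `C` is the arithmetic mean of the `C_j`.
#' `C` approximates the fraction of `p(1-p)` contributed by the two-stage
#' sampling (individuals into the pool, reads from the pool).
#'
#' @param S pool size, >= 1.
#' @param depths vector of read depths `R_j`, all >= 1.
#' @return the correction factor C.
#' @examples
#' correction_factor(400, rep(30, 12))  # ~0.034667
#' @export
correction_factor <- function(S, depths) {
  if (S < 1) stop("pool size S must be >= 1")
  if (any(depths < 1)) stop("all depths must be >= 1")
  mean(1 / (2 * S) + 1 / depths + 1 / (S * depths))
}

# expected among-replicate variance under drift + pool-seq sampling
forward_variance <- function(ne, p0, t, C) {
  p0 * (1 - p0) * (1 - (1 - C) * (1 - 1 / (2 * ne))^t)
}

# invert the variance model; NA when the bracketed base leaves (0, 1)
invert_ne <- function(vhat, p0, t, C) {
  pq <- p0 * (1 - p0)
  base <- (1 - vhat / pq) / (1 - C)
  ifelse(base > 0 & base < 1, 1 / (2 * (1 - base^(1 / t))), NA_real_)
}

#' SNP-wise Ne estimate from among-replicate allele-frequency variance
#'
#' Under drift, the expected variance of replicate-population allele
#' frequencies (as read frequencies from pool-seq) around the founder
#' frequency is `Var(p) = p0 (1 - p0) [1 - (1 - C)(1 - 1/(2 Ne))^t]`.
#' `p0` is estimated as the mean frequency across all populations (both
#' regimes), and the regime-specific variance uses the `n - 0.5`
#' denominator, reflecting the half degree of freedom each regime
#' contributes to the estimate of `p0`. Solving for Ne gives
#' `Ne = 1 / (2 (1 - [(1 - Var/(p0(1-p0)))/(1-C)]^{1/t}))`.
#'
#' @param freqs numeric vector of allele frequencies, one per population
#'   (both regimes).
#' @param design a [regime_design()] whose rows align with `freqs`.
#' @param t generations since the common base.
#' @param C pool-seq correction factor from [correction_factor()].
#' @return named numeric vector `c(ne_sel, ne_ctl)`; `NA` (flagged
#'   non-invertible) when the observed variance is below the sampling
#'   floor or above `p0(1-p0)`.
#' @export
estimate_ne_per_snp <- function(freqs, design, t, C) {
  stopifnot(length(freqs) == nrow(design), t >= 1, C >= 0, C < 1)
  p0 <- mean(freqs)
  if (p0 <= 0 || p0 >= 1) return(c(ne_sel = NA_real_, ne_ctl = NA_real_))
  sel <- design$regime == "SEL"
  n_sel <- sum(sel); n_ctl <- sum(!sel)
  v_sel <- sum((freqs[sel] - p0)^2) / (n_sel - 0.5)
  v_ctl <- sum((freqs[!sel] - p0)^2) / (n_ctl - 0.5)
  c(ne_sel = invert_ne(v_sel, p0, t, C), ne_ctl = invert_ne(v_ctl, p0, t, C))
}

# core: per-SNP Ne estimates for an arbitrary two-group split
ne_table <- function(freqs, depths, S, t, group1, group2) {
  p0 <- rowMeans(freqs)
  n1 <- length(group1); n2 <- length(group2)
  v1 <- rowSums((freqs[, group1, drop = FALSE] - p0)^2) / (n1 - 0.5)
  v2 <- rowSums((freqs[, group2, drop = FALSE] - p0)^2) / (n2 - 0.5)
  C <- rowMeans(1 / (2 * S) + 1 / depths + 1 / (S * depths))
  ok <- p0 > 0 & p0 < 1
  ne1 <- ne2 <- rep(NA_real_, nrow(freqs))
  ne1[ok] <- invert_ne(v1[ok], p0[ok], t, C[ok])
  ne2[ok] <- invert_ne(v2[ok], p0[ok], t, C[ok])
  data.frame(p0 = p0, var_1 = v1, var_2 = v2, C = C, ne_1 = ne1, ne_2 = ne2)
}

#' Estimate regime-specific Ne from putatively neutral SNPs
#'
#' Applies the SNP-wise inversion of the drift + pool-seq variance model to
#' a set of putatively neutral sites (e.g. short-intron or synonymous SNPs,
#' supplied as an annotation table), keeping SNPs with coverage >= 10 in
#' every population and mean allele frequency (across all populations) in
#' `[0.4, 0.6]` (asymmetric SNPs bias Ne upward). Reports the median Ne per
#' regime, separately for autosomal arms (2L, 2R, 3L, 3R) and the X.
#'
#' @param counts a [count_matrix()] at native coverage.
#' @param design a [regime_design()]; `S` and `t` are taken from it unless
#'   overridden.
#' @param neutral_sites optional data.frame (chrom, pos) of eligible sites
#'   (e.g. from a short-intron BED via [read_bed_mask()] expanded to
#'   positions); `NULL` uses all sites.
#' @param t,S generations and pool size (defaults from `design`).
#' @param min_coverage per-population coverage floor (default 10).
#' @param freq_range retained mean-frequency interval (default 0.4-0.6).
#' @return list of class `ne_estimate`: `snps` (per-SNP table with p0,
#'   regime variances, C, Ne per regime), `summary` (per chromosome class
#'   and regime: median Ne, number of SNPs, number non-invertible).
#' @export
estimate_ne <- function(counts, design, neutral_sites = NULL,
                        t = attr(design, "t"), S = attr(design, "S"),
                        min_coverage = 10, freq_range = c(0.4, 0.6)) {
  di <- design_index(counts, design)
  keep <- rep(TRUE, n_sites(counts))
  if (!is.null(neutral_sites)) {
    key <- paste(counts$sites$chrom, counts$sites$pos)
    keep <- key %in% paste(neutral_sites$chrom, neutral_sites$pos)
  }
  cov <- coverage(counts)
  keep <- keep & rowSums(cov < min_coverage) == 0L
  f <- allele_freqs(counts)
  p0 <- rowMeans(f)
  keep <- keep & p0 >= freq_range[1] & p0 <= freq_range[2]
  if (sum(keep) < 20)
    warning("fewer than 20 eligible neutral SNPs; Ne estimates are low-confidence")
  x <- subset_sites(counts, keep)
  f <- f[keep, , drop = FALSE]; cov <- cov[keep, , drop = FALSE]
  tab <- ne_table(f, cov, S, t, di$sel, di$ctl)
  names(tab) <- c("p0", "var_sel", "var_ctl", "C", "ne_sel", "ne_ctl")
  tab <- cbind(x$sites[, c("chrom", "pos")], tab)
  cls <- ifelse(tab$chrom == "X", "X",
                ifelse(tab$chrom %in% c("2L", "2R", "3L", "3R"), "autosome", NA))
  summ <- do.call(rbind, lapply(c("autosome", "X"), function(cc) {
    i <- which(cls == cc)
    data.frame(class = cc,
               ne_sel = median(tab$ne_sel[i], na.rm = TRUE),
               ne_ctl = median(tab$ne_ctl[i], na.rm = TRUE),
               n_snps = length(i),
               n_noninvertible = sum(is.na(tab$ne_sel[i]) | is.na(tab$ne_ctl[i])),
               stringsAsFactors = FALSE)
  }))
  structure(list(snps = tab, summary = summ, t = t, S = S), class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat("Ne estimates (median over SNP-wise inversions):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Randomization test for a regime difference in Ne
#'
#' Generates `n_perm` data sets by randomly splitting the populations into
#' two groups of equal size, each containing half of the Selected and half
#' of the Control populations, re-estimating the two group medians on each,
#' and comparing the observed |Ne_SEL - Ne_CTL| to the null distribution of
#' the absolute group differences. `p = (1 + #{null >= observed}) /
#' (n_perm + 1)`.
#'
#' @param counts,design,neutral_sites,t,S,min_coverage,freq_range as in
#'   [estimate_ne()].
#' @param chrom_class `"autosome"` or `"X"`: which chromosome class the
#'   test is run on.
#' @param n_perm number of random splits (default 100).
#' @param seed optional seed.
#' @return list with `observed` (difference of medians), `null`
#'   (permutation differences) and `p`.
#' @export
ne_randomization_test <- function(counts, design, neutral_sites = NULL,
                                  chrom_class = "autosome",
                                  t = attr(design, "t"), S = attr(design, "S"),
                                  min_coverage = 10, freq_range = c(0.4, 0.6),
                                  n_perm = 100, seed = NULL) {
  di <- design_index(counts, design)
  n_sel <- length(di$sel); n_ctl <- length(di$ctl)
  if (n_sel < 3 || n_ctl < 3)
    stop("randomization test requires at least 3 populations per regime")
  if (n_sel %% 2 || n_ctl %% 2)
    stop("randomization test requires even numbers of populations per regime")
  est <- estimate_ne(counts, design, neutral_sites, t = t, S = S,
                     min_coverage = min_coverage, freq_range = freq_range)
  tab <- est$snps
  cls <- ifelse(tab$chrom == "X", "X",
                ifelse(tab$chrom %in% c("2L", "2R", "3L", "3R"), "autosome", NA))
  tab <- tab[which(cls == chrom_class), , drop = FALSE]
  if (nrow(tab) == 0L) stop("no eligible SNPs in chromosome class ", chrom_class)
  observed <- median(tab$ne_sel, na.rm = TRUE) - median(tab$ne_ctl, na.rm = TRUE)
  # frequencies/coverages restricted to the same SNPs, for the re-splits
  key <- paste(counts$sites$chrom, counts$sites$pos)
  idx <- match(paste(tab$chrom, tab$pos), key)
  f <- allele_freqs(counts)[idx, , drop = FALSE]
  cov <- coverage(counts)[idx, , drop = FALSE]
  null <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    g1 <- c(sample(di$sel, n_sel / 2), sample(di$ctl, n_ctl / 2))
    g2 <- setdiff(c(di$sel, di$ctl), g1)
    nt <- ne_table(f, cov, S, t, g1, g2)
    median(nt$ne_1, na.rm = TRUE) - median(nt$ne_2, na.rm = TRUE)
  }, numeric(1)))
  p <- (1 + sum(abs(null) >= abs(observed))) / (n_perm + 1)
  list(observed = observed, null = null, p = p)
}
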