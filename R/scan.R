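#' Fisher exact test scan on regime-pooled counts
#'
#' At each SNP, pools reference/alternate read counts across the
#' populations of each regime (input must be at a uniform subsampled
#' coverage so every population contributes equally) and tests the 2x2
#' table (regime x allele) with a two-sided Fisher exact test.
#'
#' @param counts a [count_matrix()] subsampled to uniform coverage
#'   ([subsample_coverage()] scan mode).
#' @param design a [regime_design()]; regime labels may be an arbitrary
#'   two-group pseudo-design during permutation.
#' @return numeric vector of p-values (1 for sites monomorphic after
#'   pooling).
#' @export
fet_scan <- function(counts, design) {
  di <- design_index(counts, design)
  ref_sel <- rowSums(counts$ref[, di$sel, drop = FALSE])
  alt_sel <- rowSums(counts$alt[, di$sel, drop = FALSE])
  ref_ctl <- rowSums(counts$ref[, di$ctl, drop = FALSE])
  alt_ctl <- rowSums(counts$alt[, di$ctl, drop = FALSE])
  fisher2x2_p(ref_sel, alt_sel, ref_ctl, alt_ctl)
}

#' Binomial mixed-model scan at native coverage
#'
#' Fits, per SNP, a binomial GLMM of the alternate read count on the
#' regime (fixed effect) with a random intercept per population (which
#' absorbs replicate-level overdispersion from drift), and compares it to
#' the reduced model without the regime effect by a likelihood-ratio test
#' (chi-squared with 1 df). Fitting uses Gauss-Hermite quadrature; because
#' there is one random intercept per observation the marginal likelihood
#' factorises over populations.
#'
#' @param counts a [count_matrix()] at native coverage.
#' @param design a [regime_design()] (or pseudo-design during permutation).
#' @param n_quad number of quadrature nodes (default 12; adaptive quadrature).
#' @param maxit,tol Newton iteration cap and gradient tolerance.
#' @return data.frame with `lrt` (non-negative LRT statistic), `p`
#'   (chi-squared(1) upper tail; `NA` for non-converged fits),
#'   `sigma` (random-intercept SD), `beta_regime` (regime effect, logit
#'   scale) and `converged`.
#' @export
glmm_scan <- function(counts, design, n_quad = 12, maxit = 200, tol = 1e-6) {
  di <- design_index(counts, design)
  x <- numeric(length(counts$pops))
  x[di$sel] <- 1
  gh <- gauss_hermite(n_quad)
  fit <- .glmm_lrt_cpp(counts$alt * 1.0, coverage(counts) * 1.0, x,
                       gh$nodes, gh$weights, maxit, tol)
  p <- ifelse(fit$converged, pchisq(fit$lrt, df = 1, lower.tail = FALSE),
              NA_real_)
  data.frame(lrt = fit$lrt, p = p, sigma = fit$sigma,
             beta_regime = fit$beta_regime, converged = fit$converged)
}

#' Empirical permutation false discovery rate
#'
#' The FET and GLMM p-values in this design are statistics with unknown
#' null distributions (pooled counts are overdispersed by drift), so the
#' FDR for a raw p-value cutoff is estimated by comparing the observed
#' cumulative distribution of p-values with a null distribution obtained
#' by re-running the same test on regime-permuted data:
#' `q(P) = min over Phat >= P of CDF_E(Phat) / CDF_O(Phat)`, where `CDF_E`
#' is the null CDF averaged over the permutations and `CDF_O` the observed
#' one. q-values are clipped to `[eps, 1]` with
#' `eps = 1/(n_perm * n_SNPs + 1)` and are monotone non-decreasing in P.
#'
#' @param p_observed observed p-values (`NA` treated as 1).
#' @param p_null list of numeric vectors, one per permutation (each the
#'   p-values of the same test on one permuted design).
#' @return list of class `fdr_result`: `q` (per observed p-value), `grid`
#'   (data.frame of the sorted p grid with CDF_O, CDF_E and q) and `eps`.
#' @export
permutation_fdr <- function(p_observed, p_null) {
  stopifnot(is.list(p_null), length(p_null) >= 1)
  p_obs <- ifelse(is.na(p_observed), 1, p_observed)
  n <- length(p_obs)
  n_perm <- length(p_null)
  pooled_null <- sort(ifelse(is.na(unlist(p_null)), 1, unlist(p_null)))
  n_null <- length(pooled_null)
  grid <- sort(unique(p_obs))
  cdf_o <- findInterval(grid, sort(p_obs)) / n
  cdf_e <- findInterval(grid, pooled_null) / n_null  # mean over permutations
  ratio <- cdf_e / cdf_o
  q_grid <- rev(cummin(rev(ratio)))
  eps <- 1 / (n_perm * n + 1)
  q_grid <- pmin(1, pmax(eps, q_grid))
  q <- q_grid[match(p_obs, grid)]
  structure(list(q = q,
                 grid = data.frame(p = grid, cdf_obs = cdf_o, cdf_null = cdf_e,
                                   q = q_grid),
                 eps = eps),
            class = "fdr_result")
}

# random pseudo-design: each group gets half the Selected and half the
# Control populations
permute_design <- function(design) {
  sel <- which(design$regime == "SEL"); ctl <- which(design$regime == "CTL")
  g1 <- c(sample(sel, length(sel) / 2), sample(ctl, length(ctl) / 2))
  regime <- rep("CTL", nrow(design))
  regime[g1] <- "SEL"
  regime_design(design$pop, regime, S = attr(design, "S"), t = attr(design, "t"))
}

#' Flag candidate SNPs from the two-pronged scan
#'
#' A SNP is a candidate when it passes the FDR threshold in at least one
#' test (union first) *and* the absolute difference of regime mean allele
#' frequencies exceeds `delta_threshold` (filter second). Both q
#' thresholds are inclusive; the delta threshold is strict.
#'
#' @param scan a data.frame with columns `q_fet`, `q_glmm`, `delta` (as
#'   produced by [candidate_scan()]).
#' @param q_threshold FDR threshold (default 0.05).
#' @param delta_threshold minimum |mean_SEL - mean_CTL| (default 0.3).
#' @return the input with added logical `candidate` and character
#'   `detected_by` (`"FET"`, `"GLMM"`, `"FET+GLMM"` or `""`).
#' @export
select_candidates <- function(scan, q_threshold = 0.05, delta_threshold = 0.3) {
  hit_fet <- !is.na(scan$q_fet) & scan$q_fet <= q_threshold
  hit_glmm <- !is.na(scan$q_glmm) & scan$q_glmm <= q_threshold
  pass_delta <- scan$delta > delta_threshold
  scan$candidate <- (hit_fet | hit_glmm) & pass_delta
  scan$detected_by <- ifelse(scan$candidate,
                             paste0(ifelse(hit_fet, "FET", ""),
                                    ifelse(hit_fet & hit_glmm, "+", ""),
                                    ifelse(hit_glmm, "GLMM", "")),
                             "")
  scan
}

#' Principal-component QC of population allele frequencies
#'
#' PCA of populations on the covariance (not correlation) matrix of allele
#' frequencies — frequencies are already on a common scale — followed by a
#' Welch t-test of the first principal component scores between regimes.
#' Replicable regime divergence shows as PC1 separation.
#'
#' @param freqs numeric matrix of allele frequencies, sites x populations.
#' @param design a [regime_design()].
#' @return list with `scores` (populations x PCs), `var_frac` (variance
#'   fractions), `welch` (t statistic, df, p for PC1).
#' @export
qc_pca <- function(freqs, design) {
  stopifnot(ncol(freqs) == nrow(design))
  keep <- which(apply(freqs, 1L, function(r) all(is.finite(r))))
  X <- t(freqs[keep, , drop = FALSE])  # populations as observations
  if (all(apply(X, 2L, sd) == 0)) stop("constant frequency matrix: PCs undefined")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  sel <- design$regime == "SEL"
  tt <- t.test(pc$x[sel, 1], pc$x[!sel, 1])
  rownames(pc$x) <- design$pop
  list(scores = pc$x, var_frac = var_frac,
       welch = list(t = unname(tt$statistic), df = unname(tt$parameter),
                    p = tt$p.value))
}

#' Two-pronged candidate-SNP scan with permutation FDR
#'
#' Runs the full detection pipeline: (1) subsample to `subsample`-fold
#' coverage (scan mode; sites below target in any population are excluded
#' from the FET but kept for the GLMM) and Fisher-exact test on
#' regime-pooled counts; (2) binomial mixed-model LRT at native coverage;
#' (3) `n_perm` permutations of the design (each pseudo-group gets 3
#' Selected + 3 Control populations), re-running both tests end-to-end —
#' including a fresh coverage subsample for the FET — to build the
#' empirical null; (4) permutation FDR per test; (5) candidate flagging by
#' q-threshold union plus the mean-frequency-difference filter, with
#' regime means taken from unweighted native-coverage read frequencies.
#'
#' @param counts a [count_matrix()] at native coverage (filtered SNPs).
#' @param design a [regime_design()].
#' @param subsample target coverage for the FET branch (default 30).
#' @param n_perm number of permuted data sets (default 5).
#' @param q_threshold,delta_threshold candidate thresholds (0.05, 0.3).
#' @param seed master seed controlling subsampling and permutations.
#' @param n_quad quadrature nodes for the GLMM (default 12).
#' @return data.frame of class `scan_result`: chrom, pos, ref, alt, p_fet,
#'   q_fet, p_glmm, q_glmm, glmm_converged, mean_sel, mean_ctl, delta,
#'   candidate, detected_by. Attribute `fdr` holds the two `fdr_result`
#'   objects.
#' @export
candidate_scan <- function(counts, design, subsample = 30, n_perm = 5,
                           q_threshold = 0.05, delta_threshold = 0.3,
                           seed = NULL, n_quad = 12) {
  di <- design_index(counts, design)
  n <- n_sites(counts)
  key <- paste(counts$sites$chrom, counts$sites$pos)

  sub <- subsample_coverage(counts, subsample, mode = "scan",
                            seed = child_seed(seed, 1))
  p_fet_sub <- fet_scan(sub, design)
  p_fet <- rep(NA_real_, n)
  p_fet[match(paste(sub$sites$chrom, sub$sites$pos), key)] <- p_fet_sub

  glmm <- glmm_scan(counts, design, n_quad = n_quad)

  null_fet <- vector("list", n_perm)
  null_glmm <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    pd <- with_seed(child_seed(seed, 100 + b), permute_design(design))
    sub_b <- subsample_coverage(counts, subsample, mode = "scan",
                                seed = child_seed(seed, 200 + b))
    null_fet[[b]] <- fet_scan(sub_b, pd)
    null_glmm[[b]] <- glmm_scan(counts, pd, n_quad = n_quad)$p
  }
  fdr_fet <- permutation_fdr(p_fet_sub, null_fet)
  q_fet <- rep(NA_real_, n)
  q_fet[match(paste(sub$sites$chrom, sub$sites$pos), key)] <- fdr_fet$q
  fdr_glmm <- permutation_fdr(glmm$p, null_glmm)

  f <- allele_freqs(counts)
  mean_sel <- rowMeans(f[, di$sel, drop = FALSE])
  mean_ctl <- rowMeans(f[, di$ctl, drop = FALSE])
  res <- data.frame(counts$sites,
                    p_fet = p_fet, q_fet = q_fet,
                    p_glmm = glmm$p, q_glmm = fdr_glmm$q,
                    glmm_converged = glmm$converged,
                    mean_sel = mean_sel, mean_ctl = mean_ctl,
                    delta = abs(mean_sel - mean_ctl),
                    stringsAsFactors = FALSE)
  res <- select_candidates(res, q_threshold, delta_threshold)
  attr(res, "fdr") <- list(fet = fdr_fet, glmm = fdr_glmm)
  class(res) <- c("scan_result", "data.frame")
  res
}
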