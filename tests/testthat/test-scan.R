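test_that("pipeline Fisher p-values equal the stats::fisher.test oracle", {
  set.seed(41)
  for (case in 1:1000) {
    tab <- matrix(sample(0:60, 4, replace = TRUE), 2)
    mine <- erpool:::fisher2x2_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(mine, fisher.test(tab)$p.value, tolerance = 1e-12)
  }
})

test_that("the FET scan pools counts within regimes", {
  f <- matrix(0.5, 3, 12)
  cm <- counts_from_freqs(f, depth = 30)
  cm$alt[2, 1:6] <- 28L; cm$ref[2, 1:6] <- 2L   # strong regime split
  d <- default_design()
  p <- fet_scan(cm, d)
  expect_equal(p[1], 1)  # identical pooled counts
  expect_equal(p[2],
               fisher.test(matrix(c(6 * 2, 6 * 28, 6 * 15, 6 * 15), 2,
                                  byrow = TRUE))$p.value, tolerance = 1e-12)
  # swapping regime labels leaves p unchanged
  d_sw <- regime_design(d$pop, rev(d$regime))
  expect_equal(fet_scan(cm, d_sw), p)
})

test_that("GLMM LRT agrees with lme4::glmer on informative SNPs", {
  skip_if_not_installed("lme4")
  sim <- quick_sim(n_loci = 60, t = 60, ne = 300, seed = 42,
                   p0 = function(n) runif(n, 0.25, 0.75))
  g <- glmm_scan(sim$counts, sim$design, n_quad = 40)
  y <- sim$counts$alt; n <- coverage(sim$counts)
  x <- factor(rep(c("SEL", "CTL"), each = 6), levels = c("CTL", "SEL"))
  # restrict to SNPs where every population is polymorphic (well-behaved
  # interior optima; boundary cases are checked structurally below)
  ok <- which(apply(y > 0 & y < n, 1, all))[1:15]
  lrt_lme4 <- vapply(ok, function(i) {
    dat <- data.frame(alt = y[i, ], ref = n[i, ] - y[i, ], regime = x,
                      pop = factor(1:12))
    full <- suppressWarnings(suppressMessages(
      lme4::glmer(cbind(alt, ref) ~ regime + (1 | pop), data = dat,
                  family = binomial, nAGQ = 25)))
    red <- suppressWarnings(suppressMessages(
      lme4::glmer(cbind(alt, ref) ~ 1 + (1 | pop), data = dat,
                  family = binomial, nAGQ = 25)))
    2 * (as.numeric(logLik(full)) - as.numeric(logLik(red)))
  }, numeric(1))
  expect_lt(max(abs(g$lrt[ok] - lrt_lme4)), 0.02)
})

test_that("GLMM detects a clean regime split and ignores a flat one", {
  f <- rbind(rep(0.5, 12), c(rep(0.9, 6), rep(0.1, 6)))
  cm <- counts_from_freqs(f, depth = 40)
  g <- glmm_scan(cm, default_design())
  expect_gt(g$p[1], 0.9)     # identical populations: LRT ~ 0
  expect_lt(g$p[2], 1e-6)    # 0.9 vs 0.1 split at depth 40
})

test_that("LRT statistics are non-negative across random SNPs", {
  sim <- quick_sim(n_loci = 1000, t = 150, seed = 43)
  g <- glmm_scan(sim$counts, sim$design)
  expect_true(all(g$lrt >= 0))
  expect_true(all(is.na(g$p) | (g$p >= 0 & g$p <= 1)))
})

test_that("permutation FDR reproduces the min-ratio formula by hand", {
  # observed {0.001, 0.5}; two permutations pooling to {0.2, 0.4, 0.6, 0.8}
  fdr <- permutation_fdr(c(0.001, 0.5), list(c(0.2, 0.4), c(0.6, 0.8)))
  # at 0.001: CDF_E = 0, CDF_O = 0.5 -> ratio 0 -> clipped to eps
  expect_equal(fdr$q[1], fdr$eps)
  expect_equal(fdr$eps, 1 / (2 * 2 + 1))
  # at 0.5: CDF_E = 0.5, CDF_O = 1 -> q = 0.5
  expect_equal(fdr$q[2], 0.5)
})

test_that("null-identical p-value distributions give q of 1", {
  p <- runif(500)
  fdr <- permutation_fdr(p, list(p, p))
  expect_true(all(fdr$q == 1))
})

test_that("q-values are monotone in p on arbitrary inputs", {
  set.seed(44)
  for (case in 1:20) {
    p_obs <- runif(200)^sample(c(0.5, 1, 2), 1)
    nulls <- replicate(3, runif(200), simplify = FALSE)
    fdr <- permutation_fdr(p_obs, nulls)
    o <- order(p_obs)
    expect_true(all(diff(fdr$q[o]) >= -1e-12))
    expect_true(all(fdr$q >= fdr$eps & fdr$q <= 1))
  }
})

test_that("candidate flagging applies the union-then-delta rule", {
  scan <- data.frame(q_fet = c(0.04, NA, 0.05, 0.2),
                     q_glmm = c(0.5, 0.05, 0.04, 0.01),
                     delta = c(0.29, 0.31, 0.31, 0.50))
  out <- select_candidates(scan)
  expect_equal(out$candidate, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(out$detected_by, c("", "GLMM", "FET+GLMM", "GLMM"))
})

test_that("the scan pipeline is reproducible and finds planted loci", {
  sel <- selection_spec(260, mode = c(rep("directional", 60), rep("neutral", 200)),
                        s = 0.1)
  sim <- simulate_experiment(sim_config(
    n_loci = 260, ne_selected = 150, ne_control = 150, t = 150,
    selection = sel, p0 = c(rep(0.3, 60), runif(200, 0.05, 0.95)), seed = 45))
  res1 <- candidate_scan(sim$counts, sim$design, seed = 46)
  res2 <- candidate_scan(sim$counts, sim$design, seed = 46)
  expect_identical(res1$candidate, res2$candidate)
  planted <- sim$truth$mode == "directional"
  expect_gt(mean(res1$candidate[planted]), 0.8)
  expect_lt(mean(res1$candidate[!planted]), 0.2)
})

test_that("PCA separates regimes and reports normalized variance fractions", {
  sim <- simulate_experiment(sim_config(
    n_loci = 300, ne_selected = 150, ne_control = 150, t = 150,
    selection = selection_spec(300, mode = "directional", s = 0.1),
    p0 = function(n) runif(n, 0.2, 0.5), seed = 47))
  pc <- qc_pca(allele_freqs(sim$counts), sim$design)
  expect_equal(sum(pc$var_frac), 1)
  expect_lt(pc$welch$p, 0.01)
  # duplicated population columns give identical scores
  f <- allele_freqs(sim$counts)
  f[, 7:12] <- f[, 1:6]
  pc2 <- qc_pca(f, sim$design)
  expect_equal(unname(pc2$scores[1:6, 1]), unname(pc2$scores[7:12, 1]))
  expect_error(qc_pca(matrix(0.5, 10, 12), sim$design), "constant")
})
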