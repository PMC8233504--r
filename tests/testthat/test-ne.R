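test_that("the pool-seq correction factor matches hand arithmetic", {
  expect_equal(correction_factor(400, rep(30, 12)),
               1 / 800 + 1 / 30 + 1 / 12000, tolerance = 1e-12)
  expect_equal(correction_factor(400, c(20, 40)),
               mean(c(0.00125 + 0.05 + 0.000125, 0.00125 + 0.025 + 0.0000625)),
               tolerance = 1e-12)
  # infinite pool and depth: no sampling variance
  expect_lt(correction_factor(1e9, 1e9), 1e-8)
  expect_error(correction_factor(0, 30), "pool size")
  expect_error(correction_factor(400, c(30, 0)), "depths")
})

test_that("variance-model inversion is exact on forward-simulated variances", {
  d <- regime_design()
  # C = 0 and the textbook drift variance recover Ne exactly
  v <- 0.25 * (1 - (1 - 1 / 300)^150)
  freqs <- c(0.5 + sqrt(v * 5.5 / 6) * c(1, -1, 1, -1, 1, -1),
             0.5 + sqrt(v * 5.5 / 6) * c(1, -1, 1, -1, 1, -1))
  # constructed so that each regime's (n - 0.5)-denominator variance is v
  est <- estimate_ne_per_snp(freqs, d, t = 150, C = 0)
  expect_equal(unname(est["ne_sel"]), 150, tolerance = 1e-9)
  expect_equal(unname(est["ne_ctl"]), 150, tolerance = 1e-9)
})

test_that("forward/inverse consistency holds across the parameter grid", {
  for (ne in c(50, 100, 150, 250, 500))
    for (p0 in c(0.3, 0.5, 0.7))
      for (t in c(50, 150)) {
        C <- correction_factor(400, rep(30, 12))
        v <- erpool:::forward_variance(ne, p0, t, C)
        expect_equal(erpool:::invert_ne(v, p0, t, C), ne, tolerance = 1e-9)
      }
})

test_that("degenerate variances are flagged, not clamped", {
  # Var = 0 with C > 0 puts the bracketed base above 1 -> non-invertible
  expect_true(is.na(erpool:::invert_ne(0, 0.5, 150, 0.03)))
  # variance above p0(1-p0) -> negative base -> non-invertible
  expect_true(is.na(erpool:::invert_ne(0.3, 0.5, 150, 0.03)))
  d <- regime_design()
  est <- estimate_ne_per_snp(rep(0, 12), d, t = 150, C = 0.03)
  expect_true(all(is.na(est)))  # p0 at the boundary is excluded
})

test_that("identical regime tables give identical Ne estimates", {
  set.seed(31)
  f6 <- matrix(runif(200 * 6, 0.35, 0.65), 200, 6)
  cm <- counts_from_freqs(cbind(f6, f6), depth = 40)
  est <- estimate_ne(cm, regime_design(t = 100))
  expect_equal(est$snps$ne_sel, est$snps$ne_ctl)
})

test_that("mean-frequency and coverage filters select the estimation SNPs", {
  f <- matrix(0.5, 4, 12)
  f[2, ] <- 0.35  # mean outside [0.4, 0.6]
  cm <- counts_from_freqs(f, depth = 40)
  cm$ref[3, 4] <- 35L; cm$alt[3, 4] <- 0L  # fine (coverage 35)
  cm$ref[4, 2] <- 5L; cm$alt[4, 2] <- 0L   # coverage 5 < 10 -> excluded
  expect_warning(est <- estimate_ne(cm, regime_design(t = 100)), "fewer than 20")
  expect_equal(nrow(est$snps), 2L)
  expect_false(any(est$snps$pos == 2000L))
  expect_false(any(est$snps$pos == 4000L))
})

test_that("pure drift simulations recover the true Ne within 25 percent", {
  ne_true <- 100
  meds <- replicate(3, {
    sim <- simulate_experiment(sim_config(
      n_loci = 1200, ne_selected = ne_true, ne_control = ne_true, t = 100,
      p0 = function(n) runif(n, 0.45, 0.55), depth_mean = 40,
      seed = sample.int(1e6, 1)))
    est <- estimate_ne(sim$counts, sim$design)
    c(est$summary$ne_sel[1], est$summary$ne_ctl[1], est$summary$n_snps[1])
  })
  expect_true(all(meds[3, ] >= 500))
  expect_true(all(abs(meds[1:2, ] - ne_true) / ne_true < 0.25))
})

test_that("estimated median Ne is monotone in the simulated Ne", {
  meds <- sapply(c(50, 100, 200, 400), function(ne) {
    sim <- simulate_experiment(sim_config(
      n_loci = 800, ne_selected = ne, ne_control = ne, t = 80,
      p0 = function(n) runif(n, 0.45, 0.55), depth_mean = 40, seed = 1000 + ne))
    est <- estimate_ne(sim$counts, sim$design)
    est$summary$ne_sel[1]
  })
  expect_equal(order(meds), 1:4)
})

test_that("the regime randomization test is calibrated and deterministic", {
  sim <- simulate_experiment(sim_config(
    n_loci = 600, ne_selected = 120, ne_control = 120, t = 100,
    p0 = function(n) runif(n, 0.45, 0.55), seed = 32))
  r1 <- ne_randomization_test(sim$counts, sim$design, n_perm = 50, seed = 33)
  r2 <- ne_randomization_test(sim$counts, sim$design, n_perm = 50, seed = 33)
  expect_identical(r1$p, r2$p)
  expect_gte(r1$p, 1 / 51)
  expect_gt(r1$p, 0.05)  # identical regimes: no significant difference
  small <- regime_design(pops = c("S1", "S2", "C1", "C2"),
                         regime = c("SEL", "SEL", "CTL", "CTL"))
  expect_error(ne_randomization_test(sim$counts, small, n_perm = 10),
               "at least 3")
})
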