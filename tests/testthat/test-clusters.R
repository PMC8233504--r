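test_that("residual correlations equal direct Pearson computation", {
  set.seed(51)
  f <- matrix(runif(5 * 12), 5, 12)
  sites <- data.frame(chrom = "2L", pos = 1000L * (1:5))
  d <- default_design()
  rw <- residual_correlations(f, d, sites, candidates = 1:5)
  res <- cbind(f[, 1:6] - rowMeans(f[, 1:6]), f[, 7:12] - rowMeans(f[, 7:12]))
  for (r in seq_len(nrow(rw$pairs))) {
    i <- rw$pairs$i[r]; j <- rw$pairs$j[r]
    expect_equal(rw$pairs$r_w[r], cor(res[i, ], res[j, ]), tolerance = 1e-12)
  }
  expect_equal(diag(rw$matrix_by_arm[["2L"]]), rep(1, 5))
  # orthogonal residuals give r_w = 0: diverging pair on a fresh matrix
  f2 <- matrix(0.5, 2, 12)
  f2[1, ] <- 0.5 + c(0.1, -0.1, 0.1, -0.1, 0, 0, 0.1, -0.1, 0.1, -0.1, 0, 0)
  f2[2, ] <- 0.5 + c(0, 0, 0, 0, 0.1, -0.1, 0, 0, 0, 0, 0.1, -0.1)
  rw2 <- residual_correlations(f2, d, sites[1:2, ], 1:2)
  expect_equal(rw2$pairs$r_w, 0, tolerance = 1e-12)
})

test_that("fixed SNPs get r_w 0 with a degeneracy flag", {
  f <- rbind(rep(1, 12), runif(12))
  rw <- residual_correlations(f, default_design(),
                              data.frame(chrom = "2L", pos = c(10L, 20L)), 1:2)
  expect_true(rw$degenerate[1])
  expect_equal(rw$pairs$r_w, 0)
})

test_that("distance alone cannot join distant candidates", {
  f <- matrix(rep(runif(12), 2), 2, 12, byrow = TRUE)  # perfectly correlated
  rw <- residual_correlations(f, default_design(),
                              data.frame(chrom = "2L", pos = c(1000L, 301000L)),
                              1:2)
  cl <- delineate_clusters(rw)
  expect_equal(max(cl$cluster), 2L)  # 300 kb apart -> separate clusters
  single <- delineate_clusters(
    residual_correlations(f[1, , drop = FALSE], default_design(),
                          data.frame(chrom = "2L", pos = 1000L), 1))
  expect_equal(single$cluster, 1L)
})

test_that("cluster delineation equals brute force on random layouts", {
  set.seed(52)
  d <- default_design()
  for (case in 1:50) {
    n <- sample(3:25, 1)
    pos <- sort(sample(2000000, n))
    # random correlation structure from a few latent factors
    latent <- matrix(rnorm(3 * 12), 3, 12)
    f <- 0.5 + 0.2 * latent[sample(3, n, replace = TRUE), ] +
      matrix(rnorm(n * 12, 0, 0.02), n, 12)
    f <- pmin(pmax(f, 0), 1)  # order matters: pmax/pmin keep f's dim
    rw <- residual_correlations(f, d, data.frame(chrom = "2L", pos = pos),
                                seq_len(n))
    got <- delineate_clusters(rw)
    want <- brute_force_clusters(rw$sites$pos, rw$matrix_by_arm[["2L"]])
    expect_equal(match(got$cluster, unique(got$cluster)), want)
  }
})

test_that("planted linkage blocks are recovered exactly", {
  bm <- block_layout(n_blocks = 5, loci_per_block = 8, between_bp = 500000L)
  sim <- simulate_experiment(sim_config(
    n_loci = nrow(bm), ne_selected = 150, ne_control = 150, t = 100,
    block_map = bm, p0 = function(n) runif(n, 0.3, 0.7),
    depth_mean = 60, seed = 53))
  rw <- residual_correlations(allele_freqs(sim$counts), sim$design,
                              sim$counts$sites, seq_len(nrow(bm)))
  cl <- delineate_clusters(rw)
  expect_equal(max(cl$cluster), 5L)
  expect_equal(cl$cluster, rep(1:5, each = 8))
})

test_that("pattern classes match an independent restatement on the multiset grid", {
  # the rules are symmetric in the six populations, so enumerating all
  # multisets of the 0.05-resolution grid covers the full grid
  grid <- seq(0, 1, by = 0.05)
  combos <- combn(length(grid) + 5, 6)  # combinations with repetition
  idx <- combos - 0:5                   # de-stagger to sorted indices
  fs <- matrix(grid[idx], ncol = nrow(combos), byrow = TRUE)
  got <- erpool:::classify_selected_matrix(fs)
  # independent restatement, scalar logic
  want <- apply(fs, 1, function(v) {
    hi <- sum(v >= 0.75); lost <- sum(v < 0.05)
    if (hi == 6 || (hi == 5 && lost == 1)) return("high_frequency")
    if (all(v >= 0.1 & v <= 0.9) && mean(v) >= 0.25 && mean(v) <= 0.75)
      return("mid_frequency")
    "other"
  })
  expect_identical(got, want)
})

test_that("classification orients by the selected allele first", {
  d <- default_design()
  f <- rbind(c(rep(1, 6), rep(0.3, 6)),          # high in SEL
             c(rep(0.5, 6), rep(0.05, 6)),       # mid in SEL
             c(rep(0.95, 5), 0.0, rep(0.2, 6)),  # lost-from-one rule
             c(rep(0.02, 6), rep(0.6, 6)))       # ref allele selected
  cls <- classify_patterns(f, d, candidates = 1:4)
  expect_equal(cls$class,
               c("high_frequency", "mid_frequency", "high_frequency",
                 "high_frequency"))
  expect_equal(cls$selected_allele, c("alt", "alt", "alt", "ref"))
  expect_equal(cls$mean_sel[4], 0.98)
})

test_that("variance comparison computes n-1 SDs and the representative test", {
  expect_equal(sd(c(0.4, 0.5, 0.6, 0.4, 0.5, 0.6)), 0.0894, tolerance = 1e-3)
  set.seed(54)
  n <- 40
  f <- matrix(runif(n * 12, 0.3, 0.7), n, 12)
  sites <- data.frame(chrom = "2L", pos = 1000L * seq_len(n))
  d <- default_design()
  rw <- residual_correlations(f, d, sites, seq_len(n))
  cl <- delineate_clusters(rw)
  vc <- variance_comparison(f, d, cl, sites)
  i <- match(paste(cl$chrom, cl$pos), paste(sites$chrom, sites$pos))
  mem <- which(cl$cluster == 1L)  # first cluster's members
  k <- mem[which.min(abs(rowMeans(f[i[mem], 1:6, drop = FALSE]) - 0.5))]
  expect_equal(vc$representatives$sd[1], sd(f[i[k], 1:6]))
  # identical regimes: symmetric output and p = 1
  f2 <- cbind(f[, 1:6], f[, 1:6])
  vc2 <- variance_comparison(f2, d, cl, sites)
  expect_equal(vc2$test$p, 1)
  expect_equal(vc2$test$median_sd_sel, vc2$test$median_sd_ctl)
})

test_that("balancing selection lowers Selected-regime representative SDs", {
  # planted balanced blocks in the Selected regime vs drift in Controls
  wins <- replicate(20, {
    bm <- block_layout(n_blocks = 12, loci_per_block = 4, between_bp = 400000L)
    sim <- simulate_experiment(sim_config(
      n_loci = nrow(bm), ne_selected = 150, ne_control = 150, t = 150,
      block_map = bm,
      selection = selection_spec(nrow(bm), mode = "balanced", s = 0.3, eq = 0.5),
      p0 = function(n) runif(n, 0.4, 0.6), seed = sample.int(1e6, 1)))
    f <- allele_freqs(sim$counts)
    rw <- residual_correlations(f, sim$design, sim$counts$sites,
                                seq_len(nrow(bm)))
    cl <- delineate_clusters(rw)
    vc <- variance_comparison(f, sim$design, cl, sim$counts$sites,
                              min_representatives = 2)
    if (is.null(vc$test)) NA else
      vc$test$median_sd_sel < vc$test$median_sd_ctl
  })
  expect_gt(mean(wins, na.rm = TRUE), 0.8)
})
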