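test_that("two-set overlaps match the product formula and hypergeometric tail", {
  out <- multiset_intersection(list(A = paste0("g", 1:100), B = paste0("g", 51:100)),
                               background = 1000)
  expect_equal(out$expected, 100 * 50 / 1000)
  expect_equal(out$observed, 50)
  expect_equal(out$p, phyper(50 - 1, 100, 900, 50, lower.tail = FALSE),
               tolerance = 1e-12)
  # identical sets: maximal overlap, minimal p
  same <- multiset_intersection(list(A = paste0("g", 1:10), B = paste0("g", 1:10)),
                                background = 50)
  expect_equal(same$observed, 10)
  expect_equal(same$p, 1 / choose(50, 10), tolerance = 1e-12)
})

test_that("two-set p equals exhaustive enumeration on small universes", {
  set.seed(61)
  for (N in c(8, 12, 15)) {
    nA <- sample(2:(N - 2), 1); nB <- sample(2:(N - 2), 1)
    # enumerate all placements of B against a fixed A (symmetry)
    bsets <- combn(N, nB)
    ov <- colSums(bsets <= nA)
    A <- paste0("g", 1:nA); B <- paste0("g", sample(N, nB))
    out <- multiset_intersection(list(A = A, B = B), paste0("g", 1:N))
    obs <- length(intersect(A, B))
    expect_equal(out$p, mean(ov >= obs), tolerance = 1e-12)
  }
})

test_that("three-set p equals bitmask enumeration for N = 12", {
  N <- 12; sizes <- c(5, 6, 4)
  genes <- paste0("g", 1:N)
  set.seed(62)
  sets <- lapply(sizes, function(s) sample(genes, s))
  names(sets) <- c("A", "B", "C")
  out <- multiset_intersection(sets, genes)
  row3 <- out[out$n_sets == 3, ]
  obs <- length(Reduce(intersect, sets))
  # enumerate placements of B and C against a fixed A (exchangeability)
  ia <- which(genes %in% sets$A)
  amask <- sum(bitwShiftL(1, ia - 1))
  masks <- function(k) {
    cc <- combn(N, k)
    apply(cc, 2, function(v) sum(bitwShiftL(1, v - 1)))
  }
  pc_table <- vapply(0:(2^N - 1), function(b)
    sum(bitwAnd(b, bitwShiftL(1, 0:(N - 1))) > 0), numeric(1))
  bm <- masks(sizes[2]); cm <- masks(sizes[3])
  tally <- 0; total <- 0
  for (b in bm) {
    ab <- bitwAnd(amask, b)
    ov <- pc_table[bitwAnd(ab, cm) + 1L]
    tally <- tally + sum(ov >= obs)
    total <- total + length(cm)
  }
  expect_equal(row3$p, tally / total, tolerance = 1e-12)
  expect_equal(row3$expected, N * prod(sizes / N))
})

test_that("sets outside the background are rejected", {
  expect_error(multiset_intersection(list(A = "x", B = "y"), c("y", "z")),
               "A")
})

test_that("SNP-permutation enrichment is calibrated under random candidates", {
  set.seed(63)
  snps <- paste0("s", 1:400)
  # genes of unequal length: long genes carry more SNPs
  gene_of <- rep(paste0("g", 1:40), times = rep(c(4, 16), 20))
  s2g <- data.frame(snp = snps, gene = gene_of)
  g2c <- data.frame(gene = paste0("g", 1:40),
                    category = rep(paste0("cat", 1:8), each = 5))
  cands <- sample(snps, 40)
  out <- snp_permutation_enrichment(cands, snps, s2g, g2c, n_perm = 400,
                                    seed = 64)
  expect_true(all(out$p >= 1 / 401 & out$p <= 1, na.rm = TRUE))
  # candidates concentrated in few genes of an all-gene category: random
  # draws hit at least as many genes, so the category is never enriched
  g2c_all <- rbind(g2c, data.frame(gene = paste0("g", 1:40), category = "all"))
  long_genes <- names(sort(table(gene_of), decreasing = TRUE))[1:3]
  conc <- snps[gene_of %in% long_genes][1:40]
  out2 <- snp_permutation_enrichment(conc, snps, s2g, g2c_all, n_perm = 200,
                                     seed = 65)
  expect_gt(out2$p[out2$category == "all"], 0.9)
  # determinism
  out3 <- snp_permutation_enrichment(cands, snps, s2g, g2c, n_perm = 400,
                                     seed = 64)
  expect_identical(out, out3)
})

test_that("enrichment expected counts track the analytic mean", {
  # disjoint genes with equal SNP counts: expected hit genes per category =
  # n_genes_cat * (1 - prod_i (1 - remaining draws / remaining snps)) ~
  # n_cat * P(gene hit); with 2 SNPs per gene and 30 draws from 100 SNPs
  set.seed(66)
  snps <- paste0("s", 1:100)
  s2g <- data.frame(snp = snps, gene = rep(paste0("g", 1:50), each = 2))
  g2c <- data.frame(gene = paste0("g", 1:50),
                    category = rep(c("c1", "c2"), each = 25))
  out <- snp_permutation_enrichment(sample(snps, 30), snps, s2g, g2c,
                                    n_perm = 2000, seed = 67)
  p_hit <- 1 - choose(98, 30) / choose(100, 30)
  expect_equal(out$expected, rep(25 * p_hit, 2), tolerance = 0.02)
})

test_that("untestable categories are flagged", {
  s2g <- data.frame(snp = "s1", gene = "g1")
  g2c <- data.frame(gene = c("g1", "g2"), category = c("c1", "c2"))
  out <- snp_permutation_enrichment("s1", c("s1", "s2"), s2g, g2c,
                                    n_perm = 10, seed = 1)
  expect_false(out$testable[out$category == "c2"])
  expect_true(is.na(out$p[out$category == "c2"]))
})

test_that("matched network randomization detects a planted clique", {
  set.seed(68)
  genes <- paste0("g", 1:200)
  attrs <- data.frame(gene = genes,
                      class = rep(c("tf", "enzyme"), 100),
                      length = stats::rexp(200, 1 / 2000))
  cands <- genes[1:10]
  clique <- t(combn(cands, 2))
  sparse <- cbind(sample(genes[11:200], 30), sample(genes[11:200], 30))
  edges <- data.frame(geneA = c(clique[, 1], sparse[, 1]),
                      geneB = c(clique[, 2], sparse[, 2]))
  out <- matched_network_randomization(cands, attrs, edges, n_draws = 200,
                                       seed = 69)
  expect_equal(out$observed, 45 + sum(sparse[, 1] %in% cands &
                                        sparse[, 2] %in% cands))
  expect_lte(out$p, 0.01)
  # empty edge list: observed 0, p = 1
  out0 <- matched_network_randomization(cands, attrs,
                                        data.frame(geneA = character(),
                                                   geneB = character()),
                                        n_draws = 50, seed = 70)
  expect_equal(out0$observed, 0)
  expect_equal(out0$p, 1)
})

test_that("network test is invariant under consistent gene relabelling", {
  set.seed(71)
  genes <- paste0("g", 1:60)
  attrs <- data.frame(gene = genes, class = "x",
                      length = rep(1000, 60))  # single stratum
  edges <- data.frame(geneA = sample(genes, 40, replace = TRUE),
                      geneB = sample(genes, 40, replace = TRUE))
  cands <- genes[1:8]
  relabel <- setNames(paste0("h", 1:60), genes)
  out1 <- matched_network_randomization(cands, attrs, edges, n_draws = 100,
                                        seed = 72)
  attrs2 <- transform(attrs, gene = unname(relabel[gene]))
  edges2 <- data.frame(geneA = unname(relabel[edges$geneA]),
                       geneB = unname(relabel[edges$geneB]))
  out2 <- matched_network_randomization(unname(relabel[cands]), attrs2, edges2,
                                        n_draws = 100, seed = 72)
  expect_equal(out1$observed, out2$observed)
  expect_equal(out1$p, out2$p)
})
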