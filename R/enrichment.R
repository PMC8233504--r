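#' Multi-set intersection test against a common background
#'
#' For gene sets drawn from a common background universe of size `N`, the
#' expected size of the intersection of sets `A_1..A_k` is
#' `N * prod(|A_i| / N)`, and the exact distribution of the intersection
#' size under independent uniform draws is obtained by chaining
#' hypergeometric convolutions: conditioned on the intersection of the
#' first j sets having size i, that intersection is a uniform subset, so
#' its overlap with the next set is hypergeometric. For two sets this
#' reduces to the usual hypergeometric (Fisher) upper-tail test.
#'
#' @param sets named list of character vectors (gene sets).
#' @param background character vector (the gene universe) or a single
#'   integer giving its size `N`; every set must be contained in the
#'   background.
#' @return data.frame with one row per combination of >= 2 sets:
#'   intersection label, observed overlap, expected overlap and upper-tail
#'   p-value `P(X >= observed)`.
#' @export
multiset_intersection <- function(sets, background) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  if (is.character(background)) {
    N <- length(unique(background))
    offenders <- names(sets)[!vapply(sets, function(s)
      all(s %in% background), logical(1))]
    if (length(offenders))
      stop("sets not contained in background: ",
           paste(offenders, collapse = ", "))
  } else {
    N <- as.integer(background)
  }
  sizes <- vapply(sets, function(s) length(unique(s)), integer(1))
  if (N < max(sizes)) stop("background smaller than the largest set")
  k <- length(sets)
  combos <- unlist(lapply(2:k, function(r)
    utils::combn(k, r, simplify = FALSE)), recursive = FALSE)
  do.call(rbind, lapply(combos, function(cc) {
    obs <- length(Reduce(intersect, sets[cc]))
    expd <- N * prod(sizes[cc] / N)
    pm <- intersect_distribution(sizes[cc], N)
    p <- sum(pm[(obs + 1):length(pm)])
    data.frame(intersection = paste(names(sets)[cc], collapse = " & "),
               n_sets = length(cc), observed = obs, expected = expd,
               p = min(1, p), stringsAsFactors = FALSE)
  }))
}

# exact pmf of |A_1 n ... n A_k| over 0..min(sizes): hypergeometric chain
intersect_distribution <- function(sizes, N) {
  f <- numeric(sizes[1] + 1)
  f[sizes[1] + 1] <- 1
  for (s in sizes[-1]) {
    sup_old <- which(f > 0) - 1L
    newmax <- min(max(sup_old), s)
    g <- numeric(newmax + 1)
    for (i in sup_old) {
      x <- 0:min(i, s)
      g[x + 1] <- g[x + 1] + f[i + 1] * dhyper(x, i, N - i, s)
    }
    f <- g
  }
  f
}

#' SNP-permutation category enrichment test
#'
#' Tests whether candidate SNPs are enriched in functional categories
#' while controlling for gene length: long genes harbour more SNPs, so a
#' null that permutes *SNPs* (not genes) reproduces the length bias.
#' Each permutation draws `|candidates|` SNPs without replacement from the
#' full SNP set, maps them to genes and then to categories, counting each
#' gene at most once per draw ("gene mode").
#'
#' @param candidate_snps,all_snps character vectors of SNP identifiers
#'   (candidates must be a subset of all SNPs).
#' @param snp2gene data.frame (snp, gene); one SNP may map to several
#'   genes.
#' @param gene2cat data.frame (gene, category).
#' @param n_perm number of permutations (default 1e5; reduce for
#'   exploratory runs).
#' @param seed optional seed.
#' @param mode `"gene"` (default) or `"snp"` (genes counted once per hit
#'   SNP).
#' @return data.frame per category: observed gene count, expected (null
#'   mean), empirical `p = (1 + #{null >= obs}) / (n_perm + 1)`,
#'   Benjamini-Hochberg FDR, and a `testable` flag (categories with no
#'   annotated SNP-bearing genes are untestable).
#' @export
snp_permutation_enrichment <- function(candidate_snps, all_snps, snp2gene,
                                       gene2cat, n_perm = 1e5, seed = NULL,
                                       mode = c("gene", "snp")) {
  mode <- match.arg(mode)
  if (!all(candidate_snps %in% all_snps))
    stop("candidate SNPs must be a subset of all SNPs")
  cats <- sort(unique(gene2cat$category))
  genes <- sort(unique(c(snp2gene$gene, gene2cat$gene)))
  gene_id <- seq_along(genes)
  names(gene_id) <- genes
  snp_genes <- split(gene_id[snp2gene$gene], snp2gene$snp)  # snp -> gene ids
  cat_genes <- split(gene_id[gene2cat$gene], gene2cat$category)
  snp_bearing <- unique(unlist(snp_genes, use.names = FALSE))
  testable <- vapply(cat_genes, function(g) any(g %in% snp_bearing), logical(1))

  count_cats <- function(snps) {
    hit <- unlist(snp_genes[snps], use.names = FALSE)
    if (mode == "gene") {
      hit <- unique(hit)
      vapply(cat_genes, function(g) sum(g %in% hit), numeric(1))
    } else {
      tb <- tabulate(hit, nbins = length(genes))
      vapply(cat_genes, function(g) sum(tb[g]), numeric(1))
    }
  }
  observed <- count_cats(intersect(candidate_snps, names(snp_genes)))
  n_draw <- length(candidate_snps)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b)
      count_cats(intersect(sample(all_snps, n_draw), names(snp_genes))),
      numeric(length(cats)))
  })
  if (is.null(dim(null))) null <- matrix(null, nrow = length(cats))
  expected <- rowMeans(null)
  p <- (1 + rowSums(null >= observed)) / (n_perm + 1)
  p[!testable] <- NA_real_
  out <- data.frame(category = names(cat_genes), observed = observed,
                    expected = expected, p = p,
                    fdr = p.adjust(p, method = "BH"),
                    testable = testable, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$p), ]
}

#' Matched-gene-set network randomization test
#'
#' Tests whether candidate genes interact with each other more than
#' expected: `n_draws` times draws a noncandidate gene set from the
#' background, matched to the candidates in functional class and gene
#' length (deciles of the background length distribution), and counts
#' interaction edges with both endpoints inside the drawn set. The
#' empirical p-value is `(1 + #{null >= observed}) / (n_draws + 1)`.
#'
#' @param candidate_genes character vector.
#' @param gene_attrs data.frame (gene, class, length) covering the
#'   background universe including the candidates.
#' @param edges data.frame (geneA, geneB) of known interactions.
#' @param n_draws number of matched random draws (default 1000).
#' @param seed optional seed.
#' @param n_length_bins number of background length-quantile bins
#'   (default 10, i.e. deciles).
#' @return list: `observed` edge count, `null` counts, `null_mean`, `p`,
#'   and the `bins` used (for output metadata).
#' @export
matched_network_randomization <- function(candidate_genes, gene_attrs, edges,
                                          n_draws = 1000, seed = NULL,
                                          n_length_bins = 10) {
  stopifnot(all(candidate_genes %in% gene_attrs$gene))
  brks <- unique(quantile(gene_attrs$length,
                          probs = seq(0, 1, length.out = n_length_bins + 1)))
  bin <- cut(gene_attrs$length, breaks = brks, include.lowest = TRUE,
             labels = FALSE)
  stratum <- paste(gene_attrs$class, bin)
  names(stratum) <- gene_attrs$gene
  is_cand <- gene_attrs$gene %in% candidate_genes

  count_edges <- function(set) {
    sum(edges$geneA %in% set & edges$geneB %in% set)
  }
  observed <- count_edges(candidate_genes)
  need <- table(stratum[candidate_genes])
  # background pool per stratum: noncandidate genes
  pool <- split(gene_attrs$gene[!is_cand], stratum[gene_attrs$gene[!is_cand]])
  # strata too small: relax to the nearest length bin within the class
  relaxed <- FALSE
  null <- with_seed(seed, vapply(seq_len(n_draws), function(b) {
    drawn <- character(0)
    for (stname in names(need)) {
      k <- need[[stname]]
      avail <- setdiff(pool[[stname]], drawn)
      if (length(avail) < k) {
        if (!relaxed) {
          relaxed <<- TRUE
          warning("stratum '", stname,
                  "' has fewer background genes than candidates; ",
                  "relaxing to neighbouring length bins")
        }
        parts <- strsplit(stname, " (?=[0-9]+$)", perl = TRUE)[[1]]
        cls <- parts[1]; b0 <- as.integer(parts[2])
        for (off in seq_len(n_length_bins)) {
          for (bb in unique(c(b0 - off, b0 + off))) {
            extra <- setdiff(pool[[paste(cls, bb)]], c(drawn, avail))
            avail <- c(avail, extra)
            if (length(avail) >= k) break
          }
          if (length(avail) >= k) break
        }
        if (length(avail) < k)
          stop("cannot match stratum '", stname, "': background exhausted")
      }
      drawn <- c(drawn, sample(avail, k))
    }
    count_edges(drawn)
  }, numeric(1)))
  list(observed = observed, null = null, null_mean = mean(null),
       p = (1 + sum(null >= observed)) / (n_draws + 1),
       bins = brks)
}
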