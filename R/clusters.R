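#' Within-regime residual correlations between candidate SNPs
#'
#' Expresses each population's allele frequency as a deviation (residual)
#' from its regime mean, removing the shared response to selection, then
#' computes the Pearson correlation `r_w` of the residual vectors across
#' all populations for every pair of candidate SNPs on the same chromosome
#' arm. High `r_w` between neighbours indicates joint evolution through
#' linkage disequilibrium and drift.
#'
#' @param freqs allele-frequency matrix, sites x populations.
#' @param design a [regime_design()] aligned with the columns.
#' @param sites data.frame with chrom, pos aligned with the rows.
#' @param candidates logical or integer index of candidate SNPs.
#' @return list with `pairs` (data.frame: i, j row indices into the
#'   candidate table, chrom, r_w) and `matrix_by_arm` (named list of
#'   per-arm correlation matrices), plus the candidate `sites` table.
#'   SNPs with zero residual variance get `r_w = 0` and are flagged.
#' @export
residual_correlations <- function(freqs, design, sites, candidates) {
  stopifnot(ncol(freqs) == nrow(design), nrow(freqs) == nrow(sites))
  idx <- if (is.logical(candidates)) which(candidates) else as.integer(candidates)
  sel <- design$regime == "SEL"
  res <- freqs[idx, , drop = FALSE]
  res[, sel] <- res[, sel, drop = FALSE] - rowMeans(res[, sel, drop = FALSE])
  res[, !sel] <- res[, !sel, drop = FALSE] - rowMeans(res[, !sel, drop = FALSE])
  cs <- sites[idx, c("chrom", "pos"), drop = FALSE]
  ord <- order(cs$chrom, cs$pos)
  cs <- cs[ord, , drop = FALSE]; res <- res[ord, , drop = FALSE]
  rownames(cs) <- NULL
  degenerate <- apply(res, 1L, sd) == 0
  mats <- list(); pairs <- list()
  for (arm in unique(cs$chrom)) {
    i <- which(cs$chrom == arm)
    if (length(i) < 1) next
    m <- matrix(0, length(i), length(i))
    ok <- !degenerate[i]
    if (sum(ok) >= 2) {
      m[ok, ok] <- suppressWarnings(cor(t(res[i[ok], , drop = FALSE])))
    }
    diag(m) <- 1
    m[is.na(m)] <- 0
    mats[[arm]] <- m
    if (length(i) >= 2) {
      ut <- which(upper.tri(m), arr.ind = TRUE)
      pairs[[arm]] <- data.frame(i = i[ut[, 1]], j = i[ut[, 2]], chrom = arm,
                                 r_w = m[ut], stringsAsFactors = FALSE)
    }
  }
  list(sites = cs,
       pairs = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(i = integer(), j = integer(), chrom = character(),
                    r_w = numeric()),
       matrix_by_arm = mats,
       degenerate = degenerate)
}

#' Delineate independently evolving candidate-SNP clusters
#'
#' Scans the position-ordered candidate SNPs of each chromosome arm and
#' joins two neighbouring candidates into the same cluster when (1) the
#' distance between them is below `gap` and (2) some candidate within
#' `gap` left of their midpoint (interval `(mid - gap, mid]`) is
#' correlated at `r_w > r_threshold` with some candidate within `gap`
#' right of the midpoint (interval `(mid, mid + gap)`). Clusters are the
#' transitive closure of these joins; singletons are allowed.
#'
#' @param rw result of [residual_correlations()].
#' @param gap maximum joining distance in bp (default 200 kb).
#' @param r_threshold residual-correlation threshold (default 0.8).
#' @return data.frame of class `cluster_set`: per candidate SNP chrom,
#'   pos, cluster id; attribute `clusters` summarises each cluster (id,
#'   chrom, start, end, span, n_snps).
#' @export
delineate_clusters <- function(rw, gap = 200000, r_threshold = 0.8) {
  cs <- rw$sites
  n <- nrow(cs)
  cluster <- integer(n)
  nxt <- 0L
  for (arm in unique(cs$chrom)) {
    i <- which(cs$chrom == arm)
    m <- rw$matrix_by_arm[[arm]]
    pos <- cs$pos[i]
    nxt <- nxt + 1L
    cluster[i[1]] <- nxt
    if (length(i) > 1) {
      for (k in 2:length(i)) {
        join <- FALSE
        if (pos[k] - pos[k - 1] < gap) {
          mid <- (pos[k] + pos[k - 1]) / 2
          left <- which(pos > mid - gap & pos <= mid)
          right <- which(pos > mid & pos < mid + gap)
          if (length(left) && length(right))
            join <- any(m[left, right, drop = FALSE] > r_threshold)
        }
        if (!join) nxt <- nxt + 1L
        cluster[i[k]] <- nxt
      }
    }
  }
  out <- data.frame(cs, cluster = cluster, stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(out, out$cluster), function(d)
    data.frame(cluster = d$cluster[1], chrom = d$chrom[1],
               start = min(d$pos), end = max(d$pos),
               span = max(d$pos) - min(d$pos), n_snps = nrow(d),
               stringsAsFactors = FALSE)))
  summ <- summ[order(summ$cluster), , drop = FALSE]
  rownames(summ) <- NULL
  attr(out, "clusters") <- summ
  class(out) <- c("cluster_set", "data.frame")
  out
}

#' Classify candidate allele-frequency patterns
#'
#' Orients each candidate by its "selected" allele — the allele with the
#' higher mean frequency in the Selected than the Control populations —
#' then classifies the Selected-population frequencies of that allele:
#' `high_frequency` when >= 0.75 in all Selected populations, or >= 0.75
#' in all but one and lost (< `lost_threshold`) from that one (directional
#' selection with drift loss); `mid_frequency` when every Selected
#' population is within `[0.1, 0.9]` and the Selected mean lies in
#' `[0.25, 0.75]` (the signature expected under balancing selection);
#' `other` otherwise. `high_frequency` takes precedence when both match.
#'
#' @param freqs allele-frequency matrix (alternate allele), sites x
#'   populations.
#' @param design a [regime_design()].
#' @param candidates logical or integer index of candidate rows.
#' @param high_threshold,lost_threshold,mid_range,mid_mean_range rule
#'   constants; `lost_threshold` (default 0.05 of read frequency)
#'   operationalises "lost from the sixth population" while tolerating
#'   sequencing error.
#' @return data.frame: site row index, selected allele orientation
#'   (`"alt"` or `"ref"`), selected-allele mean per regime, class.
#' @export
classify_patterns <- function(freqs, design, candidates,
                              high_threshold = 0.75, lost_threshold = 0.05,
                              mid_range = c(0.1, 0.9),
                              mid_mean_range = c(0.25, 0.75)) {
  idx <- if (is.logical(candidates)) which(candidates) else as.integer(candidates)
  sel <- design$regime == "SEL"
  f <- freqs[idx, , drop = FALSE]
  mean_sel <- rowMeans(f[, sel, drop = FALSE])
  mean_ctl <- rowMeans(f[, !sel, drop = FALSE])
  orient_alt <- mean_sel >= mean_ctl
  fs <- f[, sel, drop = FALSE]
  fs[!orient_alt, ] <- 1 - fs[!orient_alt, , drop = FALSE]
  cls <- classify_selected_matrix(fs, high_threshold, lost_threshold,
                                  mid_range, mid_mean_range)
  data.frame(site = idx,
             selected_allele = ifelse(orient_alt, "alt", "ref"),
             mean_sel = ifelse(orient_alt, mean_sel, 1 - mean_sel),
             mean_ctl = ifelse(orient_alt, mean_ctl, 1 - mean_ctl),
             class = cls, stringsAsFactors = FALSE)
}

# classification of a matrix of selected-allele frequencies in the
# Selected populations (rows = SNPs); shared with the pattern tests
classify_selected_matrix <- function(fs, high_threshold = 0.75,
                                     lost_threshold = 0.05,
                                     mid_range = c(0.1, 0.9),
                                     mid_mean_range = c(0.25, 0.75)) {
  n_pop <- ncol(fs)
  n_high <- rowSums(fs >= high_threshold)
  n_lost <- rowSums(fs < lost_threshold)
  high <- n_high == n_pop | (n_high == n_pop - 1L & n_lost == 1L)
  within <- rowSums(fs >= mid_range[1] & fs <= mid_range[2]) == n_pop
  msel <- rowMeans(fs)
  mid <- within & msel >= mid_mean_range[1] & msel <= mid_mean_range[2]
  ifelse(high, "high_frequency", ifelse(mid, "mid_frequency", "other"))
}

#' Among-population variance comparison between regimes
#'
#' For each candidate SNP computes the standard deviation (denominator
#' n - 1) of population allele frequencies within each regime and bins it
#' by the respective regime mean. To account for linkage among candidates,
#' picks one representative SNP per cluster — the SNP whose mean frequency
#' in the focal regime is closest to 0.5 — retains representatives with
#' mean in `[0.4, 0.6]`, and compares the two sets of representative SDs
#' between regimes with a two-sided Mann-Whitney U test. Balancing
#' selection in the Selected regime predicts lower Selected SDs. The same
#' computation on a matched random draw of noncandidate SNPs (clustered by
#' the same rule) serves as a control.
#'
#' @param freqs allele-frequency matrix, sites x populations.
#' @param design a [regime_design()].
#' @param clusters a [delineate_clusters()] result (its rows identify the
#'   candidate SNPs by chrom/pos).
#' @param sites data.frame chrom/pos aligned with `freqs` rows.
#' @param bin_width width of the mean-frequency bins (default 0.1).
#' @param rep_range retained representative mean range (default 0.4-0.6).
#' @param min_representatives minimum representatives per regime for the
#'   test (default 3; otherwise the test is skipped with a warning).
#' @return list: `binned` (per regime x bin: median and mean SD, n),
#'   `representatives` (per cluster x regime: SNP, mean, sd, retained),
#'   `test` (Mann-Whitney U and p, medians per regime), or `test = NULL`
#'   when skipped.
#' @export
variance_comparison <- function(freqs, design, clusters, sites,
                                bin_width = 0.1, rep_range = c(0.4, 0.6),
                                min_representatives = 3) {
  sel <- design$regime == "SEL"
  key <- paste(sites$chrom, sites$pos)
  idx <- match(paste(clusters$chrom, clusters$pos), key)
  if (anyNA(idx)) stop("cluster SNPs missing from the frequency table")
  f <- freqs[idx, , drop = FALSE]
  stats_regime <- function(cols) {
    m <- rowMeans(f[, cols, drop = FALSE])
    s <- apply(f[, cols, drop = FALSE], 1L, sd)
    list(mean = m, sd = s)
  }
  st <- list(SEL = stats_regime(which(sel)), CTL = stats_regime(which(!sel)))
  binned <- do.call(rbind, lapply(names(st), function(rg) {
    b <- pmin(floor(st[[rg]]$mean / bin_width), 1 / bin_width - 1)
    do.call(rbind, lapply(sort(unique(b)), function(bb) {
      i <- b == bb
      data.frame(regime = rg, bin_lo = bb * bin_width,
                 bin_hi = (bb + 1) * bin_width,
                 median_sd = median(st[[rg]]$sd[i]),
                 mean_sd = mean(st[[rg]]$sd[i]), n = sum(i),
                 stringsAsFactors = FALSE)
    }))
  }))
  reps <- do.call(rbind, lapply(names(st), function(rg) {
    do.call(rbind, lapply(split(seq_len(nrow(clusters)), clusters$cluster),
                          function(i) {
      k <- i[which.min(abs(st[[rg]]$mean[i] - 0.5))]
      data.frame(regime = rg, cluster = clusters$cluster[k],
                 chrom = clusters$chrom[k], pos = clusters$pos[k],
                 mean = st[[rg]]$mean[k], sd = st[[rg]]$sd[k],
                 retained = st[[rg]]$mean[k] >= rep_range[1] &
                   st[[rg]]$mean[k] <= rep_range[2],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(reps) <- NULL
  sd_sel <- reps$sd[reps$regime == "SEL" & reps$retained]
  sd_ctl <- reps$sd[reps$regime == "CTL" & reps$retained]
  test <- NULL
  if (length(sd_sel) >= min_representatives &&
      length(sd_ctl) >= min_representatives) {
    mw <- mann_whitney(sd_sel, sd_ctl)
    test <- list(U = mw$U, p = mw$p,
                 median_sd_sel = median(sd_sel), median_sd_ctl = median(sd_ctl),
                 n_sel = length(sd_sel), n_ctl = length(sd_ctl))
  } else {
    warning("fewer than ", min_representatives,
            " representative SNPs in a regime; Mann-Whitney test skipped")
  }
  list(binned = binned, representatives = reps, test = test)
}
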