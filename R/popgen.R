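#' Per-site diversity contributions at fixed coverage
#'
#' Treats the `m` subsampled reads at a site as sampled alleles. The
#' per-site heterozygosity is `pi = 2 k (m - k) / (m (m - 1))` for
#' alternate count `k`, and the Watterson contribution is `1 / a1(m)` for a
#' segregating site (0 otherwise), with `a1(m) = sum_{i=1}^{m-1} 1/i`.
#'
#' @param ref_count,alt_count numeric vectors of reference/alternate read
#'   counts; `ref + alt` must be >= 2 (sites with lower coverage return
#'   `NA` and are skipped by callers, with a log entry).
#' @return data.frame with columns `pi` and `theta`.
#' @export
site_diversity <- function(ref_count, alt_count) {
  m <- ref_count + alt_count
  pi <- ifelse(m >= 2, 2 * alt_count * ref_count / (m * (m - 1)), NA_real_)
  a1 <- vapply(m, function(mm) if (mm >= 2) sum(1 / seq_len(mm - 1)) else NA_real_,
               numeric(1))
  theta <- ifelse(m >= 2 & alt_count > 0 & ref_count > 0, 1 / a1, 0)
  theta[m < 2] <- NA_real_
  data.frame(pi = pi, theta = theta)
}

#' Tajima (1989) normalizing constants for sample size m
#' @param m allele sample size (here: the homogenized read coverage), >= 2.
#' @return list with a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(m) {
  stopifnot(m >= 2)
  a1 <- sum(1 / seq_len(m - 1))
  a2 <- sum(1 / seq_len(m - 1)^2)
  b1 <- (m + 1) / (3 * (m - 1))
  b2 <- 2 * (m^2 + m + 3) / (9 * m * (m - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (m + 2) / (a1 * m) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D from window sums at fixed coverage
#'
#' `D = (pi - theta_W) / sqrt(e1 S + e2 S (S - 1))` where `pi` is the sum
#' of per-site heterozygosities over the window, `S` the number of
#' segregating sites and `theta_W = S / a1(m)`. Undefined (NA) with fewer
#' than 4 segregating sites.
#'
#' @param pi_sum window sum of per-site pi.
#' @param n_seg number of segregating sites in the window.
#' @param m allele sample size (homogenized coverage).
#' @return Tajima's D (NA when undefined).
#' @export
tajimas_d <- function(pi_sum, n_seg, m) {
  if (n_seg < 4) return(NA_real_)
  k <- tajima_constants(m)
  (pi_sum - n_seg / k$a1) / sqrt(k$e1 * n_seg + k$e2 * n_seg * (n_seg - 1))
}

# per-population window statistics for one repetition of alt counts
window_stats_one <- function(alt, m, win_of_site, n_win) {
  seg <- alt > 0L & alt < m
  pi_site <- 2 * alt * (m - alt) / (m * (m - 1))
  pi_sum <- vapply(seq_len(n_win), function(w) sum(pi_site[win_of_site == w]),
                   numeric(1))
  n_seg <- vapply(seq_len(n_win), function(w) sum(seg[win_of_site == w]),
                  numeric(1))
  list(pi = pi_sum, n_seg = n_seg)
}

#' Windowed diversity scan: pi, Watterson's theta and Tajima's D
#'
#' Tiles each chromosome with non-overlapping physical windows anchored at
#' position 1 (the terminal window may be truncated) and computes, per
#' population and window, the sum of per-site pi, Watterson's theta
#' (`S / a1(m)`), the number of segregating sites and Tajima's D. Input
#' must be at homogenized coverage (see [subsample_coverage()] popgen
#' mode); when resampling repetitions are attached, every statistic is
#' computed per repetition and averaged.
#'
#' Also returns per-population genome-wide mean D with a one-sample t-test
#' of window D against 0, and a two-sided Mann-Whitney U test comparing the
#' per-population genome-wide means between regimes.
#'
#' @param counts a [count_matrix()] at uniform coverage (popgen-subsampled).
#' @param design a [regime_design()].
#' @param window,step window length and step in bp; only non-overlapping
#'   tiling (`step == window`) is supported.
#' @return list with `windows` (data.frame: chrom, start, end, pop, pi,
#'   theta_w, tajimas_d, n_snps), `genome` (per population: mean D over
#'   windows, one-sample t statistic and p-value), and `regime_test`
#'   (Mann-Whitney U comparing regimes' genome-wide mean D).
#' @export
window_scan <- function(counts, design, window = 200000L, step = window) {
  stopifnot(inherits(counts, "count_matrix"))
  if (step != window) stop("only non-overlapping windows (step == window) are supported")
  cov <- coverage(counts)
  m <- attr(counts, "target")
  if (is.null(m)) {
    u <- unique(as.vector(cov))
    if (length(u) != 1L)
      stop("counts must be at homogenized coverage; run subsample_coverage(mode = 'popgen')")
    m <- u
  }
  reps <- attr(counts, "alt_reps")
  n_rep <- if (is.null(reps)) 1L else dim(reps)[3]
  sites <- counts$sites
  out <- list()
  for (ch in unique(sites$chrom)) {
    i <- which(sites$chrom == ch)
    maxpos <- max(sites$pos[i])
    n_win <- ceiling(maxpos / window)
    win_of_site <- (sites$pos[i] - 1L) %/% window + 1L
    starts <- (seq_len(n_win) - 1L) * window + 1L
    ends <- pmin(starts + window - 1L, maxpos)  # terminal window: true span
    for (j in seq_along(counts$pops)) {
      acc_pi <- acc_seg <- acc_d <- matrix(0, n_win, n_rep)
      for (r in seq_len(n_rep)) {
        alt <- if (is.null(reps)) counts$alt[i, j] else reps[i, j, r]
        st <- window_stats_one(alt, m, win_of_site, n_win)
        acc_pi[, r] <- st$pi
        acc_seg[, r] <- st$n_seg
        acc_d[, r] <- vapply(seq_len(n_win), function(w)
          tajimas_d(st$pi[w], st$n_seg[w], m), numeric(1))
      }
      pi_mean <- rowMeans(acc_pi)
      seg_mean <- rowMeans(acc_seg)
      d_mean <- rowMeans(acc_d)  # NA if undefined in any repetition
      k <- tajima_constants(m)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = starts, end = ends, pop = counts$pops[j],
        pi = pi_mean, theta_w = seg_mean / k$a1, tajimas_d = d_mean,
        n_snps = seg_mean, stringsAsFactors = FALSE)
    }
  }
  windows <- do.call(rbind, out)
  genome <- do.call(rbind, lapply(counts$pops, function(p) {
    d <- windows$tajimas_d[windows$pop == p]
    d <- d[is.finite(d)]
    tt <- if (length(d) >= 2 && sd(d) > 0) t.test(d, mu = 0) else
      list(statistic = NA_real_, p.value = NA_real_)
    data.frame(pop = p, mean_d = if (length(d)) mean(d) else NA_real_,
               n_windows = length(d),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  di <- design_index(counts, design)
  md <- setNames(genome$mean_d, genome$pop)
  sel <- md[counts$pops[di$sel]]; ctl <- md[counts$pops[di$ctl]]
  regime_test <- if (all(is.finite(c(sel, ctl)))) {
    mann_whitney(sel, ctl)
  } else list(U = NA_real_, p = NA_real_)
  list(windows = windows, genome = genome, regime_test = regime_test)
}
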