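#' Heuristic SNP-calling filter criteria
#'
#' Thresholds of the heuristic pool-seq SNP caller applied by
#' [call_snps()]: minimum per-population coverage, a per-chromosome
#' per-population maximum-coverage percentile (to remove collapsed
#' repeats), a pooled minor-allele count and frequency floor, and the
#' maximum tolerated fraction of populations violating the coverage bounds.
#'
#' @param min_total_coverage minimum read depth per population (default 10).
#' @param max_coverage_percentile coverage percentile per chromosome and
#'   population above which a population fails (default 95; in (0, 100]).
#' @param min_allele_count minimum pooled (across passing populations)
#'   minor-allele read count (default 20).
#' @param min_allele_freq minimum pooled minor-allele frequency
#'   (default 0.01).
#' @param max_failing_fraction maximum fraction of populations allowed to
#'   violate the coverage bounds at a retained site (default 0.20).
#' @return list of class `filter_criteria`.
#' @export
filter_criteria <- function(min_total_coverage = 10,
                            max_coverage_percentile = 95,
                            min_allele_count = 20,
                            min_allele_freq = 0.01,
                            max_failing_fraction = 0.20) {
  stopifnot(min_total_coverage >= 0,
            max_coverage_percentile > 0, max_coverage_percentile <= 100,
            min_allele_count >= 0,
            min_allele_freq >= 0, min_allele_freq <= 1,
            max_failing_fraction >= 0, max_failing_fraction <= 1)
  structure(list(min_total_coverage = min_total_coverage,
                 max_coverage_percentile = max_coverage_percentile,
                 min_allele_count = min_allele_count,
                 min_allele_freq = min_allele_freq,
                 max_failing_fraction = max_failing_fraction),
            class = "filter_criteria")
}

#' Call biallelic SNPs from a sync count table
#'
#' Applies the heuristic site filters in sequence: (1) mask intervals;
#' (2) coverage: a population fails a site when its depth (A+T+C+G reads)
#' is below `min_total_coverage` or above its per-chromosome
#' `max_coverage_percentile` computed from the input table itself; sites
#' where the failing fraction exceeds `max_failing_fraction` are removed;
#' (3) allele resolution on counts pooled across the populations passing
#' the coverage bounds: the two most frequent non-N, non-deletion alleles
#' become ref/alt (keeping the sync reference base as ref when it is one of
#' the two); sites with a third allele at pooled frequency >=
#' `min_allele_freq`, or a count tie between second and third allele, are
#' dropped as ambiguous; (4) pooled minor-allele count >=
#' `min_allele_count` and pooled minor-allele frequency >=
#' `min_allele_freq` (both boundaries inclusive).
#'
#' @param sync a [read_sync()] object.
#' @param criteria a [filter_criteria()].
#' @param masks optional mask intervals from [read_bed_mask()] (e.g. indel
#'   neighbourhoods, transposable elements).
#' @return a [count_matrix()] of passing biallelic sites, with an attribute
#'   `filter_log`: named integer vector of sites removed per rule.
#' @export
call_snps <- function(sync, criteria = filter_criteria(), masks = NULL) {
  stopifnot(inherits(sync, "sync"), inherits(criteria, "filter_criteria"))
  n <- nrow(sync$sites); n_pops <- dim(sync$counts)[2]
  log <- c(masked = 0L, coverage = 0L, ambiguous = 0L,
           min_allele_count = 0L, min_allele_freq = 0L)
  if (n == 0L)
    return(structure(count_matrix(character(), integer(), character(),
                                  character(),
                                  matrix(integer(), 0, n_pops),
                                  matrix(integer(), 0, n_pops),
                                  pops = sync$pops),
                     filter_log = log))
  keep <- rep(TRUE, n)

  masked <- site_masked(sync$sites$chrom, sync$sites$pos, masks)
  log["masked"] <- sum(masked)
  keep[masked] <- FALSE

  cov <- sync$counts[, , "A", drop = FALSE] + sync$counts[, , "T", drop = FALSE] +
    sync$counts[, , "C", drop = FALSE] + sync$counts[, , "G", drop = FALSE]
  dim(cov) <- c(n, n_pops)
  maxcov <- matrix(Inf, n, n_pops)
  for (ch in unique(sync$sites$chrom)) {
    i <- sync$sites$chrom == ch
    for (j in seq_len(n_pops)) {
      maxcov[i, j] <- quantile(cov[i, j], criteria$max_coverage_percentile / 100,
                               names = FALSE)
    }
  }
  pop_pass <- cov >= criteria$min_total_coverage & cov <= maxcov
  frac_fail <- rowMeans(!pop_pass)
  cov_fail <- keep & frac_fail > criteria$max_failing_fraction
  log["coverage"] <- sum(cov_fail)
  keep[cov_fail] <- FALSE

  # pooled counts per base across populations passing the coverage bounds
  bases <- c("A", "T", "C", "G")
  pooled <- vapply(bases, function(b) {
    m <- sync$counts[, , b, drop = FALSE]; dim(m) <- c(n, n_pops)
    rowSums(m * pop_pass)
  }, numeric(n))
  if (n == 1L) pooled <- matrix(pooled, nrow = 1, dimnames = list(NULL, bases))
  tot <- rowSums(pooled)
  ord <- t(apply(pooled, 1L, order, decreasing = TRUE))
  srt <- t(apply(pooled, 1L, sort, decreasing = TRUE))
  major_cnt <- srt[, 1]; minor_cnt <- srt[, 2]; third_cnt <- srt[, 3]
  amb <- keep & third_cnt > 0 &
    (minor_cnt == third_cnt |
       third_cnt / pmax(tot, 1) >= criteria$min_allele_freq)
  log["ambiguous"] <- sum(amb)
  keep[amb] <- FALSE

  mac_fail <- keep & minor_cnt < criteria$min_allele_count
  log["min_allele_count"] <- sum(mac_fail)
  keep[mac_fail] <- FALSE

  maf_fail <- keep & (tot == 0 | minor_cnt / pmax(tot, 1) < criteria$min_allele_freq)
  log["min_allele_freq"] <- sum(maf_fail)
  keep[maf_fail] <- FALSE

  idx <- which(keep)
  major <- bases[ord[idx, 1]]; minor <- bases[ord[idx, 2]]
  refb <- sync$sites$ref[idx]
  ref_allele <- ifelse(refb == major | refb == minor, refb, major)
  alt_allele <- ifelse(ref_allele == major, minor, major)
  ref_counts <- matrix(0L, length(idx), n_pops)
  alt_counts <- matrix(0L, length(idx), n_pops)
  for (j in seq_len(n_pops)) {
    m <- sync$counts[idx, j, , drop = FALSE]; dim(m) <- c(length(idx), 6L)
    ref_counts[, j] <- m[cbind(seq_along(idx), match(ref_allele, c(bases, "N", "del")))]
    alt_counts[, j] <- m[cbind(seq_along(idx), match(alt_allele, c(bases, "N", "del")))]
  }
  out <- count_matrix(sync$sites$chrom[idx], sync$sites$pos[idx],
                      ref_allele, alt_allele, ref_counts, alt_counts,
                      pops = sync$pops)
  attr(out, "filter_log") <- log
  out
}

#' Write the per-rule removal log of [call_snps()] as TSV
#' @param counts a filtered [count_matrix()].
#' @param path output file.
#' @export
write_filter_log <- function(counts, path) {
  log <- attr(counts, "filter_log")
  if (is.null(log)) stop("no filter_log attribute")
  write.table(data.frame(rule = names(log), sites_removed = as.integer(log)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
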