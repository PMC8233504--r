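#' Subsample read counts to a fixed target coverage
#'
#' Homogenizes per-population coverage, which both the Fisher-exact scan
#' and the diversity statistics require.
#'
#' `mode = "scan"`: populations above the target are hypergeometrically
#' downsampled (without replacement) to exactly `target` reads; sites where
#' any population is below the target are dropped for this analysis.
#'
#' `mode = "popgen"`: coverage above the target is downsampled without
#' replacement as above; coverage below the target is resampled *with*
#' replacement up to the target, independently `n_rep` times, and
#' downstream statistics (see [window_scan()]) are averaged over the
#' repetitions.
#'
#' @param counts a [count_matrix()].
#' @param target target coverage (reads), >= 1.
#' @param mode `"scan"` or `"popgen"`.
#' @param seed optional seed; the subsample is deterministic given the seed.
#' @param n_rep number of resampling repetitions for below-target sites in
#'   popgen mode (default 30).
#' @return a [count_matrix()] at uniform coverage `target`, with attributes
#'   `target` and, in popgen mode, `alt_reps` (sites x populations x
#'   repetitions array of alternate counts; present only when some site is
#'   below target) and `n_rep`. In scan mode the attribute `dropped` holds
#'   the number of sites removed for sub-target coverage.
#' @export
subsample_coverage <- function(counts, target, mode = c("scan", "popgen"),
                               seed = NULL, n_rep = 30) {
  mode <- match.arg(mode)
  if (target < 1) stop("target coverage must be >= 1")
  cov <- coverage(counts)
  with_seed(seed, {
    if (mode == "scan") {
      ok <- rowSums(cov < target) == 0L
      x <- subset_sites(counts, ok)
      cov <- cov[ok, , drop = FALSE]
      alt <- x$alt
      over <- which(cov > target)
      if (length(over))
        alt[over] <- rhyper(length(over), m = x$alt[over],
                            n = x$ref[over], k = target)
      ref <- matrix(as.integer(target) - alt, nrow(alt), ncol(alt))
      out <- count_matrix(x$sites$chrom, x$sites$pos, x$sites$ref,
                          x$sites$alt, ref, alt, pops = x$pops)
      attr(out, "target") <- target
      attr(out, "dropped") <- sum(!ok)
      out
    } else {
      ok <- rowSums(cov == 0L) == 0L
      x <- subset_sites(counts, ok)
      cov <- cov[ok, , drop = FALSE]
      under <- which(cov < target)
      over <- which(cov > target)
      n_eff <- if (length(under)) n_rep else 1L
      base_alt <- x$alt
      if (length(over))
        base_alt[over] <- rhyper(length(over), m = x$alt[over],
                                 n = x$ref[over], k = target)
      reps <- array(rep(base_alt, n_eff),
                    dim = c(nrow(base_alt), ncol(base_alt), n_eff))
      if (length(under)) {
        p_under <- x$alt[under] / cov[under]
        for (r in seq_len(n_eff))
          reps[under + (r - 1L) * length(base_alt)] <-
            rbinom(length(under), target, p_under)
      }
      out <- count_matrix(x$sites$chrom, x$sites$pos, x$sites$ref,
                          x$sites$alt,
                          matrix(as.integer(target) - reps[, , 1L],
                                 nrow(base_alt), ncol(base_alt)),
                          matrix(reps[, , 1L], nrow(base_alt), ncol(base_alt)),
                          pops = x$pops)
      attr(out, "target") <- target
      attr(out, "n_rep") <- n_eff
      if (length(under)) attr(out, "alt_reps") <- reps
      out
    }
  })
}
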