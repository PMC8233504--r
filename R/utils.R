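# internal helpers shared across modules

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded package functions do
#' not disturb the global random stream. A `NULL` seed leaves the stream
#' untouched.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# spawn a reproducible child seed from a master seed (kept below 2^31)
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 48271 + 7919 * k) %% 2147483647
}

#' Gauss-Hermite nodes and weights (Golub-Welsch)
#'
#' Nodes/weights for \eqn{\int e^{-x^2} f(x) dx \approx \sum w_i f(x_i)},
#' computed from the symmetric tridiagonal Jacobi matrix of the Hermite
#' recurrence.
#' @noRd
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = sqrt(pi) * (e$vectors[1, idx])^2)
}

#' Vectorised two-sided Fisher exact p for 2x2 tables
#'
#' Convention matches `stats::fisher.test`: sum of hypergeometric point
#' probabilities not exceeding the observed one, with the same 1 + 1e-7
#' relative slack. Table is (a, b; c, d) with rows = groups, cols = ref/alt.
#' @noRd
fisher2x2_p <- function(a, b, c, d) {
  stopifnot(length(a) == length(b), length(a) == length(c), length(a) == length(d))
  m <- a + c  # ref margin
  n <- b + d  # alt margin
  k <- a + b  # group-1 margin
  out <- vapply(seq_along(a), function(i) {
    if (m[i] == 0 || n[i] == 0 || k[i] == 0 || k[i] == m[i] + n[i]) return(1)
    lo <- max(0L, k[i] - n[i]); hi <- min(k[i], m[i])
    dens <- dhyper(lo:hi, m[i], n[i], k[i])
    min(1, sum(dens[dens <= dhyper(a[i], m[i], n[i], k[i]) * (1 + 1e-7)]))
  }, numeric(1))
  out
}

is_count <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))

# two-sided Mann-Whitney U robust to the all-tied case (p = 1 rather than
# the 0/0 NaN of the normal approximation)
mann_whitney <- function(a, b) {
  if (stats::sd(c(a, b)) == 0) return(list(U = length(a) * length(b) / 2, p = 1))
  wt <- suppressWarnings(wilcox.test(a, b))
  list(U = unname(wt$statistic), p = wt$p.value)
}
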