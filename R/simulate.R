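#' Per-locus selection specification
#'
#' @param n_loci number of loci.
#' @param mode per-locus selection mode, recycled: `"neutral"`,
#'   `"directional"` (additive advantage of the alternate allele, fitnesses
#'   1, 1+s/2, 1+s, acting in the Selected regime only) or `"balanced"`
#'   (overdominance tuned to an equilibrium frequency, Selected regime only).
#' @param s selection coefficient (>= 0), recycled.
#' @param eq equilibrium frequency of the alternate allele for balanced
#'   loci, recycled.
#' @return data.frame with columns locus, mode, s, eq.
#' @export
selection_spec <- function(n_loci, mode = "neutral", s = 0, eq = 0.5) {
  mode <- rep_len(mode, n_loci); s <- rep_len(s, n_loci); eq <- rep_len(eq, n_loci)
  stopifnot(all(mode %in% c("neutral", "directional", "balanced")),
            all(s >= 0), all(eq > 0 & eq < 1))
  data.frame(locus = seq_len(n_loci), mode = mode, s = s, eq = eq,
             stringsAsFactors = FALSE)
}

#' Lay out loci in equally sized linkage blocks
#'
#' Convenience builder for the `block_map` argument of [sim_config()]:
#' `n_blocks` blocks of `loci_per_block` loci on one chromosome, loci spaced
#' `within_bp` apart inside a block and blocks separated by `between_bp`.
#'
#' @param n_blocks,loci_per_block block layout.
#' @param chrom chromosome label.
#' @param start position of the first locus (bp).
#' @param within_bp,between_bp spacing inside / between blocks (bp).
#' @return data.frame with columns locus, block, chrom, pos.
#' @export
block_layout <- function(n_blocks, loci_per_block, chrom = "2L", start = 10000L,
                         within_bp = 2000L, between_bp = 500000L) {
  n <- n_blocks * loci_per_block
  block <- rep(seq_len(n_blocks), each = loci_per_block)
  within <- (seq_len(n) - 1L) %% loci_per_block
  pos <- start + (block - 1L) * between_bp + within * within_bp
  data.frame(locus = seq_len(n), block = block, chrom = chrom,
             pos = as.integer(pos), stringsAsFactors = FALSE)
}

#' Truncated Beta founder allele-frequency spectrum
#'
#' Beta(shape, shape) conditioned on `[lo, hi]` (inverse-CDF sampling, no
#' boundary atoms). The U-shaped Beta(0.2, 0.2) default mimics the
#' frequency spectrum of a laboratory population derived from a wild sample.
#' @param shape Beta shape (both parameters equal).
#' @param lo,hi truncation bounds.
#' @return a function of `n` returning founder frequencies.
#' @export
founder_beta <- function(shape = 0.2, lo = 0.02, hi = 0.98) {
  force(shape); force(lo); force(hi)
  function(n) qbeta(runif(n, pbeta(lo, shape, shape), pbeta(hi, shape, shape)),
                    shape, shape)
}

#' Simulation configuration for a two-regime pool-seq experiment
#'
#' Defines the experimental design the simulator emulates: replicate
#' Wright-Fisher populations evolved independently from a common founder
#' frequency draw under two regimes, with selection acting in the Selected
#' regime only, optional linkage blocks, and two-stage pool sampling
#' (individuals into the pool, then reads from the pool).
#'
#' @param n_loci number of simulated loci.
#' @param n_pops_per_regime replicate populations per regime (default 6).
#' @param ne_selected,ne_control diploid effective population sizes
#'   (Ne >= 1e7 is treated as the infinite-population limit: no drift).
#' @param t generations since the split from the base population.
#' @param selection a data.frame as returned by [selection_spec()].
#' @param block_map optional data.frame (locus, block, chrom, pos) assigning
#'   loci to linkage blocks and genomic coordinates; `block = NA` for
#'   independent loci. Loci in a block must share a chromosome and be
#'   ordered by position. Default: no blocks, loci 1 kb apart on "2L".
#' @param p0 founder allele frequencies: a function of `n` or a numeric
#'   vector of length `n_loci` (per *block* founder frequencies are drawn
#'   once per block). Default [founder_beta()].
#' @param S pool size, diploid individuals per sequencing library.
#' @param depth_mean,depth_dispersion read-depth model per site and
#'   population: negative binomial with this mean and size (dispersion)
#'   parameter; `Inf` dispersion gives Poisson. Depths are truncated at 1.
#' @param block_jitter_sd SD of the independent jitter added to the shared
#'   latent block trajectory for each member locus (default 0.02).
#' @param seed integer seed; the same seed gives bit-identical output.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_loci,
                       n_pops_per_regime = 6,
                       ne_selected = 150, ne_control = 150,
                       t = 150,
                       selection = selection_spec(n_loci),
                       block_map = NULL,
                       p0 = founder_beta(),
                       S = 400,
                       depth_mean = 40, depth_dispersion = Inf,
                       block_jitter_sd = 0.02,
                       seed = NULL) {
  if (n_loci < 1) stop("n_loci must be >= 1")
  if (ne_selected <= 0 || ne_control <= 0) stop("effective sizes must be positive")
  if (t < 1) stop("t must be >= 1")
  if (S < 1) stop("pool size S must be >= 1")
  if (depth_mean <= 0 || depth_dispersion <= 0) stop("depth model must be positive")
  if (n_pops_per_regime < 1) stop("n_pops_per_regime must be >= 1")
  stopifnot(nrow(selection) == n_loci)
  if (is.null(block_map)) {
    block_map <- data.frame(locus = seq_len(n_loci), block = NA_integer_,
                            chrom = "2L", pos = 1000L * seq_len(n_loci),
                            stringsAsFactors = FALSE)
  }
  stopifnot(nrow(block_map) == n_loci,
            all(c("locus", "block", "chrom", "pos") %in% names(block_map)))
  bm <- block_map[!is.na(block_map$block), , drop = FALSE]
  if (nrow(bm)) {
    bad <- vapply(split(bm, bm$block), function(b)
      length(unique(b$chrom)) > 1L || is.unsorted(b$pos, strictly = TRUE),
      logical(1))
    if (any(bad))
      stop("blocks must lie on one chromosome with strictly increasing positions: ",
           paste(names(bad)[bad], collapse = ", "))
  }
  if (is.numeric(p0)) {
    stopifnot(length(p0) == n_loci, all(p0 >= 0 & p0 <= 1))
  } else stopifnot(is.function(p0))
  structure(list(n_loci = n_loci, n_pops_per_regime = n_pops_per_regime,
                 ne_selected = ne_selected, ne_control = ne_control, t = t,
                 selection = selection, block_map = block_map, p0 = p0,
                 S = S, depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 block_jitter_sd = block_jitter_sd, seed = seed),
            class = "sim_config")
}

# one generation of viability selection; p = frequency of the alternate
# ("selected") allele, Hardy-Weinberg genotypes
select_step <- function(p, mode, s, eq) {
  q <- 1 - p
  out <- p
  d <- mode == "directional" & s > 0
  if (any(d)) {
    pd <- p[d]; sd_ <- s[d]
    out[d] <- pd * (1 + sd_ * (1 + pd) / 2) / (1 + sd_ * pd)
  }
  b <- mode == "balanced" & s > 0
  if (any(b)) {
    pb <- p[b]; qb <- q[b]; sb <- s[b]; eb <- eq[b]
    waa <- 1 - sb * (1 - eb)  # alt homozygote
    wbb <- 1 - sb * eb        # ref homozygote
    wbar <- pb^2 * waa + 2 * pb * qb + qb^2 * wbb
    out[b] <- pb * (pb * waa + qb) / wbar
  }
  out
}

# evolve a matrix of frequencies (units x pops) for t generations;
# selection applied only in columns flagged `selected`
wf_evolve <- function(p, t, ne_by_pop, selected_by_pop, mode, s, eq) {
  n_units <- nrow(p); n_pops <- ncol(p)
  sel_cols <- which(selected_by_pop)
  drift_cols <- which(ne_by_pop < 1e7)
  for (gen in seq_len(t)) {
    if (length(sel_cols))
      p[, sel_cols] <- select_step(as.vector(p[, sel_cols]),
                                   rep(mode, length(sel_cols)),
                                   rep(s, length(sel_cols)),
                                   rep(eq, length(sel_cols)))
    for (j in drift_cols) {
      nchrom <- 2 * ne_by_pop[j]
      p[, j] <- rbinom(n_units, nchrom, p[, j]) / nchrom
    }
  }
  p
}

#' Two-stage pool-seq read sampling
#'
#' Given true population allele frequencies, draws the pooled sample of
#' `2S` chromosomes binomially, then reads binomially from the pool allele
#' frequency. The unconditional variance of the resulting read frequency is
#' approximately `p(1-p) * C` with `C = 1/(2S) + 1/R + 1/(S R)` (the
#' pool-seq correction factor used by [estimate_ne()]).
#'
#' @param true_freq numeric vector or matrix of population frequencies in
#'   `[0, 1]`.
#' @param S pool size (diploid individuals), >= 1.
#' @param depth read depths (>= 0), same shape as `true_freq` (recycled if
#'   scalar).
#' @param seed optional seed.
#' @return list with integer `ref` and `alt` counts shaped like `true_freq`
#'   (counts sum to `depth`).
#' @export
sample_poolseq <- function(true_freq, S, depth, seed = NULL) {
  if (any(true_freq < 0 | true_freq > 1)) stop("frequencies must be in [0, 1]")
  if (S < 1) stop("pool size S must be >= 1")
  if (any(depth < 0)) stop("depths must be >= 0")
  n <- length(true_freq)
  depth <- rep_len(as.integer(depth), n)
  with_seed(seed, {
    pool <- rbinom(n, 2 * S, as.vector(true_freq)) / (2 * S)
    alt <- rbinom(n, depth, pool)
  })
  ref <- depth - alt
  if (is.matrix(true_freq)) {
    dim(ref) <- dim(alt) <- dim(true_freq)
    dimnames(ref) <- dimnames(alt) <- dimnames(true_freq)
  }
  list(ref = ref, alt = alt)
}

#' Simulate a full evolve-and-resequence pool-seq experiment
#'
#' Evolves `2 * n_pops_per_regime` replicate Wright-Fisher populations
#' independently from a shared founder frequency draw for `t` generations,
#' with directional or balancing selection acting in the Selected regime
#' only, then samples pool-seq read counts by two-stage binomial sampling.
#' Loci belonging to the same linkage block inherit a single shared latent
#' trajectory plus small independent jitter, which yields the high
#' within-block residual correlations consumed by [delineate_clusters()].
#'
#' @param config a [sim_config()].
#' @return list with elements `counts` (a [count_matrix()] whose columns are
#'   S1..S6, C1..C6), `truth` (per-locus data.frame: locus, chrom, pos,
#'   block, mode, s, eq, p0, and true final frequencies `freq_<pop>`),
#'   `design` (the matching [regime_design()]).
#' @examples
#' cfg <- sim_config(n_loci = 50, t = 20, seed = 1)
#' sim <- simulate_experiment(cfg)
#' sim$counts
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  npr <- cf$n_pops_per_regime
  pops <- c(paste0("S", seq_len(npr)), paste0("C", seq_len(npr)))
  n_pops <- 2L * npr
  design <- regime_design(pops, rep(c("SEL", "CTL"), each = npr),
                          S = cf$S, t = cf$t)
  bm <- cf$block_map
  # evolution units: one per block plus one per unblocked locus
  unit_of_locus <- integer(cf$n_loci)
  blk_ids <- unique(bm$block[!is.na(bm$block)])
  unit_mode <- character(0); unit_s <- numeric(0); unit_eq <- numeric(0)
  u <- 0L
  for (b in blk_ids) {
    u <- u + 1L
    members <- bm$locus[!is.na(bm$block) & bm$block == b]
    unit_of_locus[members] <- u
    # block members share the latent trajectory; its selection parameters
    # are those of the first member
    first <- members[1]
    unit_mode[u] <- cf$selection$mode[first]
    unit_s[u] <- cf$selection$s[first]
    unit_eq[u] <- cf$selection$eq[first]
  }
  singles <- bm$locus[is.na(bm$block)]
  for (l in singles) {
    u <- u + 1L
    unit_of_locus[l] <- u
    unit_mode[u] <- cf$selection$mode[l]
    unit_s[u] <- cf$selection$s[l]
    unit_eq[u] <- cf$selection$eq[l]
  }
  n_units <- u

  with_seed(cf$seed, {
    p0_units <- if (is.function(cf$p0)) cf$p0(n_units) else {
      # per-locus vector supplied: a block's founder frequency is that of
      # its first member
      vapply(seq_len(n_units), function(uu)
        cf$p0[which(unit_of_locus == uu)[1]], numeric(1))
    }
    p <- matrix(rep(p0_units, n_pops), nrow = n_units, ncol = n_pops)
    ne_by_pop <- rep(c(cf$ne_selected, cf$ne_control), each = npr)
    sel_by_pop <- rep(c(TRUE, FALSE), each = npr)
    p_final_units <- wf_evolve(p, cf$t, ne_by_pop, sel_by_pop,
                               unit_mode, unit_s, unit_eq)
    # member loci: latent value + independent jitter (blocks only)
    p_loci <- p_final_units[unit_of_locus, , drop = FALSE]
    blocked <- !is.na(bm$block)
    if (any(blocked) && cf$block_jitter_sd > 0) {
      jit <- matrix(rnorm(sum(blocked) * n_pops, 0, cf$block_jitter_sd),
                    ncol = n_pops)
      p_loci[blocked, ] <- pmin(1, pmax(0, p_loci[blocked, , drop = FALSE] + jit))
    }
    depth <- if (is.finite(cf$depth_dispersion)) {
      stats::rnbinom(cf$n_loci * n_pops, mu = cf$depth_mean,
                     size = cf$depth_dispersion)
    } else rpois(cf$n_loci * n_pops, cf$depth_mean)
    depth <- pmax(1L, depth)
    reads <- sample_poolseq(p_loci, cf$S, depth)
  })
  colnames(reads$ref) <- colnames(reads$alt) <- pops
  counts <- count_matrix(bm$chrom, bm$pos, "A", "T", reads$ref, reads$alt,
                         pops = pops)
  truth <- data.frame(locus = bm$locus, chrom = bm$chrom, pos = bm$pos,
                      block = bm$block, mode = cf$selection$mode,
                      s = cf$selection$s, eq = cf$selection$eq,
                      p0 = p0_units[unit_of_locus],
                      stringsAsFactors = FALSE)
  freqs <- p_loci
  colnames(freqs) <- paste0("freq_", pops)
  truth <- cbind(truth, as.data.frame(freqs))
  # count_matrix sorts by chrom/pos; keep truth aligned with it
  ord <- order(bm$chrom, bm$pos)
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL
  list(counts = counts, truth = truth, design = design)
}

#' Write the simulation truth table as TSV
#' @param truth the `truth` element of [simulate_experiment()].
#' @param path output file.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
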