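#' Per-SNP, per-population read-count matrix
#'
#' The backbone container of the pipeline: one row per biallelic site with
#' chromosome, 1-based position and resolved reference/alternate alleles,
#' plus integer matrices of reference and alternate read counts
#' (sites x populations).
#'
#' @param chrom character vector of chromosome (arm) labels.
#' @param pos integer vector of 1-based positions, strictly increasing
#'   within each chromosome.
#' @param ref_allele,alt_allele single-character allele labels per site.
#' @param ref,alt integer matrices of reference/alternate read counts with
#'   one column per population.
#' @param pops optional population names (default taken from `colnames(ref)`
#'   or `pop1..popK`).
#' @return An object of class `count_matrix`: a list with elements `sites`
#'   (data.frame: chrom, pos, ref, alt), `ref`, `alt` (count matrices) and
#'   `pops`.
#' @export
count_matrix <- function(chrom, pos, ref_allele, alt_allele, ref, alt, pops = NULL) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  n <- length(chrom)
  stopifnot(length(pos) == n, nrow(ref) == n, nrow(alt) == n,
            ncol(ref) == ncol(alt))
  if (!is_count(ref) || !is_count(alt))
    stop("read counts must be non-negative integers")
  if (length(ref_allele) == 1L) ref_allele <- rep(ref_allele, n)
  if (length(alt_allele) == 1L) alt_allele <- rep(alt_allele, n)
  ord <- order(chrom, pos)
  if (is.unsorted(ord)) {
    chrom <- chrom[ord]; pos <- pos[ord]
    ref_allele <- ref_allele[ord]; alt_allele <- alt_allele[ord]
    ref <- ref[ord, , drop = FALSE]; alt <- alt[ord, , drop = FALSE]
  }
  if (anyDuplicated(paste(chrom, pos)))
    stop("duplicated chromosome/position pairs")
  if (is.null(pops)) pops <- colnames(ref)
  if (is.null(pops)) pops <- paste0("pop", seq_len(ncol(ref)))
  colnames(ref) <- colnames(alt) <- pops
  storage.mode(ref) <- "integer"; storage.mode(alt) <- "integer"
  structure(
    list(sites = data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                            ref = ref_allele, alt = alt_allele,
                            stringsAsFactors = FALSE),
         ref = ref, alt = alt, pops = pops),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d sites x %d populations (%s)\n",
              nrow(x$sites), length(x$pops),
              paste(unique(x$sites$chrom), collapse = ", ")))
  invisible(x)
}

#' Number of sites in a count matrix
#' @param x a `count_matrix`.
#' @export
n_sites <- function(x) nrow(x$sites)

#' Per-site, per-population read depth (ref + alt)
#' @param x a `count_matrix`.
#' @return integer matrix, sites x populations.
#' @export
coverage <- function(x) x$ref + x$alt

#' Alternate-allele read frequencies
#'
#' @param x a `count_matrix`.
#' @return numeric matrix alt/(ref+alt); `NaN` where depth is zero.
#' @export
allele_freqs <- function(x) {
  cov <- x$ref + x$alt
  f <- x$alt / cov
  dimnames(f) <- dimnames(x$alt)
  f
}

#' Subset a count matrix by site index
#' @param x a `count_matrix`.
#' @param i logical or integer site index.
#' @export
subset_sites <- function(x, i) {
  structure(list(sites = x$sites[i, , drop = FALSE],
                 ref = x$ref[i, , drop = FALSE],
                 alt = x$alt[i, , drop = FALSE],
                 pops = x$pops),
            class = "count_matrix")
}

#' Experimental design: regimes, pool size and generations
#'
#' Describes which populations belong to which selective regime, the number
#' of diploid individuals pooled per library (S) and the number of
#' generations since the regimes split from the common base population (t).
#'
#' @param pops population names, matching `count_matrix` columns.
#' @param regime factor/character with levels/values `"SEL"` (poor diet,
#'   Selected) and `"CTL"` (standard diet, Control), one per population.
#' @param S pool size: diploid individuals per pooled library (default 400
#'   females).
#' @param t generations of divergence from the common base (default 150).
#' @return A `regime_design` data.frame with attributes `S` and `t`.
#' @examples
#' regime_design()  # the 6 Selected + 6 Control default design
#' @export
regime_design <- function(pops = c(paste0("S", 1:6), paste0("C", 1:6)),
                          regime = rep(c("SEL", "CTL"), each = 6),
                          S = 400, t = 150) {
  stopifnot(length(pops) == length(regime), !anyDuplicated(pops),
            all(regime %in% c("SEL", "CTL")), S >= 1, t >= 1)
  d <- data.frame(pop = pops, regime = regime, stringsAsFactors = FALSE)
  attr(d, "S") <- S
  attr(d, "t") <- t
  class(d) <- c("regime_design", "data.frame")
  d
}

# indices of each regime's populations in the column order of `counts`
design_index <- function(counts, design) {
  idx <- match(design$pop, counts$pops)
  if (anyNA(idx))
    stop("design populations absent from count matrix: ",
         paste(design$pop[is.na(idx)], collapse = ", "))
  list(sel = idx[design$regime == "SEL"], ctl = idx[design$regime == "CTL"])
}
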