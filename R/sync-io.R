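#' Read a PoPoolation2-style sync file
#'
#' Each line: chromosome, 1-based position, reference base, then one
#' colon-separated `A:T:C:G:N:del` count sextuple per population
#' (tab-separated). The parse is lossless; malformed lines are reported
#' with their line numbers.
#'
#' @param path path to a sync file.
#' @param pops optional population names (default `pop1..popK`).
#' @return object of class `sync`: list with `sites` (data.frame chrom,
#'   pos, ref), `counts` (integer array sites x populations x 6, bases
#'   A,T,C,G,N,del) and `pops`.
#' @export
read_sync <- function(path, pops = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.info(path)$size == 0) return(empty_sync(pops))
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = "character", data.table = TRUE)
  if (nrow(dt) == 0L || ncol(dt) < 4L) {
    if (nrow(dt) == 0L) return(empty_sync(pops))
    stop("sync line 1: expected at least 4 tab-separated fields")
  }
  n_pops <- ncol(dt) - 3L
  ragged <- which(apply(is.na(dt) | dt == "", 1L, any))
  if (length(ragged))
    stop("sync parse error: ragged row(s) at line ",
         paste(head(ragged, 5), collapse = ", "))
  pos <- suppressWarnings(as.integer(dt[[2]]))
  if (anyNA(pos))
    stop("sync parse error: non-integer position at line ",
         which(is.na(pos))[1])
  refb <- toupper(dt[[3]])
  badref <- which(!refb %in% c("A", "T", "C", "G", "N"))
  if (length(badref))
    stop("sync parse error: unknown reference base at line ", badref[1])
  counts <- array(NA_integer_, dim = c(nrow(dt), n_pops, 6L),
                  dimnames = list(NULL, NULL, c("A", "T", "C", "G", "N", "del")))
  for (j in seq_len(n_pops)) {
    parts <- data.table::tstrsplit(dt[[3L + j]], ":", fixed = TRUE)
    if (length(parts) != 6L)
      stop("sync parse error: population ", j,
           " counts are not colon-separated sextuples")
    for (b in 1:6) {
      v <- suppressWarnings(as.integer(parts[[b]]))
      if (anyNA(v))
        stop("sync parse error: non-integer count at line ",
             which(is.na(v))[1], ", population ", j)
      counts[, j, b] <- v
    }
  }
  if (any(counts < 0)) stop("sync parse error: negative count")
  if (is.null(pops)) pops <- paste0("pop", seq_len(n_pops))
  structure(list(sites = data.frame(chrom = dt[[1]], pos = pos, ref = refb,
                                    stringsAsFactors = FALSE),
                 counts = counts, pops = pops),
            class = "sync")
}

empty_sync <- function(pops = NULL) {
  structure(list(sites = data.frame(chrom = character(), pos = integer(),
                                    ref = character(), stringsAsFactors = FALSE),
                 counts = array(integer(), dim = c(0L, length(pops), 6L)),
                 pops = pops),
            class = "sync")
}

#' @export
print.sync <- function(x, ...) {
  cat(sprintf("sync: %d sites x %d populations\n",
              nrow(x$sites), dim(x$counts)[2]))
  invisible(x)
}

#' Write a sync object (or count matrix) to a sync file
#'
#' A `count_matrix` is first expanded back to the base-wise sextuple
#' representation via [as_sync()].
#'
#' @param x a `sync` or `count_matrix` object.
#' @param path output path.
#' @export
write_sync <- function(x, path) {
  if (inherits(x, "count_matrix")) x <- as_sync(x)
  stopifnot(inherits(x, "sync"))
  n_pops <- dim(x$counts)[2]
  cols <- lapply(seq_len(n_pops), function(j) {
    m <- x$counts[, j, , drop = FALSE]
    dim(m) <- dim(m)[c(1, 3)]
    do.call(paste, c(lapply(1:6, function(b) m[, b]), sep = ":"))
  })
  dt <- data.table::as.data.table(
    c(list(x$sites$chrom, x$sites$pos, x$sites$ref), cols))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Expand a biallelic count matrix to sync sextuples
#'
#' Reference counts go to the reference-base slot and alternate counts to
#' the alternate-base slot; all other slots are zero.
#'
#' @param x a [count_matrix()].
#' @return a `sync` object.
#' @export
as_sync <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  bases <- c("A", "T", "C", "G", "N", "del")
  n <- nrow(x$sites); n_pops <- length(x$pops)
  counts <- array(0L, dim = c(n, n_pops, 6L),
                  dimnames = list(NULL, NULL, bases))
  ri <- match(x$sites$ref, bases); ai <- match(x$sites$alt, bases)
  if (anyNA(ri) || anyNA(ai)) stop("alleles must be A/T/C/G")
  for (j in seq_len(n_pops)) {
    counts[cbind(seq_len(n), j, ri)] <- x$ref[, j]
    counts[cbind(seq_len(n), j, ai)] <- x$alt[, j]
  }
  structure(list(sites = data.frame(chrom = x$sites$chrom, pos = x$sites$pos,
                                    ref = x$sites$ref, stringsAsFactors = FALSE),
                 counts = counts, pops = x$pops),
            class = "sync")
}

#' Read a BED mask file
#'
#' Three-column BED (chrom, start, end), 0-based half-open as per the BED
#' convention; converted to 1-based inclusive intervals internally.
#'
#' @param path BED file path.
#' @return data.frame with chrom, start, end (1-based inclusive).
#' @export
read_bed_mask <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  info <- file.info(path)
  if (info$size == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  bed <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end"),
                    colClasses = c("character", "integer", "integer"))
  if (any(bed$end <= bed$start)) stop("BED intervals must satisfy end > start")
  data.frame(chrom = bed$chrom, start = bed$start + 1L, end = bed$end,
             stringsAsFactors = FALSE)
}

# TRUE for sites falling inside any mask interval (masks 1-based inclusive)
site_masked <- function(chrom, pos, masks) {
  if (is.null(masks) || nrow(masks) == 0L) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (k in seq_len(nrow(masks))) {
    out <- out | (chrom == masks$chrom[k] &
                    pos >= masks$start[k] & pos <= masks$end[k])
  }
  out
}
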