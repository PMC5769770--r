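#' Binned cis contact matrix
#'
#' The central Hi-C container: a symmetric matrix of contact counts over a
#' single-chromosome window binned at a fixed size, plus a per-bin mask and
#' (after balancing) a per-bin bias vector. Bin `i` (1-based) covers
#' `[start + (i-1)*bin_size, start + i*bin_size)`.
#'
#' @param counts square symmetric numeric matrix of non-negative values.
#' @param chrom chromosome name.
#' @param start 0-based start of the window (must be a multiple of
#'   `bin_size` so bin indices are absolute).
#' @param bin_size bin width in bases (40 kb or 20 kb typical).
#' @param mask logical per-bin mask (`TRUE` = masked out).
#' @param biases optional positive per-bin bias vector.
#' @param normalized whether `counts` are balanced values.
#' @return an object of class `"contact_matrix"`.
#' @export
contact_matrix <- function(counts, chrom, start, bin_size,
                           mask = NULL, biases = NULL, normalized = FALSE) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (ncol(counts) != n) stop("counts must be square")
  if (!isTRUE(all.equal(counts, t(counts), tolerance = 1e-8))) {
    stop("counts must be symmetric")
  }
  if (any(!is.finite(counts))) stop("counts must be finite")
  if (start %% bin_size != 0) {
    stop("window start must be a multiple of bin_size")
  }
  if (is.null(mask)) mask <- rep(FALSE, n)
  stopifnot(length(mask) == n)
  if (!is.null(biases)) stopifnot(length(biases) == n)
  structure(list(counts = unname(counts), chrom = chrom,
                 start = as.numeric(start), bin_size = as.numeric(bin_size),
                 mask = as.logical(mask), biases = biases,
                 normalized = isTRUE(normalized)),
            class = "contact_matrix")
}

#' @rdname contact_matrix
#' @param m a `contact_matrix`.
#' @export
n_bins <- function(m) nrow(m$counts)

#' @rdname contact_matrix
#' @export
bin_starts <- function(m) m$start + (seq_len(n_bins(m)) - 1) * m$bin_size

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "ContactMatrix %s:%s-%s | %d bins of %s bp | %d masked | %s\n",
    x$chrom, format(x$start, big.mark = ","),
    format(x$start + n_bins(x) * x$bin_size, big.mark = ","),
    n_bins(x), format(x$bin_size, big.mark = ","), sum(x$mask),
    if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Mask bins of a contact matrix
#'
#' Marks the given bins as masked and zeroes their rows and columns.
#' Masking only removes signal; it never redistributes counts.
#'
#' @param m a [contact_matrix()].
#' @param bins 1-based bin indices to mask (in addition to existing mask).
#' @export
mask_bins <- function(m, bins) {
  stopifnot(inherits(m, "contact_matrix"))
  mask <- m$mask
  mask[bins] <- TRUE
  counts <- m$counts
  counts[mask, ] <- 0
  counts[, mask] <- 0
  contact_matrix(counts, m$chrom, m$start, m$bin_size, mask = mask,
                 biases = m$biases, normalized = m$normalized)
}

# sum over the upper triangle including the diagonal = number of pairs
upper_total <- function(counts) sum(counts[upper.tri(counts, diag = TRUE)])

# assert two matrices share chrom/start/bin_size/n
check_same_grid <- function(a, b) {
  if (!identical(a$chrom, b$chrom) || a$start != b$start ||
      a$bin_size != b$bin_size || n_bins(a) != n_bins(b)) {
    stop("contact matrices are not on the same bin grid")
  }
  invisible(TRUE)
}
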