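#' Restriction fragment map
#'
#' Sorted fragment boundaries tiling one chromosome without gaps or
#' overlaps: fragment `i` (1-based) is `[boundaries[i], boundaries[i+1])`.
#'
#' @param chrom chromosome name.
#' @param boundaries increasing numeric vector of cut positions; must start
#'   at 0 and end at the chromosome length.
#' @return object of class `"restriction_map"`.
#' @export
restriction_map <- function(chrom, boundaries) {
  boundaries <- as.numeric(boundaries)
  if (boundaries[1] != 0) stop("fragment boundaries must start at 0")
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop("fragment boundaries must be strictly increasing")
  }
  structure(list(chrom = chrom, boundaries = boundaries,
                 length = boundaries[length(boundaries)]),
            class = "restriction_map")
}

#' @rdname restriction_map
#' @param rmap a `restriction_map`.
#' @export
n_fragments <- function(rmap) length(rmap$boundaries) - 1L

#' @rdname restriction_map
#' @export
fragment_midpoints <- function(rmap) {
  b <- rmap$boundaries
  floor((b[-length(b)] + b[-1]) / 2)
}

#' Build a regular restriction map
#'
#' Convenience constructor for simulations: fragments of constant size,
#' with a possibly shorter terminal fragment.
#'
#' @param chrom chromosome name.
#' @param length chromosome length.
#' @param fragment_size fragment width in bases.
#' @export
regular_restriction_map <- function(chrom, length, fragment_size) {
  b <- seq(0, length, by = fragment_size)
  if (b[base::length(b)] != length) b <- c(b, length)
  restriction_map(chrom, b)
}

#' Assign a mapped read end to a restriction fragment
#'
#' The 5' mapped position is shifted 3 bp toward the 3' end of the read
#' (`+3` on the plus strand, `-3` on the minus strand) before fragment
#' lookup, so reads whose 5' end sits exactly on a cut site are attributed
#' to the fragment they actually come from. The shifted query is clamped to
#' the chromosome ends.
#'
#' @param pos 5'-mapped base position(s), 0-based.
#' @param strand `"+"` or `"-"` (recycled).
#' @param rmap a [restriction_map()].
#' @return integer fragment indices (1-based).
#' @export
assign_fragment <- function(pos, strand, rmap) {
  stopifnot(inherits(rmap, "restriction_map"))
  if (any(pos < 0 | pos >= rmap$length)) {
    stop("position out of chromosome range")
  }
  shift <- ifelse(strand == "+", 3, -3)
  q <- pmin(pmax(pos + shift, 0), rmap$length - 1)
  findInterval(q, rmap$boundaries, rightmost.closed = FALSE)
}

#' Classify a Hi-C pair by restriction-fragment geometry
#'
#' Standard ligation-artefact taxonomy on same-fragment pairs: reads facing
#' each other on one fragment (`+` on the left, `-` on the right) are an
#' unligated dangling end; reads facing away are a self-circularised
#' fragment; same-strand same-fragment pairs are mapping errors. Pairs on
#' different fragments are valid ligation junctions.
#'
#' @param pairs data.frame with columns `chrom1 pos1 strand1 chrom2 pos2
#'   strand2`; an unmapped side has `NA` position.
#' @param rmap a [restriction_map()].
#' @return character vector: `"valid"`, `"single_side"`, `"dangling_end"`,
#'   `"self_circle"`, or `"error_pair"`; always a partition of the input.
#' @export
classify_pairs <- function(pairs, rmap) {
  n <- nrow(pairs)
  out <- character(n)
  unmapped <- is.na(pairs$pos1) | is.na(pairs$pos2)
  out[unmapped] <- "single_side"
  ok <- !unmapped
  if (any(ok)) {
    f1 <- assign_fragment(pairs$pos1[ok], pairs$strand1[ok], rmap)
    f2 <- assign_fragment(pairs$pos2[ok], pairs$strand2[ok], rmap)
    # canonical order: lower coordinate first (per-pair)
    p1 <- pairs$pos1[ok]; p2 <- pairs$pos2[ok]
    s1 <- pairs$strand1[ok]; s2 <- pairs$strand2[ok]
    swap <- p1 > p2
    tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
    tmp <- s1[swap]; s1[swap] <- s2[swap]; s2[swap] <- tmp
    cls <- rep("valid", sum(ok))
    same <- f1 == f2
    cls[same & s1 == "+" & s2 == "-"] <- "dangling_end"
    cls[same & s1 == "-" & s2 == "+"] <- "self_circle"
    cls[same & s1 == s2] <- "error_pair"
    out[ok] <- cls
  }
  out
}

#' Remove exact duplicate pairs
#'
#' Keeps one representative per identical
#' `(chrom1, pos1, strand1, chrom2, pos2, strand2)` tuple, preserving first
#' occurrence order. Replicates should be concatenated before this step so
#' cross-replicate PCR duplicates collapse too.
#'
#' @param pairs pair data.frame.
#' @export
dedupe_pairs <- function(pairs) {
  key <- paste(pairs$chrom1, pairs$pos1, pairs$strand1,
               pairs$chrom2, pairs$pos2, pairs$strand2, sep = "\r")
  pairs[!duplicated(key), , drop = FALSE]
}

#' Bin valid pairs into a contact matrix
#'
#' Each read end is assigned to its restriction fragment, each fragment to
#' the bin containing the fragment midpoint (`floor(midpoint / bin_size)`;
#' a midpoint exactly on a bin edge goes to the right bin), and each pair
#' increments the symmetric bin-pair cell. Pairs with either end outside
#' the window are tallied in `attr(,"discarded")`, not an error.
#'
#' @param pairs valid-class, deduplicated pair data.frame.
#' @param rmap a [restriction_map()].
#' @param bin_size bin width in bases.
#' @param extent a [gi()] window (start/end must be bin_size multiples).
#' @return a raw [contact_matrix()]; upper-triangle total equals the number
#'   of pairs inside the window. The per-fragment read tally needed by
#'   [compute_mask()] is attached as `attr(, "fragment_counts")`.
#' @export
bin_pairs <- function(pairs, rmap, bin_size, extent) {
  stopifnot(is_gi(extent))
  if (extent$start %% bin_size != 0 || extent$end %% bin_size != 0) {
    stop("extent must be aligned to the bin grid")
  }
  f1 <- assign_fragment(pairs$pos1, pairs$strand1, rmap)
  f2 <- assign_fragment(pairs$pos2, pairs$strand2, rmap)
  mids <- fragment_midpoints(rmap)
  b1 <- floor(mids[f1] / bin_size)
  b2 <- floor(mids[f2] / bin_size)
  lo <- extent$start / bin_size
  hi <- extent$end / bin_size      # exclusive
  inside <- b1 >= lo & b1 < hi & b2 >= lo & b2 < hi
  n <- hi - lo
  counts <- matrix(0, n, n)
  if (any(inside)) {
    i <- b1[inside] - lo + 1
    j <- b2[inside] - lo + 1
    tab <- table(factor(pmin(i, j), levels = seq_len(n)),
                 factor(pmax(i, j), levels = seq_len(n)))
    upper <- matrix(as.numeric(tab), n, n)
    counts <- upper + t(upper)
    diag(counts) <- diag(upper)
  }
  m <- contact_matrix(counts, chrom = rmap$chrom, start = extent$start,
                      bin_size = bin_size)
  fc <- tabulate(c(f1[inside], f2[inside]), nbins = n_fragments(rmap))
  attr(m, "fragment_counts") <- fc
  attr(m, "discarded") <- sum(!inside)
  m
}

#' Low-coverage mask for a raw contact matrix
#'
#' A bin is masked when its marginal read sum falls 10-fold below the
#' uniform-coverage expectation (each pair contributes to two marginals, so
#' the expectation is `2 * total_pairs / n_bins`), or when fewer than half
#' of its restriction fragments are covered by at least two reads. Without
#' per-fragment counts only the first rule applies (with a warning).
#'
#' @param m raw [contact_matrix()], typically from [bin_pairs()].
#' @param rmap the [restriction_map()] used for binning (for the
#'   fragment-coverage rule); optional.
#' @param fragment_counts reads per fragment; defaults to
#'   `attr(m, "fragment_counts")`.
#' @return logical mask vector (`TRUE` = masked).
#' @export
compute_mask <- function(m, rmap = NULL, fragment_counts = NULL) {
  stopifnot(inherits(m, "contact_matrix"))
  if (m$normalized) stop("mask must be computed on the raw matrix")
  if (is.null(fragment_counts)) {
    fragment_counts <- attr(m, "fragment_counts")
  }
  n <- n_bins(m)
  marginal <- rowSums(m$counts)
  total <- upper_total(m$counts)
  expected <- 2 * total / n
  mask <- marginal < expected / 10
  if (!is.null(fragment_counts) && !is.null(rmap)) {
    mids <- fragment_midpoints(rmap)
    fbin <- floor(mids / m$bin_size) - m$start / m$bin_size + 1
    ok <- fbin >= 1 & fbin <= n
    frag_per_bin <- tabulate(fbin[ok], nbins = n)
    cov2_per_bin <- tabulate(fbin[ok & fragment_counts >= 2], nbins = n)
    # "less than half" is strict
    mask <- mask | (cov2_per_bin < frag_per_bin / 2)
  } else if (is.null(fragment_counts) || is.null(rmap)) {
    warning("fragment coverage unavailable; applying marginal rule only")
  }
  mask
}

#' Iterative correction (ICE) of a contact matrix
#'
#' Symmetric iterative marginal balancing: at each sweep the counts are
#' divided by the outer product of the (mean-centred) unmasked marginals
#' until all unmasked marginals agree to within `tol` relative deviation.
#' The result is rescaled so the total unmasked sum is preserved, and the
#' accumulated per-bin biases are returned normalized to unit geometric
#' mean over unmasked bins (masked bins get `NA` bias).
#'
#' @param m a masked raw [contact_matrix()].
#' @param tol relative marginal deviation for convergence (default `1e-5`).
#' @param max_iter maximum sweeps (default 200).
#' @return a normalized [contact_matrix()] with `biases`; attributes
#'   `converged` (logical) and `final_deviation`.
#' @export
ice_normalize <- function(m, tol = 1e-5, max_iter = 200L) {
  stopifnot(inherits(m, "contact_matrix"))
  keep <- !m$mask
  if (!any(keep)) stop("no unmasked bins")
  counts <- m$counts
  counts[!keep, ] <- 0; counts[, !keep] <- 0
  total0 <- sum(counts[keep, keep])
  if (total0 <= 0) stop("no signal in unmasked bins")
  bias <- rep(1, n_bins(m))
  dev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    marg <- rowSums(counts)
    s <- marg[keep] / mean(marg[keep])
    dev <- max(abs(s - 1))
    if (dev < tol) { converged <- TRUE; break }
    scale <- rep(1, n_bins(m))
    scale[keep] <- s
    counts <- counts / outer(scale, scale)
    bias <- bias * scale
  }
  if (!converged) {
    warning(sprintf("ICE did not converge in %d iterations (deviation %.3g)",
                    max_iter, dev))
  }
  counts <- counts * (total0 / sum(counts[keep, keep]))
  gm <- exp(mean(log(bias[keep])))
  bias <- bias / gm
  bias[!keep] <- NA_real_
  out <- contact_matrix(counts, m$chrom, m$start, m$bin_size,
                        mask = m$mask, biases = bias, normalized = TRUE)
  attr(out, "converged") <- converged
  attr(out, "final_deviation") <- dev
  out
}

#' Subtract two normalized contact matrices
#'
#' Elementwise `a - b` on the union of unmasked bins; cells touching a
#' masked bin of either matrix are `NA` (missing, not zero). The signed
#' result is what difference heatmaps between conditions display.
#'
#' @param a,b normalized [contact_matrix()] objects on the same grid.
#' @return a matrix-like object of class `"contact_diff"` with elements
#'   `delta` (signed matrix with `NA` at masked cells), `mask`, and grid
#'   metadata.
#' @export
subtract_matrices <- function(a, b) {
  check_same_grid(a, b)
  if (!a$normalized || !b$normalized) {
    stop("both matrices must be normalized before subtraction")
  }
  mask <- a$mask | b$mask
  delta <- a$counts - b$counts
  delta[mask, ] <- NA_real_
  delta[, mask] <- NA_real_
  structure(list(delta = delta, mask = mask, chrom = a$chrom,
                 start = a$start, bin_size = a$bin_size),
            class = "contact_diff")
}

#' @export
print.contact_diff <- function(x, ...) {
  cat(sprintf("Contact difference %s: %d bins, %d masked\n",
              x$chrom, nrow(x$delta), sum(x$mask)))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Shared test used for domain-intensity comparison and the boundary
#' statistical filter. For small samples (`choose(n, n_x) <= max_exact`)
#' the two-sided p-value is computed by exhaustive enumeration of the
#' permutation distribution of the rank sum (midranks under ties):
#' `P(|W - E W| >= |w - E W|)`. Larger samples use the normal approximation
#' with tie correction and continuity correction, as in
#' `stats::wilcox.test(correct = TRUE, exact = FALSE)`.
#'
#' @param x,y numeric samples.
#' @param max_exact enumeration budget (number of combinations).
#' @return list with `statistic` (rank-sum W of `x`, Mann-Whitney form) and
#'   `p_value`.
#' @export
ranksum_test <- function(x, y, max_exact = 2e5) {
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  if (choose(nx + ny, nx) <= max_exact) {
    ew <- nx * (nx + ny + 1) / 2
    obs <- abs(w - ew)
    combs <- utils::combn(nx + ny, nx)
    ws <- colSums(matrix(r[combs], nrow = nx))
    p <- mean(abs(ws - ew) >= obs - 1e-9)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    if (is.na(p)) p <- 1   # degenerate all-tied samples
  }
  list(statistic = w - nx * (nx + 1) / 2, p_value = min(1, p))
}

#' Compare contact intensity within a domain between two matrices
#'
#' Collects the unmasked off-diagonal within-domain balanced values of each
#' matrix and applies the two-sided rank-sum test (exact by enumeration for
#' small bin counts, continuity-corrected normal approximation otherwise).
#' The diagonal is excluded.
#'
#' @param a,b normalized [contact_matrix()] objects on the same grid.
#' @param domain a [gi()] interval.
#' @return list of class `"domain_comparison"`: `domain`, `statistic`,
#'   `p_value`, `n_bins_used` (per matrix).
#' @export
compare_domain_intensity <- function(a, b, domain) {
  check_same_grid(a, b)
  stopifnot(is_gi(domain))
  vals <- function(m) {
    starts <- bin_starts(m)
    inside <- which(starts >= domain$start &
                      (starts + m$bin_size) <= domain$end & !m$mask)
    if (length(inside) < 2) {
      stop("fewer than 2 usable bins in the domain")
    }
    sub <- m$counts[inside, inside]
    sub[upper.tri(sub)]
  }
  va <- vals(a); vb <- vals(b)
  ts <- ranksum_test(va, vb)
  structure(list(domain = domain, statistic = ts$statistic,
                 p_value = ts$p_value,
                 n_bins_used = c(a = length(va), b = length(vb))),
            class = "domain_comparison")
}

#' @export
print.domain_comparison <- function(x, ...) {
  cat(sprintf(
    "Domain %s:%.0f-%.0f | rank-sum W = %.1f | p = %.4g | %d vs %d values\n",
    x$domain$chrom, x$domain$start, x$domain$end, x$statistic, x$p_value,
    x$n_bins_used[1], x$n_bins_used[2]))
  invisible(x)
}
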