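#' 4C-seq viewpoint profile
#'
#' Fragment-level contact profile of one viewpoint: an ordered set of
#' non-overlapping restriction fragments with a non-negative signal each
#' (the per-fragment score a 4C pipeline emits after mapping and
#' demultiplexing).
#'
#' @param fragments data.frame with columns `start`, `end`, `signal`
#'   (sorted, non-overlapping, half-open).
#' @param chrom chromosome name.
#' @param viewpoint a [gi()]: the bait fragment/region.
#' @param name viewpoint label.
#' @return object of class `"fourc_profile"`.
#' @export
fourc_profile <- function(fragments, chrom, viewpoint, name = "viewpoint") {
  stopifnot(is.data.frame(fragments), is_gi(viewpoint))
  fragments <- fragments[order(fragments$start),
                         c("start", "end", "signal")]
  rownames(fragments) <- NULL
  if (any(fragments$end <= fragments$start)) stop("empty fragment")
  if (nrow(fragments) > 1 &&
      any(fragments$start[-1] < fragments$end[-nrow(fragments)])) {
    stop("fragments overlap")
  }
  if (any(!is.finite(fragments$signal)) || any(fragments$signal < 0)) {
    stop("signal must be finite and non-negative")
  }
  structure(list(fragments = fragments, chrom = chrom,
                 viewpoint = viewpoint, name = name,
                 smoothed = FALSE, smooth_window = NA_integer_,
                 normalized = FALSE, norm_span = NA_real_),
            class = "fourc_profile")
}

#' @export
print.fourc_profile <- function(x, ...) {
  cat(sprintf("4C profile '%s' (%s): %d fragments, total %.4g%s%s\n",
              x$name, x$chrom, nrow(x$fragments), sum(x$fragments$signal),
              if (x$smoothed) sprintf(", smoothed (w=%d)", x$smooth_window)
              else "",
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

frag_mids <- function(p) {
  floor((p$fragments$start + p$fragments$end) / 2)
}

#' Smooth a 4C profile over fragments
#'
#' Running mean over `window` consecutive fragments centred on each
#' fragment (default 11, the usual 4C display smoothing). At the profile
#' edges the window is truncated to the available fragments, so the first
#' fragment of a profile smoothed at window 11 averages 6 fragments.
#'
#' @param p a [fourc_profile()].
#' @param window odd fragment count (default 11).
#' @export
smooth_profile <- function(p, window = 11L) {
  stopifnot(inherits(p, "fourc_profile"))
  if (window %% 2 == 0) stop("smoothing window must be odd")
  half <- (window - 1L) / 2L
  s <- p$fragments$signal
  n <- length(s)
  cs <- c(0, cumsum(s))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  p$fragments$signal <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  p$smoothed <- TRUE
  p$smooth_window <- as.integer(window)
  p
}

#' Normalize a 4C profile to its viewpoint window
#'
#' Scales the whole profile so the total signal within `span` bases
#' upstream and downstream of the viewpoint equals `target` (per-million
#' convention). Fragment membership in the window is by midpoint. All
#' downstream ratios and clusterings are invariant to `target`.
#'
#' @param p a [fourc_profile()].
#' @param span window half-width in bases (default 5 Mb).
#' @param target total signal assigned to the window (default `1e6`).
#' @export
normalize_profile <- function(p, span = 5e6, target = 1e6) {
  stopifnot(inherits(p, "fourc_profile"))
  mids <- frag_mids(p)
  win <- mids >= (p$viewpoint$start - span) & mids < (p$viewpoint$end + span)
  tot <- sum(p$fragments$signal[win])
  if (tot <= 0) stop("no signal within the normalization window")
  p$fragments$signal <- p$fragments$signal * (target / tot)
  p$normalized <- TRUE
  p$norm_span <- span
  p
}

#' Inter-domain contact ratio of a 4C profile
#'
#' Percentage split of the profile signal between two disjoint domains,
#' `100 * S_a / (S_a + S_b)`, with fragment-to-domain membership by
#' fragment midpoint. Fragments inside `exclude` (e.g. the bait cluster
#' itself) contribute to neither sum.
#'
#' @param p a [fourc_profile()].
#' @param a,b disjoint [gi()] domains.
#' @param exclude optional [gi()] removed before summation.
#' @return object of class `"domain_ratio"`: `pct_a`, `pct_b` (sum to 100),
#'   `sum_a`, `sum_b`, the intervals, `excluded`.
#' @export
domain_ratio <- function(p, a, b, exclude = NULL) {
  stopifnot(inherits(p, "fourc_profile"), is_gi(a), is_gi(b))
  if (overlaps_any(a$start, a$end, b$start, b$end)) {
    stop("domains a and b must be disjoint")
  }
  mids <- frag_mids(p)
  sig <- p$fragments$signal
  if (!is.null(exclude)) {
    sig[point_in(mids, exclude$start, exclude$end)] <- 0
  }
  sa <- sum(sig[point_in(mids, a$start, a$end)])
  sb <- sum(sig[point_in(mids, b$start, b$end)])
  if (sa + sb == 0) stop("no signal in either domain")
  structure(list(pct_a = 100 * sa / (sa + sb),
                 pct_b = 100 * sb / (sa + sb),
                 sum_a = sa, sum_b = sb, domain_a = a, domain_b = b,
                 excluded = exclude),
            class = "domain_ratio")
}

#' @export
print.domain_ratio <- function(x, ...) {
  cat(sprintf("Domain ratio: %.1f%% vs %.1f%% (sums %.4g / %.4g)\n",
              x$pct_a, x$pct_b, x$sum_a, x$sum_b))
  invisible(x)
}

#' Quantify 4C signal at a panel of regions
#'
#' Per-region signal sum and fragment count with BEDTools-intersect
#' semantics: a fragment counts if it overlaps the region by at least one
#' base (half-open intervals, so an abutting fragment does not count).
#'
#' @param p a [fourc_profile()].
#' @param panel data.frame with columns `name`, `chrom`, `start`, `end`.
#' @return data.frame `name`, `signal`, `n_fragments`.
#' @export
region_quant <- function(p, panel) {
  stopifnot(inherits(p, "fourc_profile"))
  fr <- p$fragments
  res <- lapply(seq_len(nrow(panel)), function(i) {
    hit <- overlaps_any(fr$start, fr$end, panel$start[i], panel$end[i])
    data.frame(name = panel$name[i], signal = sum(fr$signal[hit]),
               n_fragments = sum(hit))
  })
  do.call(rbind, res)
}

#' Cumulative contact curve around a viewpoint
#'
#' Shifts fragment midpoints so the viewpoint sits at offset 0, restricts
#' to `bounds`, and accumulates signal in genomic order. The curve is
#' non-decreasing and ends at the window total.
#'
#' @param p a [fourc_profile()].
#' @param bounds numeric `c(lower, upper)` offsets in bases; must bracket 0.
#' @return object of class `"cumulative_curve"`: `offsets`, `values`,
#'   `name`, `bounds`.
#' @export
cumulative_curve <- function(p, bounds) {
  stopifnot(inherits(p, "fourc_profile"), length(bounds) == 2)
  if (bounds[1] > 0 || bounds[2] < 0) stop("bounds must contain offset 0")
  off <- frag_mids(p) - gi_midpoint(p$viewpoint)
  keep <- off >= bounds[1] & off <= bounds[2]
  if (!any(keep)) stop("no fragments within bounds")
  o <- off[keep]; s <- p$fragments$signal[keep]
  ord <- order(o)
  structure(list(offsets = o[ord], values = cumsum(s[ord]),
                 name = p$name, bounds = bounds),
            class = "cumulative_curve")
}

#' @export
print.cumulative_curve <- function(x, ...) {
  cat(sprintf("Cumulative curve '%s': %d fragments in [%.0f, %.0f], total %.4g\n",
              x$name, length(x$offsets), x$bounds[1], x$bounds[2],
              x$values[length(x$values)]))
  invisible(x)
}

#' Euclidean distance and Ward clustering of cumulative curves
#'
#' Interpolates each curve onto a common offset grid (the overlap of all
#' curve ranges, at `step` spacing), computes pairwise Euclidean distances
#' and an agglomerative Ward minimum-variance merge tree. Curves are
#' usually normalized profiles, so distances compare contact distribution
#' shapes across genotypes.
#'
#' @param curves list of [cumulative_curve()] objects (length >= 2).
#' @param step grid spacing in bases (default 10 kb).
#' @param scale divide each interpolated curve by its final value, so the
#'   clustering sees relative (fraction-of-total) cumulative frequency;
#'   default `TRUE`.
#' @return list with `dist` (a `dist`), `hclust` (Ward tree), `grid`.
#' @export
curve_distance_cluster <- function(curves, step = 1e4, scale = TRUE) {
  stopifnot(length(curves) >= 2)
  lo <- max(vapply(curves, function(c) min(c$offsets), 0))
  hi <- min(vapply(curves, function(c) max(c$offsets), 0))
  if (lo >= hi) stop("curves have no overlapping offset range")
  grid <- seq(lo, hi, by = step)
  mat <- vapply(curves, function(cv) {
    v <- stats::approx(cv$offsets, cv$values, xout = grid, method = "linear",
                       rule = 2, ties = "ordered")$y
    if (scale) v / cv$values[length(cv$values)] else v
  }, numeric(length(grid)))
  mat <- t(mat)
  rownames(mat) <- vapply(curves, function(c) c$name, "")
  d <- stats::dist(mat, method = "euclidean")
  list(dist = d, hclust = stats::hclust(d, method = "ward.D2"), grid = grid)
}

#' Write a 4C profile as bedGraph
#'
#' @param p a [fourc_profile()].
#' @param path output path.
#' @export
write_profile_bedgraph <- function(p, path) {
  write_bedgraph(data.frame(chrom = p$chrom, start = p$fragments$start,
                            end = p$fragments$end,
                            value = p$fragments$signal), path)
}

#' Read a 4C profile from bedGraph
#'
#' @param path bedGraph of per-fragment scores.
#' @param viewpoint a [gi()].
#' @param name viewpoint label.
#' @export
read_profile_bedgraph <- function(path, viewpoint, name = "viewpoint") {
  bg <- read_bedgraph(path)
  fourc_profile(data.frame(start = bg$start, end = bg$end,
                           signal = bg$value),
                chrom = bg$chrom[1], viewpoint = viewpoint, name = name)
}
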