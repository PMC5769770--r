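#' Insulation diamond signal
#'
#' TopDom-style bin signal: at bin `i` the mean contact over the `w x w`
#' diamond pairing the `w` bins upstream (ending at `i`) with the `w` bins
#' downstream (starting at `i + 1`). With 40-kb bins and `w = 6` the
#' diamond spans -240 kb to +240 kb around the bin edge. The signal is
#' undefined (`NA`) where the diamond does not fit inside the window, and
#' where either side of the diamond is fully masked.
#'
#' @param m a [contact_matrix()] (normalized values recommended).
#' @param w window size in bins (`>= 1`, at most half the window).
#' @return object of class `"insulation_track"`: `signal` (per-bin, `NA`
#'   where undefined), `w`, plus grid metadata.
#' @export
insulation_signal <- function(m, w) {
  stopifnot(inherits(m, "contact_matrix"), w >= 1)
  n <- n_bins(m)
  if (w > n / 2) stop("window w larger than half the extent")
  sig <- rep(NA_real_, n)
  keep <- !m$mask
  for (i in seq_len(n)) {
    up <- (i - w + 1):i
    down <- (i + 1):(i + w)
    if (up[1] < 1 || down[w] > n) next
    ku <- up[keep[up]]; kd <- down[keep[down]]
    if (!length(ku) || !length(kd)) next    # a side fully masked
    sig[i] <- mean(m$counts[ku, kd, drop = FALSE])
  }
  structure(list(signal = sig, w = w, chrom = m$chrom, start = m$start,
                 bin_size = m$bin_size, mask = m$mask),
            class = "insulation_track")
}

#' @export
print.insulation_track <- function(x, ...) {
  cat(sprintf("Insulation track %s | w = %d bins (+/- %s bp) | %d/%d defined\n",
              x$chrom, x$w, format(diamond_span(x$w, x$bin_size),
                                   big.mark = ","),
              sum(!is.na(x$signal)), length(x$signal)))
  invisible(x)
}

#' Genomic half-span of the insulation diamond
#'
#' @param w window size in bins.
#' @param bin_size bin width in bases.
#' @return bases covered on each side of the bin edge (`w * bin_size`);
#'   e.g. `w = 6` at 40-kb bins spans +/- 240 kb.
#' @export
diamond_span <- function(w, bin_size) w * bin_size

#' Export an insulation track as a bedGraph data.frame
#'
#' @param track an [insulation_signal()] result.
#' @export
insulation_to_bedgraph <- function(track) {
  def <- which(!is.na(track$signal))
  data.frame(chrom = track$chrom,
             start = track$start + (def - 1) * track$bin_size,
             end = track$start + def * track$bin_size,
             value = track$signal[def])
}

# divide each off-diagonal by its mean over unmasked cells so the
# statistical filter compares diamond and flanking triangles free of the
# distance-decay trend
distance_scale <- function(m) {
  n <- n_bins(m)
  counts <- m$counts
  keep <- !m$mask
  scaled <- counts
  for (k in 0:(n - 1)) {
    i <- seq_len(n - k)
    j <- i + k
    ok <- keep[i] & keep[j]
    mu <- if (any(ok)) mean(counts[cbind(i[ok], j[ok])]) else 0
    if (mu > 0) {
      scaled[cbind(i, j)] <- counts[cbind(i, j)] / mu
      scaled[cbind(j, i)] <- scaled[cbind(i, j)]
    }
  }
  scaled
}

# strict local minima of a signal with NAs; plateaus resolved to the
# leftmost bin; evaluated independently within each run of defined bins
local_minima <- function(sig) {
  n <- length(sig)
  out <- integer()
  def <- !is.na(sig)
  runs <- rle(def)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in which(runs$values)) {
    idx <- starts[r]:ends[r]
    v <- sig[idx]
    if (length(v) < 3) next
    pr <- rle(v)
    pe <- cumsum(pr$lengths)
    ps <- pe - pr$lengths + 1L
    for (k in seq_along(pr$values)) {
      if (k == 1L || k == length(pr$values)) next  # run edges: no neighbour
      if (pr$values[k] < pr$values[k - 1L] &&
          pr$values[k] < pr$values[k + 1L]) {
        out <- c(out, idx[ps[k]])                  # leftmost bin of plateau
      }
    }
  }
  out
}

#' Call domains, gaps and boundaries (TopDom-style)
#'
#' Three-step procedure: (i) the insulation diamond signal at window `w`;
#' (ii) turning-point detection — strict local minima over a +/- 1 bin
#' neighbourhood, plateau ties resolved to the leftmost bin; (iii) a
#' statistical filter — the two-sided rank-sum test ([ranksum_test()]) of
#' the diamond values against the two flanking within-domain triangles,
#' after dividing each off-diagonal by its mean so the comparison is free
#' of the distance-decay trend. A minimum becomes a boundary bin when
#' `p < p_threshold` AND the scaled diamond mean falls below
#' `min_contrast` times the scaled flanking-triangle mean. The contrast
#' gate guards against the selection bias of testing at an argmin: at high
#' coverage shallow noise dips reach p < 0.05 while true boundaries
#' depress the diamond several-fold. Stretches of masked
#' bins are gaps; everything else is domain. The calls tile the window.
#'
#' @param m a normalized [contact_matrix()].
#' @param w window size in bins.
#' @param p_threshold boundary filter threshold (default 0.05).
#' @param min_contrast maximum scaled diamond/flank mean ratio for a
#'   boundary (default 0.75, i.e. at least a 25 percent insulation drop).
#' @return object of class `"domain_call_set"`: `calls` data.frame
#'   (`start`, `end`, `kind` in domain/gap/boundary_bin, bp coordinates),
#'   `boundaries` (bp start of each boundary bin), `w`, grid metadata.
#' @export
call_domains <- function(m, w, p_threshold = 0.05, min_contrast = 0.75) {
  stopifnot(inherits(m, "contact_matrix"))
  n <- n_bins(m)
  track <- insulation_signal(m, w)
  kind <- ifelse(m$mask, "gap", "domain")
  if (all(m$mask)) {
    warning("all bins masked; empty call set")
    cand <- integer()
  } else {
    cand <- local_minima(track$signal)
  }
  keep <- !m$mask
  scaled <- if (length(cand)) distance_scale(m) else m$counts
  for (i in cand) {
    up <- (i - w + 1):i
    down <- (i + 1):(i + w)
    ku <- up[keep[up]]; kd <- down[keep[down]]
    diamond <- as.vector(scaled[ku, kd, drop = FALSE])
    tri <- function(idx) {
      if (length(idx) < 2) return(numeric())
      sub <- scaled[idx, idx, drop = FALSE]
      sub[upper.tri(sub)]
    }
    flank <- c(tri(ku), tri(kd))
    if (!length(diamond) || length(flank) < 2) next
    p <- ranksum_test(diamond, flank)$p_value
    contrast_ok <- mean(flank) <= 0 ||
      mean(diamond) < min_contrast * mean(flank)
    if (p < p_threshold && contrast_ok) kind[i] <- "boundary_bin"
  }
  r <- rle(kind)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  calls <- data.frame(
    start = m$start + (starts - 1) * m$bin_size,
    end = m$start + ends * m$bin_size,
    kind = r$values)
  structure(list(calls = calls,
                 boundaries = calls$start[calls$kind == "boundary_bin"],
                 w = w, chrom = m$chrom, start = m$start,
                 bin_size = m$bin_size, n_bins = n),
            class = "domain_call_set")
}

#' @export
print.domain_call_set <- function(x, ...) {
  cat(sprintf("Domain calls (w = %d): %d domain(s), %d boundary bin(s), %d gap(s)\n",
              x$w, sum(x$calls$kind == "domain"),
              sum(x$calls$kind == "boundary_bin"),
              sum(x$calls$kind == "gap")))
  invisible(x)
}

#' Consensus TADs across caller window sizes
#'
#' Runs [call_domains()] at every window size in `window_range` and retains
#' a domain only when the exact same `(start, end)` coordinates recur in at
#' least `threshold` of the window sizes ("at least" is inclusive: with the
#' default 13 windows and 0.40, support 6 of 13 is kept, 5 is dropped).
#' Consensus boundaries are the retained domain edges.
#'
#' @param m a normalized [contact_matrix()].
#' @param window_range window sizes in bins (default `3:15`).
#' @param threshold minimum supported fraction of window sizes (default
#'   0.40).
#' @param p_threshold,min_contrast passed to [call_domains()].
#' @return a `"consensus_tad_set"`; see [consensus_from_calls()].
#' @export
consensus_tads <- function(m, window_range = 3:15, threshold = 0.40,
                           p_threshold = 0.05, min_contrast = 0.75) {
  stopifnot(length(window_range) >= 1)
  call_sets <- lapply(window_range, function(w)
    call_domains(m, w, p_threshold = p_threshold,
                 min_contrast = min_contrast))
  consensus_from_calls(call_sets, threshold = threshold)
}

#' Consensus rule on a list of per-window call sets
#'
#' The retention rule of [consensus_tads()], exposed on pre-computed (or
#' constructed) [call_domains()] outputs so the rule itself is testable.
#'
#' @param call_sets list of `"domain_call_set"` objects (one per window).
#' @param threshold minimum supported fraction of the call sets.
#' @return object of class `"consensus_tad_set"`: `tads` data.frame
#'   (`start`, `end`, `support`), `boundaries` (sorted unique retained TAD
#'   edges in bp), `n_windows`, `threshold`.
#' @export
consensus_from_calls <- function(call_sets, threshold = 0.40) {
  stopifnot(length(call_sets) >= 1)
  nw <- length(call_sets)
  doms <- do.call(rbind, lapply(call_sets, function(cs) {
    d <- cs$calls[cs$calls$kind == "domain", c("start", "end")]
    if (nrow(d)) d$w <- cs$w
    d
  }))
  if (is.null(doms) || !nrow(doms)) {
    tads <- data.frame(start = numeric(), end = numeric(),
                       support = integer())
  } else {
    key <- paste(doms$start, doms$end)
    support <- table(key)
    keep <- names(support)[as.integer(support) / nw >= threshold]
    if (length(keep)) {
      uniq <- doms[!duplicated(key) & key %in% keep, c("start", "end")]
      uniq$support <- as.integer(support[paste(uniq$start, uniq$end)])
      tads <- uniq[order(uniq$start), , drop = FALSE]
      rownames(tads) <- NULL
    } else {
      tads <- data.frame(start = numeric(), end = numeric(),
                         support = integer())
    }
  }
  structure(list(tads = tads,
                 boundaries = sort(unique(c(tads$start, tads$end))),
                 n_windows = nw, threshold = threshold,
                 chrom = call_sets[[1]]$chrom,
                 bin_size = call_sets[[1]]$bin_size),
            class = "consensus_tad_set")
}

#' @export
print.consensus_tad_set <- function(x, ...) {
  cat(sprintf("Consensus TADs: %d retained (>= %.0f%% of %d windows)\n",
              nrow(x$tads), 100 * x$threshold, x$n_windows))
  if (nrow(x$tads)) print(x$tads)
  invisible(x)
}

#' Boundary displacement between two consensus sets
#'
#' Finds the consensus boundary nearest `anchor` in each set and reports
#' the signed displacement `b - a` in bases, or `"absent"` when either set
#' has no boundary within `radius` of the anchor (e.g. fused TADs after a
#' full boundary deletion).
#'
#' @param a,b `"consensus_tad_set"` objects on the same grid.
#' @param anchor a [gi()]; its midpoint is the search centre.
#' @param radius search radius in bases (default 500 kb).
#' @return numeric displacement in bases, or the character `"absent"`.
#' @export
boundary_shift <- function(a, b, anchor, radius = 5e5) {
  stopifnot(is_gi(anchor))
  pa <- nearest_boundary(a, anchor, radius)
  pb <- nearest_boundary(b, anchor, radius)
  if (is.na(pa) || is.na(pb)) return("absent")
  pb - pa
}

#' Nearest interior consensus boundary to an anchor
#'
#' The exterior edges of the called span (window start/end) are not
#' boundaries between TADs and are excluded.
#'
#' @param set a `"consensus_tad_set"`.
#' @param anchor a [gi()]; its midpoint is the search centre.
#' @param radius search radius in bases.
#' @return boundary position (bp) or `NA` if none within `radius`.
#' @export
nearest_boundary <- function(set, anchor, radius = 5e5) {
  stopifnot(is_gi(anchor))
  centre <- (anchor$start + anchor$end) / 2
  bd <- set$boundaries
  if (length(bd) >= 2) bd <- bd[-c(1L, length(bd))]
  if (!length(bd)) return(NA_real_)
  d <- abs(bd - centre)
  if (min(d) > radius) return(NA_real_)
  bd[which.min(d)]
}

#' Export domain calls or consensus TADs as BED data.frames
#'
#' @param x a `"domain_call_set"` or `"consensus_tad_set"`.
#' @param kind for call sets, which call class to export.
#' @export
calls_to_bed <- function(x, kind = "domain") {
  if (inherits(x, "domain_call_set")) {
    d <- x$calls[x$calls$kind == kind, c("start", "end")]
    data.frame(chrom = x$chrom, start = d$start, end = d$end,
               name = sprintf("%s_w%d_%d", kind, x$w, seq_len(nrow(d))))
  } else if (inherits(x, "consensus_tad_set")) {
    data.frame(chrom = x$chrom, start = x$tads$start, end = x$tads$end,
               name = sprintf("consensus_tad_%d", seq_len(nrow(x$tads))),
               score = x$tads$support)
  } else {
    stop("unsupported object")
  }
}
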