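# evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specification of a synthetic two-TAD locus
#'
#' Generative truth for the simulators: a cis window holding two contact
#' domains separated by a boundary block of tunable permeability, with
#' power-law distance decay, optional per-bin coverage biases, enhancer
#' peaks for 4C profiles, and a fixed seed. The default geometry loosely
#' mirrors a 3-Mb limb locus: a 720-kb centromeric-like block and an
#' 880-kb telomeric-like block separated by a 2-bin (80-kb) boundary at
#' 40-kb bins.
#'
#' @param chrom chromosome name of the synthetic genome.
#' @param length window length in bases.
#' @param bin_size Hi-C bin width.
#' @param tads data.frame `start`, `end`, `intra_factor`: contact blocks
#'   and their within-block enrichment over background.
#' @param boundary a [gi()] block separating the two TADs, or `NULL` when
#'   fused.
#' @param permeability rho in `[0, 1]` scaling cross-TAD contacts
#'   (0 = perfect insulation, 1 = no boundary).
#' @param decay_exponent alpha > 0 of the `(1 + d)^-alpha` distance decay
#'   (d in bins).
#' @param biases optional positive per-bin multipliers (visibility biases);
#'   `NULL` = uniform.
#' @param coverage expected total Hi-C pair count over the window.
#' @param enhancer_peaks data.frame `position`, `amplitude`, `width`:
#'   Gaussian contact peaks added to 4C profiles (regulatory islands).
#' @param fourc_decay gamma > 0 of the 4C viewpoint distance decay
#'   (d in kilobases).
#' @param fourc_fragment_size restriction fragment size for simulated 4C.
#' @param seed RNG seed for all sampling from this spec.
#' @return object of class `"synthetic_locus_spec"`.
#' @export
synthetic_locus_spec <- function(chrom = "chrS",
                                 length = 3e6,
                                 bin_size = 4e4,
                                 tads = NULL,
                                 boundary = NULL,
                                 permeability = 0.1,
                                 decay_exponent = 1.0,
                                 biases = NULL,
                                 coverage = 2.5e5,
                                 enhancer_peaks = NULL,
                                 fourc_decay = 1.0,
                                 fourc_fragment_size = 2000,
                                 seed = 0L) {
  if (is.null(tads)) {
    tads <- data.frame(start = c(640000, 1440000),
                       end = c(1360000, 2320000),
                       intra_factor = c(3, 3))
  }
  tads <- tads[order(tads$start), , drop = FALSE]
  rownames(tads) <- NULL
  if (any(tads$start < 0 | tads$end > length)) {
    stop("TAD blocks must lie within the window")
  }
  if (nrow(tads) > 1 && any(tads$start[-1] < tads$end[-nrow(tads)])) {
    stop("TAD blocks must not overlap")
  }
  if (is.null(boundary) && nrow(tads) >= 2) {
    boundary <- gi(chrom, tads$end[1], tads$start[2])
  }
  if (is.null(enhancer_peaks)) {
    enhancer_peaks <- data.frame(position = c(900000, 1120000),
                                 amplitude = c(4, 3),
                                 width = c(20000, 15000))
  }
  stopifnot(permeability >= 0, permeability <= 1,
            decay_exponent > 0, fourc_decay > 0, coverage > 0)
  if (!is.null(biases)) {
    stopifnot(length(biases) == length %/% bin_size, all(biases > 0))
  }
  structure(list(chrom = chrom, length = as.numeric(length),
                 bin_size = as.numeric(bin_size), tads = tads,
                 boundary = boundary, permeability = permeability,
                 decay_exponent = decay_exponent, biases = biases,
                 coverage = coverage, enhancer_peaks = enhancer_peaks,
                 fourc_decay = fourc_decay,
                 fourc_fragment_size = fourc_fragment_size,
                 seed = as.integer(seed)),
            class = "synthetic_locus_spec")
}

#' @export
print.synthetic_locus_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic locus %s: %s bp, %d TAD block(s), rho = %.2g, alpha = %.2g, coverage %.3g, seed %d\n",
    x$chrom, format(x$length, big.mark = ","), nrow(x$tads),
    x$permeability, x$decay_exponent, x$coverage, x$seed))
  invisible(x)
}

# per-bin TAD membership by bin midpoint: integer block id, 0 = background
bin_tad_id <- function(spec) {
  n <- spec$length %/% spec$bin_size
  mids <- (seq_len(n) - 0.5) * spec$bin_size
  id <- integer(n)
  for (k in seq_len(nrow(spec$tads))) {
    id[mids >= spec$tads$start[k] & mids < spec$tads$end[k]] <- k
  }
  id
}

# expected contact matrix of the block model, scaled to the spec coverage
expected_hic <- function(spec) {
  n <- spec$length %/% spec$bin_size
  id <- bin_tad_id(spec)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  decay <- (1 + d)^(-spec$decay_exponent)
  tfac <- matrix(1, n, n)
  same <- outer(id, id, "==") & id > 0
  for (k in seq_len(nrow(spec$tads))) {
    sel <- id == k
    tfac[sel, sel] <- spec$tads$intra_factor[k]
  }
  cross <- outer(id, id, function(a, b) a > 0 & b > 0 & a != b)
  tfac[cross] <- spec$permeability
  b <- if (is.null(spec$biases)) rep(1, n) else spec$biases
  mu <- outer(b, b) * decay * tfac
  mu * (spec$coverage / sum(mu[upper.tri(mu, diag = TRUE)]))
}

#' Simulate a Hi-C contact matrix from a synthetic locus
#'
#' Expected counts follow `mu_ij = L * b_i * b_j * (1 + |i - j|)^-alpha *
#' T_ij`, with `T_ij` the within-block enrichment inside a TAD, the
#' permeability rho between the two TADs, and 1 elsewhere; `L` scales the
#' expected total to the spec coverage. Counts are Poisson draws under the
#' spec seed; `noiseless = TRUE` emits the expectation directly.
#'
#' @param spec a [synthetic_locus_spec()].
#' @param noiseless emit expected values instead of Poisson counts.
#' @param seed RNG seed override (defaults to `spec$seed`).
#' @return list with `matrix` (a raw [contact_matrix()]) and `truth`
#'   (boundary interval or `NULL`, TAD table, fused flag).
#' @export
simulate_hic <- function(spec, noiseless = FALSE, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_locus_spec"))
  mu <- expected_hic(spec)
  n <- nrow(mu)
  if (noiseless) {
    counts <- mu
  } else {
    counts <- with_seed(seed, {
      up <- which(upper.tri(mu, diag = TRUE))
      x <- matrix(0, n, n)
      x[up] <- stats::rpois(length(up), mu[up])
      x + t(x) - diag(diag(x))
    })
  }
  m <- contact_matrix(counts, chrom = spec$chrom, start = 0,
                      bin_size = spec$bin_size)
  list(matrix = m, truth = locus_truth(spec))
}

#' Ground truth of a synthetic locus spec
#'
#' @param spec a [synthetic_locus_spec()].
#' @return list: `boundary` ([gi()] or `NULL`), `boundary_bins` (1-based),
#'   `tads`, `fused`, `permeability`.
#' @export
locus_truth <- function(spec) {
  fused <- is.null(spec$boundary)
  bins <- if (fused) integer() else {
    lo <- floor(spec$boundary$start / spec$bin_size) + 1L
    hi <- ceiling(spec$boundary$end / spec$bin_size)
    lo:hi
  }
  list(boundary = spec$boundary, boundary_bins = bins, tads = spec$tads,
       fused = fused, permeability = spec$permeability)
}

#' Emit a simulated Hi-C matrix as mapped pair records
#'
#' Expands Poisson bin-pair counts into fragment-level pair records
#' (uniform positions inside each bin, random strands) on a regular
#' restriction map, so the full pair-to-matrix pipeline can be exercised
#' end to end. Positions keep 3 bp clear of bin edges so fragment
#' assignment with the 3-bp shift cannot cross a bin edge.
#'
#' @param spec a [synthetic_locus_spec()].
#' @param seed RNG seed override.
#' @return list with `pairs` (data.frame), `rmap` (the
#'   [restriction_map()]), `matrix` (the binned truth), `truth`.
#' @export
simulate_hic_pairs <- function(spec, seed = spec$seed) {
  sim <- simulate_hic(spec, seed = seed)
  counts <- sim$matrix$counts
  n <- nrow(counts)
  bs <- spec$bin_size
  rmap <- regular_restriction_map(spec$chrom, spec$length,
                                  spec$fourc_fragment_size)
  pairs <- with_seed(seed + 1L, {
    up <- which(upper.tri(counts, diag = TRUE) & counts > 0, arr.ind = TRUE)
    reps <- counts[cbind(up[, 1], up[, 2])]
    i <- rep(up[, 1], reps); j <- rep(up[, 2], reps)
    np <- length(i)
    pos1 <- (i - 1) * bs + 3 + floor(stats::runif(np) * (bs - 7))
    pos2 <- (j - 1) * bs + 3 + floor(stats::runif(np) * (bs - 7))
    data.frame(chrom1 = spec$chrom, pos1 = pos1,
               chrom2 = spec$chrom, pos2 = pos2,
               strand1 = sample(c("+", "-"), np, replace = TRUE),
               strand2 = sample(c("+", "-"), np, replace = TRUE))
  })
  list(pairs = pairs, rmap = rmap, matrix = sim$matrix, truth = sim$truth)
}

#' Simulate a 4C viewpoint profile from a synthetic locus
#'
#' Per-fragment expected signal proportional to `(1 + d)^-gamma` (d the
#' viewpoint distance in kilobases), multiplied by the domain factor (1 within the
#' viewpoint's TAD, rho in the opposite TAD, 1 elsewhere) and by the
#' enhancer peak profile `1 + sum(amplitude * exp(-(x - pos)^2 /
#' (2 width^2)))`. Counts are Poisson draws summing to `depth` in
#' expectation. When `cross_fraction` is given, the opposite-TAD
#' expectation is rescaled so that the expected cross-domain share of the
#' two-domain total equals it exactly (the planted leakage the domain
#' ratio should recover).
#'
#' @param spec a [synthetic_locus_spec()].
#' @param viewpoint a [gi()] inside the window.
#' @param depth expected total fragment count.
#' @param cross_fraction optional planted cross-domain fraction in `[0, 1)`.
#' @param seed RNG seed override.
#' @return list with `profile` (a [fourc_profile()]) and `truth`
#'   (`cross_fraction` expected under the model, `viewpoint_tad`).
#' @export
simulate_fourc <- function(spec, viewpoint, depth = 1e5,
                           cross_fraction = NULL, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_locus_spec"), is_gi(viewpoint))
  fs <- spec$fourc_fragment_size
  starts <- seq(0, spec$length - 1, by = fs)
  ends <- pmin(starts + fs, spec$length)
  mids <- floor((starts + ends) / 2)
  vp_mid <- gi_midpoint(viewpoint)
  d <- abs(mids - vp_mid) / 1000   # distance in kb: realistic 4C decay
  base <- (1 + d)^(-spec$fourc_decay)
  tid <- integer(length(mids))
  for (k in seq_len(nrow(spec$tads))) {
    tid[mids >= spec$tads$start[k] & mids < spec$tads$end[k]] <- k
  }
  vp_tad <- 0L
  for (k in seq_len(nrow(spec$tads))) {
    if (vp_mid >= spec$tads$start[k] && vp_mid < spec$tads$end[k]) vp_tad <- k
  }
  domfac <- rep(1, length(mids))
  if (vp_tad > 0L) domfac[tid > 0L & tid != vp_tad] <- spec$permeability
  peaks <- rep(1, length(mids))
  for (q in seq_len(nrow(spec$enhancer_peaks))) {
    pk <- spec$enhancer_peaks[q, ]
    peaks <- peaks + pk$amplitude *
      exp(-(mids - pk$position)^2 / (2 * pk$width^2))
  }
  mu <- base * domfac * peaks
  same <- tid == vp_tad & tid > 0L
  cross <- tid > 0L & tid != vp_tad
  if (!is.null(cross_fraction)) {
    stopifnot(cross_fraction >= 0, cross_fraction < 1, vp_tad > 0L)
    a <- sum(mu[same]); b <- sum(mu[cross])
    if (b > 0) {
      mu[cross] <- mu[cross] * (cross_fraction * a / ((1 - cross_fraction) * b))
    }
  }
  mu <- mu * (depth / sum(mu))
  truth_cross <- if (vp_tad > 0L) {
    sum(mu[cross]) / (sum(mu[same]) + sum(mu[cross]))
  } else {
    NA_real_
  }
  counts <- with_seed(seed, stats::rpois(length(mu), mu))
  prof <- fourc_profile(data.frame(start = starts, end = ends,
                                   signal = as.numeric(counts)),
                        chrom = spec$chrom, viewpoint = viewpoint,
                        name = sprintf("vp_%d", vp_mid))
  list(profile = prof,
       truth = list(cross_fraction = truth_cross, viewpoint_tad = vp_tad,
                    expected = mu))
}

# collapse a position through the deletions/insertions of an edit script:
# deleted positions map to the junction
collapse_pos <- function(pos, edits) {
  out <- pos
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    del <- pmax(0, pmin(e$end, pos) - e$start)
    ins <- ifelse(pos >= e$end | (e$kind == "insertion" & pos >= e$start),
                  e$inserted_length, 0)
    out <- out - del + ins
  }
  out
}

#' Apply a deletion allele to a synthetic locus spec
#'
#' Collapses the coordinates of every feature of the spec through the edit
#' script, the generative counterpart of engineering the deletion series.
#' Deleting part of the boundary block weakens it by the escalation rule
#' `rho' = rho + (1 - rho) * deleted_fraction`; deleting it entirely fuses
#' the two flanking TADs into one block (single-TAD truth). Deleting the
#' whole window is an error.
#'
#' @param spec a [synthetic_locus_spec()].
#' @param script an [edit_script()] on the spec chromosome.
#' @return list with `spec` (the mutant locus spec) and `truth`
#'   (`fused`, `permeability`, `deleted_fraction`, `boundary`).
#' @export
apply_allele <- function(spec, script) {
  stopifnot(inherits(spec, "synthetic_locus_spec"),
            inherits(script, "edit_script"))
  if (script$backbone_length != spec$length ||
      script$backbone_chrom != spec$chrom) {
    stop("edit script backbone does not match the locus spec")
  }
  ed <- script$edits
  del_total <- sum(pmax(0, ed$end - ed$start))
  ins_total <- sum(ed$inserted_length)
  new_len <- spec$length - del_total + ins_total
  if (new_len <= 0) stop("edit script deletes the whole window")
  # boundary handling
  frac <- 0
  new_boundary <- spec$boundary
  if (!is.null(spec$boundary)) {
    bw <- gi_width(spec$boundary)
    del_olap <- sum(pmax(0, pmin(ed$end, spec$boundary$end) -
                           pmax(ed$start, spec$boundary$start)))
    frac <- del_olap / bw
    s2 <- collapse_pos(spec$boundary$start, ed)
    e2 <- collapse_pos(spec$boundary$end, ed)
    new_boundary <- if (frac >= 1) NULL else gi(spec$chrom, s2, e2)
  }
  rho2 <- spec$permeability + (1 - spec$permeability) * frac
  # collapse TAD blocks; drop fully deleted ones
  t2 <- spec$tads
  t2$start <- collapse_pos(t2$start, ed)
  t2$end <- collapse_pos(t2$end, ed)
  t2 <- t2[t2$end > t2$start, , drop = FALSE]
  fused <- is.null(new_boundary)
  if (fused && nrow(t2) >= 2) {
    merged <- data.frame(start = t2$start[1], end = t2$end[nrow(t2)],
                         intra_factor = mean(t2$intra_factor))
    t2 <- merged
  }
  rownames(t2) <- NULL
  pk <- spec$enhancer_peaks
  deleted_pk <- vapply(pk$position, function(p)
    any(p >= ed$start & p < ed$end & ed$kind == "deletion"), TRUE)
  pk <- pk[!deleted_pk, , drop = FALSE]
  pk$position <- collapse_pos(pk$position, ed)
  new_spec <- synthetic_locus_spec(
    chrom = spec$chrom, length = new_len, bin_size = spec$bin_size,
    tads = t2, boundary = if (fused) NULL else new_boundary,
    permeability = if (fused) 1 else rho2,
    decay_exponent = spec$decay_exponent, biases = NULL,
    coverage = spec$coverage, enhancer_peaks = pk,
    fourc_decay = spec$fourc_decay,
    fourc_fragment_size = spec$fourc_fragment_size, seed = spec$seed)
  if (fused) new_spec$boundary <- NULL
  truth <- list(fused = fused, permeability = new_spec$permeability,
                deleted_fraction = frac, boundary = new_spec$boundary)
  list(spec = new_spec, truth = truth)
}
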