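# shared fixture builders (all data generated in code)

# random symmetric non-negative matrix on a toy grid
random_contact_matrix <- function(n, seed, bin_size = 4e4, max_count = 100) {
  set.seed(seed)
  x <- matrix(rpois(n * n, max_count / 2), n, n)
  x <- x + t(x)
  contact_matrix(x, chrom = "chrT", start = 0, bin_size = bin_size)
}

# two clean blocks with no cross-block contact
two_block_matrix <- function(n = 12, split = 6, intra = 10, bin_size = 4e4) {
  x <- matrix(0, n, n)
  x[1:split, 1:split] <- intra
  x[(split + 1):n, (split + 1):n] <- intra
  contact_matrix(x, chrom = "chrT", start = 0, bin_size = bin_size)
}

# the 100-bin locus of the acceptance world: 4-Mb window, two TADs
# separated by a 2-bin (80-kb) boundary block
spec_100bin <- function(seed, permeability = 0.1, coverage = 2.5e5) {
  synthetic_locus_spec(
    length = 4e6,
    tads = data.frame(start = c(800000, 1960000),
                      end = c(1880000, 3200000),
                      intra_factor = 3),
    permeability = permeability, coverage = coverage, seed = seed)
}

# wild-type boundary recovered within +/- 1 bin of the truth block?
boundary_within_one_bin <- function(cons, spec) {
  pos <- nearest_boundary(cons, spec$boundary)
  !is.na(pos) &&
    pos >= spec$boundary$start - spec$bin_size &&
    pos <= spec$boundary$end + spec$bin_size
}

# standard mask -> ICE processing used across tests
process_matrix <- function(raw) {
  ice_normalize(mask_bins(raw, which(suppressWarnings(compute_mask(raw)))))
}

# construct a domain_call_set without running the caller (for testing the
# consensus retention rule on hand-built per-window calls)
fake_call_set <- function(w, domains, bin_size = 4e4, chrom = "chrT") {
  calls <- data.frame(start = domains$start, end = domains$end,
                      kind = "domain")
  structure(list(calls = calls, boundaries = numeric(), w = w,
                 chrom = chrom, start = 0, bin_size = bin_size,
                 n_bins = max(domains$end) / bin_size),
            class = "domain_call_set")
}

# exhaustive two-sided rank-sum p-value by enumeration of all
# assignments of the pooled values to the two groups
enumerate_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  ew <- nx * (length(pooled) + 1) / 2
  obs <- abs(sum(r[seq_len(nx)]) - ew)
  sets <- utils::combn(length(pooled), nx)
  ws <- apply(sets, 2, function(s) sum(r[s]))
  mean(abs(ws - ew) >= obs - 1e-9)
}
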