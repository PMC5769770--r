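toy_rmap <- restriction_map("chrT", seq(0, 10000, by = 1000))

test_that("assign_fragment applies the 3-bp strand shift", {
  expect_equal(assign_fragment(998, "+", toy_rmap), 2L)   # query 1001
  expect_equal(assign_fragment(1001, "-", toy_rmap), 1L)  # query 998
  expect_equal(assign_fragment(500, "+", toy_rmap), 1L)
  # clamped at chromosome ends
  expect_equal(assign_fragment(9999, "+", toy_rmap), 10L)
  expect_equal(assign_fragment(1, "-", toy_rmap), 1L)
  expect_error(assign_fragment(10000, "+", toy_rmap), "out of")
})

test_that("classify_pairs follows same-fragment strand geometry", {
  mk <- function(p1, s1, p2, s2) {
    data.frame(chrom1 = "chrT", pos1 = p1, chrom2 = "chrT", pos2 = p2,
               strand1 = s1, strand2 = s2)
  }
  # both in fragment 7 ([6000, 7000))
  expect_equal(classify_pairs(mk(6100, "+", 6900, "-"), toy_rmap),
               "dangling_end")
  expect_equal(classify_pairs(mk(6100, "-", 6900, "+"), toy_rmap),
               "self_circle")
  expect_equal(classify_pairs(mk(6100, "+", 6900, "+"), toy_rmap),
               "error_pair")
  # canonical ordering: stored order of sides must not matter
  expect_equal(classify_pairs(mk(6900, "-", 6100, "+"), toy_rmap),
               "dangling_end")
  expect_equal(classify_pairs(mk(2100, "+", 8900, "-"), toy_rmap), "valid")
  expect_equal(classify_pairs(mk(NA, "+", 8900, "-"), toy_rmap),
               "single_side")
})

test_that("classification partitions random pair sets", {
  set.seed(20)
  n <- 2000
  pairs <- data.frame(
    chrom1 = "chrT", pos1 = sample(0:9999, n, replace = TRUE),
    chrom2 = "chrT", pos2 = sample(0:9999, n, replace = TRUE),
    strand1 = sample(c("+", "-"), n, replace = TRUE),
    strand2 = sample(c("+", "-"), n, replace = TRUE))
  pairs$pos1[sample(n, 50)] <- NA
  cls <- classify_pairs(pairs, toy_rmap)
  expect_equal(sum(table(cls)), n)
  expect_true(all(cls %in% c("valid", "single_side", "dangling_end",
                             "self_circle", "error_pair")))
})

test_that("dedupe keeps first occurrence of each exact tuple", {
  p <- data.frame(chrom1 = "chrT", pos1 = c(5, 5, 5, 5),
                  chrom2 = "chrT", pos2 = c(9, 9, 9, 9),
                  strand1 = c("+", "+", "+", "-"),
                  strand2 = c("-", "-", "-", "-"))
  out <- dedupe_pairs(p)
  expect_equal(nrow(out), 2L)          # triplicate collapses, strand variant kept
  expect_equal(out$strand1, c("+", "-"))

  # 10,000 simulated pairs with ~12% exact duplicates vs hash-set oracle
  set.seed(21)
  base <- data.frame(
    chrom1 = "chrT", pos1 = sample(0:9999, 8800, replace = TRUE),
    chrom2 = "chrT", pos2 = sample(0:9999, 8800, replace = TRUE),
    strand1 = sample(c("+", "-"), 8800, replace = TRUE),
    strand2 = sample(c("+", "-"), 8800, replace = TRUE))
  dup <- base[sample(8800, 1200, replace = TRUE), ]
  all <- rbind(base, dup)[sample(10000), ]
  oracle <- length(unique(paste(all$chrom1, all$pos1, all$strand1,
                                all$chrom2, all$pos2, all$strand2)))
  expect_equal(nrow(dedupe_pairs(all)), oracle)
})

test_that("bin_pairs bins by fragment midpoint with floor convention", {
  # fragment [74,399,000, 74,401,000): midpoint 74,400,000 -> bin 1860
  rmap <- restriction_map("chr2", c(0, 74399000, 74401000, 74800000))
  expect_equal(floor(fragment_midpoints(rmap)[2] / 4e4), 1860)
  pairs <- data.frame(chrom1 = "chr2", pos1 = 74399500,
                      chrom2 = "chr2", pos2 = 74500000,
                      strand1 = "+", strand2 = "-")
  m <- bin_pairs(pairs, rmap, bin_size = 4e4,
                 extent = gi("chr2", 74000000, 74800000))
  expect_equal(sum(m$counts[upper.tri(m$counts, diag = TRUE)]), 1)
  # the fragment midpoint, not the read position, decides the bin
  expect_equal(which(rowSums(m$counts) > 0),
               c(1860, floor(74600000 / 4e4)) - 74000000 / 4e4 + 1)
})

test_that("bin_pairs conserves pair counts and tallies discards", {
  rmap <- regular_restriction_map("chrT", 4e5, 2000)
  set.seed(22)
  n <- 1000
  pairs <- data.frame(
    chrom1 = "chrT", pos1 = sample(0:399999, n, replace = TRUE),
    chrom2 = "chrT", pos2 = sample(0:399999, n, replace = TRUE),
    strand1 = "+", strand2 = "-")
  m <- bin_pairs(pairs, rmap, bin_size = 4e4, extent = gi("chrT", 0, 4e5))
  expect_equal(sum(m$counts[upper.tri(m$counts, diag = TRUE)]), n)
  expect_equal(attr(m, "discarded"), 0L)
  m2 <- bin_pairs(pairs, rmap, bin_size = 4e4, extent = gi("chrT", 0, 2e5))
  expect_equal(sum(m2$counts[upper.tri(m2$counts, diag = TRUE)]) +
                 attr(m2, "discarded"), n)
})

test_that("compute_mask applies the 10-fold marginal rule", {
  # 4-bin toy with 200 pairs: expected marginal 2*200/4 = 100
  x <- matrix(25, 4, 4)
  x[1, ] <- x[, 1] <- 1; x[1, 1] <- 0   # bin 1 marginal far below 1/10th
  total <- sum(x[upper.tri(x, diag = TRUE)])
  x <- x * (200 / total)                 # rescale to exactly 200 pairs
  x <- (x + t(x)) / 2
  m <- contact_matrix(x, "chrT", 0, 4e4)
  mask <- suppressWarnings(compute_mask(m))
  expect_true(mask[1])
  expect_false(any(mask[2:4]))
})

test_that("compute_mask fragment-coverage rule is strict", {
  rmap <- regular_restriction_map("chrT", 4 * 4e4, 4e4 / 6)  # 6 frags/bin
  x <- matrix(50, 4, 4)
  m <- contact_matrix(x, "chrT", 0, 4e4)
  fc <- rep(2, n_fragments(rmap))
  fc[1:3] <- 0                    # bin 1: 3 of 6 fragments >= 2 reads
  expect_false(compute_mask(m, rmap, fc)[1])   # "less than half" is strict
  fc[4] <- 0                      # now 2 of 6
  expect_true(compute_mask(m, rmap, fc)[1])
})

test_that("ice_normalize balances and recovers planted biases", {
  # already balanced 2x2 matrix unchanged
  m0 <- contact_matrix(matrix(c(0, 4, 4, 0), 2), "chrT", 0, 4e4)
  out0 <- ice_normalize(m0)
  expect_equal(out0$counts, m0$counts, tolerance = 1e-8)
  expect_equal(out0$biases[1], out0$biases[2])

  # all-masked matrix errors
  mm <- contact_matrix(matrix(0, 3, 3), "chrT", 0, 4e4,
                       mask = rep(TRUE, 3))
  expect_error(ice_normalize(mm), "no unmasked bins")

  # planted biases on a balanced core: recovered up to scale
  n <- 5
  b <- c(1, 2, 0.5, 1, 1)
  # oracle: balance a decay matrix to machine tolerance by fixed-point
  core <- (1 + abs(outer(1:n, 1:n, "-")))^-1
  for (it in 1:10000) {
    s <- rowSums(core) / mean(rowSums(core))
    if (max(abs(s - 1)) < 1e-14) break
    core <- core / outer(s, s)
  }
  m <- contact_matrix(core * outer(b, b), "chrT", 0, 4e4)
  out <- ice_normalize(m, tol = 1e-9, max_iter = 2000)
  ratio <- out$biases / b
  expect_lt(max(abs(ratio / mean(ratio) - 1)), 1e-4)
  # marginal coefficient of variation and total-sum preservation
  marg <- rowSums(out$counts)
  expect_lt(stats::sd(marg) / mean(marg), 1e-8)
  expect_equal(sum(out$counts), sum(m$counts), tolerance = 1e-9)
})

test_that("ice_normalize flags non-convergence instead of failing", {
  m <- random_contact_matrix(10, seed = 23)
  expect_warning(out <- ice_normalize(m, tol = 1e-12, max_iter = 2L),
                 "did not converge")
  expect_false(attr(out, "converged"))
  expect_true(is.finite(attr(out, "final_deviation")))
})

test_that("subtraction is zero on identity and antisymmetric", {
  a <- process_matrix(random_contact_matrix(20, seed = 24))
  b <- process_matrix(random_contact_matrix(20, seed = 25))
  z <- subtract_matrices(a, a)
  expect_true(all(z$delta[!z$mask, !z$mask] == 0))
  ab <- subtract_matrices(a, b); ba <- subtract_matrices(b, a)
  expect_equal(ab$delta, -ba$delta)
  expect_error(
    subtract_matrices(a, process_matrix(random_contact_matrix(10, seed = 26))),
    "grid")
  expect_error(subtract_matrices(a, random_contact_matrix(20, seed = 27)),
               "normalized")
})

test_that("rank-sum test matches exhaustive enumeration on small samples", {
  res <- ranksum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 2 / 20)  # only the two extreme assignments
  expect_equal(res$p_value, enumerate_ranksum_p(c(1, 2, 3), c(4, 5, 6)))
  # with ties, against the same enumeration oracle
  set.seed(28)
  for (k in 1:25) {
    x <- sample(1:4, 3, replace = TRUE)
    y <- sample(1:4, 4, replace = TRUE)
    expect_equal(ranksum_test(x, y)$p_value, enumerate_ranksum_p(x, y),
                 info = paste(c(x, "|", y), collapse = " "))
  }
})

test_that("compare_domain_intensity tests off-diagonal domain values", {
  mk <- function(v) {
    x <- matrix(0, 3, 3)
    x[upper.tri(x)] <- v
    contact_matrix(x + t(x), "chrT", 0, 4e4, normalized = TRUE)
  }
  dom <- gi("chrT", 0, 12e4)
  cmp <- compare_domain_intensity(mk(c(1, 2, 3)), mk(c(4, 5, 6)), dom)
  expect_equal(cmp$p_value, 0.1)
  same <- compare_domain_intensity(mk(c(1, 2, 3)), mk(c(1, 2, 3)), dom)
  expect_equal(same$p_value, 1)
  expect_error(
    compare_domain_intensity(mk(1:3), mk(1:3), gi("chrT", 0, 4e4)),
    "fewer than 2")
})

test_that("a 1.5x domain factor is detected at realistic bin counts", {
  # two Poisson matrices, one with 1.5x within-domain intensity
  hits <- 0
  n <- 40
  dom <- gi("chrT", 0, n * 4e4)
  for (s in 1:20) {
    set.seed(400 + s)
    base <- matrix(rpois(n * n, 50), n, n); base <- base + t(base)
    up <- matrix(rpois(n * n, 75), n, n); up <- up + t(up)
    a <- contact_matrix(base, "chrT", 0, 4e4, normalized = TRUE)
    b <- contact_matrix(up, "chrT", 0, 4e4, normalized = TRUE)
    hits <- hits + (compare_domain_intensity(a, b, dom)$p_value < 0.05)
  }
  expect_gte(hits, 19)
})

test_that("simulated pair emission feeds the binning pipeline exactly", {
  spec <- synthetic_locus_spec(length = 1e6, coverage = 2e4,
                               tads = data.frame(start = c(1e5, 5.4e5),
                                                 end = c(4.6e5, 9e5),
                                                 intra_factor = 3),
                               seed = 5)
  sim <- simulate_hic_pairs(spec)
  cls <- classify_pairs(sim$pairs, sim$rmap)
  m <- bin_pairs(sim$pairs[cls == "valid", ], sim$rmap,
                 bin_size = spec$bin_size, extent = gi(spec$chrom, 0, 1e6))
  # every valid pair lands in the bin pair that generated it
  keep <- cls == "valid"
  truth <- sim$matrix$counts
  b1 <- sim$pairs$pos1[keep] %/% spec$bin_size
  b2 <- sim$pairs$pos2[keep] %/% spec$bin_size
  expect_equal(sum(m$counts[upper.tri(m$counts, diag = TRUE)]), sum(keep))
  for (k in sample(which(truth > 0), 10)) {
    ij <- arrayInd(k, dim(truth))
    expect_lte(m$counts[ij[1], ij[2]], truth[ij[1], ij[2]])
  }
})
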