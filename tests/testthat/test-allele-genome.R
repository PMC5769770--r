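random_sequence <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("edit script validation catches bad edits by label", {
  expect_error(
    edit_script("chr1", 1000, data.frame(
      label = c("a", "b"), kind = "deletion", chrom = "chr1",
      start = c(100, 150), end = c(200, 250), inserted_length = 0)),
    "'a' and 'b' overlap")
  expect_error(
    edit_script("chr1", 1000, data.frame(
      label = "offend", kind = "deletion", chrom = "chr1",
      start = 900, end = 1100, inserted_length = 0)),
    "'offend'.*outside backbone")
  expect_error(
    edit_script("chr1", 1000, data.frame(
      label = "anchored", kind = "insertion", chrom = "chr1",
      start = 100, end = 200, inserted_length = 50)),
    "zero-width")
})

test_that("build_mutant applies single deletion with exact arithmetic", {
  seq <- random_sequence(1e6, seed = 11)
  sc <- edit_script("chr1", 1e6, data.frame(
    label = "del", kind = "deletion", chrom = "chr1",
    start = 400000, end = 760000, inserted_length = 0))
  res <- build_mutant(seq, sc)
  expect_equal(nchar(res$sequence), 640000)
  expect_equal(lift_position(res$map, 800000, "wt_to_mut"), 440000)
  expect_equal(res$map$mut_length, 640000)
})

test_that("empty edit script yields identity", {
  seq <- random_sequence(5000, seed = 12)
  sc <- edit_script("chr1", 5000)
  res <- build_mutant(seq, sc)
  expect_identical(res$sequence, seq)
  expect_equal(nrow(res$map$blocks), 1L)
  expect_equal(lift_position(res$map, c(0, 2500, 4999), "wt_to_mut"),
               c(0, 2500, 4999))
})

test_that("deletion plus cassette matches independent string splicing", {
  seq <- random_sequence(1e6, seed = 13)
  set.seed(14)
  cassette <- paste(sample(c("A", "C", "G", "T"), 8000, replace = TRUE),
                    collapse = "")
  sc <- edit_script("chr1", 1e6, data.frame(
    label = "del_ins", kind = "deletion", chrom = "chr1",
    start = 400000, end = 760000, inserted_length = 8000,
    inserted_sequence = cassette))
  res <- build_mutant(seq, sc)
  # oracle: splice the strings by hand
  oracle <- paste0(substr(seq, 1, 400000), cassette,
                   substr(seq, 760001, 1e6))
  expect_identical(res$sequence, oracle)
  expect_equal(nchar(res$sequence), 648000)
  expect_equal(lift_position(res$map, 800000, "wt_to_mut"), 448000)
  # oracle: locate the 20-mer flanking wt position 800,000 in the mutant
  kmer <- substr(seq, 800001, 800020)
  hit <- regexpr(kmer, res$sequence, fixed = TRUE)
  expect_equal(as.integer(hit) - 1L, 448000)
})

test_that("lift_position handles deletions and round trips", {
  sc <- edit_script("chr2", 8e7, data.frame(
    label = "del", kind = "deletion", chrom = "chr2",
    start = 74400000, end = 74760000, inserted_length = 0))
  map <- coordinate_map(sc)
  expect_equal(lift_position(map, 75000000, "wt_to_mut"), 74640000)
  expect_true(is.na(lift_position(map, 74500000, "wt_to_mut")))
  expect_error(lift_position(map, 9e7, "wt_to_mut"), "out of range")
  # round trip on 1,000 random positions outside the edit
  set.seed(15)
  pos <- sample(c(0:74399999, 74760000:(8e7 - 1)), 1000)
  lifted <- lift_position(map, pos, "wt_to_mut")
  expect_false(anyNA(lifted))
  expect_equal(lift_position(map, lifted, "mut_to_wt"), pos)
})

test_that("lift_interval maps block-contained intervals only", {
  sc <- edit_script("chr2", 1e6, data.frame(
    label = "del", kind = "deletion", chrom = "chr2",
    start = 400000, end = 500000, inserted_length = 0))
  map <- coordinate_map(sc)
  out <- lift_interval(map, gi("chr2", 600000, 700000), "wt_to_mut")
  expect_equal(c(out$start, out$end), c(500000, 600000))
  expect_null(lift_interval(map, gi("chr2", 350000, 450000), "wt_to_mut"))
})

test_that("lift_matrix_to_backbone drops exactly the deleted bins", {
  # 40-kb bins, deletion spanning 360 kb = 9 bins
  sc <- edit_script("chr2", 8e7, data.frame(
    label = "del", kind = "deletion", chrom = "chr2",
    start = 74400000, end = 74760000, inserted_length = 0))
  map <- coordinate_map(sc)
  n_mut <- (8e7 - 360000) / 4e4
  m <- random_contact_matrix(n_mut, seed = 16)
  m$chrom <- "chr2"
  res <- lift_matrix_to_backbone(m, map)
  expect_length(res$dropped_bins, 9L)
  expect_true(all(res$matrix$mask[res$dropped_bins]))
  expect_true(all(res$matrix$counts[res$dropped_bins, ] == 0))

  # identity map: unchanged, nothing dropped
  m2 <- random_contact_matrix(20, seed = 17)
  id_map2 <- coordinate_map(edit_script("chrT", 20 * 4e4))
  res2 <- lift_matrix_to_backbone(m2, id_map2)
  expect_equal(res2$matrix$counts, m2$counts)
  expect_length(res2$dropped_bins, 0L)
})

test_that("lifting a binned matrix equals re-binning lifted pairs", {
  # 100-bin wild-type genome, 10-bin deletion
  bs <- 1000
  wt_len <- 100 * bs
  sc <- edit_script("chrT", wt_len, data.frame(
    label = "del", kind = "deletion", chrom = "chrT",
    start = 40 * bs, end = 50 * bs, inserted_length = 0))
  map <- coordinate_map(sc)
  set.seed(18)
  n_pairs <- 5000
  mut_len <- wt_len - 10 * bs
  p1 <- sample.int(mut_len, n_pairs) - 1L
  p2 <- sample.int(mut_len, n_pairs) - 1L
  # mutant-genome matrix by direct position binning
  bin_mat <- function(a, b, n) {
    x <- matrix(0, n, n)
    for (k in seq_along(a)) {
      i <- a[k] + 1L; j <- b[k] + 1L
      x[i, j] <- x[i, j] + 1
      if (i != j) x[j, i] <- x[j, i] + 1
    }
    x
  }
  mut_m <- contact_matrix(bin_mat(p1 %/% bs, p2 %/% bs, 90),
                          chrom = "chrT", start = 0, bin_size = bs)
  lifted <- lift_matrix_to_backbone(mut_m, map)
  # oracle: lift each pair position, then bin on the wild-type grid
  w1 <- lift_position(map, p1, "mut_to_wt")
  w2 <- lift_position(map, p2, "mut_to_wt")
  wt_oracle <- bin_mat(w1 %/% bs, w2 %/% bs, 100)
  keep <- setdiff(seq_len(100), lifted$dropped_bins)
  expect_equal(lifted$matrix$counts[keep, keep], wt_oracle[keep, keep])
  expect_equal(lifted$dropped_bins, 41:50)
  # counts conserved outside dropped rows/cols
  expect_equal(sum(lifted$matrix$counts), sum(wt_oracle[keep, keep]))
})

test_that("binning-then-lifting equals lifting-then-binning off junctions", {
  bs <- 1000
  sc <- edit_script("chrT", 1e5, data.frame(
    label = "del", kind = "deletion", chrom = "chrT",
    start = 20000, end = 28000, inserted_length = 0))
  map <- coordinate_map(sc)
  expect_error(
    lift_matrix_to_backbone(
      contact_matrix(matrix(0, 10, 10), "chrT", 0, 3000), map),
    "incompatible")
})

test_that("edit scripts round-trip through TSV", {
  sc <- edit_script("chr1", 1e6, data.frame(
    label = c("del1", "ins1"), kind = c("deletion", "insertion"),
    chrom = "chr1", start = c(1000, 50000), end = c(2000, 50000),
    inserted_length = c(0, 300)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edit_script(sc, path)
  back <- read_edit_script(path)
  expect_equal(back$backbone_length, sc$backbone_length)
  expect_equal(back$edits$start, sc$edits$start)
  expect_equal(back$edits$inserted_length, sc$edits$inserted_length)
})
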