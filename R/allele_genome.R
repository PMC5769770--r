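#' Edit script: an ordered set of deletions/insertions on a backbone
#'
#' An edit script describes a mutant allele as a list of non-overlapping
#' edits on a backbone chromosome, sorted by wild-type start. A deletion
#' removes `[start, end)`; it may carry a replacement cassette
#' (`inserted_length > 0`), modelling transgene knock-ins where a reporter
#' cassette replaces the deleted span. A pure insertion has a zero-width
#' anchor (`start == end`).
#'
#' @param backbone_chrom backbone chromosome name.
#' @param backbone_length backbone length in bases.
#' @param edits `NULL` or a data.frame with columns `label`, `kind`
#'   (`"deletion"`/`"insertion"`), `chrom`, `start`, `end`,
#'   `inserted_length`, and optional `inserted_sequence` (explicit cassette
#'   sequence; when absent an N-fill of `inserted_length` is used).
#' @return an object of class `"edit_script"`.
#' @export
edit_script <- function(backbone_chrom, backbone_length, edits = NULL) {
  if (is.null(edits) || nrow(edits) == 0L) {
    edits <- data.frame(label = character(), kind = character(),
                        chrom = character(), start = numeric(),
                        end = numeric(), inserted_length = numeric(),
                        inserted_sequence = character())
  }
  if (is.null(edits$inserted_sequence)) edits$inserted_sequence <- ""
  edits$inserted_sequence[is.na(edits$inserted_sequence)] <- ""
  edits <- edits[order(edits$start), , drop = FALSE]
  rownames(edits) <- NULL
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    if (!e$kind %in% c("deletion", "insertion")) {
      stop(sprintf("edit '%s': unknown kind '%s'", e$label, e$kind))
    }
    if (e$chrom != backbone_chrom) {
      stop(sprintf("edit '%s': chrom '%s' is not the backbone '%s'",
                   e$label, e$chrom, backbone_chrom))
    }
    if (e$kind == "insertion" && e$start != e$end) {
      stop(sprintf("edit '%s': insertion anchor must be zero-width",
                   e$label))
    }
    if (e$kind == "deletion" && e$start >= e$end) {
      stop(sprintf("edit '%s': deletion must have start < end", e$label))
    }
    if (e$start < 0 || e$end > backbone_length) {
      stop(sprintf("edit '%s': outside backbone [0, %.0f)",
                   e$label, backbone_length))
    }
    if (nzchar(e$inserted_sequence) &&
        nchar(e$inserted_sequence) != e$inserted_length) {
      stop(sprintf("edit '%s': inserted_sequence length != inserted_length",
                   e$label))
    }
    if (i > 1L && e$start < edits$end[i - 1L]) {
      stop(sprintf("edits '%s' and '%s' overlap",
                   edits$label[i - 1L], e$label))
    }
  }
  structure(list(backbone_chrom = backbone_chrom,
                 backbone_length = as.numeric(backbone_length),
                 edits = edits),
            class = "edit_script")
}

#' @export
print.edit_script <- function(x, ...) {
  cat(sprintf("Edit script on %s (length %s): %d edit(s)\n",
              x$backbone_chrom,
              format(x$backbone_length, big.mark = ","), nrow(x$edits)))
  if (nrow(x$edits)) {
    print(x$edits[, c("label", "kind", "start", "end", "inserted_length")])
  }
  invisible(x)
}

#' Exact coordinate map induced by an edit script
#'
#' Decomposes the wild-type/mutant correspondence into ordered collinear
#' ungapped blocks plus the wild-type segments with no mutant image
#' (deletions) and the mutant segments with no wild-type image (inserted
#' cassettes). Within a block the mapping is offset-only, so liftover is
#' exact in both directions.
#'
#' @param script an [edit_script()].
#' @return an object of class `"coord_map"` with elements `blocks`
#'   (data.frame `wt_start`, `wt_end`, `mut_start`, `mut_end`), `deleted`,
#'   `inserted`, `wt_length`, `mut_length`, `chrom`.
#' @export
coordinate_map <- function(script) {
  stopifnot(inherits(script, "edit_script"))
  L <- script$backbone_length
  ed <- script$edits
  blocks <- list(); deleted <- list(); inserted <- list()
  wt_cursor <- 0; mut_cursor <- 0
  for (i in seq_len(nrow(ed))) {
    e <- ed[i, ]
    if (e$start > wt_cursor) {           # collinear block before the edit
      w <- e$start - wt_cursor
      blocks[[length(blocks) + 1L]] <-
        c(wt_cursor, e$start, mut_cursor, mut_cursor + w)
      mut_cursor <- mut_cursor + w
    }
    if (e$end > e$start) {               # deleted span
      deleted[[length(deleted) + 1L]] <- c(e$start, e$end, i)
    }
    if (e$inserted_length > 0) {         # cassette with no wt image
      inserted[[length(inserted) + 1L]] <-
        c(mut_cursor, mut_cursor + e$inserted_length, i)
      mut_cursor <- mut_cursor + e$inserted_length
    }
    wt_cursor <- e$end
  }
  if (wt_cursor < L) {
    blocks[[length(blocks) + 1L]] <-
      c(wt_cursor, L, mut_cursor, mut_cursor + (L - wt_cursor))
    mut_cursor <- mut_cursor + (L - wt_cursor)
  }
  to_df <- function(lst, nm) {
    if (!length(lst)) {
      return(stats::setNames(data.frame(numeric(), numeric(), integer()),
                             c(nm, "edit")) )
    }
    m <- do.call(rbind, lst)
    stats::setNames(data.frame(m), c(nm, "edit"))
  }
  bl <- if (length(blocks)) {
    stats::setNames(data.frame(do.call(rbind, blocks)),
                    c("wt_start", "wt_end", "mut_start", "mut_end"))
  } else {
    data.frame(wt_start = numeric(), wt_end = numeric(),
               mut_start = numeric(), mut_end = numeric())
  }
  structure(list(chrom = script$backbone_chrom,
                 blocks = bl,
                 deleted = to_df(deleted, c("wt_start", "wt_end")),
                 inserted = to_df(inserted, c("mut_start", "mut_end")),
                 wt_length = L, mut_length = mut_cursor,
                 edits = ed),
            class = "coord_map")
}

#' @export
print.coord_map <- function(x, ...) {
  cat(sprintf(
    "Coordinate map %s: wt %s -> mut %s; %d block(s), %d deletion(s), %d insertion(s)\n",
    x$chrom, format(x$wt_length, big.mark = ","),
    format(x$mut_length, big.mark = ","),
    nrow(x$blocks), nrow(x$deleted), nrow(x$inserted)))
  invisible(x)
}

#' Build an in silico mutant chromosome
#'
#' Splices a backbone nucleotide sequence according to an edit script,
#' exactly as one builds a mutant genome to map reads from a rearranged
#' allele without gaps at the breakpoints. Cassettes without an explicit
#' sequence are N-filled at their stated length.
#'
#' @param backbone_sequence backbone nucleotide string (single character
#'   scalar); its length must equal the script's backbone length.
#' @param script an [edit_script()].
#' @return list with `sequence` (mutant nucleotide string) and `map`
#'   (a [coordinate_map()]).
#' @examples
#' sc <- edit_script("chrS", 100, data.frame(
#'   label = "del", kind = "deletion", chrom = "chrS",
#'   start = 40, end = 76, inserted_length = 0))
#' res <- build_mutant(paste(rep("ACGT", 25), collapse = ""), sc)
#' nchar(res$sequence)  # 64
#' @export
build_mutant <- function(backbone_sequence, script) {
  stopifnot(inherits(script, "edit_script"))
  if (nchar(backbone_sequence) != script$backbone_length) {
    stop(sprintf("backbone sequence length (%d) != script backbone length (%.0f)",
                 nchar(backbone_sequence), script$backbone_length))
  }
  map <- coordinate_map(script)
  pieces <- character()
  ed <- script$edits
  wt_cursor <- 0
  for (i in seq_len(nrow(ed))) {
    e <- ed[i, ]
    if (e$start > wt_cursor) {
      pieces <- c(pieces, substr(backbone_sequence, wt_cursor + 1, e$start))
    }
    if (e$inserted_length > 0) {
      cassette <- if (nzchar(e$inserted_sequence)) {
        e$inserted_sequence
      } else {
        strrep("N", e$inserted_length)
      }
      pieces <- c(pieces, cassette)
    }
    wt_cursor <- e$end
  }
  if (wt_cursor < script$backbone_length) {
    pieces <- c(pieces, substr(backbone_sequence, wt_cursor + 1,
                               script$backbone_length))
  }
  seq <- paste(pieces, collapse = "")
  stopifnot(nchar(seq) == map$mut_length)
  list(sequence = seq, map = map)
}

#' Lift positions between wild-type and mutant coordinates
#'
#' @param map a [coordinate_map()].
#' @param pos vector of base positions (0-based).
#' @param direction `"wt_to_mut"` or `"mut_to_wt"`.
#' @return numeric vector of lifted positions; `NA` where the position lies
#'   in a deleted (resp. inserted) segment with no image.
#' @export
lift_position <- function(map, pos, direction = c("wt_to_mut", "mut_to_wt")) {
  direction <- match.arg(direction)
  stopifnot(inherits(map, "coord_map"))
  src_len <- if (direction == "wt_to_mut") map$wt_length else map$mut_length
  if (any(pos < 0 | pos >= src_len)) {
    stop(sprintf("position out of range [0, %.0f)", src_len))
  }
  bl <- map$blocks
  if (direction == "wt_to_mut") {
    s <- bl$wt_start; e <- bl$wt_end; off <- bl$mut_start - bl$wt_start
  } else {
    s <- bl$mut_start; e <- bl$mut_end; off <- bl$wt_start - bl$mut_start
  }
  out <- rep(NA_real_, length(pos))
  idx <- findInterval(pos, s)
  hit <- idx >= 1L & pos < e[pmax(idx, 1L)]
  out[hit] <- pos[hit] + off[idx[hit]]
  out
}

#' Lift an interval between genomes
#'
#' Lifts an interval whose span lies entirely within one collinear block.
#'
#' @inheritParams lift_position
#' @param interval a [gi()] on the source genome.
#' @return a [gi()] on the target genome, or `NULL` if the interval has no
#'   single-block image (it overlaps an edit).
#' @export
lift_interval <- function(map, interval,
                          direction = c("wt_to_mut", "mut_to_wt")) {
  direction <- match.arg(direction)
  bl <- map$blocks
  if (direction == "wt_to_mut") {
    s <- bl$wt_start; e <- bl$wt_end; off <- bl$mut_start - bl$wt_start
  } else {
    s <- bl$mut_start; e <- bl$mut_end; off <- bl$wt_start - bl$mut_start
  }
  k <- which(interval$start >= s & interval$end <= e)
  if (!length(k)) return(NULL)
  gi(map$chrom, interval$start + off[k[1]], interval$end + off[k[1]])
}

#' Reframe a mutant contact matrix onto the wild-type bin grid
#'
#' Places the bins of a matrix computed on a mutant (deletion) genome back
#' onto the wild-type grid so mutant and wild-type matrices can be compared
#' and subtracted. Wild-type bins with no mutant image (deleted spans, and
#' bins straddling a breakpoint) are dropped: flagged in `dropped_bins`,
#' masked, and zeroed. Apply [mask_bins()] with the same `dropped_bins` to
#' the wild-type matrix so the pair is comparable before normalization.
#'
#' @param mut_matrix a [contact_matrix()] on the mutant genome, whose extent
#'   must start at a position that maps block-wise onto the wild-type grid.
#' @param map a [coordinate_map()].
#' @return list with `matrix` (a [contact_matrix()] on the wild-type grid)
#'   and `dropped_bins` (1-based wild-type bin indices with no image).
#' @export
lift_matrix_to_backbone <- function(mut_matrix, map) {
  stopifnot(inherits(mut_matrix, "contact_matrix"), inherits(map, "coord_map"))
  bs <- mut_matrix$bin_size
  # offsets between paired block starts must be bin-size multiples,
  # otherwise downstream mutant bins interleave two wild-type bins
  off <- map$blocks$mut_start - map$blocks$wt_start
  if (any(off %% bs != 0)) {
    bad <- which(off %% bs != 0)
    stop(sprintf(
      "bin size %.0f incompatible with block offsets (blocks %s): deletions/insertions must be bin-size multiples",
      bs, paste(bad, collapse = ", ")))
  }
  n_wt <- ceiling(map$wt_length / bs)
  wt_start_bin <- 0
  wt_bins_start <- (seq_len(n_wt) - 1) * bs
  wt_bins_end <- pmin(wt_bins_start + bs, map$wt_length)
  # map each wt bin to a mutant bin index in mut_matrix, or NA
  mut_image <- rep(NA_real_, n_wt)
  bl <- map$blocks
  for (k in seq_len(nrow(bl))) {
    inside <- wt_bins_start >= bl$wt_start[k] & wt_bins_end <= bl$wt_end[k]
    mut_image[inside] <- wt_bins_start[inside] + (bl$mut_start[k] - bl$wt_start[k])
  }
  # restrict to the extent covered by mut_matrix
  m0 <- mut_matrix$start
  nm <- n_bins(mut_matrix)
  mut_bin_idx <- ifelse(!is.na(mut_image) & mut_image >= m0 &
                          mut_image < m0 + nm * bs,
                        (mut_image - m0) / bs + 1, NA_real_)
  # the wild-type frame covers the lifted extent of the mutant window
  covered <- which(!is.na(mut_bin_idx))
  if (!length(covered)) stop("mutant matrix extent has no wild-type image")
  lo <- min(covered); hi <- max(covered)
  # include interior wt bins with no image (the deletion itself)
  frame <- lo:hi
  nf <- length(frame)
  counts <- matrix(0, nf, nf)
  mask <- rep(FALSE, nf)
  src <- mut_bin_idx[frame]
  has <- !is.na(src)
  counts[has, has] <- mut_matrix$counts[src[has], src[has]]
  mask[!has] <- TRUE
  mask[has] <- mut_matrix$mask[src[has]]
  counts[mask, ] <- 0; counts[, mask] <- 0
  out <- contact_matrix(counts, chrom = map$chrom,
                        start = wt_bins_start[lo], bin_size = bs,
                        mask = mask, normalized = mut_matrix$normalized)
  list(matrix = out, dropped_bins = which(!has))
}
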