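#' Read / write BED intervals
#'
#' Plain BED3+ I/O. BED is natively 0-based half-open, matching the
#' package-wide convention, so no coordinate shifting happens here.
#'
#' @param path file path.
#' @return `read_bed`: a `data.frame` with columns `chrom`, `start`, `end`
#'   and, when present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          skip = "\t", fill = TRUE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(dt, cols[seq_len(min(ncol(dt), 6L))])
  as.data.frame(dt)
}

#' @rdname read_bed
#' @param x data.frame with at least chrom/start/end.
#' @export
write_bed <- function(x, path) {
  keep <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  data.table::fwrite(x[, keep, drop = FALSE], path, sep = "\t",
                     col.names = FALSE, quote = FALSE, scipen = 50L)
  invisible(path)
}

#' Read / write bedGraph tracks
#'
#' Four-column bedGraph (chrom, start, end, value); a leading `track` line
#' is tolerated on input and never written.
#'
#' @param path file path.
#' @export
read_bedgraph <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- if (length(first) && grepl("^(track|#)", first)) 1L else 0L
  dt <- data.table::fread(path, header = FALSE, sep = "\t", skip = skip)
  data.table::setnames(dt, c("chrom", "start", "end", "value"))
  as.data.frame(dt)
}

#' @rdname read_bedgraph
#' @param x data.frame with chrom/start/end/value.
#' @export
write_bedgraph <- function(x, path) {
  data.table::fwrite(x[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", col.names = FALSE, quote = FALSE,
                     scipen = 50L)
  invisible(path)
}

#' Read / write Hi-C pair records
#'
#' 4DN `.pairs`-style six-column TSV: `chrom1 pos1 chrom2 pos2 strand1
#' strand2`. Comment lines starting with `#` are skipped on input.
#'
#' @param path file path.
#' @return a `data.frame` of pair records.
#' @export
read_pairs <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", skip = "\t")
  if (ncol(dt) < 6L) stop("pairs file must have >= 6 columns")
  dt <- dt[, 1:6]
  data.table::setnames(dt, c("chrom1", "pos1", "chrom2", "pos2",
                             "strand1", "strand2"))
  as.data.frame(dt)
}

#' @rdname read_pairs
#' @param x pair data.frame.
#' @export
write_pairs <- function(x, path) {
  data.table::fwrite(
    x[, c("chrom1", "pos1", "chrom2", "pos2", "strand1", "strand2")],
    path, sep = "\t", col.names = FALSE, quote = FALSE, scipen = 50L)
  invisible(path)
}

#' Write / read a contact matrix as text
#'
#' Two plain-text layouts are supported, both carrying an embedded header of
#' `#key=value` lines (chrom, start, bin_size, n_bins, normalized, masked
#' bin indices):
#' \describe{
#'   \item{dense}{tab-separated `n x n` matrix of values.}
#'   \item{sparse}{upper-triangle triplets `bin1 bin2 value` (1-based bin
#'     indices), zeros omitted.}
#' }
#'
#' @param m a [contact_matrix()].
#' @param path output path.
#' @param format `"dense"` or `"sparse"`.
#' @export
write_matrix <- function(m, path, format = c("dense", "sparse")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "contact_matrix"))
  hdr <- c(
    sprintf("#chrom=%s", m$chrom),
    sprintf("#start=%.0f", m$start),
    sprintf("#bin_size=%.0f", m$bin_size),
    sprintf("#n_bins=%d", n_bins(m)),
    sprintf("#normalized=%s", if (isTRUE(m$normalized)) "true" else "false"),
    sprintf("#format=%s", format),
    sprintf("#masked=%s", paste(which(m$mask), collapse = ","))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (format == "dense") {
    utils::write.table(m$counts, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  } else {
    idx <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0,
                 arr.ind = TRUE)
    utils::write.table(
      data.frame(bin1 = idx[, 1], bin2 = idx[, 2],
                 value = m$counts[idx]),
      con, sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  hdr_n <- sum(startsWith(lines, "#"))
  hdr <- lines[seq_len(hdr_n)]
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(p) {
    if (length(p) >= 2) paste(p[-1], collapse = "=") else ""
  }, ""), vapply(kv, `[`, "", 1))
  n <- as.integer(vals[["n_bins"]])
  fmt <- vals[["format"]]
  body <- lines[-seq_len(hdr_n)]
  if (fmt == "dense") {
    counts <- as.matrix(utils::read.table(text = body, sep = "\t"))
    dimnames(counts) <- NULL
  } else {
    counts <- matrix(0, n, n)
    if (length(body)) {
      trip <- utils::read.table(text = body, sep = "\t")
      counts[cbind(trip[, 1], trip[, 2])] <- trip[, 3]
      counts[cbind(trip[, 2], trip[, 1])] <- trip[, 3]
    }
  }
  mask <- rep(FALSE, n)
  if (nzchar(vals[["masked"]])) {
    mask[as.integer(strsplit(vals[["masked"]], ",")[[1]])] <- TRUE
  }
  contact_matrix(counts,
                 chrom = vals[["chrom"]],
                 start = as.numeric(vals[["start"]]),
                 bin_size = as.numeric(vals[["bin_size"]]),
                 mask = mask,
                 normalized = identical(vals[["normalized"]], "true"))
}

#' Read / write an edit script as TSV
#'
#' Columns: `label`, `kind` (deletion/insertion), `chrom`, `start`, `end`,
#' `inserted_length`, `inserted_sequence` (`.` when absent). A `#backbone=`
#' header line records the backbone chromosome and length.
#'
#' @param script an [edit_script()].
#' @param path file path.
#' @export
write_edit_script <- function(script, path) {
  stopifnot(inherits(script, "edit_script"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#backbone=%s:%.0f", script$backbone_chrom,
                     script$backbone_length), con)
  ed <- script$edits
  ed$inserted_sequence[!nzchar(ed$inserted_sequence)] <- "."
  utils::write.table(ed, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edit_script
#' @export
read_edit_script <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#backbone=")]
  if (!length(hdr)) stop("edit script missing #backbone= header")
  bb <- strsplit(sub("^#backbone=", "", hdr[1]), ":", fixed = TRUE)[[1]]
  body <- lines[!startsWith(lines, "#")]
  if (length(body)) {
    ed <- utils::read.table(text = body, sep = "\t",
                            col.names = c("label", "kind", "chrom", "start",
                                          "end", "inserted_length",
                                          "inserted_sequence"),
                            colClasses = c("character", "character",
                                           "character", "numeric", "numeric",
                                           "numeric", "character"))
    ed$inserted_sequence[ed$inserted_sequence == "."] <- ""
  } else {
    ed <- NULL
  }
  edit_script(backbone_chrom = bb[1], backbone_length = as.numeric(bb[2]),
              edits = ed)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers around `Biostrings` when available, with a plain-text
#' fallback, returning/accepting named character vectors.
#'
#' @param path file path.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readDNAStringSet(path)
    stats::setNames(as.character(ss), names(ss))
  } else {
    lines <- readLines(path)
    idx <- grep("^>", lines)
    starts <- idx + 1L
    ends <- c(idx[-1] - 1L, length(lines))
    seqs <- mapply(function(s, e) paste(lines[s:e], collapse = ""),
                   starts, ends)
    stats::setNames(seqs, sub("^>\\s*", "", sub("\\s.*$", "", lines[idx])))
  }
}

#' @rdname read_fasta
#' @param x named character vector of sequences.
#' @export
write_fasta <- function(x, path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(x)) {
      writeLines(paste0(">", names(x)[i]), con)
      writeLines(substring(x[i], seq(1, nchar(x[i]), 70),
                           pmin(seq(1, nchar(x[i]), 70) + 69, nchar(x[i]))),
                 con)
    }
  }
  invisible(path)
}
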