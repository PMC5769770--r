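#' Run configuration for the comparison workbench
#'
#' Flat key=value configuration driving [run_comparison()]. Required keys:
#' `preset` (`wildtype`, `del-partial`, or `del-full`: which allele to
#' compare against the wild-type locus), `seed`, `out_dir`. Optional keys
#' (defaults in parentheses): `coverage` (250000), `permeability` (0.1),
#' `window` (6), `windows` ("3:15"), `threshold` (0.40), `fourc_depth`
#' (100000).
#'
#' @param ... named configuration values.
#' @return object of class `"run_config"` (a named list).
#' @export
run_config <- function(...) {
  cfg <- list(...)
  defaults <- list(coverage = 2.5e5, permeability = 0.1, window = 6L,
                   windows = "3:15", threshold = 0.40, fourc_depth = 1e5)
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  }
  for (k in c("preset", "seed", "out_dir")) {
    if (is.null(cfg[[k]])) stop(sprintf("config missing field '%s'", k))
  }
  if (!cfg$preset %in% c("wildtype", "del-partial", "del-full")) {
    stop(sprintf("unknown preset '%s'", cfg$preset))
  }
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as key=value text
#'
#' @param path file path.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  cfg <- stats::setNames(
    lapply(kv, function(p) {
      v <- paste(p[-1], collapse = "=")
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    }),
    vapply(kv, `[`, "", 1))
  do.call(run_config, cfg)
}

#' @rdname read_run_config
#' @param cfg a [run_config()].
#' @export
write_run_config <- function(cfg, path) {
  writeLines(sprintf("%s=%s", names(cfg),
                     vapply(cfg, function(v) format(v, scientific = FALSE),
                            "")),
             path)
  invisible(path)
}

#' Preset deletion-allele edit scripts for the synthetic locus
#'
#' `wildtype`: empty script; `del-partial`: deletes the first of the two
#' 40-kb boundary bins (half the boundary block); `del-full`: deletes the
#' entire boundary block.
#'
#' @param preset preset name.
#' @param spec the wild-type [synthetic_locus_spec()].
#' @return an [edit_script()].
#' @export
preset_edit_script <- function(preset, spec) {
  b <- spec$boundary
  edits <- switch(preset,
    "wildtype" = NULL,
    "del-partial" = data.frame(
      label = "del-partial", kind = "deletion", chrom = spec$chrom,
      start = b$start, end = b$start + (b$end - b$start) / 2,
      inserted_length = 0),
    "del-full" = data.frame(
      label = "del-full", kind = "deletion", chrom = spec$chrom,
      start = b$start, end = b$end, inserted_length = 0),
    stop(sprintf("unknown preset '%s'", preset)))
  edit_script(spec$chrom, spec$length, edits)
}

#' Run the wild-type-versus-allele comparison end to end
#'
#' Simulates the wild-type locus and the configured deletion allele,
#' processes both Hi-C matrices (masking, ICE), reframes the mutant matrix
#' onto the wild-type grid, subtracts, calls consensus TADs on both,
#' quantifies a 4C viewpoint in each, and writes all artefacts plus a
#' deterministic text summary and a provenance record into `out_dir`.
#'
#' @param config a [run_config()].
#' @return (invisibly) the output directory; side effect: files
#'   `wt_ice.tsv`, `mut_ice.tsv`, `subtraction.tsv`, `insulation_wt.bedgraph`,
#'   `insulation_mut.bedgraph`, `consensus_wt.bed`, `consensus_mut.bed`,
#'   `ratios.tsv`, `summary.txt`, `provenance.txt`.
#' @export
run_comparison <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)

  wt_spec <- synthetic_locus_spec(coverage = config$coverage,
                                  permeability = config$permeability,
                                  seed = seed)
  script <- preset_edit_script(config$preset, wt_spec)
  allele <- apply_allele(wt_spec, script)
  map <- coordinate_map(script)

  wt_raw <- simulate_hic(wt_spec, seed = seed)$matrix
  mut_raw <- simulate_hic(allele$spec, seed = seed + 1L)$matrix

  # own-grid processing per genotype: masking, balancing, consensus TADs
  w <- as.integer(config$window)
  wr <- as.integer(strsplit(as.character(config$windows), ":")[[1]])
  wr <- wr[1]:wr[2]
  process <- function(raw) {
    ice_normalize(mask_bins(raw, which(suppressWarnings(compute_mask(raw)))))
  }
  wt_ice <- process(wt_raw)
  mut_ice <- process(mut_raw)
  cons_wt <- consensus_tads(wt_ice, window_range = wr,
                            threshold = config$threshold)
  cons_mut <- consensus_tads(mut_ice, window_range = wr,
                             threshold = config$threshold)

  # boundary presence near the (collapsed) ancestral boundary position
  anchor_wt <- wt_spec$boundary
  anchor_mut_pos <- collapse_pos((anchor_wt$start + anchor_wt$end) / 2,
                                 script$edits)
  anchor_mut <- gi(wt_spec$chrom, anchor_mut_pos, anchor_mut_pos,
                   zero_width = TRUE)
  pos_wt <- nearest_boundary(cons_wt, anchor_wt)
  pos_mut <- nearest_boundary(cons_mut, anchor_mut)
  shift <- if (is.na(pos_wt) || is.na(pos_mut)) "absent" else {
    # report in wild-type coordinates: expand the mutant position back
    back <- lift_position(map, pos_mut, "mut_to_wt")
    if (is.na(back)) "absent" else back - pos_wt
  }

  # comparable wild-type-frame pair for subtraction: the mutant matrix is
  # reframed onto the backbone grid and the dropped bins are masked in both
  lifted <- lift_matrix_to_backbone(mut_raw, map)
  wt_cmp_raw <- mask_bins(wt_raw, lifted$dropped_bins)
  mut_cmp_raw <- lifted$matrix
  union_mask <- which((suppressWarnings(compute_mask(wt_cmp_raw)) |
                         wt_cmp_raw$mask) |
                      (suppressWarnings(compute_mask(mut_cmp_raw)) |
                         mut_cmp_raw$mask))
  wt_cmp <- ice_normalize(mask_bins(wt_cmp_raw, union_mask))
  mut_cmp <- ice_normalize(mask_bins(mut_cmp_raw, union_mask))
  diff <- subtract_matrices(mut_cmp, wt_cmp)

  vp <- gi(wt_spec$chrom, wt_spec$tads$start[2] + 40000,
           wt_spec$tads$start[2] + 42000)
  wt_4c <- simulate_fourc(wt_spec, vp, depth = config$fourc_depth,
                          seed = seed + 2L)
  wt_ratio <- domain_ratio(wt_4c$profile,
                           gi(wt_spec$chrom, wt_spec$tads$start[2],
                              wt_spec$tads$end[2]),
                           gi(wt_spec$chrom, wt_spec$tads$start[1],
                              wt_spec$tads$end[1]))
  ms <- allele$spec
  vp_mut <- gi(ms$chrom, ms$tads$start[nrow(ms$tads)] + 40000,
               ms$tads$start[nrow(ms$tads)] + 42000)
  mut_4c <- simulate_fourc(ms, vp_mut, depth = config$fourc_depth,
                           seed = seed + 3L)
  mut_ratio <- if (nrow(ms$tads) >= 2) {
    r <- domain_ratio(mut_4c$profile,
                      gi(ms$chrom, ms$tads$start[2], ms$tads$end[2]),
                      gi(ms$chrom, ms$tads$start[1], ms$tads$end[1]))
    r$pct_b
  } else {
    NA_real_   # fused: no second domain to ratio against
  }

  write_matrix(wt_ice, file.path(out, "wt_ice.tsv"), format = "sparse")
  write_matrix(mut_ice, file.path(out, "mut_ice.tsv"), format = "sparse")
  utils::write.table(round(diff$delta, 6), file.path(out, "subtraction.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  write_bedgraph(insulation_to_bedgraph(insulation_signal(wt_ice, w)),
                 file.path(out, "insulation_wt.bedgraph"))
  write_bedgraph(insulation_to_bedgraph(insulation_signal(mut_ice, w)),
                 file.path(out, "insulation_mut.bedgraph"))
  write_bed(calls_to_bed(cons_wt), file.path(out, "consensus_wt.bed"))
  write_bed(calls_to_bed(cons_mut), file.path(out, "consensus_mut.bed"))
  utils::write.table(
    data.frame(genotype = c("wildtype", config$preset),
               pct_cross_domain = round(c(wt_ratio$pct_b, mut_ratio), 4)),
    file.path(out, "ratios.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)

  boundary_mut <- if (is.na(pos_mut)) "absent" else "present"
  summary_lines <- c(
    sprintf("preset=%s", config$preset),
    sprintf("seed=%d", seed),
    sprintf("truth_fused=%s", allele$truth$fused),
    sprintf("truth_permeability=%.4f", allele$truth$permeability),
    sprintf("boundary_mutant=%s", boundary_mut),
    sprintf("boundary_shift=%s",
            if (identical(shift, "absent")) "absent"
            else sprintf("%.0f", shift)),
    sprintf("consensus_tads_wt=%d", nrow(cons_wt$tads)),
    sprintf("consensus_tads_mut=%d", nrow(cons_mut$tads)),
    sprintf("pct_cross_domain_wt=%.4f", wt_ratio$pct_b),
    sprintf("pct_cross_domain_mut=%s",
            if (is.na(mut_ratio)) "NA" else sprintf("%.4f", mut_ratio)),
    sprintf("dropped_bins=%d", length(lifted$dropped_bins)))
  writeLines(summary_lines, file.path(out, "summary.txt"))
  writeLines(c(sprintf("package=tadbound %s",
                       as.character(utils::packageVersion("tadbound"))),
               sprintf("%s=%s", names(config),
                       vapply(config, function(v)
                         format(v, scientific = FALSE), ""))),
             file.path(out, "provenance.txt"))
  invisible(out)
}
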