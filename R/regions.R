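#' Regulatory region panel of the HoxD locus (mm10)
#'
#' The named enhancer/control regions of the two regulatory landscapes
#' flanking the HoxD cluster, as quantified in 4C region panels: the C-DOM
#' digit enhancers (island-1..island-5, GCR, Prox) and the T-DOM elements
#' (CS38-41, CS65). Coordinates are mm10 chromosome 2, converted from the
#' printed 1-based inclusive spans to the package-wide 0-based half-open
#' convention.
#'
#' @return data.frame with columns `name`, `chrom`, `start`, `end`.
#' @export
hoxd_region_panel <- function() {
  p <- data.frame(
    name = c("island-1", "island-2", "island-3", "island-4", "island-5",
             "GCR", "Prox", "CS38-41", "CS65"),
    first = c(73970064, 74060473, 74177798, 74263814, 74289658,
              74445394, 74604505, 75120051, 75413472),
    last = c(73983434, 74082287, 74223313, 74284643, 74313573,
             74498046, 74639799, 75165771, 75451553))
  data.frame(name = p$name, chrom = "chr2", start = p$first - 1,
             end = p$last)
}

#' The two HoxD regulatory domains (mm10)
#'
#' The centromeric (C-DOM) and telomeric (T-DOM) TADs flanking the HoxD
#' cluster. Two coordinate sets are in use: the spans used for 4C domain
#' ratios, and the slightly different spans called from 40-kb Hi-C
#' matrices in distal limb cells (bin-aligned, used for domain-intensity
#' comparisons).
#'
#' @param flavour `"fourc"` (default) or `"hic"`.
#' @return named list of two [gi()] intervals, `C_DOM` and `T_DOM`.
#' @export
hoxd_domains <- function(flavour = c("fourc", "hic")) {
  flavour <- match.arg(flavour)
  if (flavour == "fourc") {
    list(C_DOM = gi_from_1based("chr2", 73914154, 74636454),
         T_DOM = gi_from_1based("chr2", 74781516, 75605516))
  } else {
    list(C_DOM = gi("chr2", 73960000, 74680000),
         T_DOM = gi("chr2", 74720000, 75600000))
  }
}

#' The deleted span masked in wild-type/mutant Hi-C comparisons (mm10)
#'
#' The chromosome 2 interval whose bins are removed from both data sets
#' before balancing when comparing a full-deletion allele against wild
#' type; spans nine 40-kb bins.
#'
#' @export
hoxd_masked_deletion <- function() gi("chr2", 74400000, 74760000)

#' Offset bounds of the published cumulative-curve windows
#'
#' Viewpoint-relative offset windows (bases; viewpoint at 0) used for
#' relative cumulative contact curves from the island-4 and CS38
#' viewpoints; both correspond to the same 3-Mb chromosome 2 window.
#'
#' @param viewpoint `"island-4"` or `"CS38"`.
#' @return numeric `c(lower, upper)`.
#' @export
hoxd_curve_bounds <- function(viewpoint = c("island-4", "CS38")) {
  viewpoint <- match.arg(viewpoint)
  switch(viewpoint,
         "island-4" = c(-1092537, 2006380),
         "CS38" = c(-1957157, 1141528))
}
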