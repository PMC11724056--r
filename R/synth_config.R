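#' Configuration for the synthetic wound-healing multiomics generator
#'
#' Builds the configuration object consumed by [generate_single_cell()],
#' [generate_bulk()] and [generate_visium()]. The defaults emulate the
#' statistical structure of a time-course skin-wound study: three
#' post-wounding timepoints (Days 3, 7, 14), eight major cell types with
#' fibroblast subclusters F1-F8 and macrophage subclusters M1-M6,
#' wild-type versus inflammation-deficient (KO) bulk wound samples, and a
#' Visium-style spot lattice mixing 20-30 cells per 55 um spot over wound
#' and intact regions.
#'
#' Planted biology, all recorded in the returned ground truth:
#' \itemize{
#'   \item exclusive marker genes per major type and per subcluster, with
#'     log2 fold-change `marker_log2fc` over every other population;
#'   \item five true inflammation-related scarring genes (`Itgbl1`,
#'     `Clec3b`, `Ccl11`, `Lrrc17`, `Pi16`) restricted to wound fibroblast
#'     subclusters and downregulated in KO bulk samples, with `Itgbl1`
#'     peaking in F4 and F1 like the collagen anchor `Col1a1`;
#'   \item decoy genes failing exactly one screen criterion each:
#'     `Fbn1` (not KO-downregulated), `Col3a1`/`Ccl8`/`Spp1` (not a
#'     fibroblast-subcluster marker), `Ccl7`/`C3` (shared with
#'     macrophages, not fibroblast-specific), `Dpt` (expressed by
#'     intact-dermis fibroblasts, no wound-region spatial support);
#'   \item a `Tgfb1` (macrophage) to `Tgfbr1` (F8) signaling axis whose
#'     spatial geometry runs from the wound margin toward the wound
#'     center.
#' }
#'
#' @param n_genes total number of genes in the universe.
#' @param n_cells_per_timepoint cells generated per timepoint.
#' @param timepoints integer day labels.
#' @param n_markers_per_cluster exclusive markers planted per major type.
#' @param n_markers_per_subcluster exclusive markers planted per
#'   fibroblast/macrophage subcluster.
#' @param marker_log2fc planted marker log2 fold-change (> 0).
#' @param nb_dispersion negative-binomial dispersion of single-cell and
#'   spot counts (> 0).
#' @param nb_dispersion_bulk dispersion of bulk replicates; bulk
#'   libraries from inbred littermates are far less overdispersed than
#'   single cells (default 0.05).
#' @param depth_mean_cells mean library size per single cell.
#' @param n_bulk_per_genotype bulk replicates per genotype.
#' @param bulk_depth mean bulk library size.
#' @param ko_downregulation_log2fc log2 fold-change applied to flagged
#'   genes in KO bulk samples (< 0).
#' @param n_background_ko number of anonymous non-fibroblast genes also
#'   flagged KO-downregulated (the large candidate-set background).
#' @param grid_shape integer `(rows, cols)` of the spot lattice.
#' @param spot_spacing_um lattice spacing in micrometers.
#' @param cells_per_spot_range inclusive `(low, high)` cells per spot.
#' @param wound_radius_um radius of the central wound disk, micrometers.
#' @param visium_cell_depth mean library size per cell inside a spot.
#' @param lr_pairs_planted data.frame with columns `pathway`, `ligand`,
#'   `receptor`, `sender_type`, `receiver_type`, `geometry`
#'   (`"margin_to_center"` or `"center_to_margin"`).
#' @param restricted_low relative expression of fibro-restricted genes
#'   outside their designated populations.
#' @param seed integer seed controlling every random draw.
#'
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_genes = 1000L,
                         n_cells_per_timepoint = 3000L,
                         timepoints = c(3L, 7L, 14L),
                         n_markers_per_cluster = 20L,
                         n_markers_per_subcluster = 5L,
                         marker_log2fc = 2,
                         nb_dispersion = 0.2,
                         nb_dispersion_bulk = 0.05,
                         depth_mean_cells = 5000L,
                         n_bulk_per_genotype = 4L,
                         bulk_depth = 1e6,
                         ko_downregulation_log2fc = -2,
                         n_background_ko = 60L,
                         grid_shape = c(25L, 25L),
                         spot_spacing_um = 100,
                         cells_per_spot_range = c(20L, 30L),
                         wound_radius_um = 700,
                         visium_cell_depth = 500,
                         lr_pairs_planted = default_lr_planted(),
                         restricted_low = 0.02,
                         seed = 1L) {
  stopifnot(n_genes >= 100, n_cells_per_timepoint >= 100)
  if (marker_log2fc < 0) stop("marker_log2fc must be >= 0")
  if (nb_dispersion <= 0 || nb_dispersion_bulk <= 0) {
    stop("dispersions must be > 0")
  }
  if (depth_mean_cells <= 0 || bulk_depth <= 0) stop("depths must be > 0")
  if (ko_downregulation_log2fc > 0) {
    stop("ko_downregulation_log2fc must be <= 0")
  }
  if (length(cells_per_spot_range) != 2 ||
      cells_per_spot_range[1] < 1 || cells_per_spot_range[2] > 100 ||
      cells_per_spot_range[1] > cells_per_spot_range[2]) {
    stop("cells_per_spot_range must satisfy 1 <= low <= high <= 100")
  }
  half_extent <- min((grid_shape - 1) / 2) * spot_spacing_um
  if (wound_radius_um > half_extent) {
    stop("wound_radius_um exceeds the grid extent (", half_extent, " um)")
  }

  major <- major_type_table()
  fibro <- fibro_subcluster_table()
  macro <- macro_subcluster_table()
  for (tp in as.character(timepoints)) {
    check_simplex(major$props[[tp]], paste0("major proportions day ", tp))
    check_simplex(fibro$props[[tp]], paste0("fibroblast proportions day ", tp))
    check_simplex(macro$props[[tp]], paste0("macrophage proportions day ", tp))
  }

  cfg <- list(
    n_genes = as.integer(n_genes),
    n_cells_per_timepoint = as.integer(n_cells_per_timepoint),
    timepoints = as.integer(timepoints),
    major_types = major,
    fibro_subclusters = fibro,
    macro_subclusters = macro,
    n_markers_per_cluster = as.integer(n_markers_per_cluster),
    n_markers_per_subcluster = as.integer(n_markers_per_subcluster),
    marker_log2fc = marker_log2fc,
    nb_dispersion = nb_dispersion,
    nb_dispersion_bulk = nb_dispersion_bulk,
    depth_mean_cells = depth_mean_cells,
    n_bulk_per_genotype = as.integer(n_bulk_per_genotype),
    bulk_depth = bulk_depth,
    ko_downregulation_log2fc = ko_downregulation_log2fc,
    n_background_ko = as.integer(n_background_ko),
    grid_shape = as.integer(grid_shape),
    spot_spacing_um = spot_spacing_um,
    cells_per_spot_range = as.integer(cells_per_spot_range),
    wound_radius_um = wound_radius_um,
    visium_cell_depth = visium_cell_depth,
    lr_pairs_planted = lr_pairs_planted,
    restricted_low = restricted_low,
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  cfg
}

# Major cell types with per-timepoint proportions. Early wounds are
# inflammatory (neutrophils, macrophages), late wounds fibroblast-rich.
major_type_table <- function() {
  types <- c("F", "M", "N", "EpC", "EC", "P", "MC", "TC")
  props <- list(
    `3`  = c(F = .20, M = .30, N = .25, EpC = .08, EC = .06, P = .04, MC = .04, TC = .03),
    `7`  = c(F = .40, M = .35, N = .05, EpC = .06, EC = .05, P = .03, MC = .03, TC = .03),
    `14` = c(F = .50, M = .25, N = .02, EpC = .08, EC = .06, P = .04, MC = .03, TC = .02)
  )
  list(types = types, props = props)
}

# Fibroblast subclusters; F4, F6 and F8 are absent on Day 3 and appear on
# Days 7/14; remodeling subclusters F1/F4/F5 peak on Day 14. F5 is the
# resident intact-dermis fibroblast population (absent from wound spots).
fibro_subcluster_table <- function() {
  names <- paste0("F", 1:8)
  props <- list(
    `3`  = c(F1 = .20, F2 = .25, F3 = .25, F4 = 0,   F5 = .20, F6 = 0,   F7 = .10, F8 = 0),
    `7`  = c(F1 = .10, F2 = .20, F3 = .15, F4 = .05, F5 = .05, F6 = .15, F7 = .15, F8 = .15),
    `14` = c(F1 = .30, F2 = .10, F3 = .10, F4 = .25, F5 = .15, F6 = .05, F7 = .03, F8 = .02)
  )
  list(names = names, props = props)
}

# Macrophage subclusters; M3/M4/M6 decline by Day 14.
macro_subcluster_table <- function() {
  names <- paste0("M", 1:6)
  props <- list(
    `3`  = c(M1 = .30, M2 = .20, M3 = .20, M4 = .10, M5 = .10, M6 = .10),
    `7`  = c(M1 = .25, M2 = .25, M3 = .20, M4 = .15, M5 = .10, M6 = .05),
    `14` = c(M1 = .35, M2 = .40, M3 = .10, M4 = .05, M5 = .08, M6 = .02)
  )
  list(names = names, props = props)
}

#' Default planted ligand-receptor axes
#'
#' The headline axis is macrophage `Tgfb1` signaling to `Tgfbr1` on F8
#' (myofibroblast-precursor) fibroblasts, flowing from the wound margin
#' toward the granulation-tissue center.
#'
#' @return data.frame with one planted pair per row.
#' @export
default_lr_planted <- function() {
  data.frame(
    pathway = "TGFB",
    ligand = "Tgfb1",
    receptor = "Tgfbr1",
    sender_type = "M",
    receiver_type = "F8",
    geometry = "margin_to_center",
    stringsAsFactors = FALSE
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synth_config:", x$n_genes, "genes,",
      x$n_cells_per_timepoint, "cells/timepoint, days",
      paste(x$timepoints, collapse = "/"), "\n")
  cat("  grid", paste(x$grid_shape, collapse = "x"),
      "spots at", x$spot_spacing_um, "um; wound radius",
      x$wound_radius_um, "um;",
      paste(x$cells_per_spot_range, collapse = "-"), "cells/spot\n")
  cat("  bulk:", x$n_bulk_per_genotype, "WT +",
      x$n_bulk_per_genotype, "KO at depth", format(x$bulk_depth),
      "; KO lfc", x$ko_downregulation_log2fc, "\n")
  cat("  seed", x$seed, "\n")
  invisible(x)
}
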