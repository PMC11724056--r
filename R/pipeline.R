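# End-to-end pipeline: simulate -> QC/normalize -> cluster -> annotate
# -> subcluster -> markers -> bulk DE -> spatial region DEGs ->
# deconvolution -> communication -> intersection screen.

#' Pipeline configuration
#'
#' Stage parameters for [run_pipeline()], validated up front so an
#' impossible threshold fails before any stage runs.
#'
#' @param synth a [synth_config()]; its seed drives every stage.
#' @param qc_min_genes,qc_min_counts,qc_max_counts_quantile,qc_min_cells_per_gene
#'   QC thresholds, see [qc_filter()].
#' @param n_pcs,k_neighbors,resolution clustering controls.
#' @param marker_q_max,marker_lfc_min,marker_pct_min marker thresholds.
#' @param de_q_max,de_lfc_max candidate-gene thresholds (see
#'   [candidate_inflammation_genes()]).
#' @param specificity_tau fibroblast-specificity threshold.
#' @param hill_k,n_perm communication controls.
#' @param ot_epsilon,ot_cutoff_um direction-field controls.
#' @param deconv_top_genes markers per type kept for deconvolution.
#' @param anchor_gene prioritization anchor (default "Col1a1").
#' @param run_deconv,run_comm toggle the spatial deconvolution and
#'   communication stages (the screen itself does not consume them).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            qc_min_genes = 100, qc_min_counts = 500,
                            qc_max_counts_quantile = 1,
                            qc_min_cells_per_gene = 3,
                            n_pcs = 30, k_neighbors = 15, resolution = 1,
                            marker_q_max = 0.05, marker_lfc_min = 0.585,
                            marker_pct_min = 0.25,
                            de_q_max = 0.05, de_lfc_max = -1,
                            specificity_tau = 0.7,
                            hill_k = 0.5, n_perm = 100,
                            ot_epsilon = 0.05, ot_cutoff_um = 500,
                            deconv_top_genes = 50,
                            anchor_gene = "Col1a1",
                            run_deconv = TRUE, run_comm = TRUE) {
  stopifnot(inherits(synth, "synth_config"))
  chk01 <- function(x, nm) {
    if (!is.numeric(x) || x <= 0 || x >= 1) {
      stop("invalid ", nm, ": must be in (0, 1), got ", x)
    }
  }
  chk01(marker_q_max, "marker_q_max")
  chk01(de_q_max, "de_q_max")
  if (qc_max_counts_quantile <= 0 || qc_max_counts_quantile > 1) {
    stop("invalid qc_max_counts_quantile: must be in (0, 1]")
  }
  if (specificity_tau < 0 || specificity_tau > 1) {
    stop("invalid specificity_tau")
  }
  if (de_lfc_max >= 0) stop("de_lfc_max must be < 0")
  if (hill_k <= 0 || ot_epsilon <= 0 || ot_cutoff_um <= 0) {
    stop("hill_k, ot_epsilon, ot_cutoff_um must be > 0")
  }
  if (n_perm < 20) stop("n_perm must be >= 20")
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Simulate the full synthetic multiomics dataset
#'
#' @param synth a [synth_config()].
#' @return list: sc (single cell), bulk, visium (per timepoint),
#'   lr_table.
#' @export
simulate_dataset <- function(synth = synth_config()) {
  sc <- generate_single_cell(synth)
  bulk <- generate_bulk(synth, sc$truth)
  visium <- lapply(synth$timepoints, function(tp) {
    generate_visium(synth, sc$truth, tp)
  })
  names(visium) <- paste0("day", synth$timepoints)
  lr <- synth$lr_pairs_planted[, c("pathway", "ligand", "receptor")]
  list(sc = sc, bulk = bulk, visium = visium, lr_table = lr)
}

#' Run the full inflammation-related scarring gene screen
#'
#' Chains every stage on a synthetic dataset: QC and normalization,
#' clustering with canonical-marker annotation, fibroblast
#' subclustering, subcluster marker detection, bulk WT-vs-KO
#' differential expression, per-timepoint wound-region DEGs, optional
#' spot deconvolution and communication analysis, and the staged
#' intersection screen ranked against the collagen anchor.
#'
#' @param config a [pipeline_config()].
#' @param dataset optionally a pre-generated [simulate_dataset()]
#'   result (must match `config$synth`).
#' @return object of class `scar_pipeline` with the `screen_report`
#'   under `$report` and every intermediate stage result.
#' @export
run_pipeline <- function(config = pipeline_config(), dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$synth$seed
  log <- list()
  if (is.null(dataset)) dataset <- simulate_dataset(config$synth)

  # --- QC + normalize -----------------------------------------------------
  counts <- qc_filter(dataset$sc$counts, config$qc_min_genes,
                      config$qc_min_counts, config$qc_max_counts_quantile,
                      config$qc_min_cells_per_gene)
  log$qc <- attr(counts, "qc_log")
  norm <- normalize_log_cpm(counts)
  meta <- dataset$sc$meta[match(colnames(norm), dataset$sc$meta$cell_id), ]

  # --- cluster + annotate + merge to major types --------------------------
  clusters <- cluster_cells(norm, n_pcs = config$n_pcs,
                            k_neighbors = config$k_neighbors,
                            resolution = config$resolution, seed = seed)
  ann <- annotate_clusters(norm, clusters,
                           as.list(canonical_major_markers()))
  major <- setNames(ann$type[match(clusters, ann$cluster)], names(clusters))
  log$clusters <- table(major)

  # --- fibroblast subclusters + markers ----------------------------------
  sub_f <- subcluster(norm, major, "F", n_pcs = config$n_pcs,
                      k_neighbors = config$k_neighbors,
                      resolution = config$resolution, seed = seed + 1L)
  markers_f <- find_markers(norm[, names(sub_f), drop = FALSE], sub_f,
                            q_max = config$marker_q_max,
                            lfc_min = config$marker_lfc_min,
                            pct_min = config$marker_pct_min)
  proportions <- temporal_proportions(meta, sub_f)

  # --- bulk DE -> candidates ---------------------------------------------
  de <- nb_wald_test(dataset$bulk$counts, dataset$bulk$design)
  candidates <- candidate_inflammation_genes(de, config$de_q_max,
                                             config$de_lfc_max)
  # the anchor is the screen's reference hypothesis, not a candidate
  candidates <- setdiff(candidates, config$anchor_gene)
  log$n_candidates <- length(candidates)

  # --- spatial region DEGs ------------------------------------------------
  region_degs <- lapply(names(dataset$visium), function(nm) {
    vs <- dataset$visium[[nm]]
    region_deg(vs$counts, vs$spots, timepoint = vs$timepoint)
  })
  names(region_degs) <- names(dataset$visium)

  # --- deconvolution (day 7 section) -------------------------------------
  deconv <- NULL
  if (config$run_deconv) {
    ref <- build_reference(counts, major)
    genes <- select_deconv_genes(ref, config$deconv_top_genes)
    vs7 <- dataset$visium[[which.min(abs(config$synth$timepoints - 7))]]
    deconv <- deconvolve_all(vs7$counts, ref, genes = genes)
  }

  # --- communication + direction field ------------------------------------
  comm <- NULL
  field <- NULL
  if (config$run_comm) {
    labels_full <- major
    labels_full[names(sub_f)] <- sub_f
    comm <- permutation_pvalues(norm, labels_full, dataset$lr_table,
                                hill_k = config$hill_k,
                                n_perm = config$n_perm, seed = seed + 2L)
    vs7 <- dataset$visium[[which.min(abs(config$synth$timepoints - 7))]]
    pair1 <- dataset$lr_table[1, ]
    field <- signaling_direction(normalize_log_cpm(vs7$counts), vs7$spots,
                                 pair1$ligand, pair1$receptor,
                                 ot_epsilon = config$ot_epsilon,
                                 ot_cutoff_um = config$ot_cutoff_um,
                                 pathway = pair1$pathway)
  }

  # --- intersection screen -------------------------------------------------
  inter <- intersect_candidates(candidates, markers_f)
  spec_scores <- if (length(inter$union_hits)) {
    fibroblast_specificity(norm, major, inter$union_hits)
  } else setNames(numeric(0), character(0))
  fibro_specific <- specificity_filter(inter$union_hits, spec_scores,
                                       config$specificity_tau)
  spatial_res <- spatial_support_filter(fibro_specific, region_degs)
  ranked <- prioritize(spatial_res$kept, norm, sub_f,
                       anchor_gene = config$anchor_gene)
  report <- build_report(candidates, inter, fibro_specific, spatial_res,
                         ranked,
                         thresholds = list(
                           de_q_max = config$de_q_max,
                           de_lfc_max = config$de_lfc_max,
                           marker_q_max = config$marker_q_max,
                           marker_lfc_min = config$marker_lfc_min,
                           marker_pct_min = config$marker_pct_min,
                           specificity_tau = config$specificity_tau,
                           anchor_gene = config$anchor_gene,
                           seed = seed))

  structure(list(report = report, major_labels = major, sub_labels = sub_f,
                 markers_f = markers_f, proportions = proportions,
                 de = de, candidates = candidates,
                 region_degs = region_degs, deconv = deconv,
                 comm = comm, field = field,
                 specificity = spec_scores,
                 truth = dataset$sc$truth, config = config, log = log),
            class = "scar_pipeline")
}

#' @export
print.scar_pipeline <- function(x, ...) {
  cat("scar_pipeline run (seed", x$config$synth$seed, ")\n")
  cat(" cells after QC:", x$log$qc[["cells_out"]],
      "; candidates:", x$log$n_candidates, "\n")
  print(x$report)
  invisible(x)
}
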