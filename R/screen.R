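# The cross-modality intersection screen: KO-downregulated candidates
# -> fibroblast-subcluster marker hits -> fibroblast-specific ->
# spatially supported -> anchor-correlated ranking.

#' Intersect candidate genes with fibroblast subcluster markers
#'
#' @param candidates character vector of KO-downregulated genes.
#' @param markers a `marker_table` computed on the fibroblast
#'   subcluster labels.
#' @param subcluster_family subcluster labels forming the family
#'   (e.g. F1..F8); defaults to all clusters in `markers`.
#' @return list: `subcluster_hits` (subcluster -> gene set),
#'   `union_hits` (genes), `membership` (gene -> subclusters).
#' @export
intersect_candidates <- function(candidates, markers,
                                 subcluster_family = NULL) {
  if (is.null(subcluster_family)) {
    subcluster_family <- sort(unique(markers$cluster))
  }
  if (!length(candidates)) {
    warning("empty candidate set: all screen stages will be empty")
  }
  hits <- lapply(subcluster_family, function(f) {
    mk <- markers$gene[markers$cluster == f & markers$is_marker]
    sort(intersect(candidates, mk))
  })
  names(hits) <- subcluster_family
  union_hits <- sort(unique(unlist(hits)))
  membership <- lapply(union_hits, function(g) {
    subcluster_family[vapply(hits, function(h) g %in% h, TRUE)]
  })
  names(membership) <- union_hits
  list(subcluster_hits = hits, union_hits = union_hits,
       membership = membership)
}

#' Filter screen hits by fibroblast specificity
#'
#' @param union_hits character vector of genes.
#' @param specificity_scores named scores from
#'   [fibroblast_specificity()].
#' @param tau threshold (default 0.7).
#' @return genes with score >= tau.
#' @export
specificity_filter <- function(union_hits, specificity_scores, tau = 0.7) {
  miss <- setdiff(union_hits, names(specificity_scores))
  if (length(miss)) {
    stop("no specificity score for: ", paste(miss, collapse = ", "))
  }
  sort(union_hits[specificity_scores[union_hits] >= tau])
}

#' Filter by spatial wound-region support
#'
#' A gene survives when it is wound-upregulated (`supported`) in at
#' least one timepoint's region DEG table; per-timepoint membership is
#' recorded.
#'
#' @param genes character vector.
#' @param region_degs named list of `region_deg` tables, one per
#'   timepoint.
#' @return list: `kept` (genes), `membership` (gene -> timepoints).
#' @export
spatial_support_filter <- function(genes, region_degs) {
  if (!length(region_degs)) stop("need region DEG tables for >= 1 timepoint")
  membership <- lapply(genes, function(g) {
    tps <- names(region_degs)[vapply(region_degs, function(rd) {
      any(rd$gene == g & rd$supported)
    }, TRUE)]
    tps
  })
  names(membership) <- genes
  kept <- genes[lengths(membership[genes]) > 0]
  list(kept = sort(kept), membership = membership[kept])
}

#' Rank surviving genes by correlation with an anchor gene
#'
#' Each gene's profile is its mean normalized expression across the
#' fibroblast subclusters; genes are ranked by descending Pearson
#' correlation with the anchor gene's profile (default `Col1a1`, the
#' collagen scar anchor peaking in F4). Ties break lexicographically;
#' constant profiles are flagged and ranked last.
#'
#' @param survivors character vector of genes.
#' @param norm normalized gene x cell matrix.
#' @param sub_labels named fibroblast subcluster labels.
#' @param anchor_gene anchor symbol (default "Col1a1").
#' @return data.frame: gene, anchor_correlation, rank, flag.
#' @export
prioritize <- function(survivors, norm, sub_labels,
                       anchor_gene = "Col1a1") {
  if (!anchor_gene %in% rownames(norm)) {
    stop("anchor gene absent: ", anchor_gene)
  }
  subs <- sort(unique(sub_labels))
  if (length(subs) < 2) stop("need >= 2 fibroblast subclusters")
  cells <- names(sub_labels)
  membership <- sapply(subs, function(s) as.numeric(sub_labels == s))
  prof <- function(g) {
    as.numeric(norm[g, cells, drop = FALSE] %*% membership) /
      colSums(membership)
  }
  anchor <- prof(anchor_gene)
  res <- lapply(survivors, function(g) {
    pg <- prof(g)
    if (sd(pg) < 1e-12 || sd(anchor) < 1e-12) {
      data.frame(gene = g, anchor_correlation = NA_real_, flag = "constant",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene = g, anchor_correlation = cor(pg, anchor), flag = "",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  ord <- order(is.na(out$anchor_correlation), -out$anchor_correlation,
               out$gene)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Assemble the staged screen report
#'
#' Collects the staged gene sets with their thresholds and enforces the
#' nesting invariant `final \subseteq fibro_specific \subseteq
#' union_hits \subseteq candidates`.
#'
#' @param candidates stage-1 gene set.
#' @param intersect_res result of [intersect_candidates()].
#' @param fibro_specific stage-3 gene set.
#' @param spatial_res result of [spatial_support_filter()].
#' @param ranked data.frame from [prioritize()].
#' @param thresholds named list recorded verbatim.
#' @return object of class `screen_report`.
#' @export
build_report <- function(candidates, intersect_res, fibro_specific,
                         spatial_res, ranked, thresholds = list()) {
  stages <- list(candidates = sort(candidates),
                 union_hits = intersect_res$union_hits,
                 fibro_specific = sort(fibro_specific),
                 spatial_supported = spatial_res$kept,
                 final = ranked$gene)
  for (i in seq_len(length(stages) - 1)) {
    extra <- setdiff(stages[[i + 1]], stages[[i]])
    if (length(extra)) {
      stop("nesting violation: ", names(stages)[i + 1], " contains ",
           paste(extra, collapse = ", "), " absent from ",
           names(stages)[i])
    }
  }
  structure(list(
    candidate_set = stages$candidates,
    subcluster_hits = intersect_res$subcluster_hits,
    union_hits = intersect_res$union_hits,
    membership = intersect_res$membership,
    fibro_specific = stages$fibro_specific,
    spatial_supported = spatial_res$membership,
    final_ranked = ranked,
    stage_counts = vapply(stages, length, 0L),
    thresholds = thresholds
  ), class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("screen_report\n")
  cat("  stage counts:",
      paste(names(x$stage_counts), x$stage_counts, sep = "=",
            collapse = ", "), "\n")
  cat("  final ranked genes:\n")
  fr <- x$final_ranked
  for (i in seq_len(nrow(fr))) {
    g <- fr$gene[i]
    memb <- x$membership[[g]]
    cat(sprintf("   %2d. %-8s r=%.3f  subclusters: %s\n", fr$rank[i], g,
                fr$anchor_correlation[i], paste(memb, collapse = ",")))
  }
  invisible(x)
}

#' Serialize a screen report to JSON
#'
#' @param report a `screen_report`.
#' @param path output path; NULL returns the JSON string.
#' @return the JSON string, invisibly if written to a file.
#' @export
screen_report_json <- function(report, path = NULL) {
  obj <- list(
    stage_counts = as.list(report$stage_counts),
    candidate_set = report$candidate_set,
    subcluster_hits = report$subcluster_hits,
    union_hits = report$union_hits,
    membership = report$membership,
    fibro_specific = report$fibro_specific,
    spatial_supported = report$spatial_supported,
    final_ranked = report$final_ranked,
    thresholds = report$thresholds
  )
  js <- jsonlite::toJSON(obj, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}
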