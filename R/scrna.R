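# Single-cell module: QC, normalization, clustering, subclustering,
# marker detection, annotation, temporal proportions, and the
# fibroblast-specificity score used by the screen.

#' Quality-control filtering of a count matrix
#'
#' Removes cells with too few detected genes or counts, cells above a
#' library-size quantile (doublet-rich tail), then genes detected in too
#' few cells.
#'
#' @param counts gene x cell integer matrix.
#' @param min_genes minimum detected genes per cell.
#' @param min_counts minimum total counts per cell.
#' @param max_counts_quantile cells with depth strictly above this
#'   quantile of the (pre-filter) depth distribution are removed; 1
#'   disables.
#' @param min_cells_per_gene minimum cells in which a gene is detected.
#' @return filtered count matrix with attribute `qc_log` recording
#'   removal counts.
#' @export
qc_filter <- function(counts, min_genes = 0, min_counts = 0,
                      max_counts_quantile = 1, min_cells_per_gene = 0) {
  stopifnot(min_genes >= 0, min_counts >= 0, min_cells_per_gene >= 0,
            max_counts_quantile > 0, max_counts_quantile <= 1)
  depth <- colSums(counts)
  ngene <- colSums(counts > 0)
  keep_cell <- ngene >= min_genes & depth >= min_counts
  if (max_counts_quantile < 1) {
    keep_cell <- keep_cell & depth <= quantile(depth, max_counts_quantile)
  }
  if (!any(keep_cell)) stop("QC removed all cells")
  out <- counts[, keep_cell, drop = FALSE]
  keep_gene <- rowSums(out > 0) >= min_cells_per_gene
  out <- out[keep_gene, , drop = FALSE]
  attr(out, "qc_log") <- c(cells_in = ncol(counts), cells_out = ncol(out),
                           genes_in = nrow(counts), genes_out = nrow(out))
  out
}

#' Log-normalize counts to log1p counts-per-10,000
#'
#' `value = log(1 + 1e4 * count / total)` per observation; an all-zero
#' observation maps to an all-zero column.
#'
#' @param counts gene x observation matrix.
#' @return normalized matrix of the same shape.
#' @export
normalize_log_cpm <- function(counts) {
  tot <- colSums(counts)
  tot[tot == 0] <- 1
  log1p(sweep(counts, 2, tot / 1e4, `/`))
}

# Top-PC scores of cells. Genes are standardized (unit variance, zero
# mean); constant genes are dropped.
pca_scores <- function(norm, n_pcs) {
  Z <- t(norm)                                  # cells x genes
  mu <- colMeans(Z)
  sdv <- sqrt(colMeans(Z^2) - mu^2)
  keep <- sdv > 1e-12
  Z <- sweep(Z[, keep, drop = FALSE], 2, mu[keep], `-`)
  Z <- sweep(Z, 2, sdv[keep], `/`)
  n_pcs <- min(n_pcs, ncol(Z), nrow(Z) - 1)
  C <- crossprod(Z) / (nrow(Z) - 1)
  ev <- eigen(C, symmetric = TRUE)
  V <- ev$vectors[, seq_len(n_pcs), drop = FALSE]
  # sign convention: largest-magnitude loading positive, for determinism
  # under gene/cell reordering
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  Z %*% V
}

# k-nearest-neighbour edge list in PC space, computed blockwise.
knn_edges <- function(scores, k) {
  n <- nrow(scores)
  sq <- rowSums(scores^2)
  block <- max(1L, floor(2e7 / n))
  nbr <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(n, start + block - 1L)
    d2 <- outer(sq[idx], sq, `+`) - 2 * tcrossprod(scores[idx, , drop = FALSE],
                                                   scores)
    for (ii in seq_along(idx)) {
      d2[ii, idx[ii]] <- Inf
      nbr[idx[ii], ] <- order(d2[ii, ])[seq_len(k)]
    }
  }
  cbind(rep(seq_len(n), each = k), as.integer(t(nbr)))
}

#' Cluster cells by PCA, kNN graph and Louvain community detection
#'
#' Standardizes genes, projects cells to the top principal components,
#' builds a Euclidean k-nearest-neighbour graph and applies seeded
#' Louvain modularity optimization. Cluster labels are renamed by
#' descending size.
#'
#' @param norm normalized gene x cell matrix.
#' @param n_pcs number of principal components (default 30).
#' @param k_neighbors neighbours per cell (default 15).
#' @param resolution Louvain resolution; values below 1 favour coarser
#'   (major-type) partitions (default 1).
#' @param seed RNG seed for the community search.
#' @return character vector of cluster labels (`C1`, `C2`, ...) named by
#'   cell.
#' @export
cluster_cells <- function(norm, n_pcs = 30, k_neighbors = 15,
                          resolution = 1, seed = 1L) {
  n <- ncol(norm)
  if (n < k_neighbors + 1) stop("fewer cells than k_neighbors + 1")
  if (k_neighbors < 2) stop("k_neighbors must be >= 2")
  scores <- pca_scores(norm, n_pcs)
  edges <- knn_edges(scores, k_neighbors)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comm <- with_seed(seed,
                    igraph::cluster_louvain(g, resolution = resolution))
  labels <- rename_by_size(igraph::membership(comm))
  names(labels) <- colnames(norm)
  labels
}

#' Subcluster the cells of one cluster
#'
#' Re-runs [cluster_cells()] restricted to the target cluster's cells;
#' sub-labels are prefixed with the target label (e.g. `F1`, `F2`, ...).
#'
#' @param norm normalized gene x cell matrix.
#' @param labels per-cell cluster labels.
#' @param target_label the cluster to subcluster.
#' @inheritParams cluster_cells
#' @return named character vector of sub-labels for the target cells.
#' @export
subcluster <- function(norm, labels, target_label, n_pcs = 30,
                       k_neighbors = 15, resolution = 1, seed = 1L) {
  cells <- names(labels)[labels == target_label]
  if (length(cells) < 2 * k_neighbors) {
    stop("cluster ", target_label, " has too few cells to subcluster")
  }
  sub <- cluster_cells(norm[, cells, drop = FALSE], n_pcs = n_pcs,
                       k_neighbors = k_neighbors, resolution = resolution,
                       seed = seed)
  sub <- sub("^C", target_label, sub)
  names(sub) <- cells
  sub
}

#' One-vs-rest Wilcoxon marker detection
#'
#' For every gene and cluster, tests the cluster's normalized values
#' against all other cells by rank-sum (exact enumeration for small
#' datasets, normal approximation with tie correction otherwise).
#' Fold-changes are computed on back-transformed (`expm1`) cluster
#' means, i.e. on the counts-per-10k scale. Benjamini-Hochberg
#' correction is applied within each cluster's test family.
#'
#' @param norm normalized gene x cell matrix.
#' @param labels per-cell cluster labels.
#' @param q_max,lfc_min,pct_min marker call thresholds (defaults 0.05,
#'   0.585 = log2(1.5), 0.25).
#' @return data.frame of class `marker_table`: gene, cluster, log2fc,
#'   p, q, pct_in, pct_out, is_marker.
#' @export
find_markers <- function(norm, labels, q_max = 0.05, lfc_min = 0.585,
                         pct_min = 0.25) {
  labels <- labels[colnames(norm)]
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("need >= 2 clusters")
  sizes <- table(labels)
  small <- names(sizes)[sizes < 3]
  if (length(small)) {
    warning("skipping cluster(s) of size < 3: ", paste(small, collapse = ", "))
    clusters <- setdiff(clusters, small)
  }
  membership <- sapply(clusters, function(cl) as.numeric(labels == cl))
  n <- ncol(norm)

  expr <- expm1(norm)
  tot_mean <- rowMeans(expr)
  cl_mean <- expr %*% membership
  cl_mean <- sweep(cl_mean, 2, colSums(membership), `/`)
  rest_mean <- sweep(-sweep(cl_mean, 2, colSums(membership), `*`) +
                       tot_mean * n, 2, n - colSums(membership), `/`)
  det <- (norm > 0) * 1
  pct_in <- sweep(det %*% membership, 2, colSums(membership), `/`)
  pct_out <- sweep((rowSums(det) - det %*% membership), 2,
                   n - colSums(membership), `/`)
  lfc <- log2_ratio(cl_mean, rest_mean)

  if (n <= 30) {
    p <- sapply(seq_along(clusters), function(j) {
      apply(norm, 1, wilcox_rank_sum, in_group = membership[, j] > 0)
    })
  } else {
    ranks <- t(apply(norm, 1, rank))
    p <- rank_sum_p_matrix(ranks, membership)
  }

  out <- do.call(rbind, lapply(seq_along(clusters), function(j) {
    data.frame(gene = rownames(norm), cluster = clusters[j],
               log2fc = lfc[, j], p = p[, j],
               q = p.adjust(p[, j], method = "BH"),
               pct_in = pct_in[, j], pct_out = pct_out[, j],
               stringsAsFactors = FALSE)
  }))
  out$is_marker <- out$q < q_max & out$log2fc >= lfc_min & out$pct_in >= pct_min
  rownames(out) <- NULL
  class(out) <- c("marker_table", "data.frame")
  out
}

#' @export
print.marker_table <- function(x, ...) {
  cat("marker_table:", length(unique(x$cluster)), "clusters,",
      sum(x$is_marker), "marker calls\n")
  print(head(as.data.frame(x[x$is_marker, ]), 10))
  invisible(x)
}

#' Annotate clusters by canonical marker expression
#'
#' Assigns each cluster the cell type whose marker genes have the
#' highest mean normalized-expression z-score (z across clusters) in
#' that cluster. Exact ties go to the lexicographically first type and
#' are flagged; clusters expressing no mapped gene are `unassigned`.
#'
#' @param norm normalized gene x cell matrix.
#' @param labels per-cell cluster labels.
#' @param marker_map named list: type -> character vector of marker genes.
#' @return data.frame: cluster, type, score, tie.
#' @export
annotate_clusters <- function(norm, labels, marker_map) {
  if (!length(marker_map)) stop("marker_map is empty")
  labels <- labels[colnames(norm)]
  clusters <- sort(unique(labels))
  membership <- sapply(clusters, function(cl) as.numeric(labels == cl))
  cl_mean <- sweep(norm %*% membership, 2, colSums(membership), `/`)
  mu <- rowMeans(cl_mean)
  sdv <- apply(cl_mean, 1, sd)
  z <- (cl_mean - mu) / ifelse(sdv > 1e-12, sdv, 1)

  res <- lapply(clusters, function(cl) {
    sc <- vapply(marker_map, function(gs) {
      gs <- intersect(gs, rownames(norm))
      if (!length(gs)) return(NA_real_)
      mean(z[gs, cl])
    }, 0)
    if (all(is.na(sc))) {
      return(data.frame(cluster = cl, type = "unassigned", score = NA_real_,
                        tie = FALSE, stringsAsFactors = FALSE))
    }
    best <- max(sc, na.rm = TRUE)
    hits <- sort(names(sc)[!is.na(sc) & sc == best])
    data.frame(cluster = cl, type = hits[1], score = best,
               tie = length(hits) > 1, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-subcluster temporal proportions
#'
#' For each subcluster, the fraction of its cells observed at each
#' timepoint; rows sum to 1.
#'
#' @param meta data.frame with `cell_id` and `timepoint`.
#' @param sub_labels named character vector of subcluster labels.
#' @return matrix subcluster x timepoint of fractions.
#' @export
temporal_proportions <- function(meta, sub_labels) {
  tp <- meta$timepoint[match(names(sub_labels), meta$cell_id)]
  if (any(is.na(tp))) stop("every cell must have a timepoint")
  tab <- table(sub_labels, tp)
  prop <- sweep(tab, 1, rowSums(tab), `/`)
  m <- matrix(as.numeric(prop), nrow(prop), ncol(prop),
              dimnames = dimnames(prop))
  m
}

#' Fibroblast specificity score of a gene
#'
#' The fibroblast-cluster mean expression (counts-per-10k scale, i.e.
#' `expm1` of the log-normalized values) divided by the sum of all
#' major-cluster means. 1 means exclusively fibroblast; a gene is
#' called fibroblast-specific at `score >= tau` (default 0.7).
#'
#' @param norm normalized gene x cell matrix.
#' @param major_labels per-cell major-type labels.
#' @param gene gene symbol (vectorized).
#' @param fibro_label label of the fibroblast cluster (default "F").
#' @return numeric score(s) in `[0, 1]`.
#' @export
fibroblast_specificity <- function(norm, major_labels, gene,
                                   fibro_label = "F") {
  missing <- setdiff(gene, rownames(norm))
  if (length(missing)) {
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  }
  major_labels <- major_labels[colnames(norm)]
  if (!fibro_label %in% major_labels) stop("no fibroblast cluster present")
  clusters <- sort(unique(major_labels))
  membership <- sapply(clusters, function(cl) as.numeric(major_labels == cl))
  expr <- expm1(norm[gene, , drop = FALSE])
  cl_mean <- sweep(expr %*% membership, 2, colSums(membership), `/`)
  score <- cl_mean[, fibro_label] / (rowSums(cl_mean) + 1e-9)
  setNames(as.numeric(score), gene)
}
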