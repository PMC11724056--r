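# QC, normalization, clustering, markers, annotation, proportions and
# the fibroblast specificity score.

test_that("QC thresholds behave as documented on small fixtures", {
  m <- matrix(rpois(200, 5), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
  expect_equal(qc_filter(m, 0, 0, 1, 0), m, ignore_attr = TRUE)

  m0 <- m; m0[, 3] <- 0L
  kept <- qc_filter(m0, min_counts = 1)
  expect_false("c3" %in% colnames(kept))
  expect_equal(ncol(kept), 9)

  # quantile filter removes exactly the deepest of ten cells
  depths <- colSums(m)
  kept <- qc_filter(m, max_counts_quantile = 0.9)
  expect_equal(setdiff(colnames(m), colnames(kept)),
               names(which.max(depths)))

  expect_error(qc_filter(m, min_counts = 1e9), "all cells")
})

test_that("log-CPM normalization follows its closed form", {
  m <- matrix(c(0L, 1L, 1L, 0L, 2L, 2L), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  norm <- normalize_log_cpm(m)
  expect_equal(norm["g1", "a"], 0)
  expect_equal(norm["g2", "a"], log(1 + 5000))
  expect_equal(norm["g3", "a"], log(1 + 5000))
  # scale invariance within an observation
  expect_equal(norm[, "b"], normalize_log_cpm(m * 2L)[, "b"])
})

make_blobs <- function(n_per = 200, n_genes = 40, shift = 3, seed = 42) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * 2 * n_per), n_genes)
    m[1:10, seq_len(n_per)] <- m[1:10, seq_len(n_per)] + shift
    dimnames(m) <- list(paste0("g", seq_len(n_genes)),
                        paste0("c", seq_len(2 * n_per)))
    list(norm = pmax(m + 4, 0),
         truth = rep(c("A", "B"), each = n_per))
  })
}

test_that("two planted blobs are recovered perfectly and deterministically", {
  b <- make_blobs()
  lab <- cluster_cells(b$norm, n_pcs = 10, k_neighbors = 10,
                       resolution = 0.1, seed = 3L)
  expect_equal(length(unique(lab)), 2)
  expect_equal(adjusted_rand(lab, b$truth), 1)
  expect_identical(lab, cluster_cells(b$norm, n_pcs = 10, k_neighbors = 10,
                                      resolution = 0.1, seed = 3L))
})

test_that("clustering is invariant to gene order", {
  b <- make_blobs(n_per = 120)
  lab1 <- cluster_cells(b$norm, n_pcs = 10, k_neighbors = 10,
                        resolution = 0.1, seed = 1L)
  perm <- withr::with_seed(9, sample(nrow(b$norm)))
  lab2 <- cluster_cells(b$norm[perm, ], n_pcs = 10, k_neighbors = 10,
                        resolution = 0.1, seed = 1L)
  expect_equal(adjusted_rand(lab1, lab2), 1)
})

test_that("a single tight blob is not split and tiny clusters refuse to", {
  b <- make_blobs(n_per = 150, shift = 0)
  lab <- setNames(rep("A", ncol(b$norm)), colnames(b$norm))
  sub <- subcluster(b$norm, lab, "A", n_pcs = 5, k_neighbors = 10,
                    resolution = 0.1, seed = 1L)
  expect_equal(length(unique(sub)), 1)
  expect_error(cluster_cells(b$norm[, 1:5], k_neighbors = 10), "fewer cells")
  expect_error(subcluster(b$norm, lab, "missing"), "too few cells")
})

test_that("rank-sum p on the 4-vs-4 fixture equals the enumeration value", {
  x <- c(0, 0, 0, 0, 5, 5, 5, 5)
  grp <- rep(c(TRUE, FALSE), each = 4)
  p_pkg <- scarscreen:::wilcox_rank_sum(x, grp)
  # independent enumeration over all 70 group assignments
  r <- rank(x)
  combs <- combn(8, 4)
  stats <- colSums(matrix(r[combs], nrow = 4))
  p_oracle <- mean(abs(stats - mean(stats)) >= abs(sum(r[grp]) - mean(stats)))
  expect_equal(p_oracle, 2 / 70)
  expect_equal(p_pkg, p_oracle)
})

test_that("find_markers flags planted differences and obeys BH monotonicity", {
  withr::with_seed(5, {
    n <- 60
    norm <- matrix(abs(rnorm(40 * n)), 40,
                   dimnames = list(paste0("g", 1:40), paste0("c", 1:n)))
    labels <- setNames(rep(c("A", "B"), each = n / 2), colnames(norm))
    norm["g1", labels == "A"] <- norm["g1", labels == "A"] + 3
    mk <- find_markers(norm, labels)
    expect_true(mk$is_marker[mk$gene == "g1" & mk$cluster == "A"])
    # a constant gene is a marker nowhere
    norm["g2", ] <- 1
    mk <- find_markers(norm, labels)
    expect_false(any(mk$is_marker[mk$gene == "g2"]))
    # BH: q >= p within each cluster family
    expect_true(all(mk$q >= mk$p - 1e-12))
    for (cl in unique(mk$cluster)) {
      sub <- mk[mk$cluster == cl, ]
      ord <- order(sub$p)
      expect_true(all(diff(sub$q[ord]) >= -1e-12))
    }
  })
})

test_that("small clusters are skipped with a warning", {
  norm <- matrix(abs(rnorm(100)), 10,
                 dimnames = list(paste0("g", 1:10), paste0("c", 1:10)))
  labels <- setNames(c(rep("A", 8), "B", "B"), colnames(norm))
  expect_warning(find_markers(norm, labels), "size < 3")
})

test_that("annotation assigns by marker z-score with tie and fallback rules", {
  norm <- matrix(0.1, 4, 9,
                 dimnames = list(c("Dcn", "Lyz2", "Other", "None"),
                                 paste0("c", 1:9)))
  labels <- setNames(rep(c("C1", "C2", "C3"), each = 3), colnames(norm))
  norm["Dcn", labels == "C1"] <- 5
  norm["Lyz2", labels == "C2"] <- 5
  mm <- list(F = "Dcn", M = "Lyz2")
  ann <- annotate_clusters(norm, labels, mm)
  expect_equal(ann$type[ann$cluster == "C1"], "F")
  expect_equal(ann$type[ann$cluster == "C2"], "M")
  # cluster expressing no mapped gene
  ann2 <- annotate_clusters(norm, labels, list(X = "Absent"))
  expect_true(all(ann2$type == "unassigned"))
  # exact tie: lexicographically first type wins, flagged
  norm["Lyz2", ] <- norm["Dcn", ]
  ann3 <- annotate_clusters(norm, labels, mm)
  expect_equal(ann3$type[ann3$cluster == "C1"], "F")
  expect_true(ann3$tie[ann3$cluster == "C1"])
})

test_that("temporal proportions are row-normalized fractions", {
  meta <- data.frame(cell_id = paste0("c", 1:6),
                     timepoint = c(3, 7, 14, 14, 14, 7))
  sub <- setNames(c("F1", "F1", "F1", "F2", "F2", "F2"), meta$cell_id)
  pr <- temporal_proportions(meta, sub)
  expect_equal(unname(rowSums(pr)), c(1, 1), tolerance = 1e-12)
  only14 <- temporal_proportions(meta, setNames(rep("F9", 3),
                                                paste0("c", 3:5)))
  expect_equal(as.numeric(only14), 1)
})

test_that("fibroblast specificity is exclusivity on the CPM scale", {
  n_per <- 4
  clusters <- c("EC", "EpC", "F", "M", "MC", "N", "P", "TC")
  cells <- paste0("c", seq_len(8 * n_per))
  labels <- setNames(rep(clusters, each = n_per), cells)
  norm <- matrix(0, 2, length(cells),
                 dimnames = list(c("fonly", "flat"), cells))
  norm["fonly", labels == "F"] <- log1p(50)
  norm["flat", ] <- log1p(50)
  sc <- fibroblast_specificity(norm, labels, c("fonly", "flat"))
  expect_equal(unname(sc["fonly"]), 1, tolerance = 1e-6)
  expect_equal(unname(sc["flat"]), 1 / 8, tolerance = 1e-6)
  expect_error(fibroblast_specificity(norm, labels, "nope"), "absent")
})

test_that("default study conditions: majors, subclusters and markers recover", {
  fx <- fixture_default()
  pl <- fx$pl
  truth_meta <- fx$ds$sc$meta
  # annotated major labels vs planted truth
  truth_major <- truth_meta$major_label[match(names(pl$major_labels),
                                              truth_meta$cell_id)]
  expect_gte(adjusted_rand(pl$major_labels, truth_major), 0.9)
  # fibroblast subclusters vs planted subclusters
  truth_sub <- truth_meta$pop[match(names(pl$sub_labels), truth_meta$cell_id)]
  expect_gte(adjusted_rand(pl$sub_labels, truth_sub), 0.8)
  # planted subcluster-marker recovery within the fibroblast family
  cl2ty <- map_clusters_to_truth(pl$sub_labels, truth_sub)
  rp <- marker_recall_precision(pl$markers_f, pl$truth, level = "sub",
                                cluster_to_type = cl2ty)
  expect_gte(rp["recall"], 0.9)
  expect_gte(rp["precision"], 0.9)
  # macrophage-shared decoys fall below the specificity threshold
  expect_lt(max(pl$specificity[intersect(
    pl$truth$decoy_genes$fails_fibro_specificity,
    names(pl$specificity))]), 0.7)
  # planted F8 subcluster peaks on Day 7
  f8_truth <- names(which.max(table(truth_sub[pl$sub_labels ==
    names(which.max(table(pl$sub_labels[truth_sub == "F8"])))])))
  expect_equal(f8_truth, "F8")
  det_f8 <- names(cl2ty)[cl2ty == "F8"][1]
  expect_equal(colnames(pl$proportions)[which.max(pl$proportions[det_f8, ])],
               "7")
})
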