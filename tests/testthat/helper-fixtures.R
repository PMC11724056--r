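# Shared fixtures, built lazily and cached for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

# Default study-condition dataset plus one full pipeline run.
fixture_default <- function() {
  if (is.null(.fixture_env$default)) {
    cfg <- pipeline_config(synth_config(seed = 101L), n_perm = 199)
    ds <- simulate_dataset(cfg$synth)
    pl <- run_pipeline(cfg, dataset = ds)
    .fixture_env$default <- list(cfg = cfg, ds = ds, pl = pl)
  }
  .fixture_env$default
}

# Adjusted Rand index between two label vectors.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Expected counts-per-transcript profile of each major type given the
# realized population composition (independent of the detectors).
expected_major_profiles <- function(truth) {
  freq <- table(truth$cell_labels$pop)
  pops <- rownames(truth$pop_prob)
  freq <- as.numeric(freq[pops])
  freq[is.na(freq)] <- 0
  majors <- sort(unique(truth$major_of))
  t(sapply(majors, function(m) {
    w <- freq * (truth$major_of[pops] == m)
    as.numeric(crossprod(truth$pop_prob, w / sum(w)))
  }))
}

# Planted-marker recall/precision for a set of detected markers.
# Precision ignores genes that are genuinely enriched by construction
# (expected ratio >= ambiguous_ratio) without being planted exclusive
# markers: mixtures make those calls correct but unplanted.
marker_recall_precision <- function(markers, truth, level = "major",
                                    cluster_to_type,
                                    ambiguous_ratio = 1.2) {
  E <- expected_major_profiles(truth)
  colnames(E) <- colnames(truth$pop_prob)
  planted <- truth$marker_genes[[if (level == "major") "major" else "sub"]]
  tp <- 0L; n_truth <- 0L; n_det <- 0L
  for (cl in names(cluster_to_type)) {
    ty <- cluster_to_type[[cl]]
    if (!ty %in% names(planted)) next
    truth_set <- planted[[ty]]
    det <- markers$gene[markers$cluster == cl & markers$is_marker]
    if (level == "major") {
      ratio <- E[ty, ] / colMeans(E[rownames(E) != ty, , drop = FALSE])
    } else {
      P <- truth$pop_prob
      fam <- names(planted)
      ratio <- P[ty, ] / colMeans(P[setdiff(fam, ty), , drop = FALSE])
    }
    ambiguous <- setdiff(names(ratio)[ratio >= ambiguous_ratio], truth_set)
    det_scored <- setdiff(det, ambiguous)
    tp <- tp + length(intersect(det, truth_set))
    n_truth <- n_truth + length(truth_set)
    n_det <- n_det + length(det_scored)
  }
  c(recall = tp / n_truth, precision = tp / n_det)
}

# Majority-vote mapping from detected cluster labels to truth labels.
map_clusters_to_truth <- function(detected, truth_labels) {
  vapply(sort(unique(detected)), function(cl) {
    names(which.max(table(truth_labels[detected == cl])))
  }, "")
}
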