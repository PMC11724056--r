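# Ground-truth generator: determinism, planted effect sizes, simplex
# invariants, and decoy completeness.

small_cfg <- function(seed = 7L, ...) {
  synth_config(n_genes = 500L, n_cells_per_timepoint = 600L,
               grid_shape = c(12L, 12L), wound_radius_um = 400,
               seed = seed, ...)
}

test_that("generators are deterministic under a fixed seed", {
  cfg <- small_cfg()
  a <- generate_single_cell(cfg)
  b <- generate_single_cell(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$meta, b$meta)
  ba <- generate_bulk(cfg, a$truth)
  bb <- generate_bulk(cfg, b$truth)
  expect_identical(ba$counts, bb$counts)
  va <- generate_visium(cfg, a$truth, 7L)
  vb <- generate_visium(cfg, b$truth, 7L)
  expect_identical(va$counts, vb$counts)
  expect_identical(va$spot_weights, vb$spot_weights)
})

test_that("config validation rejects invalid noise and spot settings", {
  expect_error(synth_config(nb_dispersion = 0), "dispersion")
  expect_error(synth_config(ko_downregulation_log2fc = 1), "log2fc")
  expect_error(synth_config(cells_per_spot_range = c(30, 20)), "cells_per_spot")
  expect_error(synth_config(wound_radius_um = 1e6), "grid extent")
})

test_that("zero marker effect removes all planted marker fold-changes", {
  cfg <- small_cfg(marker_log2fc = 0)
  sc <- generate_single_cell(cfg)
  rates <- sc$truth$type_mean_profiles
  for (ty in names(sc$truth$marker_genes$major)) {
    mk <- sc$truth$marker_genes$major[[ty]]
    expect_equal(max(apply(rates[, mk, drop = FALSE], 2, max) /
                       apply(rates[, mk, drop = FALSE], 2, min)), 1)
  }
})

test_that("planted subcluster markers reach the configured fold-change", {
  cfg <- synth_config(seed = 5L)
  sc <- generate_single_cell(cfg)
  for (sub in c("F1", "F4")) {
    mk <- sc$truth$marker_genes$sub[[sub]][1]
    inside <- sc$meta$pop == sub
    ratio <- mean(sc$counts[mk, inside]) / mean(sc$counts[mk, !inside])
    expect_gt(sum(inside), 300)
    expect_lt(abs(ratio / 2^cfg$marker_log2fc - 1), 0.25)
  }
})

test_that("proportions, spot weights, and directions live on their simplices", {
  cfg <- small_cfg()
  sc <- generate_single_cell(cfg)
  for (tp in as.character(cfg$timepoints)) {
    expect_equal(sum(cfg$major_types$props[[tp]]), 1, tolerance = 1e-9)
    expect_equal(sum(cfg$fibro_subclusters$props[[tp]]), 1, tolerance = 1e-9)
    expect_equal(sum(cfg$macro_subclusters$props[[tp]]), 1, tolerance = 1e-9)
  }
  vs <- generate_visium(cfg, sc$truth, 7L)
  expect_equal(unname(rowSums(vs$spot_weights)), rep(1, nrow(vs$spot_weights)),
               tolerance = 1e-9)
  nrm <- sqrt(rowSums(vs$planted_direction^2))
  expect_true(all(abs(nrm[nrm > 0] - 1) < 1e-9))
})

test_that("per-timepoint subcluster composition matches the configured timing", {
  sc <- generate_single_cell(synth_config(seed = 3L))
  f <- sc$meta[sc$meta$major_label == "F", ]
  # F4, F6, F8 are planted absent on Day 3
  expect_equal(sum(f$sub_label %in% c("F4", "F6", "F8") & f$timepoint == 3), 0)
  # observed day-7 subcluster frequencies track the configured simplex
  tab7 <- table(f$sub_label[f$timepoint == 7])
  p7 <- as.numeric(tab7[paste0("F", 1:8)]) / sum(tab7)
  expect_lt(max(abs(p7 - synth_config()$fibro_subclusters$props[["7"]])), 0.05)
})

test_that("bulk KO scaling hits the configured fold-change in expectation", {
  cfg <- synth_config(seed = 9L)
  sc <- generate_single_cell(cfg)
  bk <- generate_bulk(cfg, sc$truth)
  flagged <- sc$truth$ko_flagged
  wt <- rowMeans(bk$counts[, bk$design$genotype == "WT"])
  ko <- rowMeans(bk$counts[, bk$design$genotype == "KO"])
  # averaged over flagged genes the empirical ratio approaches 2^lfc
  ratio <- mean(ko[flagged] / wt[flagged])
  expect_lt(abs(ratio / 2^cfg$ko_downregulation_log2fc - 1), 0.25)
  # housekeeping genes: mean log2 ratio within sampling error of 0
  hk <- setdiff(rownames(bk$counts), flagged)
  hk <- hk[wt[hk] > 50]
  expect_lt(abs(mean(log2(ko[hk] / wt[hk]))), 0.3)
})

test_that("zero KO effect leaves WT and KO expectations identical", {
  cfg <- small_cfg(ko_downregulation_log2fc = 0)
  sc <- generate_single_cell(cfg)
  bk <- generate_bulk(cfg, sc$truth)
  expect_equal(bk$expected_rate[, "WT"], bk$expected_rate[, "KO"])
})

test_that("wound spot count equals the lattice-disk enumeration", {
  cfg <- synth_config(seed = 2L)
  sc <- generate_single_cell(cfg)
  vs <- generate_visium(cfg, sc$truth, 7L)
  # independent geometric count: lattice points within the wound radius
  g <- expand.grid(r = 0:(cfg$grid_shape[1] - 1), c = 0:(cfg$grid_shape[2] - 1))
  x <- g$c * cfg$spot_spacing_um
  y <- g$r * cfg$spot_spacing_um
  cx <- mean(range(x)); cy <- mean(range(y))
  n_expected <- sum(sqrt((x - cx)^2 + (y - cy)^2) <= cfg$wound_radius_um)
  expect_equal(sum(vs$spots$region == "wound"), n_expected)
})

test_that("planted ligand peaks on the margin and receptor at the center", {
  R <- 700
  r_margin <- seq(0.6 * R, R, length.out = 20)
  r_center <- seq(0, 0.45 * R, length.out = 20)
  fl <- scarscreen:::lr_spatial_factor
  expect_gt(mean(fl(r_margin, R, "ligand", "margin_to_center")),
            mean(fl(r_center, R, "ligand", "margin_to_center")))
  expect_gt(mean(fl(r_center, R, "receptor", "margin_to_center")),
            mean(fl(r_margin, R, "receptor", "margin_to_center")))
  # reversed geometry swaps the roles
  expect_gt(mean(fl(r_center, R, "ligand", "center_to_margin")),
            mean(fl(r_margin, R, "ligand", "center_to_margin")))
})

test_that("every screen criterion has a dedicated decoy, disjoint from truth", {
  sc <- generate_single_cell(small_cfg())
  decoys <- sc$truth$decoy_genes
  expect_setequal(names(decoys),
                  c("fails_ko_down", "fails_fibro_marker",
                    "fails_fibro_specificity", "fails_spatial_support"))
  expect_true(all(lengths(decoys) >= 1))
  for (d in decoys) {
    expect_length(intersect(d, sc$truth$true_scar_genes), 0)
  }
})
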