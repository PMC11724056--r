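# Reference construction, EM deconvolution and region-level DEGs.

toy_reference <- function() {
  rbind(A = c(0.7, 0.2, 0.1),
        B = c(0.1, 0.2, 0.7),
        C = c(0.2, 0.6, 0.2)) ->
    ref
  colnames(ref) <- paste0("g", 1:3)
  ref
}

test_that("reference profiles are per-type means on the simplex", {
  counts <- matrix(c(2L, 0L, 0L, 2L, 0L, 4L), nrow = 2,
                   dimnames = list(c("gA", "gB"), c("c1", "c2", "c3")))
  labels <- setNames(c("T1", "T1", "T2"), colnames(counts))
  ref <- build_reference(counts, labels, min_cells = 1)
  expect_equal(unname(ref["T1", ]), c(0.5, 0.5))
  expect_equal(unname(ref["T2", ]), c(0, 1))
  expect_equal(unname(rowSums(ref)), c(1, 1), tolerance = 1e-12)
  # single type, single informative gene
  one <- build_reference(matrix(3L, 1, 1, dimnames = list("g", "c")),
                         setNames("T", "c"), min_cells = 1)
  expect_equal(unname(one[1, 1]), 1)
  expect_error(build_reference(counts, labels, min_cells = 5), "T1")
})

test_that("a pure spot deconvolves to a unit weight vector", {
  ref <- toy_reference()
  y <- round(1000 * ref["B", ])
  fit <- deconvolve_spot(y, ref)
  # at a boundary optimum the multiplicative EM converges sublinearly,
  # so the off-support weights decay like 1/iterations
  expect_gt(fit$weights["B"], 0.99)
})

test_that("gene order does not affect weights; count scaling barely does", {
  ref <- toy_reference()
  y <- c(g1 = 300, g2 = 300, g3 = 400)
  f1 <- deconvolve_spot(y, ref)
  perm <- c(3, 1, 2)
  f2 <- deconvolve_spot(y[perm], ref[, perm])
  expect_equal(f1$weights, f2$weights, tolerance = 1e-9)
  f3 <- deconvolve_spot(y * 7, ref)
  expect_equal(f1$weights, f3$weights, tolerance = 1e-4)
})

test_that("zero-count spots are skipped with a flag", {
  ref <- toy_reference()
  y0 <- setNames(c(0, 0, 0), colnames(ref))
  expect_true(deconvolve_spot(y0, ref)$skipped)
  m <- cbind(s1 = c(g1 = 10, g2 = 10, g3 = 10), s2 = c(0, 0, 0))
  expect_warning(dc <- deconvolve_all(m, ref), "skipped")
  expect_true(dc$skipped[2])
  expect_false(dc$skipped[1])
})

test_that("the EM log-likelihood trace is nondecreasing", {
  fx <- fixture_default()
  vs <- fx$ds$visium$day7
  ref <- build_reference(fx$ds$sc$counts,
                         setNames(fx$ds$sc$meta$major_label,
                                  fx$ds$sc$meta$cell_id))
  idx <- seq(1, ncol(vs$counts), length.out = 25)
  for (j in round(idx)) {
    fit <- deconvolve_spot(vs$counts[, j], ref, trace = TRUE)
    expect_true(all(diff(fit$loglik_trace) > -1e-7))
  }
})

test_that("recovery improves with spot depth", {
  ref <- toy_reference()
  w <- c(0.6, 0.3, 0.1)
  errs <- vapply(c(200, 20000), function(depth) {
    p <- as.numeric(w %*% ref)
    y <- withr::with_seed(13, as.numeric(stats::rmultinom(1, depth, p)))
    names(y) <- colnames(ref)
    fit <- deconvolve_spot(y, ref)
    max(abs(fit$weights - w))
  }, 0)
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 0.02)
})

test_that("dominant-type map reports argmax, margin and ties", {
  dc <- structure(list(weights = rbind(s1 = c(A = 0.5, B = 0.5, C = 0),
                                       s2 = c(A = 1, B = 0, C = 0))),
                  class = "spot_deconv")
  dom <- dominant_type_map(dc)
  expect_true(dom$tie[1])
  expect_equal(dom$dominant[2], "A")
  expect_equal(dom$margin[2], 1)
})

test_that("wound spots carry more fibroblast+macrophage weight than intact", {
  fx <- fixture_default()
  pl <- fx$pl
  vs <- fx$ds$visium$day7
  fm <- rowSums(pl$deconv$weights[, c("F", "M")])
  wound <- vs$spots$region == "wound"
  expect_gt(mean(fm[wound]), mean(fm[!wound]))
  # and the wound-center dominant call is fibroblast/macrophage on day 7
  r2 <- (vs$spots$x_um - mean(range(vs$spots$x_um)))^2 +
    (vs$spots$y_um - mean(range(vs$spots$y_um)))^2
  center <- which.min(r2)
  expect_true(dominant_type_map(pl$deconv)$dominant[center] %in% c("F", "M"))
})

test_that("region DEG matches the exact rank-sum enumeration on 5v5", {
  counts <- matrix(0L, 2, 10,
                   dimnames = list(c("up", "flat"), paste0("s", 1:10)))
  counts["up", ] <- c(rep(60L, 5), rep(10L, 5))
  counts["flat", ] <- 30L
  spots <- data.frame(spot_id = colnames(counts),
                      region = rep(c("wound", "intact"), each = 5))
  rd <- region_deg(counts, spots, timepoint = 7)
  expect_equal(rd$p[rd$gene == "up"], 2 / choose(10, 5))
  expect_false(rd$supported[rd$gene == "flat"])
  expect_error(region_deg(counts[, 1:6], spots[1:6, ]), "fewer than")
})

test_that("planted wound-upregulated genes are recovered spatially", {
  fx <- fixture_default()
  rd7 <- fx$pl$region_degs$day7
  truth <- fx$pl$truth
  wound_genes <- truth$true_scar_genes
  recall <- mean(rd7$supported[match(wound_genes, rd7$gene)])
  expect_gte(recall, 0.9)
  # the intact-dermis decoy is not wound-supported at any timepoint
  for (rd in fx$pl$region_degs) {
    expect_false(rd$supported[rd$gene == truth$decoy_genes$fails_spatial_support])
  }
})
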