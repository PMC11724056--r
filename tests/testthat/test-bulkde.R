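# Size factors, dispersion estimation, the NB Wald test and the
# candidate-gene rule.

sim_counts <- function(n_genes, mu, alpha, n = 8, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnbinom(n_genes * n, mu = rep(mu, n), size = 1 / alpha),
                ncol = n)
    dimnames(m) <- list(paste0("g", seq_len(n_genes)), paste0("s", seq_len(n)))
    m
  })
}

two_group <- function(n = 8) {
  data.frame(sample_id = paste0("s", 1:n),
             genotype = rep(c("WT", "KO"), each = n / 2))
}

test_that("median-of-ratios size factors have the documented closed form", {
  m <- matrix(rep(c(10L, 20L, 30L), 3), 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_equal(unname(size_factors(m)), rep(1, 3), tolerance = 1e-12)
  m2 <- cbind(m, s4 = m[, 1] * 2L)
  sf <- size_factors(m2)
  expect_equal(unname(sf[4] / sf[1]), 2, tolerance = 1e-12)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
})

test_that("size factors fall back to totals when no gene is always positive", {
  m <- matrix(c(5L, 0L, 0L, 7L), 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_warning(sf <- size_factors(m), "total-count")
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
})

test_that("dispersion estimation recovers known simulation values", {
  des <- two_group(100)
  pois <- sim_counts(300, rep(100, 300), 1e-9, n = 100, seed = 2)
  d <- estimate_dispersion(pois, des, rep(1, 100), shrink = 0)
  expect_lte(mean(d$dispersion_raw), 0.02)

  nb <- sim_counts(300, rep(100, 300), 0.5, n = 100, seed = 3)
  d2 <- estimate_dispersion(nb, des, rep(1, 100), shrink = 0)
  expect_gt(mean(d2$dispersion_raw), 0.3)
  expect_lt(mean(d2$dispersion_raw), 0.7)

  const <- matrix(7L, 10, 100,
                  dimnames = list(paste0("g", 1:10), paste0("s", 1:100)))
  d3 <- estimate_dispersion(const, des, rep(1, 100), shrink = 0)
  expect_equal(unname(d3$dispersion_raw), rep(0, 10))
})

test_that("identical genotype groups give null fold-changes", {
  half <- sim_counts(50, exp(runif(50, 2, 5)), 0.2, n = 4, seed = 4)
  cnt <- cbind(half, half)
  colnames(cnt) <- paste0("s", 1:8)
  de <- nb_wald_test(cnt, two_group())
  expect_lt(max(abs(de$log2fc), na.rm = TRUE), 1e-6)
  expect_true(all(de$p[de$tested] > 0.99))
})

test_that("exchanging genotype labels negates log2fc and keeps p-values", {
  cnt <- sim_counts(200, exp(runif(200, 2, 6)), 0.2, seed = 5)
  des <- two_group()
  de1 <- nb_wald_test(cnt, des)
  des2 <- des
  des2$genotype <- ifelse(des$genotype == "WT", "KO", "WT")
  de2 <- nb_wald_test(cnt, des2)
  expect_equal(de2$log2fc, -de1$log2fc, tolerance = 1e-6)
  expect_equal(de2$p, de1$p, tolerance = 1e-6)
})

test_that("low-expression genes are flagged untested, not given p = 1", {
  cnt <- sim_counts(50, c(rep(0.05, 25), rep(100, 25)), 0.2, seed = 6)
  de <- nb_wald_test(cnt, two_group())
  lo <- de$base_mean < 1
  expect_true(any(lo))
  expect_true(all(!de$tested[lo]))
  expect_true(all(is.na(de$q[lo])))
})

test_that("candidate rule keeps only significant KO-downregulated genes", {
  de <- structure(data.frame(
    gene = c("down_sig", "up_sig", "down_ns", "untested"),
    base_mean = c(50, 50, 50, 0.1),
    log2fc = c(-2, 2, -2, -3),
    dispersion = 0.1, wald_stat = 0,
    p = c(1e-6, 1e-6, 0.5, NA),
    q = c(1e-5, 1e-5, 0.6, NA),
    tested = c(TRUE, TRUE, TRUE, FALSE),
    converged = TRUE), class = c("de_table", "data.frame"))
  expect_equal(candidate_inflammation_genes(de), "down_sig")
  expect_warning(candidate_inflammation_genes(de, q_max = 1e-9, lfc_max = -5),
                 "no candidate")
  expect_error(candidate_inflammation_genes(de, lfc_max = 1), "lfc_max")
})

test_that("the NB Wald fit agrees with an established NB DE implementation", {
  # planted effects, moderate size; compare against DESeq2 as an
  # independent oracle for the GLM fold-change estimates
  withr::with_seed(8, {
    mu <- exp(runif(300, 3, 6))
    fc <- rep(1, 300); fc[1:40] <- 0.25
    wt <- matrix(rnbinom(300 * 4, mu = rep(mu, 4), size = 10), ncol = 4)
    ko <- matrix(rnbinom(300 * 4, mu = rep(mu * fc, 4), size = 10), ncol = 4)
    cnt <- cbind(wt, ko)
    dimnames(cnt) <- list(paste0("g", 1:300), paste0("s", 1:8))
  })
  des <- two_group()
  de <- nb_wald_test(cnt, des)

  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      cnt, data.frame(genotype = factor(des$genotype, c("WT", "KO"))),
      ~genotype)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds, contrast = c("genotype", "KO", "WT"))
  })
  ok <- de$tested & !is.na(res$log2FoldChange)
  expect_gt(cor(de$log2fc[ok], res$log2FoldChange[ok]), 0.98)
  # the planted downregulated block is called by both
  both_called <- de$q < 0.05 & de$log2fc < -1
  expect_gt(mean(both_called[1:40], na.rm = TRUE), 0.9)
  expect_gt(mean((res$padj < 0.05)[1:40], na.rm = TRUE), 0.9)
})
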