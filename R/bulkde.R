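# Bulk differential expression: negative-binomial Wald tests of WT vs
# inflammation-deficient (KO) wound samples, yielding the candidate
# inflammation-related gene set.

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors against the geometric-mean
#' pseudo-reference, computed over genes with all-positive counts and
#' rescaled to geometric mean 1.
#'
#' @param counts gene x sample matrix.
#' @return numeric vector of factors, one per sample.
#' @export
size_factors <- function(counts) {
  if (any(colSums(counts) <= 0)) stop("sample with non-positive total")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no gene positive in all samples; using total-count factors")
    sf <- colSums(counts)
  } else {
    lg <- log(counts[pos, , drop = FALSE])
    ref <- rowMeans(lg)
    sf <- exp(apply(lg - ref, 2, median))
  }
  sf / exp(mean(log(sf)))
}

#' Method-of-moments dispersion estimates with trend shrinkage
#'
#' Per gene, the pooled within-genotype moment estimator
#' `alpha = max(0, (s2 - mu) / mu^2)` on size-factor-normalized counts,
#' shrunk toward a lowess mean-dispersion trend with weight `shrink`.
#' At the n = 4 designs this pipeline targets, the trend must carry
#' most of the weight for the downstream Wald test to hold its nominal
#' size, hence the default of 0.8.
#'
#' @param counts gene x sample matrix.
#' @param design data.frame with `genotype` per sample (matrix column
#'   order).
#' @param factors size factors from [size_factors()].
#' @param shrink weight on the trended value (default 0.8).
#' @return data.frame: gene, base_mean, dispersion_raw, dispersion,
#'   defined flag.
#' @export
estimate_dispersion <- function(counts, design, factors, shrink = 0.8) {
  groups <- split(seq_len(ncol(counts)), design$genotype)
  if (any(lengths(groups) < 2)) stop("need >= 2 replicates per genotype")
  norm <- sweep(counts, 2, factors, `/`)
  base_mean <- rowMeans(norm)

  # within-group moment estimates, combined with df weights; estimating
  # per group avoids inflating the dispersion of genuinely DE genes
  num <- 0
  den <- 0
  for (g in groups) {
    m <- rowMeans(norm[, g, drop = FALSE])
    s2 <- rowSums((norm[, g, drop = FALSE] - m)^2) / (length(g) - 1)
    # denominator m^2 - s2/n corrects the bias of the plug-in group mean
    a_g <- ifelse(m > 0, (s2 - m) / pmax(m^2 - s2 / length(g), 1e-8), NA)
    w_g <- length(g) - 1
    num <- num + ifelse(is.na(a_g), 0, a_g * w_g)
    den <- den + ifelse(is.na(a_g), 0, w_g)
  }
  raw <- pmax(0, ifelse(den > 0, num / den, NA))
  defined <- base_mean > 0
  raw[!defined] <- NA

  # lowess trend of dispersion against log mean, over expressed genes
  ok <- defined & base_mean >= 1
  trend <- rep(NA_real_, length(raw))
  if (sum(ok) >= 10 && diff(range(log(base_mean[ok]))) > 0.1) {
    # iter = 0: fit the mean of the skewed raw estimates, not a
    # robustified centre, so the trend is unbiased for the dispersion
    fit <- lowess(log(base_mean[ok]), raw[ok], f = 0.5, iter = 0)
    trend[defined] <- approx(fit$x, fit$y, xout = log(base_mean[defined]),
                             rule = 2, ties = mean)$y
    trend[defined] <- pmax(trend[defined], 1e-8)
  } else {
    trend[defined] <- mean(raw[ok], na.rm = TRUE)
  }
  disp <- (1 - shrink) * raw + shrink * trend
  disp <- pmax(disp, 1e-8)
  disp[!defined] <- NA
  data.frame(gene = rownames(counts), base_mean = base_mean,
             dispersion_raw = raw, dispersion = disp,
             defined = defined, stringsAsFactors = FALSE)
}

# NB GLM with a two-group design fit by IRLS at fixed dispersion.
# Returns beta (log2 fold-change KO - WT), its SE, and convergence.
nb_fit_gene <- function(y, offset, x, alpha, max_iter = 100, tol = 1e-8) {
  # model: log mu = log(sf) + b0 + b1 * x   (natural log internally)
  b <- c(log(mean(y / exp(offset)) + 0.1), 0)
  X <- cbind(1, x)
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- offset + X %*% b
    mu <- pmin(exp(eta), 1e12)
    w <- as.numeric(mu / (1 + alpha * mu))
    z <- eta - offset + (y - mu) / mu
    XtW <- t(X * w)
    H <- XtW %*% X
    if (rcond(H) < 1e-12) break
    b_new <- solve(H, XtW %*% z)
    if (max(abs(b_new - b)) < tol) {
      b <- b_new
      conv <- TRUE
      break
    }
    b <- b_new
  }
  eta <- offset + X %*% b
  mu <- pmin(exp(eta), 1e12)
  w <- as.numeric(mu / (1 + alpha * mu))
  H <- t(X * w) %*% X
  se <- if (rcond(H) > 1e-12) sqrt(solve(H)[2, 2]) else NA_real_
  c(beta = b[2], se = se, converged = as.numeric(conv))
}

#' Negative-binomial Wald differential expression test
#'
#' Per gene, fits an NB GLM with genotype indicator by IRLS at the
#' fixed, trend-shrunk dispersion, and tests `KO - WT` with a Wald
#' z statistic (`beta / SE`, two-sided normal reference; the trend
#' shrinkage of the dispersion is what keeps the small-sample
#' calibration honest). BH correction is applied over
#' genes passing the expression floor `base_mean >= 1`; genes below the
#' floor are flagged `tested = FALSE` rather than assigned p = 1.
#'
#' @param counts gene x sample matrix.
#' @param design data.frame with `genotype` ("WT"/"KO") per sample.
#' @param factors size factors; computed if NULL.
#' @param dispersions dispersion table from [estimate_dispersion()];
#'   computed if NULL.
#' @return data.frame of class `de_table`: gene, base_mean, log2fc
#'   (KO - WT), dispersion, wald_stat, p, q, tested, converged.
#' @export
nb_wald_test <- function(counts, design, factors = NULL, dispersions = NULL) {
  stopifnot(all(design$genotype %in% c("WT", "KO")))
  if (is.null(factors)) factors <- size_factors(counts)
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersion(counts, design, factors)
  }
  x <- as.numeric(design$genotype == "KO")
  offset <- log(factors)

  res <- t(vapply(seq_len(nrow(counts)), function(i) {
    a <- dispersions$dispersion[i]
    if (is.na(a) || dispersions$base_mean[i] <= 0) {
      return(c(beta = NA, se = NA, converged = 0))
    }
    nb_fit_gene(counts[i, ], offset, x, a)
  }, c(beta = 0, se = 0, converged = 0)))

  log2fc <- res[, "beta"] / log(2)
  stat <- res[, "beta"] / res[, "se"]
  p <- 2 * pnorm(-abs(stat))
  p[res[, "converged"] == 0] <- NA

  tested <- dispersions$base_mean >= 1 & !is.na(p)
  q <- rep(NA_real_, length(p))
  q[tested] <- p.adjust(p[tested], method = "BH")

  out <- data.frame(gene = rownames(counts),
                    base_mean = dispersions$base_mean,
                    log2fc = log2fc,
                    dispersion = dispersions$dispersion,
                    wald_stat = stat, p = p, q = q,
                    tested = tested,
                    converged = res[, "converged"] > 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_table", "data.frame")
  out
}

#' @export
print.de_table <- function(x, ...) {
  cat("de_table:", nrow(x), "genes,", sum(x$tested), "tested,",
      sum(x$q < 0.05, na.rm = TRUE), "at q < 0.05\n")
  invisible(x)
}

#' Candidate inflammation-related genes
#'
#' Genes significantly downregulated in the inflammation-deficient
#' genotype: `q < q_max` and `log2fc <= lfc_max` (defaults 0.05, -1).
#'
#' @param de a `de_table` from [nb_wald_test()].
#' @param q_max FDR threshold in (0, 1).
#' @param lfc_max log2 fold-change ceiling (< 0).
#' @return character vector of gene symbols.
#' @export
candidate_inflammation_genes <- function(de, q_max = 0.05, lfc_max = -1) {
  stopifnot(q_max > 0, q_max < 1)
  if (lfc_max >= 0) stop("lfc_max must be < 0 (downregulated in KO)")
  keep <- de$tested & !is.na(de$q) & de$q < q_max & de$log2fc <= lfc_max
  out <- de$gene[keep]
  if (!length(out)) warning("no candidate genes at the given thresholds")
  out
}
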