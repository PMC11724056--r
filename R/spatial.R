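# Spatial module: reference-based spot deconvolution by multinomial EM,
# dominant-type maps, and wound-vs-intact region DEGs.

#' Build a cell-type expression reference from annotated single cells
#'
#' Per type, the mean raw count per gene, normalized so each type's
#' profile sums to 1 (an expected transcript-fraction profile). Genes
#' with zero total across all types are dropped.
#'
#' @param counts gene x cell count matrix.
#' @param major_labels per-cell type labels (named by cell or in column
#'   order).
#' @param min_cells minimum cells per type (default 10).
#' @return matrix type x gene, rows on the probability simplex.
#' @export
build_reference <- function(counts, major_labels, min_cells = 10) {
  if (!is.null(names(major_labels))) {
    major_labels <- major_labels[colnames(counts)]
  }
  types <- sort(unique(major_labels))
  sizes <- table(major_labels)
  low <- names(sizes)[sizes < min_cells]
  if (length(low)) {
    stop("type(s) below the ", min_cells, "-cell floor: ",
         paste(low, collapse = ", "))
  }
  membership <- matrix(0, length(major_labels), length(types),
                       dimnames = list(NULL, types))
  for (ty in types) membership[major_labels == ty, ty] <- 1
  prof <- t(sweep(counts %*% membership, 2, colSums(membership), `/`))
  keep <- colSums(prof) > 0
  prof <- prof[, keep, drop = FALSE]
  prof / rowSums(prof)
}

# Multinomial-mixture log-likelihood of one spot's counts under weights w.
spot_loglik <- function(y, w, R) {
  p <- as.numeric(w %*% R)
  sum(y[p > 0] * log(p[p > 0]))
}

#' Deconvolve a single spot against a reference
#'
#' Maximizes the multinomial mixture log-likelihood
#' `sum_g y_g log(sum_k w_k R_kg)` over the weight simplex by EM:
#' responsibilities `z_gk` proportional to `w_k R_kg`, then
#' `w_k <- sum_g y_g z_gk / sum_g y_g`. Uniform initialization;
#' stops when `max |dw| < tol` or `max_iter`.
#'
#' @param y named count vector (genes matching `reference` columns).
#' @param reference type x gene simplex profile matrix.
#' @param max_iter maximum EM iterations (default 500).
#' @param tol convergence threshold on the weight change (default 1e-6).
#' @param trace record the per-iteration log-likelihood.
#' @return list: weights (simplex vector), loglik, n_iter, converged,
#'   and optionally loglik_trace.
#' @export
deconvolve_spot <- function(y, reference, max_iter = 500, tol = 1e-6,
                            trace = FALSE) {
  if (!is.null(names(y))) y <- y[colnames(reference)]
  if (sum(y) <= 0) {
    return(list(weights = rep(NA_real_, nrow(reference)),
                loglik = NA_real_, n_iter = 0L, converged = FALSE,
                skipped = TRUE))
  }
  K <- nrow(reference)
  w <- rep(1 / K, K)
  names(w) <- rownames(reference)
  N <- sum(y)
  tr <- if (trace) numeric(0) else NULL
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    denom <- as.numeric(w %*% reference)       # mixture probability per gene
    pos <- denom > 0 & y > 0
    # E-step responsibilities folded into the M-step update
    w_new <- as.numeric(reference[, pos, drop = FALSE] %*%
                          (y[pos] / denom[pos])) * w / N
    w_new <- w_new / sum(w_new)
    if (trace) tr <- c(tr, spot_loglik(y, w_new, reference))
    delta <- max(abs(w_new - w))
    w <- setNames(w_new, rownames(reference))
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  out <- list(weights = w, loglik = spot_loglik(y, w, reference),
              n_iter = it, converged = converged, skipped = FALSE)
  if (trace) out$loglik_trace <- tr
  out
}

#' Select informative genes for deconvolution
#'
#' The union of the top `n_top` most type-discriminative genes per
#' reference type (highest ratio of the type's transcript fraction to
#' the mean fraction across the other types), concentrating the
#' mixture-model signal the way reference-based decomposition methods
#' do.
#'
#' @param reference type x gene simplex matrix.
#' @param n_top genes retained per type (default 50).
#' @return character vector of gene names.
#' @export
select_deconv_genes <- function(reference, n_top = 50) {
  K <- nrow(reference)
  picks <- lapply(seq_len(K), function(k) {
    rest <- colMeans(reference[-k, , drop = FALSE])
    ratio <- (reference[k, ] + 1e-12) / (rest + 1e-12)
    colnames(reference)[order(-ratio)][seq_len(min(n_top, ncol(reference)))]
  })
  sort(unique(unlist(picks)))
}

#' Deconvolve all spots of a count matrix
#'
#' Runs the multinomial EM of [deconvolve_spot()] simultaneously over
#' all spots (the updates are independent across spots and vectorize as
#' matrix products), restricted to the genes shared with the reference.
#'
#' @param spots_counts gene x spot count matrix.
#' @param reference type x gene simplex matrix from [build_reference()].
#' @param genes optional gene subset (e.g. [select_deconv_genes()]);
#'   NULL uses all shared genes.
#' @param max_iter,tol EM controls.
#' @return object of class `spot_deconv`: weights (spot x type matrix),
#'   loglik, n_iter, converged, skipped per spot.
#' @export
deconvolve_all <- function(spots_counts, reference, genes = NULL,
                           max_iter = 500, tol = 1e-6) {
  shared <- intersect(colnames(reference), rownames(spots_counts))
  if (!is.null(genes)) shared <- intersect(shared, genes)
  if (length(shared) < 2) stop("gene universes do not overlap")
  R <- reference[, shared, drop = FALSE]
  R <- R / rowSums(R)
  Y <- t(spots_counts[shared, , drop = FALSE])     # spots x genes
  n <- nrow(Y)
  K <- nrow(R)
  tot <- rowSums(Y)
  sk <- tot <= 0
  if (any(sk)) warning(sum(sk), " spot(s) with zero counts skipped")

  W <- matrix(1 / K, n, K, dimnames = list(rownames(Y), rownames(R)))
  ni <- integer(n)
  cv <- logical(n)
  live <- which(!sk)
  for (it in seq_len(max_iter)) {
    if (!length(live)) break
    D <- W[live, , drop = FALSE] %*% R
    A <- (Y[live, , drop = FALSE] / pmax(D, 1e-300)) %*% t(R)
    W_new <- W[live, , drop = FALSE] * A / tot[live]
    W_new <- W_new / rowSums(W_new)
    delta <- apply(abs(W_new - W[live, , drop = FALSE]), 1, max)
    W[live, ] <- W_new
    ni[live] <- it
    done <- delta < tol
    cv[live[done]] <- TRUE
    live <- live[!done]
  }
  W[sk, ] <- NA_real_
  ll <- vapply(seq_len(n), function(j) {
    if (sk[j]) NA_real_ else spot_loglik(Y[j, ], W[j, ], R)
  }, 0)
  structure(list(weights = W, loglik = ll, n_iter = ni,
                 converged = cv, skipped = sk,
                 reference_types = rownames(R), n_genes = length(shared)),
            class = "spot_deconv")
}

#' @export
print.spot_deconv <- function(x, ...) {
  cat("spot_deconv:", nrow(x$weights), "spots x",
      ncol(x$weights), "types (", x$n_genes, "genes );",
      sum(x$converged), "converged,", sum(x$skipped), "skipped\n")
  cat("mean weights:\n")
  print(round(colMeans(x$weights, na.rm = TRUE), 3))
  invisible(x)
}

#' @export
summary.spot_deconv <- function(object, ...) {
  cat("Deconvolution of", nrow(object$weights), "spots against",
      ncol(object$weights), "reference types\n")
  cat("EM iterations: median", median(object$n_iter),
      "max", max(object$n_iter), "\n")
  invisible(object)
}

#' Dominant cell type per spot
#'
#' @param deconv a `spot_deconv` object.
#' @return data.frame: spot_id, dominant type, margin (top1 - top2
#'   weight), tie flag.
#' @export
dominant_type_map <- function(deconv) {
  W <- deconv$weights
  res <- lapply(seq_len(nrow(W)), function(i) {
    w <- W[i, ]
    if (all(is.na(w))) {
      return(data.frame(spot_id = rownames(W)[i], dominant = NA_character_,
                        margin = NA_real_, tie = NA))
    }
    ord <- order(-w, names(w))
    data.frame(spot_id = rownames(W)[i], dominant = names(w)[ord[1]],
               margin = w[ord[1]] - w[ord[2]],
               tie = abs(w[ord[1]] - w[ord[2]]) < 1e-12,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Wound-vs-intact region differential expression
#'
#' Per gene, a Wilcoxon rank-sum test of log-CPM values in wound spots
#' against intact spots, BH-corrected within the timepoint's family.
#' A gene is "spatially supported" when `q < 0.05` and wound log2
#' fold-change > 0.
#'
#' @param spots_counts gene x spot count matrix.
#' @param spot_table SpotTable with `spot_id` and `region`.
#' @param timepoint label stored in the output.
#' @param min_spots minimum spots per region (default 5).
#' @return data.frame of class `region_deg`: gene, timepoint, log2fc
#'   (wound - intact), p, q, supported.
#' @export
region_deg <- function(spots_counts, spot_table, timepoint = NA,
                       min_spots = 5) {
  reg <- setNames(spot_table$region, spot_table$spot_id)[colnames(spots_counts)]
  for (r in c("wound", "intact")) {
    if (sum(reg == r, na.rm = TRUE) < min_spots) {
      stop("fewer than ", min_spots, " spots in region '", r, "'")
    }
  }
  use <- !is.na(reg) & reg %in% c("wound", "intact")
  norm <- normalize_log_cpm(spots_counts[, use, drop = FALSE])
  in_wound <- reg[use] == "wound"

  expr <- expm1(norm)
  m_w <- rowMeans(expr[, in_wound, drop = FALSE])
  m_i <- rowMeans(expr[, !in_wound, drop = FALSE])
  lfc <- log2_ratio(m_w, m_i)

  n <- ncol(norm)
  if (n <= 30) {
    p <- apply(norm, 1, wilcox_rank_sum, in_group = in_wound)
  } else {
    ranks <- t(apply(norm, 1, rank))
    p <- as.numeric(rank_sum_p_matrix(ranks, cbind(as.numeric(in_wound))))
  }
  q <- p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(norm), timepoint = timepoint,
                    log2fc = lfc, p = p, q = q,
                    supported = q < 0.05 & lfc > 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("region_deg", "data.frame")
  out
}
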