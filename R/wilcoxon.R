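# Rank-sum test machinery shared by marker detection and region DEGs.
# Small samples are handled by exact enumeration over group assignments
# (valid under ties); larger samples use the normal approximation with
# tie correction.

# Two-sided one-vs-rest rank-sum p-value for a single numeric vector.
# `in_group` is a logical mask. Exact enumeration when the total sample
# is small enough to enumerate choose(N, n1) assignments.
wilcox_rank_sum <- function(x, in_group, exact = NULL) {
  n1 <- sum(in_group)
  n2 <- sum(!in_group)
  N <- n1 + n2
  if (n1 == 0 || n2 == 0) return(NA_real_)
  r <- rank(x)
  W <- sum(r[in_group])
  mu <- n1 * (N + 1) / 2
  if (is.null(exact)) exact <- choose(N, n1) <= 20000
  if (exact) {
    combs <- combn(N, n1)
    perm_W <- colSums(matrix(r[combs], nrow = n1))
    mean(abs(perm_W - mu) >= abs(W - mu) - 1e-9)
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) return(1)
    z <- (W - mu) / sqrt(sigma2)
    2 * pnorm(-abs(z))
  }
}

# Vectorized one-vs-rest rank-sum over all genes and clusters.
# `ranks` is the genes x cells matrix of within-gene ranks; returns the
# genes x clusters matrix of two-sided normal-approximation p-values.
rank_sum_p_matrix <- function(ranks, membership) {
  N <- ncol(ranks)
  n1 <- colSums(membership)
  W <- ranks %*% membership
  mu <- matrix(n1 * (N + 1) / 2, nrow(ranks), ncol(membership), byrow = TRUE)
  # per-gene tie correction term
  tie_term <- apply(ranks, 1, function(r) {
    t <- table(r)
    sum(t^3 - t) / (N * (N - 1))
  })
  sig2 <- outer(((N + 1) - tie_term) / 12, n1 * (N - n1))
  sig2[sig2 <= 0] <- NA
  z <- (W - mu) / sqrt(sig2)
  p <- 2 * pnorm(-abs(z))
  p[is.na(p)] <- 1
  p
}
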