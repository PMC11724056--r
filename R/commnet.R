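# Cluster-to-cluster ligand-receptor communication scoring with
# permutation nulls, pathway aggregation, and optimal-transport
# signaling direction fields on spot grids.

# Cluster means of expm1(normalized) expression for the genes used by
# the LR database.
cluster_gene_means <- function(norm, labels, genes) {
  labels <- labels[colnames(norm)]
  clusters <- sort(unique(labels))
  membership <- sapply(clusters, function(cl) as.numeric(labels == cl))
  mns <- sweep(expm1(norm[genes, , drop = FALSE]) %*% membership, 2,
               colSums(membership), `/`)
  colnames(mns) <- clusters
  mns
}

#' Ligand-receptor communication scores between clusters
#'
#' For sender cluster i, receiver cluster j and pair (L, R), the
#' communication signal is `x = mean(L | i) * mean(R | j)` on the
#' counts-per-10k scale, saturated through a Hill function
#' `score = x / (hill_k + x)`, bounded in `[0, 1)` and zero whenever
#' either mean is zero.
#'
#' @param norm normalized gene x cell matrix.
#' @param labels per-cell cluster labels (named by cell).
#' @param lrdb data.frame with pathway, ligand, receptor columns.
#' @param hill_k Hill half-saturation constant (default 0.5).
#' @return data.frame of class `comm_table`: sender, receiver, ligand,
#'   receptor, pathway, x, score.
#' @export
communication_score <- function(norm, labels, lrdb, hill_k = 0.5) {
  stopifnot(hill_k > 0, nrow(lrdb) > 0)
  present <- lrdb$ligand %in% rownames(norm) &
    lrdb$receptor %in% rownames(norm)
  if (any(!present)) {
    warning(sum(!present), " pair(s) skipped: gene(s) absent from matrix")
    lrdb <- lrdb[present, , drop = FALSE]
  }
  if (!nrow(lrdb)) stop("no usable ligand-receptor pairs")
  genes <- unique(c(lrdb$ligand, lrdb$receptor))
  mns <- cluster_gene_means(norm, labels, genes)
  clusters <- colnames(mns)

  grid <- expand.grid(sender = clusters, receiver = clusters,
                      pair = seq_len(nrow(lrdb)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  x <- mns[lrdb$ligand[grid$pair], , drop = FALSE][
    cbind(seq_len(nrow(grid)), match(grid$sender, clusters))] *
    mns[lrdb$receptor[grid$pair], , drop = FALSE][
      cbind(seq_len(nrow(grid)), match(grid$receiver, clusters))]
  out <- data.frame(sender = grid$sender, receiver = grid$receiver,
                    ligand = lrdb$ligand[grid$pair],
                    receptor = lrdb$receptor[grid$pair],
                    pathway = lrdb$pathway[grid$pair],
                    x = x, score = x / (hill_k + x),
                    stringsAsFactors = FALSE)
  class(out) <- c("comm_table", "data.frame")
  out
}

#' @export
print.comm_table <- function(x, ...) {
  cat("comm_table:", nrow(x), "triples;", length(unique(x$pathway)),
      "pathway(s)\n")
  print(head(as.data.frame(x[order(-x$score), ]), 5))
  invisible(x)
}

#' Permutation p-values for communication scores
#'
#' Cluster labels are permuted over cells `n_perm` times under a fixed
#' seed; `p = (1 + #{permuted score >= observed}) / (n_perm + 1)`.
#'
#' @inheritParams communication_score
#' @param n_perm number of permutations (>= 20; default 100).
#' @param seed RNG seed.
#' @return the `comm_table` with columns p_perm and n_perm added.
#' @export
permutation_pvalues <- function(norm, labels, lrdb, hill_k = 0.5,
                                n_perm = 100, seed = 1L) {
  stopifnot(n_perm >= 20)
  obs <- communication_score(norm, labels, lrdb, hill_k = hill_k)
  labels <- labels[colnames(norm)]
  exceed <- integer(nrow(obs))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- setNames(sample(labels), names(labels))
      pb <- suppressWarnings(
        communication_score(norm, perm, lrdb, hill_k = hill_k))
      exceed <- exceed + (pb$score >= obs$score - 1e-15)
    }
  })
  obs$p_perm <- (1 + exceed) / (n_perm + 1)
  obs$n_perm <- n_perm
  obs
}

#' Aggregate pair scores to pathway level
#'
#' Pathway score between a sender and receiver is the probability-union
#' `1 - prod(1 - score)` over the pathway's pairs: monotone in every
#' pair score, with zero-score pairs neutral.
#'
#' @param comm a `comm_table`.
#' @return data.frame: pathway, sender, receiver, score, n_pairs.
#' @export
aggregate_pathway <- function(comm) {
  key <- interaction(comm$pathway, comm$sender, comm$receiver, drop = TRUE)
  agg <- lapply(split(seq_len(nrow(comm)), key), function(i) {
    data.frame(pathway = comm$pathway[i[1]], sender = comm$sender[i[1]],
               receiver = comm$receiver[i[1]],
               score = 1 - prod(1 - comm$score[i]),
               n_pairs = length(i), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

# ---- optimal-transport direction fields ---------------------------------

# Entropic-regularized balanced OT by Sinkhorn scaling with log-domain
# absorption: the scaling vectors are periodically folded into the dual
# potentials so the kernel stays within floating-point range even at
# small epsilon. Costs may be Inf (excluded pairs). Returns the
# transport plan.
sinkhorn_plan <- function(a, b, cost, epsilon, max_iter = 50000,
                          tol = 1e-10) {
  feas_row <- apply(is.finite(cost), 1, any)
  feas_col <- apply(is.finite(cost), 2, any)
  if (!all(feas_row) || !all(feas_col)) {
    stop("infeasible transport: a mass point has no admissible partner")
  }
  f <- numeric(length(a))                   # dual potentials / epsilon
  g <- numeric(length(b))
  M <- -cost / epsilon
  kern <- function() {
    K <- exp(outer(f, g, `+`) + M)
    K[!is.finite(cost)] <- 0
    K
  }
  K <- kern()
  u <- rep(1, length(a))
  v <- rep(1, length(b))
  for (it in seq_len(max_iter)) {
    u <- a / as.numeric(K %*% v)
    v <- b / as.numeric(crossprod(K, u))
    if (max(abs(log(u))) > 200 || max(abs(log(v))) > 200) {
      f <- f + log(u)                       # absorb scalings
      g <- g + log(v)
      K <- kern()
      u <- rep(1, length(a))
      v <- rep(1, length(b))
      next
    }
    if (it %% 10 == 0) {
      err <- max(abs(u * as.numeric(K %*% v) - a))
      if (err < tol) break
    }
  }
  f <- f + log(u)
  g <- g + log(v)
  plan <- kern()
  dimnames(plan) <- dimnames(cost)
  plan
}

#' Spatial signaling direction field for a ligand-receptor pair
#'
#' Sender mass is proportional to ligand expression, receiver mass to
#' receptor expression (each normalized to 1 over the spots carrying
#' signal). The cost between spots is Euclidean distance in
#' micrometers, with pairs beyond `ot_cutoff_um` excluded, and the
#' entropic-regularized balanced optimal-transport plan is solved by
#' Sinkhorn iterations with `epsilon = ot_epsilon *` median feasible
#' cost. The sending vector at spot s is the transport-weighted mean
#' displacement to its receivers, normalized to unit length; its
#' magnitude is the mass sent.
#'
#' @param spot_norm normalized gene x spot matrix.
#' @param spot_table SpotTable with spot_id, x_um, y_um.
#' @param ligand,receptor gene symbols.
#' @param ot_epsilon regularization as a fraction of the median
#'   feasible cost (default 0.05).
#' @param ot_cutoff_um maximum signaling distance (default 500).
#' @param pathway label stored on the result.
#' @return data.frame of class `vector_field`: spot_id, u, v
#'   (unit direction; zero where no mass is sent), magnitude, pathway.
#' @export
signaling_direction <- function(spot_norm, spot_table, ligand, receptor,
                                ot_epsilon = 0.05, ot_cutoff_um = 500,
                                pathway = NA_character_) {
  stopifnot(ot_epsilon > 0, ot_cutoff_um > 0)
  for (g in c(ligand, receptor)) {
    if (!g %in% rownames(spot_norm)) stop("gene absent from matrix: ", g)
  }
  ids <- spot_table$spot_id
  xy <- as.matrix(spot_table[, c("x_um", "y_um")])
  rownames(xy) <- ids
  lig <- expm1(spot_norm[ligand, ids])
  rec <- expm1(spot_norm[receptor, ids])

  send <- which(lig > 0)
  recv <- which(rec > 0)
  empty <- data.frame(spot_id = ids, u = 0, v = 0, magnitude = 0,
                      pathway = pathway, stringsAsFactors = FALSE)
  class(empty) <- c("vector_field", "data.frame")
  if (length(send) < 1 || length(recv) < 1) {
    warning("no spots with positive ligand and receptor signal")
    return(empty)
  }
  cost <- sqrt(outer(xy[send, 1], xy[recv, 1], `-`)^2 +
                 outer(xy[send, 2], xy[recv, 2], `-`)^2)
  feas <- cost <= ot_cutoff_um
  if (!any(feas)) {
    warning("no sender-receiver pair within the distance cutoff")
    return(empty)
  }
  # drop mass points with no partner inside the cutoff
  ok_s <- rowSums(feas) > 0
  ok_r <- colSums(feas) > 0
  send <- send[ok_s]; recv <- recv[ok_r]
  cost <- cost[ok_s, ok_r, drop = FALSE]
  feas <- feas[ok_s, ok_r, drop = FALSE]
  if (length(send) < 1 || length(recv) < 1) {
    warning("no feasible sender-receiver pair")
    return(empty)
  }
  # soft distance gate: pairs beyond the cutoff keep a heavily
  # penalized cost rather than being excluded outright, so the
  # balanced problem always satisfies Hall's condition and the
  # Sinkhorn marginals can be matched to tolerance
  cost[!feas] <- 4 * ot_cutoff_um
  a <- lig[send] / sum(lig[send])
  b <- rec[recv] / sum(rec[recv])
  eps <- ot_epsilon * median(cost[feas])
  plan <- sinkhorn_plan(a, b, cost, eps, tol = 1e-10)

  dx <- outer(xy[send, 1], xy[recv, 1], function(s, t) t - s)
  dy <- outer(xy[send, 2], xy[recv, 2], function(s, t) t - s)
  vx <- rowSums(plan * dx)
  vy <- rowSums(plan * dy)
  mag <- rowSums(plan)
  nrm <- sqrt(vx^2 + vy^2)
  vx <- ifelse(nrm > 0, vx / nrm, 0)
  vy <- ifelse(nrm > 0, vy / nrm, 0)

  out <- empty
  out$u[send] <- vx
  out$v[send] <- vy
  out$magnitude[send] <- mag
  attr(out, "plan") <- plan
  attr(out, "marginal_error") <- c(
    sender = max(abs(rowSums(plan) - a)),
    receiver = max(abs(colSums(plan) - b)))
  class(out) <- c("vector_field", "data.frame")
  out
}

#' @export
print.vector_field <- function(x, ...) {
  nz <- sum(x$magnitude > 0)
  cat("vector_field:", nrow(x), "spots,", nz, "with transported mass",
      if (!is.na(x$pathway[1])) paste0("(", x$pathway[1], ")"), "\n")
  invisible(x)
}
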