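# Synthetic multiomics generator: single-cell, bulk, and Visium-style
# spatial counts with planted ground truth shared across modalities.

# ---- gene universe and population rate profiles -------------------------

# Terminal populations: every fibroblast/macrophage subcluster plus the
# six other major types.
population_names <- function(cfg) {
  c(cfg$fibro_subclusters$names, cfg$macro_subclusters$names,
    setdiff(cfg$major_types$types, c("F", "M")))
}

population_major <- function(cfg) {
  pops <- population_names(cfg)
  major <- ifelse(pops %in% cfg$fibro_subclusters$names, "F",
                  ifelse(pops %in% cfg$macro_subclusters$names, "M", pops))
  setNames(major, pops)
}

# Canonical major-type markers used for annotation (one per major type).
canonical_major_markers <- function() {
  c(F = "Dcn", M = "Lyz2", N = "S100a9", EpC = "Krt10",
    EC = "Pecam1", P = "Rgs5", MC = "Bmp4", TC = "Cd3g")
}

# Named exclusive subcluster markers (extended with anonymous fillers).
named_subcluster_markers <- function() {
  list(
    F1 = c("Mgp", "Eln", "Cilp", "Igf1"),
    F2 = c("Postn", "Vcan", "Plod2", "Loxl2"),
    F3 = c("Prss23", "Cd55", "Sema3c", "Scara5"),
    F4 = c("Mfap4", "Pcolce2", "Ecm2", "Ctsk"),
    F5 = character(0),
    F6 = c("Acta2", "Tagln", "Lrrc15", "Tpm1"),
    F7 = character(0),
    F8 = c("Mki67", "Stmn1", "Tubb5", "Birc5"),
    M1 = c("Il1b", "Ccr2"),
    M2 = c("Mrc1", "Gas6"),
    M3 = c("Arg1", "Cd36"),
    M4 = character(0),
    M5 = c("Top2a", "Hmgb1"),
    M6 = c("G0s2", "Slpi")
  )
}

# Special genes with fibroblast-subcluster-restricted or shared profiles.
# `f_mult` is the multiplier over F1..F8; `m_mult` over M1..M6; `other`
# applies to every population not covered. Flagged genes are scaled down
# in KO bulk samples.
special_gene_table <- function(cfg) {
  low <- cfg$restricted_low
  f8 <- function(...) {
    v <- rep(low, 8); names(v) <- paste0("F", 1:8)
    dots <- list(...)
    v[names(dots)] <- unlist(dots)
    v
  }
  m6 <- function(x) setNames(rep(x, 6), paste0("M", 1:6))
  list(
    # collagen anchor: peaks in F4, second-highest in F1
    Col1a1 = list(f = c(F1 = 4, F2 = 1.5, F3 = 1.5, F4 = 8, F5 = 0.5,
                        F6 = 2, F7 = 1.5, F8 = 2),
                  m = m6(low), other = low, flagged = FALSE, base = 3),
    # true inflammation-related scarring genes
    Itgbl1 = list(f = f8(F1 = 4, F4 = 8), m = m6(low), other = low,
                  flagged = TRUE, base = 3),
    Clec3b = list(f = f8(F1 = 4, F3 = 4, F7 = 4), m = m6(low), other = low,
                  flagged = TRUE, base = 3),
    Ccl11 = list(f = f8(F1 = 4, F3 = 4), m = m6(low), other = low,
                 flagged = TRUE, base = 3),
    Lrrc17 = list(f = f8(F2 = 4, F6 = 4, F8 = 4), m = m6(low), other = low,
                  flagged = TRUE, base = 3),
    Pi16 = list(f = f8(F3 = 4, F7 = 4), m = m6(low), other = low,
                flagged = TRUE, base = 3),
    # decoys, one screen failure mode each
    Fbn1 = list(f = f8(F2 = 4), m = m6(low), other = low,
                flagged = FALSE, base = 3),              # not KO-down
    Col3a1 = list(f = setNames(rep(4, 8), paste0("F", 1:8)), m = m6(low),
                  other = low, flagged = TRUE, base = 3), # pan-F, no subcluster
    Ccl8 = list(f = f8(), m = c(M1 = low, M2 = 4, M3 = low, M4 = low,
                                M5 = low, M6 = low),
                other = low, flagged = TRUE, base = 3),   # macrophage gene
    Spp1 = list(f = f8(), m = c(M1 = low, M2 = low, M3 = 4, M4 = low,
                                M5 = low, M6 = low),
                other = low, flagged = TRUE, base = 3),   # macrophage gene
    Ccl7 = list(f = f8(F1 = 4, F2 = 4, F3 = 4, F7 = 4), m = m6(4),
                other = low, flagged = TRUE, base = 3),   # macrophage-shared
    C3 = list(f = f8(F3 = 4, F7 = 4), m = m6(4), other = low,
              flagged = TRUE, base = 3),                  # macrophage-shared
    Dpt = list(f = f8(F5 = 8), m = m6(low), other = low,
               flagged = TRUE, base = 3),                 # intact-dermis only
    # planted signaling axis (not part of the screen truth)
    Tgfb1 = list(f = f8(), m = m6(5), other = low, flagged = FALSE, base = 3),
    Tgfbr1 = list(f = f8(F8 = 6), m = m6(low), other = low,
                  flagged = FALSE, base = 3)
  )
}

true_scar_gene_names <- function() {
  c("Itgbl1", "Clec3b", "Ccl11", "Lrrc17", "Pi16")
}

# Build the planted gene universe: symbols, baseline rates, and the
# population x gene rate matrix. Deterministic given the config seed.
build_truth_profiles <- function(cfg) {
  pops <- population_names(cfg)
  major_of <- population_major(cfg)
  specials <- special_gene_table(cfg)
  canon <- canonical_major_markers()
  named_sub <- named_subcluster_markers()

  n_major_mk <- cfg$n_markers_per_cluster
  n_sub_mk <- cfg$n_markers_per_subcluster
  majors <- cfg$major_types$types
  subs <- c(cfg$fibro_subclusters$names, cfg$macro_subclusters$names)

  n_named <- length(specials)
  n_anon_major <- length(majors) * (n_major_mk - 1L)
  n_anon_sub <- sum(pmax(0L, n_sub_mk - lengths(named_sub[subs])))
  n_bg <- cfg$n_background_ko
  n_reserved <- n_named + length(majors) + sum(lengths(named_sub)) +
    n_anon_major + n_anon_sub + n_bg
  if (cfg$n_genes < n_reserved + 50) {
    stop("n_genes too small for the planted design (need > ",
         n_reserved + 50, ")")
  }

  genes <- character(cfg$n_genes)
  idx <- 1L
  take <- function(nms) {
    k <- length(nms)
    genes[idx:(idx + k - 1L)] <<- nms
    idx <<- idx + k
    nms
  }
  take(names(specials))
  marker_genes <- list(major = list(), sub = list())
  for (ty in majors) {
    anon <- sprintf("Gene%04d", idx + seq_len(n_major_mk - 1L) - 1L + 0L)
    mk <- c(canon[[ty]], anon)
    take(canon[[ty]]); take(anon)
    marker_genes$major[[ty]] <- mk
  }
  for (sc in subs) {
    named <- named_sub[[sc]] %||% character(0)
    n_anon <- max(0L, n_sub_mk - length(named))
    anon <- if (n_anon > 0) sprintf("Gene%04d", idx + seq_len(n_anon) - 1L)
            else character(0)
    if (length(named)) take(named)
    if (n_anon > 0) take(anon)
    marker_genes$sub[[sc]] <- c(named, anon)[seq_len(n_sub_mk)]
  }
  bg_ko <- sprintf("Gene%04d", idx + seq_len(n_bg) - 1L)
  take(bg_ko)
  fillers <- sprintf("Gene%04d", idx:cfg$n_genes)
  genes[idx:cfg$n_genes] <- fillers

  # baseline relative rates
  base <- with_seed(cfg$seed + 101L, {
    b <- exp(rnorm(cfg$n_genes, 0, 1))
    b
  })
  names(base) <- genes
  base[names(specials)] <- vapply(specials, function(s) s$base, 0)
  base[unlist(marker_genes$major)] <- 2
  base[unlist(marker_genes$sub)] <- 2
  base[bg_ko] <- 2

  # population x gene multiplier matrix
  mult <- matrix(1, nrow = length(pops), ncol = cfg$n_genes,
                 dimnames = list(pops, genes))
  fc <- 2^cfg$marker_log2fc
  for (ty in majors) {
    mult[major_of == ty, marker_genes$major[[ty]]] <- fc
  }
  for (sc in subs) {
    mult[sc, marker_genes$sub[[sc]]] <- fc
  }
  for (g in names(specials)) {
    s <- specials[[g]]
    mult[, g] <- s$other
    mult[cfg$fibro_subclusters$names, g] <- s$f[cfg$fibro_subclusters$names]
    mult[cfg$macro_subclusters$names, g] <- s$m[cfg$macro_subclusters$names]
  }

  rates <- sweep(mult, 2, base, `*`)
  pop_prob <- rates / rowSums(rates)

  flagged <- c(names(specials)[vapply(specials, `[[`, TRUE, "flagged")],
               bg_ko)
  decoys <- list(
    fails_ko_down = "Fbn1",
    fails_fibro_marker = c("Col3a1", "Ccl8", "Spp1"),
    fails_fibro_specificity = c("Ccl7", "C3"),
    fails_spatial_support = "Dpt"
  )

  list(genes = genes, base = base, rates = rates, pop_prob = pop_prob,
       marker_genes = marker_genes, specials = specials,
       true_scar_genes = true_scar_gene_names(),
       decoy_genes = decoys, ko_flagged = flagged,
       background_ko = bg_ko, major_of = major_of)
}

# ---- single-cell generator ----------------------------------------------

#' Generate synthetic single-cell RNA-seq counts with planted truth
#'
#' Draws per-cell negative-binomial counts from population rate profiles
#' at three wound timepoints. Cell populations are sampled per timepoint
#' from the configured major-type and subcluster proportions; each
#' planted marker gene has expected log2 fold-change `marker_log2fc`
#' over every other population.
#'
#' @param config a [synth_config()] object.
#' @return list with `counts` (gene x cell integer matrix), `meta`
#'   (data.frame: cell_id, timepoint, major_label, sub_label), and
#'   `truth` (class `synth_truth`): planted profiles, marker sets, true
#'   scarring genes, decoy sets and KO flags.
#' @export
generate_single_cell <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  prof <- build_truth_profiles(config)
  pops <- rownames(prof$pop_prob)

  with_seed(config$seed + 202L, {
    cells <- list()
    for (tp in config$timepoints) {
      key <- as.character(tp)
      pmaj <- config$major_types$props[[key]]
      pf <- config$fibro_subclusters$props[[key]]
      pm <- config$macro_subclusters$props[[key]]
      # terminal population probabilities for this timepoint
      ppop <- setNames(numeric(length(pops)), pops)
      ppop[names(pf)] <- pmaj[["F"]] * pf
      ppop[names(pm)] <- pmaj[["M"]] * pm
      other <- setdiff(names(pmaj), c("F", "M"))
      ppop[other] <- pmaj[other]
      pop <- sample(pops, config$n_cells_per_timepoint,
                    replace = TRUE, prob = ppop[pops])
      cells[[key]] <- data.frame(timepoint = tp, pop = pop,
                                 stringsAsFactors = FALSE)
    }
    meta <- do.call(rbind, cells)
    n <- nrow(meta)
    meta$cell_id <- sprintf("cell_%05d", seq_len(n))
    meta$major_label <- unname(prof$major_of[meta$pop])
    meta$sub_label <- ifelse(meta$major_label %in% c("F", "M"),
                             meta$pop, NA_character_)
    depth <- exp(rnorm(n, log(config$depth_mean_cells), 0.3))

    counts <- matrix(0L, nrow = config$n_genes, ncol = n,
                     dimnames = list(prof$genes, meta$cell_id))
    size <- 1 / config$nb_dispersion
    for (p in pops) {
      j <- which(meta$pop == p)
      if (!length(j)) next
      mu <- outer(prof$pop_prob[p, ], depth[j])
      counts[, j] <- as.integer(rnbinom(length(mu), mu = mu, size = size))
    }
    meta <- meta[, c("cell_id", "timepoint", "major_label", "sub_label", "pop")]

    truth <- structure(list(
      cell_labels = meta,
      type_mean_profiles = prof$rates,
      pop_prob = prof$pop_prob,
      marker_genes = prof$marker_genes,
      true_scar_genes = prof$true_scar_genes,
      decoy_genes = prof$decoy_genes,
      ko_flagged = prof$ko_flagged,
      background_ko = prof$background_ko,
      major_of = prof$major_of,
      config = config
    ), class = "synth_truth")

    list(counts = counts, meta = meta, truth = truth)
  })
}

#' @export
print.synth_truth <- function(x, ...) {
  cat("synth_truth:", nrow(x$cell_labels), "cells,",
      ncol(x$type_mean_profiles), "genes,",
      nrow(x$type_mean_profiles), "planted populations\n")
  cat("  true scarring genes:", paste(x$true_scar_genes, collapse = ", "), "\n")
  cat("  decoy classes:", paste(names(x$decoy_genes), collapse = ", "), "\n")
  if (!is.null(x$spot_weights)) {
    cat("  spatial truth:", nrow(x$spot_weights), "spots\n")
  }
  invisible(x)
}

# ---- bulk generator ------------------------------------------------------

#' Generate synthetic bulk WT vs inflammation-deficient wound counts
#'
#' The wild-type expectation is the cell-population-frequency-weighted
#' mixture of the planted population profiles; the KO expectation is
#' identical except that flagged genes (true scarring genes plus the
#' designated decoys and an anonymous candidate background) are scaled
#' by `2^ko_downregulation_log2fc`.
#'
#' @param config a [synth_config()].
#' @param truth the `synth_truth` from [generate_single_cell()] with the
#'   same config.
#' @return list with `counts` (gene x sample) and `design` (data.frame:
#'   sample_id, genotype, library_size).
#' @export
generate_bulk <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"), inherits(truth, "synth_truth"))
  if (!identical(rownames(truth$pop_prob), rownames(truth$type_mean_profiles)) ||
      ncol(truth$pop_prob) != config$n_genes) {
    stop("gene universe mismatch between truth and config")
  }
  freq <- table(truth$cell_labels$pop)
  freq <- freq[rownames(truth$pop_prob)]
  freq[is.na(freq)] <- 0
  w <- as.numeric(freq) / sum(freq)
  rate_wt <- as.numeric(crossprod(truth$pop_prob, w))  # sums to 1
  names(rate_wt) <- colnames(truth$pop_prob)
  rate_ko <- rate_wt
  eff <- 2^config$ko_downregulation_log2fc
  rate_ko[truth$ko_flagged] <- rate_ko[truth$ko_flagged] * eff

  n <- config$n_bulk_per_genotype
  with_seed(config$seed + 303L, {
    size <- 1 / (config$nb_dispersion_bulk %||% config$nb_dispersion)
    mu <- cbind(matrix(rate_wt * config$bulk_depth, config$n_genes, n),
                matrix(rate_ko * config$bulk_depth, config$n_genes, n))
    counts <- matrix(as.integer(rnbinom(length(mu), mu = mu, size = size)),
                     nrow = config$n_genes)
    rownames(counts) <- names(rate_wt)
    ids <- c(sprintf("WT_%d", seq_len(n)), sprintf("KO_%d", seq_len(n)))
    colnames(counts) <- ids
    design <- data.frame(sample_id = ids,
                         genotype = rep(c("WT", "KO"), each = n),
                         library_size = colSums(counts),
                         stringsAsFactors = FALSE)
    list(counts = counts, design = design,
         expected_rate = cbind(WT = rate_wt, KO = rate_ko))
  })
}

# ---- Visium-style spatial generator -------------------------------------

# Region-conditioned terminal-population probabilities for a timepoint.
# Wound spots mix infiltrating types (no F5); intact spots are resident
# dermis: F5 fibroblasts plus epithelial/endothelial/pericyte/mesenchymal.
region_population_probs <- function(config, timepoint) {
  key <- as.character(timepoint)
  pops <- population_names(config)
  pmaj <- config$major_types$props[[key]]
  pf <- config$fibro_subclusters$props[[key]]
  pm <- config$macro_subclusters$props[[key]]

  wound <- setNames(numeric(length(pops)), pops)
  wmaj <- pmaj[c("F", "M", "N", "EC")]
  wmaj <- wmaj / sum(wmaj)
  pfw <- pf
  pfw["F5"] <- 0
  pfw <- pfw / sum(pfw)
  wound[names(pfw)] <- wmaj[["F"]] * pfw
  wound[names(pm)] <- wmaj[["M"]] * pm
  wound["N"] <- wmaj[["N"]]
  wound["EC"] <- wmaj[["EC"]]

  intact <- setNames(numeric(length(pops)), pops)
  intact["F5"] <- 0.45
  intact["EpC"] <- 0.25
  intact["EC"] <- 0.10
  intact["P"] <- 0.10
  intact["MC"] <- 0.10

  list(wound = wound, intact = intact)
}

# Spatial modulation factors for a planted ligand-receptor pair.
lr_spatial_factor <- function(r, radius, role, geometry) {
  margin <- 1 + 6 * exp(-((r - 0.85 * radius) / (0.18 * radius))^2)
  center <- 1 + 6 * exp(-(r / (0.45 * radius))^2)
  if (geometry == "margin_to_center") {
    if (role == "ligand") margin else center
  } else {
    if (role == "ligand") center else margin
  }
}

#' Generate a synthetic Visium-style spot dataset
#'
#' Lays out a square lattice of spots, assigns a central wound disk and
#' surrounding intact region, samples 20-30 cells per spot with
#' region-conditioned population composition, and draws spot counts as
#' negative-binomial sums of the per-cell expectations. Planted
#' ligand-receptor pairs impose radial expression gradients matching
#' their geometry (for `margin_to_center`, ligand peaks on the wound
#' margin annulus and receptor at the wound center).
#'
#' @param config a [synth_config()].
#' @param truth `synth_truth` from [generate_single_cell()].
#' @param timepoint which day's composition to use (default 7).
#' @return list with `counts` (gene x spot), `spots` (SpotTable
#'   data.frame), `spot_weights` (spot x major-type realized cell
#'   fractions), `planted_direction` (spot x 2 unit vectors for wound
#'   spots), and `margin_mask` (wound-margin annulus indicator).
#' @export
generate_visium <- function(config, truth, timepoint = 7L) {
  stopifnot(inherits(config, "synth_config"), inherits(truth, "synth_truth"))
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  sp <- config$spot_spacing_um
  grid <- expand.grid(array_row = seq_len(nr) - 1L,
                      array_col = seq_len(nc) - 1L)
  x <- grid$array_col * sp
  y <- grid$array_row * sp
  cx <- mean(range(x)); cy <- mean(range(y))
  r <- sqrt((x - cx)^2 + (y - cy)^2)
  R <- config$wound_radius_um
  region <- ifelse(r <= R, "wound", "intact")
  n_spots <- nrow(grid)
  spot_id <- sprintf("spot_%04d", seq_len(n_spots))

  probs <- region_population_probs(config, timepoint)
  pops <- population_names(config)
  majors <- config$major_types$types
  major_of <- truth$major_of

  with_seed(config$seed + 404L + as.integer(timepoint), {
    counts <- matrix(0L, nrow = config$n_genes, ncol = n_spots,
                     dimnames = list(colnames(truth$pop_prob), spot_id))
    weights <- matrix(0, nrow = n_spots, ncol = length(majors),
                      dimnames = list(spot_id, majors))
    lo <- config$cells_per_spot_range[1]; hi <- config$cells_per_spot_range[2]
    n_cells <- sample(lo:hi, n_spots, replace = TRUE)
    disp <- config$nb_dispersion

    lr <- config$lr_pairs_planted
    for (s in seq_len(n_spots)) {
      p <- probs[[region[s]]]
      pop_counts <- as.numeric(stats::rmultinom(1, n_cells[s], p[pops]))
      names(pop_counts) <- pops
      mu <- config$visium_cell_depth *
        as.numeric(crossprod(truth$pop_prob, pop_counts))
      names(mu) <- colnames(truth$pop_prob)
      if (nrow(lr)) {
        for (k in seq_len(nrow(lr))) {
          mu[lr$ligand[k]] <- mu[lr$ligand[k]] *
            lr_spatial_factor(r[s], R, "ligand", lr$geometry[k])
          mu[lr$receptor[k]] <- mu[lr$receptor[k]] *
            lr_spatial_factor(r[s], R, "receptor", lr$geometry[k])
        }
      }
      # sum of c iid NB(mu_i, alpha) draws: mean sum(mu), dispersion alpha/c
      counts[, s] <- as.integer(rnbinom(config$n_genes, mu = mu,
                                        size = n_cells[s] / disp))
      mfrac <- tapply(pop_counts, major_of[pops], sum)[majors]
      weights[s, ] <- mfrac / sum(mfrac)
    }

    dirs <- matrix(0, n_spots, 2, dimnames = list(spot_id, c("u", "v")))
    wound_idx <- which(region == "wound" & r > 1e-9)
    inward <- cbind(cx - x, cy - y)[wound_idx, , drop = FALSE]
    inward <- inward / sqrt(rowSums(inward^2))
    geom <- if (nrow(lr)) lr$geometry[1] else "margin_to_center"
    dirs[wound_idx, ] <- if (geom == "margin_to_center") inward else -inward

    spots <- data.frame(
      spot_id = spot_id, barcode = spot_id, in_tissue = 1L,
      array_row = grid$array_row, array_col = grid$array_col,
      x_um = x, y_um = y, region = region,
      stringsAsFactors = FALSE
    )
    list(counts = counts, spots = spots, spot_weights = weights,
         planted_direction = dirs,
         margin_mask = region == "wound" & r >= 0.55 * R,
         timepoint = timepoint)
  })
}
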