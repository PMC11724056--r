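# Readers/writers for the standard formats: MatrixMarket count matrices
# with companion gene/barcode TSVs, Visium-style tissue-positions CSVs,
# and ligand-receptor pair tables.

#' Read a MatrixMarket count matrix with companion gene/barcode TSVs
#'
#' Expects `<stem>.mtx` plus `<stem>.genes.tsv` and `<stem>.barcodes.tsv`
#' (one identifier per line), the layout written by [write_mtx()].
#'
#' @param stem path stem (without the `.mtx` extension), or a `.mtx`
#'   path whose extension is stripped.
#' @return dense integer matrix, genes x observations, with dimnames.
#' @export
read_mtx <- function(stem) {
  stem <- sub("\\.mtx$", "", stem)
  mtx_path <- paste0(stem, ".mtx")
  if (!file.exists(mtx_path)) stop("no such file: ", mtx_path)
  m <- tryCatch(Matrix::readMM(mtx_path),
                error = function(e) stop("malformed MatrixMarket file ",
                                         mtx_path, ": ", conditionMessage(e),
                                         call. = FALSE))
  m <- as.matrix(m)
  if (any(m < 0)) stop("negative count in ", mtx_path)
  if (any(m != round(m))) stop("non-integer count in ", mtx_path)
  genes <- readLines(paste0(stem, ".genes.tsv"))
  obs <- readLines(paste0(stem, ".barcodes.tsv"))
  if (length(genes) != nrow(m)) {
    stop("gene file has ", length(genes), " entries but matrix has ",
         nrow(m), " rows")
  }
  if (length(obs) != ncol(m)) {
    stop("barcode file has ", length(obs), " entries but matrix has ",
         ncol(m), " columns")
  }
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  if (anyDuplicated(obs)) stop("duplicate observation identifiers")
  storage.mode(m) <- "integer"
  dimnames(m) <- list(genes, obs)
  m
}

#' Write a count matrix as MatrixMarket plus gene/barcode TSVs
#'
#' @param counts genes x observations matrix with dimnames; entries must
#'   be nonnegative integers.
#' @param stem output path stem; writes `<stem>.mtx`,
#'   `<stem>.genes.tsv`, `<stem>.barcodes.tsv`.
#' @return `stem`, invisibly.
#' @export
write_mtx <- function(counts, stem) {
  stem <- sub("\\.mtx$", "", stem)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene and observation identifiers as dimnames")
  }
  if (any(counts < 0)) stop("negative count")
  if (any(counts != round(counts))) stop("non-integer count")
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"),
                  paste0(stem, ".mtx"))
  writeLines(rownames(counts), paste0(stem, ".genes.tsv"))
  writeLines(colnames(counts), paste0(stem, ".barcodes.tsv"))
  invisible(stem)
}

SPOT_REGIONS <- c("wound", "intact", "muscle", "scab", "other")

#' Read a Visium-style tissue-positions CSV
#'
#' Requires columns `barcode`, `in_tissue`, `array_row`, `array_col`,
#' `x_um`, `y_um`; an optional `region` column with values in
#' wound/intact/muscle/scab/other. Coordinates are physical micrometers.
#'
#' @param path CSV path.
#' @param in_tissue_only drop spots with `in_tissue == 0` (default TRUE).
#' @return data.frame (SpotTable) with a `spot_id` column.
#' @export
read_spot_positions <- function(path, in_tissue_only = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("barcode", "in_tissue", "array_row", "array_col", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$barcode)) stop("duplicated spot id in ", path)
  if (!all(is.finite(df$x_um)) || !all(is.finite(df$y_um))) {
    stop("non-finite spot coordinates")
  }
  if (!"region" %in% names(df)) df$region <- "other"
  bad <- setdiff(unique(df$region), SPOT_REGIONS)
  if (length(bad)) stop("unknown region label(s): ", paste(bad, collapse = ", "))
  if (in_tissue_only) df <- df[df$in_tissue != 0, , drop = FALSE]
  df$spot_id <- df$barcode
  rownames(df) <- NULL
  df[, c("spot_id", "barcode", "in_tissue", "array_row", "array_col",
         "x_um", "y_um", "region")]
}

#' Read a ligand-receptor pair table
#'
#' TSV with columns `pathway`, `ligand`, `receptor` (a CellChatDB-style
#' mouse pair list). Duplicate pairs are dropped; pairs whose genes are
#' absent from an optional expression universe are flagged, not removed.
#'
#' @param path TSV path.
#' @param gene_universe optional character vector of known genes.
#' @return data.frame with columns pathway, ligand, receptor,
#'   genes_present.
#' @export
read_lr_table <- function(path, gene_universe = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("pathway", "ligand", "receptor")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("empty ligand-receptor table: ", path)
  df <- df[!duplicated(df[, c("ligand", "receptor")]), need, drop = FALSE]
  if (any(!nzchar(df$pathway))) stop("empty pathway label")
  df$genes_present <- TRUE
  if (!is.null(gene_universe)) {
    df$genes_present <- df$ligand %in% gene_universe &
      df$receptor %in% gene_universe
    if (any(!df$genes_present)) {
      warning(sum(!df$genes_present),
              " pair(s) reference genes absent from the expression matrix")
    }
  }
  rownames(df) <- NULL
  df
}

#' Write a SpotTable as a tissue-positions CSV
#' @param spots SpotTable data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spot_positions <- function(spots, path) {
  cols <- c("barcode", "in_tissue", "array_row", "array_col",
            "x_um", "y_um", "region")
  write.csv(spots[, intersect(cols, names(spots))], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Write a full synthetic dataset to disk
#'
#' Writes the single-cell, bulk and spatial modalities as MatrixMarket +
#' TSV/CSV, and the ground truth as JSON.
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mtx(dataset$sc$counts, file.path(dir, "sc"))
  write.table(dataset$sc$meta, file.path(dir, "sc_meta.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write_mtx(dataset$bulk$counts, file.path(dir, "bulk"))
  write.table(dataset$bulk$design, file.path(dir, "bulk_design.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  for (nm in names(dataset$visium)) {
    vs <- dataset$visium[[nm]]
    write_mtx(vs$counts, file.path(dir, paste0("visium_", nm)))
    write_spot_positions(vs$spots,
                         file.path(dir, paste0("visium_", nm, "_positions.csv")))
  }
  write.table(dataset$lr_table, file.path(dir, "lr_pairs.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  truth <- dataset$sc$truth
  jsonlite::write_json(list(
    true_scar_genes = truth$true_scar_genes,
    decoy_genes = truth$decoy_genes,
    ko_flagged = truth$ko_flagged
  ), file.path(dir, "truth.json"), auto_unbox = FALSE, pretty = TRUE)
  invisible(dir)
}
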