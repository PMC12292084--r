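#' Quality-control and normalization thresholds
#'
#' Defaults follow the standard droplet scRNA-seq recipe: drop genes
#' detected in fewer than 0.1% of cells, drop cells with mitochondrial
#' count fraction above 20% or with fewer than 200 / more than 5000
#' detected genes, library-normalize to 10,000 counts with a log
#' transform, center per gene and clip scaled values at 10, and keep the
#' 3000 most variable genes.
#'
#' @param min_gene_detection_fraction minimum fraction of cells a gene
#'   must be detected in.
#' @param max_mito_fraction maximum mitochondrial count fraction per cell.
#' @param min_genes_per_cell,max_genes_per_cell inclusive bounds on
#'   detected genes per cell.
#' @param scale_factor library-size normalization target.
#' @param clip_max upper clip for centered values.
#' @param n_hvg number of highly variable genes to keep.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_gene_detection_fraction = 0.001,
                          max_mito_fraction = 0.20,
                          min_genes_per_cell = 200,
                          max_genes_per_cell = 5000,
                          scale_factor = 1e4,
                          clip_max = 10,
                          n_hvg = 3000) {
  th <- list(min_gene_detection_fraction = min_gene_detection_fraction,
             max_mito_fraction = max_mito_fraction,
             min_genes_per_cell = min_genes_per_cell,
             max_genes_per_cell = max_genes_per_cell,
             scale_factor = scale_factor, clip_max = clip_max, n_hvg = n_hvg)
  if (any(unlist(th) <= 0)) stop_oncostage("all thresholds must be positive")
  if (min_genes_per_cell >= max_genes_per_cell)
    stop_oncostage("min_genes_per_cell must be below max_genes_per_cell")
  class(th) <- "qc_thresholds"
  th
}

#' Drop genes detected in too few cells
#'
#' A gene is "detected" in a cell when its count is positive. Genes with
#' detections in fewer than `ceiling(min_gene_detection_fraction x n_cells)`
#' cells are removed; the ceiling keeps "less than 0.1%" strict.
#'
#' @param counts gene x cell count matrix (dgCMatrix or dense) with ids.
#' @param thresholds a [qc_thresholds()] object.
#' @return filtered count matrix, cells unchanged.
#' @export
filter_genes_by_detection <- function(counts, thresholds = qc_thresholds()) {
  check_matrix_ids(counts)
  if (ncol(counts) == 0) stop_oncostage("empty count matrix")
  need <- ceiling(thresholds$min_gene_detection_fraction * ncol(counts))
  keep <- Matrix::rowSums(counts > 0) >= need
  if (!any(keep)) stop_oncostage("gene detection filter removed every gene")
  counts[keep, , drop = FALSE]
}

#' Drop low-quality cells
#'
#' Removes cells whose mitochondrial count fraction exceeds
#' `max_mito_fraction` or whose detected-gene count lies outside
#' `[min_genes_per_cell, max_genes_per_cell]`. Removal conditions are
#' strict, so cells sitting exactly on a bound are retained. The
#' mitochondrial fraction is computed on the raw counts passed in.
#'
#' @param counts gene x cell count matrix.
#' @param mito_genes character vector of mitochondrial gene ids (subset of
#'   rownames), or NULL to use the `mito_prefix`.
#' @param thresholds a [qc_thresholds()] object.
#' @param mito_prefix prefix identifying mitochondrial genes when
#'   `mito_genes` is NULL.
#' @return filtered count matrix, genes unchanged.
#' @export
filter_cells_qc <- function(counts, mito_genes = NULL,
                            thresholds = qc_thresholds(),
                            mito_prefix = "MT-") {
  check_matrix_ids(counts)
  if (is.null(mito_genes))
    mito_genes <- rownames(counts)[startsWith(rownames(counts), mito_prefix)]
  if (length(setdiff(mito_genes, rownames(counts))))
    stop_oncostage("mito_genes must be a subset of the gene ids")
  tot <- Matrix::colSums(counts)
  mito <- if (length(mito_genes))
    Matrix::colSums(counts[mito_genes, , drop = FALSE]) else rep(0, ncol(counts))
  frac <- ifelse(tot > 0, mito / tot, 0)
  ngene <- Matrix::colSums(counts > 0)
  keep <- frac <= thresholds$max_mito_fraction &
    ngene >= thresholds$min_genes_per_cell &
    ngene <= thresholds$max_genes_per_cell
  if (!any(keep)) stop_oncostage("cell QC removed every cell")
  counts[, keep, drop = FALSE]
}

#' Library-size log-normalization
#'
#' Per entry: `ln(1 + count x scale_factor / cell_total)`. Zero counts map
#' to zero, so sparsity is preserved.
#'
#' @param counts gene x cell count matrix.
#' @param thresholds a [qc_thresholds()] object (`scale_factor` used).
#' @return sparse gene x cell matrix of log-normalized values.
#' @export
log_normalize <- function(counts, thresholds = qc_thresholds()) {
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) stop_oncostage("cell(s) with zero total count: ",
    paste(utils::head(colnames(counts)[tot == 0], 3), collapse = ", "))
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  # operate on the nonzero slots only: x -> ln(1 + x * sf / tot[col])
  j <- rep(seq_len(ncol(m)), diff(m@p))
  m@x <- log1p(m@x * thresholds$scale_factor / tot[j])
  m
}

#' Center per gene and clip high values
#'
#' Subtracts each gene's mean across cells, then caps entries at
#' `clip_max`. No variance scaling and no lower clip, so the per-gene mean
#' after clipping is at most zero (exactly zero when nothing clipped).
#'
#' @param norm gene x cell log-normalized matrix.
#' @param thresholds a [qc_thresholds()] object (`clip_max` used).
#' @return dense gene x cell centered matrix.
#' @export
center_and_clip <- function(norm, thresholds = qc_thresholds()) {
  m <- as.matrix(norm)
  m <- m - rowMeans(m)
  m[m > thresholds$clip_max] <- thresholds$clip_max
  m
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their log-normalized values
#' (descending), breaking ties by gene id, and returns the top `n_hvg`.
#' When fewer genes are available all are returned with a warning.
#'
#' @param norm gene x cell log-normalized matrix.
#' @param thresholds a [qc_thresholds()] object (`n_hvg` used).
#' @return character vector of gene ids.
#' @export
select_hvg <- function(norm, thresholds = qc_thresholds()) {
  v <- row_vars(norm)
  ord <- order(-v, rownames(norm))
  n <- thresholds$n_hvg
  if (nrow(norm) < n) {
    warning("fewer genes than n_hvg; returning all ", nrow(norm), " genes")
    n <- nrow(norm)
  }
  rownames(norm)[ord[seq_len(n)]]
}

row_vars <- function(m) {
  if (methods::is(m, "sparseMatrix")) {
    mu <- Matrix::rowMeans(m)
    n <- ncol(m)
    (Matrix::rowSums(m^2) - n * mu^2) / (n - 1)
  } else {
    mu <- rowMeans(m)
    n <- ncol(m)
    (rowSums(m^2) - n * mu^2) / (n - 1)
  }
}
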