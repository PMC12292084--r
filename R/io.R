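# Disk layout: CellRanger-style triplet (matrix.mtx + genes.tsv +
# barcodes.tsv, genes as rows) plus TSV metadata and truth tables.

write_mtx_integer <- function(m, path) {
  tr <- Matrix::summary(methods::as(m, "TsparseMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), nrow(tr))), con)
  if (nrow(tr) > 0)
    writeLines(sprintf("%d %d %d", tr$i, tr$j, as.integer(tr$x)), con)
  invisible(path)
}

read_mtx_integer <- function(path) {
  m <- Matrix::readMM(path)
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write a synthetic dataset to a CellRanger-style directory
#'
#' Emits `matrix.mtx` (coordinate integer), `genes.tsv`, `barcodes.tsv`,
#' `cell_metadata.tsv`, `gene_annotation.tsv` and a `truth/` subdirectory
#' (malignant flags, non-diploid dosage entries in triplet form, DE genes,
#' regulon edges, ligand-receptor amplitudes). [read_dataset()] round-trips
#' the result.
#'
#' @param dataset a `synthetic_dataset` from [simulate_cells()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (ncol(dataset$counts) == 0 || nrow(dataset$counts) == 0)
    stop_oncostage("refusing to write an empty dataset (0 genes or 0 cells)")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop_oncostage("cannot create directory: ", dir)
  if (file.access(dir, 2) != 0)
    stop_oncostage("directory not writable: ", dir)
  write_mtx_integer(dataset$counts, file.path(dir, "matrix.mtx"))
  write_tsv(data.frame(gene = rownames(dataset$counts),
                       symbol = rownames(dataset$counts)),
            file.path(dir, "genes.tsv"))
  writeLines(colnames(dataset$counts), file.path(dir, "barcodes.tsv"))
  write_tsv(dataset$cell_metadata, file.path(dir, "cell_metadata.tsv"))
  write_tsv(dataset$gene_annotation, file.path(dir, "gene_annotation.tsv"))

  td <- file.path(dir, "truth")
  dir.create(td, showWarnings = FALSE)
  write_tsv(data.frame(cell = names(dataset$truth$malignant),
                       malignant = as.integer(dataset$truth$malignant)),
            file.path(td, "malignant.tsv"))
  d <- dataset$truth$dosage
  nz <- which(d != 1, arr.ind = TRUE)
  write_tsv(data.frame(gene = rownames(d)[nz[, 1]],
                       cell = colnames(d)[nz[, 2]],
                       dosage = d[nz]),
            file.path(td, "dosage.tsv"))
  write_tsv(dataset$truth$de_genes, file.path(td, "de_genes.tsv"))
  write_tsv(dataset$truth$regulon_edges, file.path(td, "regulon_edges.tsv"))
  write_tsv(dataset$truth$lr_amplitudes, file.path(td, "lr_amplitudes.tsv"))
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir directory holding the triplet layout.
#' @param truth read the `truth/` tables when present?
#' @return a `synthetic_dataset` list (truth element NULL when absent).
#' @export
read_dataset <- function(dir, truth = TRUE) {
  need <- c("matrix.mtx", "genes.tsv", "barcodes.tsv")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss)) stop_oncostage("missing file(s) in ", dir, ": ",
                                   paste(miss, collapse = ", "))
  counts <- read_mtx_integer(file.path(dir, "matrix.mtx"))
  genes <- read_tsv(file.path(dir, "genes.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(counts) <- list(genes[[1]], barcodes)
  meta_f <- file.path(dir, "cell_metadata.tsv")
  anno_f <- file.path(dir, "gene_annotation.tsv")
  meta <- if (file.exists(meta_f)) read_tsv(meta_f) else NULL
  anno <- if (file.exists(anno_f)) read_tsv(anno_f) else NULL

  tr <- NULL
  td <- file.path(dir, "truth")
  if (truth && dir.exists(td)) {
    mal <- read_tsv(file.path(td, "malignant.tsv"))
    malignant <- stats::setNames(mal$malignant == 1, mal$cell)
    dtab <- read_tsv(file.path(td, "dosage.tsv"))
    dosage <- matrix(1, nrow(counts), ncol(counts),
                     dimnames = dimnames(counts))
    if (nrow(dtab) > 0)
      dosage[cbind(match(dtab$gene, rownames(counts)),
                   match(dtab$cell, colnames(counts)))] <- dtab$dosage
    tr <- list(malignant = malignant, dosage = dosage,
               de_genes = read_tsv(file.path(td, "de_genes.tsv")),
               regulon_edges = read_tsv(file.path(td, "regulon_edges.tsv")),
               lr_amplitudes = read_tsv(file.path(td, "lr_amplitudes.tsv")))
  }
  structure(list(counts = counts, gene_annotation = anno,
                 cell_metadata = meta,
                 mito_genes = rownames(counts)[startsWith(rownames(counts),
                                                          "MT-")],
                 truth = tr),
            class = "synthetic_dataset")
}

#' Read a ligand-receptor interaction database
#'
#' Expects a TSV with columns `name`, `ligand_genes`, `receptor_genes`
#' (comma-joined subunit gene lists) and `pathway`.
#'
#' @param path TSV file.
#' @return data.frame of class `lr_database` with list-columns `ligand`
#'   and `receptor`.
#' @export
read_lr_database <- function(path) {
  df <- read_tsv(path)
  lr_database(df$name, strsplit(df$ligand_genes, ","),
              strsplit(df$receptor_genes, ","), df$pathway)
}

#' Construct a ligand-receptor database in memory
#'
#' @param name unique interaction names.
#' @param ligand,receptor lists of subunit gene-name vectors (non-empty).
#' @param pathway pathway label per interaction.
#' @return data.frame of class `lr_database`.
#' @export
lr_database <- function(name, ligand, receptor, pathway) {
  if (anyDuplicated(name)) stop_oncostage("interaction names must be unique")
  if (any(lengths(ligand) == 0) || any(lengths(receptor) == 0))
    stop_oncostage("subunit sets must be non-empty")
  db <- data.frame(name = name, pathway = pathway)
  db$ligand <- lapply(ligand, trimws)
  db$receptor <- lapply(receptor, trimws)
  class(db) <- c("lr_database", "data.frame")
  db
}
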