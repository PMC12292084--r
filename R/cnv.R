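#' Parameters of the expression-derived CNV malignancy pipeline
#'
#' @param max_putative_malignant_fraction maximum tumor-cell fraction of
#'   the reference mix (normals are added until this is met).
#' @param min_cells_per_gene genes expressed in fewer cells are dropped.
#' @param min_mean_log2_expr genes with lower mean log2 expression are
#'   dropped.
#' @param z_clip symmetric clip for per-gene z-scores.
#' @param window_size genes per moving window along the genome.
#' @param top_cell_fraction fraction of highest-scoring cells defining the
#'   reference CNV profile.
#' @param ms_threshold mean-square threshold of the malignancy OR-rule.
#' @param corr_threshold correlation threshold of the malignancy OR-rule.
#' @param center one of `"cell"` (default: remove each cell's mean window
#'   signal) or `"window"` (remove each window's mean across cells).
#' @param seed seed used when subsampling normal cells for the mix.
#' @return list of class `cnv_params`.
#' @export
cnv_params <- function(max_putative_malignant_fraction = 0.20,
                       min_cells_per_gene = 10,
                       min_mean_log2_expr = 0.1,
                       z_clip = 3,
                       window_size = 100,
                       top_cell_fraction = 0.05,
                       ms_threshold = 0.02,
                       corr_threshold = 0.2,
                       center = c("cell", "window"),
                       seed = 0L) {
  p <- list(max_putative_malignant_fraction = max_putative_malignant_fraction,
            min_cells_per_gene = min_cells_per_gene,
            min_mean_log2_expr = min_mean_log2_expr,
            z_clip = z_clip, window_size = window_size,
            top_cell_fraction = top_cell_fraction,
            ms_threshold = ms_threshold, corr_threshold = corr_threshold,
            center = match.arg(center), seed = as.integer(seed))
  if (p$window_size < 2) stop_oncostage("window_size must be >= 2")
  if (p$max_putative_malignant_fraction <= 0 ||
      p$max_putative_malignant_fraction >= 1 ||
      p$top_cell_fraction <= 0 || p$top_cell_fraction >= 1)
    stop_oncostage("fractions must lie in (0,1)")
  if (p$ms_threshold <= 0 || p$corr_threshold <= 0 || p$z_clip <= 0)
    stop_oncostage("thresholds must be positive")
  class(p) <- "cnv_params"
  p
}

#' Library-normalized log2 expression
#'
#' `log2(1 + count x scale_factor / cell_total)` — the input scale of the
#' CNV gene filter and z-scoring (distinct from the natural-log matrix
#' used elsewhere in the pipeline).
#'
#' @param counts gene x cell count matrix.
#' @param scale_factor library-size target.
#' @return sparse gene x cell matrix on the log2 scale.
#' @export
log2_normalize <- function(counts, scale_factor = 1e4) {
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) stop_oncostage("cell(s) with zero total count")
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  j <- rep(seq_len(ncol(m)), diff(m@p))
  m@x <- log2(1 + m@x * scale_factor / tot[j])
  m
}

#' Dilute tumor cells with normal reference cells
#'
#' Adds the smallest number of normal cells (seeded subsample of the pool)
#' such that putative malignant (tumor) cells make up at most
#' `max_putative_malignant_fraction` of the mix. When the pool is too
#' small, all normals are used and the achieved fraction is recorded with
#' a warning.
#'
#' @param tumor,normal gene x cell matrices over the same genes.
#' @param params a [cnv_params()] object.
#' @return list with `matrix` (combined, tumor cells first), `origin`
#'   (`"tumor"`/`"normal"` per column), `tumor_fraction` (achieved).
#' @export
assemble_reference_mix <- function(tumor, normal, params = cnv_params()) {
  if (ncol(tumor) == 0) stop_oncostage("zero tumor cells")
  if (ncol(normal) == 0) stop_oncostage("normal pool is empty")
  if (!identical(rownames(tumor), rownames(normal)))
    stop_oncostage("tumor and normal matrices must share the same genes")
  nt <- ncol(tumor)
  need <- ceiling(nt / params$max_putative_malignant_fraction) - nt
  if (need > ncol(normal)) {
    warning(sprintf(
      "normal pool insufficient: tumor fraction %.3f exceeds %.2f",
      nt / (nt + ncol(normal)), params$max_putative_malignant_fraction))
    sel <- seq_len(ncol(normal))
  } else {
    sel <- with_seed(derive_seed(params$seed, "mix"),
                     sort(sample.int(ncol(normal), need)))
  }
  combined <- cbind(tumor, normal[, sel, drop = FALSE])
  list(matrix = combined,
       origin = rep(c("tumor", "normal"), c(nt, length(sel))),
       tumor_fraction = nt / ncol(combined))
}

#' Filter genes for CNV inference
#'
#' Keeps genes expressed (log2 value > 0, i.e. count > 0) in at least
#' `min_cells_per_gene` cells and with mean log2 expression of at least
#' `min_mean_log2_expr` across all cells of the mix; both removal
#' conditions are strict.
#'
#' @param mat gene x cell log2-normalized matrix.
#' @param params a [cnv_params()] object.
#' @return filtered matrix.
#' @export
cnv_gene_filter <- function(mat, params = cnv_params()) {
  keep <- Matrix::rowSums(mat > 0) >= params$min_cells_per_gene &
    Matrix::rowMeans(mat) >= params$min_mean_log2_expr
  if (!any(keep)) stop_oncostage("CNV gene filter removed every gene")
  mat[keep, , drop = FALSE]
}

#' Per-gene z-scores clipped to a symmetric range
#'
#' Standardizes each gene across all cells of the mix using the sample
#' (n-1) standard deviation; constant genes map to zero; values are then
#' clipped to `[-z_clip, z_clip]`.
#'
#' @param mat gene x cell matrix.
#' @param params a [cnv_params()] object.
#' @return dense gene x cell matrix of clipped z-scores.
#' @export
zscore_clip <- function(mat, params = cnv_params()) {
  m <- as.matrix(mat)
  mu <- rowMeans(m)
  sd <- sqrt(row_vars(m))
  z <- (m - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z[z > params$z_clip] <- params$z_clip
  z[z < -params$z_clip] <- -params$z_clip
  z
}

#' Windowed CNV signal along the genome
#'
#' Orders genes by chromosome and position, then computes, per chromosome,
#' the moving average of the clipped z-scores over consecutive windows of
#' exactly `window_size` genes (step 1). Windows never cross a chromosome
#' boundary; a chromosome with fewer retained genes than `window_size`
#' contributes a single window spanning all its genes.
#'
#' @param zmat gene x cell matrix of clipped z-scores.
#' @param gene_order data.frame (`gene`, `chromosome`, `start`) in
#'   karyotype order; genes of `zmat` must be a subset.
#' @param params a [cnv_params()] object.
#' @return list of class `cnv_profile`: `windows` (data.frame with
#'   chromosome and first/last gene of each window) and `signal`
#'   (cell x window matrix).
#' @export
windowed_cnv_signal <- function(zmat, gene_order, params = cnv_params()) {
  miss <- setdiff(rownames(zmat), gene_order$gene)
  if (length(miss)) stop_oncostage("genes missing from gene_order: ", miss[1])
  ord <- gene_order[gene_order$gene %in% rownames(zmat), ]
  chrs <- unique(ord$chromosome)
  w <- params$window_size
  sig_blocks <- list(); win_blocks <- list()
  for (ch in chrs) {
    og <- ord[ord$chromosome == ch, ]
    og <- og[order(og$start), ]
    m <- zmat[og$gene, , drop = FALSE]      # genes x cells, genome order
    n <- nrow(m)
    if (n == 0) next
    if (n < w) {
      sig <- matrix(colMeans(m), ncol = 1)
      win <- data.frame(chromosome = ch, first_gene = og$gene[1],
                        last_gene = og$gene[n], n_genes = n)
    } else {
      cs <- apply(m, 2, cumsum)
      if (n == 1) cs <- matrix(cs, nrow = 1)
      k <- n - w + 1
      upper <- cs[w:n, , drop = FALSE]
      lower <- rbind(0, cs)[1:k, , drop = FALSE]
      sig <- t(upper - lower) / w            # cells x windows
      win <- data.frame(chromosome = ch, first_gene = og$gene[1:k],
                        last_gene = og$gene[w:n], n_genes = w)
    }
    sig_blocks[[ch]] <- sig
    win_blocks[[ch]] <- win
  }
  if (!length(sig_blocks)) stop_oncostage("no chromosome yields a window")
  signal <- do.call(cbind, sig_blocks)
  rownames(signal) <- colnames(zmat)
  structure(list(windows = do.call(rbind, c(win_blocks,
                                            make.row.names = FALSE)),
                 signal = signal),
            class = "cnv_profile")
}

#' Center CNV profiles
#'
#' Default (`"cell"`): subtract each cell's mean window signal, removing
#' the cell-level baseline. Alternative (`"window"`): subtract each
#' window's mean across cells.
#'
#' @param profile a `cnv_profile`.
#' @param params a [cnv_params()] object (`center` used).
#' @return the profile with centered `signal`.
#' @export
center_cnv_profiles <- function(profile, params = cnv_params()) {
  s <- profile$signal
  profile$signal <- if (params$center == "cell") s - rowMeans(s)
                    else sweep(s, 2, colMeans(s))
  profile
}

#' Mean-square and reference-correlation malignancy scores
#'
#' `ms_score` is each cell's mean squared window signal. The reference
#' profile is the window-wise mean over the `ceiling(top_cell_fraction x
#' n_cells)` cells (at least 2) with the highest `ms_score`;
#' `corr_score` is the Pearson correlation of each cell's window vector
#' with that reference, with 0 substituted for zero-variance vectors.
#'
#' @param profile a centered `cnv_profile`.
#' @param params a [cnv_params()] object.
#' @return the profile with `ms_score`, `corr_score`, `reference` added.
#' @export
malignancy_scores <- function(profile, params = cnv_params()) {
  s <- profile$signal
  if (ncol(s) < 2)
    stop_oncostage("need at least 2 windows for the correlation score")
  ms <- rowMeans(s^2)
  n_top <- max(2L, ceiling(params$top_cell_fraction * nrow(s)))
  top <- order(-ms)[seq_len(min(n_top, nrow(s)))]
  ref <- colMeans(s[top, , drop = FALSE])
  corr <- if (stats::sd(ref) == 0) rep(0, nrow(s)) else {
    cc <- suppressWarnings(as.vector(stats::cor(t(s), ref)))
    cc[is.na(cc)] <- 0
    cc
  }
  profile$ms_score <- stats::setNames(ms, rownames(s))
  profile$corr_score <- stats::setNames(corr, rownames(s))
  profile$reference <- ref
  profile
}

#' Malignancy call from the OR-rule
#'
#' A tumor-origin cell is malignant when its mean-square score strictly
#' exceeds `ms_threshold` OR its reference correlation strictly exceeds
#' `corr_threshold`; reference normals are always non-malignant.
#'
#' @param profile a `cnv_profile` with scores.
#' @param origin `"tumor"`/`"normal"` per cell of the profile.
#' @param params a [cnv_params()] object.
#' @return the profile with a named logical `malignant` added.
#' @export
classify_malignant <- function(profile, origin, params = cnv_params()) {
  stopifnot(length(origin) == nrow(profile$signal))
  mal <- origin == "tumor" &
    (profile$ms_score > params$ms_threshold |
     profile$corr_score > params$corr_threshold)
  profile$malignant <- stats::setNames(mal, rownames(profile$signal))
  profile
}

#' Full expression-derived CNV malignancy pipeline
#'
#' Chains [assemble_reference_mix()], [log2_normalize()],
#' [cnv_gene_filter()], [zscore_clip()], [windowed_cnv_signal()],
#' [center_cnv_profiles()], [malignancy_scores()] and
#' [classify_malignant()] on raw counts.
#'
#' @param tumor_counts,normal_counts gene x cell count matrices over the
#'   same genes.
#' @param gene_order data.frame (`gene`, `chromosome`, `start`) in
#'   karyotype order.
#' @param params a [cnv_params()] object.
#' @return a `cnv_profile` with `origin` recorded.
#' @export
run_cnv_pipeline <- function(tumor_counts, normal_counts, gene_order,
                             params = cnv_params()) {
  mix <- assemble_reference_mix(tumor_counts, normal_counts, params)
  l2 <- log2_normalize(mix$matrix)
  l2 <- cnv_gene_filter(l2, params)
  z <- zscore_clip(l2, params)
  prof <- windowed_cnv_signal(z, gene_order, params)
  prof <- center_cnv_profiles(prof, params)
  prof <- malignancy_scores(prof, params)
  prof <- classify_malignant(prof, mix$origin, params)
  prof$origin <- mix$origin
  prof$tumor_fraction <- mix$tumor_fraction
  prof
}
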