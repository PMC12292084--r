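#' Simulation configuration for the synthetic single-cell / bulk generator
#'
#' Builds and validates the configuration object consumed by
#' [simulate_cells()] and [simulate_bulk_cohort()]. The defaults describe a
#' small multi-stage lung-tumor world: epithelial, immune and stromal
#' populations from normal and tumor tissue across an early (IA) and a late
#' (IV) stage; one segmental copy-number amplification confined to tumor
#' epithelial cells; 50 late-vs-early differentially expressed genes;
#' five planted transcription-factor regulons (one active only in the late
#' stage); and two ligand-receptor pairs, one of which signals exclusively
#' in the late condition.
#'
#' Counts are negative binomial with mean =
#' baseline gene mean x cell size factor x CNV dosage x DE effect x regulon
#' activity, so copy-number events act multiplicatively on expression (the
#' dosage model underlying expression-derived CNV inference).
#'
#' @param chromosomes data.frame with columns `name`, `n_genes`; genome order
#'   is the row order.
#' @param groups data.frame with columns `cell_type`, `tissue`
#'   (`"normal"`/`"tumor"`), `stage`, `n` (cells per group, positive).
#' @param cnv_events data.frame with columns `cell_type`, `stage` (NA = all
#'   tumor stages of that type), `chromosome`, `start`, `end` (1-based gene
#'   indices within the chromosome), `copy_ratio` (> 0; 0.5 deletion, 1.5
#'   amplification). May have zero rows.
#' @param de_genes data.frame with columns `gene`, `lfc`: late-vs-early log2
#'   effects applied to late-stage epithelial cells.
#' @param regulons_true list of `list(tf=, targets=, strength=, stage=)`
#'   entries; `strength` in `[0,1]`, `stage` NA for stage-agnostic activity.
#' @param lr_pairs_true data.frame with columns `name`, `ligand`, `receptor`,
#'   `pathway`, `sender`, `receiver`, `amp_early`, `amp_late` (mean
#'   expression amplitude of the pair genes in the active condition; 0 means
#'   silent).
#' @param libsize_lognormal length-2 numeric `(meanlog, sdlog)` of the
#'   per-cell size factor.
#' @param baseline_nb list with `meanlog`, `sdlog` (log-normal law of
#'   baseline gene means) and `size` (negative-binomial size; smaller =
#'   more overdispersed).
#' @param gene_mean_overrides named numeric vector pinning the baseline mean
#'   of specific genes (used to give planted structures a workable
#'   expression level).
#' @param mito_fraction fraction of genes flagged mitochondrial (renamed
#'   with an `MT-` prefix; placed at the end of the last chromosome).
#' @param survival list describing the bulk cohort: `subgroups` data.frame
#'   (`name`, `hazard` >= 0, `n`), `censor_window` (uniform censoring upper
#'   bound; `Inf` = no censoring), `noise_sd` (Gaussian sd on the log2
#'   scale), `marker_effect` (log2 elevation of a subgroup's marker block),
#'   `markers` (named list subgroup -> marker genes).
#' @param seed master seed; every stream used by the generators is derived
#'   from it, so identical configs reproduce identical datasets.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(chromosomes = NULL,
                       groups = NULL,
                       cnv_events = NULL,
                       de_genes = NULL,
                       regulons_true = NULL,
                       lr_pairs_true = NULL,
                       libsize_lognormal = c(0, 0.3),
                       baseline_nb = list(meanlog = 0, sdlog = 1, size = 2),
                       gene_mean_overrides = NULL,
                       mito_fraction = 0.02,
                       survival = NULL,
                       seed = 1L) {
  if (is.null(chromosomes))
    chromosomes <- data.frame(name = paste0("chr", 1:5),
                              n_genes = rep(400L, 5))
  genes <- make_gene_names(chromosomes, mito_fraction)

  if (is.null(groups))
    groups <- data.frame(
      cell_type = rep(c("epithelial", "immune", "stromal"), 3),
      tissue    = rep(c("normal", "tumor", "tumor"), each = 3),
      stage     = rep(c("normal", "IA", "IV"), each = 3),
      n         = c(200L, 300L, 150L, 250L, 250L, 150L, 250L, 250L, 200L))

  if (is.null(cnv_events))
    cnv_events <- data.frame(cell_type = "epithelial", stage = NA_character_,
                             chromosome = "chr1", start = 1L, end = 300L,
                             copy_ratio = 1.5)

  if (is.null(de_genes))
    de_genes <- data.frame(gene = genes$gene[401:450], lfc = 2)

  if (is.null(regulons_true)) {
    pool <- genes$gene[801:905]           # chr3 block: 5 TFs + 100 targets
    regulons_true <- lapply(1:5, function(i) list(
      tf = pool[i],
      targets = pool[5 + (i - 1) * 20 + 1:20],
      strength = 0.8,
      stage = if (i == 5) "IV" else NA_character_))
  }

  if (is.null(lr_pairs_true))
    lr_pairs_true <- data.frame(
      name = c("LIGA_RECA", "LIGB_RECB"),
      ligand = genes$gene[c(1601, 1603)],
      receptor = genes$gene[c(1602, 1604)],
      pathway = c("PATHA", "PATHB"),
      sender = c("epithelial", "epithelial"),
      receiver = c("immune", "stromal"),
      amp_early = c(5, 0), amp_late = c(5, 5))

  if (is.null(gene_mean_overrides)) {
    gene_mean_overrides <- c(
      stats::setNames(rep(5, nrow(de_genes)), de_genes$gene),
      stats::setNames(rep(3, length(unique(unlist(lapply(regulons_true,
        function(r) c(r$tf, r$targets)))))),
        unique(unlist(lapply(regulons_true, function(r) c(r$tf, r$targets))))))
  }

  if (is.null(survival)) {
    mk <- split(de_genes$gene,
                rep_len(c("C1", "C2", "C3"), nrow(de_genes)))
    survival <- list(
      subgroups = data.frame(name = c("C1", "C2", "C3"),
                             hazard = c(0.02, 0.05, 0.10),
                             n = c(100L, 100L, 100L)),
      censor_window = 60, noise_sd = 1, marker_effect = 3,
      markers = mk)
  }

  cfg <- structure(list(
    chromosomes = chromosomes, genes = genes, groups = groups,
    cnv_events = cnv_events, de_genes = de_genes,
    regulons_true = regulons_true, lr_pairs_true = lr_pairs_true,
    libsize_lognormal = libsize_lognormal, baseline_nb = baseline_nb,
    gene_mean_overrides = gene_mean_overrides,
    mito_fraction = mito_fraction, survival = survival,
    seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

make_gene_names <- function(chromosomes, mito_fraction) {
  n_genes <- sum(chromosomes$n_genes)
  gene <- sprintf("G%05d", seq_len(n_genes))
  n_mito <- floor(mito_fraction * n_genes)
  if (n_mito > 0) {
    idx <- seq(n_genes - n_mito + 1, n_genes)
    gene[idx] <- paste0("MT-", gene[idx])
  }
  data.frame(
    gene = gene,
    chromosome = rep(chromosomes$name, chromosomes$n_genes),
    start = unlist(lapply(chromosomes$n_genes,
                          function(k) seq_len(k) * 1000L), use.names = FALSE))
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (any(groups$n <= 0)) stop_oncostage("group sizes must be positive")
    if (nrow(cnv_events) > 0) {
      if (any(cnv_events$copy_ratio <= 0))
        stop_oncostage("copy_ratio must be > 0")
      for (i in seq_len(nrow(cnv_events))) {
        ev <- cnv_events[i, ]
        ci <- match(ev$chromosome, chromosomes$name)
        if (is.na(ci)) stop_oncostage("unknown chromosome in cnv_events: ",
                                      ev$chromosome)
        if (ev$start < 1 || ev$end > chromosomes$n_genes[ci] ||
            ev$start > ev$end)
          stop_oncostage("cnv_event span outside chromosome ", ev$chromosome)
      }
    }
    bad <- setdiff(de_genes$gene, genes$gene)
    if (length(bad)) stop_oncostage("unknown gene in de_genes: ", bad[1])
    rg <- unlist(lapply(regulons_true, function(r) c(r$tf, r$targets)))
    bad <- setdiff(rg, genes$gene)
    if (length(bad)) stop_oncostage("unknown gene in regulons_true: ", bad[1])
    for (r in regulons_true)
      if (r$tf %in% r$targets)
        stop_oncostage("regulon TF cannot be its own target: ", r$tf)
    if (any(cfg$survival$subgroups$hazard < 0))
      stop_oncostage("hazard rates must be non-negative")
  })
  invisible(cfg)
}

#' Map stage labels to early/late/normal conditions
#'
#' Stage IV is the late condition; any other tumor stage is early; the
#' literal `"normal"` marks normal-tissue cells.
#' @param stage character vector of stage labels.
#' @return character vector in `{"early","late","normal"}`.
#' @export
stage_to_condition <- function(stage) {
  ifelse(stage == "normal", "normal", ifelse(stage == "IV", "late", "early"))
}

cells_matching_event <- function(meta, ev) {
  hit <- meta$cell_type == ev$cell_type & meta$tissue == "tumor"
  if (!is.na(ev$stage)) hit <- hit & meta$stage == ev$stage
  hit
}

#' Generate a synthetic single-cell dataset with full ground truth
#'
#' Draws a sparse gene x cell count matrix under the model described in
#' [sim_config()], together with genomically ordered gene annotation, cell
#' metadata and a `truth` list (malignant flag, per-cell per-gene dosage,
#' DE gene table, regulon edge list, ligand-receptor amplitudes).
#'
#' @param config a [sim_config()] object.
#' @return list of class `synthetic_dataset` with elements `counts`
#'   (dgCMatrix, genes x cells), `gene_annotation`, `cell_metadata`,
#'   `mito_genes`, `truth`.
#' @export
simulate_cells <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- config$genes
  G <- nrow(genes)

  meta <- do.call(rbind, lapply(seq_len(nrow(config$groups)), function(i) {
    g <- config$groups[i, ]
    data.frame(cell_type = g$cell_type, tissue = g$tissue, stage = g$stage,
               n_idx = seq_len(g$n))
  }))
  n_cells <- nrow(meta)
  meta$cell <- sprintf("C%05d", seq_len(n_cells))
  # deterministic sample assignment: 3 samples per tissue/stage combination
  key <- paste(meta$tissue, meta$stage, sep = "_")
  meta$sample <- paste0(ifelse(meta$tissue == "normal", "N", "T"),
                        key, "_S", (meta$n_idx %% 3L) + 1L)
  meta <- meta[, c("cell", "sample", "tissue", "stage", "cell_type")]

  base <- with_seed(derive_seed(config$seed, "baseline"),
                    stats::rlnorm(G, config$baseline_nb$meanlog,
                                  config$baseline_nb$sdlog))
  names(base) <- genes$gene
  ov <- config$gene_mean_overrides
  if (length(ov)) base[names(ov)] <- ov
  lr_genes <- unique(c(config$lr_pairs_true$ligand,
                       config$lr_pairs_true$receptor))
  base[lr_genes] <- 0   # LR genes silent except where planted

  sf <- with_seed(derive_seed(config$seed, "libsize"),
                  stats::rlnorm(n_cells, config$libsize_lognormal[1],
                                config$libsize_lognormal[2]))

  # dosage matrix (genes x cells), 1 = diploid
  dosage <- matrix(1, G, n_cells, dimnames = list(genes$gene, meta$cell))
  touched <- matrix(FALSE, G, n_cells)
  if (nrow(config$cnv_events) > 0) {
    for (i in seq_len(nrow(config$cnv_events))) {
      ev <- config$cnv_events[i, ]
      gi <- which(genes$chromosome == ev$chromosome)[ev$start:ev$end]
      ci <- which(cells_matching_event(meta, ev))
      if (any(touched[gi, ci]))
        stop_oncostage("overlapping cnv_events on the same cells and genes")
      touched[gi, ci] <- TRUE
      dosage[gi, ci] <- ev$copy_ratio
    }
  }
  malignant <- colSums(touched) > 0
  names(malignant) <- meta$cell

  mu <- base * matrix(sf, G, n_cells, byrow = TRUE) * dosage

  # late-vs-early DE effect on late-stage epithelial cells
  late_epi <- meta$cell_type == "epithelial" &
    stage_to_condition(meta$stage) == "late"
  if (any(late_epi) && nrow(config$de_genes) > 0) {
    gi <- match(config$de_genes$gene, genes$gene)
    mu[gi, late_epi] <- mu[gi, late_epi] * 2^config$de_genes$lfc
  }

  # planted regulons: latent lognormal TF activity scales TF and targets
  act_seed <- derive_seed(config$seed, "regulon_activity")
  for (k in seq_along(config$regulons_true)) {
    r <- config$regulons_true[[k]]
    a <- with_seed(act_seed + k, stats::rlnorm(n_cells, 0, 1))
    if (!is.null(r$stage) && !is.na(r$stage))
      a[meta$stage != r$stage] <- 0.1
    ti <- match(r$targets, genes$gene)
    mu[ti, ] <- mu[ti, ] * matrix(a^r$strength, length(ti), n_cells,
                                  byrow = TRUE)
    mu[match(r$tf, genes$gene), ] <- mu[match(r$tf, genes$gene), ] * a
  }

  # planted ligand-receptor signaling: pair genes expressed only in the
  # stated sender/receiver type under the stated condition
  cond <- stage_to_condition(meta$stage)
  if (nrow(config$lr_pairs_true) > 0) {
    for (i in seq_len(nrow(config$lr_pairs_true))) {
      p <- config$lr_pairs_true[i, ]
      for (cc in c("early", "late")) {
        amp <- if (cc == "early") p$amp_early else p$amp_late
        if (amp <= 0) next
        snd <- meta$cell_type == p$sender & cond == cc
        rcv <- meta$cell_type == p$receiver & cond == cc
        mu[match(p$ligand, genes$gene), snd] <- amp * sf[snd]
        mu[match(p$receptor, genes$gene), rcv] <- amp * sf[rcv]
      }
    }
  }

  counts <- with_seed(derive_seed(config$seed, "counts"),
    matrix(stats::rnbinom(G * n_cells, size = config$baseline_nb$size,
                          mu = as.vector(mu)),
           G, n_cells, dimnames = list(genes$gene, meta$cell)))
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")

  truth <- list(
    malignant = malignant,
    dosage = dosage,
    de_genes = config$de_genes,
    regulon_edges = if (length(config$regulons_true) == 0)
      data.frame(tf = character(), target = character(),
                 strength = numeric(), stage = character())
    else do.call(rbind, lapply(config$regulons_true, function(r)
      data.frame(tf = r$tf, target = r$targets, strength = r$strength,
                 stage = r$stage %||% NA_character_))),
    lr_amplitudes = config$lr_pairs_true)

  structure(list(counts = counts, gene_annotation = genes,
                 cell_metadata = meta,
                 mito_genes = genes$gene[startsWith(genes$gene, "MT-")],
                 truth = truth),
            class = "synthetic_dataset")
}

#' Generate a bulk expression cohort with subgroup-specific survival
#'
#' Each sample draws log2(x+1) expression from its subgroup's mean profile
#' (baseline plus a `marker_effect` elevation on the subgroup's marker
#' block) with Gaussian noise; survival time is exponential with the
#' subgroup hazard, censored uniformly on `(0, censor_window)`.
#'
#' @param config a [sim_config()] object (the `survival` element drives
#'   this generator).
#' @return list with `expr` (samples x genes matrix, log2 scale),
#'   `survival` (data.frame: sample, time, event, subgroup), `subgroups`
#'   (named character vector, the planted truth).
#' @export
simulate_bulk_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sv <- config$survival
  if (any(sv$subgroups$hazard < 0))
    stop_oncostage("hazard rates must be non-negative")
  genes <- config$genes$gene
  G <- length(genes)
  subgroup <- rep(sv$subgroups$name, sv$subgroups$n)
  n <- length(subgroup)
  samples <- sprintf("S%04d", seq_len(n))
  names(subgroup) <- samples

  mu0 <- with_seed(derive_seed(config$seed, "bulk_baseline"),
                   pmax(0, stats::rnorm(G, 3, 1.5)))
  names(mu0) <- genes
  expr <- with_seed(derive_seed(config$seed, "bulk_noise"), {
    e <- matrix(stats::rnorm(n * G, sd = sv$noise_sd), n, G,
                dimnames = list(samples, genes))
    e <- sweep(e, 2, mu0, "+")
    for (sg in names(sv$markers)) {
      gi <- match(sv$markers[[sg]], genes)
      e[subgroup == sg, gi] <- e[subgroup == sg, gi] + sv$marker_effect
    }
    pmax(e, 0)
  })

  surv <- with_seed(derive_seed(config$seed, "survival"), {
    hz <- sv$subgroups$hazard[match(subgroup, sv$subgroups$name)]
    death <- ifelse(hz > 0, stats::rexp(n, pmax(hz, 1e-300)), Inf)
    cens <- if (is.finite(sv$censor_window))
      stats::runif(n, 0, sv$censor_window) else rep(Inf, n)
    time <- pmin(death, cens)
    if (any(!is.finite(time)))
      stop_oncostage("infinite survival time: zero hazard needs a finite censor window")
    data.frame(sample = samples, time = time,
               event = as.integer(death <= cens), subgroup = subgroup,
               row.names = NULL)
  })

  list(expr = expr, survival = surv, subgroups = subgroup)
}
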