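# Shared simulation worlds and small-matrix builders for the suite.

# dense gene x cell matrix with ids
toy_counts <- function(values, n_genes, n_cells,
                       genes = sprintf("g%02d", seq_len(n_genes)),
                       cells = sprintf("c%02d", seq_len(n_cells))) {
  matrix(values, n_genes, n_cells, dimnames = list(genes, cells))
}

empty_events <- function() {
  data.frame(cell_type = character(), stage = character(),
             chromosome = character(), start = integer(), end = integer(),
             copy_ratio = numeric())
}

no_de <- function() data.frame(gene = character(), lfc = numeric())

no_lr <- function() {
  data.frame(name = character(), ligand = character(),
             receptor = character(), pathway = character(),
             sender = character(), receiver = character(),
             amp_early = numeric(), amp_late = numeric())
}

# CNV parameter-recovery world: 200 diploid + 200 event-bearing tumor
# epithelial cells, 1600 normals, one 300-gene event on chr1, baseline
# NB mean >= 2 (lognormal median 5)
cnv_recovery_config <- function(copy_ratio, seed) {
  sim_config(
    groups = data.frame(cell_type = rep("epithelial", 3),
                        tissue = c("tumor", "tumor", "normal"),
                        stage = c("IA", "IV", "normal"),
                        n = c(200L, 200L, 1600L)),
    cnv_events = data.frame(cell_type = "epithelial", stage = "IV",
                            chromosome = "chr1", start = 1L, end = 300L,
                            copy_ratio = copy_ratio),
    de_genes = no_de(), regulons_true = list(), lr_pairs_true = no_lr(),
    baseline_nb = list(meanlog = log(5), sdlog = 0.5, size = 2),
    gene_mean_overrides = stats::setNames(numeric(0), character(0)),
    seed = seed)
}

# Consensus-GRN recovery world: 500 cells, 5 planted regulons (20 targets,
# strength 0.8), candidate list of 5 true + 200 decoy TFs, expression
# panel of TFs + targets + 100 distractor genes
grn_recovery_world <- function(seed) {
  g <- sprintf("G%05d", 1:2000)
  regs <- lapply(1:5, function(i)
    list(tf = g[800 + i], targets = g[805 + (i - 1) * 20 + 1:20],
         strength = 0.8, stage = NA_character_))
  cfg <- sim_config(
    groups = data.frame(cell_type = "epithelial", tissue = "tumor",
                        stage = "IA", n = 500L),
    cnv_events = empty_events(), de_genes = no_de(),
    regulons_true = regs, seed = seed)
  ds <- simulate_cells(cfg)
  norm <- log_normalize(ds$counts)
  tfs_true <- vapply(regs, `[[`, "", "tf")
  targets <- unlist(lapply(regs, `[[`, "targets"))
  rest <- setdiff(cfg$genes$gene[1:800], c(tfs_true, targets))
  pick <- with_seed_test(1, {
    decoys <- sample(rest, 200)
    list(decoys = decoys, extra = sample(setdiff(rest, decoys), 100))
  })
  list(norm = norm[unique(c(tfs_true, pick$decoys, targets, pick$extra)), ],
       tf_list = c(tfs_true, pick$decoys),
       truth_edges = paste(rep(tfs_true, each = 20), targets))
}

# Ligand-receptor world: 200 genes, 3 cell types x {IA, IV}, pathway
# PATHB silent in the early condition
lr_world_config <- function(seed) {
  sim_config(
    chromosomes = data.frame(name = c("chr1", "chr2"),
                             n_genes = c(100L, 100L)),
    groups = data.frame(
      cell_type = rep(c("epithelial", "immune", "stromal"), 2),
      tissue = "tumor", stage = rep(c("IA", "IV"), each = 3), n = 50L),
    cnv_events = empty_events(), de_genes = no_de(),
    regulons_true = list(),
    lr_pairs_true = data.frame(
      name = c("LIGA_RECA", "LIGB_RECB"),
      ligand = c("G00101", "G00103"), receptor = c("G00102", "G00104"),
      pathway = c("PATHA", "PATHB"),
      sender = "epithelial", receiver = c("immune", "stromal"),
      amp_early = c(5, 0), amp_late = c(5, 5)),
    mito_fraction = 0, seed = seed)
}

lr_db_from_config <- function(cfg) {
  lr_database(cfg$lr_pairs_true$name,
              as.list(cfg$lr_pairs_true$ligand),
              as.list(cfg$lr_pairs_true$receptor),
              cfg$lr_pairs_true$pathway)
}

# mean of a (possibly sparse) matrix without relying on a mean() method
mean_sp <- function(m) sum(m) / prod(dim(m))

# all n! permutations of 1..n as a matrix (tiny n only)
perm_matrix <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- perm_matrix(n - 1)
  do.call(rbind, lapply(1:n, function(i)
    cbind(i, matrix((1:n)[-i][sub], nrow(sub)))))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
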