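test_that("identical config reproduces identical datasets and serialized form", {
  cfg1 <- sim_config(seed = 3)
  cfg2 <- sim_config(seed = 3)
  ds1 <- simulate_cells(cfg1)
  ds2 <- simulate_cells(cfg2)
  expect_identical(as.matrix(ds1$counts), as.matrix(ds2$counts))
  expect_identical(ds1$cell_metadata, ds2$cell_metadata)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_dataset(ds1, d1); write_dataset(ds2, d2)
  for (f in list.files(d1, recursive = TRUE))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  expect_false(identical(as.matrix(ds1$counts),
                         as.matrix(simulate_cells(sim_config(seed = 4))$counts)))
})

test_that("zero cnv_events gives an identically-1 dosage matrix", {
  cfg <- sim_config(cnv_events = empty_events(), seed = 5)
  ds <- simulate_cells(cfg)
  expect_true(all(ds$truth$dosage == 1))
  expect_false(any(ds$truth$malignant))
})

test_that("a 0.5 deletion halves the mean count of spanned genes", {
  # Monte-Carlo check of the simulator's own mean structure: 500 affected
  # cells, 300-gene span, baseline mean pinned at 5
  g <- sprintf("G%05d", 1:2000)
  cfg <- sim_config(
    groups = data.frame(cell_type = c("epithelial", "epithelial"),
                        tissue = "tumor", stage = c("IV", "IA"),
                        n = c(500L, 500L)),
    cnv_events = data.frame(cell_type = "epithelial", stage = "IV",
                            chromosome = "chr1", start = 1L, end = 300L,
                            copy_ratio = 0.5),
    de_genes = no_de(), regulons_true = list(), lr_pairs_true = no_lr(),
    gene_mean_overrides = stats::setNames(rep(5, 300), g[1:300]),
    seed = 11)
  ds <- simulate_cells(cfg)
  affected <- ds$cell_metadata$stage == "IV"
  span <- g[1:300]
  ratio <- mean_sp(ds$counts[span, affected]) /
    mean_sp(ds$counts[span, !affected])
  expect_lt(abs(ratio - 0.5), 0.05)
})

test_that("dosage monotonicity: higher copy ratio raises spanned-gene means", {
  means <- vapply(c(0.5, 1, 1.5, 2), function(cr) {
    cfg <- sim_config(
      cnv_events = data.frame(cell_type = "epithelial", stage = NA,
                              chromosome = "chr1", start = 1L, end = 300L,
                              copy_ratio = cr),
      seed = 7)
    ds <- simulate_cells(cfg)
    aff <- ds$truth$malignant
    span <- rownames(ds$counts)[1:300]
    mean_sp(ds$counts[span, aff])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(cnv_events = data.frame(
    cell_type = "epithelial", stage = NA, chromosome = "chr1",
    start = 1L, end = 9999L, copy_ratio = 1.5)), "span")
  expect_error(sim_config(cnv_events = data.frame(
    cell_type = "epithelial", stage = NA, chromosome = "chr1",
    start = 1L, end = 10L, copy_ratio = -1)), "copy_ratio")
  expect_error(sim_config(de_genes = data.frame(gene = "NOPE", lfc = 1)),
               "unknown gene")
  # two events touching the same cells and genes
  cfg <- sim_config(cnv_events = data.frame(
    cell_type = "epithelial", stage = c(NA, "IV"), chromosome = "chr1",
    start = c(1L, 100L), end = c(300L, 150L), copy_ratio = c(1.5, 0.5)))
  expect_error(simulate_cells(cfg), "overlapping")
})

test_that("ground truth records every planted structure", {
  cfg <- sim_config(seed = 2)
  ds <- simulate_cells(cfg)
  expect_setequal(ds$truth$de_genes$gene, cfg$de_genes$gene)
  expect_equal(nrow(ds$truth$regulon_edges),
               sum(lengths(lapply(cfg$regulons_true, `[[`, "targets"))))
  expect_setequal(ds$truth$lr_amplitudes$name, cfg$lr_pairs_true$name)
  expect_length(ds$truth$malignant, ncol(ds$counts))
  # metadata/annotation bijection
  expect_setequal(ds$cell_metadata$cell, colnames(ds$counts))
  expect_setequal(ds$gene_annotation$gene, rownames(ds$counts))
})

test_that("bulk cohort: equal hazards give indistinguishable event times", {
  cfg <- sim_config(survival = list(
    subgroups = data.frame(name = c("A", "B"), hazard = 0.1,
                           n = c(250L, 250L)),
    censor_window = Inf, noise_sd = 1, marker_effect = 3,
    markers = list(A = "G00401", B = "G00402")), seed = 13)
  bulk <- simulate_bulk_cohort(cfg)
  ks <- stats::ks.test(bulk$survival$time[bulk$subgroups == "A"],
                       bulk$survival$time[bulk$subgroups == "B"])
  expect_gt(ks$p.value, 0.01)
  expect_true(all(bulk$survival$event == 1))
})

test_that("bulk cohort: zero hazard with finite window yields zero events", {
  cfg <- sim_config(survival = list(
    subgroups = data.frame(name = c("A", "B"), hazard = c(0.2, 0),
                           n = c(50L, 50L)),
    censor_window = 30, noise_sd = 1, marker_effect = 3,
    markers = list(A = "G00401", B = "G00402")), seed = 17)
  bulk <- simulate_bulk_cohort(cfg)
  expect_true(all(bulk$survival$event[bulk$subgroups == "B"] == 0))
  expect_gt(sum(bulk$survival$event[bulk$subgroups == "A"]), 0)
})

test_that("bulk cohort: median survival scales as the inverse hazard ratio", {
  cfg <- sim_config(survival = list(
    subgroups = data.frame(name = c("A", "B"), hazard = c(0.1, 0.4),
                           n = c(200L, 200L)),
    censor_window = Inf, noise_sd = 1, marker_effect = 3,
    markers = list(A = "G00401", B = "G00402")), seed = 19)
  bulk <- simulate_bulk_cohort(cfg)
  r <- stats::median(bulk$survival$time[bulk$subgroups == "A"]) /
    stats::median(bulk$survival$time[bulk$subgroups == "B"])
  expect_lt(abs(r - 4) / 4, 0.25)
})

test_that("negative hazards are rejected", {
  expect_error(sim_config(survival = list(
    subgroups = data.frame(name = "A", hazard = -1, n = 10L),
    censor_window = 10, noise_sd = 1, marker_effect = 3,
    markers = list(A = "G00401"))), "hazard")
})

test_that("write/read round-trips a dataset", {
  cfg <- sim_config(chromosomes = data.frame(name = "chr1", n_genes = 100L),
                    groups = data.frame(cell_type = "epithelial",
                                        tissue = "tumor", stage = "IA",
                                        n = 50L),
                    cnv_events = data.frame(cell_type = "epithelial",
                                            stage = NA, chromosome = "chr1",
                                            start = 1L, end = 20L,
                                            copy_ratio = 0.5),
                    de_genes = no_de(), regulons_true = list(),
                    lr_pairs_true = no_lr(), mito_fraction = 0, seed = 23)
  ds <- simulate_cells(cfg)
  dir <- file.path(tempdir(), "roundtrip")
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(as.matrix(back$counts), as.matrix(ds$counts))
  expect_equal(back$cell_metadata, ds$cell_metadata)
  expect_equal(back$gene_annotation, ds$gene_annotation)
  expect_equal(back$truth$malignant, ds$truth$malignant)
  expect_equal(back$truth$dosage, ds$truth$dosage)
})

test_that("mtx header declares dimensions and stored entries", {
  cfg <- sim_config(chromosomes = data.frame(name = "chr1", n_genes = 100L),
                    groups = data.frame(cell_type = "epithelial",
                                        tissue = "tumor", stage = "IA",
                                        n = 50L),
                    cnv_events = empty_events(), de_genes = no_de(),
                    regulons_true = list(), lr_pairs_true = no_lr(),
                    mito_fraction = 0, seed = 29)
  ds <- simulate_cells(cfg)
  dir <- file.path(tempdir(), "header")
  write_dataset(ds, dir)
  hdr <- readLines(file.path(dir, "matrix.mtx"), n = 2)
  expect_match(hdr[1], "coordinate integer general")
  expect_equal(as.integer(strsplit(hdr[2], " ")[[1]]),
               c(100L, 50L, sum(ds$counts != 0)))
})

test_that("an empty dataset is refused, not written", {
  cfg <- sim_config(seed = 1)
  ds <- simulate_cells(cfg)
  ds$counts <- ds$counts[, integer(0)]
  expect_error(write_dataset(ds, file.path(tempdir(), "empty")), "empty")
})
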