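toy_db <- function() {
  lr_database(name = c("L1_R1", "L2_R2"),
              ligand = list("LIG1", c("LIG2A", "LIG2B")),
              receptor = list("REC1", "REC2"),
              pathway = c("PW1", "PW2"))
}

# log-normalized matrix whose expm1 means are easy to reason about
lognorm_of <- function(raw) log1p(raw)

test_that("group means aggregate subunits by zero-dominant geometric mean", {
  raw <- rbind(LIG1 = c(2, 2, 0, 0), LIG2A = c(1, 1, 4, 4),
               LIG2B = c(4, 4, 0, 0), REC1 = c(0, 0, 3, 3),
               REC2 = c(1, 1, 1, 1))
  colnames(raw) <- paste0("c", 1:4)
  norm <- lognorm_of(raw)
  types <- c("A", "A", "B", "B")
  expect_equal(group_mean_expression(norm, types, "LIG1"),
               c(A = 2, B = 0))                       # plain mean
  expect_equal(group_mean_expression(norm, types, c("LIG2A", "LIG2B")),
               c(A = 2, B = 0))                       # sqrt(1 x 4); zero wins
  expect_error(group_mean_expression(norm, types, "LIG1", types = "C"),
               "unknown cell type")
  expect_error(group_mean_expression(norm, types, "NOPE"), "absent")
})

test_that("interaction strength is the ligand-receptor mean product", {
  raw <- rbind(LIG1 = c(2, 2, 0, 0), LIG2A = 0, LIG2B = 0,
               REC1 = c(0, 0, 3, 3), REC2 = 0)
  colnames(raw) <- paste0("c", 1:4)
  sc <- interaction_scores(lognorm_of(raw), c("A", "A", "B", "B"), toy_db())
  expect_equal(nrow(sc), 2 * 2 * 2)           # ordered pairs incl self
  expect_equal(sc$strength[sc$sender == "A" & sc$receiver == "B" &
                             sc$interaction == "L1_R1"], 6)   # 2 x 3
  expect_equal(sc$strength[sc$sender == "B" & sc$receiver == "A" &
                             sc$interaction == "L1_R1"], 0)   # ligand absent
  expect_true(all(sc$strength[sc$interaction == "L2_R2"] == 0))
  # bilinearity: doubling all expression quadruples strengths
  sc2 <- interaction_scores(lognorm_of(raw * 2), c("A", "A", "B", "B"),
                            toy_db())
  expect_equal(sc2$strength, sc$strength * 4)
})

test_that("strength is invariant to cell order and type duplication", {
  set.seed(157)
  raw <- matrix(rpois(5 * 30, 3), 5, 30,
                dimnames = list(c("LIG1", "LIG2A", "LIG2B", "REC1", "REC2"),
                                paste0("c", 1:30)))
  types <- rep(c("A", "B", "C"), each = 10)
  norm <- lognorm_of(raw)
  s1 <- interaction_scores(norm, types, toy_db())
  p <- sample(30)
  s2 <- interaction_scores(norm[, p], types[p], toy_db())
  key <- function(s) s[order(s$sender, s$receiver, s$interaction), ]
  expect_equal(key(s1)$strength, key(s2)$strength)
  # duplicating every cell of a type leaves means unchanged
  dup <- cbind(norm, norm[, types == "A"])
  s3 <- interaction_scores(dup, c(types, rep("A", 10)), toy_db())
  expect_equal(key(s1)$strength, key(s3)$strength)
})

test_that("permutation p-values follow the add-one estimator", {
  # strong planted signal: observed strength above every permutation
  raw <- rbind(LIG1 = c(rep(50, 10), rep(0, 10)),
               LIG2A = 0, LIG2B = 0,
               REC1 = c(rep(0, 10), rep(50, 10)), REC2 = 0)
  colnames(raw) <- paste0("c", 1:20)
  types <- rep(c("A", "B"), each = 10)
  sc <- permutation_pvalues(lognorm_of(raw), types, toy_db(),
                            n_perm = 100, seed = 3)
  expect_equal(sc$p[sc$sender == "A" & sc$receiver == "B" &
                      sc$interaction == "L1_R1"], 1 / 101)
  # constant expression: permutations tie everywhere, p = 1
  rawc <- raw; rawc[] <- 2
  scc <- permutation_pvalues(lognorm_of(rawc), types, toy_db(),
                             n_perm = 50, seed = 3)
  expect_true(all(scc$p == 1))
  # zero strength can never be significant
  expect_true(all(sc$p[sc$strength == 0] == 1))
})

test_that("seeded permutation p agrees with exhaustive label enumeration", {
  raw <- rbind(LIG1 = c(9, 4, 1, 0, 2, 0), LIG2A = 0, LIG2B = 0,
               REC1 = c(0, 1, 3, 8, 0, 5), REC2 = 0)
  colnames(raw) <- paste0("c", 1:6)
  types <- c("A", "A", "A", "B", "B", "B")
  norm <- lognorm_of(raw)
  # exhaustive: every permutation of the 6 labels, equally likely
  all_perm <- perm_matrix(6)
  obs <- interaction_scores(norm, types, toy_db())
  row_ab <- which(obs$sender == "A" & obs$receiver == "B" &
                    obs$interaction == "L1_R1")
  exceed <- vapply(seq_len(nrow(all_perm)), function(i) {
    sc <- interaction_scores(norm, types[all_perm[i, ]], toy_db())
    s <- sc$strength[sc$sender == "A" & sc$receiver == "B" &
                       sc$interaction == "L1_R1"]
    s >= obs$strength[row_ab]
  }, logical(1))
  exact_p <- mean(exceed)
  est <- permutation_pvalues(norm, types, toy_db(), n_perm = 1000, seed = 7)
  expect_lt(abs(est$p[row_ab] - exact_p), 0.05)
})

test_that("network summary tallies significant triples only", {
  sc <- data.frame(sender = c("A", "A", "B"), receiver = c("B", "B", "A"),
                   interaction = c("i1", "i2", "i1"),
                   pathway = "PW", strength = c(6, 2, 1),
                   p = c(0.01, 0.2, 0.01))
  net <- network_summary(sc, alpha = 0.05)
  expect_equal(net$count["A", "B"], 1)
  expect_equal(net$strength["A", "B"], 6)
  expect_equal(net$count["B", "A"], 1)
  expect_equal(net$strength["B", "A"], 1)
  expect_equal(net$count["A", "A"], 0)
  none <- network_summary(transform(sc, p = 1), alpha = 0.05)
  expect_true(all(none$count == 0) && all(none$strength == 0))
})

test_that("differential networks are antisymmetric and type-checked", {
  mk <- function(x) structure(list(
    count = matrix(x, 2, 2, dimnames = list(c("A", "B"), c("A", "B"))),
    strength = matrix(x * 2, 2, 2,
                      dimnames = list(c("A", "B"), c("A", "B"))),
    alpha = 0.05), class = "condition_network")
  d1 <- differential_network(mk(1), mk(3))
  expect_true(all(d1$count == 2) && all(d1$strength == 4))
  d2 <- differential_network(mk(3), mk(1))
  expect_equal(d1$count, -d2$count)
  expect_equal(differential_network(mk(2), mk(2))$count,
               matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B"))))
  bad <- mk(1); dimnames(bad$count) <- list(c("A", "C"), c("A", "C"))
  expect_error(differential_network(mk(1), bad), "differ")
})

test_that("pathway flow sums significant strengths and flags exclusivity", {
  mk_scores <- function(p2) data.frame(
    sender = "A", receiver = "B", interaction = c("L1_R1", "L2_R2"),
    pathway = c("PW1", "PW2"), strength = c(4, 7), p = c(0.2, p2))
  pf <- pathway_flow(mk_scores(0.5), mk_scores(0.01), toy_db())
  expect_equal(pf$flow_early[pf$pathway == "PW2"], 0)
  expect_equal(pf$flow_late[pf$pathway == "PW2"], 7)
  expect_equal(pf$exclusive[pf$pathway == "PW2"], "late")
  expect_equal(pf$exclusive[pf$pathway == "PW1"], "none")
  expect_equal(pf$flow_early[pf$pathway == "PW1"], 0)
})

test_that("a planted late-only signal yields a positive differential entry", {
  cfg <- lr_world_config(163)
  ds <- simulate_cells(cfg)
  meta <- ds$cell_metadata
  norm <- log_normalize(ds$counts)
  db <- lr_db_from_config(cfg)
  cond <- stage_to_condition(meta$stage)
  se <- permutation_pvalues(norm[, cond == "early"],
                            meta$cell_type[cond == "early"], db, 100, 1)
  sl <- permutation_pvalues(norm[, cond == "late"],
                            meta$cell_type[cond == "late"], db, 100, 1)
  dn <- differential_network(network_summary(se), network_summary(sl))
  expect_gt(dn$strength["epithelial", "stromal"], 0)
  pf <- pathway_flow(se, sl, db)
  expect_equal(pf$exclusive[pf$pathway == "PATHB"], "late")
})
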