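#' Built-in stochastic TF-target importance backend
#'
#' A deliberately simple learner satisfying the backend contract used by
#' [consensus_network()]: bootstrap-resamples cells (seeded), computes the
#' absolute Pearson correlation between every candidate TF and every
#' non-TF gene on the resample, and emits the `top_k_per_target` TFs per
#' target as edges with importance `|r|`. The consensus aggregation, not
#' this base learner, is what stabilizes the network.
#'
#' @param expr gene x cell expression matrix (log-normalized).
#' @param tf_list candidate TF gene ids (subset of rownames).
#' @param seed bootstrap seed; same seed gives the same edge list.
#' @param top_k_per_target TFs kept per target gene.
#' @return data.frame with columns tf, target, importance (>= 0).
#' @export
builtin_importance_backend <- function(expr, tf_list, seed,
                                       top_k_per_target = 10) {
  if (length(setdiff(tf_list, rownames(expr))))
    stop_oncostage("tf_list must be a subset of the genes")
  targets <- setdiff(rownames(expr), tf_list)
  boot <- with_seed(seed, sample.int(ncol(expr), replace = TRUE))
  if (length(unique(boot)) < 2)
    stop_oncostage("bootstrap resample holds fewer than 2 distinct cells")
  m <- as.matrix(expr[, boot, drop = FALSE])
  r <- abs(suppressWarnings(stats::cor(t(m[tf_list, , drop = FALSE]),
                                       t(m[targets, , drop = FALSE]))))
  r[is.na(r)] <- 0
  k <- min(top_k_per_target, length(tf_list))
  edges <- lapply(seq_along(targets), function(j) {
    top <- order(-r[, j], tf_list)[seq_len(k)]
    data.frame(tf = tf_list[top], target = targets[j],
               importance = r[top, j], row.names = NULL)
  })
  do.call(rbind, edges)
}

#' Consensus TF-target network over repeated stochastic runs
#'
#' Runs the backend `R` times with seeds `seed0 .. seed0 + R - 1`, counts
#' in how many runs each (TF, target) edge appears (its support), and
#' retains edges with support at least `min_support` (inclusive). The
#' importance of a retained edge is the average of its importances across
#' the runs in which it appeared.
#'
#' @param expr gene x cell expression matrix.
#' @param tf_list candidate TF gene ids.
#' @param backend a function `(expr, tf_list, seed, ...)` returning a
#'   tf/target/importance data.frame; defaults to
#'   [builtin_importance_backend()].
#' @param R number of runs.
#' @param min_support minimum run count for retention.
#' @param seed0 seed of the first run.
#' @param ... passed to the backend.
#' @return list of class `consensus_network`: `edges` (tf, target,
#'   support, mean_importance), `R`, `min_support`.
#' @export
consensus_network <- function(expr, tf_list,
                              backend = builtin_importance_backend,
                              R = 100, min_support = 80, seed0 = 1, ...) {
  if (R < 1 || min_support > R)
    stop_oncostage("need R >= 1 and min_support <= R")
  acc <- new.env(parent = emptyenv())
  support <- c(); imp_sum <- c()
  for (i in seq_len(R)) {
    e <- tryCatch(backend(expr, tf_list, seed = seed0 + i - 1, ...),
                  error = function(err)
                    stop_oncostage("backend failed in run ", i, ": ",
                                   conditionMessage(err)))
    key <- paste(e$tf, e$target, sep = "\r")
    hit <- match(key, names(support))
    new <- is.na(hit)
    if (any(new)) {
      support <- c(support, stats::setNames(rep(0, sum(new)), key[new]))
      imp_sum <- c(imp_sum, stats::setNames(rep(0, sum(new)), key[new]))
      hit <- match(key, names(support))
    }
    support[hit] <- support[hit] + 1
    imp_sum[hit] <- imp_sum[hit] + e$importance
  }
  keep <- support >= min_support
  parts <- strsplit(names(support)[keep], "\r", fixed = TRUE)
  edges <- data.frame(
    tf = vapply(parts, `[`, "", 1),
    target = vapply(parts, `[`, "", 2),
    support = as.integer(support[keep]),
    mean_importance = imp_sum[keep] / support[keep], row.names = NULL)
  edges <- edges[order(edges$tf, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, R = R, min_support = min_support),
            class = "consensus_network")
}

#' Group consensus edges into regulons
#'
#' One regulon per TF with at least one retained target. When an
#' allowlist is supplied (a named list TF -> permitted targets, standing
#' in for motif-based pruning), targets are intersected with it; TFs left
#' without targets are dropped.
#'
#' @param network a [consensus_network()] result.
#' @param allowlist optional named list of permitted target sets per TF.
#' @return named list (TF -> character vector of targets).
#' @export
build_regulons <- function(network, allowlist = NULL) {
  stopifnot(inherits(network, "consensus_network"))
  if (nrow(network$edges) == 0) stop_oncostage("consensus network is empty")
  regs <- split(network$edges$target, network$edges$tf)
  if (!is.null(allowlist))
    regs <- mapply(function(tf, tg)
      intersect(tg, allowlist[[tf]] %||% character()),
      names(regs), regs, SIMPLIFY = FALSE)
  regs[lengths(regs) > 0]
}

#' Recovery-curve (AUC) regulon activity per cell
#'
#' For each cell, genes are ranked by expression (descending; ties broken
#' by one seeded random gene permutation shared by all cells of the run).
#' The recovery curve counts regulon genes among the top
#' `ceiling(top_fraction x G)` ranks; the area under it is normalized so
#' that a regulon occupying the topmost ranks scores exactly 1 and a
#' regulon absent from the top fraction scores 0.
#'
#' @param expr gene x cell expression matrix.
#' @param regulons named list (TF -> targets) as from [build_regulons()];
#'   target genes must exist in `expr`.
#' @param top_fraction fraction of the ranking examined.
#' @param seed tie-break permutation seed.
#' @return regulon x cell matrix of AUC values in [0, 1].
#' @export
regulon_activity_auc <- function(expr, regulons, top_fraction = 0.05,
                                 seed = 0) {
  G <- nrow(expr)
  if (top_fraction * G < 1)
    stop_oncostage("top_fraction x n_genes is below 1 rank")
  bad <- setdiff(unique(unlist(regulons)), rownames(expr))
  if (length(bad)) stop_oncostage("regulon gene absent from expr: ", bad[1])
  K <- ceiling(top_fraction * G)
  tie <- with_seed(derive_seed(seed, "aucell_ties"), sample.int(G))
  m <- as.matrix(expr)
  auc <- matrix(0, length(regulons), ncol(m),
                dimnames = list(names(regulons), colnames(m)))
  reg_idx <- lapply(regulons, function(g) match(g, rownames(m)))
  max_auc <- vapply(reg_idx, function(gi) {
    s <- min(length(gi), K)
    s * (s + 1) / 2 + (K - s) * s
  }, numeric(1))
  for (cc in seq_len(ncol(m))) {
    ord <- order(-m[, cc], tie)
    rk <- integer(G)
    rk[ord] <- seq_len(G)
    for (rr in seq_along(reg_idx)) {
      # sum over recovered genes of (K - rank + 1) equals the area under
      # the step recovery curve evaluated at ranks 1..K
      r <- rk[reg_idx[[rr]]]
      auc[rr, cc] <- sum(pmax(0, K - r + 1)) / max_auc[rr]
    }
  }
  auc
}

#' Jensen-Shannon regulon specificity per stage
#'
#' Normalizes each regulon's activity over cells to a probability vector
#' P and compares it with the uniform indicator distribution over each
#' stage's cells: `rss = 1 - sqrt(JSD(P, I_s))` with base-2 JSD, so values
#' lie in [0, 1] and equal 1 when activity is uniform on exactly the
#' stage's cells.
#'
#' @param activity regulon x cell matrix from [regulon_activity_auc()].
#' @param stage_labels stage per cell (same order as columns).
#' @return regulon x stage matrix of specificity scores.
#' @export
regulon_specificity <- function(activity, stage_labels) {
  if (length(stage_labels) != ncol(activity))
    stop_oncostage("one stage label per cell required")
  stages <- unique(stage_labels)
  rss <- matrix(0, nrow(activity), length(stages),
                dimnames = list(rownames(activity), stages))
  for (rr in seq_len(nrow(activity))) {
    tot <- sum(activity[rr, ])
    if (tot == 0) {
      warning("regulon ", rownames(activity)[rr],
              " has all-zero activity; specificity set to 0")
      next
    }
    P <- activity[rr, ] / tot
    for (s in stages) {
      I <- as.numeric(stage_labels == s)
      I <- I / sum(I)
      rss[rr, s] <- 1 - sqrt(js_divergence(P, I))
    }
  }
  rss
}

# base-2 Jensen-Shannon divergence between probability vectors
js_divergence <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}
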