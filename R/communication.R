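# Mass-action ligand-receptor communication scoring with label-permutation
# significance. Strength for (sender, receiver, interaction) is the product
# of the sender's mean ligand expression and the receiver's mean receptor
# expression; multi-subunit complexes are aggregated by geometric mean
# (zero-dominant AND-logic).

# per-type arithmetic mean of expm1(norm) for the given genes:
# returns types x genes matrix
type_gene_means <- function(X, labels, types) {
  out <- matrix(0, length(types), nrow(X),
                dimnames = list(types, rownames(X)))
  for (ty in types) {
    idx <- labels == ty
    out[ty, ] <- if (sum(idx) == 1) X[, idx] else rowMeans(X[, idx,
                                                             drop = FALSE])
  }
  out
}

geom_mean <- function(x) {
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}

#' Per-cell-type subunit-aggregated mean expression
#'
#' Geometric mean, over the subunit genes of a complex, of each cell
#' type's arithmetic mean expression (on the expm1 scale of the
#' log-normalized input). Any silent subunit zeroes the complex.
#'
#' @param norm gene x cell log-normalized matrix.
#' @param cell_types type label per cell.
#' @param gene_set subunit gene ids (subset of rownames).
#' @param types types to report (default: all observed); unknown types
#'   raise an error.
#' @return named numeric vector per type.
#' @export
group_mean_expression <- function(norm, cell_types, gene_set,
                                  types = unique(cell_types)) {
  if (length(setdiff(gene_set, rownames(norm))))
    stop_oncostage("gene_set contains genes absent from the matrix")
  if (length(setdiff(types, cell_types)))
    stop_oncostage("unknown cell type requested")
  X <- expm1(as.matrix(norm[gene_set, , drop = FALSE]))
  tm <- type_gene_means(X, cell_types, types)
  apply(tm, 1, geom_mean)
}

# strengths for every ordered (sender, receiver) pair and interaction,
# given precomputed types x genes means
strengths_from_means <- function(tm, db, types) {
  n_int <- nrow(db)
  out <- vector("list", n_int)
  for (i in seq_len(n_int)) {
    L <- apply(tm[, db$ligand[[i]], drop = FALSE], 1, geom_mean)
    R <- apply(tm[, db$receptor[[i]], drop = FALSE], 1, geom_mean)
    out[[i]] <- data.frame(
      sender = rep(types, times = length(types)),
      receiver = rep(types, each = length(types)),
      interaction = db$name[i], pathway = db$pathway[i],
      strength = as.vector(outer(L, R)), row.names = NULL)
  }
  do.call(rbind, out)
}

db_genes <- function(db) unique(unlist(c(db$ligand, db$receptor)))

#' Mass-action interaction strengths between cell types
#'
#' `strength = L_mean(sender) x R_mean(receiver)` for every ordered type
#' pair (self-pairs included) and database interaction.
#'
#' @param norm gene x cell log-normalized matrix.
#' @param labels cell-type label per cell.
#' @param db an [lr_database()].
#' @return data.frame: sender, receiver, interaction, pathway, strength.
#' @export
interaction_scores <- function(norm, labels, db) {
  types <- unique(labels)
  if (length(types) < 2) stop_oncostage("need at least 2 cell types")
  gs <- db_genes(db)
  if (length(setdiff(gs, rownames(norm))))
    stop_oncostage("database gene(s) absent from the matrix")
  X <- expm1(as.matrix(norm[gs, , drop = FALSE]))
  tm <- type_gene_means(X, labels, types)
  strengths_from_means(tm, db, types)
}

#' Label-permutation p-values for interaction strengths
#'
#' Cell-type labels are permuted globally `n_perm` times (seeded); for
#' each (sender, receiver, interaction) triple
#' `p = (1 + #\{permuted strength >= observed\}) / (1 + n_perm)`, the
#' positively biased estimator that never returns 0. A strength of 0 can
#' never be significant (every permuted strength is >= 0).
#'
#' @param norm gene x cell log-normalized matrix.
#' @param labels cell-type label per cell.
#' @param db an [lr_database()].
#' @param n_perm number of label permutations.
#' @param seed permutation seed.
#' @return [interaction_scores()] data.frame with a `p` column appended.
#' @export
permutation_pvalues <- function(norm, labels, db, n_perm = 100, seed = 1) {
  if (n_perm < 1) stop_oncostage("n_perm must be >= 1")
  obs <- interaction_scores(norm, labels, db)
  types <- unique(labels)
  gs <- db_genes(db)
  X <- expm1(as.matrix(norm[gs, , drop = FALSE]))
  exceed <- numeric(nrow(obs))
  perm_seed <- derive_seed(seed, "lr_perm")
  for (b in seq_len(n_perm)) {
    pl <- with_seed(perm_seed + b, sample(labels))
    tm <- type_gene_means(X, pl, types)
    ps <- strengths_from_means(tm, db, types)
    exceed <- exceed + (ps$strength >= obs$strength)
  }
  obs$p <- (1 + exceed) / (1 + n_perm)
  obs
}

#' Aggregate significant interactions into a condition network
#'
#' @param scores data.frame from [permutation_pvalues()].
#' @param alpha significance cutoff (strict).
#' @return list of class `condition_network`: `count` and `strength`
#'   (sender x receiver matrices over significant interactions), `alpha`.
#' @export
network_summary <- function(scores, alpha = 0.05) {
  if (is.null(scores$p)) stop_oncostage("scores carry no p-values")
  types <- unique(c(scores$sender, scores$receiver))
  sig <- scores$p < alpha & scores$strength > 0
  cnt <- matrix(0, length(types), length(types),
                dimnames = list(sender = types, receiver = types))
  str <- cnt
  ss <- scores[sig, , drop = FALSE]
  for (i in seq_len(nrow(ss))) {
    cnt[ss$sender[i], ss$receiver[i]] <- cnt[ss$sender[i], ss$receiver[i]] + 1
    str[ss$sender[i], ss$receiver[i]] <-
      str[ss$sender[i], ss$receiver[i]] + ss$strength[i]
  }
  structure(list(count = cnt, strength = str, alpha = alpha),
            class = "condition_network")
}

#' Differential communication network (late minus early)
#'
#' Element-wise difference of the count and strength matrices; the two
#' networks must cover the same cell types (exclude condition-specific
#' types before calling).
#'
#' @param early,late `condition_network` objects.
#' @return list with signed `count` and `strength` matrices.
#' @export
differential_network <- function(early, late) {
  te <- rownames(early$count); tl <- rownames(late$count)
  if (!setequal(te, tl))
    stop_oncostage("cell-type sets differ between conditions")
  tl <- te
  list(count = late$count[te, te] - early$count[te, te],
       strength = late$strength[te, te] - early$strength[te, te])
}

#' Pathway information flow per condition
#'
#' Flow of a pathway in a condition is the sum of its significant
#' interaction strengths over all type pairs. A pathway is exclusive to a
#' condition when its flow is positive there and exactly zero in the
#' other.
#'
#' @param scores_early,scores_late data.frames from
#'   [permutation_pvalues()].
#' @param db an [lr_database()].
#' @param alpha significance cutoff (strict).
#' @return data.frame: pathway, flow_early, flow_late, exclusive in
#'   `{"none","early","late"}`.
#' @export
pathway_flow <- function(scores_early, scores_late, db, alpha = 0.05) {
  pws <- unique(db$pathway)
  flow <- function(sc, pw) {
    rows <- sc$pathway == pw & sc$p < alpha & sc$strength > 0
    sum(sc$strength[rows])
  }
  out <- do.call(rbind, lapply(pws, function(pw) {
    if (!any(db$pathway == pw))
      stop_oncostage("pathway without interactions: ", pw)
    fe <- flow(scores_early, pw)
    fl <- flow(scores_late, pw)
    data.frame(pathway = pw, flow_early = fe, flow_late = fl,
               exclusive = if (fl > 0 && fe == 0) "late"
                           else if (fe > 0 && fl == 0) "early" else "none")
  }))
  rownames(out) <- NULL
  out
}
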