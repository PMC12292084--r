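#' Marker-based hierarchical subgrouping of bulk samples
#'
#' Agglomerative clustering (Lance-Williams Ward.D update on unsquared
#' Euclidean distances, the classic R `hclust(method = "ward.D")`) of
#' samples on the marker-gene submatrix, and of genes on its transpose;
#' both trees are cut at fixed k. Subgroup labels are ordered by
#' decreasing mean marker expression so that labels are deterministic.
#'
#' @param expr samples x genes matrix, log2(x+1) scale.
#' @param marker_genes genes to cluster on; markers absent from `expr`
#'   are dropped with a warning.
#' @param k_samples number of sample subgroups.
#' @param k_genes number of gene clusters.
#' @return list of class `subgroup_assignment`: `sample_subgroup` (named
#'   "S1".."Sk"), `gene_cluster` (named "G1".."Gk"), `markers_used`,
#'   `hclust_samples`, `hclust_genes`.
#' @export
hierarchical_subgroups <- function(expr, marker_genes, k_samples = 3,
                                   k_genes = 4) {
  miss <- setdiff(marker_genes, colnames(expr))
  if (length(miss)) {
    warning(length(miss), " marker gene(s) absent from expression; dropped")
    marker_genes <- setdiff(marker_genes, miss)
  }
  if (!length(marker_genes))
    stop_oncostage("no marker gene present in the expression matrix")
  if (k_samples > nrow(expr) || k_genes > length(marker_genes))
    stop_oncostage("k exceeds the number of items to cluster")
  sub <- expr[, marker_genes, drop = FALSE]

  hs <- stats::hclust(stats::dist(sub), method = "ward.D")
  cs <- stats::cutree(hs, k = k_samples)
  hg <- stats::hclust(stats::dist(t(sub)), method = "ward.D")
  cg <- stats::cutree(hg, k = k_genes)

  # relabel subgroups by decreasing mean marker expression
  mexpr <- tapply(rowMeans(sub), cs, mean)
  rk <- rank(-mexpr, ties.method = "first")
  sample_subgroup <- stats::setNames(paste0("S", rk[as.character(cs)]),
                                     rownames(sub))
  gexpr <- tapply(colMeans(sub), cg, mean)
  gk <- rank(-gexpr, ties.method = "first")
  gene_cluster <- stats::setNames(paste0("G", gk[as.character(cg)]),
                                  marker_genes)
  structure(list(sample_subgroup = sample_subgroup,
                 gene_cluster = gene_cluster,
                 markers_used = marker_genes,
                 hclust_samples = hs, hclust_genes = hg),
            class = "subgroup_assignment")
}

#' Kaplan-Meier product-limit estimator
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times;
#' times with only censoring shrink the risk set without a step. The
#' curve is non-increasing, right-continuous, with `S(0) = 1`.
#'
#' @param time positive follow-up times.
#' @param event 1 = event, 0 = censored.
#' @return data.frame with columns time (distinct event times), n_risk,
#'   n_event, surv.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), all(time > 0), all(is.finite(time)))
  o <- order(time)
  time <- time[o]; event <- event[o]
  et <- unique(time[event == 1])
  n_risk <- vapply(et, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(time == t & event == 1), numeric(1))
  data.frame(time = et, n_risk = n_risk, n_event = n_event,
             surv = cumprod(1 - n_event / n_risk))
}

#' Kaplan-Meier curves per subgroup
#'
#' @param records data.frame with columns time, event, subgroup.
#' @return named list of [km_estimate()] data.frames.
#' @export
km_by_group <- function(records) {
  lapply(split(records, records$subgroup),
         function(d) km_estimate(d$time, d$event))
}

#' k-sample log-rank test
#'
#' At each distinct event time the observed events per group are compared
#' with their expectation under the at-risk proportions; the chi-square
#' statistic uses the hypergeometric variance-covariance form on the
#' first k-1 groups, with k-1 degrees of freedom.
#'
#' @param time positive follow-up times.
#' @param event 1 = event, 0 = censored.
#' @param group group label per observation (>= 2 groups).
#' @return list of class `logrank_result`: `chi2`, `df`, `p`, `observed`,
#'   `expected` (named per group).
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  group <- as.character(group)
  gs <- unique(group)
  k <- length(gs)
  if (k < 2) stop_oncostage("need at least 2 groups")
  if (sum(event) == 0) stop_oncostage("no events observed")
  et <- sort(unique(time[event == 1]))
  OE <- stats::setNames(numeric(k), gs)
  E <- stats::setNames(numeric(k), gs)
  O <- stats::setNames(numeric(k), gs)
  V <- matrix(0, k, k, dimnames = list(gs, gs))
  for (t in et) {
    at <- time >= t
    n <- sum(at)
    ng <- vapply(gs, function(g) sum(at & group == g), numeric(1))
    d <- sum(time == t & event == 1)
    dg <- vapply(gs, function(g) sum(time == t & event == 1 & group == g),
                 numeric(1))
    e <- d * ng / n
    O <- O + dg
    E <- E + e
    OE <- OE + (dg - e)
    if (n > 1) {
      c1 <- d * (n - d) / (n - 1)
      V <- V + c1 * (diag(ng / n, k) - tcrossprod(ng / n))
    }
  }
  idx <- seq_len(k - 1)
  Vi <- V[idx, idx, drop = FALSE]
  chi2 <- tryCatch(
    drop(t(OE[idx]) %*% solve(Vi, OE[idx])),
    error = function(e) drop(t(OE[idx]) %*% MASS_ginv(Vi) %*% OE[idx]))
  chi2 <- max(0, chi2)
  structure(list(chi2 = chi2, df = k - 1,
                 p = stats::pchisq(chi2, df = k - 1, lower.tail = FALSE),
                 observed = O, expected = E),
            class = "logrank_result")
}

# Moore-Penrose pseudoinverse via SVD (fallback for singular covariance)
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}
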