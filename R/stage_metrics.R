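#' Cluster x stage contingency table
#'
#' Tabulates cluster/stage co-occurrence. Category order is order of first
#' appearance in the inputs.
#'
#' @param cluster_labels,stage_labels equal-length vectors without missing
#'   values.
#' @return object of class `stage_contingency`: the counts table plus
#'   marginals `c_i` (clusters), `t_j` (stages), totals `N` and `C`.
#' @export
stage_contingency <- function(cluster_labels, stage_labels) {
  if (length(cluster_labels) != length(stage_labels))
    stop_oncostage("label vectors differ in length")
  if (length(cluster_labels) == 0) stop_oncostage("empty label vectors")
  if (anyNA(cluster_labels) || anyNA(stage_labels))
    stop_oncostage("missing labels are not allowed")
  cl <- factor(cluster_labels, levels = unique(cluster_labels))
  st <- factor(stage_labels, levels = unique(stage_labels))
  tab <- table(cluster = cl, stage = st)
  structure(list(counts = unclass(tab), N = sum(tab),
                 c_i = rowSums(tab), t_j = colSums(tab),
                 C = ncol(tab)),
            class = "stage_contingency")
}

#' Clustering purity against stage labels
#'
#' Overall purity is the fraction of cells falling in their cluster's
#' dominant stage, `sum_i max_j n_ij / N`; it ranges from 0 (no
#' homogeneity) to 1 (every cluster single-stage). Per-cluster purity is
#' `max_j n_ij / c_i`.
#'
#' @param table a [stage_contingency()] object.
#' @return list with `overall_purity` and named `per_cluster_purity`.
#' @export
purity <- function(table) {
  stopifnot(inherits(table, "stage_contingency"))
  if (table$N <= 0) stop_oncostage("empty contingency table")
  mx <- apply(table$counts, 1, max)
  list(overall_purity = sum(mx) / table$N,
       per_cluster_purity = mx / table$c_i)
}

#' Per-cluster stage entropy
#'
#' Shannon entropy (bits) of each cluster's stage proportions,
#' `-sum_j p_j log2 p_j` with `0 log 0 := 0`. Because raw entropy is
#' bounded by `log2(C)` rather than 1 when more than two stages exist,
#' a normalized version (raw divided by `log2(C)`; 0 when `C = 1`) is
#' also reported so the range is `[0, 1]` for any number of stages.
#'
#' @param table a [stage_contingency()] object.
#' @return list with named `raw_entropy` (bits) and `normalized_entropy`.
#' @export
cluster_entropy <- function(table) {
  stopifnot(inherits(table, "stage_contingency"))
  if (table$N <= 0) stop_oncostage("empty contingency table")
  raw <- apply(table$counts, 1, function(r) {
    p <- r[r > 0] / sum(r)
    -sum(p * log2(p))
  })
  norm <- if (table$C > 1) raw / log2(table$C) else raw * 0
  list(raw_entropy = raw, normalized_entropy = norm)
}

#' Combined stage-homogeneity report
#'
#' @param table a [stage_contingency()] object.
#' @return list merging [purity()] and [cluster_entropy()] output.
#' @export
stage_homogeneity <- function(table) {
  c(purity(table), cluster_entropy(table))
}
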