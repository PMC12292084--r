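#' Differential-expression thresholds
#'
#' @param min_pct minimum expression fraction (in at least one of the two
#'   groups) for a gene to be tested.
#' @param alpha adjusted p-value cutoff (strict) for marker retention.
#' @param min_log2fc log2 fold-change cutoff (strict) for marker retention.
#' @return list of class `deg_thresholds`.
#' @export
deg_thresholds <- function(min_pct = 0.25, alpha = 0.01, min_log2fc = 1) {
  stopifnot(min_pct >= 0, min_pct <= 1, alpha > 0, alpha <= 1,
            min_log2fc >= 0)
  structure(list(min_pct = min_pct, alpha = alpha,
                 min_log2fc = min_log2fc), class = "deg_thresholds")
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact p by enumeration of all group assignments when both groups have
#' at most `exact_limit` observations (ties handled by enumerating the
#' observed pooled values); otherwise the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param x,y numeric samples.
#' @param exact_limit enumeration cutoff per group.
#' @return p-value in (0, 1].
#' @export
wilcoxon_p <- function(x, y, exact_limit = 8) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (n1 <= exact_limit && n2 <= exact_limit) {
    combs <- utils::combn(n, n1)
    ws <- colSums(matrix(r[combs], nrow = n1))
    p <- 2 * min(mean(ws <= w), mean(ws >= w))
    return(min(1, p))
  }
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(1)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' For each gene expressed (normalized value > 0) in at least `min_pct`
#' of either group, computes the two-sided rank-sum p-value
#' ([wilcoxon_p()]), the log2 fold change
#' `log2((mean(expm1 late) + 1) / (mean(expm1 early) + 1))` on the
#' natural-log-normalized input, and the expression fractions. BH
#' adjustment is applied over the tested genes only.
#'
#' @param norm gene x cell log-normalized matrix.
#' @param cells_late,cells_early disjoint cell-id (or index) vectors, each
#'   of size >= 3.
#' @param thresholds a [deg_thresholds()] object.
#' @return data.frame with columns gene, log2fc, pct_late, pct_early, p,
#'   p_adj (tested genes only, input gene order).
#' @export
wilcoxon_de <- function(norm, cells_late, cells_early,
                        thresholds = deg_thresholds()) {
  if (length(cells_late) == 0 || length(cells_early) == 0)
    stop_oncostage("both groups must be non-empty")
  a <- as.matrix(norm[, cells_late, drop = FALSE])
  b <- as.matrix(norm[, cells_early, drop = FALSE])
  if (length(intersect(colnames(a), colnames(b))))
    stop_oncostage("groups must be disjoint")
  if (ncol(a) < 3 || ncol(b) < 3)
    stop_oncostage("each group needs at least 3 cells")
  pct_late <- rowMeans(a > 0)
  pct_early <- rowMeans(b > 0)
  test <- pmax(pct_late, pct_early) >= thresholds$min_pct
  idx <- which(test)
  if (!length(idx)) return(data.frame(gene = character(), log2fc = numeric(),
    pct_late = numeric(), pct_early = numeric(), p = numeric(),
    p_adj = numeric()))
  lfc <- log2((rowMeans(expm1(a[idx, , drop = FALSE])) + 1) /
              (rowMeans(expm1(b[idx, , drop = FALSE])) + 1))
  p <- vapply(idx, function(i) wilcoxon_p(a[i, ], b[i, ]), numeric(1))
  data.frame(gene = rownames(norm)[idx], log2fc = lfc,
             pct_late = pct_late[idx], pct_early = pct_early[idx],
             p = p, p_adj = bh_adjust(p), row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts p ascending, sets `adj_(i) = min_{k >= i} p_(k) n / k` capped at
#' 1, and returns values in the input order.
#'
#' @param pvals p-values in (0, 1].
#' @return adjusted p-values, same order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals <= 0 | pvals > 1 | is.na(pvals)))
    stop_oncostage("p-values must lie in (0, 1]")
  n <- length(pvals)
  o <- order(pvals)
  adj <- pmin(1, rev(cummin(rev(pvals[o] * n / seq_len(n)))))
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Retain significant stage markers
#'
#' Keeps records with `p_adj < alpha` and `log2fc > min_log2fc`
#' (direction "up"; mirrored for "down"), both strict, sorted by
#' ascending `p_adj`, then descending `|log2fc|`, then gene id.
#'
#' @param records output of [wilcoxon_de()].
#' @param thresholds a [deg_thresholds()] object.
#' @param direction `"up"` (late over early) or `"down"`.
#' @return filtered, sorted data.frame.
#' @export
filter_markers <- function(records, thresholds = deg_thresholds(),
                           direction = c("up", "down")) {
  direction <- match.arg(direction)
  keep <- records$p_adj < thresholds$alpha &
    (if (direction == "up") records$log2fc > thresholds$min_log2fc
     else records$log2fc < -thresholds$min_log2fc)
  out <- records[keep, , drop = FALSE]
  out[order(out$p_adj, -abs(out$log2fc), out$gene), , drop = FALSE]
}
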