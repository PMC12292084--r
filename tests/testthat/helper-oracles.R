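# Independent brute-force oracles shared by the module tests and the
# acceptance suite. Plain loops only; no code shared with R/.

# independent brute-force oracle for the windowed signal + scores, used on
# tiny matrices: plain loops, no shared code with the implementation
oracle_windows <- function(zmat, anno, w) {
  sig <- NULL
  for (ch in unique(anno$chromosome)) {
    gs <- anno$gene[anno$chromosome == ch]
    gs <- gs[gs %in% rownames(zmat)]
    n <- length(gs)
    if (n == 0) next
    if (n < w) {
      sig <- cbind(sig, apply(zmat[gs, , drop = FALSE], 2, mean))
    } else {
      for (i in 1:(n - w + 1))
        sig <- cbind(sig, apply(zmat[gs[i:(i + w - 1)], , drop = FALSE],
                                2, mean))
    }
  }
  sig
}

oracle_scores <- function(sig, top_fraction = 0.05) {
  sig <- sig - apply(sig, 1, mean)          # per-cell centering
  ms <- apply(sig^2, 1, mean)
  ntop <- max(2, ceiling(top_fraction * nrow(sig)))
  ref <- apply(sig[order(ms, decreasing = TRUE)[1:ntop], , drop = FALSE],
               2, mean)
  corr <- numeric(nrow(sig))
  for (i in 1:nrow(sig)) {
    if (stats::sd(sig[i, ]) == 0 || stats::sd(ref) == 0) corr[i] <- 0
    else corr[i] <- stats::cor(sig[i, ], ref)
  }
  list(ms = ms, corr = corr)
}

# independent enumeration oracle for the two-sided rank-sum p-value,
# handling ties: enumerate every assignment of the pooled values
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(x)])
  combs <- utils::combn(length(pooled), length(x))
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# exhaustive greedy Ward oracle: at each step merge the pair of clusters
# whose union minimizes the increase in within-cluster sum of squares
oracle_ward_merges <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), identity)
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_cost <- Inf
    for (i in 1:(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      a <- clusters[[i]]; b <- clusters[[j]]
      ma <- colMeans(X[a, , drop = FALSE]); mb <- colMeans(X[b, , drop = FALSE])
      cost <- length(a) * length(b) / (length(a) + length(b)) *
        sum((ma - mb)^2)
      if (cost < best_cost) { best_cost <- cost; best <- c(i, j) }
    }
    merges[[length(merges) + 1]] <-
      sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  merges
}

# members of each merged cluster, in merge order, from an hclust tree
hclust_merge_sets <- function(hc) {
  sets <- list()
  for (i in seq_len(nrow(hc$merge))) {
    get <- function(v) if (v < 0) -v else sets[[v]]
    sets[[i]] <- sort(c(get(hc$merge[i, 1]), get(hc$merge[i, 2])))
  }
  sets
}

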