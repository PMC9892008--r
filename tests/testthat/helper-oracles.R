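# Independent oracles used across the suite. These deliberately avoid
# the code paths they check.

# Brute-force patristic distances: per-leaf root-path depths, then
# d(x, y) = depth(x) + depth(y) - 2 * depth(mrca(x, y)).
oracle_patristic <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent <- integer(max(tree$edge))
  plen <- numeric(max(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  plen[tree$edge[, 2L]] <- tree$edge.length
  path_to_root <- function(node) {
    nodes <- node
    while (node != root) {
      node <- parent[node]
      nodes <- c(nodes, node)
    }
    nodes
  }
  depth <- function(node) {
    d <- 0
    while (node != root) {
      d <- d + plen[node]
      node <- parent[node]
    }
    d
  }
  depths <- vapply(seq_len(max(tree$edge)), depth, numeric(1))
  paths <- lapply(seq_len(n), path_to_root)
  out <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      common <- intersect(paths[[i]], paths[[j]])
      mrca <- common[which.max(depths[common])]
      out[i, j] <- out[j, i] <- depths[i] + depths[j] - 2 * depths[mrca]
    }
  }
  out
}

# Textbook 2x2 chi-squared: n(|ad - bc| - correction)^2 over the
# product of the margins, correction = n/2 (Yates, clamped at zero) or
# 0.
oracle_chi2 <- function(a, b, c_, d_, continuity = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c_ <- as.numeric(c_); d_ <- as.numeric(d_)
  n <- a + b + c_ + d_
  num <- abs(a * d_ - b * c_)
  if (continuity) num <- max(0, num - n / 2)
  stat <- n * num^2 / ((a + b) * (c_ + d_) * (a + c_) * (b + d_))
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1,
                                                 lower.tail = FALSE))
}

# Exhaustive constrained-Youden search over the same candidate grid,
# written as a direct double loop over candidates.
oracle_youden <- function(same, unrelated, fp_bound = 0.05) {
  pooled <- sort(unique(c(same, unrelated)))
  cand <- if (length(pooled) > 1L) {
    c(max(pooled[1L] - (pooled[2L] - pooled[1L]) / 2, 0),
      (pooled[-length(pooled)] + pooled[-1L]) / 2)
  } else {
    max(pooled - max(pooled / 2, .Machine$double.eps), 0)
  }
  best_j <- -Inf; best_t <- NA_real_
  for (t in cand) {
    fp <- sum(unrelated <= t) / length(unrelated)
    if (fp > fp_bound) next
    j <- sum(same <= t) / length(same) + (1 - fp) - 1
    if (j > best_j || (j == best_j && t < best_t)) {
      best_j <- j; best_t <- t
    }
  }
  list(threshold = best_t, j = best_j)
}

write_newick <- function(txt) {
  f <- tempfile(fileext = ".nwk")
  writeLines(txt, f)
  f
}
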