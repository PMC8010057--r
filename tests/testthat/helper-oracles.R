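# Independent brute-force oracles used to check the package's optimized
# implementations on small inputs.

# all-pairs O(n*m) interval overlap scan
brute_overlap <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] &&
        max(a$start[i], b$start[j]) < min(a$end[i], b$end[j]))
      out[[length(out) + 1]] <- c(i, j)
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer()))
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2])
}

# signal value of a piecewise-constant track at single base positions
base_signal <- function(track, chrom, pos) {
  vapply(pos, function(p) {
    hit <- track$chrom == chrom & track$start <= p & p < track$end
    if (any(hit)) track$value[which(hit)[1]] else 0
  }, numeric(1))
}

# per-base averaging oracle for profile aggregation (unstranded anchors)
profile_oracle <- function(track, anchors, flank, nbins) {
  w <- 2 * flank / nbins
  res <- vapply(seq_len(nrow(anchors)), function(r) {
    center <- floor((anchors$start[r] + anchors$end[r]) / 2)
    vapply(seq_len(nbins), function(b) {
      lo <- center - flank + (b - 1) * w
      mean(base_signal(track, anchors$chrom[r], seq(lo, lo + w - 1)))
    }, numeric(1))
  }, numeric(nbins))
  if (nbins == 1) matrix(res, ncol = 1) else t(res)
}

# exact one-sided rank-sum p-value by enumeration of group allocations
enum_ranksum_less <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  stat <- function(idx) {
    xx <- pooled[idx]; yy <- pooled[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  obs <- stat(seq_len(nx))
  alloc <- utils::combn(length(pooled), nx)
  mean(apply(alloc, 2, stat) <= obs + 1e-9)
}

# exact two-sided rank-sum p by enumeration (tie-free inputs)
enum_ranksum_twosided <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  rs <- function(idx) sum(rank(pooled)[idx])
  obs <- rs(seq_len(nx))
  alloc <- utils::combn(length(pooled), nx)
  all_rs <- apply(alloc, 2, rs)
  mu <- mean(all_rs)
  mean(abs(all_rs - mu) >= abs(obs - mu) - 1e-9)
}

# maximal cliques (>= min_size) by exhaustive subset enumeration;
# adj: symmetric logical matrix over candidate nodes
brute_cliques <- function(adj, min_size = 2) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  subsets <- list()
  for (sz in min_size:n) {
    cmb <- utils::combn(n, sz)
    for (k in seq_len(ncol(cmb))) {
      s <- cmb[, k]
      if (all(adj[s, s] | diag(TRUE, length(s)))) subsets[[length(subsets) + 1]] <- s
    }
  }
  # keep maximal only
  is_clq <- function(s) all(adj[s, s] | diag(TRUE, length(s)))
  maximal <- Filter(function(s) {
    !any(vapply(setdiff(seq_len(n), s), function(v) is_clq(c(s, v)),
                logical(1)))
  }, subsets)
  out <- unique(lapply(maximal, function(s) sort(nodes[s])))
  out[order(vapply(out, paste, "", collapse = "\r"))]
}

# hand Pearson chi-squared on a 2x2 table, no continuity correction
chisq_hand <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# quantile normalization oracle with rank-range tie handling
quantile_oracle <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(col) {
    r <- rank(col, ties.method = "average")
    # mean of reference values over each value's (possibly fractional) rank range
    vapply(seq_along(col), function(i) {
      ties <- which(col == col[i])
      mean(ref[rank(col, ties.method = "first")[ties]])
    }, numeric(1))
  })
}

random_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 2000,
                         width_max = 120) {
  start <- sample.int(max_pos, n, replace = TRUE)
  peak_table(sample(chroms, n, replace = TRUE), start,
             start + sample.int(width_max, n, replace = TRUE))
}
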