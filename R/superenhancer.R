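# Super-enhancer calling: peak stitching with TSS-exclusion, the
# hockey-stick tangent cutoff on the rank-ordered signal curve, nearest-TSS
# gene assignment, and the cross-lineage rank test that nominates master
# transcription factors.

#' Stitch enhancer peaks into regions
#'
#' Chains peaks whose gaps are at most `stitch_dist` into single regions.
#' Peaks lying within `tss_exclude` of a transcription start site may join
#' a region but never bridge two otherwise-separate regions: stitching is
#' computed on TSS-distal peaks, and each TSS-proximal peak is then
#' attached to the nearest distal chain within `stitch_dist` (or kept as
#' its own region).
#'
#' @param peaks interval table with a `score` column (peak signal).
#' @param stitch_dist maximum gap joined, bp (default 12500).
#' @param tss optional data.frame with `chrom` and `tss` columns.
#' @param tss_exclude distance defining TSS-proximal peaks, bp (default 2500).
#' @return data.frame of stitched regions: chrom, start, end, name,
#'   signal (sum of constituent peak scores), n_constituents, and a list
#'   column `constituents` of row indices into `peaks`.
#' @export
stitch_peaks <- function(peaks, stitch_dist = 12500, tss = NULL,
                         tss_exclude = 2500) {
  if (stitch_dist < 0) stop("stitch_dist must be >= 0")
  validate_intervals(peaks)
  peaks <- sort_intervals(cbind(peaks, .idx = seq_len(nrow(peaks)))[
    order(peaks$chrom, peaks$start, peaks$end), ])
  is_prox <- rep(FALSE, nrow(peaks))
  if (!is.null(tss) && nrow(tss)) {
    for (r in seq_len(nrow(peaks))) {
      tt <- tss$tss[tss$chrom == peaks$chrom[r]]
      if (length(tt))
        is_prox[r] <- min(pmax(tt - peaks$end[r] + 1, peaks$start[r] - tt, 0)) <=
          tss_exclude
    }
  }
  comp <- integer(nrow(peaks))   # component id per peak
  ncomp <- 0
  for (ch in unique(peaks$chrom)) {
    rows <- which(peaks$chrom == ch)
    distal <- rows[!is_prox[rows]]
    # chain distal peaks by gap
    if (length(distal)) {
      gaps <- peaks$start[distal[-1]] - peaks$end[distal[-length(distal)]]
      brk <- c(TRUE, gaps > stitch_dist)
      comp[distal] <- ncomp + cumsum(brk)
      ncomp <- max(comp[distal])
    }
    # attach proximal peaks to nearest distal chain within stitch_dist
    for (r in rows[is_prox[rows]]) {
      if (length(distal)) {
        d <- pmax(peaks$start[distal] - peaks$end[r],
                  peaks$start[r] - peaks$end[distal], 0)
        k <- which.min(d)
        if (d[k] <= stitch_dist) { comp[r] <- comp[distal[k]]; next }
      }
      ncomp <- ncomp + 1
      comp[r] <- ncomp
    }
  }
  groups <- split(seq_len(nrow(peaks)), comp)
  out <- do.call(rbind, lapply(groups, function(rs) {
    data.frame(chrom = peaks$chrom[rs[1]],
               start = min(peaks$start[rs]),
               end = max(peaks$end[rs]),
               signal = sum(peaks$score[rs], na.rm = TRUE),
               n_constituents = length(rs),
               stringsAsFactors = FALSE)
  }))
  out$constituents <- lapply(groups, function(rs) sort(peaks$.idx[rs]))
  ord <- order(out$chrom, out$start, out$end)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$name <- sprintf("stitched_%d", seq_len(nrow(out)))
  out[, c("chrom", "start", "end", "name", "signal", "n_constituents",
          "constituents")]
}

#' Flag super-enhancers by the hockey-stick tangent cutoff
#'
#' Sorts region signals ascending, scales rank and signal to the unit
#' square, and places the cutoff at the point where the slope of the
#' scaled curve equals 1 -- the point of maximal vertical distance below
#' the diagonal.  Regions with signal strictly above the cutoff are super-
#' enhancers.  When a control signal is supplied it is subtracted first
#' (floored at zero).  An all-equal signal curve is degenerate and yields
#' zero super-enhancers, with a warning.
#'
#' @param regions data.frame from [stitch_peaks()].
#' @param control_signal optional numeric vector of control (input) signal
#'   per region, subtracted from `signal`.
#' @return `regions` with columns `signal` (adjusted), `rank`
#'   (1 = highest signal) and logical `is_super`, plus attribute `cutoff`.
#' @export
call_superenhancers <- function(regions, control_signal = NULL) {
  stopifnot(nrow(regions) >= 2)
  sig <- regions$signal
  if (!is.null(control_signal)) sig <- pmax(sig - control_signal, 0)
  regions$signal <- sig
  regions$rank <- rank(-sig, ties.method = "first")
  if (diff(range(sig)) == 0) {
    warning("all region signals equal: degenerate curve, no super-enhancers")
    regions$is_super <- FALSE
    attr(regions, "cutoff") <- Inf
    return(regions)
  }
  s <- sort(sig)
  n <- length(s)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1]) / (s[n] - s[1])
  cutoff <- s[which.max(x - y)]
  regions$is_super <- sig > cutoff
  attr(regions, "cutoff") <- cutoff
  regions
}

#' Assign stitched regions to genes and select TF super-enhancers
#'
#' Each region is assigned to the gene with the nearest TSS within
#' `max_dist` (distance from the region boundary, 0 when the TSS falls
#' inside the region; equidistant ties go to the lexicographically smaller
#' gene id).  Regions farther than `max_dist` from any TSS stay
#' unassigned.
#'
#' @param regions data.frame from [call_superenhancers()].
#' @param genes gene table with `gene_id`, `chrom`, `tss`.
#' @param tf_list character vector of transcription-factor gene ids (must
#'   be non-empty).
#' @param max_dist assignment cap in bp (default 5e5).
#' @return `regions` with columns `gene` (NA when unassigned) and logical
#'   `is_tf_se` (assigned gene is a TF and region is a super-enhancer).
#' @export
assign_se_to_tf <- function(regions, genes, tf_list, max_dist = 5e5) {
  if (!length(tf_list)) stop("tf_list is empty")
  gene <- rep(NA_character_, nrow(regions))
  for (r in seq_len(nrow(regions))) {
    g <- genes[genes$chrom == regions$chrom[r], , drop = FALSE]
    if (!nrow(g)) next
    d <- pmax(g$tss - regions$end[r] + 1, regions$start[r] - g$tss, 0)
    ok <- d <= max_dist
    if (!any(ok)) next
    g <- g[ok, , drop = FALSE]; d <- d[ok]
    best <- which(d == min(d))
    if (length(best) > 1) {
      ids <- sort(g$gene_id[best])
      message("assign_se_to_tf: equidistant tie at ", regions$name[r],
              ", choosing ", ids[1])
      gene[r] <- ids[1]
    } else gene[r] <- g$gene_id[best]
  }
  regions$gene <- gene
  regions$is_tf_se <- !is.na(gene) & gene %in% tf_list &
    (if ("is_super" %in% names(regions)) regions$is_super else TRUE)
  regions
}

#' Build the TF x sample super-enhancer rank table
#'
#' For each sample, region ranks come from [call_superenhancers()] (1 =
#' highest signal); a TF's entry is the best rank among super-enhancers
#' assigned to it.  A TF without a super-enhancer in a sample receives
#' that sample's worst observed rank + 1 so downstream rank tests remain
#' defined.
#'
#' @param region_list named list (per sample) of region data.frames carrying
#'   `rank`, `gene`, `is_tf_se`.
#' @param tf_list TF gene ids defining the table rows.
#' @return integer matrix TFs x samples.
#' @export
tf_se_rank_table <- function(region_list, tf_list) {
  out <- matrix(NA_real_, length(tf_list), length(region_list),
                dimnames = list(tf_list, names(region_list)))
  for (s in names(region_list)) {
    reg <- region_list[[s]]
    worst <- max(reg$rank) + 1
    for (tf in tf_list) {
      rk <- reg$rank[reg$is_tf_se & !is.na(reg$gene) & reg$gene == tf]
      out[tf, s] <- if (length(rk)) min(rk) else worst
    }
  }
  out
}

#' One-sided Mann-Whitney U test (x smaller than y)
#'
#' Computes U = #(x > y pairs) + 0.5 #(ties), which is small when x ranks
#' better (lower) than y, and the one-sided p-value
#' P(U* <= U) by full enumeration of group allocations when
#' `choose(n, nx)` is at most `max_enum` (exact even under ties), falling
#' back to the normal approximation with tie correction otherwise.
#'
#' @param x,y numeric vectors (here: super-enhancer ranks per sample).
#' @param max_enum enumeration budget (default 20000 allocations).
#' @return list with `u` and `p`.
#' @export
mann_whitney_less <- function(x, y, max_enum = 20000) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xx <- pooled[idx]; yy <- pooled[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u <- u_of(seq_len(nx))
  if (choose(nx + ny, nx) <= max_enum) {
    combos <- utils::combn(nx + ny, nx)
    us <- apply(combos, 2, u_of)
    p <- mean(us <= u + 1e-9)
  } else {
    n <- nx + ny
    ties <- table(pooled)
    mu <- nx * ny / 2
    sig2 <- nx * ny / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
    p <- stats::pnorm(u + 0.5, mu, sqrt(sig2))   # continuity-corrected
  }
  list(u = u, p = p)
}

#' Rank test for lineage-enriched TF super-enhancers
#'
#' Restricts to TFs whose median rank falls in the top `top_frac` of all
#' TFs within either lineage, then applies a one-sided Mann-Whitney U test
#' per candidate (alternative: ranks better, i.e. smaller, in the focal
#' lineage), with Benjamini-Hochberg correction across candidates and
#' significance at `padj <= fdr`.
#'
#' @param rank_table TF x sample matrix from [tf_se_rank_table()].
#' @param lineages character vector of per-sample lineage labels (length =
#'   ncol, exactly two distinct values, >= 2 samples each).
#' @param top_frac candidate fraction by median rank (default 0.05).
#' @param fdr significance level on BH-adjusted p (default 0.10).
#' @return data.frame: tf, focal lineage, median ranks per lineage, U
#'   statistic, p, padj, significant.  Empty (with a warning) when no TF
#'   enters the candidate set.
#' @export
se_rank_test <- function(rank_table, lineages, top_frac = 0.05, fdr = 0.10) {
  stopifnot(ncol(rank_table) == length(lineages))
  lins <- unique(lineages)
  stopifnot(length(lins) == 2)
  if (any(table(lineages) < 2)) stop("each lineage needs >= 2 samples")
  med <- vapply(lins, function(l)
    apply(rank_table[, lineages == l, drop = FALSE], 1, stats::median),
    numeric(nrow(rank_table)))
  k <- max(1, ceiling(top_frac * nrow(rank_table)))
  cand <- list()
  for (l in lins) {
    top <- rownames(rank_table)[rank(med[, l], ties.method = "min") <= k]
    for (tf in top) cand[[length(cand) + 1]] <- list(tf = tf, focal = l)
  }
  if (!length(cand)) {
    warning("candidate set empty")
    return(data.frame(tf = character(), focal = character(), u = numeric(),
                      p = numeric(), padj = numeric(),
                      significant = logical()))
  }
  rows <- lapply(cand, function(cc) {
    x <- rank_table[cc$tf, lineages == cc$focal]
    y <- rank_table[cc$tf, lineages != cc$focal]
    mw <- mann_whitney_less(x, y)
    data.frame(tf = cc$tf, focal = cc$focal,
               median_focal = stats::median(x), median_other = stats::median(y),
               u = mw$u, p = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, "BH")
  out$significant <- out$padj <= fdr
  out[order(out$padj, out$p), , drop = FALSE]
}
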