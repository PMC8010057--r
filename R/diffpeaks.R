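# Differential candidate-regulatory-element analysis: union peak-count
# matrix, normalization, NB Wald test with trend-shrunken dispersions,
# threshold-based enrichment calls, sample clustering, and the multi-state
# shared/differential cistrome comparison.

#' Construct a count matrix object
#'
#' @param peaks interval table of union peaks (one row per matrix row).
#' @param counts numeric matrix, peaks x samples.
#' @param samples data.frame with columns `sample` and `lineage`, one row
#'   per matrix column.
#' @param normalized character vector recording normalization steps applied.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(peaks, counts, samples, normalized = character()) {
  stopifnot(nrow(peaks) == nrow(counts), nrow(samples) == ncol(counts),
            all(c("sample", "lineage") %in% names(samples)))
  if (!length(normalized) && any(counts != round(counts)))
    stop("raw counts must be integers")
  colnames(counts) <- samples$sample
  structure(list(peaks = peaks, counts = counts, samples = samples,
                 normalized = normalized),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d peaks x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (length(x$normalized)) paste(x$normalized, collapse = " + ")
              else "raw"))
  cat("lineages:", paste(sprintf("%s=%d", names(table(x$samples$lineage)),
                                 table(x$samples$lineage)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Build the union-peak count matrix
#'
#' Merges per-sample peak calls into a union set (peaks overlapping by >= 1
#' bp collapse into maximal connected regions) and counts each sample's
#' fragments over every union peak.
#'
#' @param peak_sets named list of per-sample interval tables (peak calls).
#' @param fragments named list of per-sample fragment interval tables; names
#'   must match `samples$sample`.
#' @param samples data.frame with `sample` and `lineage` columns.
#' @return `count_matrix` of raw counts.
#' @export
build_union_matrix <- function(peak_sets, fragments, samples) {
  stopifnot(length(peak_sets) >= 2)
  if (!all(samples$sample %in% names(fragments)))
    stop("fragments missing for sample(s): ",
         paste(setdiff(samples$sample, names(fragments)), collapse = ", "))
  union <- merge_intervals(do.call(rbind, lapply(peak_sets, function(p)
    p[, c("chrom", "start", "end", "name", "score", "strand")])))
  if (nrow(union) == 0) stop("union peak set is empty")
  counts <- matrix(vapply(samples$sample,
                          function(s) count_fragments(fragments[[s]], union),
                          integer(nrow(union))),
                   nrow = nrow(union))
  count_matrix(union, counts, samples)
}

#' Library-size normalization
#'
#' Scales each sample column by (mean total across samples) / (its total),
#' so column totals become equal while the grand mean stays on the raw
#' count scale.
#'
#' @param m `count_matrix`.
#' @param totals optional per-sample mapped-fragment totals; defaults to
#'   column sums.
#' @return `count_matrix` with normalization recorded.
#' @export
normalize_libsize <- function(m, totals = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  if (is.null(totals)) totals <- colSums(m$counts)
  if (any(totals == 0)) stop("zero library total for sample(s): ",
                             paste(m$samples$sample[totals == 0], collapse = ", "))
  m$counts <- sweep(m$counts, 2, mean(totals) / totals, "*")
  m$normalized <- c(m$normalized, "libsize")
  m
}

#' Quantile normalization
#'
#' Forces every sample column onto the common reference distribution given
#' by the row-wise mean of column-sorted values.  Ties within a column
#' receive the mean of the reference values over their rank range, so tied
#' entries share one value.  On tie-free matrices every column's sorted
#' values equal the reference exactly.
#'
#' @param m `count_matrix`.
#' @return `count_matrix` with quantile-normalized columns.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  x <- m$counts
  ref <- rowMeans(apply(x, 2, sort))
  cumref <- cumsum(ref)
  m$counts <- apply(x, 2, function(col) {
    lo <- rank(col, ties.method = "min")
    hi <- rank(col, ties.method = "max")
    (cumref[hi] - c(0, cumref)[lo]) / (hi - lo + 1)
  })
  colnames(m$counts) <- m$samples$sample
  m$normalized <- c(m$normalized, "quantile")
  m
}

# Mean-dispersion trend: bin peaks by mean, average the per-peak moment
# dispersions within bins, fit alpha(mu) = a0 + a1/mu to the bin summaries.
fit_dispersion_trend <- function(mu, alpha_mom, nbins = 20) {
  ok <- is.finite(mu) & mu > 0 & is.finite(alpha_mom)
  br <- unique(stats::quantile(mu[ok], probs = seq(0, 1, length.out = nbins + 1)))
  if (length(br) < 3) return(function(x) pmax(mean(alpha_mom[ok]), 1e-8))
  bin <- cut(mu[ok], br, include.lowest = TRUE)
  bm <- tapply(mu[ok], bin, mean)
  ba <- tapply(alpha_mom[ok], bin, mean)
  keep <- is.finite(bm) & is.finite(ba)
  fit <- stats::lm(ba[keep] ~ I(1 / bm[keep]))
  a0 <- stats::coef(fit)[1]; a1 <- stats::coef(fit)[2]
  function(x) pmax(a0 + a1 / pmax(x, 1e-8), 1e-8)
}

#' Negative-binomial Wald test for lineage-differential peaks
#'
#' Tests each peak for a difference in mean signal between two lineages.
#' Per-peak dispersions are estimated by moments (var = mu + alpha mu^2),
#' shrunk toward a fitted mean-dispersion trend with weight
#' `shrink_weight`, and the Wald statistic on the log2 ratio of group means
#' (pseudo-count 0.5) is referred to a t distribution with effective
#' degrees of freedom `(nA + nB - 2) / (1 - shrink_weight)^2`, reflecting
#' the variance stabilization from shrinkage.  Normalized matrices are
#' treated as continuous pseudo-counts (all size factors 1).
#'
#' @param m `count_matrix` (normalized or raw).
#' @param contrast character pair `c(A, B)`: log2 fold-changes are B over A.
#' @param shrink_weight weight of the trend in dispersion shrinkage
#'   (default 0.5).
#' @return data.frame of class `differential_result` with one row per union
#'   peak: `peak`, `base_mean`, `log2fc`, `p`, `padj`, plus attribute
#'   `contrast`.
#' @export
nb_differential <- function(m, contrast, shrink_weight = 0.5) {
  stopifnot(inherits(m, "count_matrix"), length(contrast) == 2)
  lin <- m$samples$lineage
  A <- m$counts[, lin == contrast[1], drop = FALSE]
  B <- m$counts[, lin == contrast[2], drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  if (nA < 2 || nB < 2)
    stop("each group needs >= 2 samples (got ", nA, " vs ", nB, ")")
  mA <- rowMeans(A); mB <- rowMeans(B)
  mu <- (mA + mB) / 2
  s2 <- (rowSums((A - mA)^2) + rowSums((B - mB)^2)) / (nA + nB - 2)
  alpha_mom <- ifelse(mu > 0, (s2 - mu) / mu^2, NA_real_)
  trend <- fit_dispersion_trend(mu, alpha_mom)
  alpha <- pmax((1 - shrink_weight) * pmax(alpha_mom, 0, na.rm = TRUE) +
                  shrink_weight * trend(mu), 1e-8)
  log2fc <- log2((mB + 0.5) / (mA + 0.5))
  se <- sqrt((mA + alpha * mA^2) / (nA * pmax(mA, 0.5)^2) +
               (mB + alpha * mB^2) / (nB * pmax(mB, 0.5)^2)) / log(2)
  stat <- log2fc / se
  df <- (nA + nB - 2) / (1 - shrink_weight)^2
  p <- 2 * stats::pt(-abs(stat), df = df)
  zero <- rowSums(m$counts) == 0
  p[zero] <- 1
  log2fc[zero] <- 0
  res <- data.frame(peak = m$peaks$name, base_mean = mu, log2fc = log2fc,
                    p = p, padj = stats::p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  attr(res, "contrast") <- contrast
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Enrichment-call presets
#'
#' Thresholds used for lineage-enriched peak calls per assay:
#' H3K27ac padj < 0.001 and |log2fc| > 3; FOXA1 padj < 0.001 and
#' |log2fc| > 2; H3K27me3 padj < 0.01 and |log2fc| > 1.
#'
#' @param assay one of "h3k27ac", "foxa1", "h3k27me3".
#' @return list with `lfc` and `padj` thresholds.
#' @export
cre_preset <- function(assay = c("h3k27ac", "foxa1", "h3k27me3")) {
  switch(match.arg(assay),
         h3k27ac = list(lfc = 3, padj = 0.001),
         foxa1 = list(lfc = 2, padj = 0.001),
         h3k27me3 = list(lfc = 1, padj = 0.01))
}

#' Call lineage-enriched peaks at fixed thresholds
#'
#' Applies strict inequalities `padj < padj_thresh` and
#' `|log2fc| > lfc_thresh`; sign of log2fc sets the direction.
#'
#' @param r `differential_result`.
#' @param lfc_thresh log2 fold-change threshold (> 0).
#' @param padj_thresh adjusted-p threshold (> 0).
#' @return `r` with an added `label` column:
#'   `enriched_in_B` / `enriched_in_A` / `not_called`, plus attribute
#'   `thresholds`.
#' @export
call_enriched <- function(r, lfc_thresh, padj_thresh) {
  stopifnot(lfc_thresh > 0, padj_thresh > 0)
  lab <- rep("not_called", nrow(r))
  sig <- r$padj < padj_thresh & abs(r$log2fc) > lfc_thresh
  lab[sig & r$log2fc > 0] <- "enriched_in_B"
  lab[sig & r$log2fc < 0] <- "enriched_in_A"
  r$label <- lab
  attr(r, "thresholds") <- list(lfc = lfc_thresh, padj = padj_thresh)
  r
}

#' Cluster samples by Spearman correlation; PCA
#'
#' Hierarchical clustering of samples on distance 1 - Spearman rho between
#' columns (average linkage by default) and principal components of the
#' row-centered matrix.
#'
#' @param m `count_matrix` with >= 3 samples.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return list with `hclust` (the dendrogram), `dist` (distance matrix)
#'   and `pca` (sample scores from [stats::prcomp()]).
#' @export
cluster_samples <- function(m, linkage = "average") {
  stopifnot(inherits(m, "count_matrix"), ncol(m$counts) >= 3)
  const <- apply(m$counts, 2, function(x) stats::sd(x) == 0)
  if (any(const))
    stop("constant column(s), correlation undefined: ",
         paste(m$samples$sample[const], collapse = ", "))
  rho <- stats::cor(m$counts, method = "spearman")
  d <- stats::as.dist(1 - rho)
  hc <- stats::hclust(d, method = linkage)
  pca <- stats::prcomp(t(m$counts - rowMeans(m$counts)), center = FALSE)
  list(hclust = hc, dist = d, pca = pca)
}

#' Multi-state cistrome comparison with shared-peak definition
#'
#' Runs pairwise differential tests over consecutive pairs of ordered
#' states (e.g. normal -> localized -> metastatic -> neuroendocrine) on a
#' common union peak set, then defines shared peaks as those present in
#' every state (peak called in >= 1 sample of each state) and significant
#' in no comparison (at `padj < padj_thresh` and `|log2fc| > lfc_thresh`).
#'
#' @param m `count_matrix` whose `samples$lineage` holds the state labels.
#' @param states character vector giving the state order; each state needs
#'   >= 2 samples.
#' @param presence logical matrix peaks x states: TRUE when the peak was
#'   called in at least one sample of that state.
#' @param lfc_thresh,padj_thresh thresholds (defaults 2 and 0.001).
#' @return list with `comparisons` (named list of labeled
#'   `differential_result`s, one per consecutive state pair) and `shared`
#'   (interval table of shared peaks).
#' @export
multi_state_compare <- function(m, states, presence,
                                lfc_thresh = 2, padj_thresh = 0.001) {
  stopifnot(inherits(m, "count_matrix"), length(states) >= 2,
            nrow(presence) == nrow(m$peaks), ncol(presence) == length(states))
  tab <- table(m$samples$lineage)
  small <- states[!(states %in% names(tab)) | tab[states] < 2]
  if (length(small)) stop("state(s) with < 2 samples: ",
                          paste(small, collapse = ", "))
  comparisons <- list()
  sig_any <- rep(FALSE, nrow(m$peaks))
  for (k in seq_len(length(states) - 1)) {
    res <- call_enriched(nb_differential(m, contrast = states[k + 0:1]),
                         lfc_thresh, padj_thresh)
    comparisons[[paste(states[k], states[k + 1], sep = "_vs_")]] <- res
    sig_any <- sig_any | res$label != "not_called"
  }
  shared_idx <- which(rowSums(presence) == length(states) & !sig_any)
  list(comparisons = comparisons,
       shared = m$peaks[shared_idx, , drop = FALSE])
}
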