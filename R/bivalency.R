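# Promoter chromatin-state classification: two-component Gaussian mixture
# fits to H3K4me3 and H3K27me3 TSS signal, +/-4 sigma cutoffs, the
# active/bivalent/unmarked/repressed quadrants, and the enrichment test of
# upregulated genes among bivalent promoters.

#' Fit a two-component Gaussian mixture by EM
#'
#' One-dimensional EM with deterministic initialization: the data are
#' split at the median and each half provides one component's starting
#' mean/sd; weights start at the split proportions.  Components are
#' relabeled so `mu_low <= mu_high`.  Convergence when the log-likelihood
#' gain drops below `tol` (default 1e-8) or after `max_iter` iterations.
#'
#' @param values numeric vector (>= 50 values, nonzero variance).
#' @param max_iter maximum EM iterations (default 1000).
#' @param tol log-likelihood convergence tolerance (default 1e-8).
#' @return list of class `mixture_fit`: `mu_low`, `sigma_low`, `mu_high`,
#'   `sigma_high`, `weight_high`, `loglik` (trace), `converged`,
#'   `responsibility_high` (per observation).
#' @export
fit_mixture <- function(values, max_iter = 1000, tol = 1e-8) {
  values <- values[is.finite(values)]
  if (length(values) < 50) stop("need >= 50 finite values to fit a mixture")
  if (stats::sd(values) == 0) stop("zero variance: mixture fit undefined")
  med <- stats::median(values)
  lo <- values[values <= med]; hi <- values[values > med]
  if (!length(hi)) hi <- lo
  sd_floor <- 1e-6 * stats::sd(values)
  mu <- c(mean(lo), mean(hi))
  sg <- pmax(c(stats::sd(lo), stats::sd(hi)), sd_floor, na.rm = TRUE)
  w <- c(length(lo), length(hi)) / length(values)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(values, mu[1], sg[1])
    d2 <- w[2] * stats::dnorm(values, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    r2 <- d2 / tot
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
    n2 <- sum(r2); n1 <- length(values) - n2
    if (n1 < 1e-8 || n2 < 1e-8)
      stop("degenerate mixture fit (empty component); check the data")
    mu <- c(sum((1 - r2) * values) / n1, sum(r2 * values) / n2)
    sg <- sqrt(c(sum((1 - r2) * (values - mu[1])^2) / n1,
                 sum(r2 * (values - mu[2])^2) / n2))
    if (any(!is.finite(sg)) || any(sg < sd_floor))
      stop("degenerate mixture fit (sigma -> 0); check the data")
    w <- c(n1, n2) / length(values)
  }
  if (mu[1] > mu[2]) {   # relabel so component 2 is "high"
    mu <- rev(mu); sg <- rev(sg); w <- rev(w); r2 <- 1 - r2
  }
  structure(list(mu_low = mu[1], sigma_low = sg[1], mu_high = mu[2],
                 sigma_high = sg[2], weight_high = w[2],
                 loglik = ll_trace, converged = converged,
                 responsibility_high = r2),
            class = "mixture_fit")
}

#' High/low cutoffs from the fitted mixtures
#'
#' The H3K4me3 cutoff sits four standard deviations below the mean of the
#' H3K4me3-high component; the H3K27me3 cutoff sits four standard
#' deviations above the mean of the H3K27me3-low component (the latter fit
#' on H3K4me3-high promoters only).
#'
#' @param k4_fit `mixture_fit` of H3K4me3 promoter signal (all TSSs).
#' @param k27_fit `mixture_fit` of H3K27me3 signal at H3K4me3-high TSSs.
#' @param n_sd number of standard deviations (default 4).
#' @return list with `k4_cutoff` and `k27_cutoff`.
#' @export
derive_cutoffs <- function(k4_fit, k27_fit, n_sd = 4) {
  list(k4_cutoff = k4_fit$mu_high - n_sd * k4_fit$sigma_high,
       k27_cutoff = k27_fit$mu_low + n_sd * k27_fit$sigma_low)
}

#' Classify promoters into chromatin-state quadrants
#'
#' Quadrants from the two cutoffs: H3K4me3-high and H3K27me3-high is
#' bivalent; H3K4me3-high only is active; H3K27me3-high only is
#' repressed; neither is unmarked.
#'
#' @param signals data.frame with `gene_id`, `k4`, `k27` (group-mean
#'   normalized tag densities around the TSS).
#' @param cutoffs list from [derive_cutoffs()].
#' @return `signals` with an added factor column `quadrant`.
#' @export
classify_promoters <- function(signals, cutoffs) {
  stopifnot(is.finite(cutoffs$k4_cutoff), is.finite(cutoffs$k27_cutoff))
  k4_hi <- signals$k4 > cutoffs$k4_cutoff
  k27_hi <- signals$k27 > cutoffs$k27_cutoff
  q <- ifelse(k4_hi & k27_hi, "bivalent",
              ifelse(k4_hi, "active",
                     ifelse(k27_hi, "repressed", "unmarked")))
  signals$quadrant <- factor(q, levels = c("active", "bivalent",
                                           "repressed", "unmarked"))
  attr(signals, "cutoffs") <- cutoffs
  signals
}

#' Two-stage promoter-state classification
#'
#' Fits the H3K4me3 mixture on all promoters, the H3K27me3 mixture on
#' H3K4me3-high promoters only (membership by the K4 cutoff), derives the
#' +/-4 sigma cutoffs and classifies every promoter.
#'
#' @param signals data.frame with `gene_id`, `k4`, `k27`.
#' @param n_sd cutoff width in component standard deviations (default 4).
#' @return list: `states` (classified signals), `k4_fit`, `k27_fit`,
#'   `cutoffs`.
#' @export
promoter_states <- function(signals, n_sd = 4) {
  k4_fit <- fit_mixture(signals$k4)
  k4_cut <- k4_fit$mu_high - n_sd * k4_fit$sigma_high
  k27_fit <- fit_mixture(signals$k27[signals$k4 > k4_cut])
  cutoffs <- derive_cutoffs(k4_fit, k27_fit, n_sd = n_sd)
  list(states = classify_promoters(signals, cutoffs),
       k4_fit = k4_fit, k27_fit = k27_fit, cutoffs = cutoffs)
}

#' Enrichment of upregulated genes among bivalent promoters
#'
#' Pearson chi-squared test (no continuity correction) on the 2 x 2 table
#' crossing promoter class (bivalent vs the two H3K4me3-low quadrants,
#' unmarked + repressed) with membership in the upregulated gene set.
#' Genes in the active quadrant do not enter the table.
#'
#' @param states classified data.frame from [classify_promoters()].
#' @param upregulated character vector of upregulated gene ids.
#' @return list: `table` (2 x 2 counts), `statistic`, `p`.
#' @export
bivalent_enrichment_test <- function(states, upregulated) {
  grp <- ifelse(states$quadrant == "bivalent", "bivalent",
                ifelse(states$quadrant %in% c("unmarked", "repressed"),
                       "bottom", NA))
  keep <- !is.na(grp)
  up <- states$gene_id %in% upregulated
  tab <- table(factor(grp[keep], levels = c("bivalent", "bottom")),
               factor(ifelse(up[keep], "up", "not_up"),
                      levels = c("up", "not_up")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin in the 2x2 table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab, statistic = unname(ct$statistic), p = ct$p.value)
}

#' Select upregulated genes from a differential-expression table
#'
#' @param diff_expr data.frame with `gene_id`, `log2fc`, `padj`.
#' @param lfc_thresh log2 fold-change threshold, strict `>` (default 3).
#' @param padj_thresh adjusted-p threshold, strict `<` (default 1e-6).
#' @return character vector of gene ids.
#' @export
upregulated_genes <- function(diff_expr, lfc_thresh = 3, padj_thresh = 1e-6) {
  diff_expr$gene_id[diff_expr$log2fc > lfc_thresh &
                      diff_expr$padj < padj_thresh]
}

#' Quadrant composition of genes losing promoter H3K27me3
#'
#' Intersects genes with significant promoter H3K27me3 loss
#' (`log2fc < lfc_thresh` and `padj < padj_thresh`) with their promoter
#' quadrant labels and counts each quadrant.
#'
#' @param diff_k27 data.frame with `gene_id`, `log2fc`, `padj` (promoter-
#'   level H3K27me3 differential, focal lineage over reference).
#' @param states classified data.frame from [classify_promoters()].
#' @param lfc_thresh log2 fold-change upper bound, strict `<` (default -1).
#' @param padj_thresh adjusted-p threshold, strict `<` (default 0.01).
#' @return list: `loss_genes` (ids), `counts` (per quadrant, summing to
#'   the number of loss genes present in `states`).
#' @export
h3k27me3_loss_overlap <- function(diff_k27, states, lfc_thresh = -1,
                                  padj_thresh = 0.01) {
  loss <- diff_k27$gene_id[diff_k27$log2fc < lfc_thresh &
                             diff_k27$padj < padj_thresh]
  tb <- table(states$quadrant[states$gene_id %in% loss])
  list(loss_genes = loss,
       counts = stats::setNames(as.integer(tb), names(tb)))
}
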