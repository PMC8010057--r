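# HiChIP loop assignment: promoter-anchored loop filtering, gene/CRE link
# counting, the looped-CRE expression association test, and selection of
# super-enhancers in contact with a target locus.

#' Load and filter chromatin loops
#'
#' Reads (or takes) a bedpe table, drops trans-chromosomal records (with a
#' warning), restricts anchor-midpoint spans to `[min_span, max_span]`,
#' optionally filters on loop significance `q`, and normalizes anchor
#' order so `start1 <= start2`.
#'
#' @param bedpe path to a bedpe file or a data.frame from [read_bedpe()].
#' @param min_span,max_span inclusive span bounds in bp (defaults 5 kb and
#'   3 Mb).
#' @param max_q optional maximum significance q; default keeps all rows.
#' @return filtered loop data.frame; dropped-record counts are reported
#'   via [message()].
#' @export
load_loops <- function(bedpe, min_span = 5000, max_span = 3e6, max_q = NULL) {
  loops <- if (is.character(bedpe)) read_bedpe(bedpe) else bedpe
  trans <- loops$chrom1 != loops$chrom2
  if (any(trans)) {
    warning("dropping ", sum(trans), " trans-chromosomal loop record(s)")
    loops <- loops[!trans, , drop = FALSE]
  }
  swap <- loops$start1 > loops$start2
  if (any(swap)) {
    tmp <- loops[swap, c("start1", "end1")]
    loops[swap, c("start1", "end1")] <- loops[swap, c("start2", "end2")]
    loops[swap, c("start2", "end2")] <- tmp
  }
  span <- abs((loops$start2 + loops$end2) / 2 - (loops$start1 + loops$end1) / 2)
  drop_span <- span < min_span | span > max_span
  if (any(drop_span))
    message("load_loops: ", sum(drop_span), " loop(s) outside [",
            min_span, ", ", max_span, "] bp span dropped")
  loops <- loops[!drop_span, , drop = FALSE]
  if (!is.null(max_q) && "q" %in% names(loops))
    loops <- loops[is.na(loops$q) | loops$q <= max_q, , drop = FALSE]
  rownames(loops) <- NULL
  loops
}

#' Promoter windows 0-5 kb upstream of the TSS
#'
#' Builds strand-reflected half-open windows covering the `size` bases
#' strictly upstream of each TSS: `[tss - size, tss)` on the plus strand
#' and `[tss + 1, tss + 1 + size)` on the minus strand (the TSS base
#' itself is excluded).  Windows are clipped at coordinate 0.
#'
#' @param genes gene table with `gene_id`, `chrom`, `strand`, `tss`.
#' @param size window size in bp (default 5000).
#' @return interval table named by gene id; genes with unknown strand are
#'   skipped with a [message()].
#' @export
promoter_windows <- function(genes, size = 5000) {
  bad <- !genes$strand %in% c("+", "-")
  if (any(bad))
    message("promoter_windows: skipping ", sum(bad),
            " gene(s) with unknown strand")
  g <- genes[!bad, , drop = FALSE]
  start <- ifelse(g$strand == "+", pmax(g$tss - size, 0), g$tss + 1)
  end <- ifelse(g$strand == "+", g$tss, g$tss + 1 + size)
  keep <- start < end
  peak_table(g$chrom[keep], start[keep], end[keep], name = g$gene_id[keep],
             strand = g$strand[keep])
}

loop_anchor <- function(loops, which) {
  peak_table(loops[[paste0("chrom", which)]], loops[[paste0("start", which)]],
             loops[[paste0("end", which)]],
             name = sprintf("loop_%d", seq_len(nrow(loops))))
}

#' Assign loops to gene promoters and distal peaks
#'
#' A gene is linked to a peak when some loop has one anchor overlapping
#' the gene's upstream promoter window and the other anchor overlapping
#' the peak.  Links are deduplicated per (gene, peak), so `n_links` counts
#' distinct looped peaks.
#'
#' @param loops loop data.frame from [load_loops()].
#' @param genes gene table (`gene_id`, `chrom`, `strand`, `tss`).
#' @param peaks interval table of distal CREs/peaks with unique names.
#' @param promoter_size promoter window size in bp (default 5000).
#' @return list: `links` (data.frame gene_id/peak), `n_links` (named
#'   integer per gene, zero included for every gene in `genes`).
#' @export
assign_promoter_loops <- function(loops, genes, peaks, promoter_size = 5000) {
  prom <- promoter_windows(genes, promoter_size)
  validate_intervals(peaks)
  links <- data.frame(gene_id = character(), peak = character(),
                      stringsAsFactors = FALSE)
  if (nrow(loops) && nrow(prom) && nrow(peaks)) {
    a1 <- loop_anchor(loops, 1)
    a2 <- loop_anchor(loops, 2)
    pairs <- list()
    for (side in 1:2) {
      pa <- if (side == 1) a1 else a2
      ca <- if (side == 1) a2 else a1
      ov_p <- interval_overlap(pa, prom)     # loop i ~ promoter j
      ov_c <- interval_overlap(ca, peaks)    # loop i ~ peak k
      if (nrow(ov_p) && nrow(ov_c)) {
        m <- merge(ov_p, ov_c, by = "i")     # same loop on both sides
        if (nrow(m))
          pairs[[side]] <- data.frame(gene_id = prom$name[m$j.x],
                                      peak = peaks$name[m$j.y],
                                      stringsAsFactors = FALSE)
      }
    }
    if (length(pairs)) links <- unique(do.call(rbind, pairs))
  }
  links <- links[order(links$gene_id, links$peak), , drop = FALSE]
  rownames(links) <- NULL
  n <- table(factor(links$gene_id, levels = genes$gene_id))
  list(links = links,
       n_links = stats::setNames(as.integer(n), genes$gene_id))
}

#' Association between looped-CRE count and differential expression
#'
#' Bins genes by their number of distinct looped peaks and compares the
#' expression log2 fold-changes of genes with exactly one looped peak
#' against genes with two or more, using a two-sided Wilcoxon rank-sum
#' test (exact when group sizes permit and there are no ties).
#'
#' @param n_links named integer vector of looped-peak counts per gene.
#' @param log2fc named numeric vector of expression log2 fold-changes
#'   (names matched to `n_links`).
#' @param alpha significance level (default 0.01).
#' @return list: `bins` (data.frame n_links bin, n genes, median log2fc),
#'   `statistic`, `p`, `significant`.
#' @export
loop_expression_association <- function(n_links, log2fc, alpha = 0.01) {
  common <- intersect(names(n_links), names(log2fc))
  k <- n_links[common]
  fc <- log2fc[common]
  x <- fc[k == 1]
  y <- fc[k >= 2]
  if (length(x) < 2 || length(y) < 2)
    stop("need >= 2 genes in each compared bin (got ", length(x), " and ",
         length(y), ")")
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            exact = length(x) + length(y) <= 50 &&
                                              !any(duplicated(c(x, y)))))
  bins <- do.call(rbind, lapply(sort(unique(k)), function(b)
    data.frame(n_links = b, n_genes = sum(k == b),
               median_log2fc = stats::median(fc[k == b]))))
  list(bins = bins, statistic = unname(wt$statistic), p = wt$p.value,
       significant = wt$p.value < alpha)
}

#' Super-enhancers looped to a target locus
#'
#' Selects the super-enhancers that form three-dimensional contacts with a
#' target gene: an SE is selected when at least one loop has an anchor
#' overlapping the SE while its mate anchor overlaps the target gene span
#' extended by `flank` on both sides.  Each SE appears once.
#'
#' @param loops loop data.frame from [load_loops()].
#' @param target_gene single row of a gene table with `gene_id`, `chrom`,
#'   `start`, `end` (gene span).
#' @param se_regions interval table of super-enhancers with unique names.
#' @param flank locus extension in bp (default 5000).
#' @return subset of `se_regions` looped to the locus.
#' @export
ses_looped_to_locus <- function(loops, target_gene, se_regions, flank = 5000) {
  if (is.null(target_gene) || nrow(target_gene) != 1)
    stop("target gene absent from annotation")
  locus <- peak_table(target_gene$chrom,
                      max(target_gene$start - flank, 0),
                      target_gene$end + flank, name = target_gene$gene_id)
  sel <- logical(nrow(se_regions))
  if (nrow(loops)) {
    a1 <- loop_anchor(loops, 1)
    a2 <- loop_anchor(loops, 2)
    for (side in 1:2) {
      la <- if (side == 1) a1 else a2
      ma <- if (side == 1) a2 else a1
      at_locus <- unique(interval_overlap(la, locus)$i)
      if (length(at_locus)) {
        ov <- interval_overlap(ma[at_locus, , drop = FALSE], se_regions)
        sel[unique(ov$j)] <- TRUE
      }
    }
  }
  se_regions[sel, , drop = FALSE]
}
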