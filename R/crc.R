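# Core regulatory circuitry: PWM scanning in open chromatin, the directed
# TF regulatory graph over super-enhancers, maximal-clique enumeration,
# clique enrichment scores, cross-sample CES clustering, and motif
# base-pair coverage of super-enhancer sets.

# log2-odds matrix of a probability PWM against background
pwm_logodds <- function(pwm, background = rep(0.25, 4), eps = 1e-4) {
  stopifnot(nrow(pwm) == 4, ncol(pwm) >= 4,
            max(abs(colSums(pwm) - 1)) < 1e-6)
  log2((pwm + eps) / (1 + 4 * eps)) - log2(background)
}

#' Scan regions of a genome with a PWM
#'
#' Computes the log2-odds score of `pwm` against a background base
#' composition at every offset of every region, on both strands, and
#' reports hits scoring at least `threshold_frac` times the PWM's maximum
#' achievable score.  Offsets covering N bases are skipped (reported once
#' via [message()]).
#'
#' @param genome [Biostrings::DNAStringSet] (or named character vector).
#' @param regions interval table of regions to scan (e.g. ATAC peaks).
#' @param pwm 4 x L column-stochastic probability matrix, rows A/C/G/T.
#' @param background background base frequencies (default uniform).
#' @param threshold_frac hit threshold as a fraction of the maximum
#'   log-odds score (default 0.7).
#' @param min_score optional absolute threshold in bits, overriding
#'   `threshold_frac` (useful for information-free PWMs whose maximum
#'   score is 0).
#' @return interval table of hits with columns chrom, start, end, name,
#'   score (log2-odds bits), strand; coordinates are genomic.
#' @export
scan_pwm <- function(genome, regions, pwm, background = rep(0.25, 4),
                     threshold_frac = 0.7, min_score = NULL) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  validate_intervals(regions)
  lod <- pwm_logodds(pwm, background)
  L <- ncol(lod)
  thr <- if (is.null(min_score)) threshold_frac * sum(apply(lod, 2, max))
         else min_score
  lod_rc <- lod[4:1, L:1]   # reverse complement strand scores
  hits <- list()
  n_skipped <- 0
  for (r in seq_len(nrow(regions))) {
    chrom <- regions$chrom[r]
    if (!chrom %in% names(genome)) next
    if (regions$end[r] - regions$start[r] < L) next
    seq <- substr(as.character(genome[[chrom]]), regions$start[r] + 1,
                  regions$end[r])
    code <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
    n_off <- length(code) - L + 1
    fwd <- numeric(n_off); rev <- numeric(n_off)
    for (j in seq_len(L)) {
      b <- code[j:(j + n_off - 1)]
      fwd <- fwd + lod[cbind(b, j)]
      rev <- rev + lod_rc[cbind(b, j)]
    }
    n_skipped <- n_skipped + sum(is.na(fwd))
    for (strand in c("+", "-")) {
      sc <- if (strand == "+") fwd else rev
      pos <- which(!is.na(sc) & sc >= thr)
      if (length(pos))
        hits[[length(hits) + 1]] <- data.frame(
          chrom = chrom, start = regions$start[r] + pos - 1,
          end = regions$start[r] + pos - 1 + L, name = ".",
          score = sc[pos], strand = strand, stringsAsFactors = FALSE)
    }
  }
  if (n_skipped > 0)
    message("scan_pwm: skipped ", n_skipped, " offsets containing N")
  if (!length(hits))
    return(peak_table(character(), numeric(), numeric()))
  out <- do.call(rbind, hits)
  sort_intervals(out)
}

#' Build the TF regulatory graph over super-enhancers
#'
#' Nodes are expressed TFs with at least one super-enhancer.  A directed
#' edge A -> B exists when a motif hit of A's PWM falls inside open
#' chromatin (an ATAC peak) within B's super-enhancer; an A -> A edge
#' marks A as auto-regulated.
#'
#' @param se_map named list: TF -> interval table of its super-enhancers.
#' @param atac interval table of open-chromatin (ATAC) peaks.
#' @param hits named list: TF -> interval table of its motif hits (from
#'   [scan_pwm()]).  TFs present in `se_map` but absent here keep their
#'   node but can have no outgoing edges (warning).
#' @param expressed character vector of expressed TF ids.
#' @return list of class `crc_graph`: `nodes`, `edges` (data.frame
#'   from/to), `auto` (named logical: auto-regulated).
#' @export
build_crc_graph <- function(se_map, atac, hits, expressed) {
  nodes <- sort(intersect(names(se_map)[vapply(se_map, nrow, 0L) > 0],
                          expressed))
  no_pwm <- setdiff(nodes, names(hits))
  if (length(no_pwm))
    warning("TF(s) without motif hits (no PWM?): ",
            paste(no_pwm, collapse = ", "))
  # open chromatin inside each TF's SEs
  open_se <- lapply(se_map[nodes], function(se) {
    if (!nrow(se) || !nrow(atac)) return(se[0, c("chrom", "start", "end")])
    gr <- GenomicRanges::intersect(as_granges(se), as_granges(atac))
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1,
               end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  })
  edges <- list()
  for (a in intersect(nodes, names(hits))) {
    h <- hits[[a]]
    if (!nrow(h)) next
    for (b in nodes) {
      tgt <- open_se[[b]]
      if (!nrow(tgt)) next
      if (nrow(interval_overlap(h, tgt)) > 0)
        edges[[length(edges) + 1]] <- data.frame(from = a, to = b,
                                                 stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character())
  auto <- vapply(nodes, function(n) any(edges$from == n & edges$to == n),
                 logical(1))
  structure(list(nodes = nodes, edges = edges, auto = auto),
            class = "crc_graph")
}

#' Enumerate regulatory cliques
#'
#' Candidate nodes are the auto-regulated TFs; the undirected support
#' graph joins A and B when both A -> B and B -> A hold.  Cliques are the
#' maximal cliques of this graph with at least `min_size` members,
#' returned with sorted members in lexicographic order (deterministic).
#' Delegates the maximal-clique search to [igraph::max_cliques()].
#'
#' @param g `crc_graph` from [build_crc_graph()].
#' @param min_size minimum clique size (default 2).
#' @return list of character vectors (sorted TF ids per clique).
#' @export
enumerate_cliques <- function(g, min_size = 2) {
  cand <- g$nodes[g$auto[g$nodes]]
  if (length(cand) < min_size) return(list())
  e <- g$edges[g$edges$from != g$edges$to &
                 g$edges$from %in% cand & g$edges$to %in% cand, , drop = FALSE]
  key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
  recip <- names(which(table(key) == 2))
  if (!length(recip)) return(list())
  pairs <- do.call(rbind, strsplit(recip, " "))
  ig <- igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1], to = pairs[, 2]),
    directed = FALSE,
    vertices = sort(unique(c(pairs[, 1], pairs[, 2]))))
  cl <- igraph::max_cliques(ig, min = min_size)
  out <- lapply(cl, function(v) sort(igraph::V(ig)$name[v]))
  out[order(vapply(out, paste, "", collapse = "\r"))]
}

#' Clique enrichment score per TF
#'
#' CES(TF) = number of cliques containing the TF divided by the total
#' number of cliques.
#'
#' @param cliques list of character vectors from [enumerate_cliques()].
#' @param tfs optional TF universe; TFs absent from all cliques get 0.
#' @return named numeric vector of CES values in `[0, 1]`; all-NA (with a
#'   warning) when there are no cliques.
#' @export
clique_enrichment <- function(cliques, tfs = NULL) {
  if (is.null(tfs)) tfs <- sort(unique(unlist(cliques)))
  if (!length(cliques)) {
    warning("no cliques: CES undefined")
    return(stats::setNames(rep(NA_real_, length(tfs)), tfs))
  }
  counts <- table(factor(unlist(cliques), levels = tfs))
  stats::setNames(as.numeric(counts) / length(cliques), tfs)
}

#' Cluster TFs by clique enrichment across samples
#'
#' Keeps TFs with a nonzero CES in at least `ceiling(presence_frac * n)`
#' samples of at least one lineage, then clusters with Canberra distance
#' and Ward linkage (`ward.D2`: squared-distance Ward convention).
#' Missing CES entries (samples without cliques) are treated as 0.
#'
#' @param ces_matrix numeric matrix TFs x samples.
#' @param lineages per-sample lineage labels.
#' @param presence_frac presence fraction per lineage (default 0.8).
#' @return list: `matrix` (filtered), `tf_hclust`, `sample_hclust`,
#'   `kept` (TF ids).
#' @export
ces_cluster <- function(ces_matrix, lineages, presence_frac = 0.8) {
  stopifnot(ncol(ces_matrix) == length(lineages))
  m <- ces_matrix
  m[is.na(m)] <- 0
  present <- m > 0
  keep <- rep(FALSE, nrow(m))
  for (l in unique(lineages)) {
    need <- ceiling(presence_frac * sum(lineages == l))
    keep <- keep | rowSums(present[, lineages == l, drop = FALSE]) >= need
  }
  if (!any(keep))
    stop("no TF passes the presence filter; max presence = ",
         max(rowSums(present)))
  m <- m[keep, , drop = FALSE]
  # all-zero profile pairs have no defined Canberra terms: distance 0
  canberra <- function(x) {
    d <- stats::dist(x, method = "canberra")
    d[is.na(d)] <- 0
    d
  }
  list(matrix = m,
       tf_hclust = if (nrow(m) >= 3)
         stats::hclust(canberra(m), method = "ward.D2") else NULL,
       sample_hclust = if (ncol(m) >= 3)
         stats::hclust(canberra(t(m)), method = "ward.D2") else NULL,
       kept = rownames(m))
}

#' Motif base-pair coverage of a super-enhancer set
#'
#' Fraction of the summed SE length covered by at least one motif hit
#' (hits are union-merged so overlapping hits count once, and clipped to
#' the SE set).
#'
#' @param se_set interval table of super-enhancers.
#' @param hits named list: TF -> interval table of motif hits.
#' @return named numeric vector, one coverage fraction in `[0, 1]` per TF.
#' @export
motif_coverage <- function(se_set, hits) {
  validate_intervals(se_set)
  se_gr <- GenomicRanges::reduce(as_granges(se_set))
  total <- sum(GenomicRanges::width(se_gr))
  if (total == 0) stop("zero total super-enhancer length")
  vapply(hits, function(h) {
    if (!nrow(h)) return(0)
    ov <- GenomicRanges::intersect(GenomicRanges::reduce(as_granges(h)), se_gr)
    sum(GenomicRanges::width(ov)) / total
  }, numeric(1))
}

#' Expressed-TF filter from promoter/gene-body H3K27ac
#'
#' A gene counts as expressed when the mean H3K27ac signal over its body
#' plus `upstream` bp of promoter exceeds the median of that quantity over
#' all genes (strictly).
#'
#' @param track bedGraph-style signal data.frame.
#' @param genes gene table with `gene_id`, `chrom`, `strand`, `start`,
#'   `end` columns (gene span).
#' @param upstream promoter extension in bp (default 5000).
#' @return character vector of expressed gene ids.
#' @export
expressed_genes <- function(track, genes, upstream = 5000) {
  ints <- lapply(split(track, track$chrom), track_integral)
  mean_sig <- vapply(seq_len(nrow(genes)), function(i) {
    Fc <- ints[[genes$chrom[i]]]
    if (is.null(Fc)) return(0)
    a <- if (genes$strand[i] == "-") genes$start[i] else
      max(genes$start[i] - upstream, 0)
    b <- if (genes$strand[i] == "-") genes$end[i] + upstream else genes$end[i]
    (Fc(b) - Fc(a)) / (b - a)
  }, numeric(1))
  genes$gene_id[mean_sig > stats::median(mean_sig)]
}
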