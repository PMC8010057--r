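# Interval arithmetic on BED-style tables.
#
# All coordinates in this package are 0-based, half-open ([start, end)),
# exactly as stored in BED/narrowPeak/bedGraph files.  GenomicRanges is used
# as the overlap engine internally (shifting start by +1 to its 1-based
# closed convention); user-facing tables never leave BED convention.

#' Construct a peak/interval table
#'
#' Builds the plain data.frame used throughout the package to represent
#' genomic intervals (peaks, fragments, anchors, DHS sites...).  Coordinates
#' are 0-based half-open as in BED.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `0 <= start < end` per row.
#' @param name optional feature names (recycled).
#' @param score optional numeric score (e.g. fold enrichment).
#' @param strand optional strand, one of `"+"`, `"-"`, `"."`.
#' @return data.frame with columns chrom, start, end, name, score, strand.
#' @export
peak_table <- function(chrom, start, end, name = ".", score = NA_real_,
                       strand = ".") {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = rep_len(as.numeric(start), n),
                   end = rep_len(as.numeric(end), n),
                   name = rep_len(as.character(name), n),
                   score = rep_len(as.numeric(score), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' Validate an interval table
#'
#' Checks the interval invariants (`0 <= start < end`, non-empty chrom) and
#' errors naming the first offending record.
#'
#' @param df data.frame with chrom/start/end columns.
#' @return `df`, invisibly, if valid.
#' @export
validate_intervals <- function(df) {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(!(df$start >= 0 & df$start < df$end) | is.na(df$chrom) |
                 df$chrom == "")
  if (length(bad)) {
    stop(sprintf("malformed interval at record %d: %s:%s-%s", bad[1],
                 df$chrom[bad[1]], format(df$start[bad[1]], scientific = FALSE),
                 format(df$end[bad[1]], scientific = FALSE)))
  }
  invisible(df)
}

#' Sort intervals by (chrom, start, end)
#'
#' Chromosomes are ordered lexicographically; ties broken by start then end.
#'
#' @param df interval table.
#' @return sorted data.frame (row names dropped).
#' @export
sort_intervals <- function(df) {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# BED half-open -> GRanges 1-based closed
as_granges <- function(df) {
  validate_intervals(df)
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' All overlapping pairs between two interval sets
#'
#' Two intervals overlap when they share at least one base on the same
#' chromosome; half-open adjacency (`end(a) == start(b)`) does not count.
#'
#' @param a,b interval tables.
#' @return data.frame with integer columns `i` (row in `a`) and `j` (row in
#'   `b`), one row per overlapping pair, sorted by (i, j).
#' @export
interval_overlap <- function(a, b) {
  validate_intervals(a)
  validate_intervals(b)
  if (nrow(a) == 0 || nrow(b) == 0)
    return(data.frame(i = integer(), j = integer()))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(a), as_granges(b),
                                minoverlap = 1L))
  out <- data.frame(i = S4Vectors::queryHits(hits),
                    j = S4Vectors::subjectHits(hits))
  out[order(out$i, out$j), , drop = FALSE]
}

#' Merge intervals into maximal connected regions
#'
#' Union-merges intervals that overlap by >= 1 bp (transitively) into single
#' regions, the operation used to build union peak sets across samples.
#'
#' @param df interval table (possibly concatenated across samples).
#' @return sorted interval table of merged regions, named `union_<k>`.
#' @export
merge_intervals <- function(df) {
  validate_intervals(df)
  if (nrow(df) == 0) return(peak_table(character(), numeric(), numeric()))
  red <- GenomicRanges::reduce(as_granges(df), min.gapwidth = 0L)
  out <- peak_table(as.character(GenomicRanges::seqnames(red)),
                    GenomicRanges::start(red) - 1,
                    GenomicRanges::end(red))
  out <- sort_intervals(out)
  out$name <- sprintf("union_%d", seq_len(nrow(out)))
  out
}

#' Count fragments over peaks
#'
#' Counts, for every peak, the number of fragments overlapping it by at
#' least one base.  A fragment overlapping k peaks increments all k counts,
#' so each peak's count is its own independent overlap tally.  Fragments on
#' chromosomes absent from the peak set contribute nothing (reported once
#' per chromosome via [message()]).
#'
#' @param fragments interval table of deduplicated aligned fragments.
#' @param peaks interval table of peaks.
#' @return integer vector of counts, one per row of `peaks`.
#' @export
count_fragments <- function(fragments, peaks) {
  validate_intervals(fragments)
  validate_intervals(peaks)
  if (nrow(peaks) == 0) return(integer())
  if (nrow(fragments) == 0) return(integer(nrow(peaks)))
  missing_chrom <- setdiff(unique(fragments$chrom), unique(peaks$chrom))
  if (length(missing_chrom))
    message("count_fragments: no peaks on chromosome(s) ",
            paste(missing_chrom, collapse = ", "),
            "; their fragments contribute 0")
  as.integer(suppressWarnings(
    GenomicRanges::countOverlaps(as_granges(peaks), as_granges(fragments),
                                 minoverlap = 1L)))
}

#' ChIP-seq sample quality metrics
#'
#' Computes the standard ChIP quality summary: total peak number, FrIP
#' (fraction of fragments in peaks), number of high-confidence peaks
#' (fold enrichment strictly greater than `fold_cutoff` over background) and
#' the fraction of peaks overlapping a DNase hypersensitivity reference set.
#'
#' @param fragments fragment interval table (must be non-empty).
#' @param peaks peak table whose `score` column holds fold enrichment over
#'   background (narrowPeak signalValue).
#' @param dhs reference interval table of DNase hypersensitive sites.
#' @param fold_cutoff high-confidence threshold, default 10 (strict `>`).
#' @return list with elements `peak_count`, `frip`,
#'   `high_confidence_count`, `dhs_overlap_fraction`.
#' @export
qc_metrics <- function(fragments, peaks, dhs, fold_cutoff = 10) {
  validate_intervals(peaks)
  validate_intervals(dhs)
  if (nrow(fragments) == 0) stop("qc_metrics: zero fragments, FrIP undefined")
  validate_intervals(fragments)
  n_in_peak <- if (nrow(peaks)) {
    sum(suppressWarnings(
      GenomicRanges::countOverlaps(as_granges(fragments), as_granges(peaks),
                                   minoverlap = 1L)) > 0)
  } else 0L
  dhs_frac <- if (nrow(peaks) == 0) {
    NA_real_
  } else if (nrow(dhs) == 0) {
    0
  } else {
    mean(suppressWarnings(
      GenomicRanges::countOverlaps(as_granges(peaks), as_granges(dhs),
                                   minoverlap = 1L)) > 0)
  }
  list(peak_count = nrow(peaks),
       frip = n_in_peak / nrow(fragments),
       high_confidence_count = sum(!is.na(peaks$score) &
                                     peaks$score > fold_cutoff),
       dhs_overlap_fraction = dhs_frac)
}
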