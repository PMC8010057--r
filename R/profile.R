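# Signal-profile aggregation: mean bedGraph coverage in equal-width bins
# around anchor centers, the primitive behind ChIP heatmaps (peak center
# +/- 2 kb) and methylation metaprofiles (peak center +/- 3 kb).

# Per-chromosome cumulative integral of a piecewise-constant track.
# Returns a function F with F(x) = integral of the track over [0, x);
# positions outside the covered span extend with zero signal.
track_integral <- function(segments) {
  segments <- segments[order(segments$start), , drop = FALSE]
  if (any(utils::head(segments$end, -1) > utils::tail(segments$start, -1)))
    stop("overlapping bedGraph segments on one chromosome")
  pos <- as.numeric(rbind(segments$start, segments$end))
  # areas at interleaved (start_i, end_i): start_i repeats previous end area
  areas <- numeric(2 * nrow(segments))
  a <- 0
  for (i in seq_len(nrow(segments))) {
    areas[2 * i - 1] <- a
    a <- a + segments$value[i] * (segments$end[i] - segments$start[i])
    areas[2 * i] <- a
  }
  keep <- !duplicated(pos)   # contiguous segments share a boundary point
  stats::approxfun(pos[keep], areas[keep], rule = 2)
}

#' Aggregate a signal track around anchor centers
#'
#' Computes, for each anchor interval, the coverage-weighted mean of a
#' piecewise-constant signal track in `nbins` equal-width bins spanning the
#' anchor center +/- `flank`.  Anchors on the minus strand are reversed so
#' bins read 5' to 3'.  Spans beyond the track (chromosome edges) count as
#' zero signal.
#'
#' @param track bedGraph-style data.frame (chrom, start, end, value) with
#'   non-overlapping segments per chromosome.
#' @param anchors interval table; the anchor point is
#'   `floor((start + end) / 2)`.
#' @param flank half-window in bp (> 0).
#' @param nbins number of bins (>= 1).
#' @return numeric matrix, one row per anchor, `nbins` columns of mean
#'   signal per bin.
#' @export
aggregate_profile <- function(track, anchors, flank, nbins) {
  stopifnot(flank > 0, nbins >= 1)
  validate_intervals(anchors)
  if (any(!is.finite(track$value))) stop("track values must be finite")
  ints <- lapply(split(track, track$chrom), track_integral)
  centers <- floor((anchors$start + anchors$end) / 2)
  w <- 2 * flank / nbins
  out <- matrix(0, nrow(anchors), nbins)
  for (r in seq_len(nrow(anchors))) {
    Fc <- ints[[anchors$chrom[r]]]
    if (is.null(Fc)) next
    edges <- centers[r] - flank + (0:nbins) * w
    vals <- diff(Fc(edges)) / w
    if (!is.null(anchors$strand) && anchors$strand[r] == "-") vals <- rev(vals)
    out[r, ] <- vals
  }
  rownames(out) <- anchors$name
  out
}
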