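# Readers and writers for the plain-text genomics formats the pipeline
# consumes: BED3/BED6, ENCODE narrowPeak/broadPeak, bedGraph, bedpe, FASTA,
# JASPAR matrix text, and the TSV tables (sample sheet, gene annotation,
# expression matrix).  All writers emit tab-separated text whose header
# line, when present, begins with '#'.

read_tsv_noheader <- function(path, col_names) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "", col.names = col_names,
                          fill = TRUE, colClasses = NA)
  df
}

#' Read a BED file (3 or 6+ columns)
#'
#' @param path BED file path.
#' @return interval table (see [peak_table()]); missing name/score/strand
#'   columns are filled with defaults.
#' @export
read_bed <- function(path) {
  first <- readLines(path, n = 50)
  first <- first[!startsWith(first, "#") & nzchar(first)]
  ncol <- if (length(first)) length(strsplit(first[1], "\t")[[1]]) else 3
  cols <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(ncol, 6))]
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "")[, seq_along(cols), drop = FALSE]
  names(df) <- cols
  peak_table(df$chrom, df$start, df$end,
             name = if ("name" %in% cols) df$name else ".",
             score = if ("score" %in% cols) suppressWarnings(as.numeric(df$score)) else NA_real_,
             strand = if ("strand" %in% cols) df$strand else ".")
}

#' Write intervals as BED6
#'
#' @param df interval table.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  out <- data.frame(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
                    format(df$end, scientific = FALSE, trim = TRUE),
                    df$name, ifelse(is.na(df$score), 0, df$score), df$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ENCODE narrowPeak (10-col) or broadPeak (9-col) file
#'
#' The score column of the returned table is signalValue (column 7, fold
#' enrichment).  For narrowPeak the summit offset (column 10) is kept in a
#' `summit` column as an absolute coordinate `start + offset` (NA when the
#' offset is -1).
#'
#' @param path peak file path.
#' @return interval table with extra columns `pvalue`, `qvalue` (-log10)
#'   and, for narrowPeak, `summit`.
#' @export
read_narrowpeak <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "")
  if (!ncol(df) %in% c(9, 10))
    stop("expected 9 (broadPeak) or 10 (narrowPeak) columns, got ", ncol(df))
  out <- peak_table(df[[1]], df[[2]], df[[3]], name = df[[4]],
                    score = df[[7]], strand = df[[6]])
  out$pvalue <- df[[8]]
  out$qvalue <- df[[9]]
  if (ncol(df) == 10)
    out$summit <- ifelse(df[[10]] < 0, NA_real_, df[[2]] + df[[10]])
  out
}

#' @rdname read_narrowpeak
#' @export
read_broadpeak <- read_narrowpeak

#' Write an ENCODE narrowPeak file
#'
#' Writes a 10-column narrowPeak; `score` goes to signalValue, the display
#' score (column 5) is `round(score * 10)` capped at 1000.
#'
#' @param df interval table (optional columns pvalue, qvalue, summit).
#' @param path output path.
#' @export
write_narrowpeak <- function(df, path) {
  validate_intervals(df)
  sig <- ifelse(is.na(df$score), 0, df$score)
  pv <- if ("pvalue" %in% names(df)) df$pvalue else -1
  qv <- if ("qvalue" %in% names(df)) df$qvalue else -1
  smt <- if ("summit" %in% names(df)) {
    ifelse(is.na(df$summit), -1, df$summit - df$start)
  } else -1
  out <- data.frame(df$chrom,
                    format(df$start, scientific = FALSE, trim = TRUE),
                    format(df$end, scientific = FALSE, trim = TRUE),
                    df$name, pmin(1000, round(sig * 10)), df$strand,
                    sig, pv, qv, smt)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' @param path bedGraph path; `track` header lines are skipped.
#' @return data.frame chrom/start/end/value with non-overlapping segments.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track") & !startsWith(lines, "#") &
                   nzchar(lines)]
  df <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  if (any(!is.finite(df$value))) stop("bedGraph contains non-finite values")
  validate_intervals(df)
  df
}

#' Write a bedGraph signal track
#'
#' @param df data.frame chrom/start/end/value.
#' @param path output path.
#' @export
write_bedgraph <- function(df, path) {
  out <- data.frame(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
                    format(df$end, scientific = FALSE, trim = TRUE), df$value)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedpe loop file
#'
#' Six coordinate columns, then optional name and numeric columns; the first
#' numeric column after the name is taken as contact count and the second,
#' when present, as loop significance q.
#'
#' @param path bedpe path.
#' @return data.frame chrom1/start1/end1/chrom2/start2/end2/name/counts/q.
#' @export
read_bedpe <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "")
  if (ncol(df) < 6) stop("bedpe needs at least 6 columns")
  out <- data.frame(chrom1 = as.character(df[[1]]), start1 = df[[2]],
                    end1 = df[[3]], chrom2 = as.character(df[[4]]),
                    start2 = df[[5]], end2 = df[[6]],
                    stringsAsFactors = FALSE)
  out$name <- if (ncol(df) >= 7) as.character(df[[7]]) else "."
  out$counts <- if (ncol(df) >= 8) as.numeric(df[[8]]) else NA_real_
  out$q <- if (ncol(df) >= 9) as.numeric(df[[9]]) else NA_real_
  out
}

#' Write a bedpe loop file
#' @param loops data.frame as returned by [read_bedpe()].
#' @param path output path.
#' @export
write_bedpe <- function(loops, path) {
  out <- loops[, c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                   "name", "counts", "q")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read the sample sheet
#'
#' Tab-separated with header columns `sample`, `lineage`, `assay` and
#' optionally `path`; a leading '#' on the header line is tolerated.
#'
#' @param path sample sheet path.
#' @return data.frame with those columns.
#' @export
read_sample_sheet <- function(path) {
  lines <- readLines(path)
  lines[1] <- sub("^#\\s*", "", lines[1])
  df <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  need <- c("sample", "lineage", "assay")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  df
}

#' Read a gene annotation table
#'
#' Tab-separated with header `gene_id`, `chrom`, `strand`, `tss` (0-based
#' coordinate of the TSS base) and optionally `start`/`end` (gene span).
#'
#' @param path genes TSV path.
#' @return data.frame of genes.
#' @export
read_genes <- function(path) {
  lines <- readLines(path)
  lines[1] <- sub("^#\\s*", "", lines[1])
  df <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  need <- c("gene_id", "chrom", "strand", "tss")
  if (!all(need %in% names(df)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Write a data.frame as TSV with a '#'-prefixed header
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv_commented <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_commented()]
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_commented <- function(path) {
  lines <- readLines(path)
  lines[1] <- sub("^#", "", lines[1])
  utils::read.table(text = lines, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "")
}

#' Read PWMs in JASPAR matrix text format
#'
#' Parses records of the form `>ID NAME` followed by four lines
#' `A [ 1 2 3 ]` ... `T [ ... ]` (counts or probabilities).  Counts are
#' converted to column-stochastic probability matrices.
#'
#' @param path motif file path.
#' @return named list of 4 x L probability matrices (rows A, C, G, T),
#'   named by TF name.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no JASPAR records in ", path)
  out <- list()
  for (k in seq_along(heads)) {
    h <- heads[k]
    fields <- strsplit(sub("^>\\s*", "", lines[h]), "\\s+")[[1]]
    nm <- if (length(fields) >= 2) fields[2] else fields[1]
    rows <- lines[(h + 1):(h + 4)]
    parse_row <- function(r) {
      txt <- sub("^\\s*[ACGT]", "", r)
      as.numeric(regmatches(txt, gregexpr("[0-9.eE+-]+", txt))[[1]])
    }
    mat <- t(vapply(rows, parse_row, numeric(length(parse_row(rows[1])))))
    rownames(mat) <- c("A", "C", "G", "T")
    mat <- sweep(mat, 2, colSums(mat), "/")
    out[[nm]] <- mat
  }
  out
}

#' Write PWMs in JASPAR matrix text format
#'
#' @param pwms named list of 4 x L matrices (rows A, C, G, T).
#' @param path output path.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(pwms)) {
    writeLines(sprintf(">%s %s", nm, nm), con)
    m <- pwms[[nm]]
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(m[b, ], digits = 6), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA path.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)

#' Write a genome FASTA
#' @param seqs named character vector or DNAStringSet.
#' @param path output path.
#' @export
write_genome <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
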