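# Seeded synthetic-data generators.  Every generator is a deterministic
# function of its configuration (including the seed) and returns both the
# simulated inputs and the ground truth that downstream stages are tested
# against: planted differential peaks, true super-enhancer clusters,
# planted motif positions, true gene-CRE link counts, and generating
# promoter quadrants.

default_motif_set <- function() {
  consensus <- c(TFalpha = "ACGGTCAAGT",
                 TFbeta = "CCATGGAATC",
                 TFgamma = "GTTCACGTTG",
                 TFnull = "AGAGAGCTCT")
  lapply(consensus, function(s) {
    b <- strsplit(s, "")[[1]]
    m <- matrix(0.03, 4, length(b), dimnames = list(c("A", "C", "G", "T"), NULL))
    m[cbind(match(b, rownames(m)), seq_along(b))] <- 0.91
    m
  })
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic generators.  Defaults describe
#' the reference simulation: 5 + 5 samples, 5,000 peaks with negative-
#' binomial counts (baseline mean 50 fragments/peak, dispersion 0.1,
#' log-normal(0, 0.25) library-size factors), 250 planted lineage effects
#' at |log2 fold-change| = 4, five planted super-enhancer clusters over
#' 500 background enhancers, a 120 kb motif genome with one reciprocal
#' TF clique, loop effects of 1 expression log2fc unit per looped CRE, and
#' promoter-mark mixtures separated by 6 component standard deviations.
#'
#' @param seed integer master seed.
#' @param n_peaks union-peak count for the count-matrix generator.
#' @param n_samples_per_group samples per lineage (>= 2).
#' @param nb_mean baseline negative-binomial mean per peak.
#' @param nb_dispersion NB dispersion alpha in var = mu + alpha mu^2.
#' @param n_planted_diff number of true lineage-enriched peaks.
#' @param planted_log2fc planted |log2 fold-change|.
#' @param libsize_sdlog sd(log) of library-size factors.
#' @param mean_sdlog sd(log) of per-peak baseline means.
#' @param genome_length motif-genome length in bp.
#' @param se_count planted super-enhancer clusters.
#' @param se_background_peaks background enhancer peaks in the landscape.
#' @param motif_set named list of PWMs (default [default_motif_set()]);
#'   the last entry is left unplanted.
#' @param n_genes_loops genes in the loop/expression generator.
#' @param loop_gene_effect expression log2fc shift per looped CRE.
#' @param loop_noise_sd residual sd of expression log2fc.
#' @param n_promoters genes in the promoter-mark generator.
#' @param mixture_params list with elements `k4` and `k27`, each
#'   `c(mu_low, sigma_low, mu_high, sigma_high, weight_high)`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_peaks = 5000,
                       n_samples_per_group = 5,
                       nb_mean = 50,
                       nb_dispersion = 0.1,
                       n_planted_diff = 250,
                       planted_log2fc = 4,
                       libsize_sdlog = 0.25,
                       mean_sdlog = 0.7,
                       genome_length = 120000,
                       se_count = 5,
                       se_background_peaks = 500,
                       motif_set = default_motif_set(),
                       n_genes_loops = 60,
                       loop_gene_effect = 1,
                       loop_noise_sd = 0.5,
                       n_promoters = 10000,
                       mixture_params = list(
                         k4 = c(mu_low = 2, sigma_low = 1, mu_high = 8,
                                sigma_high = 1, weight_high = 0.55),
                         k27 = c(mu_low = 1, sigma_low = 0.5, mu_high = 4,
                                 sigma_high = 0.5, weight_high = 0.3))) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_peaks > 0, cfg$nb_dispersion > 0, cfg$nb_mean > 0,
            cfg$n_planted_diff >= 0, cfg$genome_length > 0,
            cfg$se_count > 0, cfg$n_promoters > 0)
  for (mk in c("k4", "k27")) {
    w <- cfg$mixture_params[[mk]][["weight_high"]]
    if (!(w > 0 && w < 1)) stop("mixture weight must be in (0, 1)")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate the union-peak count matrix with planted lineage effects
#'
#' Peak baseline means are log-normal around `nb_mean`; counts are
#' negative binomial (var = mu + alpha mu^2) scaled by per-sample
#' log-normal library factors.  `n_planted_diff` randomly chosen peaks
#' carry a group-B mean ratio of `2^planted_log2fc`, alternating in
#' direction.  Peaks are laid on a synthetic chromosome (width 500 bp,
#' gap 1,500 bp) so the matrix can round-trip through interval I/O.
#'
#' @param cfg `sim_config`.
#' @return list: `matrix` (a raw [count_matrix()]), `truth` (data.frame
#'   peak index + direction), `lib_factors`.
#' @export
simulate_count_matrix <- function(cfg) {
  if (cfg$n_samples_per_group < 2)
    stop("n_samples_per_group must be >= 2")
  set.seed(cfg$seed)
  n <- cfg$n_samples_per_group
  mu <- exp(stats::rnorm(cfg$n_peaks, log(cfg$nb_mean), cfg$mean_sdlog))
  lib <- exp(stats::rnorm(2 * n, 0, cfg$libsize_sdlog))
  eff <- rep(1, cfg$n_peaks)
  truth <- data.frame(peak_index = integer(), direction = integer())
  if (cfg$n_planted_diff > 0) {
    idx <- sort(sample.int(cfg$n_peaks, cfg$n_planted_diff))
    dirs <- rep_len(c(1L, -1L), cfg$n_planted_diff)
    eff[idx] <- 2^(cfg$planted_log2fc * dirs)
    truth <- data.frame(peak_index = idx, direction = dirs)
  }
  group <- rep(c("A", "B"), each = n)
  counts <- matrix(0L, cfg$n_peaks, 2 * n)
  for (j in seq_len(2 * n)) {
    m <- mu * lib[j] * (if (group[j] == "B") eff else 1)
    counts[, j] <- stats::rnbinom(cfg$n_peaks, mu = m,
                                  size = 1 / cfg$nb_dispersion)
  }
  peaks <- peak_table("chrSim", (seq_len(cfg$n_peaks) - 1) * 2000,
                      (seq_len(cfg$n_peaks) - 1) * 2000 + 500,
                      name = sprintf("peak_%d", seq_len(cfg$n_peaks)))
  samples <- data.frame(sample = sprintf("%s%d", group, rep(seq_len(n), 2)),
                        lineage = group, stringsAsFactors = FALSE)
  list(matrix = count_matrix(peaks, counts, samples), truth = truth,
       lib_factors = lib)
}

#' Simulate a super-enhancer signal landscape
#'
#' Background enhancer peaks (1 kb wide, 20 kb apart so they never
#' stitch) carry exponential-tailed signal; `se_count` clusters of five
#' closely spaced (2 kb gaps, well under the stitch default) high-signal
#' peaks are inserted at random positions and recorded as true
#' super-enhancers.
#'
#' @param cfg `sim_config`.
#' @return list: `peaks` (interval table with `score`), `truth`
#'   (data.frame of true SE spans with constituent indices).
#' @export
simulate_se_landscape <- function(cfg) {
  if (cfg$se_count > cfg$se_background_peaks / 10)
    stop("se_count too large for the background peak count")
  set.seed(cfg$seed + 1L)
  n_bg <- cfg$se_background_peaks
  slots <- sort(sample.int(n_bg - 1, cfg$se_count))  # insert after these
  chrom <- "chrSE"
  rows <- list(); truth <- list()
  pos <- 0; idx <- 0
  for (i in seq_len(n_bg)) {
    idx <- idx + 1
    rows[[length(rows) + 1]] <- data.frame(
      chrom = chrom, start = pos, end = pos + 1000,
      name = sprintf("bg_%d", i),
      score = 0.5 + stats::rexp(1, rate = 2), strand = ".",
      stringsAsFactors = FALSE)
    pos <- pos + 1000 + 20000
    if (i %in% slots) {
      k <- which(slots == i)
      first <- idx + 1
      se_start <- pos
      for (p in 1:5) {
        idx <- idx + 1
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chrom, start = pos, end = pos + 1000,
          name = sprintf("se%d_p%d", k, p),
          score = 200 + stats::rexp(1, rate = 0.02), strand = ".",
          stringsAsFactors = FALSE)
        pos <- pos + 1000 + 2000
      }
      truth[[k]] <- data.frame(chrom = chrom, start = se_start,
                               end = pos - 2000,
                               first_peak = first, last_peak = idx,
                               stringsAsFactors = FALSE)
      pos <- pos + 18000   # restore wide gap after the cluster
    }
  }
  list(peaks = do.call(rbind, rows), truth = do.call(rbind, truth))
}

plant_site <- function(seq_chars, at, consensus) {
  seq_chars[at:(at + nchar(consensus) - 1)] <- strsplit(consensus, "")[[1]]
  seq_chars
}

pwm_consensus <- function(pwm) {
  paste(rownames(pwm)[apply(pwm, 2, which.max)], collapse = "")
}

#' Simulate a genome with motifs planted in open chromatin within SEs
#'
#' Background sequence is i.i.d. uniform ACGT.  Each TF of the motif set
#' except the last receives a super-enhancer containing two ATAC peaks;
#' the consensus site of every planted TF (including itself) is written
#' into each TF's first ATAC peak, producing one fully reciprocal,
#' auto-regulated TF clique.  The last TF of the set is left without
#' planted sites as a negative control, and one background ATAC peak
#' outside all SEs carries no sites.
#'
#' @param cfg `sim_config`.
#' @return list: `genome` (DNAStringSet, one chromosome `chrM1`), `atac`
#'   (interval table), `se_map` (named list TF -> SE interval table),
#'   `genes` (TF gene table), `pwms` (the motif set), `truth` (data.frame
#'   of planted sites: tf, target, chrom, start, end).
#' @export
simulate_motif_genome <- function(cfg) {
  set.seed(cfg$seed + 2L)
  chrom <- "chrM1"
  seq_chars <- sample(c("A", "C", "G", "T"), cfg$genome_length, replace = TRUE)
  pwms <- cfg$motif_set
  planted_tfs <- utils::head(names(pwms), -1)
  se_len <- 6000
  pitch <- 30000
  if (cfg$genome_length < 10000 + length(planted_tfs) * pitch)
    stop("genome_length too small for the motif layout")
  se_map <- list(); atac <- list(); genes <- list(); truth <- list()
  # background ATAC peak with no planted sites
  atac[["bg"]] <- data.frame(chrom = chrom, start = 5000, end = 5400,
                             name = "atac_bg", score = 5, strand = ".",
                             stringsAsFactors = FALSE)
  for (i in seq_along(planted_tfs)) {
    tf <- planted_tfs[i]
    se_start <- 10000 + (i - 1) * pitch
    se_map[[tf]] <- peak_table(chrom, se_start, se_start + se_len,
                               name = paste0("SE_", tf))
    a1 <- se_start + 1000; a2 <- se_start + 3500
    atac[[paste0(tf, "_1")]] <- data.frame(chrom = chrom, start = a1,
                                           end = a1 + 400,
                                           name = paste0("atac_", tf, "_1"),
                                           score = 10, strand = ".",
                                           stringsAsFactors = FALSE)
    atac[[paste0(tf, "_2")]] <- data.frame(chrom = chrom, start = a2,
                                           end = a2 + 400,
                                           name = paste0("atac_", tf, "_2"),
                                           score = 10, strand = ".",
                                           stringsAsFactors = FALSE)
    genes[[tf]] <- data.frame(gene_id = tf, chrom = chrom, strand = "+",
                              tss = se_start - 3000,
                              start = se_start - 3000, end = se_start - 500,
                              stringsAsFactors = FALSE)
    # plant every clique member's consensus in this TF's first ATAC peak
    at <- a1 + 20
    for (reg in planted_tfs) {
      cons <- pwm_consensus(pwms[[reg]])
      seq_chars <- plant_site(seq_chars, at + 1, cons)   # 1-based substring
      truth[[length(truth) + 1]] <- data.frame(
        tf = reg, target = tf, chrom = chrom, start = at,
        end = at + nchar(cons), stringsAsFactors = FALSE)
      at <- at + nchar(cons) + 15
    }
  }
  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(seq_chars, collapse = ""), chrom))
  list(genome = genome, atac = do.call(rbind, atac), se_map = se_map,
       genes = do.call(rbind, genes), pwms = pwms,
       truth = do.call(rbind, truth))
}

#' Simulate loops and loop-dependent differential expression
#'
#' Each gene receives k in 0..5 distinct looped CREs (cycling so every
#' bin is populated); its expression log2 fold-change is
#' `k * loop_gene_effect` plus Gaussian noise.  Loops anchor a 5 kb bin
#' over the promoter window and a 5 kb bin over each CRE peak.
#'
#' @param cfg `sim_config`.
#' @return list: `loops` (bedpe-style data.frame), `peaks` (CRE interval
#'   table), `genes` (gene table with strand), `expression` (data.frame
#'   gene_id/log2fc), `truth` (data.frame gene_id/k).
#' @export
simulate_loops_expression <- function(cfg) {
  set.seed(cfg$seed + 3L)
  n <- cfg$n_genes_loops
  chrom <- "chrL1"
  ks <- rep_len(0:5, n)[sample.int(n)]
  genes <- data.frame(gene_id = sprintf("gene_%03d", seq_len(n)),
                      chrom = chrom,
                      strand = rep_len(c("+", "-"), n),
                      tss = 100000 * seq_len(n) + 50000,
                      stringsAsFactors = FALSE)
  genes$start <- ifelse(genes$strand == "+", genes$tss, genes$tss - 20000)
  genes$end <- ifelse(genes$strand == "+", genes$tss + 20000, genes$tss + 1)
  peaks <- list(); loops <- list()
  for (i in seq_len(n)) {
    if (ks[i] == 0) next
    tss <- genes$tss[i]
    # promoter anchor: 5 kb bin covering the upstream window
    pa_start <- if (genes$strand[i] == "+") tss - 5000 else tss + 1
    for (j in seq_len(ks[i])) {
      cre_start <- tss + 30000 + 10000 * (j - 1)
      nm <- sprintf("cre_%03d_%d", i, j)
      peaks[[nm]] <- data.frame(chrom = chrom, start = cre_start,
                                end = cre_start + 1000, name = nm,
                                score = 10, strand = ".",
                                stringsAsFactors = FALSE)
      loops[[length(loops) + 1]] <- data.frame(
        chrom1 = chrom, start1 = pa_start, end1 = pa_start + 5000,
        chrom2 = chrom, start2 = cre_start - 2000, end2 = cre_start + 3000,
        name = sprintf("loop_%03d_%d", i, j),
        counts = 5 + stats::rpois(1, 10), q = 0.001,
        stringsAsFactors = FALSE)
    }
  }
  expr <- data.frame(gene_id = genes$gene_id,
                     log2fc = ks * cfg$loop_gene_effect +
                       stats::rnorm(n, 0, cfg$loop_noise_sd),
                     stringsAsFactors = FALSE)
  list(loops = do.call(rbind, loops), peaks = do.call(rbind, peaks),
       genes = genes, expression = expr,
       truth = data.frame(gene_id = genes$gene_id, k = ks,
                          stringsAsFactors = FALSE))
}

#' Simulate promoter H3K4me3/H3K27me3 signal with known quadrants
#'
#' Per-gene H3K4me3 and H3K27me3 TSS-window means are drawn from the
#' configured two-component Gaussians; the generating components define
#' the true quadrant (high K4 + high K27 = bivalent, etc.).
#'
#' @param cfg `sim_config`.
#' @param genes optional gene table; by default `n_promoters` genes are
#'   laid 6 kb apart on `chrP1`.
#' @return list: `signals` (data.frame gene_id/tss/k4/k27), `genes`,
#'   `truth` (data.frame with component indicators and quadrant).
#' @export
simulate_promoter_marks <- function(cfg, genes = NULL) {
  set.seed(cfg$seed + 4L)
  if (is.null(genes)) {
    n <- cfg$n_promoters
    genes <- data.frame(gene_id = sprintf("prom_%05d", seq_len(n)),
                        chrom = "chrP1", strand = "+",
                        tss = 6000 * seq_len(n),
                        stringsAsFactors = FALSE)
  }
  n <- nrow(genes)
  p4 <- cfg$mixture_params$k4
  p27 <- cfg$mixture_params$k27
  k4_high <- stats::rbinom(n, 1, p4[["weight_high"]]) == 1
  k4 <- ifelse(k4_high,
               stats::rnorm(n, p4[["mu_high"]], p4[["sigma_high"]]),
               stats::rnorm(n, p4[["mu_low"]], p4[["sigma_low"]]))
  k27_high <- stats::rbinom(n, 1, p27[["weight_high"]]) == 1
  k27 <- ifelse(k27_high,
                stats::rnorm(n, p27[["mu_high"]], p27[["sigma_high"]]),
                stats::rnorm(n, p27[["mu_low"]], p27[["sigma_low"]]))
  quadrant <- ifelse(k4_high & k27_high, "bivalent",
                     ifelse(k4_high, "active",
                            ifelse(k27_high, "repressed", "unmarked")))
  # planted lineage expression: upregulation enriched at bivalent promoters
  p_up <- ifelse(quadrant == "bivalent", 0.3, 0.05)
  up <- stats::rbinom(n, 1, p_up) == 1
  expr <- data.frame(gene_id = genes$gene_id,
                     log2fc = ifelse(up, stats::rnorm(n, 4, 0.3),
                                     stats::rnorm(n, 0, 0.5)),
                     padj = ifelse(up, 1e-8, 0.5),
                     stringsAsFactors = FALSE)
  list(signals = data.frame(gene_id = genes$gene_id, tss = genes$tss,
                            k4 = k4, k27 = k27, stringsAsFactors = FALSE),
       genes = genes, expression = expr,
       truth = data.frame(gene_id = genes$gene_id, k4_high = k4_high,
                          k27_high = k27_high, quadrant = quadrant,
                          upregulated = up, stringsAsFactors = FALSE))
}

#' Signal tracks carrying the simulated promoter marks
#'
#' Writes each gene's simulated mark level as a constant bedGraph segment
#' over its TSS +/- 2 kb so the values can be recovered with
#' [aggregate_profile()].
#'
#' @param marks result of [simulate_promoter_marks()].
#' @param flank half-window in bp (default 2000).
#' @return list of two bedGraph data.frames, `k4` and `k27`.
#' @export
promoter_mark_tracks <- function(marks, flank = 2000) {
  s <- marks$signals
  mk <- function(v) data.frame(chrom = "chrP1",
                               start = pmax(s$tss - flank, 0),
                               end = s$tss + flank, value = v,
                               stringsAsFactors = FALSE)
  list(k4 = mk(s$k4), k27 = mk(s$k27))
}

#' Write a complete simulated input directory
#'
#' Runs every generator under `cfg` and writes a self-contained directory
#' of standard-format inputs plus `truth.json`: per-sample
#' `peaks/*.narrowPeak` and `fragments/*.bed`, `tracks/*.bedGraph`,
#' `loops.bedpe`, `genome.fa`, `motifs.jaspar`, `genes.tsv`,
#' `expression.tsv`, `samples.tsv`.
#'
#' @param cfg `sim_config`.
#' @param dir output directory (created).
#' @return invisibly, the list of written paths.
#' @export
write_simulation <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("peaks", "fragments", "tracks"))
    dir.create(file.path(dir, d), showWarnings = FALSE)
  paths <- character()
  add <- function(p) { paths <<- c(paths, p); p }

  cm <- simulate_count_matrix(cfg)
  m <- cm$matrix
  for (j in seq_len(ncol(m$counts))) {
    s <- m$samples$sample[j]
    pk <- m$peaks
    pk$score <- 5 + 15 * (m$counts[, j] > stats::quantile(m$counts[, j], 0.9))
    write_narrowpeak(pk, add(file.path(dir, "peaks",
                                       paste0(s, ".narrowPeak"))))
    cnt <- m$counts[, j]
    frag <- data.frame(chrom = rep(pk$chrom, cnt),
                       start = rep(pk$start + 10, cnt),
                       end = rep(pk$start + 210, cnt),
                       name = ".", score = 0, strand = ".",
                       stringsAsFactors = FALSE)
    write_bed(frag, add(file.path(dir, "fragments", paste0(s, ".bed"))))
  }
  utils::write.table(
    data.frame(sample = m$samples$sample, lineage = m$samples$lineage,
               assay = "H3K27ac",
               path = file.path("fragments", paste0(m$samples$sample, ".bed"))),
    add(file.path(dir, "samples.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)

  se <- simulate_se_landscape(cfg)
  write_narrowpeak(se$peaks, add(file.path(dir, "peaks", "se_landscape.narrowPeak")))

  mg <- simulate_motif_genome(cfg)
  write_genome(mg$genome, add(file.path(dir, "genome.fa")))
  write_jaspar(mg$pwms, add(file.path(dir, "motifs.jaspar")))
  write_narrowpeak(mg$atac, add(file.path(dir, "peaks", "atac.narrowPeak")))

  mg_ses <- do.call(rbind, lapply(names(mg$se_map), function(tf) {
    se <- mg$se_map[[tf]]; se$name <- tf; se
  }))
  write_bed(mg_ses, add(file.path(dir, "peaks", "tf_ses.bed")))

  lp <- simulate_loops_expression(cfg)
  write_bedpe(lp$loops, add(file.path(dir, "loops.bedpe")))
  write_narrowpeak(lp$peaks, add(file.path(dir, "peaks", "cres.narrowPeak")))
  pm <- simulate_promoter_marks(cfg)
  expr <- rbind(cbind(lp$expression, padj = 1), pm$expression)
  write_tsv_commented(expr, add(file.path(dir, "expression.tsv")))
  genes <- rbind(lp$genes[, c("gene_id", "chrom", "strand", "tss")],
                 mg$genes[, c("gene_id", "chrom", "strand", "tss")],
                 pm$genes[, c("gene_id", "chrom", "strand", "tss")])
  write_tsv_commented(genes, add(file.path(dir, "genes.tsv")))
  tracks <- promoter_mark_tracks(pm)
  write_bedgraph(tracks$k4, add(file.path(dir, "tracks", "k4me3.bedGraph")))
  write_bedgraph(tracks$k27, add(file.path(dir, "tracks", "k27me3.bedGraph")))

  truth <- list(seed = cfg$seed,
                planted_diff = cm$truth,
                se_regions = se$truth,
                motif_sites = mg$truth,
                loop_links = lp$truth,
                promoter_quadrants = pm$truth)
  jsonlite::write_json(truth, add(file.path(dir, "truth.json")),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
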