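# End-to-end pipeline: simulate -> differential CREs -> super-enhancers ->
# regulatory cliques -> loop assignment -> promoter bivalency, with a
# manifest recording every output file hash, seed and threshold used.

#' Run the full synthetic-to-results pipeline
#'
#' Writes a simulated input directory under `outdir/sim`, then runs every
#' analysis stage on those files exactly as it would run on real data:
#' union count matrix + NB differential test + enrichment calls;
#' super-enhancer stitching and hockey-stick calling; PWM scanning, clique
#' enumeration and clique enrichment scores; loop-to-promoter assignment
#' and the looped-CRE expression association; and promoter-state
#' classification with the bivalent enrichment test.  All randomness
#' derives from `cfg$seed`; rerunning with the same configuration
#' reproduces every output hash.
#'
#' @param cfg `sim_config` describing the simulation and seed.
#' @param outdir output directory (created; stages write into
#'   subdirectories).
#' @param preset enrichment preset for the differential stage (default
#'   "h3k27ac").
#' @param quantile apply quantile normalization before the differential
#'   test (default FALSE; fold-change recovery is only interpretable on a
#'   scale-preserving normalization, see the vignette).
#' @return the manifest, invisibly: a list with `seed`, `thresholds`,
#'   `files` (data.frame path/md5) and per-stage summaries.
#' @export
run_pipeline <- function(cfg = sim_config(), outdir, preset = "h3k27ac",
                         quantile = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim_dir <- file.path(outdir, "sim")
  res_dir <- file.path(outdir, "results")
  dir.create(res_dir, showWarnings = FALSE)
  write_simulation(cfg, sim_dir)
  outputs <- character()
  add <- function(p) { outputs <<- c(outputs, p); p }
  summaries <- list()

  ## differential CREs -------------------------------------------------
  sheet <- read_sample_sheet(file.path(sim_dir, "samples.tsv"))
  peak_sets <- lapply(stats::setNames(sheet$sample, sheet$sample), function(s)
    read_narrowpeak(file.path(sim_dir, "peaks", paste0(s, ".narrowPeak"))))
  fragments <- lapply(stats::setNames(sheet$sample, sheet$sample), function(s)
    read_bed(file.path(sim_dir, "fragments", paste0(s, ".bed"))))
  m <- build_union_matrix(peak_sets, fragments, sheet)
  m <- normalize_libsize(m)
  if (quantile) m <- quantile_normalize(m)
  thr <- cre_preset(preset)
  res <- call_enriched(nb_differential(m, contrast = c("A", "B")),
                       thr$lfc, thr$padj)
  write_bed(m$peaks, add(file.path(res_dir, "union_peaks.bed")))
  write_tsv_commented(res, add(file.path(res_dir, "differential.tsv")))
  summaries$differential <- table(res$label)

  ## super-enhancers ----------------------------------------------------
  land <- read_narrowpeak(file.path(sim_dir, "peaks",
                                    "se_landscape.narrowPeak"))
  se <- call_superenhancers(stitch_peaks(land))
  write_tsv_commented(se[, c("chrom", "start", "end", "name", "signal",
                             "rank", "is_super")],
                      add(file.path(res_dir, "stitched.tsv")))
  summaries$superenhancers <- sum(se$is_super)

  ## core regulatory circuitry ------------------------------------------
  genome <- read_genome(file.path(sim_dir, "genome.fa"))
  pwms <- read_jaspar(file.path(sim_dir, "motifs.jaspar"))
  atac <- read_narrowpeak(file.path(sim_dir, "peaks", "atac.narrowPeak"))
  tf_ses <- read_bed(file.path(sim_dir, "peaks", "tf_ses.bed"))
  se_map <- lapply(split(tf_ses, tf_ses$name), identity)
  hits <- lapply(pwms, function(p) scan_pwm(genome, atac, p))
  g <- build_crc_graph(se_map, atac, hits, expressed = names(se_map))
  cliques <- enumerate_cliques(g)
  ces <- clique_enrichment(cliques, tfs = g$nodes)
  write_tsv_commented(g$edges, add(file.path(res_dir, "edges.tsv")))
  writeLines(vapply(cliques, paste, "", collapse = ","),
             add(file.path(res_dir, "cliques.txt")))
  write_tsv_commented(data.frame(tf = names(ces), ces = as.numeric(ces)),
                      add(file.path(res_dir, "ces.tsv")))
  summaries$cliques <- length(cliques)

  ## loops ---------------------------------------------------------------
  loops <- load_loops(file.path(sim_dir, "loops.bedpe"))
  genes <- read_genes(file.path(sim_dir, "genes.tsv"))
  cres <- read_narrowpeak(file.path(sim_dir, "peaks", "cres.narrowPeak"))
  expr <- read_tsv_commented(file.path(sim_dir, "expression.tsv"))
  loop_genes <- genes[startsWith(genes$gene_id, "gene_"), , drop = FALSE]
  links <- assign_promoter_loops(loops, loop_genes, cres)
  fc <- stats::setNames(expr$log2fc, expr$gene_id)
  assoc <- loop_expression_association(links$n_links, fc)
  write_tsv_commented(data.frame(gene_id = names(links$n_links),
                                 n_links = as.integer(links$n_links)),
                      add(file.path(res_dir, "gene_links.tsv")))
  writeLines(c(sprintf("wilcoxon_statistic\t%g", assoc$statistic),
               sprintf("p_value\t%g", assoc$p),
               sprintf("significant\t%s", assoc$significant)),
             add(file.path(res_dir, "association.txt")))
  summaries$loop_association_p <- assoc$p

  ## bivalency -----------------------------------------------------------
  k4_track <- read_bedgraph(file.path(sim_dir, "tracks", "k4me3.bedGraph"))
  k27_track <- read_bedgraph(file.path(sim_dir, "tracks", "k27me3.bedGraph"))
  prom_genes <- genes[startsWith(genes$gene_id, "prom_"), , drop = FALSE]
  anchors <- peak_table(prom_genes$chrom, prom_genes$tss,
                        prom_genes$tss + 1, name = prom_genes$gene_id)
  sig <- data.frame(gene_id = prom_genes$gene_id,
                    k4 = aggregate_profile(k4_track, anchors, 2000, 1)[, 1],
                    k27 = aggregate_profile(k27_track, anchors, 2000, 1)[, 1],
                    stringsAsFactors = FALSE)
  ps <- promoter_states(sig)
  up <- upregulated_genes(expr)
  enr <- bivalent_enrichment_test(ps$states, up)
  write_tsv_commented(ps$states[, c("gene_id", "k4", "k27", "quadrant")],
                      add(file.path(res_dir, "promoter_states.tsv")))
  jsonlite::write_json(list(
    k4 = ps$k4_fit[c("mu_low", "sigma_low", "mu_high", "sigma_high",
                     "weight_high", "converged")],
    k27 = ps$k27_fit[c("mu_low", "sigma_low", "mu_high", "sigma_high",
                       "weight_high", "converged")],
    cutoffs = ps$cutoffs),
    add(file.path(res_dir, "mixture_fits.json")), auto_unbox = TRUE,
    digits = NA)
  writeLines(c(sprintf("chi_squared\t%g", enr$statistic),
               sprintf("p_value\t%g", enr$p)),
             add(file.path(res_dir, "enrichment.txt")))
  summaries$bivalent_enrichment_p <- enr$p

  ## manifest ------------------------------------------------------------
  files <- data.frame(path = file.path("results", basename(outputs)),
                      md5 = unname(tools::md5sum(outputs)),
                      stringsAsFactors = FALSE)
  manifest <- list(seed = cfg$seed,
                   thresholds = list(preset = preset, lfc = thr$lfc,
                                     padj = thr$padj,
                                     stitch_dist = 12500,
                                     pwm_threshold_frac = 0.7,
                                     loop_span = c(5000, 3e6),
                                     cutoff_sd = 4),
                   quantile_normalized = quantile,
                   files = files,
                   summaries = summaries)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       force = TRUE)
  invisible(manifest)
}
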