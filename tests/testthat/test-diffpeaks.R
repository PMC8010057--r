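two_group_samples <- function(n = 2) {
  data.frame(sample = c(paste0("A", 1:n), paste0("B", 1:n)),
             lineage = rep(c("A", "B"), each = n), stringsAsFactors = FALSE)
}

test_that("union matrix merges overlapping peaks across samples", {
  samples <- two_group_samples()
  frag <- peak_table("chr1", 10, 60)
  peak_sets <- list(A1 = peak_table("chr1", 0, 100),
                    A2 = peak_table("chr1", 50, 150),
                    B1 = peak_table("chr1", 0, 100),
                    B2 = peak_table("chr1", 300, 400))
  fragments <- list(A1 = frag, A2 = frag, B1 = frag, B2 = frag)
  m <- build_union_matrix(peak_sets, fragments, samples)
  expect_equal(m$peaks$start, c(0, 300))
  expect_equal(m$peaks$end, c(150, 400))
  expect_equal(unname(m$counts[, "A1"]), c(1L, 0L))
  # identical single peaks collapse to one
  ps <- list(A1 = peak_table("chr1", 0, 100), B1 = peak_table("chr1", 0, 100))
  m2 <- build_union_matrix(ps, fragments[c("A1", "B1")],
                           two_group_samples(1))
  expect_equal(nrow(m2$peaks), 1)
})

test_that("library-size normalization scales columns to the mean total", {
  m <- count_matrix(peak_table("chr1", c(0, 200), c(100, 300)),
                    matrix(c(40L, 60L, 80L, 120L), 2),
                    two_group_samples(1))
  n <- normalize_libsize(m)
  # totals 100 and 200, mean 150: columns scaled by 1.5 and 0.75
  expect_equal(unname(n$counts[, 1]), c(60, 90))
  expect_equal(unname(n$counts[, 2]), c(60, 90))
  expect_equal(n$counts[2, ] / n$counts[1, ], m$counts[2, ] / m$counts[1, ])
  m0 <- count_matrix(peak_table("chr1", 0, 100), matrix(c(0L, 5L), 1),
                     two_group_samples(1))
  expect_error(normalize_libsize(m0), "zero library total")
})

test_that("quantile normalization maps the hand example and handles ties", {
  m <- count_matrix(peak_table("chr1", c(0, 200, 400), c(100, 300, 500)),
                    cbind(c(1L, 2L, 3L), c(4L, 5L, 6L)),
                    two_group_samples(1))
  q <- quantile_normalize(m)
  expect_equal(unname(q$counts[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(q$counts[, 2]), c(2.5, 3.5, 4.5))
  # identical columns unchanged
  mi <- m; mi$counts <- cbind(c(1L, 5L, 9L), c(1L, 5L, 9L))
  expect_equal(quantile_normalize(mi)$counts, mi$counts, ignore_attr = TRUE)
  # ties share one value equal to the rank-range mean of the reference
  mt <- m; mt$counts <- cbind(c(1L, 1L, 3L), c(4L, 5L, 6L))
  qt <- quantile_normalize(mt)$counts
  expect_equal(qt[1, 1], qt[2, 1])
  expect_equal(unname(qt), quantile_oracle(mt$counts), tolerance = 1e-12)
})

test_that("sorted columns agree exactly on tie-free matrices", {
  set.seed(5)
  counts <- matrix(rgamma(1000 * 8, 4, 1 / 8), 1000)
  m <- count_matrix(peak_table("chr1", 200 * (0:999), 200 * (0:999) + 100),
                    counts, two_group_samples(4), normalized = "libsize")
  q <- quantile_normalize(m)$counts
  ref <- sort(q[, 1])
  for (j in 2:8) expect_lt(max(abs(sort(q[, j]) - ref)), 1e-12)
  # tie-free result agrees with the standard limma implementation
  expect_equal(unname(q), limma::normalizeQuantiles(counts),
               tolerance = 1e-12)
})

test_that("NB test is calibrated and recovers planted effects", {
  cfg <- sim_config(seed = 101, n_peaks = 3000, n_planted_diff = 150)
  cm <- simulate_count_matrix(cfg)
  m <- normalize_libsize(cm$matrix)
  r <- call_enriched(nb_differential(m, c("A", "B")), 3, 0.001)
  called <- which(r$label != "not_called")
  sens <- mean(cm$truth$peak_index %in% called)
  expect_gte(sens, 0.9)
  if (length(called) > 0)
    expect_lte(mean(!(called %in% cm$truth$peak_index)), 0.1)
  # direction: planted-up peaks labeled enriched_in_B
  up <- cm$truth$peak_index[cm$truth$direction == 1]
  expect_true(all(r$label[intersect(up, called)] == "enriched_in_B"))
})

test_that("constant matrices give zero fold-changes and p = 1 at zeros", {
  counts <- matrix(7L, 10, 4)
  counts[1, ] <- 0L
  m <- count_matrix(peak_table("chr1", 200 * (0:9), 200 * (0:9) + 100),
                    counts, two_group_samples(2))
  r <- nb_differential(m, c("A", "B"))
  expect_equal(r$log2fc, rep(0, 10))
  expect_equal(r$p[1], 1)
  expect_error(nb_differential(m, c("A", "C")), ">= 2 samples")
})

test_that("BH adjustment keeps padj >= p and label flips with contrast", {
  cfg <- sim_config(seed = 102, n_peaks = 500, n_planted_diff = 50)
  m <- normalize_libsize(simulate_count_matrix(cfg)$matrix)
  r <- nb_differential(m, c("A", "B"))
  expect_true(all(r$padj >= r$p - 1e-15))
  ord <- order(r$p)
  expect_true(all(diff(r$padj[ord]) >= -1e-12))
  fwd <- call_enriched(r, 3, 0.001)
  rev <- call_enriched(nb_differential(m, c("B", "A")), 3, 0.001)
  expect_equal(fwd$label == "enriched_in_B", rev$label == "enriched_in_A")
  expect_equal(fwd$log2fc, -rev$log2fc, tolerance = 1e-12)
})

test_that("enrichment presets apply the printed strict thresholds", {
  r <- data.frame(peak = c("p1", "p2", "p3"),
                  base_mean = 10, log2fc = c(3.1, 2.9, 2.5),
                  p = 1e-10, padj = c(1e-4, 1e-9, 1e-4))
  h <- cre_preset("h3k27ac")
  lab <- call_enriched(r, h$lfc, h$padj)$label
  expect_equal(lab, c("enriched_in_B", "not_called", "not_called"))
  f <- cre_preset("foxa1")
  expect_equal(call_enriched(r, f$lfc, f$padj)$label[3], "enriched_in_B")
  expect_equal(cre_preset("h3k27me3"), list(lfc = 1, padj = 0.01))
})

test_that("sample clustering is rank-based and separates groups", {
  cfg <- sim_config(seed = 103, n_peaks = 400, n_planted_diff = 80)
  m <- normalize_libsize(simulate_count_matrix(cfg)$matrix)
  cl <- cluster_samples(m)
  d <- as.matrix(cl$dist)
  # duplicated sample: distance 0
  m2 <- m; m2$counts[, 2] <- m2$counts[, 1]
  expect_equal(as.matrix(cluster_samples(m2)$dist)[1, 2], 0)
  # monotone transform of one column leaves its distances unchanged
  m3 <- m; m3$counts[, 3] <- m3$counts[, 3]^2 + 1
  expect_equal(as.matrix(cluster_samples(m3)$dist)[, 3], d[, 3])
  # top split separates lineages
  groups <- cutree(cl$hclust, 2)
  expect_equal(length(unique(groups[m$samples$lineage == "A"])), 1)
  expect_equal(length(unique(groups[m$samples$lineage == "B"])), 1)
  mc <- m; mc$counts[, 1] <- 5
  expect_error(cluster_samples(mc), "A1")
})

test_that("multi-state comparison defines shared peaks correctly", {
  set.seed(9)
  n_peak <- 60
  states <- c("normal", "localized", "metastatic")
  samples <- data.frame(sample = paste0("s", 1:9),
                        lineage = rep(states, each = 3))
  mu <- rep(50, n_peak)
  counts <- sapply(1:9, function(j) rpois(n_peak, mu))
  # peak 1 much higher in metastatic only
  counts[1, 7:9] <- counts[1, 7:9] * 40
  # peak 2 absent (not called) in normal
  presence <- matrix(TRUE, n_peak, 3)
  presence[2, 1] <- FALSE
  m <- count_matrix(peak_table("chr1", 200 * seq_len(n_peak),
                               200 * seq_len(n_peak) + 100,
                               name = sprintf("p%d", seq_len(n_peak))),
                    counts, samples)
  out <- multi_state_compare(m, states, presence)
  expect_equal(names(out$comparisons),
               c("normal_vs_localized", "localized_vs_metastatic"))
  shared_names <- out$shared$name
  expect_false(m$peaks$name[1] %in% shared_names)  # significant in one pair
  expect_false(m$peaks$name[2] %in% shared_names)  # absent from one state
  expect_true(m$peaks$name[3] %in% shared_names)
  expect_error(multi_state_compare(m, c("normal", "missing"), presence[, 1:2]),
               "missing")
})
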