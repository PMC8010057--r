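test_that("stitching joins gaps up to the stitch distance", {
  near <- peak_table("chr1", c(0, 13400), c(1000, 14400), score = 1)
  far <- peak_table("chr1", c(0, 13600), c(1000, 14600), score = 1)
  expect_equal(nrow(stitch_peaks(near)), 1)   # gap 12,400
  expect_equal(nrow(stitch_peaks(far)), 2)    # gap 12,600
  single <- peak_table("chr1", 5, 105, score = 2)
  st <- stitch_peaks(single)
  expect_equal(st[, c("start", "end")], data.frame(start = 5, end = 105))
  chain <- peak_table("chr1", c(0, 11000, 22000), c(1000, 12000, 23000),
                      score = 1)
  st3 <- stitch_peaks(chain)   # transitive 10 kb gaps
  expect_equal(nrow(st3), 1)
  expect_equal(st3$end - st3$start, 23000)
  expect_equal(st3$n_constituents, 3)
  expect_error(stitch_peaks(chain, stitch_dist = -1), ">= 0")
})

test_that("stitching is idempotent and separates regions by > stitch_dist", {
  set.seed(12)
  starts <- sort(sample.int(5e5, 80)) * 3
  peaks <- peak_table("chr1", starts, starts + 500, score = rexp(80))
  st <- stitch_peaks(peaks)
  gaps <- st$start[-1] - st$end[-nrow(st)]
  expect_true(all(gaps > 12500))
  st2 <- stitch_peaks(peak_table(st$chrom, st$start, st$end, score = st$signal))
  expect_equal(st2$start, st$start)
  expect_equal(st2$end, st$end)
})

test_that("TSS-proximal peaks never bridge two regions", {
  # two 1 kb peaks 20 kb apart with a TSS peak centered between them
  peaks <- peak_table("chr1", c(0, 10000, 21000), c(1000, 11000, 22000),
                      score = 1)
  tss <- data.frame(chrom = "chr1", tss = 10500)
  no_excl <- stitch_peaks(peaks)
  expect_equal(nrow(no_excl), 1)     # middle peak bridges
  excl <- stitch_peaks(peaks, tss = tss)
  expect_equal(nrow(excl), 2)        # bridge removed; TSS peak attaches
  expect_equal(sum(excl$n_constituents), 3)
})

test_that("hockey-stick cutoff matches the geometric oracle", {
  # brute-force oracle: argmax of vertical distance below the unit diagonal
  oracle_cutoff <- function(sig) {
    s <- sort(sig); n <- length(s)
    x <- (seq_len(n) - 1) / (n - 1)
    y <- (s - s[1]) / (s[n] - s[1])
    s[which.max(x - y)]
  }
  set.seed(99)
  for (i in 1:20) {
    sig <- c(rexp(200, 1), 50 + rexp(3, 0.1))
    reg <- data.frame(chrom = "chr1", start = 2e4 * seq_along(sig),
                      end = 2e4 * seq_along(sig) + 1000,
                      name = paste0("r", seq_along(sig)), signal = sig)
    called <- call_superenhancers(reg)
    expect_equal(attr(called, "cutoff"), oracle_cutoff(sig))
  }
})

test_that("one extreme outlier over a flat background is the only SE", {
  reg <- data.frame(chrom = "chr1", start = 2e4 * (1:50),
                    end = 2e4 * (1:50) + 1000,
                    name = paste0("r", 1:50),
                    signal = c(rep(1, 49) + (1:49) * 1e-4, 100))
  called <- call_superenhancers(reg)
  expect_equal(which(called$is_super), 50)
  expect_equal(called$rank[50], 1)
})

test_that("degenerate all-equal curve yields no super-enhancers", {
  reg <- data.frame(chrom = "chr1", start = c(0, 2e4), end = c(1000, 2.1e4),
                    name = c("a", "b"), signal = c(3, 3))
  expect_warning(called <- call_superenhancers(reg), "degenerate")
  expect_false(any(called$is_super))
})

test_that("raising a flagged region's signal never un-flags it", {
  set.seed(13)
  sig <- c(rexp(100), 40, 60, 80)
  reg <- data.frame(chrom = "chr1", start = 2e4 * seq_along(sig),
                    end = 2e4 * seq_along(sig) + 1000,
                    name = paste0("r", seq_along(sig)), signal = sig)
  base <- call_superenhancers(reg)
  flagged <- which(base$is_super)
  for (f in flagged) {
    reg2 <- reg; reg2$signal[f] <- reg2$signal[f] * 2
    expect_true(call_superenhancers(reg2)$is_super[f])
  }
})

test_that("planted SE clusters are recovered from the landscape", {
  se <- simulate_se_landscape(sim_config(seed = 7))
  called <- call_superenhancers(stitch_peaks(se$peaks))
  sup <- called[called$is_super, ]
  ov <- interval_overlap(sup, se$truth[, c("chrom", "start", "end")])
  matched <- length(unique(ov$j))
  jaccard <- matched / (nrow(sup) + nrow(se$truth) - matched)
  expect_gte(jaccard, 0.9)
})

test_that("regions are assigned to the nearest TSS within the cap", {
  genes <- data.frame(gene_id = c("TF1", "geneX", "farGene"),
                      chrom = c("chr1", "chr1", "chr1"),
                      tss = c(9000, 60000, 2e6), stringsAsFactors = FALSE)
  reg <- data.frame(chrom = "chr1", start = 10000, end = 12000,
                    name = "se1", signal = 10, is_super = TRUE)
  out <- assign_se_to_tf(reg, genes, tf_list = "TF1")
  expect_equal(out$gene, "TF1")
  expect_true(out$is_tf_se)
  # > 500 kb from any TSS: unassigned
  reg2 <- data.frame(chrom = "chr1", start = 1e6, end = 1.001e6,
                     name = "se2", signal = 10, is_super = TRUE)
  genes2 <- genes[genes$gene_id != "farGene", ]
  expect_true(is.na(assign_se_to_tf(reg2, genes2, "TF1")$gene))
  # equidistant tie (1000 bp from each region edge) goes to the smaller id
  genes3 <- data.frame(gene_id = c("zz", "aa"), chrom = "chr1",
                       tss = c(9000, 12999), stringsAsFactors = FALSE)
  expect_message(out3 <- assign_se_to_tf(reg, genes3, "aa"), "aa")
  expect_equal(out3$gene, "aa")
  expect_error(assign_se_to_tf(reg, genes, character()), "empty")
})

test_that("rank table records best ranks and worst + 1 for absent TFs", {
  reg_a <- data.frame(gene = c("TF1", "TF2", NA), rank = c(2, 5, 1),
                      is_tf_se = c(TRUE, TRUE, FALSE))
  reg_b <- data.frame(gene = "TF2", rank = 1, is_tf_se = TRUE)
  tab <- tf_se_rank_table(list(sampleA = reg_a, sampleB = reg_b),
                          c("TF1", "TF2"))
  expect_equal(tab["TF1", ], c(sampleA = 2, sampleB = 2))  # worst(1) + 1
  expect_equal(tab["TF2", ], c(sampleA = 5, sampleB = 1))
})

test_that("identical rank distributions give no significant master TFs", {
  set.seed(3)
  tab <- matrix(sample(1:100, 40 * 10, replace = TRUE), 40,
                dimnames = list(paste0("TF", 1:40), paste0("s", 1:10)))
  tab[, 6:10] <- tab[, 1:5]
  out <- se_rank_test(tab, rep(c("NEPC", "PRAD"), each = 5))
  expect_false(any(out$significant))
})

test_that("the 5-vs-11 all-better configuration gives p = 1/4368", {
  set.seed(4)
  n_tf <- 40
  tab <- matrix(sample(100:400, n_tf * 16, replace = TRUE), n_tf,
                dimnames = list(paste0("TF", seq_len(n_tf)), paste0("s", 1:16)))
  tab["TF1", 1:5] <- 1
  tab["TF1", 6:16] <- sample(100:400, 11)
  lineages <- rep(c("NEPC", "PRAD"), c(5, 11))
  out <- se_rank_test(tab, lineages)
  row <- out[out$tf == "TF1" & out$focal == "NEPC", ]
  expect_equal(row$p, 1 / choose(16, 5), tolerance = 1e-12)
  expect_true(row$significant)
})

test_that("rank-test p-values match full enumeration up to (6,6)", {
  set.seed(8)
  for (i in 1:5) {
    x <- sample(1:50, 6); y <- sample(1:50, 6)
    got <- mann_whitney_less(x, y)$p
    expect_equal(got, enum_ranksum_less(x, y), tolerance = 1e-12)
  }
  # with ties
  x <- c(1, 1, 2, 7); y <- c(2, 3, 9, 9)
  expect_equal(mann_whitney_less(x, y)$p, enum_ranksum_less(x, y),
               tolerance = 1e-12)
})

test_that("TFs outside the top median fraction are never tested", {
  # distinct medians 10, 20, ..., 400: only the best ceiling(5%) = 2 enter
  tab <- matrix(rep(10 * (1:40), 6), 40,
                dimnames = list(paste0("TF", 1:40), paste0("s", 1:6)))
  out <- se_rank_test(tab, rep(c("A", "B"), each = 3))
  expect_setequal(unique(out$tf), c("TF1", "TF2"))
  expect_false(any(out$significant))   # identical rank distributions
})
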