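uniform_pwm <- function(L = 8) {
  matrix(0.25, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
}

test_that("PWM scanning finds planted consensus sites", {
  mg <- simulate_motif_genome(sim_config(seed = 5))
  for (tf in c("TFalpha", "TFbeta")) {
    hits <- scan_pwm(mg$genome, mg$atac, mg$pwms[[tf]])
    planted <- mg$truth[mg$truth$tf == tf, ]
    ov <- interval_overlap(planted[, c("chrom", "start", "end")], hits)
    expect_equal(length(unique(ov$i)), nrow(planted))
  }
  expect_equal(nrow(scan_pwm(mg$genome, mg$atac, mg$pwms$TFnull)), 0)
})

test_that("reverse complements hit on the minus strand at the same locus", {
  pwm <- default_motif_set()$TFalpha
  cons <- pwm_consensus(pwm)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  set.seed(2)
  bg <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  seqs <- paste0(substr(bg, 1, 100), rc, substr(bg, 111, 500))
  genome <- Biostrings::DNAStringSet(c(chrT = seqs))
  regions <- peak_table("chrT", 0, 500)
  hits <- scan_pwm(genome, regions, pwm)
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, 100)
  expect_equal(hits$end, 110)
  # forward scan of a sequence == mirrored reverse scan of its complement
  fwd <- scan_pwm(Biostrings::DNAStringSet(c(chrT = cons)),
                  peak_table("chrT", 0, nchar(cons)), pwm)
  expect_equal(fwd$strand, "+")
})

test_that("a uniform PWM scores zero bits so positive thresholds kill hits", {
  genome <- Biostrings::DNAStringSet(c(chrT = "ACGTACGTACGTACGTACGT"))
  hits <- scan_pwm(genome, peak_table("chrT", 0, 20), uniform_pwm(),
                   min_score = 0.5)
  expect_equal(nrow(hits), 0)
  # every offset scores exactly 0 bits
  hits0 <- scan_pwm(genome, peak_table("chrT", 0, 20), uniform_pwm(),
                    min_score = -0.5)
  expect_equal(nrow(hits0), 2 * (20 - 8 + 1))   # both strands
  expect_true(all(abs(hits0$score) < 1e-9))
})

test_that("offsets containing N are skipped with a log message", {
  pwm <- default_motif_set()$TFalpha
  cons <- pwm_consensus(pwm)
  genome <- Biostrings::DNAStringSet(c(chrT = paste0("NNNN", cons, "NNNN")))
  expect_message(hits <- scan_pwm(genome, peak_table("chrT", 0, 18), pwm),
                 "skipped")
  expect_equal(hits$start[hits$strand == "+"], 4)
})

test_that("edges require hits in open chromatin inside the target SE", {
  se_map <- list(TF1 = peak_table("chr1", 0, 10000, name = "SE_TF1"),
                 TF2 = peak_table("chr1", 20000, 30000, name = "SE_TF2"))
  atac <- peak_table("chr1", c(1000, 21000), c(1400, 21400))
  # TF1 motif inside TF2's SE but OUTSIDE open chromatin: no edge
  hits_outside <- list(TF1 = peak_table("chr1", 25000, 25010),
                       TF2 = peak_table("chr1", 21100, 21110))
  g1 <- build_crc_graph(se_map, atac, hits_outside, c("TF1", "TF2"))
  expect_false(any(g1$edges$from == "TF1" & g1$edges$to == "TF2"))
  expect_true(any(g1$edges$from == "TF2" & g1$edges$to == "TF2"))
  expect_true(g1$auto[["TF2"]])
  # same hit moved into atac & SE: edge appears
  hits_inside <- list(TF1 = peak_table("chr1", 21050, 21060))
  g2 <- suppressWarnings(build_crc_graph(se_map, atac, hits_inside,
                                         c("TF1", "TF2")))
  expect_true(any(g2$edges$from == "TF1" & g2$edges$to == "TF2"))
  expect_false(g2$auto[["TF1"]])
  # TF with SE but no PWM keeps its node
  expect_warning(g3 <- build_crc_graph(se_map, atac, hits_inside["TF1"],
                                       c("TF1", "TF2")), "TF2")
  expect_true("TF2" %in% g3$nodes)
})

test_that("cliques require reciprocity and auto-regulation", {
  mk_graph <- function(edges, nodes) {
    structure(list(nodes = nodes,
                   edges = data.frame(from = edges[, 1], to = edges[, 2],
                                      stringsAsFactors = FALSE),
                   auto = vapply(nodes, function(n)
                     any(edges[, 1] == n & edges[, 2] == n), logical(1))),
              class = "crc_graph")
  }
  tri <- rbind(c("A", "A"), c("B", "B"), c("C", "C"),
               c("A", "B"), c("B", "A"), c("B", "C"), c("C", "B"),
               c("A", "C"), c("C", "A"))
  expect_equal(enumerate_cliques(mk_graph(tri, c("A", "B", "C"))),
               list(c("A", "B", "C")))
  # one-way edge breaks the pair
  oneway <- rbind(c("A", "A"), c("B", "B"), c("A", "B"))
  expect_equal(enumerate_cliques(mk_graph(oneway, c("A", "B"))), list())
  # node without a self-edge is excluded even with reciprocal edges
  noauto <- rbind(c("A", "A"), c("B", "B"),
                  c("A", "B"), c("B", "A"), c("A", "C"), c("C", "A"))
  expect_equal(enumerate_cliques(mk_graph(noauto, c("A", "B", "C"))),
               list(c("A", "B")))
})

test_that("clique enumeration matches exhaustive subset search", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(3:8, 1)
    nodes <- LETTERS[seq_len(n)]
    adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      adj[i, j] <- adj[j, i] <- runif(1) < 0.45
    }
    idx <- which(adj, arr.ind = TRUE)
    edges <- rbind(cbind(nodes, nodes),  # all auto-regulated
                   cbind(nodes[idx[, 1]], nodes[idx[, 2]]))
    g <- structure(list(nodes = nodes,
                        edges = data.frame(from = edges[, 1], to = edges[, 2],
                                           stringsAsFactors = FALSE),
                        auto = setNames(rep(TRUE, n), nodes)),
                   class = "crc_graph")
    expect_equal(enumerate_cliques(g), brute_cliques(adj))
  }
})

test_that("clique enrichment scores count membership fractions", {
  cliques <- list(c("A", "B", "C"), c("B", "C", "D"))
  ces <- clique_enrichment(cliques)
  expect_equal(unname(ces[c("A", "B", "C", "D")]), c(0.5, 1, 1, 0.5))
  expect_equal(unname(clique_enrichment(list(c("A", "B")))), c(1, 1))
  expect_equal(unname(clique_enrichment(cliques, tfs = c("A", "Z"))[["Z"]]), 0)
  expect_warning(out <- clique_enrichment(list(), tfs = "A"), "no cliques")
  expect_true(is.na(out[["A"]]))
  # conservation: sum(CES) * n_cliques == sum of clique sizes
  expect_equal(sum(clique_enrichment(cliques)) * length(cliques),
               sum(lengths(cliques)))
})

test_that("CES clustering applies the lineage presence filter", {
  set.seed(6)
  lineages <- rep(c("NEPC", "PRAD"), c(5, 14))
  m <- matrix(runif(4 * 19, 0.1, 1), 4,
              dimnames = list(c("keep45", "drop35", "drop814", "keep1214"),
                              paste0("s", 1:19)))
  m["keep45", 1:5] <- c(0.5, 0.5, 0.5, 0.5, 0)     # 4/5 NEPC
  m["keep45", 6:19] <- 0
  m["drop35", ] <- c(rep(0.5, 3), 0, 0, rep(0.5, 8), rep(0, 6))  # 3/5 & 8/14
  m["drop814", ] <- c(rep(0, 5), rep(0.4, 8), rep(0, 6))          # 8/14 only
  m["keep1214", ] <- c(rep(0, 5), rep(0.4, 12), 0, 0)             # 12/14
  out <- ces_cluster(m, lineages)
  expect_setequal(out$kept, c("keep45", "keep1214"))
  # Canberra distance of identical rows is 0
  m2 <- rbind(a = c(0.2, 0.4, 0.4, 0.3, 0.6), b = c(0.2, 0.4, 0.4, 0.3, 0.6))
  expect_equal(as.numeric(dist(m2, method = "canberra")), 0)
  mz <- matrix(0, 2, 19, dimnames = list(c("x", "y"), colnames(m)))
  expect_error(ces_cluster(mz, lineages), "presence")
})

test_that("motif coverage is the union length over the SE length", {
  ses <- peak_table("chr1", c(0, 50), c(40, 110))   # total 100 bp
  hits <- list(TF1 = peak_table("chr1", c(0, 5), c(10, 15)),
               TF2 = peak_table("chr1", 0, 0.5)[0, ],
               TF3 = peak_table("chr1", 0, 200))
  cov <- motif_coverage(ses, hits)
  expect_equal(unname(cov["TF1"]), 0.15)   # union [0,15) = 15 bp
  expect_equal(unname(cov["TF2"]), 0)
  expect_equal(unname(cov["TF3"]), 1)
  expect_error(motif_coverage(ses[0, ], hits), "zero total")
})

test_that("the planted reciprocal TF clique is recovered end to end", {
  for (seed in c(1, 17, 23)) {
    mg <- simulate_motif_genome(sim_config(seed = seed))
    hits <- lapply(mg$pwms, function(p) scan_pwm(mg$genome, mg$atac, p))
    g <- build_crc_graph(mg$se_map, mg$atac, hits, names(mg$se_map))
    cl <- enumerate_cliques(g)
    expect_true(list(sort(c("TFalpha", "TFbeta", "TFgamma"))) %in% cl ||
                  any(vapply(cl, function(x)
                    all(c("TFalpha", "TFbeta", "TFgamma") %in% x), logical(1))))
  }
})
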