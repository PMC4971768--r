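test_that("promoter flagging matches the 30% coverage rule and a brute-force counter", {
  proms <- data.frame(gene_id = c("a", "b", "c"), chrom = "chr1",
                      start = c(1000, 5000, 9000), end = c(2000, 6000, 10000))
  peaks <- data.frame(chrom = "chr1", start = c(1200, 1600), end = c(1400, 1700))
  # 300 of 1000 bp covered: flagged (inclusive); others untouched
  flags <- flag_promoters(proms, peaks)
  expect_equal(flags, c(TRUE, FALSE, FALSE))
  # brute force agreement on random fixtures
  set.seed(66)
  for (i in 1:50) {
    pk <- data.frame(chrom = "chr1",
                     start = sort(sample(0:9000, 5)))
    pk$end <- pk$start + sample(100:1500, 5, replace = TRUE)
    got <- flag_promoters(proms, pk)
    exp <- vapply(seq_len(nrow(proms)), function(j) {
      oracle_flag_promoter(proms$start[j], proms$end[j], pk, 0.3)
    }, logical(1))
    expect_equal(got, exp)
  }
})

test_that("promoter-pair interactions respect the span threshold and dual flags", {
  segs <- make_segments(30, w = 1000)
  proms <- data.frame(gene_id = c("a", "b", "c"), chrom = "chr1",
                      start = c(500, 10500, 20500), end = c(1500, 11500, 21500))
  flags <- c(TRUE, TRUE, FALSE)
  loops <- data.frame(seg_a = c(1, 11, 1), seg_b = c(11, 21, 6),
                      D = c(10000, 10000, 5000))
  res <- promoter_pair_interactions(loops, segs, proms, flags)
  # loop 3 spans < 6 kb and is excluded; loop 1 is dual-flagged
  expect_equal(res$n_pairs, 2L)
  expect_equal(res$n_dual_flagged, 1L)
  # span 5999 excluded, 6000 included
  l2 <- data.frame(seg_a = 1, seg_b = 7, D = 5999)
  expect_equal(promoter_pair_interactions(l2, segs, proms, flags)$n_pairs, 0L)
  # no promoter overlap at all
  l3 <- data.frame(seg_a = 4, seg_b = 15, D = 11000)
  expect_equal(promoter_pair_interactions(l3, segs, proms, flags)$n_pairs, 0L)
})

test_that("feature shifts wrap circularly and conserve count and length", {
  sizes <- c(chr1 = 10000)
  track <- data.frame(chrom = "chr1", start = c(100, 9500), end = c(600, 9900))
  # identity at offset 0
  s0 <- shift_features(track, 0, sizes)
  expect_equal(s0$start, track$start)
  expect_equal(s0$end, track$end)
  # wrap conserves feature count and covered length
  s <- shift_features(track, 800, sizes)
  expect_equal(length(unique(s$feature_id)), 2L)
  expect_equal(sum(s$end - s$start), sum(track$end - track$start))
  expect_true(all(s$start >= 0 & s$end <= 10000))
  # composing +x then -x restores the original intervals
  back <- shift_features(s, -800, sizes)
  expect_equal(back$start, track$start)
  expect_equal(back$end, track$end)
  expect_error(shift_features(track, 10000, sizes), "smaller")
})

test_that("random shift compositions conserve totals", {
  set.seed(67)
  sizes <- c(chr1 = 50000, chr2 = 30000)
  track <- data.frame(
    chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
    start = sample(0:25000, 30)
  )
  track$end <- track$start + sample(200:3000, 30, replace = TRUE)
  for (off in c(-20000, -10000, 4000, 8000, 10000, 20000)) {
    s <- shift_features(track, off, sizes)
    expect_equal(length(unique(s$feature_id)), 30L)
    expect_equal(sum(s$end - s$start), sum(track$end - track$start))
    back <- shift_features(s, -off, sizes)
    ord <- order(back$feature_id)
    expect_equal(back$start[ord], track$start)
  }
})

test_that("empirical enrichment uses the add-one estimator", {
  expect_equal(empirical_enrichment(10, c(1, 2, 3, 4))$p, 1 / 5)
  expect_equal(empirical_enrichment(0, c(1, 2, 3, 4))$p, 1)
  expect_equal(empirical_enrichment(3, c(1, 2, 3, 4))$p, 3 / 5)
  expect_error(empirical_enrichment(1, numeric(0)), "at least one")
})

test_that("expression shuffling rotates levels within chromosomes", {
  genes <- data.frame(id = letters[1:6], chrom = rep(c("chr1", "chr2"), each = 3),
                      strand = "+", tss = rep(c(100, 200, 300), 2),
                      tts = rep(c(150, 250, 350), 2), expression = c(1, 2, 3, 4, 5, 6))
  # lag 1 down: [a,b,c] -> [b,c,a] per chromosome
  sh <- expression_shuffle(genes, lag = 1, direction = "down")
  expect_equal(sh$expression, c(2, 3, 1, 5, 6, 4))
  # lag equal to the chromosome gene count: identity
  sh3 <- expression_shuffle(genes, lag = 3)
  expect_equal(sh3$expression, genes$expression)
  # up is the inverse of down
  up <- expression_shuffle(sh, lag = 1, direction = "up")
  expect_equal(up$expression, genes$expression)
  # multiset preserved per chromosome under any lag
  sh20 <- expression_shuffle(genes, lag = 20)
  expect_equal(sort(sh20$expression[1:3]), c(1, 2, 3))
})

test_that("signal ratios follow the log ratio with pseudocounts", {
  expect_equal(signal_ratio(c(5, 5), c(5, 5)), c(0, 0))
  # unnormalized: doubled signal gives ln 2 (up to the pseudocount)
  expect_equal(signal_ratio(200, 100, pseudocount = 0, normalize = FALSE),
               log(2))
  expect_error(signal_ratio(1, 0, pseudocount = 0, normalize = FALSE), "pseudocount")
  # depth normalization removes a global scale factor
  expect_equal(signal_ratio(c(200, 400), c(100, 200), pseudocount = 0), c(0, 0))
})

test_that("within-gene and between-gene short loops are separated", {
  segs <- make_segments(30, w = 1000)
  genes <- data.frame(id = c("g1", "g2"), chrom = "chr1", strand = "+",
                      start = c(1000, 9000), end = c(8000, 14000),
                      tss = c(1000, 9000), tts = c(8000, 14000))
  loops <- data.frame(seg_a = c(2, 6, 2, 20), seg_b = c(6, 10, 10, 24),
                      D = c(4000, 4000, 8000, 4000))
  res <- classify_gene_pair_loops(loops, segs, genes)
  # (2,6) inside g1; (6,10) bridges g1-g2; (2,10) is too long; (20,24) is intergenic
  expect_equal(res$n_within_gene, 1L)
  expect_equal(res$n_between_gene, 1L)
  # flag restriction: keep only dual-flagged loops
  flags <- rep(FALSE, 30); flags[c(2, 6)] <- TRUE
  res2 <- classify_gene_pair_loops(loops, segs, genes, flags = flags)
  expect_equal(res2$n_within_gene, 1L)
  expect_equal(res2$n_between_gene, 0L)
})

test_that("dual-enrichment counts use both loop anchors", {
  loops <- data.frame(seg_a = c(1, 2, 3), seg_b = c(4, 5, 6))
  ratios <- c(`1` = 1, `2` = -1, `3` = 2, `4` = 0.5, `5` = 3, `6` = 0.2)
  expect_equal(count_dual_enriched(loops, ratios, lo = 0.1), 2L)
  expect_equal(count_dual_enriched(loops, ratios, lo = 0.6), 0L)
})
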