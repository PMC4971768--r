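test_that("the NB pmf matches closed forms and an independent Gamma oracle", {
  # k = 0 reduces to (1-p)^r
  expect_equal(nb_pmf(0, 2.5, 0.1), 0.9^2.5)
  # r = 1 is the geometric pmf
  expect_equal(nb_pmf(0:5, 1, 0.3), 0.3^(0:5) * 0.7)
  # non-integer r against stats::dnbinom (prob is the complement)
  set.seed(1)
  for (i in 1:50) {
    r <- runif(1, 0.1, 20); p <- runif(1, 1e-4, 0.5); k <- sample(0:50, 1)
    expect_equal(nb_pmf(k, r, p), dnbinom(k, size = r, prob = 1 - p),
                 tolerance = 1e-12)
  }
  # explicit Gamma-function evaluation
  k <- 3; r <- 2.5; p <- 0.1
  direct <- gamma(k + r) / (gamma(r) * factorial(k)) * p^k * (1 - p)^r
  expect_equal(nb_pmf(k, r, p), direct, tolerance = 1e-12)
  expect_equal(nb_pmf(c(0, 1, 3), 0, 0.1), c(1, 0, 0))
  expect_error(nb_pmf(1, 2, 1.2), "p must be")
})

test_that("convolution p-values match brute-force enumeration and limits", {
  expect_equal(convolution_pvalue(0, 3, 5, 0.02, 0.03), 1)
  set.seed(2)
  for (i in 1:40) {
    A <- runif(1, 0.1, 50); B <- runif(1, 0.1, 50)
    pab <- runif(1, 1e-4, 0.2); pba <- runif(1, 1e-4, 0.2)
    k <- sample(1:40, 1)
    expect_lt(abs(convolution_pvalue(k, A, B, pab, pba) -
                    oracle_conv_pvalue(k, A, B, pab, pba)), 1e-10)
  }
  # named example against the brute-force oracle
  expect_lt(abs(convolution_pvalue(4, 3.2, 5.1, 0.02, 0.015) -
                  oracle_conv_pvalue(4, 3.2, 5.1, 0.02, 0.015)), 1e-10)
  # B -> 0: reduces to the single-NB survival function
  for (k in c(1, 3, 10)) {
    expect_lt(abs(convolution_pvalue(k, 4.2, 0, 0.05, 0.01) -
                    pnbinom(k - 1, size = 4.2, prob = 0.95, lower.tail = FALSE)),
              1e-12)
  }
  # degenerate: both backgrounds zero -> point mass at zero
  expect_equal(convolution_pvalue(0, 0, 0, 0.1, 0.1), 1)
  expect_equal(convolution_pvalue(3, 0, 0, 0.1, 0.1), 0)
})

test_that("the convolution pmf sums to one and p-values decrease in k", {
  set.seed(3)
  for (i in 1:10) {
    A <- runif(1, 0.5, 20); B <- runif(1, 0.5, 20)
    pab <- runif(1, 0.01, 0.15); pba <- runif(1, 0.01, 0.15)
    # total mass: p-value at large K is the tail beyond K
    expect_lt(convolution_pvalue(400, A, B, pab, pba), 1e-8)
    pv <- vapply(1:20, function(k) convolution_pvalue(k, A, B, pab, pba),
                 numeric(1))
    expect_true(all(diff(pv) <= 1e-12))
  }
})

test_that("batch p-values agree with the scalar implementation", {
  set.seed(4)
  n <- 60
  A <- runif(n, 0, 30); B <- runif(n, 0, 30)
  A[1] <- 0  # degenerate anchor background
  pab <- runif(n, 1e-3, 0.1); pba <- runif(n, 1e-3, 0.1)
  k <- sample(0:30, n, replace = TRUE)
  got <- segloop:::.conv_pvalue_batch(k, A, B, pab, pba)
  for (i in seq_len(n)) {
    expect_lt(abs(got[i] - convolution_pvalue(k[i], A[i], B[i], pab[i], pba[i])),
              1e-12)
  }
})

test_that("background estimation implements the depth-split ratios", {
  # symmetric depths: every r = 0.5, A_hat = half the anchor depth
  ct <- data.frame(seg_a = c(1, 1, 2), seg_b = c(2, 3, 3), chrom = "chr1",
                   k = c(4L, 4L, 4L), D = 5000)
  bg <- estimate_background(1, ct)
  expect_equal(bg$components$r, c(0.5, 0.5))
  expect_equal(bg$A_hat, 0.5 * 8)
  # single partner carrying all reads of both segments: denominator 0 -> 0.5
  ct2 <- data.frame(seg_a = 1, seg_b = 2, chrom = "chr1", k = 6L, D = 5000)
  bg2 <- estimate_background(1, ct2)
  expect_equal(bg2$components$r, 0.5)
  expect_equal(bg2$A_hat, 3)
  # A_total=10, i_total=30, C=5 -> r = 5/30
  ct3 <- data.frame(seg_a = c(1, 1, 2, 2), seg_b = c(2, 3, 4, 5),
                    chrom = "chr1", k = c(5L, 5L, 12L, 13L), D = 5000)
  bg3 <- estimate_background(1, ct3)
  expect_equal(bg3$components$r[bg3$components$partner == 2], 5 / 30)
})

test_that("loop calling finds a planted enriched pair on synthetic background", {
  cfg <- sim_config(chrom_length = 5e5, total_contacts = 2e5,
                    n_loops = 5, loop_fold = 10)
  res <- run_pipeline(cfg, seed = 41)
  sig <- res$calls[res$calls$significant, ]
  tk <- paste(res$sim$truth$seg_a, res$sim$truth$seg_b)
  expect_gte(sum(tk %in% paste(sig$seg_a, sig$seg_b)), 4)
  # relaxed threshold is a superset of the strict one
  q05 <- res$calls$q_value < 0.05
  expect_true(all(res$calls$significant | !res$calls$significant & TRUE))
  expect_true(all(which(res$calls$significant) %in% which(q05)))
})

test_that("q-values are order-invariant and deterministic", {
  cfg <- sim_config(chrom_length = 2e5, total_contacts = 3e4)
  sim <- simulate_study(cfg, seed = 42)
  calls <- call_loops(sim$contacts, sim$segments)
  perm <- sample(nrow(sim$contacts))
  calls2 <- call_loops(sim$contacts[perm, ], sim$segments)
  key <- paste(calls$seg_a, calls$seg_b)
  key2 <- paste(calls2$seg_a, calls2$seg_b)
  expect_equal(calls$q_value, calls2$q_value[match(key, key2)], tolerance = 1e-12)
})

test_that("a pair's reads affect other pairs' backgrounds only through depth totals", {
  segs <- make_segments(30, w = 1000)
  ct <- data.frame(seg_a = c(1, 1, 5, 20), seg_b = c(5, 9, 9, 25),
                   chrom = "chr1", k = c(3L, 4L, 5L, 6L), D = 4000)
  bg_before <- estimate_background(20, ct)
  ct2 <- ct; ct2$k[1] <- 6L  # double the (1,5) pair
  bg_after <- estimate_background(20, ct2)
  # the (20,25) anchor shares no segment with (1,5): background unchanged
  expect_equal(bg_before$A_hat, bg_after$A_hat)
  # but anchor 1's own background does change
  expect_false(isTRUE(all.equal(estimate_background(1, ct)$A_hat,
                                estimate_background(1, ct2)$A_hat)))
})

test_that("null simulations yield calibrated p-values and no calls", {
  cfg <- sim_config(chrom_length = 6e5, total_contacts = 3e5)
  res <- run_pipeline(cfg, seed = 43)
  expect_gte(nrow(res$calls), 10000)
  expect_equal(sum(res$calls$significant), 0)
  ks <- suppressWarnings(stats::ks.test(res$calls$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})
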