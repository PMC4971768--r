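test_that("beta estimation is the length-normalized coverage ratio with mean 1", {
  segs <- make_segments(4, w = 1000)
  # uniform coverage -> all beta 1
  cov <- data.frame(id = 1:4, depth = c(100, 100, 100, 100))
  b <- estimate_beta(cov, segs)
  expect_equal(b$beta, rep(1, 4))
  # one segment at twice the mean
  cov2 <- data.frame(id = 1:4, depth = c(200, 100, 100, 100))
  b2 <- estimate_beta(cov2, segs)
  expect_equal(b2$beta[1], 200 / 125)
  expect_equal(mean(b2$beta), 1)
  # pooled data sets: rows with the same id are summed
  cov3 <- rbind(cov, cov)
  expect_equal(estimate_beta(cov3, segs)$beta, b$beta)
  # length normalization: same depth on a longer segment = lower beta
  segs4 <- make_segments(2, w = 1000); segs4$length <- c(1000, 2000)
  b4 <- estimate_beta(data.frame(id = 1:2, depth = c(100, 100)), segs4)
  expect_equal(b4$beta, c(4 / 3, 2 / 3))
  expect_error(estimate_beta(data.frame(id = 1:4, depth = 0), segs), "zero total")
})

test_that("beta estimates are invariant to segment order and recover the truth", {
  sim <- simulate_study(sim_config(chrom_length = 3e5, total_contacts = 5000),
                        seed = 31)
  b <- estimate_beta(sim$reseq, sim$segments)
  expect_gt(stats::cor(b$beta, sim$beta_true), 0.95)
  perm <- sample(nrow(sim$reseq))
  b2 <- estimate_beta(sim$reseq[perm, ], sim$segments)
  expect_equal(b2$beta, b$beta)
})

test_that("the beta filter removes contacts with extreme bias, bounds inclusive", {
  ct <- data.frame(seg_a = c(1, 1, 1, 1), seg_b = c(2, 3, 4, 5),
                   chrom = "chr1", k = 1L, D = 5000)
  biases <- data.frame(id = 1:5, beta = c(1, 0.04, 1, 20, 25),
                       usable = c(TRUE, FALSE, TRUE, TRUE, FALSE))
  f <- apply_beta_filter(ct, biases)
  expect_equal(f$seg_b, c(3, 4))  # 0.04 removed, 20 retained, 25 removed
  # missing bias -> dropped with a warning
  ct2 <- data.frame(seg_a = 1, seg_b = 9, chrom = "chr1", k = 1L, D = 5000)
  expect_warning(f2 <- apply_beta_filter(ct2, biases), "no bias")
  expect_equal(nrow(f2), 0L)
})

test_that("the fragment-end-density fit recovers exact log-linear relationships", {
  segs <- make_segments(12, w = 1000)
  segs$n_ends <- rep(2:7, 2)
  # depth proportional to E -> slope 1
  dep <- data.frame(id = segs$id, depth = 50 * segs$n_ends)
  m <- fit_end_density(dep, segs)
  expect_lt(abs(m$slope - 1), 1e-6)
  # multipliers scale as E under slope 1: E=4 doubles E=2
  mult <- evaluate_end_density(m, c(2, 4))
  expect_equal(mult[2] / mult[1], 2, tolerance = 1e-6)
  expect_equal(mean(evaluate_end_density(m, segs$n_ends)), 1, tolerance = 1e-9)
  # constant depth -> slope 0, multiplier identically 1
  m0 <- fit_end_density(data.frame(id = segs$id, depth = 100), segs)
  expect_lt(abs(m0$slope), 1e-9)
  expect_equal(evaluate_end_density(m0, 2:7), rep(1, 6), tolerance = 1e-9)
  # all E identical -> constant model
  segs$n_ends <- 3L
  mc <- fit_end_density(dep, segs)
  expect_true(mc$constant)
  expect_equal(evaluate_end_density(mc, c(2, 9)), c(1, 1))
})

test_that("adjusted probabilities implement the normalized factor model", {
  segs <- make_segments(21, w = 1000)
  decay <- make_flat_decay()
  # symmetric partners at equal distance under a flat model share probability
  pr <- adjusted_probabilities(11, segs, decay)
  expect_equal(sum(pr$p), 1, tolerance = 1e-12)
  up <- pr$partners < 11
  expect_equal(sum(pr$p[up]), 0.5, tolerance = 1e-12)

  # with all biases 1 and flat f_E, p reduces to the f(D)*l-only form
  powered <- fit_decay(make_powerlaw_bins(-1))
  pr2 <- adjusted_probabilities(11, segs, powered)
  w <- evaluate_decay(powered, pr2$D) * 1000
  expect_equal(pr2$p, w / sum(w), tolerance = 1e-12)

  # doubling a partner's length and beta quadruples its relative weight
  segs3 <- make_segments(11, w = 1000)
  segs3$length[4] <- 2000
  biases <- data.frame(id = 1:11, beta = 1, usable = TRUE)
  biases$beta[4] <- 2
  # partner 4 and partner 8 are equidistant from anchor 6
  pr3 <- adjusted_probabilities(6, segs3, decay, biases = biases)
  p4 <- pr3$p[pr3$partners == 4]
  p8 <- pr3$p[pr3$partners == 8]
  expect_equal(p4 / p8, 4, tolerance = 1e-12)
})

test_that("unusable segments drop out of anchor and partner sets consistently", {
  segs <- make_segments(21, w = 1000)
  decay <- make_flat_decay()
  biases <- data.frame(id = 1:21, beta = 1, usable = TRUE)
  biases$beta[14] <- 30; biases$usable[14] <- FALSE
  pr <- adjusted_probabilities(11, segs, decay, biases = biases)
  expect_false(14 %in% pr$partners)
  expect_equal(sum(pr$p), 1, tolerance = 1e-12)
  # removing a partner and renormalizing equals computing on the reduced set
  pr_full <- adjusted_probabilities(11, segs, decay)
  keep <- pr_full$partners != 14
  renorm <- pr_full$p[keep] / sum(pr_full$p[keep])
  expect_equal(pr$p, renorm, tolerance = 1e-12)
  # unusable anchors are flagged
  expect_equal(adjusted_probabilities(14, segs, decay, biases = biases)$error,
               "anchor unusable")
  # an isolated segment has no partners
  lone <- make_segments(1)
  expect_equal(adjusted_probabilities(1, lone, decay)$error,
               "no usable partners")
})
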