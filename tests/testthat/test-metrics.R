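test_that("NMI hits its closed-form anchor cases", {
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(nmi(c(0, 0, 1, 1), c(5, 5, 2, 2)), 1)  # label permutation
  expect_equal(nmi(c(0, 0, 1, 1), c(1, 1, 1, 1)), 0)  # one predicted cluster
  expect_equal(nmi(c(1, 1, 1), c(1, 1, 1)), 1)        # degenerate 0/0 case
  # hand contingency: truth (0,0,1,1), predicted (0,1,1,1)
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 1, 1, 1)),
               oracle_nmi(c(0, 0, 1, 1), c(0, 1, 1, 1)))
  expect_error(nmi(c(1, 2), c(1, 2, 3)), "length")
})

test_that("NMI and ARI match independent oracles on random partitions", {
  has_mclust <- requireNamespace("mclust", quietly = TRUE)
  for (seed in 1:15) {
    set.seed(seed)
    n <- sample(5:10, 1)
    truth <- sample.int(3, n, replace = TRUE)
    pred <- sample.int(4, n, replace = TRUE)
    expect_equal(nmi(truth, pred), oracle_nmi(truth, pred),
                 tolerance = 1e-12)
    expect_equal(ari(truth, pred), oracle_ari(truth, pred),
                 tolerance = 1e-12)
    if (has_mclust) {
      expect_equal(ari(truth, pred),
                   mclust::adjustedRandIndex(truth, pred),
                   tolerance = 1e-12)
    }
    expect_gte(nmi(truth, pred), 0)
    expect_lte(nmi(truth, pred), 1)
    expect_lte(ari(truth, pred), 1)
  }
})

test_that("ARI anchors: identity, permutation invariance, near-zero under independence", {
  expect_equal(ari(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(ari(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  set.seed(99)
  vals <- replicate(200, ari(sample.int(2, 40, TRUE), sample.int(2, 40, TRUE)))
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("macro F1 and accuracy use the optimal cluster-to-class mapping", {
  expect_equal(mapped_f1_accuracy(c(0, 0, 1, 1), c(0, 0, 1, 1)),
               c(macro_f1 = 1, accuracy = 1))
  expect_equal(mapped_f1_accuracy(c(0, 0, 1, 1), c(7, 7, 3, 3)),
               c(macro_f1 = 1, accuracy = 1))
  # truth (0,0,1,1), predicted (0,1,1,1): best map is identity-like,
  # acc 3/4, F1 = mean(2/3 * 2... ) enumerated by hand:
  # map {0->0, 1->1}: tp0=1 fp0=0 fn0=1 -> F1_0 = 2/3; tp1=2 fp1=1 fn1=0
  # -> F1_1 = 4/5; macro = (2/3 + 4/5) / 2 = 11/15; acc = 3/4
  r <- mapped_f1_accuracy(c(0, 0, 1, 1), c(0, 1, 1, 1))
  expect_equal(unname(r["macro_f1"]), 11 / 15)
  expect_equal(unname(r["accuracy"]), 3 / 4)
  # surplus clusters stay unmapped and count as errors
  r2 <- mapped_f1_accuracy(c(1, 1, 1, 1), c(1, 1, 2, 3))
  expect_equal(unname(r2["accuracy"]), 1 / 2)
})

test_that("SNR scores follow the one-vs-rest closed form", {
  # class1 {1,3}: mu 2, sd 1; class2 {-1,1}: mu 0, sd 1 -> SNR 100
  expr <- matrix(c(1, 3, -1, 1), 1, 4)
  expect_equal(unname(snr_scores(expr, c(TRUE, TRUE, FALSE, FALSE))), 100)
  # identical distributions score 0; swapping classes negates
  e2 <- rbind(c(1, 2, 1, 2), c(5, 9, 1, 3))
  s <- snr_scores(e2, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(s[1]), 0)
  sneg <- snr_scores(e2, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(unname(sneg), -unname(s))
  # shifting class 1 by c raises SNR by 100 c / (sd1 + sd2)
  e3 <- e2; e3[, 1:2] <- e3[, 1:2] + 3
  s3 <- snr_scores(e3, c(TRUE, TRUE, FALSE, FALSE))
  sd1 <- sqrt(mean(e2[2, 1:2]^2) - mean(e2[2, 1:2])^2)
  sd2 <- sqrt(mean(e2[2, 3:4]^2) - mean(e2[2, 3:4])^2)
  expect_equal(unname(s3[2] - s[2]), 100 * 3 / (sd1 + sd2))
  # zero-sd genes warn and score 0
  e4 <- rbind(c(2, 2, 2, 2))
  expect_warning(s4 <- snr_scores(e4, c(TRUE, TRUE, FALSE, FALSE)),
                 "zero sd")
  expect_equal(unname(s4), 0)
  expect_error(snr_scores(e2, c(TRUE, TRUE, TRUE, TRUE)), "non-empty")
})

test_that("marker selection flags the extremes with deterministic ties", {
  snr <- c(g1 = 3, g2 = 1, g3 = -2)
  mk <- select_markers(snr, n_up = 1, n_down = 1)
  expect_identical(mk$gene[mk$flag == "up"], "g1")
  expect_identical(mk$gene[mk$flag == "down"], "g3")
  tied <- select_markers(c(a = 1, b = 1, c = 1, d = 1), 1, 1)
  expect_identical(tied$gene[tied$flag == "up"], "a")
  expect_identical(tied$gene[tied$flag == "down"], "d")
  none <- select_markers(snr, n_up = 0, n_down = 2)
  expect_identical(sum(none$flag == "up"), 0L)
  expect_error(select_markers(snr, 2, 2), "exceeds")
})
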