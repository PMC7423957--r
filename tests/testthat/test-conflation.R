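test_that("discrete conflation is the normalized product with its identities", {
  expect_equal(conflate_discrete(list(c(0.5, 0.5), c(0.8, 0.2))),
               c(0.8, 0.2))                      # (0.4, 0.1) / 0.5
  f <- c(0.1, 0.6, 0.3)
  expect_equal(conflate_discrete(list(f)), f)    # m = 1 identity
  expect_equal(conflate_discrete(list(f, rep(1 / 3, 3))), f,
               tolerance = 1e-15)                # uniform is neutral
  expect_error(conflate_discrete(list(c(1, 0), c(0, 1))), "disjoint")
  expect_error(conflate_discrete(list(c(1, 0), c(0.5, 0.5, 0))), "length")
})

test_that("discrete conflation is order invariant and associative", {
  set.seed(1)
  for (rep in 1:10) {
    fs <- lapply(1:3, function(i) { p <- runif(6, 0.01, 1); p / sum(p) })
    ref <- conflate_discrete(fs)
    expect_equal(conflate_discrete(rev(fs)), ref, tolerance = 1e-12)
    two <- conflate_discrete(list(conflate_discrete(fs[1:2]), fs[[3]]))
    expect_equal(two, ref, tolerance = 1e-12)
  }
})

test_that("conflating two discretized normals contracts the variance towards the sharper input", {
  x <- seq(-10, 10, length.out = 2001)
  f1 <- dnorm(x, 0, 1); f1 <- f1 / sum(f1)
  f2 <- dnorm(x, 1, 2); f2 <- f2 / sum(f2)
  g <- conflate_discrete(list(f1, f2))
  mu <- sum(x * g)
  v <- sum((x - mu)^2 * g)
  expect_lt(v, 1)                       # below min(1, 4)
  expect_lt(abs(mu - 0.2), 0.01)        # precision-weighted mean
  # unimodal: the density rises then falls
  peak <- which.max(g)
  expect_true(all(diff(g[1:peak]) >= -1e-15))
  expect_true(all(diff(g[peak:length(g)]) <= 1e-15))
})

test_that("single-view conflation returns the view's rows before symmetrization", {
  vp <- rand_view_probs(5, 1, seed = 3)
  up <- conflate_views_complete(vp)
  # the Eq. for one view forces each row back to the view's row; after
  # symmetrization the result is the symmetrized view
  expected <- (vp[[1]]$probs + t(vp[[1]]$probs)) / (2 * 5)
  expect_equal(up$P, expected, tolerance = 1e-12)
})

test_that("complete conflation matches the brute-force oracle and its invariants", {
  for (seed in 1:6) {
    n <- sample(3:6, 1)
    m <- sample(1:3, 1)
    vp <- rand_view_probs(n, m, seed = seed)
    plist <- lapply(vp, `[[`, "probs")
    for (renorm in c(TRUE, FALSE)) {
      up <- conflate_views_complete(vp, renormalize = renorm)
      expect_equal(up$P, oracle_conflate_complete(plist, renorm),
                   tolerance = 1e-12)
      expect_equal(up$P, t(up$P))
      expect_equal(diag(up$P), rep(0, n))
      expect_true(all(up$P >= 0))
      if (renorm) expect_equal(sum(up$P), 1, tolerance = 1e-12)
    }
  }
})

test_that("identical equidistant views conflate to a uniform symmetric joint", {
  P3 <- matrix(1 / 2, 3, 3); diag(P3) <- 0
  vp <- lapply(1:2, function(v) {
    structure(list(probs = P3, sigmas = rep(1, 3), k_eff = 2L,
                   present = rep(TRUE, 3)), class = "view_prob")
  })
  up <- conflate_views_complete(vp)
  off <- up$P[upper.tri(up$P)]
  expect_equal(off, rep(off[1], 3))
  expect_equal(sum(up$P), 1, tolerance = 1e-14)
})

test_that("incomplete conflation reduces bitwise to the complete path on full data", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:30, 1)
    m <- sample(1:3, 1)
    vp <- rand_view_probs(n, m, seed = seed + 100)
    full <- matrix(TRUE, n, m)
    a <- conflate_views_complete(vp)
    b <- conflate_views_incomplete(vp, full)
    expect_identical(a$P, b$P)
  }
})

test_that("incomplete conflation matches the printed case-wise oracle", {
  # 3 samples, 2 views, s3 only in view 2 (hand-checkable case layout)
  pres <- matrix(c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE), 3, 2)
  vp <- rand_view_probs(3, 2, seed = 5, presence = pres)
  up <- conflate_views_incomplete(vp, pres)
  plist <- lapply(vp, `[[`, "probs")
  expect_equal(up$P, oracle_conflate_incomplete(plist, pres),
               tolerance = 1e-12)
  # larger random instances
  for (seed in 6:10) {
    set.seed(seed)
    n <- sample(5:8, 1)
    m <- 3
    pres <- matrix(runif(n * m) > 0.3, n, m)
    pres[rowSums(pres) == 0, 1] <- TRUE
    vp <- rand_view_probs(n, m, seed = seed + 50, presence = pres)
    up <- conflate_views_incomplete(vp, pres)
    expect_equal(up$P, oracle_conflate_incomplete(lapply(vp, `[[`, "probs"),
                                                  pres),
                 tolerance = 1e-12)
    expect_equal(sum(up$P), 1, tolerance = 1e-12)
  }
})

test_that("probability averaging keeps every mode instead of sharpening", {
  vp <- rand_view_probs(4, 2, seed = 11)
  # identical views: mean equals each view (after symmetrization)
  same <- list(vp[[1]], vp[[1]])
  up <- average_probabilities(same)
  expect_equal(up$P, (vp[[1]]$probs + t(vp[[1]]$probs)) / 8,
               tolerance = 1e-12)
  # two opposed rows average to a bimodal row
  r1 <- c(1, 0); r2 <- c(0, 1)
  expect_equal(conflate_discrete(list(c(r1, 1e-9) / sum(c(r1, 1e-9)),
                                      c(r2, 1e-9) / sum(c(r2, 1e-9))))[3],
               1, tolerance = 1e-3)  # conflation collapses to the overlap
  expect_equal((r1 + r2) / 2, c(0.5, 0.5))  # averaging keeps both modes
  # m = 1 identity
  one <- average_probabilities(vp[1])
  expect_equal(one$P, (vp[[1]]$probs + t(vp[[1]]$probs)) / 8,
               tolerance = 1e-12)
})

test_that("distance averaging rebuilds calibrated rows on the mean distances", {
  set.seed(12)
  X <- matrix(rnorm(6 * 2), 6, 2)
  # identical views: same P as the single-view pipeline
  up1 <- average_data(list(X, X), k = 3)
  vp <- view_probabilities(X, k = 3)
  single <- (vp$probs + t(vp$probs)) / 12
  expect_equal(up1$P, single, tolerance = 1e-8)
  # two 1-D views with distances 2 and 4 between a pair average to 3
  A <- matrix(c(0, 2, 10), ncol = 1)
  B <- matrix(c(0, 4, 10), ncol = 1)
  upd <- average_data(list(A, B), k = 2)
  vpd <- view_probabilities(matrix(c(0, 3, 10), ncol = 1), k = 2)
  # the averaged distance between s1 and s2 is 3; remaining pairs differ,
  # so only check symmetry + normalization here
  expect_equal(upd$P, t(upd$P))
  expect_equal(sum(upd$P), 1, tolerance = 1e-12)
})
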