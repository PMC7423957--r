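test_that("the Xie-Beni index matches hand arithmetic and the brute-force oracle", {
  Y <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  sol <- cluster_solution(Y, rbind(c(0, 0.5), c(10, 0.5)))
  # numerator 4 * 0.25 = 1; denominator 4 * 100
  expect_equal(xb_index(Y, sol), 0.0025)
  # shrinking within-cluster spread decreases XB
  Ys <- rbind(c(0, 0.4), c(0, 0.6), c(10, 0.4), c(10, 0.6))
  sols <- cluster_solution(Ys, rbind(c(0, 0.5), c(10, 0.5)))
  expect_lt(xb_index(Ys, sols), 0.0025)
  # coincident centers
  solc <- list(centers = rbind(c(0, 0.5), c(0, 0.5)),
               labels = c(1, 1, 2, 2), K = 2L)
  expect_identical(xb_index(Y, solc), Inf)
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(6:10, 1); K <- sample(2:4, 1)
    Yr <- matrix(rnorm(n * 2), n, 2)
    solr <- cluster_solution(Yr, Yr[sample.int(n, K), , drop = FALSE])
    expect_equal(xb_index(Yr, solr),
                 oracle_xb(Yr, solr$centers, solr$labels),
                 tolerance = 1e-12)
  }
})

test_that("the PBM index matches hand arithmetic and the brute-force oracle", {
  Y <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  centers <- rbind(c(0, 0.5), c(10, 0.5))
  sol <- cluster_solution(Y, centers)
  E1 <- sum(sqrt(rowSums(sweep(Y, 2, colMeans(Y))^2)))  # 4*sqrt(25.25)
  EK <- 4 * 0.5
  DK <- 10
  expect_equal(pbm_index(Y, sol), (1 / 2) * (E1 / EK) * DK,
               tolerance = 1e-12)
  # K = 1 with the center at the centroid: D1 = 0 so PBM = 0
  sol1 <- list(centers = matrix(colMeans(Y), 1), labels = rep(1L, 4), K = 1L)
  expect_equal(pbm_index(Y, sol1), 0)
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(6:10, 1); K <- sample(2:4, 1)
    Yr <- matrix(rnorm(n * 2), n, 2)
    solr <- cluster_solution(Yr, Yr[sample.int(n, K), , drop = FALSE])
    expect_equal(pbm_index(Yr, solr),
                 oracle_pbm(Yr, solr$centers, solr$labels),
                 tolerance = 1e-12)
  }
})

test_that("mutation operators respect the center-count bounds", {
  set.seed(20)
  Y <- matrix(rnorm(30 * 2), 30, 2)
  sol <- cluster_solution(Y, Y[1:2, ])
  # delete at K = 2 must be redrawn as normal or insert
  for (i in 1:20) {
    mt <- mutate_solution(sol, Y, kind = "delete", k_min = 2, k_max = 5)
    expect_gte(mt$K, 2)
  }
  ins <- mutate_solution(sol, Y, kind = "insert", k_min = 2, k_max = 5)
  expect_identical(ins$K, 3L)
  expect_equal(ins$centers[1:2, ], sol$centers)
  # inserted center is a data point
  expect_true(any(apply(Y, 1, function(p) all(p == ins$centers[3, ]))))
  # normal mutation with delta -> 0 leaves the solution essentially unchanged
  nm <- mutate_solution(sol, Y, kind = "normal", delta = 1e-12)
  expect_equal(nm$centers, sol$centers, tolerance = 1e-9)
})

test_that("the temperature ladder has the closed-form number of levels", {
  sch <- anneal_schedule(T_max = 100, T_min = 0.001, cooling = 0.9)
  expect_equal(ceiling(log(sch$T_min / sch$T_max) / log(sch$cooling)), 110)
})

test_that("annealing returns a mutually non-dominated archive, deterministically", {
  em <- rand_embedding(40, 3, 2, sep = 10, noise = 0.5, seed = 30)
  sch <- anneal_schedule(T_max = 10, T_min = 0.1, cooling = 0.7,
                         iters_per_temp = 30, seed = 30)
  arch <- amosa_anneal(em$Y, sch)
  objs <- t(vapply(arch$solutions,
                   function(s) c(s$objectives[["xb"]],
                                 -s$objectives[["pbm"]]),
                   numeric(2)))
  for (i in seq_len(nrow(objs))) {
    for (j in seq_len(nrow(objs))) {
      if (i != j) {
        expect_false(all(objs[i, ] <= objs[j, ]) && any(objs[i, ] < objs[j, ]))
      }
    }
  }
  arch2 <- amosa_anneal(em$Y, sch)
  expect_equal(arch$solutions, arch2$solutions)
})

test_that("annealing recovers well-separated clusters", {
  em <- rand_embedding(60, 4, 2, sep = 12, noise = 0.5, seed = 31)
  sch <- anneal_schedule(T_max = 50, T_min = 0.01, cooling = 0.8,
                         iters_per_temp = 50, seed = 31)
  arch <- amosa_anneal(em$Y, sch)
  best <- select_solution(arch, "best_pbm")
  expect_identical(best$K, 4L)
  expect_gte(nmi(em$labels, best$labels), 0.9)
})

test_that("archive selection strategies pick the documented solution", {
  em <- rand_embedding(30, 2, 2, sep = 8, noise = 0.5, seed = 32)
  sch <- anneal_schedule(T_max = 5, T_min = 0.5, cooling = 0.7,
                         iters_per_temp = 15, seed = 32)
  arch <- amosa_anneal(em$Y, sch)
  pbms <- vapply(arch$solutions, function(s) s$objectives[["pbm"]],
                 numeric(1))
  best <- select_solution(arch, "best_pbm")
  expect_equal(best$objectives[["pbm"]], max(pbms))
  sup <- select_solution(arch, "supervised_nmi", labels = em$labels)
  nmis <- vapply(arch$solutions, function(s) nmi(em$labels, s$labels),
                 numeric(1))
  expect_equal(nmi(em$labels, sup$labels), max(nmis))
  expect_error(select_solution(arch, "supervised_nmi"), "labels")
  one <- list(solutions = arch$solutions[1])
  expect_identical(select_solution(one, "best_pbm")$labels,
                   arch$solutions[[1]]$labels)
})

test_that("degenerate identical-point data yields a warned degenerate archive", {
  Y <- matrix(1, 6, 2)
  expect_warning(arch <- amosa_anneal(Y, anneal_schedule(seed = 1)),
                 "identical")
  expect_gte(length(arch$solutions), 1)
})
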