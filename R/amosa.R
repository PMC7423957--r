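# squared distances from every row of Y to every center (n x K); computed
# per center in the direct (y - c)^2 form, which keeps full precision
.dist_to_centers <- function(Y, centers) {
  K <- nrow(centers)
  D2 <- matrix(0, nrow(Y), K)
  for (q in seq_len(K)) {
    D2[, q] <- rowSums(sweep(Y, 2, centers[q, ], "-")^2)
  }
  D2
}

#' Build a cluster solution from centers
#'
#' Assigns every sample to its nearest center (crisp memberships), repairs
#' empty clusters by moving their center onto the sample farthest from its
#' current center, and computes the two validity objectives.
#'
#' @param Y Embedding matrix (n x d).
#' @param centers K x d matrix of cluster centers.
#' @return Object of class `cluster_solution`: `centers`, `labels`,
#'   `objectives` (named vector `xb`, `pbm`), `K`.
#' @export
cluster_solution <- function(Y, centers) {
  centers <- as.matrix(centers)
  for (rep in 1:5) {
    D2 <- .dist_to_centers(Y, centers)
    labels <- max.col(-D2, ties.method = "first")
    sizes <- tabulate(labels, nbins = nrow(centers))
    if (all(sizes > 0)) break
    # empty-cluster repair: farthest sample from its own center
    far <- which.max(D2[cbind(seq_len(nrow(Y)), labels)])
    centers[which(sizes == 0)[1L], ] <- Y[far, ]
  }
  sol <- structure(list(centers = centers, labels = labels,
                        K = nrow(centers)),
                   class = "cluster_solution")
  sol$objectives <- c(xb = xb_index(Y, sol), pbm = pbm_index(Y, sol))
  sol
}

#' Xie-Beni cluster validity index
#'
#' Ratio of within-cluster compactness to cluster separation with crisp
#' memberships and squared Euclidean distances:
#' `XB = sum_r d2(x_r, C_{label(r)}) / (n * min_{l != m} d2(C_l, C_m))`.
#' Lower is better; coincident centers yield `Inf`.
#'
#' @param Y Embedding matrix.
#' @param solution A `cluster_solution` (its `centers` and `labels` are
#'   used).
#' @return The index value.
#' @export
xb_index <- function(Y, solution) {
  centers <- solution$centers
  K <- nrow(centers)
  stopifnot(K >= 2)
  labels <- solution$labels
  D2 <- .dist_to_centers(Y, centers)
  compact <- sum(D2[cbind(seq_len(nrow(Y)), labels)])
  C2 <- .dist_to_centers(centers, centers)
  sep <- min(C2[upper.tri(C2)])
  if (sep == 0) return(Inf)
  compact / (nrow(Y) * sep)
}

#' PBM cluster validity index
#'
#' `PBM(K) = (1/K) * (E1 / EK) * DK` with Euclidean distances: `E1` the
#' total distance of all samples to the global centroid, `EK` the total
#' within-cluster distance to the assigned centers, `DK` the maximum
#' pairwise center distance. Higher is better; `EK = 0` yields `Inf`.
#'
#' @inheritParams xb_index
#' @return The index value.
#' @export
pbm_index <- function(Y, solution) {
  centers <- solution$centers
  K <- nrow(centers)
  labels <- solution$labels
  g <- colMeans(Y)
  E1 <- sum(sqrt(rowSums(sweep(Y, 2, g, "-")^2)))
  D2 <- .dist_to_centers(Y, centers)
  EK <- sum(sqrt(D2[cbind(seq_len(nrow(Y)), labels)]))
  if (EK == 0) return(Inf)
  DK <- if (K == 1L) 0 else {
    C2 <- .dist_to_centers(centers, centers)
    sqrt(max(C2))
  }
  (1 / K) * (E1 / EK) * DK
}

# Laplace(mu, delta) draws by inverse CDF
.rlaplace <- function(k, mu = 0, delta = 1) {
  u <- stats::runif(k, -0.5, 0.5)
  mu - delta * sign(u) * log(1 - 2 * abs(u))
}

#' Mutate a cluster solution
#'
#' Three operators explore the variable-length center encoding: `normal`
#' replaces the coordinates of one randomly chosen center with Laplace
#' draws centred on the old values (scale `delta`); `insert` adds a
#' uniformly chosen data point as a new center; `delete` removes a
#' uniformly chosen center. A kind that would leave `K` outside
#' `[k_min, k_max]` is redrawn.
#'
#' @param solution A `cluster_solution`.
#' @param Y Embedding matrix (source of inserted centers; used to
#'   re-evaluate).
#' @param kind One of `"normal"`, `"insert"`, `"delete"`, or `NULL` to draw
#'   uniformly.
#' @param k_min,k_max Bounds on the number of clusters.
#' @param delta Laplace scale for the normal mutation.
#' @return The mutated, re-evaluated `cluster_solution`.
#' @export
mutate_solution <- function(solution, Y, kind = NULL, k_min = 2,
                            k_max = floor(sqrt(nrow(Y))), delta = 1) {
  K <- solution$K
  repeat {
    kd <- if (is.null(kind)) {
      sample(c("normal", "insert", "delete"), 1L)
    } else kind
    if (kd == "insert" && K + 1 > k_max) { kind <- NULL; next }
    if (kd == "delete" && K - 1 < k_min) { kind <- NULL; next }
    break
  }
  centers <- solution$centers
  if (kd == "normal") {
    r <- sample.int(K, 1L)
    centers[r, ] <- .rlaplace(ncol(centers), mu = centers[r, ],
                              delta = delta)
  } else if (kd == "insert") {
    centers <- rbind(centers, Y[sample.int(nrow(Y), 1L), ])
  } else {
    centers <- centers[-sample.int(K, 1L), , drop = FALSE]
  }
  cluster_solution(Y, centers)
}

#' Annealing schedule for the multi-objective clustering
#'
#' @param T_max,T_min Initial and final temperature.
#' @param cooling Geometric cooling rate in (0, 1).
#' @param iters_per_temp Proposals evaluated at each temperature level.
#' @param soft_limit,hard_limit Archive sizes: above `soft_limit` the
#'   archive is clustered down to `hard_limit` members.
#' @param seed Integer seed.
#' @return A list of class `anneal_schedule`.
#' @export
anneal_schedule <- function(T_max = 100, T_min = 0.001, cooling = 0.9,
                            iters_per_temp = 100, soft_limit = 50,
                            hard_limit = 40, seed = 1L) {
  stopifnot(cooling > 0, cooling < 1, T_min < T_max)
  structure(list(T_max = T_max, T_min = T_min, cooling = cooling,
                 iters_per_temp = iters_per_temp, soft_limit = soft_limit,
                 hard_limit = hard_limit, seed = as.integer(seed)),
            class = "anneal_schedule")
}

# minimization objective vector of a solution
.obj_min <- function(sol) c(sol$objectives[["xb"]], -sol$objectives[["pbm"]])

# TRUE if a dominates b (both minimized)
.dominates <- function(a, b) all(a <= b) && any(a < b)

# amount of domination between objective vectors, normalized by ranges
.dom_amount <- function(a, b, ranges) {
  d <- abs(a - b) / ranges
  prod(d[d > 0])
}

.obj_matrix <- function(solutions) {
  t(vapply(solutions, .obj_min, numeric(2)))
}

# cluster the archive's objective vectors down to `hard_limit` members
# (single linkage on the normalized objective space, keep the member
# nearest each cluster mean)
.prune_archive <- function(solutions, hard_limit) {
  if (length(solutions) <= hard_limit) return(solutions)
  M <- .obj_matrix(solutions)
  Mf <- M
  Mf[!is.finite(Mf)] <- max(abs(Mf[is.finite(Mf)]), 1) * 10
  rng <- apply(Mf, 2, function(x) diff(range(x)))
  rng[rng == 0] <- 1
  Mn <- sweep(Mf, 2, apply(Mf, 2, min), "-")
  Mn <- sweep(Mn, 2, rng, "/")
  cl <- stats::cutree(stats::hclust(stats::dist(Mn), method = "single"),
                      k = hard_limit)
  keep <- integer(hard_limit)
  for (g in seq_len(hard_limit)) {
    idx <- which(cl == g)
    ctr <- colMeans(Mn[idx, , drop = FALSE])
    keep[g] <- idx[which.min(colSums((t(Mn[idx, , drop = FALSE]) - ctr)^2))]
  }
  solutions[sort(keep)]
}

# insert `sol` into the archive, dropping members it dominates; returns the
# archive unchanged when a member dominates `sol`
.archive_insert <- function(solutions, sol, soft_limit, hard_limit) {
  obj <- .obj_min(sol)
  objs <- .obj_matrix(solutions)
  dominated_by <- vapply(seq_along(solutions),
                         function(i) .dominates(objs[i, ], obj), logical(1))
  if (any(dominated_by)) return(solutions)
  dominates <- vapply(seq_along(solutions),
                      function(i) .dominates(obj, objs[i, ]), logical(1))
  solutions <- c(solutions[!dominates], list(sol))
  if (length(solutions) > soft_limit) {
    solutions <- .prune_archive(solutions, hard_limit)
  }
  solutions
}

#' Archived multi-objective simulated annealing of the embedding
#'
#' Clusters the embedded samples with a variable number of centers by
#' simultaneously minimizing the Xie-Beni index and maximizing the PBM
#' index. A current solution is mutated at every step; acceptance follows
#' the domination relation between the candidate, the current solution and
#' the archive, with dominated candidates accepted with probability
#' `1 / (1 + exp(avg_dom / T))` (worse moves become rare as the temperature
#' falls). The archive holds the mutually non-dominated solutions found and
#' is clustered down to `hard_limit` whenever it outgrows `soft_limit`.
#'
#' @param Y Embedding matrix (n x d), `n >= 4`.
#' @param schedule An [anneal_schedule()].
#' @param k_min,k_max Bounds on the number of clusters (defaults 2 and
#'   `floor(sqrt(n))`).
#' @param n_init Random initial solutions seeding the archive.
#' @param delta Laplace scale of the normal mutation.
#' @return Object of class `amosa_archive`: `solutions` (list of
#'   `cluster_solution`), `schedule`, `n_levels`.
#' @export
amosa_anneal <- function(Y, schedule = anneal_schedule(), k_min = 2,
                         k_max = floor(sqrt(nrow(Y))), n_init = 10,
                         delta = 1) {
  n <- nrow(Y)
  stopifnot(n >= 4)
  k_max <- max(k_min, k_max)
  set.seed(schedule$seed)
  if (all(.sq_euclid(Y) == 0)) {
    warning("all points identical; returning a degenerate K = 2 archive")
    sol <- cluster_solution(Y, Y[1:2, , drop = FALSE])
    return(structure(list(solutions = list(sol), schedule = schedule,
                          n_levels = 0L),
                     class = "amosa_archive"))
  }
  init <- lapply(seq_len(n_init), function(i) {
    K <- k_min + sample.int(k_max - k_min + 1L, 1L) - 1L
    cluster_solution(Y, Y[sample.int(n, K), , drop = FALSE])
  })
  archive <- list(init[[1L]])
  for (s in init[-1L]) {
    archive <- .archive_insert(archive, s, schedule$soft_limit,
                               schedule$hard_limit)
  }
  current <- archive[[sample.int(length(archive), 1L)]]

  n_levels <- ceiling(log(schedule$T_min / schedule$T_max) /
                        log(schedule$cooling))
  Temp <- schedule$T_max
  for (level in seq_len(n_levels)) {
    for (it in seq_len(schedule$iters_per_temp)) {
      cand <- mutate_solution(current, Y, k_min = k_min, k_max = k_max,
                              delta = delta)
      oc <- .obj_min(current)
      on <- .obj_min(cand)
      if (any(!is.finite(on))) next
      objs <- .obj_matrix(archive)
      allobj <- rbind(objs, oc, on)
      allobj[!is.finite(allobj)] <- NA
      ranges <- apply(allobj, 2, function(x) diff(range(x, na.rm = TRUE)))
      ranges[!is.finite(ranges) | ranges == 0] <- 1
      dom_by_arch <- which(vapply(seq_along(archive), function(i) {
        .dominates(objs[i, ], on)
      }, logical(1)))
      if (.dominates(oc, on)) {
        # candidate worse than current: annealed acceptance
        amounts <- c(.dom_amount(oc, on, ranges),
                     vapply(dom_by_arch, function(i) {
                       .dom_amount(objs[i, ], on, ranges)
                     }, numeric(1)))
        p <- 1 / (1 + exp(mean(amounts) / Temp))
        if (stats::runif(1) < p) current <- cand
      } else if (length(dom_by_arch) > 0 && !.dominates(on, oc)) {
        # non-dominating wrt current but dominated in the archive
        amounts <- vapply(dom_by_arch, function(i) {
          .dom_amount(objs[i, ], on, ranges)
        }, numeric(1))
        p <- 1 / (1 + exp(mean(amounts) / Temp))
        if (stats::runif(1) < p) current <- cand
      } else {
        current <- cand
        archive <- .archive_insert(archive, cand, schedule$soft_limit,
                                   schedule$hard_limit)
      }
    }
    Temp <- Temp * schedule$cooling
  }
  structure(list(solutions = archive, schedule = schedule,
                 n_levels = n_levels),
            class = "amosa_archive")
}

#' @export
print.amosa_archive <- function(x, ...) {
  Ks <- vapply(x$solutions, `[[`, integer(1), "K")
  cat("amosa_archive: ", length(x$solutions),
      " non-dominated solution(s), K in [", min(Ks), ", ", max(Ks),
      "], ", x$n_levels, " temperature levels\n", sep = "")
  invisible(x)
}

#' Pick one solution from the archive
#'
#' `best_pbm` (unsupervised default) returns the archive member with the
#' largest PBM index; `supervised_nmi` returns the member whose labels have
#' the highest normalized mutual information with supplied ground truth — a
#' label-using reporting mode, not part of the unsupervised pipeline.
#'
#' @param archive An `amosa_archive`.
#' @param strategy `"best_pbm"` or `"supervised_nmi"`.
#' @param labels Ground-truth labels (required for `supervised_nmi`).
#' @return The chosen `cluster_solution` with an added `strategy` field.
#' @export
select_solution <- function(archive,
                            strategy = c("best_pbm", "supervised_nmi"),
                            labels = NULL) {
  strategy <- match.arg(strategy)
  sols <- archive$solutions
  if (length(sols) == 0L) stop("empty archive")
  if (strategy == "best_pbm") {
    score <- vapply(sols, function(s) s$objectives[["pbm"]], numeric(1))
    score[!is.finite(score)] <- -Inf
  } else {
    if (is.null(labels)) stop("supervised_nmi requires labels")
    score <- vapply(sols, function(s) nmi(labels, s$labels), numeric(1))
  }
  sol <- sols[[which.max(score)]]
  sol$strategy <- strategy
  sol
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("cluster_solution: K = ", x$K, ", XB = ",
      format(x$objectives[["xb"]], digits = 5), ", PBM = ",
      format(x$objectives[["pbm"]], digits = 5), "\n", sep = "")
  invisible(x)
}
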