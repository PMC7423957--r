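# Direct, unvectorized reference implementations. These stay deliberately
# naive (double loops, no log-space tricks) so they are independent of the
# package's computation paths.

# Gaussian row-conditional neighbour distribution for given bandwidths
oracle_view_probs <- function(X, sigmas) {
  n <- nrow(X)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w <- numeric(n)
    for (j in seq_len(n)) {
      if (j != i) {
        d2 <- sum((X[i, ] - X[j, ])^2) / (2 * sigmas[i]^2)
        w[j] <- exp(-d2)
      }
    }
    P[i, ] <- w / sum(w)
  }
  P
}

# complete-data conflation + symmetrization, straight from the formulas
oracle_conflate_complete <- function(plist, renormalize = TRUE) {
  n <- nrow(plist[[1]])
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      num <- prod(vapply(plist, function(pv) pv[i, j], numeric(1)))
      compl <- prod(vapply(plist, function(pv) sum(pv[i, -j]), numeric(1)))
      P[i, j] <- num / (num + compl)
    }
  }
  if (renormalize) P <- P / rowSums(P)
  (P + t(P)) / (2 * n)
}

# case-wise incomplete conflation as printed: (a) neighbour j in one view /
# i in several, (b) i in one view, (c) both in several views
oracle_conflate_incomplete <- function(plist, presence,
                                       renormalize = TRUE) {
  n <- nrow(presence)
  m <- length(plist)
  counts <- rowSums(presence)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (counts[i] == 1) {
        v <- which(presence[i, ])
        P[i, j] <- plist[[v]][i, j]
      } else if (counts[j] == 1) {
        v <- which(presence[j, ])
        P[i, j] <- if (presence[i, v]) plist[[v]][i, j] / m else 0
      } else {
        shared <- which(presence[i, ] & presence[j, ])
        if (length(shared) == 0) next
        num <- prod(vapply(shared, function(v) plist[[v]][i, j],
                           numeric(1)))
        compl <- prod(vapply(shared, function(v) {
          sum(plist[[v]][i, setdiff(which(presence[, v]), j)])
        }, numeric(1)))
        P[i, j] <- num / (num + compl)
      }
    }
  }
  if (renormalize) {
    rs <- rowSums(P)
    rs[rs == 0] <- 1
    P <- P / rs
  }
  (P + t(P)) / (2 * n)
}

oracle_q <- function(Y) {
  n <- nrow(Y)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) W[i, j] <- 1 / (1 + sum((Y[i, ] - Y[j, ])^2))
    }
  }
  W / sum(W)
}

oracle_kl <- function(P, Q) {
  s <- 0
  for (i in seq_len(nrow(P))) {
    for (j in seq_len(ncol(P))) {
      if (P[i, j] > 0) s <- s + P[i, j] * log(P[i, j] / max(Q[i, j], 1e-12))
    }
  }
  s
}

# central finite differences of the KL cost w.r.t. every coordinate of Y
oracle_fd_gradient <- function(P, Y, h = 1e-5) {
  G <- Y * 0
  for (i in seq_len(nrow(Y))) {
    for (d in seq_len(ncol(Y))) {
      Yp <- Y; Yp[i, d] <- Yp[i, d] + h
      Ym <- Y; Ym[i, d] <- Ym[i, d] - h
      G[i, d] <- (oracle_kl(P, oracle_q(Yp)) -
                    oracle_kl(P, oracle_q(Ym))) / (2 * h)
    }
  }
  G
}

oracle_xb <- function(Y, centers, labels) {
  n <- nrow(Y)
  num <- 0
  for (r in seq_len(n)) {
    num <- num + sum((Y[r, ] - centers[labels[r], ])^2)
  }
  sep <- Inf
  K <- nrow(centers)
  for (l in seq_len(K)) {
    for (mm in seq_len(K)) {
      if (l != mm) sep <- min(sep, sum((centers[l, ] - centers[mm, ])^2))
    }
  }
  if (sep == 0) return(Inf)
  num / (n * sep)
}

oracle_pbm <- function(Y, centers, labels) {
  n <- nrow(Y)
  K <- nrow(centers)
  g <- colMeans(Y)
  E1 <- 0
  for (r in seq_len(n)) E1 <- E1 + sqrt(sum((Y[r, ] - g)^2))
  EK <- 0
  for (r in seq_len(n)) {
    EK <- EK + sqrt(sum((Y[r, ] - centers[labels[r], ])^2))
  }
  DK <- 0
  for (l in seq_len(K)) {
    for (mm in seq_len(K)) {
      DK <- max(DK, sqrt(sum((centers[l, ] - centers[mm, ])^2)))
    }
  }
  if (EK == 0) return(Inf)
  (1 / K) * (E1 / EK) * DK
}

# all-pairs Rand counting
oracle_ari <- function(truth, predicted) {
  n <- length(truth)
  a <- b <- c_ <- d <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      st <- truth[i] == truth[j]
      sp <- predicted[i] == predicted[j]
      if (st && sp) a <- a + 1
      else if (st && !sp) b <- b + 1
      else if (!st && sp) c_ <- c_ + 1
      else d <- d + 1
    }
  }
  tot <- a + b + c_ + d
  expected <- (a + b) * (a + c_) / tot
  max_idx <- ((a + b) + (a + c_)) / 2
  if (max_idx == expected) return(1)
  (a - expected) / (max_idx - expected)
}

oracle_nmi <- function(truth, predicted) {
  tu <- sort(unique(truth)); pu <- sort(unique(predicted))
  n <- length(truth)
  cont <- matrix(0, length(tu), length(pu))
  for (i in seq_len(n)) {
    cont[match(truth[i], tu), match(predicted[i], pu)] <-
      cont[match(truth[i], tu), match(predicted[i], pu)] + 1
  }
  pij <- cont / n
  mi <- 0
  for (r in seq_along(tu)) {
    for (cc in seq_along(pu)) {
      if (pij[r, cc] > 0) {
        mi <- mi + pij[r, cc] *
          log(pij[r, cc] / (sum(pij[r, ]) * sum(pij[, cc])))
      }
    }
  }
  H <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  denom <- H(rowSums(pij)) + H(colSums(pij))
  if (denom == 0) return(1)
  2 * mi / denom
}

# random row-stochastic per-view distributions on a common sample set
rand_view_probs <- function(n, m, seed, presence = NULL) {
  set.seed(seed)
  if (is.null(presence)) presence <- matrix(TRUE, n, m)
  lapply(seq_len(m), function(v) {
    pres <- presence[, v]
    P <- matrix(0, n, n)
    idx <- which(pres)
    sub <- matrix(stats::runif(length(idx)^2, 0.05, 1),
                  length(idx), length(idx))
    diag(sub) <- 0
    sub <- sub / rowSums(sub)
    P[idx, idx] <- sub
    structure(list(probs = P, sigmas = ifelse(pres, 1, NA_real_),
                   k_eff = 2L, present = pres),
              class = "view_prob")
  })
}

# small labelled Gaussian-mixture embedding for clustering tests
rand_embedding <- function(n, K, d, sep, noise, seed) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(K * d), K, d)
  D2 <- as.matrix(dist(centers))^2
  centers <- centers * (sep / sqrt(min(D2[upper.tri(D2)])))
  labels <- rep_len(seq_len(K), n)
  Y <- centers[labels, ] + matrix(stats::rnorm(n * d, sd = noise), n, d)
  list(Y = Y, labels = labels, centers = centers)
}
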