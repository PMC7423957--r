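#' Scaled squared Euclidean distances
#'
#' Entry (i, j) is `||x_i - x_j||^2 / (2 sigma_i^2)`; asymmetric in general
#' because the bandwidth is row-specific.
#'
#' @param Xv Numeric matrix of present samples (rows) of one view.
#' @param sigmas Positive numeric vector, one bandwidth per row.
#' @return n x n matrix with zero diagonal.
#' @export
pairwise_scaled_distances <- function(Xv, sigmas) {
  if (any(sigmas <= 0)) stop("sigmas must be positive")
  D2 <- .sq_euclid(Xv)
  D2 / (2 * sigmas^2)
}

# squared Euclidean distance matrix; stats::dist works on coordinate
# differences directly, so the result is stable under large common shifts
.sq_euclid <- function(X) {
  D2 <- as.matrix(stats::dist(X))^2
  dimnames(D2) <- NULL
  D2
}

# row distribution p_j = exp(-d2_j / (2 sigma^2)) over j != i, log-sum-exp;
# returns list(p = probabilities over the given neighbours, H = entropy in
# nats). d2 excludes the self distance.
.row_affinity <- function(d2, sigma) {
  z <- -d2 / (2 * sigma^2)
  z <- z - max(z)
  w <- exp(z)
  s <- sum(w)
  p <- w / s
  # H = -sum p log p, with log p = z - log s; 0 log 0 -> 0
  lp <- z - log(s)
  H <- -sum(ifelse(p > 0, p * lp, 0))
  list(p = p, H = H)
}

#' Calibrate the Gaussian bandwidth of one sample
#'
#' Finds `sigma_i` such that the Shannon entropy (nats) of the neighbour
#' distribution built from the squared distances equals `log k` within
#' `tol`, by a doubling bracket followed by bisection. Entropy is monotone
#' non-decreasing in sigma, from 0 (nearest neighbour only) to
#' `log(#neighbours)` (uniform).
#'
#' @param distances_row Squared Euclidean distances from sample i to its
#'   potential neighbours (self excluded).
#' @param k Target effective neighbour count (`k >= 2`).
#' @param tol Entropy tolerance (default `1e-5`).
#' @param max_bisect Bisection steps after bracketing.
#' @return The calibrated sigma.
#' @export
calibrate_sigma <- function(distances_row, k, tol = 1e-5, max_bisect = 50L) {
  stopifnot(length(distances_row) >= 2L, k >= 2)
  target <- log(k)
  if (target > log(length(distances_row)) + tol) {
    warning("entropy target log(k) exceeds log(#neighbours); ",
            "returning large-sigma boundary")
  }
  scale0 <- sqrt(mean(distances_row))
  if (scale0 == 0) return(1)  # identical points: any sigma gives uniform
  H_at <- function(s) .row_affinity(distances_row, s)$H
  lo <- hi <- scale0
  H0 <- H_at(scale0)
  if (abs(H0 - target) <= tol) return(scale0)
  if (H0 < target) {
    for (i in 1:60) {
      hi <- hi * 2
      if (H_at(hi) >= target) break
      lo <- hi
    }
    if (H_at(hi) < target - tol) {
      warning("entropy target unreachable; returning boundary sigma")
      return(hi)
    }
  } else {
    for (i in 1:60) {
      lo <- lo / 2
      if (H_at(lo) <= target) break
      hi <- lo
    }
    if (H_at(lo) > target + tol) {
      warning("entropy target unreachable; returning boundary sigma")
      return(lo)
    }
  }
  for (i in seq_len(max_bisect)) {
    mid <- (lo + hi) / 2
    Hm <- H_at(mid)
    if (abs(Hm - target) <= tol) return(mid)
    if (Hm < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Per-view neighbour probability distribution
#'
#' For each present sample i a Gaussian is centred on i and its bandwidth is
#' calibrated so the row entropy equals `log k`; row i then holds the
#' probability that i selects each other present sample as its neighbour
#' (rows sum to 1, zero diagonal). Rows/columns of absent samples are zero
#' and masked via `present`.
#'
#' @param Xv Numeric matrix (n x d_v); only rows with `present == TRUE`
#'   participate.
#' @param k Effective number of nearest neighbours (`2 <= k < n_present`).
#' @param present Logical vector of present samples (default all).
#' @param tol Entropy tolerance for [calibrate_sigma()].
#' @return Object of class `view_prob`: list with `probs` (n x n), `sigmas`
#'   (length n, `NA` for absent), `k_eff`, `present`.
#' @export
view_probabilities <- function(Xv, k, present = rep(TRUE, nrow(Xv)),
                               tol = 1e-5) {
  n <- nrow(Xv)
  idx <- which(present)
  np <- length(idx)
  if (k >= np) stop("k must be smaller than the number of present samples")
  Xp <- Xv[idx, , drop = FALSE]
  D2 <- .sq_euclid(Xp)
  sig <- numeric(np)
  Pp <- matrix(0, np, np)
  for (r in seq_len(np)) {
    d2 <- D2[r, -r]
    sig[r] <- calibrate_sigma(d2, k, tol = tol)
    row <- .row_affinity(d2, sig[r])$p
    if (!all(is.finite(row))) {
      warning("degenerate affinity row ", idx[r], "; using uniform")
      row <- rep(1 / (np - 1), np - 1)
    }
    Pp[r, -r] <- row
  }
  probs <- matrix(0, n, n)
  probs[idx, idx] <- Pp
  sigmas <- rep(NA_real_, n)
  sigmas[idx] <- sig
  structure(list(probs = probs, sigmas = sigmas, k_eff = k,
                 present = present),
            class = "view_prob")
}

#' @export
print.view_prob <- function(x, ...) {
  cat("view_prob: ", sum(x$present), "/", length(x$present),
      " present samples, k = ", x$k_eff, "\n", sep = "")
  invisible(x)
}
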