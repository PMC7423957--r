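#' Conflate discrete probability distributions
#'
#' The conflation of distributions is their normalized elementwise product;
#' it minimizes the maximal loss of Shannon information when several
#' independent measurements are merged into one, and weights each input by
#' its precision.
#'
#' @param dists List of non-negative numeric vectors of equal length, each
#'   summing to 1.
#' @return Numeric vector: `f1 * f2 * ... / sum(f1 * f2 * ...)`.
#' @export
conflate_discrete <- function(dists) {
  stopifnot(length(dists) >= 1L)
  len <- unique(vapply(dists, length, integer(1)))
  if (length(len) != 1L) stop("distributions must have equal length")
  prod <- Reduce(`*`, dists)
  s <- sum(prod)
  if (s == 0) stop("disjoint supports: conflation undefined")
  prod / s
}

# Case-wise unified-probability engine.
#
# For each ordered pair (i, j):
#   (a) j occurs in exactly one view v but i in more than one:
#       p_ij = p^v_ij / m (0 when i is absent from j's single view);
#   (b) i occurs in exactly one view v: p_ij = p^v_ij from that view;
#   (c) both occur in >1 view: conflation restricted to the views holding
#       both i and j,
#       p_ij = prod_v p^v_ij / (prod_v p^v_ij + prod_v sum_{k != j} p^v_ik),
#       products over the shared views, inner sums over samples present in
#       each view. Pairs sharing no view (and fitting neither (a) nor (b))
#       get p_ij = 0.
# With a fully-true presence mask only case (c) fires, over all views: the
# complete-data conflation formula.
.conflate_engine <- function(view_probs, presence, renormalize = TRUE) {
  m <- length(view_probs)
  n <- nrow(presence)
  counts <- rowSums(presence)
  if (any(counts == 0)) stop("every sample must be present in >= 1 view")

  # per view: log p^v and log complement sum_{k != j} p^v_ik, with absent
  # pairs contributing "no information" (log 1 = 0) plus a share mask
  logp <- vector("list", m)
  logc <- vector("list", m)
  share <- vector("list", m)  # TRUE where both i and j present in view v
  for (v in seq_len(m)) {
    P <- view_probs[[v]]$probs
    pres <- presence[, v]
    sh <- outer(pres, pres, "&")
    diag(sh) <- FALSE
    comp <- rowSums(P) - P       # sum over k != j of p_ik (rows sum to 1)
    lp <- lc <- matrix(0, n, n)
    lp[sh] <- log(pmax(P[sh], .Machine$double.xmin))
    lc[sh] <- log(pmax(comp[sh], .Machine$double.xmin))
    logp[[v]] <- lp
    logc[[v]] <- lc
    share[[v]] <- sh
  }
  n_share <- Reduce(`+`, lapply(share, function(s) s * 1))
  lognum <- Reduce(`+`, logp)
  logden <- Reduce(`+`, logc)
  # conflated value for pairs sharing >= 1 view: 1 / (1 + exp(logden - lognum))
  Pc <- 1 / (1 + exp(logden - lognum))
  Pc[n_share == 0] <- 0

  P <- matrix(0, n, n)
  multi_i <- counts > 1L
  case_c <- outer(multi_i, multi_i, "&")
  P[case_c] <- Pc[case_c]
  # case (b): i in exactly one view -> its row from that view
  for (i in which(!multi_i)) {
    v <- which(presence[i, ])
    P[i, ] <- view_probs[[v]]$probs[i, ]
  }
  # case (a): j in one view, i in several -> p^v_ij / m from j's view
  for (j in which(!multi_i)) {
    v <- which(presence[j, ])
    rows <- which(multi_i)
    P[rows, j] <- view_probs[[v]]$probs[rows, j] / m
  }
  diag(P) <- 0

  if (renormalize) {
    rs <- rowSums(P)
    zero <- rs == 0
    if (any(zero)) {
      warning("row(s) with no probability mass; using uniform fallback")
      P[zero, ] <- 1 / (n - 1)
      diag(P) <- 0
      rs <- rowSums(P)
    }
    P <- P / rs
  }
  P <- (P + t(P)) / (2 * n)
  P
}

.unified <- function(P, mode, renormalized) {
  structure(list(P = P, mode = mode, renormalized = renormalized),
            class = "unified_prob")
}

#' @export
print.unified_prob <- function(x, ...) {
  cat("unified_prob (", x$mode, "): ", nrow(x$P), " samples, sum = ",
      format(sum(x$P)), "\n", sep = "")
  invisible(x)
}

#' Conflate per-view distributions (complete views)
#'
#' Combines the per-view neighbour distributions of samples present in every
#' view into one unified joint distribution: per-pair conflation, optional
#' row renormalization, then symmetrization
#' `p_ij <- (p_ij + p_ji) / (2n)` so the matrix sums to 1.
#'
#' @param view_probs List of `view_prob` objects on a common sample set.
#' @param renormalize Renormalize each row to sum 1 after conflation and
#'   before symmetrization (default `TRUE`; `FALSE` keeps the literal
#'   per-pair values).
#' @return A `unified_prob` object.
#' @export
conflate_views_complete <- function(view_probs, renormalize = TRUE) {
  n <- nrow(view_probs[[1L]]$probs)
  for (vp in view_probs) {
    if (!all(vp$present)) stop("complete conflation requires all samples present in all views")
  }
  presence <- matrix(TRUE, n, length(view_probs))
  P <- .conflate_engine(view_probs, presence, renormalize)
  .unified(P, "conflation-complete", renormalize)
}

#' Conflate per-view distributions (incomplete views)
#'
#' Case-wise combination for datasets where some samples are missing from
#' some views: samples present in several views are conflated over the views
#' they share with their neighbour; a sample present in exactly one view
#' keeps its single-view row; a neighbour present in exactly one view
#' contributes its single-view probability divided by the number of views.
#' Reduces exactly to [conflate_views_complete()] when every sample is
#' present everywhere.
#'
#' @param view_probs List of `view_prob` objects.
#' @param presence n x m logical presence mask.
#' @param renormalize As in [conflate_views_complete()].
#' @return A `unified_prob` object.
#' @export
conflate_views_incomplete <- function(view_probs, presence,
                                      renormalize = TRUE) {
  P <- .conflate_engine(view_probs, presence, renormalize)
  .unified(P, "conflation-incomplete", renormalize)
}

#' Baseline combiner: average of probabilities
#'
#' Arithmetic mean of the per-view neighbour distributions (over the views
#' where both samples are present), then symmetrization. Averaging preserves
#' every mode of the inputs, so disagreeing views yield a multi-modal
#' mixture rather than a sharpened consensus.
#'
#' @param view_probs List of `view_prob` objects.
#' @param presence Optional n x m presence mask (default: from the views).
#' @return A `unified_prob` object.
#' @export
average_probabilities <- function(view_probs, presence = NULL) {
  m <- length(view_probs)
  n <- nrow(view_probs[[1L]]$probs)
  if (is.null(presence)) {
    presence <- vapply(view_probs, `[[`, logical(n), "present")
    presence <- matrix(presence, n, m)
  }
  num <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  for (v in seq_len(m)) {
    sh <- outer(presence[, v], presence[, v], "&")
    num <- num + view_probs[[v]]$probs * sh
    cnt <- cnt + sh
  }
  P <- ifelse(cnt > 0, num / pmax(cnt, 1), 0)
  diag(P) <- 0
  rs <- rowSums(P)
  P <- P / ifelse(rs > 0, rs, 1)
  P <- (P + t(P)) / (2 * n)
  .unified(P, "avgprob", TRUE)
}

#' Baseline combiner: average of distance matrices
#'
#' Averages the per-view Euclidean distance matrices (over the views where
#' both samples are present), rebuilds Gaussian neighbour distributions with
#' entropy calibration on the averaged distances, and symmetrizes.
#'
#' @param views List of n x d_v matrices.
#' @param k Effective neighbour count for the calibration.
#' @param presence Optional n x m presence mask (default: all present).
#' @param tol Entropy tolerance.
#' @return A `unified_prob` object.
#' @export
average_data <- function(views, k, presence = NULL, tol = 1e-5) {
  m <- length(views)
  n <- nrow(views[[1L]])
  if (is.null(presence)) presence <- matrix(TRUE, n, m)
  num <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  for (v in seq_len(m)) {
    pres <- presence[, v]
    idx <- which(pres)
    D <- sqrt(.sq_euclid(views[[v]][idx, , drop = FALSE]))
    sh <- outer(pres, pres, "&")
    full <- matrix(0, n, n)
    full[idx, idx] <- D
    num <- num + full
    cnt <- cnt + sh
  }
  if (any(cnt == 0 & row(cnt) != col(cnt))) {
    warning("sample pair(s) sharing no view; masked with zero affinity")
  }
  Dbar <- ifelse(cnt > 0, num / pmax(cnt, 1), NA_real_)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- which(is.finite(Dbar[i, ]) & seq_len(n) != i)
    if (length(nb) < 2L) next
    d2 <- Dbar[i, nb]^2
    sigma <- calibrate_sigma(d2, min(k, length(nb)), tol = tol)
    P[i, nb] <- .row_affinity(d2, sigma)$p
  }
  P <- (P + t(P)) / (2 * n)
  .unified(P, "avgdata", TRUE)
}

#' Floor a unified distribution for KL use
#'
#' @param P Numeric matrix.
#' @param floor Minimum probability (default `1e-12`).
#' @return Matrix with off-diagonal entries bounded below by `floor`.
#' @export
floor_probabilities <- function(P, floor = 1e-12) {
  Q <- pmax(P, floor)
  diag(Q) <- 0
  Q
}
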