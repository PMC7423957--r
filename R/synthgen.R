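#' Specification of a synthetic multi-view Gaussian-mixture dataset
#'
#' Each view draws its own cluster centers (minimum pairwise distance
#' `center_separation`) and adds isotropic Gaussian noise; the cluster
#' assignment of a sample is shared across views. Optionally a fraction of
#' samples is flagged absent per view, never leaving a sample absent from
#' every view.
#'
#' @param n_samples Number of samples.
#' @param n_clusters Number of clusters (`>= 2`).
#' @param view_dims Integer vector of per-view feature counts.
#' @param center_separation Minimum pairwise distance between cluster
#'   centers within a view (recycled over views).
#' @param noise_sd Within-cluster standard deviation per feature (recycled
#'   over views).
#' @param missing_fraction Fraction of samples absent per view, in
#'   `[0, 1)` (recycled over views).
#' @param mixing Cluster mixing proportions (default equal).
#' @param seed Integer seed.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_samples = 200, n_clusters = 4,
                       view_dims = c(400, 170, 400),
                       center_separation = 6, noise_sd = 1,
                       missing_fraction = 0, mixing = NULL, seed = 1L) {
  stopifnot(n_clusters >= 2, all(center_separation > 0),
            all(missing_fraction >= 0), all(missing_fraction < 1))
  m <- length(view_dims)
  if (is.null(mixing)) mixing <- rep(1 / n_clusters, n_clusters)
  mixing <- mixing / sum(mixing)
  structure(list(n_samples = n_samples, n_clusters = n_clusters,
                 view_dims = view_dims,
                 center_separation = rep_len(center_separation, m),
                 noise_sd = rep_len(noise_sd, m),
                 missing_fraction = rep_len(missing_fraction, m),
                 mixing = mixing, seed = as.integer(seed)),
            class = "synth_spec")
}

# K centers in d dimensions with min pairwise distance exactly `sep`
.draw_centers <- function(K, d, sep) {
  C <- matrix(stats::rnorm(K * d), K, d)
  D2 <- .sq_euclid(C)
  mind <- sqrt(min(D2[upper.tri(D2)]))
  if (mind == 0) stop("degenerate center draw")
  C * (sep / mind)
}

#' Generate a synthetic multi-view dataset
#'
#' @param spec A [synth_spec()].
#' @return A list: `dataset` (an `mv_dataset` with `labels` filled in) and
#'   `labels` (the integer cluster assignments).
#' @export
synth_multiview <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  K <- spec$n_clusters
  m <- length(spec$view_dims)
  labels <- sample.int(K, n, replace = TRUE, prob = spec$mixing)
  # guarantee every cluster is represented
  for (k in seq_len(K)) {
    if (!any(labels == k)) labels[sample.int(n, 1L)] <- k
  }
  ids <- sprintf("s%03d", seq_len(n))
  views <- vector("list", m)
  presence <- matrix(TRUE, n, m, dimnames = list(ids, NULL))
  for (v in seq_len(m)) {
    d <- spec$view_dims[v]
    C <- .draw_centers(K, d, spec$center_separation[v])
    X <- C[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * d, sd = spec$noise_sd[v]), n, d)
    rownames(X) <- ids
    colnames(X) <- sprintf("v%df%d", v, seq_len(d))
    views[[v]] <- X
    frac <- spec$missing_fraction[v]
    if (frac > 0) {
      absent <- sample.int(n, floor(frac * n))
      presence[absent, v] <- FALSE
    }
  }
  # no sample may be absent everywhere: re-add to a random view
  orphans <- which(rowSums(presence) == 0)
  if (length(orphans) > 0) {
    warning(length(orphans),
            " sample(s) were absent from every view; re-added to one view")
    for (i in orphans) presence[i, sample.int(m, 1L)] <- TRUE
  }
  for (v in seq_len(m)) views[[v]][!presence[, v], ] <- 0
  ds <- structure(list(views = views, sample_ids = ids,
                       presence = presence, labels = labels),
                  class = "mv_dataset")
  list(dataset = ds, labels = labels)
}

#' Add extra noise to a single view
#'
#' Leaves all other views untouched; used to probe how a combiner copes
#' with one unreliable view (conflation should down-weight it
#' automatically, averaging should not).
#'
#' @param ds An `mv_dataset`.
#' @param view View index to degrade.
#' @param extra_noise_sd Standard deviation of the added Gaussian noise.
#' @param seed Integer seed.
#' @return The modified `mv_dataset`.
#' @export
degrade_view <- function(ds, view, extra_noise_sd, seed = 1L) {
  stopifnot(inherits(ds, "mv_dataset"))
  if (view < 1 || view > length(ds$views)) stop("view index out of range")
  if (extra_noise_sd == 0) return(ds)
  set.seed(seed)
  X <- ds$views[[view]]
  noise <- matrix(stats::rnorm(length(X), sd = extra_noise_sd),
                  nrow(X), ncol(X))
  noise[!ds$presence[, view], ] <- 0
  ds$views[[view]] <- X + noise
  ds
}
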