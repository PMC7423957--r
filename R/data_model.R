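#' Read one view from a delimited text file
#'
#' Reads a rectangular table whose first column holds sample identifiers and
#' whose header row names the features. All remaining cells must be finite
#' numbers.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter, `"\t"` (default) or `","`.
#' @return A list with `matrix` (numeric, samples x features, rownames set to
#'   the sample ids) and `sample_ids` (character vector in file order).
#' @export
read_view <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  fields <- utils::count.fields(path, sep = delimiter, quote = "\"",
                                comment.char = "")
  if (length(fields) == 0L) stop("no data rows in ", path)
  if (length(unique(fields)) > 1L) {
    bad <- which(fields != fields[1L])[1L]
    stop("ragged table in ", path, ": line ", bad, " has ", fields[bad],
         " fields, expected ", fields[1L])
  }
  tab <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"")
  if (nrow(tab) == 0L) stop("no data rows in ", path)
  ids <- tab[[1L]]
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                 dimnames = dimnames(raw)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-numeric or non-finite value in ", path, " at row ",
         ids[bad[1L, 1L]], " (line ", bad[1L, 1L] + 1L, "), column '",
         colnames(raw)[bad[1L, 2L]], "'")
  }
  rownames(num) <- ids
  list(matrix = num, sample_ids = ids)
}

#' Write a view in the dialect `read_view` reads
#'
#' @param X Numeric matrix (samples x features); rownames used as ids when
#'   `sample_ids` is `NULL`.
#' @param path Output path.
#' @param sample_ids Optional character vector of ids.
#' @param delimiter Field delimiter.
#' @return `path`, invisibly.
#' @export
write_view <- function(X, path, sample_ids = NULL, delimiter = "\t") {
  ids <- if (is.null(sample_ids)) rownames(X) else sample_ids
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  # %.17g guarantees a bit-exact double round trip through text
  chr <- matrix(sprintf("%.17g", X), nrow(X), dimnames = dimnames(X))
  df <- data.frame(sample = ids, chr, check.names = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Align raw views into a multi-view dataset
#'
#' The row universe is the union of sample ids across views, ordered by first
#' appearance (view order, then file order within a view). Samples absent
#' from a view get zero-filled placeholder rows flagged absent in the
#' presence mask.
#'
#' @param raw_views List of views, each a list with `matrix` and
#'   `sample_ids` as returned by [read_view()], or a bare matrix with
#'   rownames.
#' @param labels Optional named integer/character vector of ground-truth
#'   labels (names are sample ids) or an unnamed vector aligned to the
#'   resulting row universe.
#' @return An object of class `mv_dataset`: list with `views` (list of
#'   n x d_v matrices), `sample_ids`, `presence` (n x m logical), `labels`
#'   (or `NULL`).
#' @export
align_views <- function(raw_views, labels = NULL) {
  stopifnot(length(raw_views) >= 1L)
  raw_views <- lapply(raw_views, function(v) {
    if (is.matrix(v)) list(matrix = v, sample_ids = rownames(v)) else v
  })
  for (v in seq_along(raw_views)) {
    ids <- raw_views[[v]]$sample_ids
    if (is.null(ids)) stop("view ", v, " has no sample ids")
    if (anyDuplicated(ids)) {
      stop("duplicate sample id in view ", v, ": ",
           ids[duplicated(ids)][1L])
    }
  }
  universe <- unique(unlist(lapply(raw_views, `[[`, "sample_ids")))
  n <- length(universe)
  m <- length(raw_views)
  presence <- matrix(FALSE, n, m, dimnames = list(universe, NULL))
  views <- vector("list", m)
  for (v in seq_len(m)) {
    Xv <- raw_views[[v]]$matrix
    ids <- raw_views[[v]]$sample_ids
    if (any(!is.finite(Xv))) stop("non-finite values in view ", v)
    full <- matrix(0, n, ncol(Xv),
                   dimnames = list(universe, colnames(Xv)))
    full[ids, ] <- Xv
    presence[ids, v] <- TRUE
    views[[v]] <- full
  }
  if (!is.null(labels)) {
    if (!is.null(names(labels))) labels <- labels[universe]
    stopifnot(length(labels) == n)
    labels <- as.integer(factor(labels))
  }
  structure(list(views = views, sample_ids = universe,
                 presence = presence, labels = labels),
            class = "mv_dataset")
}

#' @export
print.mv_dataset <- function(x, ...) {
  dims <- vapply(x$views, ncol, integer(1))
  cat("mv_dataset: ", length(x$sample_ids), " samples, ",
      length(x$views), " view(s) [d = ", paste(dims, collapse = ", "),
      "]\n", sep = "")
  miss <- sum(!x$presence)
  if (miss > 0) cat("  absent sample/view entries: ", miss, "\n", sep = "")
  if (!is.null(x$labels)) {
    cat("  labels: ", length(unique(x$labels)), " classes\n", sep = "")
  }
  invisible(x)
}

# population (1/n) column variances over the rows in `present`
.col_pop_var <- function(X, present) {
  Xp <- X[present, , drop = FALSE]
  n <- nrow(Xp)
  if (n == 0L) stop("no present rows")
  mu <- colMeans(Xp)
  colMeans(Xp^2) - mu^2
}

#' Keep the highest-variance features of a view
#'
#' Ranks columns by population variance computed over present samples only
#' and keeps the top `k_features` (ties broken towards the lower column
#' index); surviving columns retain their original order.
#'
#' @param X Numeric matrix (samples x features).
#' @param k_features Number of columns to keep; alternatively use `fraction`.
#' @param fraction Fraction of columns to keep (used when `k_features` is
#'   `NULL`); the count is `max(1, round(fraction * ncol(X)))`.
#' @param present Logical vector of present rows (default: all).
#' @return The column-subset matrix.
#' @export
variance_rank_select <- function(X, k_features = NULL, fraction = 0.23,
                                 present = rep(TRUE, nrow(X))) {
  if (is.null(k_features)) {
    k_features <- max(1L, as.integer(round(fraction * ncol(X))))
  }
  if (k_features <= 0) stop("k_features must be positive")
  if (k_features > ncol(X)) stop("k_features exceeds number of columns")
  v <- .col_pop_var(X, present)
  keep <- sort(order(-v, seq_along(v))[seq_len(k_features)])
  X[, keep, drop = FALSE]
}

#' Normalize features of a view
#'
#' Column statistics are computed over present samples only; absent
#' placeholder rows are transformed with those statistics (they stay zero
#' semantically via the presence mask downstream).
#'
#' @param X Numeric matrix.
#' @param mode `"zscore"` (mean 0, population sd 1; constant columns become
#'   0), `"minmax"` (range to `[0, 1]`; constant columns become 0), or
#'   `"none"`.
#' @param present Logical vector of present rows.
#' @return Matrix of the same shape; absent rows are reset to zero.
#' @export
normalize_features <- function(X, mode = c("zscore", "minmax", "none"),
                               present = rep(TRUE, nrow(X))) {
  mode <- match.arg(mode)
  if (mode == "none") return(X)
  Xp <- X[present, , drop = FALSE]
  if (mode == "zscore") {
    mu <- colMeans(Xp)
    sd <- sqrt(pmax(colMeans(Xp^2) - mu^2, 0))
    sd[sd == 0] <- Inf  # constant columns -> 0 after centering
    Xn <- sweep(sweep(X, 2, mu, "-"), 2, sd, "/")
  } else {
    lo <- apply(Xp, 2, min)
    hi <- apply(Xp, 2, max)
    rng <- hi - lo
    rng[rng == 0] <- Inf
    Xn <- sweep(sweep(X, 2, lo, "-"), 2, rng, "/")
  }
  Xn[!present, ] <- 0
  Xn
}

#' Concatenate all views into one wide matrix
#'
#' Horizontal concatenation in view order; the feature block of a view is
#' exactly zero for samples absent from that view (missing features are
#' replaced with zeros).
#'
#' @param ds An `mv_dataset`.
#' @return A list of class `concat_matrix`: `data` (n x sum(d_v)),
#'   `block_offsets` (list of per-view column index vectors).
#' @export
concatenate_views <- function(ds) {
  stopifnot(inherits(ds, "mv_dataset"))
  m <- length(ds$views)
  views <- ds$views
  for (v in seq_len(m)) views[[v]][!ds$presence[, v], ] <- 0
  data <- do.call(cbind, views)
  dims <- vapply(views, ncol, integer(1))
  ends <- cumsum(dims)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  offsets <- Map(function(s, e) seq.int(s, e), starts, ends)
  structure(list(data = data, block_offsets = offsets),
            class = "concat_matrix")
}

#' Preprocess a multi-view dataset
#'
#' Applies variance-ranking feature selection then per-view normalization
#' (selection first; both computed over present samples only).
#'
#' @param ds An `mv_dataset`.
#' @param k_features Integer vector (recycled over views) of feature counts,
#'   or `NA` entries to use `fraction` for that view, or `NULL` to keep all.
#' @param fraction Fallback fraction for `NA` entries.
#' @param mode Normalization mode passed to [normalize_features()].
#' @return The preprocessed `mv_dataset`.
#' @export
preprocess_views <- function(ds, k_features = NULL, fraction = 0.23,
                             mode = "zscore") {
  stopifnot(inherits(ds, "mv_dataset"))
  m <- length(ds$views)
  if (!is.null(k_features)) k_features <- rep_len(k_features, m)
  for (v in seq_len(m)) {
    pres <- ds$presence[, v]
    Xv <- ds$views[[v]]
    if (!is.null(k_features)) {
      kv <- k_features[v]
      if (is.na(kv)) {
        Xv <- variance_rank_select(Xv, fraction = fraction, present = pres)
      } else {
        Xv <- variance_rank_select(Xv, k_features = min(kv, ncol(Xv)),
                                   present = pres)
      }
    }
    ds$views[[v]] <- normalize_features(Xv, mode = mode, present = pres)
  }
  ds
}

#' Read ground-truth labels
#'
#' Two-column delimited file (id, label), no header requirement: a header
#' line is detected when its second field is non-numeric and equals
#' `"label"` ignoring case.
#'
#' @param path File path.
#' @param delimiter Field delimiter.
#' @return Named integer vector of labels.
#' @export
read_labels <- function(path, delimiter = "\t") {
  tab <- utils::read.table(path, sep = delimiter, header = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("labels file needs two columns: id, label")
  if (tolower(tab[1L, 2L]) == "label") tab <- tab[-1L, , drop = FALSE]
  labels <- as.integer(factor(tab[[2L]]))
  names(labels) <- tab[[1L]]
  labels
}
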