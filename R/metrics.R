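.check_pair <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted labels differ in length")
  }
  list(truth = as.integer(factor(truth)),
       predicted = as.integer(factor(predicted)))
}

#' Normalized mutual information between two partitions
#'
#' `NMI(C, E) = 2 I(C; E) / (H(C) + H(E))` with natural logarithms (the
#' ratio is base-invariant). When both partitions are single-class the 0/0
#' case is defined as 1 (the partitions are trivially identical).
#'
#' @param truth,predicted Label vectors of equal length.
#' @return Value in `[0, 1]`.
#' @export
nmi <- function(truth, predicted) {
  p <- .check_pair(truth, predicted)
  tab <- table(p$truth, p$predicted)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij)
  p_j <- colSums(pij)
  H <- function(q) -sum(ifelse(q > 0, q * log(q), 0))
  denom <- H(pi_) + H(p_j)
  if (denom == 0) return(1)
  mi <- sum(ifelse(pij > 0, pij * log(pij / outer(pi_, p_j)), 0))
  2 * mi / denom
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement corrected for chance under the permutation
#' model: 1 for identical partitions, expectation ~0 for independent random
#' labelings.
#'
#' @param truth,predicted Label vectors of equal length.
#' @return Value `<= 1`.
#' @export
ari <- function(truth, predicted) {
  p <- .check_pair(truth, predicted)
  tab <- table(p$truth, p$predicted)
  n <- sum(tab)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_i <- sum(ch2(rowSums(tab)))
  sum_j <- sum(ch2(colSums(tab)))
  expected <- sum_i * sum_j / ch2(n)
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

# best one-to-one mapping of predicted clusters onto truth classes,
# maximizing total agreement; exhaustive over the smaller label set
.best_mapping <- function(tab) {
  r <- nrow(tab); c <- ncol(tab)
  if (min(r, c) > 9L) stop("too many classes for exhaustive mapping")
  best <- list(score = -1L, map = NULL)
  assign_rec <- function(free_rows, cols_left, map, score) {
    if (length(cols_left) == 0L || length(free_rows) == 0L) {
      if (score > best$score) best <<- list(score = score, map = map)
      return(invisible())
    }
    cl <- cols_left[1L]
    for (rw in free_rows) {
      m2 <- map; m2[cl] <- rw
      assign_rec(setdiff(free_rows, rw), cols_left[-1L], m2,
                 score + tab[rw, cl])
    }
    # leave this cluster unmapped
    assign_rec(free_rows, cols_left[-1L], map, score)
    invisible()
  }
  assign_rec(seq_len(r), seq_len(c), rep(NA_integer_, c), 0L)
  best$map
}

#' Macro F1 and accuracy after optimal cluster-to-class mapping
#'
#' Predicted clusters are mapped one-to-one onto truth classes by the
#' assignment maximizing total agreement (surplus clusters stay unmapped
#' and count as errors); macro F1 is the unweighted mean of per-class F1
#' scores and accuracy the fraction of correctly mapped samples.
#'
#' @param truth,predicted Label vectors of equal length.
#' @return Named numeric vector `c(macro_f1, accuracy)`.
#' @export
mapped_f1_accuracy <- function(truth, predicted) {
  p <- .check_pair(truth, predicted)
  tab <- as.matrix(table(p$truth, p$predicted))
  map <- .best_mapping(tab)
  n <- length(p$truth)
  mapped <- map[p$predicted]           # NA for unmapped clusters
  acc <- sum(mapped == p$truth, na.rm = TRUE) / n
  classes <- sort(unique(p$truth))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(mapped == cl & p$truth == cl, na.rm = TRUE)
    fp <- sum(mapped == cl & p$truth != cl, na.rm = TRUE)
    fn <- sum(p$truth == cl) - tp
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  c(macro_f1 = mean(f1), accuracy = acc)
}

#' Signal-to-noise marker scores (one class vs the rest)
#'
#' `SNR = (mu1 - mu2) / (sd1 + sd2) * 100` per gene, with population
#' standard deviations; genes with a zero denominator score 0 with a
#' warning. High SNR marks genes over-expressed in the class, low (most
#' negative) SNR marks under-expressed genes.
#'
#' @param expr Matrix, genes x samples.
#' @param class_mask Logical vector over samples: `TRUE` = class 1 (the
#'   class of interest), `FALSE` = class 2 (the rest). Both must be
#'   non-empty.
#' @return Numeric vector of per-gene scores (names from `rownames(expr)`).
#' @export
snr_scores <- function(expr, class_mask) {
  class_mask <- as.logical(class_mask)
  if (!any(class_mask) || all(class_mask)) {
    stop("both classes must be non-empty")
  }
  X1 <- expr[, class_mask, drop = FALSE]
  X2 <- expr[, !class_mask, drop = FALSE]
  mu1 <- rowMeans(X1); mu2 <- rowMeans(X2)
  sd1 <- sqrt(rowMeans(X1^2) - mu1^2)
  sd2 <- sqrt(rowMeans(X2^2) - mu2^2)
  denom <- sd1 + sd2
  out <- numeric(nrow(expr))
  zero <- denom == 0
  if (any(zero)) warning(sum(zero), " gene(s) with zero sd sum; SNR set to 0")
  out[!zero] <- (mu1[!zero] - mu2[!zero]) / denom[!zero] * 100
  names(out) <- rownames(expr)
  out
}

#' Select up- and down-regulated marker genes from SNR scores
#'
#' @param snr Numeric vector of per-gene scores.
#' @param n_up,n_down Numbers of top (highest-SNR, up-regulated) and bottom
#'   (lowest-SNR, down-regulated) genes to flag; ties broken by gene order.
#' @return Data frame with columns `gene`, `snr`, `flag`
#'   (`"up"`/`"down"`), ordered up markers first.
#' @export
select_markers <- function(snr, n_up = 5, n_down = 5) {
  ng <- length(snr)
  if (n_up + n_down > ng) stop("n_up + n_down exceeds the number of genes")
  genes <- if (is.null(names(snr))) paste0("g", seq_len(ng)) else names(snr)
  up <- if (n_up > 0) order(-snr, seq_len(ng))[seq_len(n_up)] else integer(0)
  down <- if (n_down > 0) {
    rev(order(-snr, seq_len(ng)))[seq_len(n_down)]
  } else integer(0)
  data.frame(gene = c(genes[up], genes[down]),
             snr = c(snr[up], snr[down]),
             flag = rep(c("up", "down"), c(length(up), length(down))),
             row.names = NULL, stringsAsFactors = FALSE)
}
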