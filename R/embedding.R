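#' Low-dimensional neighbour distribution (Student-t kernel)
#'
#' `q_ij = (1 + ||y_i - y_j||^2)^-1 / sum_{l != k} (1 + ||y_l - y_k||^2)^-1`
#' with zero diagonal; the heavy-tailed kernel lets moderately dissimilar
#' samples sit far apart in the embedding without crushing the cost.
#'
#' @param Y Numeric matrix (n x d_emb), `n >= 2`.
#' @return List of class `lowdim_prob`: `Q` (n x n, sums to 1 over ordered
#'   pairs), `W` (the unnormalized kernel `(1 + d^2)^-1`, zero diagonal),
#'   `S` (the normalizer).
#' @export
compute_q <- function(Y) {
  stopifnot(nrow(Y) >= 2L)
  W <- 1 / (1 + .sq_euclid(Y))
  diag(W) <- 0
  S <- sum(W)
  structure(list(Q = W / S, W = W, S = S), class = "lowdim_prob")
}

#' Kullback-Leibler divergence between unified and embedded distributions
#'
#' `C = sum_{i,j} p_ij log(p_ij / q_ij)`; terms with `p_ij = 0` contribute
#' nothing, and `q` is floored at `1e-12` before the log.
#'
#' @param P Unified joint distribution: matrix or `unified_prob`.
#' @param Q Embedded distribution: matrix or `lowdim_prob`.
#' @param floor Probability floor applied inside the log.
#' @return The scalar cost.
#' @export
kl_cost <- function(P, Q, floor = 1e-12) {
  if (inherits(P, "unified_prob")) P <- P$P
  if (inherits(Q, "lowdim_prob")) Q <- Q$Q
  pos <- P > 0
  sum(P[pos] * log(pmax(P[pos], floor) / pmax(Q[pos], floor)))
}

#' Gradient of the KL cost with respect to the embedding
#'
#' `dC/dy_i = 4 sum_j (p_ij - q_ij) (1 + ||y_i - y_j||^2)^-1 (y_i - y_j)`.
#'
#' @param P Unified joint distribution (matrix or `unified_prob`).
#' @param Y Embedding coordinates (n x d_emb).
#' @return n x d_emb gradient matrix.
#' @export
kl_gradient <- function(P, Y) {
  if (inherits(P, "unified_prob")) P <- P$P
  q <- compute_q(Y)
  M <- 4 * (P - q$Q) * q$W
  # grad_i = sum_j M_ij (y_i - y_j) = rowSums(M) * y_i - M %*% Y
  rowSums(M) * Y - M %*% Y
}

#' Optimize the embedding by gradient descent on the KL cost
#'
#' Full-batch gradient descent with a momentum schedule (initial momentum
#' until `momentum_switch`, final momentum afterwards) and per-coordinate
#' adaptive gains (delta-bar-delta: gain grows additively when the gradient
#' agrees in sign with the running update, shrinks multiplicatively
#' otherwise). The embedding is recentred to zero mean after every update
#' for numerical stability.
#'
#' @param P Unified joint distribution (matrix or `unified_prob`).
#' @param Y_init Initial coordinates (n x d_emb).
#' @param iterations Number of gradient steps (default 2000).
#' @param eta Base learning rate (default 200).
#' @param momentum_initial,momentum_final Momentum before/after the switch.
#' @param momentum_switch Iteration at which momentum changes (default 250).
#' @param gain_add,gain_mult,gain_min Delta-bar-delta constants.
#' @param verbose Print the cost every 100 iterations.
#' @return Object of class `embedding_state`: `Y`, `velocity`, `gains`,
#'   `iteration`, `eta`, `momentum`, `cost_trace`.
#' @export
optimize_embedding <- function(P, Y_init, iterations = 2000, eta = 200,
                               momentum_initial = 0.5, momentum_final = 0.9,
                               momentum_switch = 250, gain_add = 0.2,
                               gain_mult = 0.8, gain_min = 0.01,
                               verbose = FALSE) {
  if (inherits(P, "unified_prob")) P <- P$P
  Y <- as.matrix(Y_init)
  stopifnot(nrow(Y) == nrow(P))
  Pf <- floor_probabilities(P)
  vel <- Y * 0
  gains <- Y * 0 + 1
  trace <- numeric(iterations)
  mom <- momentum_initial
  for (it in seq_len(iterations)) {
    q <- compute_q(Y)
    grad <- {
      M <- 4 * (Pf - q$Q) * q$W
      rowSums(M) * Y - M %*% Y
    }
    cost <- kl_cost(Pf, q)
    if (!is.finite(cost)) {
      warning("non-finite cost at iteration ", it, "; returning last state")
      trace <- trace[seq_len(it - 1L)]
      break
    }
    trace[it] <- cost
    if (it == momentum_switch) mom <- momentum_final
    agree <- sign(grad) == sign(vel)
    gains <- ifelse(agree, gains * gain_mult, gains + gain_add)
    gains[gains < gain_min] <- gain_min
    vel <- mom * vel - eta * gains * grad
    Y <- Y + vel
    Y <- sweep(Y, 2, colMeans(Y), "-")
    if (verbose && it %% 100 == 0) {
      message("iteration ", it, ": KL = ", format(cost, digits = 6))
    }
  }
  structure(list(Y = Y, velocity = vel, gains = gains,
                 iteration = length(trace), eta = eta, momentum = mom,
                 cost_trace = trace),
            class = "embedding_state")
}

#' @export
print.embedding_state <- function(x, ...) {
  cat("embedding_state: ", nrow(x$Y), " samples x ", ncol(x$Y),
      " dims, ", x$iteration, " iterations, final KL = ",
      format(utils::tail(x$cost_trace, 1), digits = 6), "\n", sep = "")
  invisible(x)
}
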