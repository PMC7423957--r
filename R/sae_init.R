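#' Stacked denoising autoencoder configuration
#'
#' The network is symmetric about the bottleneck:
#' `d -> hidden -> d_emb -> hidden -> d`, ReLU on the hidden layers and the
#' bottleneck, linear output (inputs are z-scored reals, so a ReLU output
#' would clip negative values). Each layer is pretrained as a denoising
#' autoencoder with dropout corruption on its input and hidden activations,
#' then the stack is fine-tuned end-to-end on mean squared reconstruction
#' error.
#'
#' @param d_emb Bottleneck (embedding) dimension.
#' @param hidden Hidden layer width.
#' @param dropout Corruption rate in `[0, 1)` applied during pretraining.
#' @param pretrain_epochs,finetune_epochs Training epochs per phase.
#' @param batch_size Minibatch size (capped at n at fit time).
#' @param learning_rate Adam learning rate.
#' @param seed Integer seed controlling weight init, corruption and batches.
#' @return A list of class `sae_config`.
#' @export
sae_config <- function(d_emb = 80, hidden = 500, dropout = 0.05,
                       pretrain_epochs = 200, finetune_epochs = 400,
                       batch_size = 64, learning_rate = 1e-3, seed = 1L) {
  stopifnot(dropout >= 0, dropout < 1, d_emb >= 1, hidden >= 1)
  structure(list(d_emb = d_emb, hidden = hidden, dropout = dropout,
                 pretrain_epochs = pretrain_epochs,
                 finetune_epochs = finetune_epochs,
                 batch_size = batch_size, learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "sae_config")
}

# ---- minimal dense network machinery (matrix ops + Adam) -------------------

.mk_layer <- function(d_in, d_out, act) {
  sd <- sqrt(2 / d_in)  # He init for ReLU stacks
  list(W = matrix(stats::rnorm(d_in * d_out, sd = sd), d_in, d_out),
       b = rep(0, d_out), act = act)
}

.act_fwd <- function(z, act) if (act == "relu") pmax(z, 0) else z

.act_grad <- function(z, act) if (act == "relu") (z > 0) * 1 else 1

# forward pass; drop = per-layer-input dropout rates (length = #layers),
# applied as corruption (zeroing, no rescale) when > 0
.net_forward <- function(X, layers, drop = NULL) {
  acts <- vector("list", length(layers) + 1L)
  zs <- vector("list", length(layers))
  a <- X
  for (l in seq_along(layers)) {
    if (!is.null(drop) && drop[l] > 0) {
      mask <- matrix(stats::runif(length(a)) >= drop[l], nrow(a), ncol(a))
      a <- a * mask
    }
    acts[[l]] <- a
    z <- a %*% layers[[l]]$W
    z <- sweep(z, 2, layers[[l]]$b, "+")
    zs[[l]] <- z
    a <- .act_fwd(z, layers[[l]]$act)
  }
  acts[[length(layers) + 1L]] <- a
  list(acts = acts, zs = zs, out = a)
}

# backprop of mean squared error; returns list of (dW, db)
.net_backward <- function(fw, layers, target) {
  L <- length(layers)
  out <- fw$out
  delta <- 2 * (out - target) / length(target)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    delta <- delta * .act_grad(fw$zs[[l]], layers[[l]]$act)
    grads[[l]] <- list(dW = crossprod(fw$acts[[l]], delta),
                       db = colSums(delta))
    if (l > 1L) delta <- tcrossprod(delta, layers[[l]]$W)
  }
  grads
}

.adam_init <- function(layers) {
  lapply(layers, function(ly) list(mW = ly$W * 0, vW = ly$W * 0,
                                   mb = ly$b * 0, vb = ly$b * 0))
}

.adam_step <- function(layers, grads, state, lr, t,
                       b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (l in seq_along(layers)) {
    s <- state[[l]]; g <- grads[[l]]
    s$mW <- b1 * s$mW + (1 - b1) * g$dW
    s$vW <- b2 * s$vW + (1 - b2) * g$dW^2
    s$mb <- b1 * s$mb + (1 - b1) * g$db
    s$vb <- b2 * s$vb + (1 - b2) * g$db^2
    ch <- 1 - b1^t; cv <- 1 - b2^t
    layers[[l]]$W <- layers[[l]]$W - lr * (s$mW / ch) / (sqrt(s$vW / cv) + eps)
    layers[[l]]$b <- layers[[l]]$b - lr * (s$mb / ch) / (sqrt(s$vb / cv) + eps)
    state[[l]] <- s
  }
  list(layers = layers, state = state)
}

# train `layers` to map X -> target under MSE with Adam; drop gives the
# corruption rate in front of each layer. Returns layers + per-epoch loss.
.net_train <- function(X, target, layers, epochs, batch_size, lr, drop) {
  n <- nrow(X)
  batch_size <- min(batch_size, n)
  state <- .adam_init(layers)
  t <- 0L
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      fw <- .net_forward(X[idx, , drop = FALSE], layers, drop)
      grads <- .net_backward(fw, layers, target[idx, , drop = FALSE])
      t <- t + 1L
      up <- .adam_step(layers, grads, state, lr, t)
      layers <- up$layers; state <- up$state
    }
    out <- .net_forward(X, layers)$out
    trace[ep] <- mean((out - target)^2)
    if (!is.finite(trace[ep])) {
      stop("non-finite reconstruction loss at epoch ", ep,
           "; lower the learning rate")
    }
  }
  list(layers = layers, trace = trace)
}

# ---------------------------------------------------------------------------

#' Pretrain one denoising-autoencoder layer
#'
#' Trains `input -> hidden (ReLU) -> input` to reconstruct its own input
#' under dropout corruption of the input and the hidden activations, then
#' returns the clean (uncorrupted) encoding.
#'
#' @param input Numeric matrix (n x d_in), finite.
#' @param hidden_size Width of the hidden (encoding) layer.
#' @param cfg An [sae_config()].
#' @param decoder_act `"linear"` (first layer, real-valued targets) or
#'   `"relu"` (inner layers whose targets are ReLU activations).
#' @return List with `encoder` (layer), `decoder` (layer), `encoding`
#'   (n x hidden_size clean forward pass), `loss_trace`.
#' @export
pretrain_layer <- function(input, hidden_size, cfg,
                           decoder_act = c("linear", "relu")) {
  decoder_act <- match.arg(decoder_act)
  stopifnot(all(is.finite(input)))
  layers <- list(.mk_layer(ncol(input), hidden_size, "relu"),
                 .mk_layer(hidden_size, ncol(input), decoder_act))
  fit <- .net_train(input, input, layers, cfg$pretrain_epochs,
                    cfg$batch_size, cfg$learning_rate,
                    drop = c(cfg$dropout, cfg$dropout))
  enc <- .net_forward(input, fit$layers[1L])$out
  list(encoder = fit$layers[[1L]], decoder = fit$layers[[2L]],
       encoding = enc, loss_trace = fit$trace)
}

#' Initial embedding from a stacked denoising autoencoder
#'
#' Greedy layer-wise pretraining of the `d -> hidden -> d_emb` encoder
#' (each layer a denoising autoencoder reconstructing the previous layer's
#' output), stacking with the mirrored decoder, end-to-end fine-tuning on
#' mean squared reconstruction error, and a final clean encoder pass.
#'
#' @param X Numeric matrix (n x d) or a `concat_matrix`.
#' @param cfg An [sae_config()].
#' @return List of class `sae_embedding`: `Y_init` (n x d_emb),
#'   `reconstruction_loss_trace` (fine-tuning per-epoch MSE),
#'   `pretrain_traces`, `encoder` (list of layers).
#' @export
build_and_finetune <- function(X, cfg = sae_config()) {
  if (inherits(X, "concat_matrix")) X <- X$data
  stopifnot(nrow(X) >= 2L)
  if (cfg$d_emb >= ncol(X)) {
    warning("d_emb >= input dimension: the autoencoder performs no compression")
  }
  set.seed(cfg$seed)
  l1 <- pretrain_layer(X, cfg$hidden, cfg, decoder_act = "linear")
  l2 <- pretrain_layer(l1$encoding, cfg$d_emb, cfg, decoder_act = "relu")
  stack <- list(l1$encoder, l2$encoder, l2$decoder, l1$decoder)
  fit <- .net_train(X, X, stack, cfg$finetune_epochs, cfg$batch_size,
                    cfg$learning_rate, drop = rep(0, 4L))
  Y <- .net_forward(X, fit$layers[1:2])$out
  structure(list(Y_init = Y,
                 reconstruction_loss_trace = fit$trace,
                 pretrain_traces = list(l1$loss_trace, l2$loss_trace),
                 encoder = fit$layers[1:2]),
            class = "sae_embedding")
}

#' PCA initial embedding (alternative initializer)
#'
#' Projects onto the top `d_emb` principal components; a deterministic,
#' training-free alternative to the autoencoder initializer.
#'
#' @param X Numeric matrix (n x d) or a `concat_matrix`.
#' @param d_emb Embedding dimension.
#' @return n x d_emb matrix of component scores.
#' @export
pca_initial_embedding <- function(X, d_emb) {
  if (inherits(X, "concat_matrix")) X <- X$data
  d_emb <- min(d_emb, ncol(X), nrow(X) - 1L)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = d_emb)
  sc <- pc$x[, seq_len(d_emb), drop = FALSE]
  unname(sc)
}
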