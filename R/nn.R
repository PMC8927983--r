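# Minimal feed-forward network engine with Adam, shared by the
# deconfounding autoencoder (adae.R) and the compression autoencoders
# (tau.R, grn.R). Everything is dense matrix algebra; instances are rows.
# Not exported: the public surface is the autoencoder-level functions.

nn_init <- function(sizes, acts, seed) {
  stopifnot(length(sizes) == length(acts) + 1L)
  set.seed(seed)
  layers <- vector("list", length(acts))
  for (l in seq_along(acts)) {
    fan_in <- sizes[l]
    fan_out <- sizes[l + 1L]
    # seeded uniform-He: limit sqrt(6/fan_in), biases zero
    lim <- sqrt(6 / fan_in)
    layers[[l]] <- list(
      W = matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
      b = numeric(fan_out)
    )
  }
  list(layers = layers, acts = acts, sizes = sizes)
}

nn_act <- function(z, act) {
  switch(act,
    relu     = pmax(z, 0),
    linear   = z,
    softplus = {
      # numerically stable log(1 + exp(z))
      out <- pmax(z, 0) + log1p(exp(-abs(z)))
      out
    },
    softmax  = {
      m <- apply(z, 1L, max)
      e <- exp(z - m)
      e / rowSums(e)
    },
    stop("unknown activation: ", act)
  )
}

# derivative wrt pre-activation, elementwise (softmax handled jointly
# with cross-entropy by the caller)
nn_act_grad <- function(z, act) {
  switch(act,
    relu     = (z > 0) * 1,
    linear   = array(1, dim(z)),
    softplus = 1 / (1 + exp(-z)),
    stop("no elementwise gradient for activation: ", act)
  )
}

# forward pass; X is n x sizes[1]. Returns activations A (A[[1]] = X) and
# pre-activations Z per layer.
nn_forward <- function(net, X) {
  L <- length(net$layers)
  A <- vector("list", L + 1L)
  Z <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% net$layers[[l]]$W, 2L, net$layers[[l]]$b, "+")
    A[[l + 1L]] <- nn_act(Z[[l]], net$acts[l])
  }
  list(A = A, Z = Z)
}

# backward pass. dtop: either gradient wrt the final activation (when
# top_is_dZ = FALSE) or directly wrt the final pre-activation (TRUE; used
# for softmax + cross-entropy). Returns per-layer gradients and the
# gradient wrt the input matrix (needed to chain through frozen networks).
nn_backward <- function(net, fwd, dtop, top_is_dZ = FALSE) {
  L <- length(net$layers)
  grads <- vector("list", L)
  dA <- dtop
  for (l in rev(seq_len(L))) {
    dZ <- if (l == L && top_is_dZ) dA else dA * nn_act_grad(fwd$Z[[l]], net$acts[l])
    grads[[l]] <- list(
      W = crossprod(fwd$A[[l]], dZ),
      b = colSums(dZ)
    )
    dA <- tcrossprod(dZ, net$layers[[l]]$W)
  }
  list(grads = grads, dX = dA)
}

adam_init <- function(net) {
  lapply(net$layers, function(ly) list(
    mW = array(0, dim(ly$W)), vW = array(0, dim(ly$W)),
    mb = numeric(length(ly$b)), vb = numeric(length(ly$b))
  ))
}

adam_step <- function(net, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(net$layers)) {
    g <- grads[[l]]
    s <- state[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    mW_hat <- s$mW / (1 - beta1^t)
    vW_hat <- s$vW / (1 - beta2^t)
    mb_hat <- s$mb / (1 - beta1^t)
    vb_hat <- s$vb / (1 - beta2^t)
    net$layers[[l]]$W <- net$layers[[l]]$W - lr * mW_hat / (sqrt(vW_hat) + eps)
    net$layers[[l]]$b <- net$layers[[l]]$b - lr * mb_hat / (sqrt(vb_hat) + eps)
    state[[l]] <- s
  }
  list(net = net, state = state)
}

nn_mse <- function(Xhat, X) mean((Xhat - X)^2)

# categorical cross-entropy; P n x K probabilities, y integer class 1..K
nn_xent <- function(P, y) {
  idx <- cbind(seq_along(y), y)
  -mean(log(pmax(P[idx], 1e-12)))
}

nn_onehot <- function(y, K) {
  Y <- matrix(0, length(y), K)
  Y[cbind(seq_along(y), y)] <- 1
  Y
}

# deterministic sub-seed derivation (kept below 2^31)
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 1103515245 + salt * 12345) %% 2147483647)
}
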