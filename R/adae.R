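#' Specification of the adversarial deconfounding autoencoder
#'
#' Architecture follows the deconfounding setup: encoder
#' `M -> ceiling(M/2) -> D` with ReLU, linear-output decoder mirroring it,
#' and an adversary `D -> 100 -> 100 -> S` (softmax) that tries to predict
#' the confounder class (data source) from the embedding. With
#' `lambda = 0` the model is a plain autoencoder.
#'
#' @param input_dim M, genes per sample.
#' @param embedding_dim D, size of the embedded layer (default 100).
#' @param hidden_dim encoder/decoder hidden size (default `ceiling(M/2)`).
#' @param adversary_hidden sizes of the adversary's hidden layers
#'   (default `c(100, 100)`).
#' @param lambda adversarial weight (>= 0; default 1 — the weight is a
#'   free hyperparameter placed on the CV grid).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param minibatch_size default 128.
#' @param max_epochs cap on alternation rounds (default 200).
#' @param patience stop after this many rounds without validation
#'   reconstruction improvement (default 10).
#' @param standardize per-gene centering/scaling before training,
#'   inverted on reconstruction (default TRUE).
#' @param seed integer; all initialization and shuffling derives from it.
#' @return An `adae_spec` list.
#' @export
adae_spec <- function(input_dim, embedding_dim = 100,
                      hidden_dim = ceiling(input_dim / 2),
                      adversary_hidden = c(100, 100), lambda = 1,
                      learning_rate = 1e-4, minibatch_size = 128,
                      max_epochs = 200, patience = 10,
                      standardize = TRUE, seed = 1) {
  if (embedding_dim >= input_dim)
    stop("embedding_dim must be smaller than input_dim")
  if (lambda < 0) stop("lambda must be >= 0")
  if (minibatch_size < 1) stop("minibatch_size must be >= 1")
  structure(list(input_dim = input_dim, embedding_dim = embedding_dim,
                 hidden_dim = hidden_dim, adversary_hidden = adversary_hidden,
                 lambda = lambda, learning_rate = learning_rate,
                 minibatch_size = minibatch_size, max_epochs = max_epochs,
                 patience = patience, standardize = standardize,
                 seed = seed), class = "adae_spec")
}

# Core trainer shared by the deconfounding AE (instances = samples) and
# the compression AEs (instances = genes). X: instances x features.
# y: integer confounder class per instance (or NULL). Alternation per
# round: (a) adversary frozen, autoencoder one full pass over shuffled
# minibatches on MSE - lambda * CE; (b) autoencoder frozen, adversary one
# full epoch on CE. The autoencoder and the adversary consume independent
# derived RNG streams, so the lambda = 0 trajectory is identical with and
# without an adversary attached.
adae_engine <- function(X, y, spec, embed_act = "relu", out_act = "linear",
                        val_idx = NULL) {
  if (!all(is.finite(X))) stop("non-finite values in input")
  n <- nrow(X); M <- ncol(X)
  stopifnot(M == spec$input_dim)

  center <- rep(0, M); scl <- rep(1, M)
  if (isTRUE(spec$standardize)) {
    center <- colMeans(X)
    scl <- pmax(apply(X, 2L, stats::sd), 1e-8)
  }
  Xs <- sweep(sweep(X, 2L, center, "-"), 2L, scl, "/")

  if (is.null(val_idx)) {
    set.seed(derive_seed(spec$seed, 1L))
    val_idx <- sample(n, max(1L, floor(0.2 * n)))
  }
  train_idx <- setdiff(seq_len(n), val_idx)
  if (!length(train_idx)) stop("no training samples left after split")

  enc <- nn_init(c(M, spec$hidden_dim, spec$embedding_dim),
                 c("relu", embed_act), derive_seed(spec$seed, 2L))
  dec <- nn_init(c(spec$embedding_dim, spec$hidden_dim, M),
                 c("relu", out_act), derive_seed(spec$seed, 3L))
  adv <- NULL; S <- 0L
  if (!is.null(y)) {
    S <- max(y)
    adv <- nn_init(c(spec$embedding_dim, spec$adversary_hidden, S),
                   c(rep("relu", length(spec$adversary_hidden)), "softmax"),
                   derive_seed(spec$seed, 4L))
  }
  st_enc <- adam_init(enc); st_dec <- adam_init(dec)
  st_adv <- if (!is.null(adv)) adam_init(adv)
  t_ae <- 0L; t_adv <- 0L

  recon_loss <- function(idx) {
    f <- nn_forward(enc, Xs[idx, , drop = FALSE])
    g <- nn_forward(dec, f$A[[length(f$A)]])
    nn_mse(g$A[[length(g$A)]], Xs[idx, , drop = FALSE])
  }
  adv_eval <- function(idx) {
    if (is.null(adv)) return(c(NA_real_, NA_real_))
    f <- nn_forward(enc, Xs[idx, , drop = FALSE])
    P <- nn_forward(adv, f$A[[length(f$A)]])
    P <- P$A[[length(P$A)]]
    c(nn_xent(P, y[idx]), mean(max.col(P) == y[idx]))
  }

  hist <- list()
  best_val <- Inf; best_epoch <- 0L; best_w <- NULL
  for (r in seq_len(spec$max_epochs)) {
    # (a) autoencoder pass, adversary frozen
    set.seed(derive_seed(spec$seed, 100L + r))
    perm <- sample(train_idx)
    nb <- ceiling(length(perm) / spec$minibatch_size)
    for (b in seq_len(nb)) {
      idx <- perm[((b - 1L) * spec$minibatch_size + 1L):
                    min(b * spec$minibatch_size, length(perm))]
      Xb <- Xs[idx, , drop = FALSE]
      fe <- nn_forward(enc, Xb)
      E <- fe$A[[length(fe$A)]]
      fd <- nn_forward(dec, E)
      Xhat <- fd$A[[length(fd$A)]]
      dXhat <- 2 * (Xhat - Xb) / length(Xb)
      bd <- nn_backward(dec, fd, dXhat)
      dE <- bd$dX
      if (!is.null(adv) && spec$lambda > 0) {
        fa <- nn_forward(adv, E)
        P <- fa$A[[length(fa$A)]]
        dZ <- (P - nn_onehot(y[idx], S)) / length(idx)
        ba <- nn_backward(adv, fa, dZ, top_is_dZ = TRUE)
        dE <- dE - spec$lambda * ba$dX
      }
      be <- nn_backward(enc, fe, dE)
      t_ae <- t_ae + 1L
      up <- adam_step(enc, be$grads, st_enc, t_ae, spec$learning_rate)
      enc <- up$net; st_enc <- up$state
      up <- adam_step(dec, bd$grads, st_dec, t_ae, spec$learning_rate)
      dec <- up$net; st_dec <- up$state
    }
    # (b) adversary epoch, autoencoder frozen
    if (!is.null(adv)) {
      fe <- nn_forward(enc, Xs[train_idx, , drop = FALSE])
      Etr <- fe$A[[length(fe$A)]]
      set.seed(derive_seed(spec$seed, 200000L + r))
      perm2 <- sample(seq_along(train_idx))
      for (b in seq_len(nb)) {
        ii <- perm2[((b - 1L) * spec$minibatch_size + 1L):
                      min(b * spec$minibatch_size, length(perm2))]
        fa <- nn_forward(adv, Etr[ii, , drop = FALSE])
        P <- fa$A[[length(fa$A)]]
        dZ <- (P - nn_onehot(y[train_idx][ii], S)) / length(ii)
        ba <- nn_backward(adv, fa, dZ, top_is_dZ = TRUE)
        t_adv <- t_adv + 1L
        up <- adam_step(adv, ba$grads, st_adv, t_adv, spec$learning_rate * 10)
        adv <- up$net; st_adv <- up$state
      }
    }
    val <- recon_loss(val_idx)
    av <- adv_eval(val_idx)
    hist[[r]] <- c(epoch = r, train_recon = recon_loss(train_idx),
                   val_recon = val, adv_val_xent = av[1L],
                   adv_val_acc = av[2L])
    if (val < best_val - 1e-12) {
      best_val <- val; best_epoch <- r
      if (spec$lambda == 0 || is.null(adv)) best_w <- list(enc = enc, dec = dec)
    }
    if (r - best_epoch >= spec$patience) break
  }
  # plain AE keeps the epoch minimizing validation loss; the adversarial
  # model keeps the final round (deconfounding accumulates over rounds)
  if (!is.null(best_w) && (spec$lambda == 0 || is.null(adv))) {
    enc <- best_w$enc; dec <- best_w$dec
  }
  list(encoder = enc, decoder = dec, adversary = adv,
       history = as.data.frame(do.call(rbind, hist)),
       center = center, scale = scl, best_epoch = best_epoch,
       best_val_recon = best_val, final_val_recon = recon_loss(val_idx),
       train_idx = train_idx, val_idx = val_idx)
}

labels_to_int <- function(labels, sample_ids) {
  if (is.null(names(labels))) {
    stopifnot(length(labels) == length(sample_ids))
    lab <- as.character(labels)
  } else {
    miss <- setdiff(sample_ids, names(labels))
    if (length(miss)) stop("unlabeled sample: ", paste(miss, collapse = ", "))
    lab <- as.character(labels[sample_ids])
  }
  lev <- sort(unique(lab))
  list(y = match(lab, lev), levels = lev)
}

#' Train a plain autoencoder on an expression bundle
#'
#' Minimizes mean squared reconstruction error with Adam under an 80/20
#' train/validation split; the returned weights are those of the epoch
#' minimizing validation loss. Samples are the training instances.
#'
#' @param bundle an [expression_bundle()] (any unit; values must be
#'   finite).
#' @param spec an [adae_spec()]; its `lambda` is ignored (treated as 0).
#' @return An `adae_model` with elements `encoder`, `decoder`,
#'   `adversary` (NULL here), `history`, standardization parameters and
#'   the bundle's gene order.
#' @export
train_autoencoder <- function(bundle, spec) {
  stopifnot(inherits(bundle, "expression_bundle"), inherits(spec, "adae_spec"))
  spec$lambda <- 0
  fit <- adae_engine(t(bundle$matrix), NULL, spec)
  structure(c(fit, list(spec = spec, gene_ids = rownames(bundle$matrix),
                        unit = bundle$unit, classes = NULL)),
            class = "adae_model")
}

#' Train the adversarial deconfounding autoencoder
#'
#' Alternates per round: (a) with the adversary frozen, the autoencoder
#' takes one full pass over shuffled minibatches against
#' `||x - g(f(x))||^2 - lambda * CE(h(f(x)), c)`; (b) with the
#' autoencoder frozen, the adversary trains one full epoch on the
#' cross-entropy. At convergence the adversary should predict the
#' confounder at chance while reconstruction stays good.
#'
#' @param bundle an [expression_bundle()].
#' @param labels confounder classes: a named vector (sample ID -> class)
#'   or a vector aligned with the bundle's columns. Defaults to the
#'   bundle's `source` column when `NULL`.
#' @param spec an [adae_spec()] with `lambda > 0` (with `lambda = 0` the
#'   trajectory equals [train_autoencoder()] under the same seed, and the
#'   adversary is still fitted as a diagnostic).
#' @return An `adae_model`; `$history` has per-epoch reconstruction and
#'   adversary losses, `$classes` the confounder levels.
#' @export
train_adae <- function(bundle, labels = NULL, spec) {
  stopifnot(inherits(bundle, "expression_bundle"), inherits(spec, "adae_spec"))
  if (is.null(labels))
    labels <- stats::setNames(bundle$sample_meta$source,
                              bundle$sample_meta$sample_id)
  li <- labels_to_int(labels, colnames(bundle$matrix))
  if (length(li$levels) < 2L && spec$lambda > 0) {
    warning("single confounder class: degenerating to a plain autoencoder")
    spec$lambda <- 0
  }
  fit <- adae_engine(t(bundle$matrix), li$y, spec)
  structure(c(fit, list(spec = spec, gene_ids = rownames(bundle$matrix),
                        unit = bundle$unit, classes = li$levels)),
            class = "adae_model")
}

model_forward <- function(model, bundle) {
  if (!identical(model$gene_ids, rownames(bundle$matrix)))
    stop("gene order mismatch between model and bundle (no silent reordering)")
  X <- t(bundle$matrix)
  sweep(sweep(X, 2L, model$center, "-"), 2L, model$scale, "/")
}

#' Embed samples with a trained (AD-)AE
#'
#' @param model an `adae_model`.
#' @param bundle an [expression_bundle()] with the model's exact gene
#'   order.
#' @return samples x D embedding matrix (rownames = sample IDs).
#' @export
encode <- function(model, bundle) {
  Xs <- model_forward(model, bundle)
  f <- nn_forward(model$encoder, Xs)
  E <- f$A[[length(f$A)]]
  rownames(E) <- colnames(bundle$matrix)
  colnames(E) <- paste0("dim_", seq_len(ncol(E)))
  E
}

#' Reconstruct expression through a trained (AD-)AE
#'
#' Deterministic forward pass; standardization is inverted so the output
#' is on the input scale. The result keeps gene/sample IDs and unit and
#' is tagged `reconstructed`.
#'
#' @inheritParams encode
#' @return An [expression_bundle()] with `reconstructed = TRUE`.
#' @export
reconstruct <- function(model, bundle) {
  Xs <- model_forward(model, bundle)
  f <- nn_forward(model$encoder, Xs)
  g <- nn_forward(model$decoder, f$A[[length(f$A)]])
  Xhat <- g$A[[length(g$A)]]
  Xhat <- sweep(sweep(Xhat, 2L, model$scale, "*"), 2L, model$center, "+")
  mat <- t(Xhat)
  dimnames(mat) <- dimnames(bundle$matrix)
  if (bundle$unit != "log2") mat[mat < 0] <- 0
  expression_bundle(mat, bundle$sample_meta, bundle$unit,
                    reconstructed = TRUE)
}

#' Adversary accuracy on a set of samples
#'
#' @param model an `adae_model` trained with labels.
#' @param bundle bundle to evaluate on.
#' @param labels confounder labels (defaults to `source`).
#' @param idx optional integer subset of samples (e.g. the model's
#'   `val_idx` for held-out accuracy).
#' @return fraction of samples whose confounder class the adversary
#'   predicts correctly.
#' @export
adversary_accuracy <- function(model, bundle, labels = NULL, idx = NULL) {
  if (is.null(model$adversary)) stop("model has no adversary")
  if (is.null(labels))
    labels <- stats::setNames(bundle$sample_meta$source,
                              bundle$sample_meta$sample_id)
  lab <- as.character(labels[colnames(bundle$matrix)])
  E <- encode(model, bundle)
  if (!is.null(idx)) { E <- E[idx, , drop = FALSE]; lab <- lab[idx] }
  P <- nn_forward(model$adversary, E)
  P <- P$A[[length(P$A)]]
  mean(model$classes[max.col(P)] == lab)
}

#' Softmax-regression probe accuracy on an embedding
#'
#' Fits a multinomial logistic probe on the training rows of an embedding
#' and reports accuracy on held-out rows. Used to check that biological
#' signal (e.g. tissue) survives deconfounding.
#'
#' @param embedding samples x D matrix.
#' @param labels class labels aligned with embedding rows.
#' @param train_idx,test_idx row indices; default 80/20 split by `seed`.
#' @param seed,iters,lr probe training controls.
#' @return held-out accuracy in `[0, 1]`.
#' @export
probe_accuracy <- function(embedding, labels, train_idx = NULL,
                           test_idx = NULL, seed = 1, iters = 400,
                           lr = 0.05) {
  lab <- as.character(labels)
  lev <- sort(unique(lab))
  y <- match(lab, lev)
  n <- nrow(embedding)
  if (is.null(train_idx)) {
    set.seed(derive_seed(seed, 9L))
    test_idx <- sample(n, max(1L, floor(0.2 * n)))
    train_idx <- setdiff(seq_len(n), test_idx)
  }
  ctr <- colMeans(embedding[train_idx, , drop = FALSE])
  scl <- pmax(apply(embedding[train_idx, , drop = FALSE], 2L, stats::sd), 1e-8)
  Z <- sweep(sweep(embedding, 2L, ctr, "-"), 2L, scl, "/")
  net <- nn_init(c(ncol(Z), length(lev)), "softmax", derive_seed(seed, 10L))
  st <- adam_init(net)
  for (t in seq_len(iters)) {
    f <- nn_forward(net, Z[train_idx, , drop = FALSE])
    P <- f$A[[2L]]
    dZtop <- (P - nn_onehot(y[train_idx], length(lev))) / length(train_idx)
    b <- nn_backward(net, f, dZtop, top_is_dZ = TRUE)
    up <- adam_step(net, b$grads, st, t, lr)
    net <- up$net; st <- up$state
  }
  f <- nn_forward(net, Z[test_idx, , drop = FALSE])
  mean(max.col(f$A[[2L]]) == y[test_idx])
}

#' Fivefold cross-validated hyperparameter selection for the AD-AE
#'
#' Evaluates each grid point with fivefold CV over samples and selects
#' the one minimizing mean validation reconstruction loss subject to the
#' adversary's held-fold accuracy being at most `chance + margin`; ties
#' break toward smaller embedding dimension. If no point satisfies the
#' constraint, the minimum-reconstruction point is returned with a
#' warning.
#'
#' @param bundle an [expression_bundle()] with at least 5 samples.
#' @param labels confounder labels (default: `source` column).
#' @param grid non-empty list of lists of [adae_spec()] overrides (e.g.
#'   `list(list(embedding_dim = 2), list(embedding_dim = 50))`).
#' @param base_spec spec providing the non-gridded fields.
#' @param margin adversary-accuracy slack above chance (default 0.1).
#' @param folds number of CV folds (default 5).
#' @param tie_tol relative reconstruction-loss tolerance within which grid
#'   points count as tied (default 0.05); among tied points the smallest
#'   embedding dimension wins. A strict float comparison would never tie.
#' @return the chosen `adae_spec`, with a `cv` attribute holding the
#'   per-point table.
#' @export
select_hyperparameters <- function(bundle, labels = NULL, grid,
                                   base_spec = NULL, margin = 0.1,
                                   folds = 5, tie_tol = 0.05) {
  stopifnot(inherits(bundle, "expression_bundle"))
  if (!length(grid)) stop("grid must be non-empty")
  n <- ncol(bundle$matrix)
  if (n < folds) stop("need at least ", folds, " samples for ", folds,
                      "-fold CV")
  if (is.null(labels))
    labels <- stats::setNames(bundle$sample_meta$source,
                              bundle$sample_meta$sample_id)
  if (is.null(base_spec))
    base_spec <- adae_spec(input_dim = nrow(bundle$matrix))
  li <- labels_to_int(labels, colnames(bundle$matrix))
  chance <- max(table(li$y)) / n  # majority-class chance level
  set.seed(derive_seed(base_spec$seed, 777L))
  fold_id <- sample(rep_len(seq_len(folds), n))
  X <- t(bundle$matrix)
  rows <- lapply(seq_along(grid), function(gi) {
    sp <- base_spec
    for (f in names(grid[[gi]])) sp[[f]] <- grid[[gi]][[f]]
    res <- vapply(seq_len(folds), function(k) {
      fit <- adae_engine(X, li$y, sp, val_idx = which(fold_id == k))
      acc <- if (!is.null(fit$adversary)) {
        utils::tail(fit$history$adv_val_acc, 1L)
      } else NA_real_
      c(fit$best_val_recon, acc)
    }, numeric(2L))
    data.frame(point = gi, embedding_dim = sp$embedding_dim,
               lambda = sp$lambda, mean_val_recon = mean(res[1L, ]),
               mean_adv_acc = mean(res[2L, ]))
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$mean_adv_acc) & tab$mean_adv_acc <= chance + margin
  if (!any(ok)) {
    if (all(is.na(tab$mean_adv_acc))) ok <- rep(TRUE, nrow(tab))
    else {
      warning("no grid point met the adversary-accuracy constraint; ",
              "returning the minimum-reconstruction point")
      ok <- rep(TRUE, nrow(tab))
    }
  }
  cand <- tab[ok, , drop = FALSE]
  lo <- min(cand$mean_val_recon)
  tied <- cand[cand$mean_val_recon <= lo * (1 + tie_tol) + 1e-12, ,
               drop = FALSE]
  tied <- tied[order(tied$embedding_dim, tied$mean_val_recon), , drop = FALSE]
  best <- grid[[tied$point[1L]]]
  sp <- base_spec
  for (f in names(best)) sp[[f]] <- best[[f]]
  attr(sp, "cv") <- tab
  sp
}
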