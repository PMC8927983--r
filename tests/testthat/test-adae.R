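# Autoencoder / adversarial-deconfounding contracts. Training specs use
# the fast settings from helper-fixtures.R; architectures are unchanged.

subspace_bundle <- function(n = 120, M = 40, D = 3, noise = 0, seed = 42) {
  set.seed(seed)
  Z <- matrix(rnorm(n * D), n, D)
  W <- matrix(rnorm(D * M), D, M)
  X <- Z %*% W + matrix(rnorm(n * M, 0, noise), n, M)
  mat <- t(X) - min(X)
  dimnames(mat) <- list(sprintf("g%03d", 1:M), sprintf("s%03d", 1:n))
  toy_bundle(mat, unit = "intensity",
             source = rep(c("srcA", "srcB"), length.out = n))
}

test_that("AE recovers a low-dimensional linear subspace", {
  b <- subspace_bundle()
  sp <- fast_adae_spec(40, 3, seed = 3, max_epochs = 300)
  sp$learning_rate <- 3e-3
  m <- train_autoencoder(b, sp)
  # data variance on the standardized training scale is ~1 per gene, so
  # best validation MSE < 0.01 means < 1% of data variance unexplained
  expect_lt(m$best_val_recon, 0.01)
})

test_that("constant dataset reconstructs exactly with constant embedding", {
  mat <- matrix(5, 20, 30, dimnames = list(sprintf("g%03d", 1:20),
                                           sprintf("s%03d", 1:30)))
  b <- toy_bundle(mat, unit = "intensity")
  m <- train_autoencoder(b, fast_adae_spec(20, 2, seed = 1, max_epochs = 5))
  expect_lt(m$best_val_recon, 1e-6)
  E <- encode(m, b)
  expect_lt(max(apply(E, 2, sd)), 1e-8)
  rec <- reconstruct(m, b)
  expect_equal(rec$matrix, mat, tolerance = 1e-6)
  expect_true(rec$reconstructed)
})

test_that("training is deterministic and lambda = 0 reduces to the plain AE", {
  b <- subspace_bundle(n = 60, M = 20, noise = 0.1)
  sp <- fast_adae_spec(20, 3, lambda = 0, seed = 3, max_epochs = 8)
  m1 <- train_autoencoder(b, sp)
  m2 <- train_autoencoder(b, sp)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$encoder, m2$encoder)
  # with an adversary attached but lambda = 0 the AE trajectory is identical
  ma <- train_adae(b, spec = sp)
  expect_equal(ma$history$val_recon, m1$history$val_recon)
  expect_equal(ma$history$train_recon, m1$history$train_recon)
  expect_identical(ma$encoder, m1$encoder)
  # non-finite input is rejected; D >= M is rejected
  bb <- b; bb$matrix[1, 1] <- NA
  expect_error(train_autoencoder(bb, sp), "finite")
  expect_error(adae_spec(input_dim = 20, embedding_dim = 20),
               "embedding_dim")
})

test_that("adversary outputs a probability simplex point per sample", {
  b <- subspace_bundle(n = 60, M = 20, noise = 0.1)
  sp <- fast_adae_spec(20, 4, lambda = 1, seed = 2, max_epochs = 6)
  m <- train_adae(b, spec = sp)
  E <- encode(m, b)
  P <- deconet:::nn_forward(m$adversary, E)
  P <- P$A[[length(P$A)]]
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-12)
  expect_true(all(P >= 0))
})

test_that("encode/reconstruct bookkeeping: per-sample ops, finite outputs", {
  b <- subspace_bundle(n = 50, M = 20, noise = 0.1)
  m <- train_autoencoder(b, fast_adae_spec(20, 3, seed = 4, max_epochs = 10))
  E <- encode(m, b)
  set.seed(8)
  perm <- sample(ncol(b$matrix))
  bp <- subset_samples(b, colnames(b$matrix)[perm])
  expect_equal(encode(m, bp), E[perm, , drop = FALSE])
  # zero-input sample stays finite
  bz <- b; bz$matrix[, 1] <- 0
  expect_true(all(is.finite(encode(m, bz))))
  expect_true(all(is.finite(reconstruct(m, bz)$matrix)))
  # gene-order mismatch errors, no silent reordering
  br <- b
  br$matrix <- br$matrix[rev(seq_len(nrow(br$matrix))), ]
  expect_error(encode(m, br), "gene order")
  # reconstruction is lossy: re-encoding reconstructed data differs
  rec <- reconstruct(m, b)
  expect_false(isTRUE(all.equal(encode(m, rec), E)))
})

test_that("deconfounding removes source information but keeps tissue signal", {
  # smaller sibling of acceptance criterion 4, single seed
  cfg <- sim_config(n_genes = 200, n_tissues = 3, samples_per_group = 30,
                    n_sources = 4, n_specific_per_tissue = 20,
                    confounder_effect = 1.5, seed = 21)
  sim <- simulate_bundle(cfg)
  lb <- log2_transform(sim$bundle)
  sp1 <- fast_adae_spec(200, 64, lambda = 1, seed = 5, max_epochs = 150)
  m1 <- train_adae(lb, spec = sp1)
  acc1 <- adversary_accuracy(m1, lb, idx = m1$val_idx)
  sp0 <- fast_adae_spec(200, 64, lambda = 0, seed = 5, max_epochs = 60)
  m0 <- train_adae(lb, spec = sp0)
  acc0 <- adversary_accuracy(m0, lb, idx = m0$val_idx)
  # directional contract at reduced scale (the full-margin version is
  # acceptance criterion 4): deconfounding collapses adversary accuracy
  # while a tissue probe on the embedding stays informative
  expect_lte(acc1, acc0 - 0.2)
  cond <- ifelse(lb$sample_meta$group == "control", "control",
                 lb$sample_meta$tissue)
  pa <- probe_accuracy(encode(m1, lb), cond, train_idx = m1$train_idx,
                       test_idx = m1$val_idx, seed = 2, iters = 600)
  expect_gte(pa, 0.6)
})

test_that("adversary accuracy decreases in lambda on average (5 seeds)", {
  accs <- matrix(NA_real_, 5, 3, dimnames = list(NULL, c("0", "0.1", "1")))
  for (i in 1:5) {
    cfg <- sim_config(n_genes = 120, n_tissues = 2, samples_per_group = 30,
                      n_sources = 3, n_specific_per_tissue = 10,
                      confounder_effect = 1.5, n_tfs = 2, targets_per_tf = 2,
                      n_diff_pairs = 2, seed = 30 + i)
    lb <- log2_transform(simulate_bundle(cfg)$bundle)
    for (lam in c(0, 0.1, 1)) {
      sp <- fast_adae_spec(120, 24, lambda = lam, seed = 7, max_epochs = 120)
      m <- train_adae(lb, spec = sp)
      accs[i, as.character(lam)] <-
        adversary_accuracy(m, lb, idx = m$val_idx)
    }
  }
  mu <- colMeans(accs)
  expect_gte(mu["0"], mu["0.1"])
  expect_gte(mu["0.1"], mu["1"])
})

test_that("hyperparameter CV mechanics: single point, determinism, errors", {
  b <- subspace_bundle(n = 40, M = 20, noise = 0.1)
  base <- fast_adae_spec(20, 3, lambda = 0, seed = 3, max_epochs = 6)
  ch <- select_hyperparameters(b, grid = list(list(embedding_dim = 3)),
                               base_spec = base)
  expect_equal(ch$embedding_dim, 3)
  cv1 <- attr(select_hyperparameters(b, grid = list(list(embedding_dim = 3)),
                                     base_spec = base), "cv")
  expect_identical(attr(ch, "cv"), cv1) # fold assignment reproducible
  small <- subset_samples(b, colnames(b$matrix)[1:4])
  expect_error(select_hyperparameters(small,
                                      grid = list(list(embedding_dim = 2)),
                                      base_spec = base), "5")
  expect_error(select_hyperparameters(b, grid = list(), base_spec = base),
               "non-empty")
})

test_that("single confounder class degenerates to plain AE with a warning", {
  b <- subspace_bundle(n = 40, M = 20, noise = 0.1)
  b$sample_meta$source <- "only"
  sp <- fast_adae_spec(20, 3, lambda = 1, seed = 3, max_epochs = 4)
  expect_warning(m <- train_adae(b, spec = sp), "single confounder")
  expect_equal(m$spec$lambda, 0)
})
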