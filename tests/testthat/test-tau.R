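test_that("compute_tau matches hand-evaluated cases and brute force", {
  expect_equal(compute_tau(c(4, 0, 0, 0)), 1)
  expect_equal(compute_tau(c(2, 2, 2, 2)), 0)
  expect_equal(compute_tau(c(8, 4, 2, 2)), 2 / 3)
  # brute-force oracle on random vectors, matrix and vector paths agree
  brute <- function(y) {
    yh <- y / max(y)
    s <- 0
    for (v in yh) s <- s + (1 - v)
    s / (length(y) - 1)
  }
  set.seed(1)
  Y <- matrix(runif(200 * 5, 0, 10), 200, 5,
              dimnames = list(sprintf("g%03d", 1:200), NULL))
  tm <- compute_tau(Y)
  for (i in seq_len(nrow(Y))) {
    expect_equal(tm[[i]], brute(Y[i, ]), tolerance = 1e-12)
    expect_equal(compute_tau(Y[i, ]), brute(Y[i, ]), tolerance = 1e-12)
  }
  # all-zero gene: undefined (NA), flagged out of selection
  expect_true(is.na(compute_tau(c(0, 0, 0))))
  expect_error(compute_tau(c(-1, 2)), "non-negative")
})

test_that("tau invariances: positive scaling and monotone decrease", {
  set.seed(2)
  for (i in 1:50) {
    y <- runif(6, 0, 5)
    expect_equal(compute_tau(y), compute_tau(y * runif(1, 0.1, 100)),
                 tolerance = 1e-12)
    # decreasing a non-maximal component cannot decrease tau
    j <- which(y < max(y))[1]
    y2 <- y; y2[j] <- y2[j] * runif(1)
    expect_gte(compute_tau(y2), compute_tau(y) - 1e-12)
  }
})

test_that("calibration recovers affine maps and preserves ranking", {
  set.seed(3)
  m <- runif(50, 1, 10)
  names(m) <- sprintf("g%03d", 1:50)
  # embedding already equal to the mean: identity
  out <- calibrate_across_conditions(list(leaf = m), list(leaf = m))
  expect_equal(out[, "leaf"], m, tolerance = 1e-10)
  # affine invertibility: embedding = 2*mean + 3 recovers the mean exactly
  out2 <- calibrate_across_conditions(list(leaf = 2 * m + 3),
                                      list(leaf = m))
  expect_equal(out2[, "leaf"], m, tolerance = 1e-10)
  expect_identical(order(out2[, "leaf"]), order(m))
  expect_error(
    calibrate_across_conditions(list(leaf = stats::setNames(rep(1, 50),
                                                            names(m))),
                                list(leaf = m)),
    "zero-variance")
})

test_that("selection applies the interpolated Q3 threshold and argmax rule", {
  tab <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    tau = c(1.0, 0.9, 0.2, 0.1),
    argmax = c("leaf", "leaf", "root", "leaf"))
  sets <- select_specific_genes(tab)
  expect_equal(attr(sets, "threshold"), 0.925) # type-7 interpolation
  expect_identical(sets$leaf, "g1")
  expect_length(sets$root, 0)
  # argmax = control is never selected regardless of tau
  tab2 <- tab; tab2$argmax[1] <- "control"
  sets2 <- select_specific_genes(tab2)
  expect_false("g1" %in% unlist(sets2))
  expect_error(select_specific_genes(tab[1:3, ]), "4")
})

test_that("compression embeddings are non-negative and track magnitude", {
  s <- simulate_bundle(sim_config(n_genes = 150, n_tissues = 2,
                                  samples_per_group = 30,
                                  n_specific_per_tissue = 15, n_tfs = 5,
                                  targets_per_tf = 2, n_diff_pairs = 2,
                                  seed = 9))
  b <- log2_transform(tpm_normalize(s$bundle, s$gene_lengths))
  leaf <- condition_bundle(b, "leaf")
  y <- compress_tissue(leaf, fast_compression_spec(ncol(leaf$matrix),
                                                   seed = 4,
                                                   max_epochs = 100,
                                                   patience = 25))
  expect_true(all(y >= 0))
  expect_gte(cor(y, rowMeans(leaf$matrix), method = "spearman"), 0.9)
  # identical inputs give identical outputs
  cm <- matrix(3, 40, 10, dimnames = list(sprintf("g%03d", 1:40),
                                          sprintf("s%03d", 1:10)))
  cb <- toy_bundle(cm, unit = "intensity")
  yc <- compress_tissue(cb, fast_compression_spec(10, seed = 2,
                                                  max_epochs = 10))
  expect_lt(diff(range(yc)), 1e-8)
  expect_error(compress_tissue(subset_samples(leaf,
                                              colnames(leaf$matrix)[1])),
               "2 samples")
})

test_that("embedding path and mean baseline both recover planted genes", {
  # clean simulation: both paths recall >= 0.9 (directional property under
  # heavy confounding is exercised at acceptance scale)
  s <- simulate_bundle(sim_config(n_genes = 400, n_tissues = 4,
                                  samples_per_group = 40,
                                  n_specific_per_tissue = 25,
                                  confounder_effect = 0.5, seed = 14))
  b <- log2_transform(tpm_normalize(s$bundle, s$gene_lengths))
  for (meth in c("autoencoder", "mean")) {
    vals <- condition_values(b, method = meth,
                             spec_fn = function(n, i)
                               fast_compression_spec(n, seed = 100 + i,
                                                     max_epochs = 100,
                                                     patience = 25))
    sets <- select_specific_genes(tau_table(vals))
    rep <- truth_recovery_report(sets, s$truth, "specific_genes")
    expect_gte(rep$overall$recall, 0.9)
  }
})

test_that("platform combination tags provenance and drops conflicts", {
  ma <- list(leaf = c("g1", "g2"), root = c("g5"))
  rs <- list(leaf = c("g2", "g3"), root = c("g6"))
  expect_message(out <- combine_platforms(ma, rs), NA)
  expect_setequal(out$gene_id[out$tissue == "leaf"], c("g1", "g2", "g3"))
  expect_equal(out$platform[out$gene_id == "g2"], "both")
  expect_equal(sort(out$platform[out$gene_id %in% c("g1", "g3")]),
               c("microarray", "rnaseq"))
  # identical sets: union is either set, all tagged both
  same <- combine_platforms(list(leaf = c("a", "b")),
                            list(leaf = c("a", "b")))
  expect_true(all(same$platform == "both"))
  # disjoint sets add up
  dis <- combine_platforms(list(leaf = "a"), list(leaf = "b"))
  expect_equal(nrow(dis), 2L)
  # cross-tissue claim on different platforms is dropped and logged
  expect_message(
    conf <- combine_platforms(list(leaf = "gX"), list(root = "gX")),
    "gX")
  expect_false("gX" %in% conf$gene_id)
  expect_identical(attr(conf, "conflicts"), "gX")
})
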