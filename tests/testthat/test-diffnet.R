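test_that("fisher_z closed forms, antisymmetry and clamping", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.54931, tolerance = 1e-5) # log(3)/2
  set.seed(1)
  r <- runif(1000, -0.99, 0.99)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-12)
  expect_warning(z1 <- fisher_z(1), "clamped")
  expect_equal(suppressWarnings(fisher_z(1)), atanh(1 - 1e-6))
})

test_that("diff_z closed form, symmetry and guards", {
  d <- diff_z(0.54931, 64, 0, 64)
  expect_equal(d$dz, 3.0337, tolerance = 1e-4) # 0.54931/sqrt(2/61)
  expect_equal(d$p, 0.00242, tolerance = 2e-3)
  expect_equal(diff_z(1.2, 30, 1.2, 30)$dz, 0)
  expect_equal(diff_z(1.2, 30, 1.2, 30)$p, 1)
  set.seed(2)
  for (i in 1:20) {
    z <- rnorm(2); n <- sample(5:80, 2)
    a <- diff_z(z[1], n[1], z[2], n[2])
    b <- diff_z(z[2], n[2], z[1], n[1])
    expect_equal(a$dz, -b$dz, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
  }
  expect_error(diff_z(1, 3, 0, 30), "n1")
  expect_error(diff_z(1, 30, 0, 2), "n2")
})

test_that("BH step-up matches the worked example and the stats oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(3)
  for (n in c(10, 100, 5000, 10000)) {
    p <- runif(n)^2
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("pairwise_diffcorr covers all pairs and degenerates correctly", {
  m <- rand_mat(12, 20, seed = 4)
  tab <- pairwise_diffcorr(m, m)
  expect_equal(nrow(tab), 12 * 11 / 2)
  expect_true(all(tab$dz == 0) && all(tab$p == 1))
  expect_true(all(tab$p_adj >= tab$p - 1e-15))
  expect_true(all(abs(tab$rho_tissue) <= 1))
  mz <- m; mz[3, ] <- 7
  expect_error(pairwise_diffcorr(mz, m), "g003")
  expect_error(pairwise_diffcorr(m, m[, 1:4]), "5 columns")
  expect_error(pairwise_diffcorr(m, rand_mat(12, 20, prefix = "x")),
               "universes")
})

test_that("permutation null: add-one arithmetic, determinism, modes", {
  # one overwhelming pair among small nulls: its pooled empirical p is the
  # add-one minimum 1/(1 + n_perm * P)
  set.seed(5)
  n <- 30
  base <- rand_mat(8, n, seed = 5)
  mt <- base; mc <- rand_mat(8, n, seed = 6)
  z <- rnorm(n)
  mt["g001", ] <- z + rnorm(n, 0, 0.1)
  mt["g002", ] <- z + rnorm(n, 0, 0.1)      # rho ~ +0.99 in tissue
  mc["g001", ] <- z + rnorm(n, 0, 0.1)
  mc["g002", ] <- -z + rnorm(n, 0, 0.1)     # rho ~ -0.99 in control
  pp <- permutation_null(mt, mc, n_perm = 50, seed = 9)
  P <- 8 * 7 / 2
  expect_equal(min(pp), 1 / (1 + 50 * P), tolerance = 1e-12)
  tab <- pairwise_diffcorr(mt, mc)
  expect_equal(which.min(pp),
               which(tab$gene_a == "g001" & tab$gene_b == "g002"))
  expect_identical(pp, permutation_null(mt, mc, n_perm = 50, seed = 9))
  pp2 <- permutation_null(mt, mc, n_perm = 20, seed = 9, pooled = FALSE)
  expect_true(all(pp2 >= 1 / 21 - 1e-15))
  expect_error(permutation_null(mt, mc, n_perm = 0), "n_perm")
})

test_that("network construction caps, signs and orders deterministically", {
  m1 <- rand_mat(10, 20, seed = 7)
  m2 <- rand_mat(10, 20, seed = 8)
  tab <- pairwise_diffcorr(m1, m2)
  net <- build_network(tab, cap = 1000)
  expect_equal(nrow(net$edges), nrow(tab)) # fewer pairs than the cap
  net1 <- build_network(tab, cap = 1)
  expect_equal(nrow(net1$edges), 1L)
  expect_equal(net1$edges$p_adj, min(tab$p_adj))
  expect_identical(build_network(tab, 10)$edges,
                   build_network(tab, 10)$edges)
  expect_true(all(net$edges$sign %in% c("gain", "loss")))
})

test_that("hub scores average dz over partners", {
  tab <- data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
                    dz = c(0, 0, 0))
  expect_true(all(hub_scores(tab)$score == 0))
  tab2 <- data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
                     dz = c(2, 2, 0))
  h <- hub_scores(tab2)
  expect_equal(h$gene_id[1], "a")
  expect_equal(h$score[h$gene_id == "a"], 2)
  expect_equal(h$score[h$gene_id == "b"], 1)
})

test_that("greedy modularity: cliques, determinism, disconnected parts", {
  cl <- function(nodes) {
    cc <- t(combn(nodes, 2))
    data.frame(gene_a = cc[, 1], gene_b = cc[, 2])
  }
  edges <- rbind(cl(paste0("a", 1:5)), cl(paste0("b", 1:5)),
                 data.frame(gene_a = "a1", gene_b = "b1"))
  mem <- detect_modules(edges)
  expect_equal(length(unique(mem)), 2L)
  expect_length(unique(mem[paste0("a", 1:5)]), 1L)
  expect_length(unique(mem[paste0("b", 1:5)]), 1L)
  expect_identical(detect_modules(edges), mem)
  # disconnected components never share a module
  disc <- rbind(cl(paste0("a", 1:4)), cl(paste0("b", 1:4)))
  md <- detect_modules(disc)
  expect_length(intersect(unique(md[paste0("a", 1:4)]),
                          unique(md[paste0("b", 1:4)])), 0L)
  expect_warning(iso <- detect_modules(edges[0, ], nodes = c("x", "y")),
                 "edgeless")
  expect_equal(length(unique(iso)), 2L)
})

test_that("adjusted Rand index behaves at its anchors", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)),
               adjusted_rand_index(c(2, 2, 1, 1), c(1, 2, 1, 2)))
  set.seed(10)
  x <- sample(3, 60, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(x, sample(x))), 0.3)
})

test_that("planted diff pairs travel through the latent-compression path", {
  # 64 latent columns rather than raw samples: the compression preserves
  # differential-pair structure only partially (clear enrichment, not the
  # raw-column top-1% ranking; see the methods vignette)
  cfg <- sim_config(n_genes = 80, n_tissues = 2, samples_per_group = 150,
                    n_specific_per_tissue = 5, n_tfs = 2, targets_per_tf = 2,
                    n_diff_pairs = 6, platform = "intensity_like", seed = 12)
  sim <- simulate_bundle(cfg)
  b <- log2_transform(sim$bundle)
  sp <- function(n) fast_compression_spec(n, embedding_dim = 64, seed = 5,
                                          max_epochs = 100, patience = 25)
  mt <- compress_samples(condition_bundle(b, "leaf"),
                         embedding_dim = 64,
                         spec = sp(ncol(condition_bundle(b, "leaf")$matrix)))
  mc <- compress_samples(condition_bundle(b, "control"),
                         embedding_dim = 64,
                         spec = sp(ncol(condition_bundle(b, "control")$matrix)))
  tab <- pairwise_diffcorr(mt, mc)
  keys <- pair_key(tab$gene_a, tab$gene_b)
  planted <- pair_key(sim$truth$diff_pairs$gene_a, sim$truth$diff_pairs$gene_b)
  au <- auroc(abs(tab$dz), keys %in% planted)
  expect_gte(au, 0.75)
})
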