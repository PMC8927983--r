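# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the whole suite stays inside a single-CPU budget.

# minimal metadata for a hand-built matrix
toy_meta <- function(sample_ids, tissue = "leaf", source = "srcA",
                     platform = "rnaseq", group = "case") {
  data.frame(sample_id = sample_ids,
             tissue = rep_len(tissue, length(sample_ids)),
             source = rep_len(source, length(sample_ids)),
             platform = rep_len(platform, length(sample_ids)),
             group = rep_len(group, length(sample_ids)),
             stringsAsFactors = FALSE)
}

toy_bundle <- function(mat, unit = "counts", ...) {
  expression_bundle(mat, toy_meta(colnames(mat), ...), unit)
}

# random named genes x samples matrix
rand_mat <- function(G, n, seed = 1, prefix = "g") {
  set.seed(seed)
  matrix(rnorm(G * n), G, n,
         dimnames = list(sprintf("%s%03d", prefix, seq_len(G)),
                         sprintf("s%03d", seq_len(n))))
}

# fast modularity of a membership vector (test-side oracle helper)
fast_q <- function(ia, ib, deg, m, part) {
  e_in <- sum(part[ia] == part[ib]) / m
  a <- tapply(deg, part[seq_along(deg)], sum) / (2 * m)
  e_in - sum(a^2)
}

# training spec used by tests: same architecture, faster optimizer settings
fast_adae_spec <- function(input_dim, embedding_dim, lambda = 0, seed = 1,
                          max_epochs = 60, ...) {
  adae_spec(input_dim = input_dim, embedding_dim = embedding_dim,
            lambda = lambda, learning_rate = 1e-3, minibatch_size = 32,
            max_epochs = max_epochs, patience = max_epochs, seed = seed, ...)
}

fast_compression_spec <- function(input_dim, embedding_dim = 1, seed = 1,
                                  max_epochs = 60, patience = 15) {
  compression_spec(input_dim = input_dim, embedding_dim = embedding_dim,
                   minibatch_size = 32, learning_rate = 1e-3,
                   max_epochs = max_epochs, patience = patience, seed = seed)
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "~")
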