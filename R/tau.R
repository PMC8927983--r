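#' Specification of the per-tissue compression autoencoder
#'
#' Genes are the training instances: each gene's N-sample profile is one
#' input vector. The embedding layer (size 1 for tissue-specificity
#' scoring, 64/32 for GRN latent matrices) uses a softplus activation so
#' compressed values are non-negative; the hidden layer is half the
#' sample number.
#'
#' @param input_dim N, samples of the tissue.
#' @param embedding_dim latent size (default 1).
#' @param hidden_dim default `ceiling(N/2)`.
#' @param minibatch_size default 12.
#' @param learning_rate Adam rate, default 1e-4.
#' @param max_epochs,patience early-stopping controls.
#' @param seed integer seed.
#' @return A `compression_spec` (an [adae_spec()] variant with softplus
#'   embedding and no standardization, so magnitude information is
#'   preserved).
#' @export
compression_spec <- function(input_dim, embedding_dim = 1,
                             hidden_dim = ceiling(input_dim / 2),
                             minibatch_size = 12, learning_rate = 1e-4,
                             max_epochs = 200, patience = 10, seed = 1) {
  if (embedding_dim >= input_dim)
    stop("embedding_dim must be smaller than the sample number")
  sp <- adae_spec(input_dim = input_dim, embedding_dim = embedding_dim,
                  hidden_dim = hidden_dim, lambda = 0,
                  learning_rate = learning_rate,
                  minibatch_size = minibatch_size, max_epochs = max_epochs,
                  patience = patience, standardize = FALSE, seed = seed)
  class(sp) <- c("compression_spec", class(sp))
  sp
}

# shared trainer for gene-profile compression (tau 1-D and GRN 64/32-D)
compress_genes <- function(mat, spec) {
  if (ncol(mat) < 2L) stop("need at least 2 samples to compress")
  fit <- adae_engine(mat, NULL, spec, embed_act = "softplus",
                     out_act = "softplus")
  f <- nn_forward(fit$encoder, mat)
  E <- f$A[[length(f$A)]]
  rownames(E) <- rownames(mat)
  colnames(E) <- paste0("latent_", seq_len(ncol(E)))
  attr(E, "history") <- fit$history
  E
}

#' Compress a tissue's expression to one value per gene
#'
#' Trains the 1-D compression autoencoder on the tissue's genes x samples
#' matrix and returns the softplus embedding: a learned non-negative
#' summary of each gene's expression magnitude in that tissue.
#'
#' @param tissue_bundle an [expression_bundle()] restricted to one
#'   condition (see [condition_bundle()]), typically log2 scale.
#' @param spec a [compression_spec()] with `embedding_dim = 1`; defaults
#'   are built from the bundle when `NULL`.
#' @return named numeric vector, one non-negative value per gene.
#' @export
compress_tissue <- function(tissue_bundle, spec = NULL) {
  stopifnot(inherits(tissue_bundle, "expression_bundle"))
  n <- ncol(tissue_bundle$matrix)
  if (n < 2L) stop("need at least 2 samples")
  if (is.null(spec)) spec <- compression_spec(input_dim = n)
  E <- compress_genes(tissue_bundle$matrix, spec)
  stats::setNames(E[, 1L], rownames(tissue_bundle$matrix))
}

#' Calibrate per-condition compressed values onto the expression scale
#'
#' Independently trained per-tissue embeddings have no common scale. Each
#' condition's embedding vector is least-squares mapped (slope and
#' intercept against that condition's per-gene mean expression) onto the
#' expression scale; negative calibrated values are clipped to 0.
#'
#' @param embeddings named list (condition -> per-gene vector) of
#'   compressed values, same gene universe everywhere.
#' @param means named list (condition -> per-gene mean expression).
#' @return genes x conditions matrix of calibrated values.
#' @export
calibrate_across_conditions <- function(embeddings, means) {
  conds <- names(embeddings)
  stopifnot(!is.null(conds), setequal(conds, names(means)))
  genes <- names(embeddings[[1L]])
  if (is.null(genes)) stop("embedding vectors must carry gene names")
  out <- matrix(NA_real_, length(genes), length(conds),
                dimnames = list(genes, conds))
  for (cn in conds) {
    e <- embeddings[[cn]][genes]
    m <- means[[cn]][genes]
    if (stats::sd(e) < 1e-12)
      stop("zero-variance embedding for condition '", cn,
           "'; fall back to per-condition mean expression")
    fit <- stats::lm.fit(cbind(1, e), m)
    y <- fit$coefficients[1L] + fit$coefficients[2L] * e
    out[, cn] <- pmax(y, 0)
  }
  out
}

#' Tissue-specificity index tau
#'
#' `tau = sum_i (1 - y_i / max(y)) / (n - 1)` over the n conditions
#' (tissues plus control): 1 when expressed in a single condition, 0 when
#' uniform. Requires non-negative values; an all-zero gene has undefined
#' tau (`NA`) and is excluded from selection downstream.
#'
#' @param y non-negative numeric vector (one gene across conditions), or
#'   a genes x conditions matrix.
#' @return tau in `[0, 1]` per gene (`NA` for all-zero genes).
#' @export
compute_tau <- function(y) {
  if (is.matrix(y)) {
    if (ncol(y) < 2L) stop("need at least 2 conditions")
    if (any(y < 0)) stop("tau requires non-negative values")
    mx <- apply(y, 1L, max)
    tau <- rowSums(1 - y / ifelse(mx > 0, mx, NA_real_)) / (ncol(y) - 1L)
    return(stats::setNames(tau, rownames(y)))
  }
  if (length(y) < 2L) stop("need at least 2 conditions")
  if (any(y < 0)) stop("tau requires non-negative values")
  if (max(y) == 0) return(NA_real_)
  sum(1 - y / max(y)) / (length(y) - 1L)
}

#' Build a tau table from calibrated per-condition values
#'
#' @param values genes x conditions matrix (conditions include
#'   `"control"`), e.g. from [calibrate_across_conditions()].
#' @return data.frame: gene_id, one `y_<condition>` column per condition,
#'   `tau`, `argmax` (condition of the maximum).
#' @export
tau_table <- function(values) {
  stopifnot(is.matrix(values), ncol(values) >= 2L)
  tau <- compute_tau(values)
  am <- colnames(values)[max.col(values, ties.method = "first")]
  am[is.na(tau)] <- NA_character_
  out <- data.frame(gene_id = rownames(values), stringsAsFactors = FALSE)
  for (cn in colnames(values)) out[[paste0("y_", cn)]] <- values[, cn]
  out$tau <- tau
  out$argmax <- am
  out
}

#' Select tissue-specific genes by the upper-quartile tau rule
#'
#' Threshold = 75th percentile (linear interpolation) of tau over all
#' scored genes. A gene is assigned to tissue t iff `tau >= threshold`,
#' its maximal condition is t, and t is not the control mixture. All-zero
#' (NA-tau) genes are never selected.
#'
#' @param tab a [tau_table()] data.frame (needs `gene_id`, `tau`,
#'   `argmax`).
#' @param control_label condition treated as the control mixture
#'   (default `"control"`).
#' @param quantile_prob selection quantile (default 0.75).
#' @return named list tissue -> character vector of gene IDs, with the
#'   threshold as attribute `threshold`.
#' @export
select_specific_genes <- function(tab, control_label = "control",
                                  quantile_prob = 0.75) {
  stopifnot(all(c("gene_id", "tau", "argmax") %in% names(tab)))
  scored <- tab[!is.na(tab$tau), , drop = FALSE]
  if (nrow(scored) < 4L) stop("need tau for at least 4 genes")
  thr <- stats::quantile(scored$tau, quantile_prob, type = 7, names = FALSE)
  tissues <- setdiff(sort(unique(scored$argmax)), control_label)
  sets <- lapply(tissues, function(t)
    scored$gene_id[scored$tau >= thr & scored$argmax == t])
  names(sets) <- tissues
  attr(sets, "threshold") <- thr
  sets
}

#' Per-condition compressed values for a whole bundle
#'
#' Convenience wrapper: splits a bundle into its tissue conditions (case
#' samples per tissue) plus the control mixture, compresses each to one
#' value per gene, and (by default) calibrates the per-condition vectors
#' against per-condition mean expression. With `method = "mean"` the
#' compression is skipped and per-condition mean expression is used
#' directly — the traditional baseline.
#'
#' @param bundle an [expression_bundle()] on the log2 scale (typically
#'   AD-AE-reconstructed).
#' @param method `"autoencoder"` (default) or `"mean"`.
#' @param spec_fn function(n_samples, condition_index) returning the
#'   [compression_spec()] to use; default uses package defaults with a
#'   per-condition derived seed.
#' @param seed master seed for per-condition spec derivation.
#' @param calibrate apply [calibrate_across_conditions()] (default TRUE).
#' @return genes x conditions matrix ready for [tau_table()].
#' @export
condition_values <- function(bundle, method = c("autoencoder", "mean"),
                             spec_fn = NULL, seed = 1, calibrate = TRUE) {
  method <- match.arg(method)
  tissues <- sort(unique(
    bundle$sample_meta$tissue[bundle$sample_meta$group == "case"]))
  conds <- c(tissues, "control")
  mats <- lapply(conds, function(cn) condition_bundle(bundle, cn)$matrix)
  names(mats) <- conds
  means <- lapply(mats, rowMeans)
  if (method == "mean")
    return(do.call(cbind, means)[rownames(bundle$matrix), , drop = FALSE])
  if (is.null(spec_fn))
    spec_fn <- function(n, i) compression_spec(
      input_dim = n, seed = derive_seed(seed, 3000L + i))
  emb <- lapply(seq_along(conds), function(i) {
    sp <- spec_fn(ncol(mats[[i]]), i)
    E <- compress_genes(mats[[i]], sp)
    stats::setNames(E[, 1L], rownames(mats[[i]]))
  })
  names(emb) <- conds
  if (calibrate) calibrate_across_conditions(emb, means)
  else do.call(cbind, emb)
}

#' Combine per-platform tissue gene sets
#'
#' Per tissue, the union of the microarray and RNA-seq sets; each gene is
#' tagged by provenance. A gene claimed by different tissues on different
#' platforms has no platform-agreement tissue and is dropped with a
#' logged conflict.
#'
#' @param sets_microarray,sets_rnaseq named lists tissue -> gene IDs.
#' @return data.frame (gene_id, tissue, platform); dropped conflicts are
#'   recorded in attribute `conflicts` and reported via `message()`.
#' @export
combine_platforms <- function(sets_microarray, sets_rnaseq) {
  tissues <- union(names(sets_microarray), names(sets_rnaseq))
  long <- function(sets, platform) {
    do.call(rbind, lapply(names(sets), function(t)
      if (length(sets[[t]])) data.frame(gene_id = sets[[t]], tissue = t,
                                        platform = platform,
                                        stringsAsFactors = FALSE)))
  }
  both <- rbind(long(sets_microarray, "microarray"),
                long(sets_rnaseq, "rnaseq"))
  if (is.null(both))
    return(structure(data.frame(gene_id = character(), tissue = character(),
                                platform = character()),
                     conflicts = character()))
  claim <- tapply(both$tissue, both$gene_id,
                  function(x) length(unique(x)))
  conflicted <- names(claim)[claim > 1L]
  if (length(conflicted))
    message("dropping ", length(conflicted),
            " gene(s) claimed by different tissues on different platforms: ",
            paste(conflicted, collapse = ", "))
  keep <- both[!both$gene_id %in% conflicted, , drop = FALSE]
  if (!nrow(keep))
    return(structure(data.frame(gene_id = character(), tissue = character(),
                                platform = character()),
                     conflicts = conflicted))
  agg <- stats::aggregate(platform ~ gene_id + tissue, keep, function(p)
    if (length(unique(p)) > 1L) "both" else unique(p))
  agg <- agg[order(agg$tissue, agg$gene_id), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, conflicts = conflicted)
}
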