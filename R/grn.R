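#' Embedding size rule for sample compression
#'
#' 64 latent dimensions when more than 64 samples are available, else 32;
#' fewer than 33 samples cannot support the 32-dimension fallback.
#'
#' @param n_samples sample count of the tissue.
#' @return 64 or 32.
#' @export
choose_embedding_dim <- function(n_samples) {
  if (n_samples > 64L) return(64L)
  if (n_samples > 32L) return(32L)
  stop("only ", n_samples,
       " samples: too few even for the 32-dimension fallback")
}

#' Compress a tissue's samples into a latent matrix for GRN inference
#'
#' Same machinery as [compress_tissue()] but with a 64- (or 32-)
#' dimensional embedding: rows are genes, columns are latent
#' pseudo-samples. Regulator-target dependence across samples is
#' preserved across the compression and drives the tree-ensemble scoring.
#'
#' @param tissue_bundle an [expression_bundle()] for one tissue.
#' @param embedding_dim latent size; `NULL` applies
#'   [choose_embedding_dim()].
#' @param spec optional [compression_spec()] override.
#' @param seed seed used when building the default spec.
#' @return genes x embedding_dim matrix.
#' @export
compress_samples <- function(tissue_bundle, embedding_dim = NULL,
                             spec = NULL, seed = 1) {
  stopifnot(inherits(tissue_bundle, "expression_bundle"))
  n <- ncol(tissue_bundle$matrix)
  if (is.null(embedding_dim)) embedding_dim <- choose_embedding_dim(n)
  if (embedding_dim >= n)
    stop("embedding_dim (", embedding_dim, ") must be below the sample ",
         "count (", n, "); consider the 32-dimension fallback")
  if (is.null(spec))
    spec <- compression_spec(input_dim = n, embedding_dim = embedding_dim,
                             seed = seed)
  compress_genes(tissue_bundle$matrix, spec)
}

#' Tree-ensemble gene regulatory network inference
#'
#' For each target gene, a regression random forest predicts its latent
#' (or expression) profile from the profiles of all candidate regulators
#' other than itself; the edge weight regulator -> target is the
#' regulator's accumulated impurity-reduction importance. Targets are
#' normalized to unit variance so importances are comparable across
#' targets; the global edge list is ranked by weight.
#'
#' @param mat genes x columns numeric matrix (latent pseudo-samples from
#'   [compress_samples()], or expression columns).
#' @param regulators character vector of TF gene IDs; intersected with
#'   the matrix's genes, at least 2 must remain.
#' @param targets target gene IDs (default: all genes in the matrix).
#' @param n_trees trees per target (default 1000).
#' @param min_split minimum node size to attempt a split (default 5).
#' @param seed master seed; per-target forests are seeded derivatively.
#' @param normalize if `TRUE` (default) per-target importances are also
#'   provided normalized to sum 1 (column `weight_norm`).
#' @return data.frame (`regulator`, `target`, `weight`, `weight_norm`)
#'   sorted by weight descending (ties by regulator then target ID);
#'   class `weighted_edge_list`. Zero-variance targets are skipped with
#'   a message.
#' @export
infer_grn <- function(mat, regulators, targets = NULL, n_trees = 1000,
                      min_split = 5, seed = 1, normalize = TRUE) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  # canonical (sorted) regulator order and name-derived per-target seeds
  # make the result invariant to the row order of the input matrix
  regulators <- sort(intersect(unique(regulators), rownames(mat)))
  if (length(regulators) < 2L)
    stop("need at least 2 regulators present in the matrix")
  if (is.null(targets)) targets <- rownames(mat)
  targets <- sort(intersect(targets, rownames(mat)))
  R <- t(mat[regulators, , drop = FALSE]) # columns = regulators
  out <- vector("list", length(targets))
  skipped <- character()
  for (k in seq_along(targets)) {
    tg <- targets[k]
    yv <- mat[tg, ]
    s <- stats::sd(yv)
    if (!is.finite(s) || s < 1e-12) {
      skipped <- c(skipped, tg)
      next
    }
    yv <- (yv - mean(yv)) / s
    preds <- setdiff(regulators, tg)
    Xk <- R[, preds, drop = FALSE]
    mtry <- max(1L, floor(sqrt(ncol(Xk))))
    h <- sum(utf8ToInt(tg) * seq_along(utf8ToInt(tg))) %% 100000L
    imp <- rf_importance_cpp(Xk, yv, as.integer(n_trees), mtry,
                             as.integer(min_split),
                             derive_seed(seed, 5000L + h))
    w <- pmax(imp, 0)
    out[[k]] <- data.frame(
      regulator = preds, target = tg, weight = w,
      weight_norm = if (normalize && sum(w) > 0) w / sum(w) else w,
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    message("skipped zero-variance target(s): ",
            paste(skipped, collapse = ", "))
  edges <- do.call(rbind, out)
  if (is.null(edges)) stop("no scorable targets")
  edges <- edges[order(-edges$weight, edges$regulator, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(edges, class = c("weighted_edge_list", "data.frame"),
            seed = seed, n_trees = n_trees)
}

#' Keep the top-k edges by weight
#'
#' Ties at the boundary break by (regulator, target) lexicographic order;
#' if fewer than k edges exist all are returned.
#'
#' @param edges a `weighted_edge_list` (or data.frame with `weight`).
#' @param k number of edges to keep (default 1000).
#' @return the truncated edge list.
#' @export
top_edges <- function(edges, k = 1000) {
  if (k < 1) stop("k must be >= 1")
  o <- order(-edges$weight, edges$regulator, edges$target)
  out <- edges[o[seq_len(min(k, nrow(edges)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank hub TFs by degree in a retained network
#'
#' Degree is the number of incident retained edges; `mode = "out"`
#' (default) counts a TF's outgoing edges, `"undirected"` counts every
#' incidence (a TF that is also a target gains degree from incoming
#' edges). Descending order, ties by ID.
#'
#' @param edges retained edge list (e.g. from [top_edges()]).
#' @param mode `"out"` or `"undirected"`.
#' @return data.frame (`tf`, `degree`) ranked.
#' @export
rank_hub_tfs <- function(edges, mode = c("out", "undirected")) {
  mode <- match.arg(mode)
  if (!nrow(edges)) stop("empty network")
  deg <- table(edges$regulator)
  if (mode == "undirected") {
    inc <- table(edges$target[edges$target %in% names(deg)])
    deg[names(inc)] <- deg[names(inc)] + inc
  }
  out <- data.frame(tf = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  out
}
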