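#' Fisher z-transformation of a Pearson correlation
#'
#' `z = 0.5 * log((1 + rho) / (1 - rho)) = atanh(rho)`; approximately
#' normal with variance `1/(n - 3)`. Correlations at or beyond +-1 are
#' clamped to `+-(1 - 1e-6)` with a warning.
#'
#' @param rho numeric vector of correlations.
#' @return z values.
#' @export
fisher_z <- function(rho) {
  if (any(abs(rho) >= 1)) {
    warning("correlation(s) with |rho| >= 1 clamped to 1 - 1e-6")
    rho <- pmin(pmax(rho, -(1 - 1e-6)), 1 - 1e-6)
  }
  atanh(rho)
}

#' Difference of Fisher z statistics and its two-sided p-value
#'
#' `dz = (z1 - z2) / sqrt(1/(n1 - 3) + 1/(n2 - 3))`, referred to the
#' standard normal: `p = 2 * (1 - Phi(|dz|))`. Group 1 is the tissue,
#' group 2 the control. (The sum-of-variances denominator is the
#' standard convention; a literal difference of variances vanishes for
#' equal group sizes.)
#'
#' @param z1,z2 Fisher z values.
#' @param n1,n2 column counts behind each correlation; must exceed 3.
#' @return list with `dz` and `p` (vectors).
#' @export
diff_z <- function(z1, n1, z2, n2) {
  if (any(n1 <= 3)) stop("n1 (tissue group) must be > 3")
  if (any(n2 <= 3)) stop("n2 (control group) must be > 3")
  dz <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(dz = dz, p = 2 * stats::pnorm(-abs(dz)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; rank order of
#' the p-values is preserved.
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  n <- length(p)
  if (n <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' All-pairs differential correlation between a tissue and the control
#'
#' Pearson correlation of every unordered gene pair in each condition,
#' Fisher z per condition, the dz statistic with normal-theory two-sided
#' p, and BH adjustment across all pairs. `n` for each correlation is
#' the column count of the matrix it was computed on (the latent
#' dimension when operating on compressed matrices).
#'
#' @param tissue_mat,control_mat genes x columns matrices over the same
#'   gene universe (rownames must match; >= 5 columns each). Genes must
#'   have non-zero variance in both (filter upstream).
#' @return data.frame of class `diffcorr_table`: `gene_a`, `gene_b`,
#'   `rho_tissue`, `rho_control`, `z1`, `z2`, `dz`, `p`, `p_adj`, `n1`,
#'   `n2`; one row per unordered pair.
#' @export
pairwise_diffcorr <- function(tissue_mat, control_mat) {
  stopifnot(is.matrix(tissue_mat), is.matrix(control_mat))
  if (!identical(rownames(tissue_mat), rownames(control_mat)))
    stop("gene universes differ between the two matrices")
  if (ncol(tissue_mat) < 5L || ncol(control_mat) < 5L)
    stop("need at least 5 columns per condition")
  for (nm in list(c("tissue", 1L), c("control", 2L))) {
    m <- if (nm[1L] == "tissue") tissue_mat else control_mat
    v <- apply(m, 1L, stats::sd)
    if (any(v < 1e-12))
      stop("zero-variance gene in ", nm[1L], " matrix: ",
           paste(rownames(m)[v < 1e-12], collapse = ", "),
           " (filter upstream)")
  }
  g <- rownames(tissue_mat)
  C1 <- stats::cor(t(tissue_mat))
  C2 <- stats::cor(t(control_mat))
  ut <- upper.tri(C1)
  ij <- which(ut, arr.ind = TRUE)
  r1 <- C1[ut]; r2 <- C2[ut]
  z1 <- fisher_z(r1); z2 <- fisher_z(r2)
  dd <- diff_z(z1, ncol(tissue_mat), z2, ncol(control_mat))
  out <- data.frame(
    gene_a = g[ij[, 1L]], gene_b = g[ij[, 2L]],
    rho_tissue = r1, rho_control = r2, z1 = z1, z2 = z2,
    dz = dd$dz, p = dd$p, p_adj = bh_adjust(dd$p),
    n1 = ncol(tissue_mat), n2 = ncol(control_mat),
    stringsAsFactors = FALSE)
  structure(out, class = c("diffcorr_table", "data.frame"))
}

#' Permutation null for the differential-correlation statistic
#'
#' Pools the two matrices' columns and repeatedly reassigns columns to
#' two groups of the original sizes, recomputing dz for every pair.
#' Empirical p-values use the add-one rule. With `pooled = TRUE`
#' (default, makes 100 permutations informative) the null is pooled
#' across pairs: `p = (1 + #\{permuted |dz| >= observed\}) /
#' (1 + n_perm * n_pairs)`; with `pooled = FALSE` each pair is compared
#' only against its own permuted values.
#'
#' @inheritParams pairwise_diffcorr
#' @param n_perm number of permutations (default 100).
#' @param seed RNG seed.
#' @param pooled pool the null across pairs (default TRUE).
#' @return numeric vector of empirical p-values in the pair order of
#'   [pairwise_diffcorr()].
#' @export
permutation_null <- function(tissue_mat, control_mat, n_perm = 100,
                             seed = 1, pooled = TRUE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs <- pairwise_diffcorr(tissue_mat, control_mat)
  pooled_mat <- cbind(tissue_mat, control_mat)
  n1 <- ncol(tissue_mat); n2 <- ncol(control_mat)
  set.seed(seed)
  P <- nrow(obs)
  perm_abs <- matrix(NA_real_, P, n_perm)
  ut <- upper.tri(diag(nrow(tissue_mat)))
  for (b in seq_len(n_perm)) {
    pick <- sample(n1 + n2)
    m1 <- pooled_mat[, pick[seq_len(n1)], drop = FALSE]
    m2 <- pooled_mat[, pick[n1 + seq_len(n2)], drop = FALSE]
    z1 <- fisher_z(stats::cor(t(m1))[ut])
    z2 <- fisher_z(stats::cor(t(m2))[ut])
    perm_abs[, b] <- abs(diff_z(z1, n1, z2, n2)$dz)
  }
  o_abs <- abs(obs$dz)
  if (pooled) {
    srt <- sort(as.numeric(perm_abs))
    total <- length(srt)
    # count of permuted values >= observed, via position in sorted nulls
    ge <- total - findInterval(o_abs - 1e-12, srt)
    (1 + ge) / (1 + total)
  } else {
    ge <- rowSums(perm_abs >= o_abs - 1e-12)
    (1 + ge) / (1 + n_perm)
  }
}

#' Build the differential network from a diffcorr table
#'
#' Edges are the `cap` pairs with the smallest adjusted p (ties by |dz|
#' descending, then gene IDs); the edge sign is the sign of dz
#' (positive = correlation gained in the tissue relative to control).
#'
#' @param table a [pairwise_diffcorr()] result.
#' @param cap maximum edge count (default 1000).
#' @return list of class `differential_network`: `edges` (gene_a, gene_b,
#'   dz, p_adj, sign), `nodes`.
#' @export
build_network <- function(table, cap = 1000) {
  if (!nrow(table)) stop("empty diffcorr table")
  o <- order(table$p_adj, -abs(table$dz), table$gene_a, table$gene_b)
  keep <- table[o[seq_len(min(cap, nrow(table)))], , drop = FALSE]
  edges <- data.frame(gene_a = keep$gene_a, gene_b = keep$gene_b,
                      dz = keep$dz, p_adj = keep$p_adj,
                      sign = ifelse(keep$dz >= 0, "gain", "loss"),
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$gene_a, edges$gene_b)))),
            class = "differential_network")
}

#' Per-gene average correlation change (hub scores)
#'
#' `score(g)` = mean dz over all pairs containing g; genes are ranked by
#' `|score|` descending and the sign is reported as gain/loss.
#'
#' @param table a [pairwise_diffcorr()] result covering all pairs.
#' @return data.frame (`gene_id`, `score`, `direction`) ranked by
#'   absolute score.
#' @export
hub_scores <- function(table) {
  genes <- sort(unique(c(table$gene_a, table$gene_b)))
  s <- numeric(length(genes)); k <- integer(length(genes))
  names(s) <- names(k) <- genes
  ta <- tapply(table$dz, table$gene_a, sum)
  tb <- tapply(table$dz, table$gene_b, sum)
  ca <- table(table$gene_a); cb <- table(table$gene_b)
  s[names(ta)] <- s[names(ta)] + ta
  s[names(tb)] <- s[names(tb)] + tb
  k[names(ca)] <- k[names(ca)] + ca
  k[names(cb)] <- k[names(cb)] + cb
  score <- ifelse(k > 0, s / k, 0)
  out <- data.frame(gene_id = genes, score = score,
                    direction = ifelse(score >= 0, "gain", "loss"),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$score), out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy modularity module detection
#'
#' Agglomerative modularity maximization on the undirected unweighted
#' edge set: every node starts as its own community; at each step the
#' connected community pair whose merge maximizes the modularity gain
#' `2 * (e_ij - a_i * a_j)` is merged (ties: the pair whose smallest
#' member node IDs are lexicographically smallest); the partition with
#' the maximum modularity along the merge sequence is returned. Nodes
#' without edges become singleton modules (with a warning when the whole
#' graph is edgeless).
#'
#' @param network a `differential_network`, or a data.frame of edges with
#'   columns `gene_a`, `gene_b` (self-loops and duplicate pairs are
#'   collapsed).
#' @param nodes optional node universe (defaults to nodes with edges).
#' @return named integer vector: module ID (1-based, by decreasing module
#'   size then ID order) per node; attribute `modularity` holds the
#'   achieved modularity.
#' @export
detect_modules <- function(network, nodes = NULL) {
  edges <- if (inherits(network, "differential_network"))
    network$edges else as.data.frame(network)
  stopifnot(all(c("gene_a", "gene_b") %in% names(edges)))
  edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
  key <- paste(pmin(edges$gene_a, edges$gene_b),
               pmax(edges$gene_a, edges$gene_b))
  edges <- edges[!duplicated(key), , drop = FALSE]
  if (is.null(nodes))
    nodes <- sort(unique(c(edges$gene_a, edges$gene_b,
                           if (inherits(network, "differential_network"))
                             network$nodes)))
  if (!nrow(edges)) {
    warning("edgeless graph: every node is its own module")
    return(structure(stats::setNames(seq_along(nodes), nodes),
                     modularity = 0))
  }
  m <- nrow(edges)
  ia <- match(edges$gene_a, nodes)
  ib <- match(edges$gene_b, nodes)
  n <- length(nodes)
  # community edge-fraction matrix e and degree fractions a
  E <- matrix(0, n, n)
  for (r in seq_len(m)) {
    E[ia[r], ib[r]] <- E[ia[r], ib[r]] + 0.5 / m
    E[ib[r], ia[r]] <- E[ib[r], ia[r]] + 0.5 / m
  }
  a <- rowSums(E)
  comm <- as.list(seq_len(n))       # member node indices per community
  alive <- rep(TRUE, n)
  member_of <- seq_len(n)
  Q <- sum(diag(E)) - sum(a^2)
  best_Q <- Q
  best_members <- member_of
  repeat {
    pairs <- which(E > 0 & upper.tri(E), arr.ind = TRUE)
    pairs <- pairs[alive[pairs[, 1L]] & alive[pairs[, 2L]], , drop = FALSE]
    if (!nrow(pairs)) break
    gain <- 2 * (E[pairs] - a[pairs[, 1L]] * a[pairs[, 2L]])
    mx <- max(gain)
    tied <- which(gain >= mx - 1e-15)
    if (length(tied) > 1L) {
      # lexicographically smallest (min-member, min-member) pair
      keymat <- vapply(tied, function(t) {
        i <- pairs[t, 1L]; j <- pairs[t, 2L]
        mi <- min(nodes[comm[[i]]]); mj <- min(nodes[comm[[j]]])
        c(min(mi, mj), max(mi, mj))
      }, character(2L))
      tied <- tied[order(keymat[1L, ], keymat[2L, ])][1L]
    }
    i <- pairs[tied, 1L]; j <- pairs[tied, 2L]
    Q <- Q + 2 * (E[i, j] - a[i] * a[j])
    # merge j into i
    E[i, ] <- E[i, ] + E[j, ]
    E[, i] <- E[, i] + E[, j]
    E[j, ] <- 0; E[, j] <- 0
    a[i] <- a[i] + a[j]; a[j] <- 0
    comm[[i]] <- c(comm[[i]], comm[[j]])
    alive[j] <- FALSE
    member_of[comm[[i]]] <- i
    if (Q > best_Q + 1e-15) {
      best_Q <- Q
      best_members <- member_of
    }
  }
  labs <- best_members
  sizes <- table(labs)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  structure(stats::setNames(as.integer(relabel[as.character(labs)]), nodes),
            modularity = best_Q)
}

#' Modularity of a partition of an edge set
#'
#' `Q = sum_c (e_cc - a_c^2)` over communities; useful as an independent
#' check of [detect_modules()].
#'
#' @param edges data.frame with `gene_a`, `gene_b`.
#' @param membership named vector mapping node -> community label.
#' @return modularity value.
#' @export
modularity_score <- function(edges, membership) {
  m <- nrow(edges)
  ca <- membership[edges$gene_a]
  cb <- membership[edges$gene_b]
  e_in <- sum(ca == cb) / m
  deg <- table(c(edges$gene_a, edges$gene_b))
  a <- tapply(as.numeric(deg), membership[names(deg)], sum) / (2 * m)
  e_in - sum(a^2)
}

#' Adjusted Rand index between two partitions
#'
#' @param x,y membership vectors over the same elements.
#' @return ARI in `[-1, 1]` (1 = identical partitions).
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- comb2(as.numeric(tab))
  sum_i <- comb2(as.numeric(rowSums(tab)))
  sum_j <- comb2(as.numeric(colSums(tab)))
  n2 <- comb2(length(x))
  expected <- sum_i * sum_j / n2
  maxi <- (sum_i + sum_j) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
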