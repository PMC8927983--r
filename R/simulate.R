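#' Simulation configuration for synthetic expression bundles
#'
#' Builds and validates the configuration of the synthetic generator.
#' The generator plants, on a log2-Gaussian baseline: tissue-specific
#' fold-changes, per-source (batch) additive log shifts, TF-to-target
#' regulatory dependence, and tissue-vs-control differential-correlation
#' pairs — and returns the ground truth needed to score every stage.
#'
#' Default sizes describe the stated benchmark world: 4 tissues plus a
#' control mixture, 50 planted specific genes per tissue out of 800 genes
#' (planted fraction 25%, aligned with the upper-quartile tau selection
#' rule), 4 sources with a strong log-scale shift, 20 TFs with 5 targets
#' each, and 10 differential pairs.
#'
#' @param n_genes,n_tissues,samples_per_group,n_sources sizes; `n_sources
#'   >= 2` unless a single (no-confounding) source is wanted.
#' @param n_specific_per_tissue planted specific genes per tissue.
#' @param specific_effect fold-change (> 1 plants signal; exactly 1 plants
#'   nothing and the truth sets are empty).
#' @param confounder_effect per-source additive shift scale (log2 units);
#'   0 disables confounding.
#' @param n_tfs,targets_per_tf planted regulator structure.
#' @param n_diff_pairs,diff_rho_tissue,diff_rho_control planted
#'   differential-correlation pairs (tissue group = first tissue).
#' @param diff_hub if `TRUE`, all differential pairs share one hub gene
#'   (a planted correlation star) instead of being disjoint.
#' @param platform `"count_like"` (negative-binomial counts, rnaseq) or
#'   `"intensity_like"` (log-normal intensities, microarray).
#' @param noise_dispersion NB dispersion shared across genes (count_like).
#' @param noise_sd per-gene residual s.d. on the log2 scale.
#' @param baseline_mean,baseline_sd log2 baseline distribution per gene.
#' @param tf_slope,tf_noise target = slope * TF + noise (log2 scale).
#' @param seed integer seed; identical seed gives identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 800, n_tissues = 4, samples_per_group = 40,
                       n_sources = 4, n_specific_per_tissue = 50,
                       specific_effect = 8, confounder_effect = 1.5,
                       n_tfs = 20, targets_per_tf = 5, n_diff_pairs = 10,
                       diff_rho_tissue = 0.8, diff_rho_control = 0,
                       diff_hub = FALSE, platform = "count_like",
                       noise_dispersion = 0.5, noise_sd = 0.75,
                       baseline_mean = 6, baseline_sd = 1.5,
                       tf_slope = 0.9, tf_noise = 0.4, seed = 1) {
  cfg <- list(n_genes = n_genes, n_tissues = n_tissues,
              samples_per_group = samples_per_group, n_sources = n_sources,
              n_specific_per_tissue = n_specific_per_tissue,
              specific_effect = specific_effect,
              confounder_effect = confounder_effect, n_tfs = n_tfs,
              targets_per_tf = targets_per_tf, n_diff_pairs = n_diff_pairs,
              diff_rho_tissue = diff_rho_tissue,
              diff_rho_control = diff_rho_control, diff_hub = diff_hub,
              platform = platform, noise_dispersion = noise_dispersion,
              noise_sd = noise_sd, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, tf_slope = tf_slope,
              tf_noise = tf_noise, seed = seed)
  errs <- character()
  pos_int <- function(x) length(x) == 1L && is.numeric(x) && x >= 1 &&
    x == floor(x)
  for (f in c("n_genes", "n_tissues", "samples_per_group", "n_sources",
              "n_specific_per_tissue", "n_tfs", "targets_per_tf",
              "n_diff_pairs"))
    if (!pos_int(cfg[[f]]) && !(f == "n_diff_pairs" && cfg[[f]] == 0))
      errs <- c(errs, paste0(f, " must be a positive integer"))
  if (!is.numeric(specific_effect) || specific_effect < 1)
    errs <- c(errs, "specific_effect must be a fold change >= 1")
  if (!is.numeric(confounder_effect) || confounder_effect < 0)
    errs <- c(errs, "confounder_effect must be >= 0")
  if (abs(diff_rho_tissue) > 1) errs <- c(errs, "diff_rho_tissue must be in [-1, 1]")
  if (abs(diff_rho_control) > 1) errs <- c(errs, "diff_rho_control must be in [-1, 1]")
  if (n_diff_pairs > 0 && diff_rho_tissue == diff_rho_control)
    errs <- c(errs, "diff_rho_tissue must differ from diff_rho_control")
  if (!platform %in% c("count_like", "intensity_like"))
    errs <- c(errs, "platform must be count_like or intensity_like")
  if (!is.numeric(noise_dispersion) || noise_dispersion <= 0)
    errs <- c(errs, "noise_dispersion must be positive")
  if (n_specific_per_tissue * n_tissues > n_genes)
    errs <- c(errs, "n_specific_per_tissue x n_tissues exceeds n_genes")
  if (n_tfs >= n_genes) errs <- c(errs, "n_tfs must be < n_genes")
  n_diff_genes <- if (isTRUE(diff_hub)) n_diff_pairs + 1L else 2L * n_diff_pairs
  used <- n_specific_per_tissue * n_tissues + n_tfs +
    n_tfs * targets_per_tf + n_diff_genes
  if (used > n_genes)
    errs <- c(errs, sprintf(
      "planted roles need %d genes but n_genes = %d (reduce n_specific_per_tissue, n_tfs, targets_per_tf or n_diff_pairs)",
      used, n_genes))
  if (length(errs)) stop("invalid sim_config:\n  - ",
                         paste(errs, collapse = "\n  - "))
  class(cfg) <- "sim_config"
  cfg
}

tissue_labels <- function(n) {
  base <- c("leaf", "root", "seed", "nodule")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, paste0("tissue", seq(length(base) + 1L, n)))
}

#' Simulate an expression bundle with planted ground truth
#'
#' See [sim_config()] for the generative model. The control group is a
#' mixture: control samples draw baseline expression with no tissue
#' effect. Source labels cycle within each condition, so tissue and
#' source are balanced (not aliased). The per-source shift is additive on
#' the log2 scale and drawn independently per gene and source. Planted
#' differential-pair genes carry no source shift, so their within-group
#' correlation equals the configured value by construction.
#'
#' @param config a [sim_config()].
#' @return A list with elements `bundle` (an [expression_bundle()]),
#'   `truth` (class `synthetic_truth`: `specific_genes` per tissue,
#'   `source_of_sample`, `planted_edges`, `diff_pairs`, `tf_ids`), and
#'   `gene_lengths` (count_like platform only; uniform 500-5000 bp).
#' @export
simulate_bundle <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  G <- config$n_genes
  tis <- tissue_labels(config$n_tissues)
  conditions <- c(tis, "control")
  spg <- config$samples_per_group
  n_samples <- length(conditions) * spg

  gene_ids <- sprintf("g%04d", seq_len(G))
  sample_ids <- sprintf("s%04d", seq_len(n_samples))
  cond_of_sample <- rep(conditions, each = spg)
  source_of_sample <- paste0(
    "src", rep(rep_len(seq_len(config$n_sources), spg), length(conditions)))

  # gene role layout (deterministic, front of the gene list)
  n_spec <- config$n_specific_per_tissue
  spec_idx <- split(seq_len(n_spec * config$n_tissues),
                    rep(seq_len(config$n_tissues), each = n_spec))
  names(spec_idx) <- tis
  cursor <- n_spec * config$n_tissues
  tf_idx <- cursor + seq_len(config$n_tfs); cursor <- cursor + config$n_tfs
  target_idx <- cursor + seq_len(config$n_tfs * config$targets_per_tf)
  cursor <- cursor + length(target_idx)
  if (config$n_diff_pairs > 0) {
    if (isTRUE(config$diff_hub)) {
      hub <- cursor + 1L
      diff_pairs_idx <- cbind(rep(hub, config$n_diff_pairs),
                              cursor + 1L + seq_len(config$n_diff_pairs))
      diff_gene_idx <- cursor + seq_len(config$n_diff_pairs + 1L)
    } else {
      diff_gene_idx <- cursor + seq_len(2L * config$n_diff_pairs)
      diff_pairs_idx <- matrix(diff_gene_idx, ncol = 2L, byrow = TRUE)
    }
  } else {
    diff_gene_idx <- integer()
    diff_pairs_idx <- matrix(integer(), ncol = 2L)
  }

  mu <- stats::rnorm(G, config$baseline_mean, config$baseline_sd)
  delta <- matrix(stats::rnorm(G * config$n_sources, 0,
                               config$confounder_effect),
                  G, config$n_sources)
  resid <- matrix(stats::rnorm(G * n_samples, 0, config$noise_sd),
                  G, n_samples)

  # correlated residuals for planted differential pairs
  tissue1_cols <- which(cond_of_sample == tis[1L])
  control_cols <- which(cond_of_sample == "control")
  mix <- function(ea, rho, nsd) rho * ea +
    sqrt(max(0, 1 - rho^2)) * stats::rnorm(length(ea), 0, nsd)
  for (p in seq_len(nrow(diff_pairs_idx))) {
    a <- diff_pairs_idx[p, 1L]; b <- diff_pairs_idx[p, 2L]
    resid[b, tissue1_cols] <- mix(resid[a, tissue1_cols],
                                  config$diff_rho_tissue, config$noise_sd)
    resid[b, control_cols] <- mix(resid[a, control_cols],
                                  config$diff_rho_control, config$noise_sd)
  }
  # diff-pair genes carry no per-source shift (it would attenuate the
  # planted correlation); scale their residuals to variance parity with
  # the shifted genes — a common scale factor leaves correlations intact
  if (length(diff_gene_idx) && config$confounder_effect > 0) {
    k <- sqrt(1 + (config$confounder_effect / config$noise_sd)^2)
    resid[diff_gene_idx, ] <- resid[diff_gene_idx, ] * k
  }

  src_num <- rep(rep_len(seq_len(config$n_sources), spg), length(conditions))
  L <- mu + resid
  no_shift <- logical(G); no_shift[diff_gene_idx] <- TRUE
  shift <- delta[, src_num, drop = FALSE]
  shift[no_shift, ] <- 0
  L <- L + shift

  eff <- log2(config$specific_effect)
  if (eff > 0) {
    for (t in tis) {
      cols <- which(cond_of_sample == t)
      L[spec_idx[[t]], cols] <- L[spec_idx[[t]], cols] + eff
    }
  }

  # targets as noisy linear functions of their TF (after all other effects,
  # so targets inherit their TF's source shift through the slope)
  edges <- NULL
  if (config$n_tfs > 0 && config$targets_per_tf > 0) {
    edges <- data.frame(
      regulator = gene_ids[rep(tf_idx, each = config$targets_per_tf)],
      target = gene_ids[target_idx], stringsAsFactors = FALSE)
    for (k in seq_along(target_idx)) {
      tf <- tf_idx[(k - 1L) %/% config$targets_per_tf + 1L]
      tg <- target_idx[k]
      L[tg, ] <- mu[tg] + config$tf_slope * (L[tf, ] - mean(L[tf, ])) +
        stats::rnorm(n_samples, 0, config$tf_noise)
    }
  }

  gene_lengths <- NULL
  if (config$platform == "count_like") {
    counts <- matrix(
      stats::rnbinom(G * n_samples, mu = 2^L, size = 1 / config$noise_dispersion),
      G, n_samples)
    mat <- counts
    unit <- "counts"
    platform <- "rnaseq"
    gene_lengths <- stats::setNames(
      as.numeric(round(stats::runif(G, 500, 5000))), gene_ids)
  } else {
    mat <- 2^L
    unit <- "intensity"
    platform <- "microarray"
  }
  dimnames(mat) <- list(gene_ids, sample_ids)

  meta <- data.frame(
    sample_id = sample_ids,
    tissue = ifelse(cond_of_sample == "control", "mixed", cond_of_sample),
    source = source_of_sample,
    platform = platform,
    group = ifelse(cond_of_sample == "control", "control", "case"),
    stringsAsFactors = FALSE)

  truth <- structure(list(
    specific_genes = if (eff > 0)
      lapply(spec_idx, function(i) gene_ids[i])
      else stats::setNames(rep(list(character()), length(tis)), tis),
    source_of_sample = stats::setNames(source_of_sample, sample_ids),
    planted_edges = if (is.null(edges))
      data.frame(regulator = character(), target = character())
      else edges,
    diff_pairs = data.frame(
      gene_a = gene_ids[diff_pairs_idx[, 1L]],
      gene_b = gene_ids[diff_pairs_idx[, 2L]],
      rho_tissue = rep(config$diff_rho_tissue, nrow(diff_pairs_idx)),
      rho_control = rep(config$diff_rho_control, nrow(diff_pairs_idx)),
      tissue = rep(tis[1L], nrow(diff_pairs_idx)),
      stringsAsFactors = FALSE),
    tf_ids = gene_ids[tf_idx]
  ), class = "synthetic_truth")

  list(bundle = expression_bundle(mat, meta, unit), truth = truth,
       gene_lengths = gene_lengths)
}

#' Write the simulator truth as JSON
#'
#' @param truth a `synthetic_truth` object.
#' @param path output JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Precision and recall of a predicted set against a truth set
#'
#' @param predicted,truth character vectors (IDs or encoded pairs/edges).
#' @return list with `precision`, `recall` (NA when undefined: empty
#'   prediction or empty truth respectively).
#' @export
precision_recall <- function(predicted, truth) {
  tp <- length(intersect(predicted, truth))
  list(
    precision = if (length(predicted)) tp / length(predicted) else NA_real_,
    recall = if (length(truth)) tp / length(truth) else NA_real_)
}

#' Area under the ROC curve from a full ranking
#'
#' Rank-based (Mann-Whitney) AUROC with average ranks for ties.
#'
#' @param scores numeric scores, larger = more confident positive.
#' @param labels logical vector, `TRUE` for planted positives.
#' @return AUROC in `[0, 1]`, or `NA` if either class is empty.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' Recovery metrics of predictions against the planted truth
#'
#' @param predicted for `type = "specific_genes"`: a named list of gene-ID
#'   vectors per tissue (e.g. from [select_specific_genes()]); for
#'   `"edges"`: a data.frame with `regulator`, `target` and optionally
#'   `weight` (full ranked list, for AUROC); for `"diff_pairs"`: a
#'   data.frame with `gene_a`, `gene_b` and optionally a score column
#'   `score` covering all candidate pairs.
#' @param truth a `synthetic_truth` object.
#' @param type which planted structure to score against.
#' @return list of metrics in `[0, 1]`; recall is `NA` (not 0) when the
#'   truth set is empty.
#' @export
truth_recovery_report <- function(predicted, truth,
                                  type = c("specific_genes", "edges",
                                           "diff_pairs")) {
  type <- match.arg(type)
  stopifnot(inherits(truth, "synthetic_truth"))
  if (type == "specific_genes") {
    per_tissue <- lapply(names(truth$specific_genes), function(t) {
      pred_t <- if (is.list(predicted)) predicted[[t]] else character()
      if (is.null(pred_t)) pred_t <- character()
      precision_recall(pred_t, truth$specific_genes[[t]])
    })
    names(per_tissue) <- names(truth$specific_genes)
    all_pred <- unlist(lapply(names(truth$specific_genes), function(t)
      paste(t, if (is.list(predicted)) predicted[[t]] else character())))
    all_true <- unlist(lapply(names(truth$specific_genes), function(t)
      paste(t, truth$specific_genes[[t]])))
    c(list(overall = precision_recall(all_pred, all_true)), per_tissue)
  } else if (type == "edges") {
    key <- function(r, t) paste(r, t, sep = "->")
    true_keys <- key(truth$planted_edges$regulator,
                     truth$planted_edges$target)
    pred_keys <- key(predicted$regulator, predicted$target)
    out <- precision_recall(pred_keys, true_keys)
    if (!is.null(predicted$weight))
      out$auroc <- auroc(predicted$weight, pred_keys %in% true_keys)
    out
  } else {
    pkey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "~")
    true_keys <- pkey(truth$diff_pairs$gene_a, truth$diff_pairs$gene_b)
    pred_keys <- pkey(predicted$gene_a, predicted$gene_b)
    out <- precision_recall(pred_keys, true_keys)
    if (!is.null(predicted$score))
      out$auroc <- auroc(predicted$score, pred_keys %in% true_keys)
    out
  }
}
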