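#' Default pipeline configuration
#'
#' Stage blocks mirror the module specifications; values are the package
#' defaults (paper-scale training settings — tests and quick runs pass
#' smaller ones).
#'
#' @return nested list of stage parameter blocks.
#' @export
default_config <- function() {
  list(
    seed = 1,
    out_dir = NULL,
    sim = list(),
    preprocess = list(tpm = TRUE, log2 = TRUE, pseudocount = 1,
                      filter_var = 0.25),
    adae = list(run = TRUE, embedding_dim = 100, lambda = 1,
                learning_rate = 1e-4, minibatch_size = 128,
                max_epochs = 200, patience = 10),
    tau = list(run = TRUE, method = "autoencoder", learning_rate = 1e-4,
               minibatch_size = 12, max_epochs = 200, patience = 10),
    grn = list(run = TRUE, embedding_dim = NULL, n_trees = 1000,
               top_k = 1000, min_split = 5),
    diffnet = list(run = TRUE, cap = 1000, n_perm = 0)
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a JSON file path or a nested list; unknown keys are rejected
#' and all problems are collected into a single error, not reported
#' first-failure. Missing fields are filled with documented defaults.
#'
#' @param config path to a JSON config, or a list.
#' @return a merged, validated config list of class `run_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (inherits(config, "run_config")) return(config)
  def <- default_config()
  errs <- character()
  unknown_top <- setdiff(names(config), names(def))
  if (length(unknown_top))
    errs <- c(errs, paste0("unknown config key(s): ",
                           paste(unknown_top, collapse = ", ")))
  sim_fields <- setdiff(names(formals(sim_config)), "...")
  for (blk in intersect(names(config), names(def))) {
    if (blk %in% c("seed", "out_dir")) next
    allowed <- if (blk == "sim") sim_fields else names(def[[blk]])
    unknown <- setdiff(names(config[[blk]]), allowed)
    if (length(unknown))
      errs <- c(errs, paste0("unknown key(s) in '", blk, "': ",
                             paste(unknown, collapse = ", ")))
  }
  merged <- def
  for (blk in intersect(names(config), names(def))) {
    if (blk %in% c("seed", "out_dir")) merged[[blk]] <- config[[blk]]
    else for (f in intersect(names(config[[blk]]),
                             c(names(def[[blk]]), sim_fields)))
      merged[[blk]][[f]] <- config[[blk]][[f]]
  }
  if (!is.numeric(merged$seed) || length(merged$seed) != 1L)
    errs <- c(errs, "seed must be a single number")
  if (is.numeric(merged$preprocess$filter_var) &&
      (merged$preprocess$filter_var < 0 || merged$preprocess$filter_var >= 1))
    errs <- c(errs, "preprocess$filter_var must be in [0, 1)")
  if (is.numeric(merged$adae$lambda) && merged$adae$lambda < 0)
    errs <- c(errs, "adae$lambda must be >= 0")
  if (is.numeric(merged$diffnet$cap) && merged$diffnet$cap < 1)
    errs <- c(errs, "diffnet$cap must be >= 1")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  class(merged) <- "run_config"
  merged
}

digest_of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2L), f)
  unname(tools::md5sum(f))
}

#' Run the full pipeline on a simulated bundle
#'
#' simulate -> preprocess (TPM for counts, log2, low-variance filter) ->
#' adversarial deconfounding -> tau tissue-specificity -> GRN inference
#' on the first tissue -> differential network of the first tissue vs
#' control. Every stochastic stage is seeded derivatively from the
#' master seed, so identical configs give digest-identical reports.
#'
#' @param config a [validate_config()] input (list or JSON path).
#' @return a `run_report` list: resolved parameters, per-stage counts,
#'   output digests, recovery metrics against the planted truth, and the
#'   decision log of defaults actually exercised.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  seed <- cfg$seed
  report <- list(stages = character(), params = cfg, counts = list(),
                 digests = list(), recovery = list(),
                 decisions = list(
                   log2_pseudocount = cfg$preprocess$pseudocount,
                   adae_lambda = cfg$adae$lambda,
                   tau_percentile_rule = "type 7 linear interpolation, Q3",
                   dz_denominator = "sqrt(1/(n1-3) + 1/(n2-3))"))
  done <- function(stage) report$stages <<- c(report$stages, stage)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed after [",
           paste(report$stages, collapse = ", "), "]: ",
           conditionMessage(e), call. = FALSE))
  }

  sim <- run_stage("simulate", {
    scfg <- do.call(sim_config, utils::modifyList(list(seed = seed),
                                                  as.list(cfg$sim)))
    simulate_bundle(scfg)
  })
  done("simulate")
  report$digests$bundle <- digest_of(sim$bundle$matrix)
  report$counts$genes <- nrow(sim$bundle$matrix)
  report$counts$samples <- ncol(sim$bundle$matrix)

  bundle <- run_stage("preprocess", {
    b <- sim$bundle
    if (b$unit == "counts" && isTRUE(cfg$preprocess$tpm))
      b <- tpm_normalize(b, sim$gene_lengths)
    if (isTRUE(cfg$preprocess$log2))
      b <- log2_transform(b, cfg$preprocess$pseudocount)
    if (cfg$preprocess$filter_var > 0)
      b <- filter_low_variance(b, cfg$preprocess$filter_var)
    b
  })
  done("preprocess")
  report$counts$genes_after_filter <- nrow(bundle$matrix)

  work <- bundle
  if (isTRUE(cfg$adae$run)) {
    model <- run_stage("deconfound", {
      sp <- adae_spec(input_dim = nrow(bundle$matrix),
                      embedding_dim = cfg$adae$embedding_dim,
                      lambda = cfg$adae$lambda,
                      learning_rate = cfg$adae$learning_rate,
                      minibatch_size = cfg$adae$minibatch_size,
                      max_epochs = cfg$adae$max_epochs,
                      patience = cfg$adae$patience,
                      seed = derive_seed(seed, 11L))
      train_adae(bundle, spec = sp)
    })
    done("deconfound")
    work <- reconstruct(model, bundle)
    report$counts$adae_epochs <- nrow(model$history)
    report$counts$adae_val_recon <- model$final_val_recon
    report$digests$reconstructed <- digest_of(work$matrix)
  }

  tau_res <- if (!isTRUE(cfg$tau$run)) NULL else run_stage("tau", {
    vals <- condition_values(
      work, method = cfg$tau$method,
      spec_fn = function(n, i) compression_spec(
        input_dim = n, learning_rate = cfg$tau$learning_rate,
        minibatch_size = cfg$tau$minibatch_size,
        max_epochs = cfg$tau$max_epochs, patience = cfg$tau$patience,
        seed = derive_seed(seed, 3000L + i)),
      seed = derive_seed(seed, 13L))
    tab <- tau_table(vals)
    list(table = tab, sets = select_specific_genes(tab))
  })
  if (!is.null(tau_res)) {
    done("tau")
    report$counts$specific_genes <- vapply(tau_res$sets, length, integer(1L))
    report$digests$tau <- digest_of(tau_res$table)
    report$recovery$specific_genes <-
      truth_recovery_report(tau_res$sets, sim$truth, "specific_genes")
  }

  tissue1 <- tissue_labels(1L)
  if (isTRUE(cfg$grn$run)) {
    grn <- run_stage("grn", {
      tb <- condition_bundle(work, tissue1)
      dim_used <- if (is.null(cfg$grn$embedding_dim))
        choose_embedding_dim(ncol(tb$matrix)) else cfg$grn$embedding_dim
      cm <- compress_samples(tb, embedding_dim = dim_used,
                             spec = compression_spec(
                               input_dim = ncol(tb$matrix),
                               embedding_dim = dim_used,
                               learning_rate = cfg$tau$learning_rate,
                               minibatch_size = cfg$tau$minibatch_size,
                               max_epochs = cfg$tau$max_epochs,
                               seed = derive_seed(seed, 17L)))
      regs <- intersect(sim$truth$tf_ids, rownames(cm))
      edges <- infer_grn(cm, regs, n_trees = cfg$grn$n_trees,
                         min_split = cfg$grn$min_split,
                         seed = derive_seed(seed, 19L))
      list(edges = top_edges(edges, cfg$grn$top_k),
           all_edges = edges, hubs = rank_hub_tfs(top_edges(edges, cfg$grn$top_k)))
    })
    done("grn")
    report$counts$grn_edges <- nrow(grn$edges)
    report$digests$grn <- digest_of(grn$edges)
    report$recovery$grn <-
      truth_recovery_report(grn$all_edges, sim$truth, "edges")
  }

  if (isTRUE(cfg$diffnet$run)) {
    dn <- run_stage("diffnet", {
      mt <- condition_bundle(work, tissue1)$matrix
      mc <- condition_bundle(work, "control")$matrix
      tab <- pairwise_diffcorr(mt, mc)
      if (cfg$diffnet$n_perm > 0)
        tab$p_perm <- permutation_null(mt, mc, cfg$diffnet$n_perm,
                                       seed = derive_seed(seed, 23L))
      net <- build_network(tab, cfg$diffnet$cap)
      list(table = tab, net = net, hubs = hub_scores(tab),
           modules = detect_modules(net))
    })
    done("diffnet")
    report$counts$diffnet_edges <- nrow(dn$net$edges)
    report$counts$modules <- length(unique(dn$modules))
    report$digests$diffnet <- digest_of(dn$net$edges)
    pred_pairs <- dn$net$edges
    names(pred_pairs)[names(pred_pairs) == "dz"] <- "score"
    report$recovery$diff_pairs <-
      truth_recovery_report(pred_pairs, sim$truth, "diff_pairs")
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_bundle(work, file.path(cfg$out_dir, "bundle"))
    write_truth(sim$truth, file.path(cfg$out_dir, "truth.json"))
    jsonlite::write_json(report_to_json(report),
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  class(report) <- "run_report"
  report
}

report_to_json <- function(report) {
  r <- unclass(report)
  r$params <- unclass(r$params)
  r
}

#' @export
print.run_report <- function(x, ...) {
  cat("deconet run report\n")
  cat("stages:", paste(x$stages, collapse = " -> "), "\n")
  for (nm in names(x$counts))
    cat(sprintf("  %s: %s\n", nm, paste(x$counts[[nm]], collapse = "/")))
  invisible(x)
}
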