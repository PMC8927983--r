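#' Expression bundle: matrix plus aligned sample metadata
#'
#' The common currency of the pipeline: a genes x samples numeric matrix
#' with a per-sample metadata table. Units are tracked explicitly so that
#' normalization steps can enforce their preconditions.
#'
#' @param matrix numeric genes x samples matrix, non-negative (unless the
#'   unit is `log2`, which may be negative after transformation of values
#'   below 1), with unique rownames (gene IDs) and colnames (sample IDs).
#' @param sample_meta data.frame with columns `sample_id`, `tissue`,
#'   `source`, `platform` (one of `"microarray"`, `"rnaseq"`), `group`
#'   (`"case"` or `"control"`); rows must align one-to-one with matrix
#'   columns. Extra columns (cultivar, stage) are kept.
#' @param unit one of `"counts"`, `"tpm"`, `"log2"`, `"intensity"`.
#' @param reconstructed logical; `TRUE` marks output of
#'   [reconstruct()] (autoencoder-denoised values).
#' @return An object of class `expression_bundle`.
#' @export
expression_bundle <- function(matrix, sample_meta, unit,
                              reconstructed = FALSE) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("matrix must be a numeric matrix")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("matrix must have gene rownames and sample colnames")
  dup_g <- rownames(matrix)[duplicated(rownames(matrix))]
  if (length(dup_g))
    stop("duplicated gene ID: ", paste(unique(dup_g), collapse = ", "))
  dup_s <- colnames(matrix)[duplicated(colnames(matrix))]
  if (length(dup_s))
    stop("duplicated sample ID: ", paste(unique(dup_s), collapse = ", "))
  unit <- match.arg(unit, c("counts", "tpm", "log2", "intensity"))
  storage.mode(matrix) <- "double"
  if (unit != "log2" && any(matrix < 0))
    stop("negative values not allowed for unit '", unit, "'")
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  req <- c("sample_id", "tissue", "source", "platform", "group")
  miss <- setdiff(req, names(sample_meta))
  if (length(miss))
    stop("sample_meta missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(sample_meta) != ncol(matrix))
    stop("sample_meta rows (", nrow(sample_meta),
         ") do not match matrix columns (", ncol(matrix), ")")
  unknown <- setdiff(colnames(matrix), sample_meta$sample_id)
  if (length(unknown))
    stop("sample missing from metadata: ", paste(unknown, collapse = ", "))
  sample_meta <- sample_meta[match(colnames(matrix), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  bad_p <- setdiff(unique(sample_meta$platform), c("microarray", "rnaseq"))
  if (length(bad_p)) stop("unknown platform: ", paste(bad_p, collapse = ", "))
  bad_gr <- setdiff(unique(sample_meta$group), c("case", "control"))
  if (length(bad_gr)) stop("unknown group: ", paste(bad_gr, collapse = ", "))
  structure(
    list(matrix = matrix, sample_meta = sample_meta, unit = unit,
         reconstructed = isTRUE(reconstructed)),
    class = "expression_bundle"
  )
}

#' @export
print.expression_bundle <- function(x, ...) {
  cat(sprintf(
    "expression_bundle: %d genes x %d samples [unit: %s%s]\n",
    nrow(x$matrix), ncol(x$matrix), x$unit,
    if (x$reconstructed) ", reconstructed" else ""))
  cat("tissues: ", paste(sort(unique(x$sample_meta$tissue)), collapse = ", "),
      "\n", sep = "")
  cat("sources: ", paste(sort(unique(x$sample_meta$source)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_bundle <- function(x) dim(x$matrix)

#' Subset a bundle to a set of samples (keeps metadata aligned)
#'
#' @param bundle an [expression_bundle()].
#' @param sample_ids character vector of sample IDs to keep.
#' @return The subsetted bundle.
#' @export
subset_samples <- function(bundle, sample_ids) {
  stopifnot(inherits(bundle, "expression_bundle"))
  missing <- setdiff(sample_ids, colnames(bundle$matrix))
  if (length(missing))
    stop("unknown sample ID: ", paste(missing, collapse = ", "))
  expression_bundle(bundle$matrix[, sample_ids, drop = FALSE],
                    bundle$sample_meta[match(sample_ids,
                                             bundle$sample_meta$sample_id), ],
                    bundle$unit, bundle$reconstructed)
}

#' Samples of one condition (tissue cases, or the control mixture)
#'
#' Case samples enter their tissue's matrix; control samples form the
#' control condition regardless of tissue annotation.
#'
#' @param bundle an [expression_bundle()].
#' @param condition a tissue label, or `"control"` for the control mixture.
#' @return The subsetted bundle.
#' @export
condition_bundle <- function(bundle, condition) {
  meta <- bundle$sample_meta
  ids <- if (identical(condition, "control")) {
    meta$sample_id[meta$group == "control"]
  } else {
    meta$sample_id[meta$tissue == condition & meta$group == "case"]
  }
  if (!length(ids)) stop("no samples for condition '", condition, "'")
  subset_samples(bundle, ids)
}

#' TPM normalization
#'
#' Per sample, `TPM_g = 1e6 * (count_g/length_g) / sum_j(count_j/length_j)`.
#' Every output column sums to one million.
#'
#' @param bundle an [expression_bundle()] with unit `"counts"`.
#' @param lengths named numeric vector or two-column data.frame
#'   (`gene_id`, `length_bp`) covering every gene in the bundle.
#' @return A bundle with unit `"tpm"`.
#' @export
tpm_normalize <- function(bundle, lengths) {
  stopifnot(inherits(bundle, "expression_bundle"))
  if (bundle$unit != "counts")
    stop("tpm_normalize requires unit 'counts', got '", bundle$unit, "'")
  if (is.data.frame(lengths))
    lengths <- stats::setNames(lengths$length_bp, lengths$gene_id)
  miss <- setdiff(rownames(bundle$matrix), names(lengths))
  if (length(miss))
    stop("missing gene length for: ", paste(miss, collapse = ", "))
  len <- lengths[rownames(bundle$matrix)]
  if (any(len <= 0)) stop("gene lengths must be positive")
  zero <- colSums(bundle$matrix) == 0
  if (any(zero))
    stop("all-zero sample column: ",
         paste(colnames(bundle$matrix)[zero], collapse = ", "))
  rate <- bundle$matrix / len
  tpm <- sweep(rate, 2L, colSums(rate), "/") * 1e6
  expression_bundle(tpm, bundle$sample_meta, "tpm", bundle$reconstructed)
}

#' Log2 transform with pseudocount
#'
#' @param bundle an [expression_bundle()] with unit counts, tpm or intensity.
#' @param pseudocount positive offset added before taking log2 (default 1;
#'   zero counts force one even when a workflow names a plain
#'   log2 of raw counts).
#' @return A bundle with unit `"log2"`.
#' @export
log2_transform <- function(bundle, pseudocount = 1) {
  stopifnot(inherits(bundle, "expression_bundle"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      pseudocount <= 0)
    stop("pseudocount must be a positive number")
  if (!bundle$unit %in% c("counts", "tpm", "intensity"))
    stop("log2_transform requires counts, tpm or intensity; got '",
         bundle$unit, "'")
  expression_bundle(log2(bundle$matrix + pseudocount), bundle$sample_meta,
                    "log2", bundle$reconstructed)
}

#' Drop the lowest-variance genes
#'
#' Removes the `floor(drop_fraction * n_genes)` genes with the smallest
#' across-sample variance; survivor order is preserved. Ties in variance
#' are resolved by original gene order (earlier genes dropped first).
#'
#' @param bundle an [expression_bundle()] with at least two samples.
#' @param drop_fraction fraction in `[0, 1)` of genes to remove
#'   (default 0.25).
#' @return The filtered bundle.
#' @export
filter_low_variance <- function(bundle, drop_fraction = 0.25) {
  stopifnot(inherits(bundle, "expression_bundle"))
  if (ncol(bundle$matrix) < 2L) stop("need at least 2 samples")
  if (!is.numeric(drop_fraction) || drop_fraction < 0 || drop_fraction >= 1)
    stop("drop_fraction must be in [0, 1)")
  n <- nrow(bundle$matrix)
  k <- floor(drop_fraction * n)
  if (k >= n) stop("drop_fraction would leave zero genes")
  if (k == 0L) return(bundle)
  v <- apply(bundle$matrix, 1L, stats::var)
  drop_idx <- order(v, seq_len(n))[seq_len(k)]
  keep <- sort(setdiff(seq_len(n), drop_idx))
  expression_bundle(bundle$matrix[keep, , drop = FALSE], bundle$sample_meta,
                    bundle$unit, bundle$reconstructed)
}

#' Write / read an expression bundle as TSV files
#'
#' The on-disk dialect: `expression.tsv` with first column `gene_id` and a
#' header row of sample IDs; `sample_meta.tsv` with fixed column names
#' (`sample_id`, `tissue`, `source`, `platform`, `group`); `unit.txt`
#' holding the unit tag. Round trips exactly (matrix at full precision).
#'
#' @param bundle an [expression_bundle()].
#' @param dir output directory (created if needed).
#' @return `write_bundle` invisibly returns the directory; `read_bundle`
#'   returns the bundle.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "expression_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  # write numbers at full round-trip precision (%.17g)
  con <- file(file.path(dir, "expression.tsv"), "w")
  writeLines(paste(c("gene_id", colnames(bundle$matrix)), collapse = "\t"),
             con)
  body <- vapply(seq_len(nrow(bundle$matrix)), function(i)
    paste(c(rownames(bundle$matrix)[i],
            sprintf("%.17g", bundle$matrix[i, ])), collapse = "\t"),
    character(1L))
  writeLines(body, con)
  close(con)
  data.table::fwrite(data.table::as.data.table(bundle$sample_meta),
                     file.path(dir, "sample_meta.tsv"), sep = "\t",
                     quote = FALSE)
  writeLines(c(bundle$unit, if (bundle$reconstructed) "reconstructed"),
             file.path(dir, "unit.txt"))
  invisible(dir)
}

#' @rdname write_bundle
#' @param check_names unused, reserved.
#' @export
read_bundle <- function(dir, check_names = TRUE) {
  expr_path <- file.path(dir, "expression.tsv")
  meta_path <- file.path(dir, "sample_meta.tsv")
  if (!file.exists(expr_path)) stop("missing ", expr_path)
  if (!file.exists(meta_path)) stop("missing ", meta_path)
  expr <- data.table::fread(expr_path, sep = "\t")
  if (names(expr)[1L] != "gene_id")
    stop("expression.tsv must start with a gene_id column")
  gid <- as.character(expr$gene_id)
  mat <- as.matrix(expr[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- gid
  meta <- as.data.frame(data.table::fread(meta_path, sep = "\t"))
  missing_meta <- setdiff(colnames(mat), meta$sample_id)
  if (length(missing_meta))
    stop("metadata missing sample: ", paste(missing_meta, collapse = ", "))
  unit_lines <- readLines(file.path(dir, "unit.txt"))
  expression_bundle(mat, meta, unit_lines[1L],
                    reconstructed = "reconstructed" %in% unit_lines[-1L])
}

#' Write / read a gene-length table (gene_id, length_bp)
#'
#' @param lengths named numeric vector (names are gene IDs, values bp).
#' @param path TSV path.
#' @export
write_gene_lengths <- function(lengths, path) {
  data.table::fwrite(
    data.table::data.table(gene_id = names(lengths),
                           length_bp = as.integer(lengths)),
    path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_gene_lengths
#' @export
read_gene_lengths <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  stats::setNames(as.numeric(dt$length_bp), as.character(dt$gene_id))
}
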