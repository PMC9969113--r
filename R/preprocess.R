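#' Read a gene-by-sample count matrix
#'
#' Supports the two fixture formats written by [write_fixture()]: a TSV with a
#' `gene_id` first column and one column per sample, or a MatrixMarket
#' coordinate file with `genes.txt` / `samples.txt` sidecars in the same
#' directory. Entries must be non-negative integers and ids unique.
#'
#' @param path path to `counts.tsv` or `counts.mtx`.
#' @param format `"auto"` (by extension), `"tsv"` or `"mtx"`.
#' @return an integer matrix with gene ids as rownames, sample ids as colnames.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path))
    abort_eoc(sprintf("count file '%s' does not exist", path), "eoclines_io_error")
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  counts <- if (format == "tsv") read_counts_tsv(path) else read_counts_mtx(path)
  if (anyDuplicated(rownames(counts)))
    abort_eoc(sprintf("duplicate gene ids in '%s'", path), "eoclines_parse_error")
  if (anyDuplicated(colnames(counts)))
    abort_eoc(sprintf("duplicate sample ids in '%s'", path), "eoclines_parse_error")
  check_count_matrix(counts, sprintf("counts from '%s'", path))
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1, ]
    abort_eoc(sprintf("non-integer count at gene '%s', sample '%s' in '%s'",
                      rownames(counts)[bad[1]], colnames(counts)[bad[2]], path),
              "eoclines_parse_error")
  }
  storage.mode(counts) <- "integer"
  counts
}

read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "gene_id")
    abort_eoc(sprintf("malformed TSV header in '%s': expected a 'gene_id' first column", path),
              "eoclines_parse_error")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    abort_eoc(sprintf("non-numeric count entries in '%s'", path), "eoclines_parse_error")
  rownames(m) <- df$gene_id
  m
}

read_counts_mtx <- function(path) {
  m <- tryCatch(as.matrix(Matrix::readMM(path)),
                error = function(e) abort_eoc(
                  sprintf("cannot parse MatrixMarket file '%s': %s", path, conditionMessage(e)),
                  "eoclines_parse_error"))
  gpath <- file.path(dirname(path), "genes.txt")
  spath <- file.path(dirname(path), "samples.txt")
  if (!file.exists(gpath) || !file.exists(spath))
    abort_eoc(sprintf("missing genes.txt/samples.txt sidecars next to '%s'", path),
              "eoclines_io_error")
  genes <- readLines(gpath)
  samples <- readLines(spath)
  if (length(genes) != nrow(m) || length(samples) != ncol(m))
    abort_eoc(sprintf("sidecar dimensions (%d genes, %d samples) do not match '%s' (%d x %d)",
                      length(genes), length(samples), path, nrow(m), ncol(m)),
              "eoclines_parse_error")
  dimnames(m) <- list(genes, samples)
  m
}

#' Median-of-ratios size factors
#'
#' For every gene expressed in all samples, the ratio of its count to its
#' geometric mean across samples is formed; a sample's size factor is the
#' median of those ratios.
#'
#' @param counts non-negative count matrix (genes x samples).
#' @return a positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  check_count_matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    abort_eoc(paste("no gene has positive counts in every sample;",
                    "add a pseudocount before computing size factors"),
              "eoclines_input_error")
  lg <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  f <- apply(lg, 2, function(x) exp(stats::median(x - geo)))
  names(f) <- colnames(counts)
  f
}

#' Variance-stabilizing transform (log2 of size-factor-normalized counts)
#'
#' Computes `log2(count / factor + 1)`. This is a deterministic, monotone
#' stabilizer adequate for MAD-based gene ranking; it deliberately does not
#' fit a parametric dispersion trend.
#'
#' @param counts count matrix (genes x samples).
#' @param factors per-sample positive size factors; defaults to
#'   [size_factors()] of `counts`.
#' @return a numeric matrix with a `transform_chain` attribute recording
#'   `"vst"`.
#' @export
vst_transform <- function(counts, factors = size_factors(counts)) {
  check_count_matrix(counts)
  if (length(factors) != ncol(counts))
    abort_eoc("length(factors) must equal ncol(counts)", "eoclines_input_error")
  if (any(factors <= 0)) abort_eoc("size factors must be positive", "eoclines_input_error")
  out <- log2(sweep(counts, 2, factors, "/") + 1)
  add_transform(out, "vst")
}

#' Filter genes by median absolute deviation
#'
#' Per-gene MAD is `scale_constant * median(|x - median(x)|)` across samples;
#' genes at or above `threshold` are kept. The default constant 1.4826 makes
#' the MAD a consistent estimator of the standard deviation under normality;
#' set `scale_constant = 1` for the raw MAD.
#'
#' @param expr expression matrix (genes x samples), at least 2 samples.
#' @param threshold non-negative MAD cutoff.
#' @param scale_constant multiplier applied to the raw MAD.
#' @return an object of class `eoc_gene_filter` with `kept_genes`,
#'   `mad_values` and the cutoff used.
#' @export
mad_filter <- function(expr, threshold = 1.5, scale_constant = 1.4826) {
  if (ncol(expr) < 2)
    abort_eoc("MAD filtering needs at least 2 samples", "eoclines_input_error")
  if (threshold < 0) abort_eoc("threshold must be >= 0", "eoclines_input_error")
  mads <- apply(expr, 1, stats::mad, constant = scale_constant)
  kept <- rownames(expr)[mads >= threshold]
  structure(list(kept_genes = kept, mad_values = mads,
                 threshold = threshold, scale_constant = scale_constant),
            class = "eoc_gene_filter")
}

#' @export
print.eoc_gene_filter <- function(x, ...) {
  cat(sprintf("MAD filter: %d / %d genes kept at MAD >= %g (constant %g)\n",
              length(x$kept_genes), length(x$mad_values), x$threshold, x$scale_constant))
  invisible(x)
}

#' Upper-quartile normalization
#'
#' Each sample is divided by the 75th percentile (type-7 quantile) of its
#' nonzero counts, then rescaled by the global mean of those percentiles so
#' values stay on a count-like magnitude. Optionally log2(x + 1) afterwards.
#'
#' @param counts count matrix; every sample must have at least one nonzero.
#' @param log2_transform apply log2(x + 1) after scaling.
#' @return numeric matrix with transform chain `"uq"` (or `c("uq", "log2")`).
#' @export
upper_quartile_normalize <- function(counts, log2_transform = FALSE) {
  check_count_matrix(counts)
  uq <- apply(counts, 2, function(x) {
    nz <- x[x > 0]
    if (length(nz) == 0) return(NA_real_)
    stats::quantile(nz, 0.75, type = 7, names = FALSE)
  })
  if (anyNA(uq))
    abort_eoc(sprintf("sample(s) with all-zero counts: %s",
                      paste(colnames(counts)[is.na(uq)], collapse = ", ")),
              "eoclines_input_error")
  out <- sweep(counts, 2, uq, "/") * mean(uq)
  out <- add_transform(out, "uq")
  if (log2_transform) out <- add_transform(log2(out + 1), "log2", from = out)
  out
}

#' Harmonize two expression matrices to a shared, ordered gene set
#'
#' @param x,y matrices with gene rownames.
#' @return a list with both matrices restricted to the intersection of their
#'   gene ids, in a common order.
#' @export
harmonize_genes <- function(x, y) {
  genes <- intersect(rownames(x), rownames(y))
  if (length(genes) == 0) abort_eoc("no shared genes", "eoclines_input_error")
  list(x = x[genes, , drop = FALSE], y = y[genes, , drop = FALSE], genes = genes)
}
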