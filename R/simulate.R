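#' Configuration for the synthetic EOC expression-panel generator
#'
#' Bundles every knob of the generator into a validated list. The defaults
#' mirror the study design the package targets: a 56-line cell panel with five
#' balanced planted subtypes drawn from three source batches, and 93 tumors
#' split 16/64/8/5 across CCOC/HGSOC/ENOC/MOC (no tumor analogue exists for
#' LGSOC) from three further batches. Counts are negative binomial with
#' variance \eqn{\mu + \alpha\mu^2}.
#'
#' @param n_genes number of genes.
#' @param k_subtypes number of planted subtypes (>= 2).
#' @param subtype_names labels for the planted subtypes; length `k_subtypes`.
#' @param n_cell_lines number of cell-line samples (balanced across subtypes).
#' @param n_tumors_per_subtype named integer vector of tumor counts per
#'   subtype; names must be a subset of `subtype_names`.
#' @param n_sig_genes_per_subtype signature genes planted per subtype; the
#'   sets are disjoint, so `k_subtypes * n_sig_genes_per_subtype <= n_genes`.
#' @param logfc_mean,logfc_sd log2 fold-change distribution of signature genes
#'   in their own subtype relative to baseline.
#' @param sig_baseline_shift natural-log shift applied to the baseline weight
#'   of signature genes (default -3). Marker genes are modeled as lowly
#'   expressed outside their own subtype; this off/on structure is what makes
#'   the planted metagenes identifiable rather than arbitrary rotations of a
#'   shared expression cone.
#' @param nb_dispersion negative-binomial dispersion \eqn{\alpha} (> 0; values
#'   below 1e-12 fall back to Poisson sampling).
#' @param library_size_logmean,library_size_logsd log-normal library sizes.
#' @param baseline_logmean,baseline_logsd per-gene baseline relative-expression
#'   weights, log-normal on the natural-log scale.
#' @param n_batches_cell_lines,n_batches_tumors number of source batches.
#' @param batch_location_sd sd of the per-batch per-gene location shift on the
#'   natural-log mean scale (first batch is the unshifted reference).
#' @param batch_scale_sd sd of the log of the per-batch per-gene scale factor
#'   applied to deviations from the gene's mean log expression.
#' @param purity_low,purity_high uniform bounds for tumor purity, in (0, 1].
#' @param line_similarity optional per-line similarity dial in \[0, 1\]: the
#'   line's expected profile is `s * subtype + (1 - s) * drift`, where `drift`
#'   is a line-specific random expression profile emulating culture-acquired
#'   transcriptional divergence from any tumor. `NULL` means all lines are
#'   faithful models (`s = 1`).
#' @param rng_seed integer master seed; every stochastic step derives its own
#'   sub-seed from it, so a config reproduces its panel bit-for-bit.
#'
#' @return an object of class `eoc_sim_config` (a named list).
#' @seealso [generate_signatures()], [simulate_cell_lines()], [simulate_tumors()]
#' @export
sim_config <- function(n_genes = 1200L,
                       k_subtypes = 5L,
                       subtype_names = c("HGSOC", "CCOC", "ENOC", "MOC", "LGSOC"),
                       n_cell_lines = 56L,
                       n_tumors_per_subtype = c(CCOC = 16L, HGSOC = 64L, ENOC = 8L, MOC = 5L),
                       n_sig_genes_per_subtype = 60L,
                       logfc_mean = 2,
                       logfc_sd = 0.25,
                       sig_baseline_shift = -4,
                       nb_dispersion = 0.02,
                       library_size_logmean = log(3e5),
                       library_size_logsd = 0.15,
                       baseline_logmean = 0,
                       baseline_logsd = 0.5,
                       n_batches_cell_lines = 3L,
                       n_batches_tumors = 3L,
                       batch_location_sd = 0.4,
                       batch_scale_sd = 0.1,
                       purity_low = 0.6,
                       purity_high = 0.95,
                       line_similarity = NULL,
                       rng_seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), k_subtypes = as.integer(k_subtypes),
    subtype_names = as.character(subtype_names),
    n_cell_lines = as.integer(n_cell_lines),
    n_tumors_per_subtype = n_tumors_per_subtype,
    n_sig_genes_per_subtype = as.integer(n_sig_genes_per_subtype),
    logfc_mean = logfc_mean, logfc_sd = logfc_sd,
    sig_baseline_shift = sig_baseline_shift,
    nb_dispersion = nb_dispersion,
    library_size_logmean = library_size_logmean,
    library_size_logsd = library_size_logsd,
    baseline_logmean = baseline_logmean, baseline_logsd = baseline_logsd,
    n_batches_cell_lines = as.integer(n_batches_cell_lines),
    n_batches_tumors = as.integer(n_batches_tumors),
    batch_location_sd = batch_location_sd, batch_scale_sd = batch_scale_sd,
    purity_low = purity_low, purity_high = purity_high,
    line_similarity = line_similarity,
    rng_seed = as.integer(rng_seed))
  validate_sim_config(cfg)
  class(cfg) <- "eoc_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1L, cfg$n_cell_lines >= 1L)
  if (cfg$k_subtypes < 2L)
    abort_eoc("at least 2 subtypes are required", "eoclines_config_error")
  if (length(cfg$subtype_names) != cfg$k_subtypes)
    abort_eoc("subtype_names must have length k_subtypes", "eoclines_config_error")
  if (anyDuplicated(cfg$subtype_names))
    abort_eoc("subtype_names must be unique", "eoclines_config_error")
  if (!all(names(cfg$n_tumors_per_subtype) %in% cfg$subtype_names))
    abort_eoc("n_tumors_per_subtype names must be subtype_names", "eoclines_config_error")
  if (any(cfg$n_tumors_per_subtype < 1))
    abort_eoc("tumor counts must be positive", "eoclines_config_error")
  if (cfg$nb_dispersion < 0)
    abort_eoc("nb_dispersion must be non-negative", "eoclines_config_error")
  if (cfg$purity_low <= 0 || cfg$purity_high > 1 || cfg$purity_low > cfg$purity_high)
    abort_eoc("purity bounds must satisfy 0 < low <= high <= 1", "eoclines_config_error")
  if (cfg$logfc_sd < 0 || cfg$batch_location_sd < 0 || cfg$batch_scale_sd < 0)
    abort_eoc("sd parameters must be non-negative", "eoclines_config_error")
  if (!is.null(cfg$line_similarity) &&
      (any(cfg$line_similarity < 0) || any(cfg$line_similarity > 1)))
    abort_eoc("line_similarity values must lie in [0, 1]", "eoclines_config_error")
  invisible(cfg)
}

# fixed offsets deriving one sub-seed per stochastic phase from the master seed
sim_seed <- function(cfg, phase) {
  off <- c(signatures = 11L, lines = 21L, lines_counts = 22L,
           tumors = 31L, tumors_counts = 32L,
           batch_lines = 41L, batch_tumors = 42L)[[phase]]
  cfg$rng_seed + off
}

#' Plant subtype expression signatures
#'
#' Draws per-gene baseline expression weights and plants `k` disjoint sets of
#' signature genes, each carrying a log2 fold-change in its own subtype. The
#' signature matrix is the generative analogue of the metagenes that drive
#' cluster assignment downstream.
#'
#' @param config an [sim_config()] object.
#' @return an object of class `eoc_signatures`: gene ids, the genes-by-subtype
#'   signature matrix of relative expression weights, the per-subtype signature
#'   gene sets, and the per-gene baseline log weights.
#' @export
generate_signatures <- function(config) {
  validate_sim_config(config)
  k <- config$k_subtypes
  if (k * config$n_sig_genes_per_subtype > config$n_genes)
    abort_eoc(sprintf("cannot plant %d disjoint sets of %d signature genes in %d genes",
                      k, config$n_sig_genes_per_subtype, config$n_genes),
              "eoclines_config_error")
  genes <- sprintf("G%06d", seq_len(config$n_genes))
  with_seed(sim_seed(config, "signatures"), {
    baseline_log <- stats::rnorm(config$n_genes, config$baseline_logmean, config$baseline_logsd)
    picked <- sample.int(config$n_genes, k * config$n_sig_genes_per_subtype)
    baseline_log[picked] <- baseline_log[picked] + (config$sig_baseline_shift %||% 0)
    sig_idx <- split(picked, rep(seq_len(k), each = config$n_sig_genes_per_subtype))
    lfc <- matrix(0, config$n_genes, k)
    for (j in seq_len(k))
      lfc[sig_idx[[j]], j] <- stats::rnorm(config$n_sig_genes_per_subtype,
                                           config$logfc_mean, config$logfc_sd)
    sig <- exp(baseline_log) * 2^lfc
    dimnames(sig) <- list(genes, config$subtype_names)
    names(baseline_log) <- genes
    signature_genes <- lapply(sig_idx, function(i) genes[i])
    names(signature_genes) <- config$subtype_names
    structure(list(genes = genes,
                   signatures = sig,
                   signature_genes = signature_genes,
                   baseline_log = baseline_log,
                   config = config),
              class = "eoc_signatures")
  })
}

#' @export
print.eoc_signatures <- function(x, ...) {
  cat(sprintf("Planted subtype signatures: %d genes, %d subtypes (%s), %d signature genes each\n",
              length(x$genes), ncol(x$signatures),
              paste(colnames(x$signatures), collapse = ", "),
              length(x$signature_genes[[1]])))
  invisible(x)
}

# normalized expression profile (sums to 1) for one subtype or the baseline
subtype_profile <- function(signatures, subtype) {
  s <- signatures$signatures[, subtype]
  s / sum(s)
}
baseline_profile <- function(signatures) {
  b <- exp(signatures$baseline_log)
  b / sum(b)
}

new_eoc_sim <- function(counts, metadata, truth, mu, dispersion, count_seed, config) {
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, metadata = metadata, truth = truth,
                 mu = mu, dispersion = dispersion, count_seed = count_seed,
                 config = config),
            class = "eoc_sim")
}

#' @export
print.eoc_sim <- function(x, ...) {
  cat(sprintf("Synthetic %s panel: %d genes x %d samples, %d batches, subtypes: %s\n",
              paste(unique(x$metadata$kind), collapse = "+"),
              nrow(x$counts), ncol(x$counts),
              length(unique(x$metadata$batch)),
              paste(sort(unique(x$truth$true_subtype)), collapse = ", ")))
  invisible(x)
}

draw_counts <- function(mu, dispersion, seed) {
  with_seed(seed, {
    x <- if (dispersion < 1e-12) stats::rpois(length(mu), lambda = mu)
         else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    counts <- matrix(x, nrow = nrow(mu), dimnames = dimnames(mu))
    counts
  })
}

#' Simulate a cell-line count panel with planted subtypes
#'
#' Each line receives a planted subtype (balanced round-robin by default), a
#' log-normal library size, and an expected profile
#' `s * subtype_profile + (1 - s) * drift_profile`, where `s` is the line's
#' similarity dial and the drift profile is an independent random expression
#' profile unique to the line (culture-acquired divergence; a line with
#' `s = 0` resembles no tumor). Counts are negative binomial with the
#' configured dispersion. Truth labels (subtype, similarity) are recorded.
#'
#' @param signatures an `eoc_signatures` object.
#' @param config the matching [sim_config()].
#' @return an object of class `eoc_sim` holding the integer count matrix, a
#'   `metadata` data frame (sample_id, kind, batch, annotation) and a `truth`
#'   data frame (true_subtype, purity, similarity).
#' @export
simulate_cell_lines <- function(signatures, config = signatures$config) {
  validate_sim_config(config)
  n <- config$n_cell_lines
  ids <- sprintf("CL%03d", seq_len(n))
  subtypes <- rep_len(config$subtype_names, n)
  batches <- rep_len(paste0("LB", seq_len(config$n_batches_cell_lines)), n)
  sim <- if (is.null(config$line_similarity)) rep(1, n)
         else rep_len(config$line_similarity, n)
  drawn <- with_seed(sim_seed(config, "lines"), {
    lib <- exp(stats::rnorm(n, config$library_size_logmean, config$library_size_logsd))
    drift <- if (all(sim == 1)) NULL else {
      d <- matrix(exp(stats::rnorm(config$n_genes * n, config$baseline_logmean,
                                   config$baseline_logsd)),
                  config$n_genes, n)
      sweep(d, 2, colSums(d), "/")
    }
    list(lib = lib, drift = drift)
  })
  lib <- drawn$lib
  if (any(!is.finite(lib)) || any(lib <= 0))
    abort_eoc("library sizes must be positive and finite", "eoclines_config_error")
  prof <- vapply(seq_len(n), function(i) {
    p <- sim[i] * subtype_profile(signatures, subtypes[i])
    if (sim[i] < 1) p <- p + (1 - sim[i]) * drawn$drift[, i]
    lib[i] * p
  }, numeric(config$n_genes))
  dimnames(prof) <- list(signatures$genes, ids)
  count_seed <- sim_seed(config, "lines_counts")
  counts <- draw_counts(prof, config$nb_dispersion, count_seed)
  metadata <- data.frame(sample_id = ids, kind = "cell_line", batch = batches,
                         annotation = subtypes, stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = ids, true_subtype = subtypes,
                      purity = NA_real_, similarity = sim, stringsAsFactors = FALSE)
  new_eoc_sim(counts, metadata, truth, prof, config$nb_dispersion, count_seed, config)
}

#' Simulate a subtype-stratified tumor count panel with purity dilution
#'
#' Tumors draw a purity `p ~ Uniform(purity_low, purity_high)`; the expected
#' profile is the convex mixture `p * subtype_profile + (1 - p) * stromal
#' baseline profile`, emulating the stromal admixture that separates bulk
#' tumors from pure cell lines. Counts are negative binomial.
#'
#' @inheritParams simulate_cell_lines
#' @return an `eoc_sim` object; purity is recorded in `truth$purity`.
#' @export
simulate_tumors <- function(signatures, config = signatures$config) {
  validate_sim_config(config)
  nper <- config$n_tumors_per_subtype
  subtypes <- rep(names(nper), times = nper)
  n <- length(subtypes)
  ids <- sprintf("TU%03d", seq_len(n))
  batches <- rep_len(paste0("TB", seq_len(config$n_batches_tumors)), n)
  res <- with_seed(sim_seed(config, "tumors"), {
    purity <- stats::runif(n, config$purity_low, config$purity_high)
    lib <- exp(stats::rnorm(n, config$library_size_logmean, config$library_size_logsd))
    list(purity = purity, lib = lib)
  })
  base <- baseline_profile(signatures)
  prof <- vapply(seq_len(n), function(i) {
    p <- res$purity[i] * subtype_profile(signatures, subtypes[i]) + (1 - res$purity[i]) * base
    res$lib[i] * p
  }, numeric(config$n_genes))
  dimnames(prof) <- list(signatures$genes, ids)
  count_seed <- sim_seed(config, "tumors_counts")
  counts <- draw_counts(prof, config$nb_dispersion, count_seed)
  metadata <- data.frame(sample_id = ids, kind = "tumor", batch = batches,
                         annotation = subtypes, stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = ids, true_subtype = subtypes,
                      purity = res$purity, similarity = NA_real_, stringsAsFactors = FALSE)
  new_eoc_sim(counts, metadata, truth, prof, config$nb_dispersion, count_seed, config)
}

#' Overlay per-batch location/scale effects and redraw counts
#'
#' Creates the nuisance structure that batch correction later removes. For
#' each non-reference batch `b` and gene `g`, the log expected mean is moved to
#' `center_g + lambda_bg * (log mu - center_g) + delta_bg`, where `delta_bg ~
#' N(0, batch_location_sd)` and `log lambda_bg ~ N(0, batch_scale_sd)`;
#' `center_g` is the gene's mean log expected expression across samples. The
#' first batch level is the unshifted reference. Counts are redrawn from the
#' shifted means using the object's original count seed, so zero-magnitude
#' effects reproduce the input exactly; truth labels are untouched.
#'
#' @param data an `eoc_sim` object whose metadata assigns every sample a batch.
#' @param config simulation config providing the effect magnitudes.
#' @return a new `eoc_sim` object with shifted means and redrawn counts.
#' @export
apply_batch_effects <- function(data, config = data$config) {
  stopifnot(inherits(data, "eoc_sim"))
  batch <- data$metadata$batch
  if (any(is.na(batch) | !nzchar(batch)))
    abort_eoc("every sample needs a batch label", "eoclines_input_error")
  batch <- factor(batch)
  phase <- if (identical(data$metadata$kind[1], "tumor")) "batch_tumors" else "batch_lines"
  G <- nrow(data$mu)
  nb <- nlevels(batch)
  eff <- with_seed(sim_seed(config, phase), {
    delta <- matrix(0, G, nb)
    lambda <- matrix(1, G, nb)
    if (nb > 1) {
      for (b in 2:nb) {
        delta[, b] <- stats::rnorm(G, 0, config$batch_location_sd)
        lambda[, b] <- exp(stats::rnorm(G, 0, config$batch_scale_sd))
      }
    }
    list(delta = delta, lambda = lambda)
  })
  logmu <- log(pmax(data$mu, 1e-12))
  center <- rowMeans(logmu)
  bi <- as.integer(batch)
  shifted <- center + eff$lambda[, bi, drop = FALSE] * (logmu - center) + eff$delta[, bi, drop = FALSE]
  mu <- exp(shifted)
  dimnames(mu) <- dimnames(data$mu)
  counts <- draw_counts(mu, data$dispersion, data$count_seed)
  new_eoc_sim(counts, data$metadata, data$truth, mu, data$dispersion,
              data$count_seed, config)
}

#' Combine cell-line and tumor panels into one joint panel
#'
#' @param x,y `eoc_sim` objects sharing the same gene universe.
#' @return an `eoc_sim` object with concatenated samples.
#' @export
combine_panels <- function(x, y) {
  stopifnot(inherits(x, "eoc_sim"), inherits(y, "eoc_sim"))
  genes <- intersect(rownames(x$counts), rownames(y$counts))
  if (length(genes) == 0)
    abort_eoc("panels share no genes", "eoclines_input_error")
  if (any(colnames(x$counts) %in% colnames(y$counts)))
    abort_eoc("panels share sample ids", "eoclines_input_error")
  new_eoc_sim(cbind(x$counts[genes, , drop = FALSE], y$counts[genes, , drop = FALSE]),
              rbind(x$metadata, y$metadata),
              rbind(x$truth, y$truth),
              cbind(x$mu[genes, , drop = FALSE], y$mu[genes, , drop = FALSE]),
              x$dispersion, x$count_seed, x$config)
}

#' Write a synthetic panel to disk as plain-text fixtures
#'
#' Emits `counts.tsv` (gene_id column + one column per sample),
#' `counts.mtx` (MatrixMarket coordinate integer) with `genes.txt` /
#' `samples.txt` sidecars, `metadata.tsv`, `truth.tsv`, and the generating
#' config as `sim_config.yaml`. The files round-trip losslessly through
#' [read_counts()].
#'
#' @param data an `eoc_sim` object.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(data, dir) {
  stopifnot(inherits(data, "eoc_sim"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) abort_eoc(sprintf("cannot create fixture directory '%s'", dir), "eoclines_io_error")
  paths <- file.path(dir, c("counts.tsv", "counts.mtx", "genes.txt", "samples.txt",
                            "metadata.tsv", "truth.tsv", "sim_config.yaml"))
  names(paths) <- basename(paths)
  tsv <- data.frame(gene_id = rownames(data$counts), data$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tsv, paths[["counts.tsv"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_mm_integer(data$counts, paths[["counts.mtx"]])
  writeLines(rownames(data$counts), paths[["genes.txt"]])
  writeLines(colnames(data$counts), paths[["samples.txt"]])
  utils::write.table(data$metadata, paths[["metadata.tsv"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data$truth, paths[["truth.tsv"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- unclass(data$config)
  yaml::write_yaml(cfg, paths[["sim_config.yaml"]])
  invisible(paths)
}

# MatrixMarket "coordinate integer general" writer; Matrix::writeMM only emits
# the real field, and the fixture contract requires integer.
write_mm_integer <- function(counts, path) {
  nz <- which(counts != 0L)
  i <- ((nz - 1L) %% nrow(counts)) + 1L
  j <- ((nz - 1L) %/% nrow(counts)) + 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate integer general", con)
  writeLines(sprintf("%d %d %d", nrow(counts), ncol(counts), length(nz)), con)
  if (length(nz))
    writeLines(sprintf("%d %d %d", i, j, as.integer(counts[nz])), con)
  invisible(path)
}
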