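#' Pipeline configuration
#'
#' Collects every stage parameter (all serializable to YAML) with the stage
#' toggles. A config plus its seed reproduces a run bit-for-bit for the
#' deterministic stages.
#'
#' @param out_dir run directory (created by [run_pipeline()]).
#' @param seed master seed; stage seeds are derived from it deterministically.
#' @param sim an [sim_config()] (its `rng_seed` is overridden by `seed` unless
#'   `sim` is supplied explicitly), or `NULL` with `stages$simulate = FALSE`.
#' @param paths when not simulating: named list with `lines_counts`,
#'   `tumors_counts`, `metadata` file paths.
#' @param stages named logical list toggling `simulate`, `survey`, `nmf`,
#'   `subtype`, `correlate`, `rank`, `recommend`.
#' @param mad_threshold,mad_constant gene-filter settings for the NMF branch.
#' @param survey_ranks,survey_runs rank-survey settings.
#' @param nmf_rank factorization rank; `NULL` defers to the survey selection
#'   (or the simulated subtype count when the survey is off).
#' @param nmf_runs restarts for the final consensus run.
#' @param uq_log2 apply log2 after upper-quartile normalization in the
#'   correlation branch.
#' @param q_low,top_n,top_k recommendation-rule thresholds (see
#'   [recommend_lines()]).
#' @return an object of class `eoc_pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            sim = NULL,
                            paths = NULL,
                            stages = list(),
                            mad_threshold = 0.65,
                            mad_constant = 1.4826,
                            survey_ranks = 2:8,
                            survey_runs = 15L,
                            nmf_rank = NULL,
                            nmf_runs = 50L,
                            uq_log2 = TRUE,
                            q_low = 0.25,
                            top_n = 20L,
                            top_k = 10L) {
  default_stages <- list(simulate = TRUE, survey = FALSE, nmf = TRUE,
                         subtype = TRUE, correlate = TRUE, rank = TRUE,
                         recommend = TRUE)
  stages <- utils::modifyList(default_stages, stages)
  if (is.null(sim) && isTRUE(stages$simulate))
    sim <- sim_config(rng_seed = seed)
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
              paths = paths, stages = stages,
              mad_threshold = mad_threshold, mad_constant = mad_constant,
              survey_ranks = as.integer(survey_ranks),
              survey_runs = as.integer(survey_runs),
              nmf_rank = if (is.null(nmf_rank)) NULL else as.integer(nmf_rank),
              nmf_runs = as.integer(nmf_runs),
              uq_log2 = isTRUE(uq_log2),
              q_low = q_low, top_n = as.integer(top_n), top_k = as.integer(top_k))
  class(cfg) <- "eoc_pipeline_config"
  cfg
}

#' Read / write a pipeline config as YAML
#' @param config an `eoc_pipeline_config`.
#' @param path YAML file path.
#' @return `read_pipeline_config` returns the config object.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$sim)) x$sim <- unclass(x$sim)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- if (!is.null(x$sim)) do.call(sim_config, x$sim) else NULL
  pipeline_config(out_dir = x$out_dir, seed = x$seed, sim = sim,
                  paths = x$paths, stages = x$stages,
                  mad_threshold = x$mad_threshold, mad_constant = x$mad_constant,
                  survey_ranks = x$survey_ranks, survey_runs = x$survey_runs,
                  nmf_rank = x$nmf_rank, nmf_runs = x$nmf_runs,
                  uq_log2 = x$uq_log2, q_low = x$q_low,
                  top_n = x$top_n, top_k = x$top_k)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> preprocess -> rank survey (optional) ->
#' consensus NMF -> subtype mapping -> correlation -> ranking ->
#' recommendation, persisting every intermediate under the run directory and
#' recording parameters, file hashes and timings in `manifest.json`. Stages
#' fail fast with stage-scoped errors; no stage mutates its inputs.
#'
#' @param config an [pipeline_config()] object (or a path to its YAML form).
#' @return the manifest, invisibly (class `eoc_manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "eoc_pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "eoclines",
                   version = as.character(utils::packageVersion("eoclines")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = config$seed,
                   config = unclass_deep(config),
                   stages = list())
  env <- new.env(parent = emptyenv())

  stage <- function(name, enabled, params, fun) {
    if (!enabled) {
      manifest$stages[[name]] <<- list(skipped = TRUE)
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    files <- tryCatch(fun(),
                      error = function(e) abort_eoc(
                        sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                        "eoclines_stage_error"))
    manifest$stages[[name]] <<- list(
      params = params,
      outputs = as.list(tools::md5sum(unlist(files))),
      elapsed_sec = round(proc.time()[["elapsed"]] - t0, 3))
    invisible(NULL)
  }

  # --- simulate -------------------------------------------------------------
  stage("simulate", isTRUE(config$stages$simulate),
        params = unclass_deep(config$sim), fun = function() {
    sig <- generate_signatures(config$sim)
    lines <- apply_batch_effects(simulate_cell_lines(sig), config$sim)
    tumors <- apply_batch_effects(simulate_tumors(sig), config$sim)
    env$lines <- lines
    env$tumors <- tumors
    c(write_fixture(lines, file.path(out, "sim", "lines")),
      write_fixture(tumors, file.path(out, "sim", "tumors")))
  })
  if (!isTRUE(config$stages$simulate)) {
    p <- config$paths
    if (is.null(p$lines_counts) || is.null(p$metadata))
      abort_eoc("paths$lines_counts and paths$metadata are required when not simulating",
                "eoclines_config_error")
    meta <- utils::read.delim(p$metadata, stringsAsFactors = FALSE)
    lc <- read_counts(p$lines_counts)
    lmeta <- meta[match(colnames(lc), meta$sample_id), ]
    env$lines <- new_eoc_sim(lc, lmeta, data.frame(sample_id = colnames(lc)),
                             mu = lc * 1.0, dispersion = NA_real_,
                             count_seed = NA_integer_, config = NULL)
    if (!is.null(p$tumors_counts)) {
      tc <- read_counts(p$tumors_counts)
      tmeta <- meta[match(colnames(tc), meta$sample_id), ]
      env$tumors <- new_eoc_sim(tc, tmeta, data.frame(sample_id = colnames(tc)),
                                mu = tc * 1.0, dispersion = NA_real_,
                                count_seed = NA_integer_, config = NULL)
    }
  }

  # --- preprocess (NMF branch: cell lines only) -----------------------------
  stage("preprocess", TRUE,
        params = list(mad_threshold = config$mad_threshold,
                      mad_constant = config$mad_constant), fun = function() {
    counts <- env$lines$counts
    vst <- vst_transform(counts)
    # remove source/batch structure before clustering; clamp at zero so the
    # matrix stays NMF-ready
    adj0 <- combat_adjust(vst, env$lines$metadata$batch)
    adj <- add_transform(pmax(adj0, 0), "clamp0", from = adj0)
    filt <- mad_filter(adj, config$mad_threshold, config$mad_constant)
    if (length(filt$kept_genes) < 10)
      abort_eoc(sprintf("only %d genes pass the MAD filter; lower mad_threshold",
                        length(filt$kept_genes)), "eoclines_config_error")
    env$V <- adj[filt$kept_genes, , drop = FALSE]
    env$filter <- filt
    f1 <- write_matrix_tsv(env$V, file.path(out, "expression_vst.tsv"), "gene_id")
    f2 <- file.path(out, "mad_filter.json")
    jsonlite::write_json(list(threshold = filt$threshold,
                              scale_constant = filt$scale_constant,
                              n_kept = length(filt$kept_genes),
                              kept_genes = filt$kept_genes,
                              transform_chain = transform_chain(env$V)),
                         f2, auto_unbox = TRUE, pretty = TRUE)
    c(f1, f2)
  })

  # --- rank survey ----------------------------------------------------------
  stage("survey", isTRUE(config$stages$survey),
        params = list(ranks = config$survey_ranks, n_runs = config$survey_runs), fun = function() {
    sv <- rank_survey(env$V, config$survey_ranks, config$survey_runs, seed = config$seed)
    sel <- select_rank(sv)
    env$selected_rank <- sel$selected_rank
    f1 <- write_tsv(sv$table, file.path(out, "survey.tsv"))
    f2 <- file.path(out, "rank_selection.json")
    jsonlite::write_json(list(selected_rank = sel$selected_rank,
                              overfit_rank = sel$overfit_rank,
                              eligible = sel$eligible, rule = sel$rule),
                         f2, auto_unbox = TRUE, pretty = TRUE)
    c(f1, f2)
  })

  rank_used <- config$nmf_rank %||% env$selected_rank %||% config$sim$k_subtypes
  if (is.null(rank_used))
    abort_eoc("no factorization rank: set nmf_rank or enable the survey", "eoclines_config_error")

  # --- consensus NMF --------------------------------------------------------
  stage("nmf", isTRUE(config$stages$nmf),
        params = list(rank = rank_used, n_runs = config$nmf_runs,
                      seed = config$seed), fun = function() {
    rc <- run_consensus(env$V, rank_used, n_runs = config$nmf_runs, seed = config$seed)
    env$rc <- rc
    f <- c(write_matrix_tsv(rc$consensus, file.path(out, "consensus.tsv"), "sample_id"),
           write_tsv(data.frame(sample_id = names(rc$labels),
                                cluster = as.integer(rc$labels),
                                hclust_cluster = as.integer(rc$hclust_labels),
                                silhouette = unname(rc$silhouettes)),
                     file.path(out, "labels.tsv")),
           write_matrix_tsv(rc$best_fit$W, file.path(out, "W.tsv"), "gene_id"),
           write_matrix_tsv(rc$best_fit$H, file.path(out, "H.tsv"), "metagene"))
    fm <- file.path(out, "metrics.json")
    jsonlite::write_json(list(rank = rc$r, n_runs = rc$n_runs, seed = rc$seed,
                              cophenetic = rc$cophenetic, dispersion = rc$dispersion,
                              mean_silhouette = mean(rc$silhouettes),
                              min_silhouette = min(rc$silhouettes),
                              rss = rc$rss, best_run = rc$best_run),
                         fm, auto_unbox = TRUE, pretty = TRUE)
    c(f, fm)
  })

  # --- subtype mapping ------------------------------------------------------
  stage("subtype", isTRUE(config$stages$subtype) && isTRUE(config$stages$nmf),
        params = list(), fun = function() {
    ann <- data.frame(sample_id = env$lines$metadata$sample_id,
                      subtype = env$lines$metadata$annotation,
                      stringsAsFactors = FALSE)
    asn <- suppressWarnings(map_clusters_to_subtypes(env$rc$labels, ann))
    env$assignment <- asn
    write_tsv(as.data.frame(asn), file.path(out, "assignment.tsv"))
  })

  # --- correlation branch ---------------------------------------------------
  stage("correlate", isTRUE(config$stages$correlate),
        params = list(uq_log2 = config$uq_log2), fun = function() {
    if (is.null(env$tumors)) abort_eoc("no tumor panel available", "eoclines_config_error")
    joint <- combine_panels(env$lines, env$tumors)
    expr <- upper_quartile_normalize(joint$counts, log2_transform = config$uq_log2)
    expr <- combat_adjust(expr, joint$metadata$batch)
    genes <- intersect(env$filter$kept_genes, rownames(expr))
    is_line <- joint$metadata$kind == "cell_line"
    rho <- spearman_matrix(expr[, is_line, drop = FALSE],
                           expr[, !is_line, drop = FALSE], gene_set = genes)
    env$corr <- rho
    env$tumor_subtypes <- stats::setNames(
      joint$metadata$annotation[!is_line], joint$metadata$sample_id[!is_line])
    long <- data.frame(cell_line = rep(rownames(rho), times = ncol(rho)),
                       tumor = rep(colnames(rho), each = nrow(rho)),
                       subtype = rep(unname(env$tumor_subtypes[colnames(rho)]), each = nrow(rho)),
                       rho = as.vector(rho), stringsAsFactors = FALSE)
    c(write_tsv(long, file.path(out, "corr_long.tsv")),
      write_matrix_tsv(rho, file.path(out, "corr_matrix.tsv"), "cell_line"))
  })

  # --- per-subtype ranking --------------------------------------------------
  stage("rank", isTRUE(config$stages$rank) && isTRUE(config$stages$correlate),
        params = list(statistic = "median"), fun = function() {
    subs <- unique(unname(env$tumor_subtypes))
    rk <- do.call(rbind, lapply(subs, function(s)
      as.data.frame(suppressMessages(
        rank_by_correlation(env$corr, env$tumor_subtypes, s, "median")))))
    env$ranking <- rk
    write_tsv(rk, file.path(out, "ranking.tsv"))
  })

  # --- recommendations ------------------------------------------------------
  stage("recommend",
        isTRUE(config$stages$recommend) && isTRUE(config$stages$correlate) &&
          isTRUE(config$stages$subtype) && isTRUE(config$stages$nmf),
        params = list(q_low = config$q_low, top_n = config$top_n, top_k = config$top_k),
        fun = function() {
    rec <- recommend_lines(env$corr, env$tumor_subtypes, env$assignment,
                           q_low = config$q_low, top_n = config$top_n,
                           top_k = config$top_k)
    write_tsv(as.data.frame(rec), file.path(out, "recommendations.tsv"))
  })

  mpath <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  class(manifest) <- "eoc_manifest"
  invisible(manifest)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Verify the file hashes recorded in a run manifest
#'
#' @param run_dir a directory written by [run_pipeline()].
#' @return TRUE invisibly if every recorded hash matches; errors otherwise.
#' @export
verify_manifest <- function(run_dir) {
  mpath <- file.path(run_dir, "manifest.json")
  if (!file.exists(mpath)) abort_eoc("no manifest.json in run_dir", "eoclines_io_error")
  manifest <- jsonlite::read_json(mpath)
  for (st in names(manifest$stages)) {
    outs <- manifest$stages[[st]]$outputs
    for (f in names(outs)) {
      if (!file.exists(f))
        abort_eoc(sprintf("manifest file missing: %s", f), "eoclines_io_error")
      if (!identical(unname(tools::md5sum(f)), outs[[f]]))
        abort_eoc(sprintf("hash mismatch for %s", f), "eoclines_io_error")
    }
  }
  invisible(TRUE)
}
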