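#' Render the report figures for a pipeline run
#'
#' Produces three PNG figures from the files a [run_pipeline()] run left in
#' `run_dir`: the consensus heatmap (rows and columns in the average-linkage
#' dendrogram leaf order shared with [consensus_order()]), the
#' cell-line-by-tumor correlation heatmap with subtype side annotations, and
#' per-subtype boxplots of correlations ordered exactly as `ranking.tsv`.
#' Ordering is deterministic.
#'
#' @param run_dir pipeline run directory.
#' @param width,height device size in pixels.
#' @return character vector of figure paths (those whose inputs were present).
#' @export
render_reports <- function(run_dir, width = 900, height = 800) {
  made <- character(0)

  cons_path <- file.path(run_dir, "consensus.tsv")
  if (file.exists(cons_path)) {
    C <- read_matrix_tsv(cons_path)
    ord <- consensus_order(C)
    f <- file.path(run_dir, "consensus_heatmap.png")
    grDevices::png(f, width, height)
    graphics::par(mar = c(6, 1, 3, 6))
    graphics::image(t(C[ord, rev(ord)]), axes = FALSE,
                    col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                    main = "Consensus map")
    n <- nrow(C)
    graphics::axis(1, at = seq(0, 1, length.out = n), labels = rownames(C)[ord],
                   las = 2, cex.axis = 0.6, tick = FALSE)
    graphics::axis(4, at = seq(0, 1, length.out = n), labels = rev(rownames(C)[ord]),
                   las = 2, cex.axis = 0.6, tick = FALSE)
    grDevices::dev.off()
    made <- c(made, f)
  } else {
    message("render_reports: consensus.tsv missing, skipping consensus heatmap")
  }

  corr_path <- file.path(run_dir, "corr_matrix.tsv")
  long_path <- file.path(run_dir, "corr_long.tsv")
  if (file.exists(corr_path) && file.exists(long_path)) {
    R <- read_matrix_tsv(corr_path)
    long <- utils::read.delim(long_path, stringsAsFactors = FALSE)
    tsub <- long$subtype[match(colnames(R), long$tumor)]
    tord <- order(tsub, colnames(R))
    f <- file.path(run_dir, "correlation_heatmap.png")
    grDevices::png(f, width, height)
    graphics::par(mar = c(6, 1, 3, 6))
    graphics::image(t(R[, tord, drop = FALSE]), axes = FALSE,
                    col = grDevices::hcl.colors(64, "Blue-Red 2"),
                    main = "Cell line vs tumor Spearman correlation")
    graphics::axis(1, at = seq(0, 1, length.out = ncol(R)), labels = colnames(R)[tord],
                   las = 2, cex.axis = 0.5, tick = FALSE)
    graphics::axis(4, at = seq(0, 1, length.out = nrow(R)), labels = rownames(R),
                   las = 2, cex.axis = 0.5, tick = FALSE)
    grDevices::dev.off()
    made <- c(made, f)
  } else {
    message("render_reports: correlation outputs missing, skipping correlation heatmap")
  }

  rank_path <- file.path(run_dir, "ranking.tsv")
  if (file.exists(rank_path) && file.exists(long_path) && exists("long", inherits = FALSE)) {
    rk <- utils::read.delim(rank_path, stringsAsFactors = FALSE)
    subs <- unique(rk$subtype)
    f <- file.path(run_dir, "ranking_boxplots.png")
    grDevices::png(f, width, height)
    graphics::par(mfrow = c(length(subs), 1), mar = c(5, 4, 2, 1))
    for (s in subs) {
      ord_lines <- rk$cell_line[rk$subtype == s]
      vals <- lapply(ord_lines, function(cl)
        long$rho[long$cell_line == cl & long$subtype == s])
      names(vals) <- ord_lines
      graphics::boxplot(vals, las = 2, cex.axis = 0.5,
                        ylab = "Spearman rho",
                        main = sprintf("Correlation to %s tumors (median-ranked)", s))
    }
    grDevices::dev.off()
    made <- c(made, f)
  } else if (!file.exists(rank_path)) {
    message("render_reports: ranking.tsv missing, skipping boxplots")
  }

  if (length(made) == 0)
    abort_eoc(sprintf("no renderable pipeline outputs found in '%s'", run_dir),
              "eoclines_io_error")
  made
}
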