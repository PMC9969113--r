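#' Consensus clustering over NMF restarts
#'
#' Runs `n_runs` independently initialized NMF fits (restart seeds are derived
#' deterministically as `seed + restart index`), averages their connectivity
#' matrices into a consensus matrix, and attaches the stability metrics:
#' cophenetic coefficient, dispersion, and silhouettes. Final sample labels
#' come from the best-objective restart via [assign_clusters()]; a second
#' label set (`hclust_labels`) comes from cutting the average-linkage
#' dendrogram of `1 - consensus` at `r`, mirroring the ordering of a consensus
#' map, and is the label set the silhouettes are computed on.
#'
#' @param V non-negative expression matrix (genes x samples).
#' @param r factorization rank.
#' @param n_runs number of restarts (the reference analysis uses 200).
#' @param seed master seed.
#' @param ... further arguments to [nmf_fit()].
#' @return an object of class `eoc_consensus` with elements `consensus`,
#'   `cophenetic`, `dispersion`, `silhouettes`, `labels`, `hclust_labels`,
#'   `best_fit` (data matrix dropped), `rss`, `n_runs`, `r`, `seed`.
#' @export
run_consensus <- function(V, r, n_runs = 200L, seed = 1L, ...) {
  if (n_runs < 1) abort_eoc("n_runs must be >= 1", "eoclines_input_error")
  fits <- vector("list", n_runs)
  conns <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    fit <- nmf_fit(V, r, seed = seed + i, keep_data = FALSE, ...)
    conns[[i]] <- connectivity_matrix(suppressWarnings(assign_clusters(fit$H)))
    fits[[i]] <- fit
  }
  consensus <- consensus_matrix(conns)
  dimnames(consensus) <- list(colnames(V), colnames(V))
  best <- which.min(vapply(fits, `[[`, numeric(1), "objective"))
  best_fit <- fits[[best]]
  labels <- suppressWarnings(assign_clusters(best_fit$H))
  names(labels) <- colnames(V)
  hl <- if (nrow(consensus) >= 3 && r >= 2) {
    stats::cutree(stats::hclust(stats::as.dist(1 - consensus), "average"), k = r)
  } else labels
  sil <- if (length(unique(hl)) >= 2) consensus_silhouettes(consensus, hl)
         else rep(NA_real_, ncol(V))
  coph <- if (nrow(consensus) >= 3) cophenetic_coefficient(consensus) else NA_real_
  structure(list(consensus = consensus,
                 cophenetic = coph,
                 dispersion = dispersion(consensus),
                 silhouettes = sil,
                 labels = labels,
                 hclust_labels = hl,
                 best_fit = best_fit,
                 best_run = best,
                 rss = best_fit$rss,
                 n_runs = as.integer(n_runs),
                 r = as.integer(r),
                 seed = seed),
            class = "eoc_consensus")
}

#' @export
print.eoc_consensus <- function(x, ...) {
  cat(sprintf("Consensus NMF clustering: %d samples, rank %d, %d restarts\n",
              nrow(x$consensus), x$r, x$n_runs))
  cat(sprintf("  cophenetic %.4f | dispersion %.4f | mean silhouette %.4f\n",
              x$cophenetic, x$dispersion, mean(x$silhouettes)))
  cat("  cluster sizes:", paste(sprintf("%d:%d", seq_len(x$r), tabulate(x$labels, x$r)),
                                collapse = "  "), "\n")
  invisible(x)
}

#' @export
summary.eoc_consensus <- function(object, ...) {
  out <- list(r = object$r, n_runs = object$n_runs,
              cophenetic = object$cophenetic, dispersion = object$dispersion,
              silhouette_range = range(object$silhouettes),
              cluster_sizes = tabulate(object$labels, object$r))
  class(out) <- "summary.eoc_consensus"
  out
}

#' @export
print.summary.eoc_consensus <- function(x, ...) {
  cat(sprintf("rank %d, %d restarts: cophenetic %.4f, dispersion %.4f, silhouettes in [%.3f, %.3f]\n",
              x$r, x$n_runs, x$cophenetic, x$dispersion,
              x$silhouette_range[1], x$silhouette_range[2]))
  cat("cluster sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Dendrogram leaf order of a consensus matrix
#'
#' Average-linkage clustering on `1 - consensus`; the returned order is shared
#' by the consensus heatmap so map and metrics agree.
#'
#' @param consensus consensus matrix.
#' @return integer permutation of samples.
#' @export
consensus_order <- function(consensus) {
  stats::hclust(stats::as.dist(1 - consensus), method = "average")$order
}

#' @export
plot.eoc_consensus <- function(x, ...) {
  ord <- consensus_order(x$consensus)
  graphics::image(x$consensus[ord, rev(ord)], axes = FALSE,
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  main = sprintf("Consensus map (rank %d, %d runs)", x$r, x$n_runs), ...)
  invisible(x)
}

#' Survey factorization ranks on original and permuted data
#'
#' For every rank in `ranks`, runs [run_consensus()] on `V` and on a
#' column-permuted copy of `V` (one fixed permutation for the whole survey),
#' recording cophenetic coefficient, dispersion, mean silhouette and the
#' best-restart residual sum of squares for both. The permuted arm provides
#' the overfitting null used by [select_rank()].
#'
#' @param V non-negative expression matrix.
#' @param ranks integer vector of ranks to survey (e.g. `2:8`).
#' @param n_runs restarts per rank (the reference analysis uses 50).
#' @param seed master seed; per-rank and per-arm seeds are derived from it.
#' @param ... further arguments to [nmf_fit()].
#' @return an object of class `eoc_rank_survey` whose `table` element has one
#'   row per (rank, data arm) with columns `rank`, `data`
#'   (`original`/`permuted`), `cophenetic`, `dispersion`, `mean_silhouette`,
#'   `rss`.
#' @export
rank_survey <- function(V, ranks = 2:8, n_runs = 50L, seed = 1L, ...) {
  ranks <- sort(as.integer(ranks))
  if (any(ranks < 1) || any(ranks >= min(dim(V))))
    abort_eoc("ranks out of valid bounds for V", "eoclines_input_error")
  Vp <- permute_matrix(V, seed = seed + 104729L)
  rows <- list()
  for (r in ranks) {
    for (arm in c("original", "permuted")) {
      M <- if (arm == "original") V else Vp
      rc <- run_consensus(M, r, n_runs = n_runs,
                          seed = seed + 1000L * r + if (arm == "permuted") 500L else 0L,
                          ...)
      rows[[length(rows) + 1L]] <- data.frame(
        rank = r, data = arm,
        cophenetic = rc$cophenetic, dispersion = rc$dispersion,
        mean_silhouette = mean(rc$silhouettes), rss = rc$rss,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(table = do.call(rbind, rows),
                 ranks = ranks, n_runs = as.integer(n_runs), seed = seed),
            class = "eoc_rank_survey")
}

#' @export
print.eoc_rank_survey <- function(x, ...) {
  cat(sprintf("Rank survey over r = %s (%d restarts per rank)\n",
              paste(range(x$ranks), collapse = ".."), x$n_runs))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.eoc_rank_survey <- function(x, ...) {
  tab <- x$table
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (metric in c("cophenetic", "rss")) {
    o <- tab[tab$data == "original", ]
    p <- tab[tab$data == "permuted", ]
    graphics::plot(o$rank, o[[metric]], type = "b", pch = 16, col = "firebrick",
                   ylim = range(tab[[metric]], na.rm = TRUE),
                   xlab = "factorization rank", ylab = metric, ...)
    graphics::lines(p$rank, p[[metric]], type = "b", pch = 1, col = "grey40")
    graphics::legend("topright", legend = c("original", "permuted"),
                     col = c("firebrick", "grey40"), pch = c(16, 1), bty = "n")
  }
  invisible(x)
}

#' Select the factorization rank from a survey
#'
#' Combines the two published selection criteria into one deterministic rule.
#' The overfitting bound is the smallest rank `r` at which the decrease in
#' residual sum of squares on the original data,
#' `RSS(r - 1) - RSS(r)`, falls below the decrease on permuted data (if never,
#' the bound is `max(ranks) + 1`). Among surveyed ranks strictly below the
#' bound, the rank with the maximal cophenetic coefficient is selected, ties
#' broken toward the larger rank. Both raw curves remain available in the
#' returned object so the rule can be overridden by inspection.
#'
#' @param survey an `eoc_rank_survey` over at least 3 consecutive ranks.
#' @return an object of class `eoc_rank_selection` with `selected_rank`,
#'   `overfit_rank`, `eligible`, `rule` and the survey table.
#' @export
select_rank <- function(survey) {
  stopifnot(inherits(survey, "eoc_rank_survey"))
  ranks <- survey$ranks
  if (length(ranks) < 3 || any(diff(ranks) != 1L))
    abort_eoc("select_rank needs a survey over >= 3 consecutive ranks", "eoclines_input_error")
  tab <- survey$table
  orig <- tab[tab$data == "original", ]
  perm <- tab[tab$data == "permuted", ]
  orig <- orig[order(orig$rank), ]
  perm <- perm[order(perm$rank), ]
  d_orig <- -diff(orig$rss)
  d_perm <- -diff(perm$rss)
  trig <- which(d_orig < d_perm)
  overfit <- if (length(trig)) ranks[trig[1] + 1L] else max(ranks) + 1L
  eligible <- ranks[ranks < overfit]
  if (length(eligible) == 0)
    abort_eoc(paste0("no rank below the overfitting bound; full survey:\n",
                     paste(utils::capture.output(print(tab)), collapse = "\n")),
              "eoclines_selection_error")
  coph <- orig$cophenetic[match(eligible, orig$rank)]
  best <- eligible[coph == max(coph)]
  selected <- max(best)
  structure(list(selected_rank = selected,
                 overfit_rank = overfit,
                 eligible = eligible,
                 rule = "max cophenetic below first rank where dRSS(original) < dRSS(permuted); ties to larger rank",
                 table = tab),
            class = "eoc_rank_selection")
}

#' @export
print.eoc_rank_selection <- function(x, ...) {
  cat(sprintf("Selected factorization rank: %d\n", x$selected_rank))
  cat(sprintf("  overfitting bound at rank %s; eligible ranks: %s\n",
              x$overfit_rank, paste(x$eligible, collapse = ", ")))
  cat(sprintf("  rule: %s\n", x$rule))
  invisible(x)
}
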