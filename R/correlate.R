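#' Spearman correlation matrix between cell lines and tumors
#'
#' Both matrices are restricted to `gene_set` in a common order; for every
#' (line, tumor) pair the profiles are ranked with average tie handling and
#' the Pearson correlation of the ranks is taken. Zero-variance profiles give
#' `NA` with a warning.
#'
#' @param lines_expr expression matrix, genes x cell lines.
#' @param tumors_expr expression matrix, genes x tumors.
#' @param gene_set genes to correlate over (>= 3); defaults to the
#'   intersection of rownames.
#' @return matrix of Spearman coefficients, cell lines x tumors.
#' @export
spearman_matrix <- function(lines_expr, tumors_expr,
                            gene_set = intersect(rownames(lines_expr), rownames(tumors_expr))) {
  if (length(gene_set) < 3)
    abort_eoc("gene_set must contain at least 3 genes", "eoclines_input_error")
  missing_l <- setdiff(gene_set, rownames(lines_expr))
  missing_t <- setdiff(gene_set, rownames(tumors_expr))
  if (length(missing_l) || length(missing_t))
    abort_eoc("gene_set contains genes absent from the expression matrices", "eoclines_input_error")
  L <- lines_expr[gene_set, , drop = FALSE]
  Tm <- tumors_expr[gene_set, , drop = FALSE]
  rho <- suppressWarnings(stats::cor(L, Tm, method = "spearman"))
  if (anyNA(rho)) {
    flat <- unique(c(colnames(L)[apply(L, 2, stats::sd) == 0],
                     colnames(Tm)[apply(Tm, 2, stats::sd) == 0]))
    warning(sprintf("spearman_matrix: zero-variance profile(s) gave NA: %s",
                    paste(flat, collapse = ", ")))
  }
  rho
}

#' Rank cell lines by correlation to tumors of one subtype
#'
#' The chosen statistic (median by default) is taken over the subtype's tumor
#' columns for each line and lines are ordered by decreasing value; exact ties
#' are broken lexicographically by id (with a message).
#'
#' @param corr cell-line-by-tumor correlation matrix (see
#'   [spearman_matrix()]).
#' @param tumor_subtypes subtype per tumor, named by tumor id or aligned to
#'   the columns of `corr`.
#' @param subtype tumor subtype to rank against.
#' @param statistic `"median"` or `"mean"`.
#' @return an object of class `eoc_ranking`: data frame with `cell_line`,
#'   `value`, `rank`, `subtype`, `statistic`.
#' @export
rank_by_correlation <- function(corr, tumor_subtypes, subtype,
                                statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  if (!is.null(names(tumor_subtypes)))
    tumor_subtypes <- tumor_subtypes[colnames(corr)]
  if (length(tumor_subtypes) != ncol(corr))
    abort_eoc("tumor_subtypes must cover every tumor column", "eoclines_input_error")
  cols <- which(tumor_subtypes == subtype)
  if (length(cols) == 0)
    abort_eoc(sprintf("no tumors of subtype '%s'", subtype), "eoclines_input_error")
  fun <- if (statistic == "median") stats::median else mean
  vals <- apply(corr[, cols, drop = FALSE], 1, fun)
  if (anyDuplicated(vals))
    message("rank_by_correlation: tied statistics broken lexicographically by id")
  ord <- order(-vals, rownames(corr))
  out <- data.frame(cell_line = rownames(corr)[ord],
                    value = unname(vals[ord]),
                    rank = seq_along(ord),
                    subtype = subtype,
                    statistic = statistic,
                    stringsAsFactors = FALSE)
  class(out) <- c("eoc_ranking", "data.frame")
  out
}

#' Compare two suitability rankings
#'
#' Spearman correlation of the rank positions over the common items, with a
#' two-sided p-value from the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}}.
#'
#' @param rank_a,rank_b orderings: character vectors of ids (best first) or
#'   `eoc_ranking` objects.
#' @return list with `rho`, `p_value` and `n` (common items, >= 5 required).
#' @export
compare_rankings <- function(rank_a, rank_b) {
  ids_a <- if (inherits(rank_a, "data.frame")) rank_a$cell_line else as.character(rank_a)
  ids_b <- if (inherits(rank_b, "data.frame")) rank_b$cell_line else as.character(rank_b)
  common <- intersect(ids_a, ids_b)
  n <- length(common)
  if (n < 5)
    abort_eoc(sprintf("rankings share only %d item(s); need at least 5", n),
              "eoclines_input_error")
  pos_a <- match(common, ids_a)
  pos_b <- match(common, ids_b)
  rho <- stats::cor(pos_a, pos_b, method = "spearman")
  p <- if (abs(rho) >= 1) 0 else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Flag cell lines for recommendation or avoidance
#'
#' A deterministic rule engine over the correlation matrix and the subtype
#' assignment, with every threshold exposed:
#' \describe{
#'   \item{rule i (`avoid`)}{overall median correlation (across all tumors)
#'     strictly below the `q_low` quantile of all lines' overall medians.}
#'   \item{rule ii (`avoid`)}{assigned a subtype with tumor data but not
#'     within the `top_n` median-correlation ranking for that subtype.}
#'   \item{rule iii (`ambiguous`)}{within the `top_k` ranking for at least 3
#'     tumor subtypes.}
#'   \item{rule iv (`potential_LGSOC`)}{assigned to a subtype lacking tumor
#'     data and not caught by rule iii.}
#' }
#' Rules are checked in that order; the first hit is the primary flag, and
#' lines with no hit are `recommended` for their assigned subtype. All
#' triggered rules are recorded.
#'
#' @param corr cell-line-by-tumor Spearman matrix.
#' @param tumor_subtypes subtype per tumor column.
#' @param assignment subtype per line (an `eoc_subtype_assignment` or a data
#'   frame with `sample_id`, `subtype`).
#' @param q_low quantile of overall medians below which a line is avoided.
#' @param top_n rank cutoff for rule ii.
#' @param top_k rank cutoff for rule iii.
#' @return an object of class `eoc_recommendations`: one row per line with
#'   the per-subtype medians, overall median, primary `flag`,
#'   `recommended_for` and the triggering `rules`.
#' @export
recommend_lines <- function(corr, tumor_subtypes, assignment,
                            q_low = 0.25, top_n = 20L, top_k = 10L) {
  if (q_low < 0 || q_low > 1 || top_n < 1 || top_k < 1)
    abort_eoc("invalid thresholds", "eoclines_input_error")
  sub <- stats::setNames(assignment$subtype, assignment$sample_id)
  lines <- rownames(corr)
  if (any(!lines %in% names(sub)))
    abort_eoc("assignment does not cover all lines in corr", "eoclines_input_error")
  sub <- sub[lines]
  if (!is.null(names(tumor_subtypes)))
    tumor_subtypes <- tumor_subtypes[colnames(corr)]
  tumor_sub_levels <- unique(tumor_subtypes)

  overall <- apply(corr, 1, stats::median)
  cutoff <- stats::quantile(overall, q_low, type = 7, names = FALSE)
  pos <- sapply(tumor_sub_levels, function(s) {
    rk <- rank_by_correlation(corr, tumor_subtypes, s, "median")
    match(lines, rk$cell_line)
  })
  med <- sapply(tumor_sub_levels, function(s) {
    apply(corr[, tumor_subtypes == s, drop = FALSE], 1, stats::median)
  })

  flag <- character(length(lines))
  rec_for <- rep(NA_character_, length(lines))
  rules <- character(length(lines))
  for (i in seq_along(lines)) {
    hits <- character(0)
    if (overall[i] < cutoff) hits <- c(hits, "i")
    if (sub[i] %in% tumor_sub_levels && pos[i, sub[i]] > top_n) hits <- c(hits, "ii")
    n_top <- sum(pos[i, ] <= top_k)
    if (n_top >= 3) hits <- c(hits, "iii")
    if (!sub[i] %in% c(tumor_sub_levels, "unassigned") && !("iii" %in% hits))
      hits <- c(hits, "iv")
    flag[i] <- if ("i" %in% hits || "ii" %in% hits) "avoid"
               else if ("iii" %in% hits) "ambiguous"
               else if ("iv" %in% hits) "potential_LGSOC"
               else "recommended"
    if (flag[i] == "recommended") rec_for[i] <- sub[i]
    rules[i] <- paste(hits, collapse = ",")
  }
  out <- data.frame(cell_line = lines, subtype = unname(sub),
                    overall_median = unname(overall),
                    stringsAsFactors = FALSE)
  for (s in tumor_sub_levels) out[[paste0("median_", s)]] <- unname(med[, s])
  out$flag <- flag
  out$recommended_for <- rec_for
  out$rules <- rules
  class(out) <- c("eoc_recommendations", "data.frame")
  out
}
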