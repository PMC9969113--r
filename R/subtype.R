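eoc_subtypes <- c("HGSOC", "CCOC", "ENOC", "MOC", "LGSOC")

#' Characteristic alteration gene panel per EOC subtype
#'
#' Loads the bundled subtype-to-gene-set panel (near-ubiquitous TP53 and
#' BRCA1/2 in HGSOC, ARID1A/PIK3CA in CCOC and ENOC, KRAS/NRAS-driven MOC and
#' LGSOC, ...). Any named list of character vectors with the same shape can be
#' supplied to the functions that consume it.
#'
#' @param path optional path to a YAML panel overriding the bundled one.
#' @return named list: subtype -> character vector of gene symbols.
#' @export
default_gene_panel <- function(path = NULL) {
  path <- path %||% system.file("extdata", "gene_panel.yaml", package = "eoclines")
  panel <- yaml::read_yaml(path)
  if (any(lengths(panel) == 0))
    abort_eoc("gene panel has an empty subtype set", "eoclines_input_error")
  lapply(panel, as.character)
}

#' Map consensus clusters to named subtypes by annotation vote
#'
#' Each cluster receives the majority subtype among its annotated members
#' (annotations valued `"unknown"` or `NA` do not vote). Ties, or clusters with
#' no annotated member, become `"unassigned"`. Two clusters may not share a
#' subtype: on collision the cluster with the higher vote fraction keeps it
#' and the other is unassigned, with a warning.
#'
#' @param labels integer cluster labels named by sample id (e.g. from
#'   [run_consensus()]).
#' @param annotations data frame with columns `sample_id` and `subtype`
#'   (multiple rows per sample allowed, e.g. one per literature source).
#' @param subtypes the admissible subtype vocabulary.
#' @return an object of class `eoc_subtype_assignment`: a data frame with one
#'   row per sample (`sample_id`, `cluster`, `subtype`, `votes`,
#'   `confidence`), plus a `clusters` attribute summarizing the per-cluster
#'   vote.
#' @export
map_clusters_to_subtypes <- function(labels, annotations,
                                     subtypes = eoc_subtypes) {
  if (is.null(names(labels)))
    abort_eoc("labels must be named by sample id", "eoclines_input_error")
  if (!all(c("sample_id", "subtype") %in% names(annotations)))
    abort_eoc("annotations need sample_id and subtype columns", "eoclines_input_error")
  unknown_ids <- setdiff(annotations$sample_id, names(labels))
  if (length(unknown_ids))
    abort_eoc(sprintf("annotation sample id(s) absent from labels: %s",
                      paste(utils::head(unknown_ids, 5), collapse = ", ")),
              "eoclines_input_error")
  bad <- setdiff(stats::na.omit(unique(annotations$subtype)), c(subtypes, "unknown"))
  if (length(bad))
    abort_eoc(sprintf("annotation subtype(s) outside vocabulary: %s",
                      paste(bad, collapse = ", ")),
              "eoclines_input_error")

  ann <- annotations[!is.na(annotations$subtype) & annotations$subtype != "unknown", ]
  clusters <- sort(unique(labels))
  cl_sub <- stats::setNames(rep("unassigned", length(clusters)), clusters)
  cl_conf <- stats::setNames(rep(NA_real_, length(clusters)), clusters)
  cl_votes <- stats::setNames(rep(0L, length(clusters)), clusters)
  for (cl in clusters) {
    members <- names(labels)[labels == cl]
    votes <- table(ann$subtype[ann$sample_id %in% members])
    cl_votes[as.character(cl)] <- sum(votes)
    if (length(votes) == 0) next
    top <- votes[votes == max(votes)]
    if (length(top) > 1) next # tie -> unassigned
    cl_sub[as.character(cl)] <- names(top)
    cl_conf[as.character(cl)] <- max(votes) / sum(votes)
  }
  # resolve subtype collisions: the higher vote fraction keeps the label
  for (s in unique(cl_sub[cl_sub != "unassigned"])) {
    claimants <- names(cl_sub)[cl_sub == s]
    if (length(claimants) <= 1) next
    conf <- cl_conf[claimants]
    keep <- claimants[conf == max(conf)]
    if (length(keep) > 1) keep <- character(0) # equal fractions: nobody keeps it
    drop <- setdiff(claimants, keep)
    cl_sub[drop] <- "unassigned"
    cl_conf[drop] <- NA_real_
    warning(sprintf("map_clusters_to_subtypes: clusters %s all voted %s; %s",
                    paste(claimants, collapse = ", "), s,
                    if (length(keep)) sprintf("cluster %s keeps it", keep)
                    else "tied vote fractions, all unassigned"))
  }
  out <- data.frame(sample_id = names(labels),
                    cluster = as.integer(labels),
                    subtype = unname(cl_sub[as.character(labels)]),
                    votes = unname(cl_votes[as.character(labels)]),
                    confidence = unname(cl_conf[as.character(labels)]),
                    stringsAsFactors = FALSE)
  attr(out, "clusters") <- data.frame(cluster = as.integer(names(cl_sub)),
                                      subtype = unname(cl_sub),
                                      votes = unname(cl_votes),
                                      confidence = unname(cl_conf),
                                      stringsAsFactors = FALSE)
  class(out) <- c("eoc_subtype_assignment", "data.frame")
  out
}

#' Per-subtype alteration frequencies over a gene panel
#'
#' Frequency is `altered / (altered + wild_type)` within each inferred
#' subtype; `missing` statuses are excluded from the denominator, and an empty
#' denominator yields `NA` (never imputed).
#'
#' @param mutations data frame with columns `cell_line`, `gene`, `status`
#'   (`altered`, `wild_type` or `missing`).
#' @param assignment an `eoc_subtype_assignment` (or data frame with
#'   `sample_id` and `subtype`).
#' @return data frame with one row per (subtype, gene): counts and `frequency`.
#' @export
alteration_frequency <- function(mutations, assignment) {
  if (!all(c("cell_line", "gene", "status") %in% names(mutations)))
    abort_eoc("mutations need cell_line, gene, status columns", "eoclines_input_error")
  if (!all(mutations$status %in% c("altered", "wild_type", "missing")))
    abort_eoc("status must be altered/wild_type/missing", "eoclines_input_error")
  sub <- stats::setNames(assignment$subtype, assignment$sample_id)
  if (any(!mutations$cell_line %in% names(sub)))
    abort_eoc("assignment does not cover all mutation-table lines", "eoclines_input_error")
  mutations$subtype <- unname(sub[mutations$cell_line])
  grid <- expand.grid(subtype = unique(mutations$subtype),
                      gene = unique(mutations$gene),
                      stringsAsFactors = FALSE)
  grid$n_altered <- grid$n_wild_type <- grid$n_missing <- 0L
  for (k in seq_len(nrow(grid))) {
    st <- mutations$status[mutations$subtype == grid$subtype[k] & mutations$gene == grid$gene[k]]
    grid$n_altered[k] <- sum(st == "altered")
    grid$n_wild_type[k] <- sum(st == "wild_type")
    grid$n_missing[k] <- sum(st == "missing")
  }
  denom <- grid$n_altered + grid$n_wild_type
  grid$frequency <- ifelse(denom > 0, grid$n_altered / denom, NA_real_)
  grid[order(grid$subtype, grid$gene), ]
}

#' Concordance of a line's alterations with its inferred subtype
#'
#' The fraction of the line's observed altered genes that belong to the
#' inferred subtype's characteristic gene set; `NA` when no alteration was
#' observed.
#'
#' @param altered_genes character vector of genes altered in the line.
#' @param subtype the inferred subtype.
#' @param panel subtype gene panel (see [default_gene_panel()]).
#' @return a scalar in \[0, 1\], or NA.
#' @export
concordance_score <- function(altered_genes, subtype, panel = default_gene_panel()) {
  if (!subtype %in% names(panel))
    abort_eoc(sprintf("unknown subtype '%s' (panel covers %s)", subtype,
                      paste(names(panel), collapse = ", ")),
              "eoclines_input_error")
  if (length(altered_genes) == 0) return(NA_real_)
  mean(altered_genes %in% panel[[subtype]])
}
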