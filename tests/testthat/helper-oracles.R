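# Independent brute-force oracles and small fixture builders shared by the
# tests. These deliberately avoid the package's own code paths (and stats::
# shortcuts the package uses) so that oracle-vs-implementation checks are
# genuinely dual-route.

# naive UPGMA (average linkage) cophenetic distances from a full distance
# matrix, by explicit agglomeration over original pairwise distances
bf_cophenetic_matrix <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        d_ij <- mean(D[clusters[[i]], clusters[[j]]])
        if (d_ij < best_d) {
          best_d <- d_ij
          best <- c(i, j)
        }
      }
    }
    a <- clusters[[best[1]]]
    b <- clusters[[best[2]]]
    coph[a, b] <- best_d
    coph[b, a] <- best_d
    clusters[[best[2]]] <- c(a, b)
    clusters[[best[1]]] <- NULL
  }
  coph
}

bf_cophenetic_coefficient <- function(consensus) {
  D <- 1 - consensus
  coph <- bf_cophenetic_matrix(D)
  ut <- upper.tri(D)
  x <- D[ut]
  y <- coph[ut]
  # Pearson by the definition formula
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# textbook silhouette on a precomputed distance matrix
bf_silhouette <- function(D, labels) {
  n <- nrow(D)
  out <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(labels == labels[i])
    if (length(same) == 1) {
      out[i] <- 0
      next
    }
    a <- mean(D[i, setdiff(same, i)])
    b <- Inf
    for (l in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(D[i, which(labels == l)]))
    out[i] <- (b - a) / max(a, b)
  }
  out
}

# Spearman rho of two vectors: average ranks, then the Pearson formula
bf_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# small 3-subtype config so unit tests stay fast; 2 batches (not 3) so that
# the round-robin batch and subtype assignments are not confounded at k = 3
tiny_cfg <- function(seed = 42L, ...) {
  args <- list(n_genes = 300L, k_subtypes = 3L,
               subtype_names = c("HGSOC", "CCOC", "MOC"),
               n_cell_lines = 18L,
               n_tumors_per_subtype = c(HGSOC = 6L, CCOC = 5L, MOC = 4L),
               n_sig_genes_per_subtype = 25L,
               n_batches_cell_lines = 2L, n_batches_tumors = 2L,
               rng_seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# VST + batch-corrected, MAD-filtered expression for a cell-line panel
nmf_input <- function(lines, threshold = 0.65, min_genes = 50L) {
  adj <- suppressWarnings(
    combat_adjust(vst_transform(lines$counts), lines$metadata$batch))
  adj <- pmax(adj, 0)
  filt <- mad_filter(adj, threshold)
  kept <- filt$kept_genes
  if (length(kept) < min_genes)
    kept <- names(sort(filt$mad_values, decreasing = TRUE))[seq_len(min_genes)]
  adj[kept, , drop = FALSE]
}
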