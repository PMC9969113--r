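#' Random uniform initialization for NMF
#'
#' Entries of the initial basis and coefficient matrices are drawn uniformly
#' on the range of the input matrix, `[max(eps, min(V)), max(V)]`, with
#' `eps = 1e-6` guarding all-zero inputs.
#'
#' @param V non-negative numeric matrix (genes x samples).
#' @param r factorization rank.
#' @param seed optional integer seed for reproducible draws.
#' @return a list with matrices `W` (genes x r) and `H` (r x samples).
#' @export
nmf_init <- function(V, r, seed = NULL) {
  if (any(V < 0)) abort_eoc("V must be non-negative", "eoclines_input_error")
  if (r < 1) abort_eoc("rank must be >= 1", "eoclines_input_error")
  lo <- max(1e-6, min(V))
  hi <- max(V)
  with_seed(seed, {
    W <- matrix(stats::runif(nrow(V) * r, lo, hi), nrow(V), r)
    H <- matrix(stats::runif(r * ncol(V), lo, hi), r, ncol(V))
    list(W = W, H = H)
  })
}

#' Fit a single NMF by multiplicative updates
#'
#' Factorizes a non-negative matrix `V` as `W %*% H` with all factors
#' non-negative. The default objective is the (generalized) Kullback-Leibler
#' divergence \eqn{\sum V \log(V / WH) - V + WH}, minimized by the classic
#' multiplicative updates
#' \deqn{H \leftarrow H \odot \frac{W^T (V \oslash WH)}{W^T 1}, \quad
#'       W \leftarrow W \odot \frac{(V \oslash WH) H^T}{1 H^T},}
#' which never increase the objective. A Frobenius (squared-error) objective
#' with the matching Lee-Seung updates is available behind `method =
#' "frobenius"`. Zeros in `V` are floored at `eps` inside the KL updates only;
#' the reported residuals use the original `V`.
#'
#' Iteration stops at `max_iter`, or earlier once the relative objective
#' change stays below `tol` for 10 consecutive checks (one check every
#' `check_every` iterations).
#'
#' @param V non-negative matrix (genes x samples); rank must satisfy
#'   `r < min(dim(V))`.
#' @param r factorization rank.
#' @param seed integer seed for the random initialization (see [nmf_init()]).
#' @param max_iter iteration cap.
#' @param tol relative objective-change tolerance.
#' @param method `"kl"` (default) or `"frobenius"`.
#' @param eps flooring value for zeros of `V` in the KL objective.
#' @param check_every objective evaluation interval, in iterations.
#' @param init optional list with `W` and `H` starting values, overriding the
#'   random initialization.
#' @param keep_data store `V` in the fit (needed by [residuals.eoc_nmf()]).
#' @return an object of class `eoc_nmf`: factors `W` and `H`, the objective
#'   trace (one value per check), the Frobenius residual sum of squares `rss`,
#'   iteration count, convergence flag, seed and method.
#' @seealso [run_consensus()] for multi-restart consensus clustering.
#' @export
nmf_fit <- function(V, r, seed = NULL, max_iter = 2000L, tol = 1e-6,
                    method = c("kl", "frobenius"), eps = 1e-6,
                    check_every = 10L, init = NULL, keep_data = TRUE) {
  method <- match.arg(method)
  V <- as.matrix(V)
  if (any(V < 0)) abort_eoc("V must be non-negative", "eoclines_input_error")
  if (r < 1 || r >= min(dim(V)))
    abort_eoc(sprintf("rank %d out of range for a %d x %d matrix", r, nrow(V), ncol(V)),
              "eoclines_input_error")
  if (is.null(init)) init <- nmf_init(V, r, seed)
  W <- init$W
  H <- init$H
  Vw <- V
  if (method == "kl") Vw[Vw == 0] <- eps
  tiny <- 1e-300

  kl_obj <- function(WH) sum(Vw * log(Vw / WH)) - sum(Vw) + sum(WH)
  fr_obj <- function(WH) sum((Vw - WH)^2)

  trace <- numeric(0)
  trace_iter <- integer(0)
  consec <- 0L
  prev <- Inf
  n_iter <- max_iter
  converged <- FALSE

  WH <- pmax(W %*% H, tiny)
  for (t in seq_len(max_iter)) {
    if (method == "kl") {
      H <- H * crossprod(W, Vw / WH) / pmax(colSums(W), tiny)
      WH <- pmax(W %*% H, tiny)
      W <- W * sweep((Vw / WH) %*% t(H), 2, pmax(rowSums(H), tiny), "/")
      WH <- pmax(W %*% H, tiny)
    } else {
      H <- H * crossprod(W, Vw) / pmax(crossprod(W, W %*% H), tiny)
      W <- W * (Vw %*% t(H)) / pmax(W %*% tcrossprod(H, H), tiny)
      WH <- pmax(W %*% H, tiny)
    }
    if (any(!is.finite(H)) || any(!is.finite(W)))
      abort_eoc("NMF updates diverged to non-finite values; check for all-zero rows/columns and increase eps",
                "eoclines_numeric_error")
    if (t %% check_every == 0L || t == max_iter) {
      obj <- if (method == "kl") kl_obj(WH) else fr_obj(WH)
      trace <- c(trace, obj)
      trace_iter <- c(trace_iter, t)
      rel <- (prev - obj) / max(abs(prev), .Machine$double.eps)
      if (is.finite(rel) && abs(rel) < tol) consec <- consec + 1L else consec <- 0L
      prev <- obj
      if (consec >= 10L) {
        n_iter <- t
        converged <- TRUE
        break
      }
    }
  }

  dimnames(W) <- list(rownames(V), sprintf("M%d", seq_len(r)))
  dimnames(H) <- list(sprintf("M%d", seq_len(r)), colnames(V))
  fit <- structure(list(W = W, H = H, r = as.integer(r),
                        objective_trace = trace, trace_iterations = trace_iter,
                        objective = trace[length(trace)],
                        rss = sum((V - W %*% H)^2),
                        n_iter = n_iter, converged = converged,
                        seed = seed, method = method, eps = eps,
                        dims = dim(V),
                        sample_ids = colnames(V), gene_ids = rownames(V)),
                   class = "eoc_nmf")
  if (keep_data) fit$V <- V
  fit
}

#' Frobenius residual sum of squares of a factorization
#'
#' `sum((V - W H)^2)`, reported on the original data regardless of the
#' optimization objective.
#'
#' @param V the data matrix the fit approximates.
#' @param W,H factor matrices, or pass an `eoc_nmf` fit as `W`.
#' @return a scalar.
#' @export
nmf_rss <- function(V, W, H = NULL) {
  if (inherits(W, "eoc_nmf")) {
    H <- W$H
    W <- W$W
  }
  if (!all(dim(V) == c(nrow(W), ncol(H))))
    abort_eoc("dimension mismatch between V and W %*% H", "eoclines_input_error")
  sum((V - W %*% H)^2)
}

#' @export
print.eoc_nmf <- function(x, ...) {
  cat(sprintf("NMF fit (%s objective): %d x %d matrix at rank %d\n",
              x$method, x$dims[1], x$dims[2], x$r))
  cat(sprintf("  objective %.6g after %d iterations (%s); RSS %.6g\n",
              x$objective, x$n_iter,
              if (x$converged) "converged" else "iteration cap", x$rss))
  invisible(x)
}

#' @export
fitted.eoc_nmf <- function(object, ...) object$W %*% object$H

#' @export
residuals.eoc_nmf <- function(object, V = object$V, ...) {
  if (is.null(V))
    abort_eoc("fit was built with keep_data = FALSE; supply V", "eoclines_input_error")
  V - fitted(object)
}

#' @export
coef.eoc_nmf <- function(object, ...) object$H

#' Basis (metagene) matrix of an NMF fit
#' @param object an `eoc_nmf` fit.
#' @return the genes-by-rank basis matrix `W`.
#' @export
basis <- function(object) {
  stopifnot(inherits(object, "eoc_nmf"))
  object$W
}

#' @export
plot.eoc_nmf <- function(x, ...) {
  graphics::plot(x$trace_iterations, x$objective_trace, type = "b", pch = 16,
                 xlab = "iteration", ylab = sprintf("%s objective", x$method),
                 main = sprintf("NMF convergence (rank %d)", x$r), ...)
  invisible(x)
}

#' Assign samples to clusters by maximum coefficient
#'
#' Each sample is assigned to the metagene with the largest coefficient in its
#' column of `H`. Exact ties go to the lowest cluster index with a warning.
#'
#' @param H non-negative coefficient matrix (rank x samples) or an `eoc_nmf`
#'   fit.
#' @return an integer vector of cluster labels in `1..r`, named by sample.
#' @export
assign_clusters <- function(H) {
  if (inherits(H, "eoc_nmf")) H <- H$H
  if (any(H < 0)) abort_eoc("H must be non-negative", "eoclines_input_error")
  labels <- integer(ncol(H))
  tied <- logical(ncol(H))
  for (j in seq_len(ncol(H))) {
    labels[j] <- which.max(H[, j])
    tied[j] <- sum(H[, j] == max(H[, j])) > 1L
  }
  if (any(tied))
    warning(sprintf("assign_clusters: tie(s) broken toward the lowest cluster index for sample(s) %s",
                    paste(colnames(H)[tied] %||% which(tied), collapse = ", ")))
  names(labels) <- colnames(H)
  labels
}

#' Connectivity matrix of one clustering
#'
#' Binary samples-by-samples matrix with entry 1 iff the two samples share a
#' label; symmetric with unit diagonal.
#'
#' @param labels cluster labels, one per sample.
#' @return a 0/1 matrix.
#' @export
connectivity_matrix <- function(labels) {
  C <- outer(labels, labels, "==") * 1
  dimnames(C) <- list(names(labels), names(labels))
  C
}

#' Consensus matrix over NMF restarts
#'
#' Entry-wise mean of per-run connectivity matrices; entries estimate the
#' probability that two samples co-cluster.
#'
#' @param connectivities list of equally-sized connectivity matrices.
#' @return a symmetric matrix with entries in \[0, 1\] and unit diagonal.
#' @export
consensus_matrix <- function(connectivities) {
  if (length(connectivities) < 1)
    abort_eoc("need at least one connectivity matrix", "eoclines_input_error")
  d <- dim(connectivities[[1]])
  if (!all(vapply(connectivities, function(m) all(dim(m) == d), logical(1))))
    abort_eoc("connectivity matrices differ in shape", "eoclines_input_error")
  Reduce(`+`, connectivities) / length(connectivities)
}

#' Cophenetic correlation coefficient of a consensus matrix
#'
#' Average-linkage hierarchical clustering is run on the distance
#' `1 - consensus`; the coefficient is the Pearson correlation between the
#' original distances and the cophenetic distances of the resulting
#' dendrogram. Values near 1 indicate the consensus is faithfully
#' hierarchical, i.e. the clustering is robust at this rank.
#'
#' @param consensus symmetric consensus matrix with unit diagonal.
#' @return a scalar in \[-1, 1\] (NA if all distances are equal).
#' @export
cophenetic_coefficient <- function(consensus) {
  if (nrow(consensus) < 3)
    abort_eoc("cophenetic coefficient needs at least 3 samples", "eoclines_input_error")
  d <- stats::as.dist(1 - consensus)
  hc <- stats::hclust(d, method = "average")
  cp <- stats::cophenetic(hc)
  if (stats::sd(d) == 0 || stats::sd(cp) == 0) return(NA_real_)
  stats::cor(c(d), c(cp))
}

#' Dispersion of a consensus matrix
#'
#' \eqn{(1/m^2) \sum_{ij} 4 (c_{ij} - 1/2)^2}: 1 for a perfectly binary
#' (reproducible) consensus, approaching 0 for a maximally scattered one.
#'
#' @param consensus consensus matrix.
#' @return a scalar in \[0, 1\].
#' @export
dispersion <- function(consensus) {
  mean(4 * (consensus - 0.5)^2)
}

#' Silhouette scores on consensus distances
#'
#' Standard silhouettes `s = (b - a) / max(a, b)` computed on the distance
#' `1 - consensus`, where `a` is the mean distance to the sample's own cluster
#' and `b` the smallest mean distance to any other cluster. Samples in
#' singleton clusters score 0 by convention.
#'
#' @param consensus consensus matrix.
#' @param labels cluster labels (at least 2 distinct).
#' @return numeric vector of per-sample scores in \[-1, 1\].
#' @export
consensus_silhouettes <- function(consensus, labels) {
  m <- nrow(consensus)
  if (length(labels) != m)
    abort_eoc("labels must match consensus dimension", "eoclines_input_error")
  if (length(unique(labels)) < 2)
    abort_eoc("silhouettes need at least 2 clusters", "eoclines_input_error")
  D <- 1 - consensus
  sizes <- table(labels)
  scores <- numeric(m)
  for (i in seq_len(m)) {
    li <- as.character(labels[i])
    if (sizes[[li]] == 1L) {
      scores[i] <- 0
      next
    }
    own <- which(labels == labels[i])
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    scores[i] <- (b - a) / max(a, b)
  }
  names(scores) <- rownames(consensus)
  scores
}

#' Permute a matrix column-wise
#'
#' Independently permutes the entries within each column, preserving every
#' column's multiset of values while destroying gene-wise structure. Used to
#' build the permutation null for rank selection.
#'
#' @param V matrix.
#' @param seed integer seed.
#' @return the permuted matrix.
#' @export
permute_matrix <- function(V, seed = NULL) {
  with_seed(seed, {
    out <- apply(V, 2, function(x) x[sample.int(length(x))])
    dimnames(out) <- dimnames(V)
    out
  })
}
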