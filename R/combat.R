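#' Parametric empirical-Bayes batch correction
#'
#' Location/scale batch adjustment in the parametric empirical-Bayes framework:
#' each gene is standardized against its pooled grand mean and variance, batch
#' location parameters are shrunk toward a normal prior and batch scale
#' parameters toward an inverse-gamma prior (hyperparameters moment-matched
#' across genes within each batch), the posterior estimates are found by the
#' standard fixed-point iteration, and the standardized data are adjusted and
#' de-standardized. No covariates are modeled, only batch.
#'
#' With a single batch the data are returned unchanged. Zero-variance genes
#' cannot be standardized and are passed through unadjusted with a warning.
#'
#' @param expr expression matrix (genes x samples).
#' @param batch batch label per sample; every non-trivial batch needs at least
#'   2 samples.
#' @param eb_tol relative convergence tolerance of the EB fixed-point
#'   iteration.
#' @param max_iter iteration cap per batch.
#' @return the adjusted matrix, with `"combat"` appended to its transform
#'   chain.
#' @export
combat_adjust <- function(expr, batch, eb_tol = 1e-6, max_iter = 5000L) {
  X <- as.matrix(expr)
  if (length(batch) != ncol(X))
    abort_eoc("length(batch) must equal ncol(expr)", "eoclines_input_error")
  if (any(is.na(batch)))
    abort_eoc("batch labels must cover all samples", "eoclines_input_error")
  batch <- factor(batch)
  if (nlevels(batch) == 1) {
    message("combat_adjust: single batch, nothing to adjust")
    return(add_transform(X, "combat", from = expr))
  }
  tab <- table(batch)
  if (any(tab < 2))
    abort_eoc(sprintf("singleton batch(es) with no variance estimate: %s",
                      paste(names(tab)[tab < 2], collapse = ", ")),
              "eoclines_input_error")
  n_array <- ncol(X)
  bi <- as.integer(batch)
  nb <- nlevels(batch)

  batch_means <- vapply(seq_len(nb),
                        function(b) rowMeans(X[, bi == b, drop = FALSE]),
                        numeric(nrow(X)))
  grand <- drop(batch_means %*% (as.numeric(tab) / n_array))
  var_pooled <- rowSums((X - batch_means[, bi, drop = FALSE])^2) / n_array

  zero_var <- var_pooled <= .Machine$double.eps
  if (any(zero_var))
    warning(sprintf("combat_adjust: %d zero-variance gene(s) passed through unadjusted",
                    sum(zero_var)))
  s <- sqrt(var_pooled)
  s[zero_var] <- 1

  Z <- (X - grand) / s
  gamma_star <- matrix(0, nrow(X), nb)
  delta_star <- matrix(1, nrow(X), nb)
  for (b in seq_len(nb)) {
    Zb <- Z[, bi == b, drop = FALSE]
    n_b <- ncol(Zb)
    g_hat <- rowMeans(Zb)
    d_hat <- rowVars(Zb)
    g_bar <- mean(g_hat)
    t2 <- stats::var(g_hat)
    m <- mean(d_hat)
    s2 <- stats::var(d_hat)
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    g_old <- g_hat
    d_old <- d_hat
    for (it in seq_len(max_iter)) {
      g_new <- (n_b * t2 * g_hat + d_old * g_bar) / (n_b * t2 + d_old)
      sum2 <- rowSums((Zb - g_new)^2)
      d_new <- (b_prior + 0.5 * sum2) / (n_b / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                    abs(d_new - d_old) / pmax(d_old, 1e-12))
      g_old <- g_new
      d_old <- d_new
      if (change < eb_tol) break
    }
    gamma_star[, b] <- g_old
    delta_star[, b] <- d_old
  }

  adj <- (Z - gamma_star[, bi, drop = FALSE]) / sqrt(delta_star[, bi, drop = FALSE])
  out <- adj * s + grand
  out[zero_var, ] <- X[zero_var, , drop = FALSE]
  dimnames(out) <- dimnames(X)
  add_transform(out, "combat", from = expr)
}
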