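make_counts <- function(x, genes = NULL, samples = NULL) {
  m <- as.matrix(x)
  dimnames(m) <- list(genes %||% sprintf("G%d", seq_len(nrow(m))),
                      samples %||% sprintf("S%d", seq_len(ncol(m))))
  storage.mode(m) <- "integer"
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the TSV reader rejects negative and non-integer entries by name", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "counts.tsv")
  writeLines(c("gene_id\tS1\tS2", "G1\t1\t2", "G2\t-3\t4"), f)
  expect_error(read_counts(f), "G2.*S1", class = "eoclines_input_error")
  writeLines(c("gene_id\tS1\tS2", "G1\t1.5\t2", "G2\t3\t4"), f)
  expect_error(read_counts(f), "non-integer", class = "eoclines_parse_error")
  writeLines(c("gene_id\tS1\tS2", "G1\t1\t2", "G1\t3\t4"), f)
  expect_error(read_counts(f), "duplicate", class = "eoclines_parse_error")
})

test_that("the MatrixMarket reader detects sidecar dimension mismatches", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "counts.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 2", "1 1 5", "3 2 7"), f)
  writeLines(c("G1", "G2"), file.path(dir, "genes.txt")) # one too few
  writeLines(c("S1", "S2"), file.path(dir, "samples.txt"))
  expect_error(read_counts(f), "sidecar", class = "eoclines_parse_error")
})

test_that("size factors are 1 for identical samples and scale-equivariant", {
  m <- make_counts(matrix(c(5L, 9L, 13L), 3, 4, byrow = FALSE))
  expect_equal(unname(size_factors(m)), rep(1, 4))
  m2 <- make_counts(cbind(c(4L, 10L, 6L), 2L * c(4L, 10L, 6L)))
  f <- size_factors(m2)
  expect_equal(unname(f[2] / f[1]), 2)
})

test_that("size factors match the hand-computed median-of-ratios toy case", {
  m <- make_counts(matrix(c(2L, 8L, 2L, 4L, 16L, 2L), 3, 2))
  # geometric means: sqrt(8), sqrt(128), 2; medians of ratios: 1/sqrt(2), sqrt(2)
  expect_equal(unname(size_factors(m)), c(sqrt(0.5), sqrt(2)))
})

test_that("size factors agree with the reference median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(31)
  m <- make_counts(matrix(rnbinom(600, mu = 80, size = 8) + 1L, 60, 10))
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("size factors refuse a matrix with no always-expressed gene", {
  m <- make_counts(rbind(c(0L, 4L), c(3L, 0L)))
  expect_error(size_factors(m), "pseudocount", class = "eoclines_input_error")
})

test_that("the VST maps known counts to known values and preserves shape", {
  m <- make_counts(rbind(c(0L, 7L), c(7L, 0L)))
  v <- vst_transform(m, factors = c(1, 1))
  expect_equal(v[1, 1], 0)
  expect_equal(v[1, 2], 3)
  expect_identical(dimnames(v), dimnames(m))
  expect_identical(attr(v, "transform_chain"), "vst")
})

test_that("the VST keeps per-gene variance within one order of magnitude across means", {
  # negative-binomial draws at the package's count model: once biological
  # dispersion dominates shot noise, the log transform flattens the
  # mean-variance trend
  set.seed(8)
  vars <- sapply(c(10, 100, 1000), function(mu) {
    m <- matrix(rnbinom(200 * 50, mu = mu, size = 20), 200, 50)
    rownames(m) <- sprintf("G%d", 1:200)
    colnames(m) <- sprintf("S%d", 1:50)
    storage.mode(m) <- "integer"
    v <- vst_transform(m, factors = rep(1, 50))
    median(apply(v, 1, var))
  })
  expect_lt(max(vars) / min(vars), 10)
})

test_that("MAD filtering reproduces hand-computed values and edge cases", {
  m <- rbind(const = rep(3, 5), spike = c(1, 2, 3, 4, 100))
  colnames(m) <- sprintf("S%d", 1:5)
  res <- mad_filter(m, threshold = 1.5)
  expect_equal(unname(res$mad_values["const"]), 0)
  expect_equal(unname(res$mad_values["spike"]), 1.4826) # raw MAD 1, scaled
  expect_length(res$kept_genes, 0)
  expect_equal(mad_filter(m, threshold = 0)$kept_genes, rownames(m))
  raw <- mad_filter(m, threshold = 1.5, scale_constant = 1)
  expect_equal(unname(raw$mad_values["spike"]), 1)
  expect_error(mad_filter(m[, 1, drop = FALSE], 1.5), class = "eoclines_input_error")
})

test_that("MAD filtering is sample-order invariant and monotone in the threshold", {
  set.seed(21)
  m <- matrix(rnorm(400, sd = 2), 40, 10,
              dimnames = list(sprintf("G%d", 1:40), sprintf("S%d", 1:10)))
  perm <- sample(10)
  expect_identical(mad_filter(m, 1)$kept_genes, mad_filter(m[, perm], 1)$kept_genes)
  sizes <- sapply(c(0, 0.5, 1, 2, 4), function(t) length(mad_filter(m, t)$kept_genes))
  expect_true(all(diff(sizes) <= 0))
})

test_that("upper-quartile normalization is scale-invariant and hand-checkable", {
  a <- c(2L, 4L, 6L, 8L)
  m <- make_counts(cbind(a, 3L * a))
  out <- upper_quartile_normalize(m)
  expect_equal(out[, 1], out[, 2])
  # UQ of sample 1 is 6.5 (type-7), of sample 2 is 19.5; global mean 13
  expect_equal(unname(out[, 1]), a / 6.5 * 13)
  m2 <- make_counts(cbind(a, a))
  out2 <- upper_quartile_normalize(m2)
  expect_equal(out2[, 1], out2[, 2])
  logged <- upper_quartile_normalize(m, log2_transform = TRUE)
  expect_identical(attr(logged, "transform_chain"), c("uq", "log2"))
})

test_that("upper-quartile normalization names an all-zero sample", {
  m <- make_counts(cbind(c(1L, 2L), c(0L, 0L)), samples = c("ok", "empty"))
  expect_error(upper_quartile_normalize(m), "empty", class = "eoclines_input_error")
})

test_that("a single all-covering batch is a no-op for batch correction", {
  set.seed(5)
  m <- matrix(rnorm(200, 6), 20, 10)
  expect_message(out <- combat_adjust(m, rep("A", 10)), "single batch")
  expect_equal(out, m, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("singleton batches are rejected", {
  m <- matrix(rnorm(60, 6), 20, 3)
  expect_error(combat_adjust(m, c("A", "A", "B")), "singleton",
               class = "eoclines_input_error")
})

test_that("batch correction removes a planted mean shift almost entirely", {
  set.seed(9)
  G <- 500
  Y <- matrix(rnorm(G * 100, 5, 0.3), G)
  delta <- rnorm(G, 1, 0.3)
  batch <- rep(c("A", "B"), each = 50)
  Y[, batch == "B"] <- Y[, batch == "B"] + delta
  adj <- combat_adjust(Y, batch)
  resid <- rowMeans(adj[, batch == "B"]) - rowMeans(adj[, batch == "A"])
  expect_lt(mean(abs(resid)) / mean(abs(delta)), 0.05)
  # grand per-gene means survive and nothing becomes NaN
  expect_equal(rowMeans(adj), rowMeans(Y), tolerance = 0.05)
  expect_false(anyNA(adj))
})

test_that("batch correction is invariant to sample order within batches", {
  set.seed(10)
  Y <- matrix(rnorm(300, 4), 30, 10)
  batch <- rep(c("A", "B"), each = 5)
  perm <- c(sample(1:5), sample(6:10))
  a <- combat_adjust(Y, batch)
  b <- combat_adjust(Y[, perm], batch[perm])
  expect_equal(a[, perm], b, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("batch correction matches the reference parametric implementation", {
  skip_if_not_installed("sva")
  set.seed(11)
  G <- 300
  Y <- matrix(rnorm(G * 60, 5, 1), G)
  batch <- rep(c("A", "B", "C"), each = 20)
  Y[, batch == "B"] <- Y[, batch == "B"] + rnorm(G, 0.5, 0.3)
  Y[, batch == "C"] <- Y[, batch == "C"] * 1.1
  mine <- combat_adjust(Y, batch)
  ref <- suppressMessages(sva::ComBat(Y, batch = factor(batch)))
  expect_equal(mine, ref, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("zero-variance genes pass through unadjusted with a warning", {
  set.seed(12)
  Y <- rbind(flat = rep(2, 10), matrix(rnorm(90, 4), 9, 10))
  batch <- rep(c("A", "B"), each = 5)
  expect_warning(out <- combat_adjust(Y, batch), "zero-variance")
  expect_equal(unname(out[1, ]), rep(2, 10))
})

test_that("end-to-end, batch correction shrinks between-batch distances on synthetic data", {
  cfg <- tiny_cfg(33L, n_cell_lines = 24L, batch_location_sd = 0.6)
  lines <- apply_batch_effects(simulate_cell_lines(generate_signatures(cfg)))
  v <- vst_transform(lines$counts)
  adj <- suppressWarnings(combat_adjust(v, lines$metadata$batch))
  batch_dist <- function(m) {
    bs <- unique(lines$metadata$batch)
    bm <- sapply(bs, function(b) rowMeans(m[, lines$metadata$batch == b, drop = FALSE]))
    tot <- 0
    for (i in seq_along(bs)) for (j in seq_len(i - 1))
      tot <- tot + mean(abs(bm[, i] - bm[, j]))
    tot
  }
  expect_lt(batch_dist(adj), batch_dist(v))
})

test_that("gene harmonization returns the ordered intersection", {
  x <- matrix(1, 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  y <- matrix(1, 3, 2, dimnames = list(c("C", "B", "D"), c("t1", "t2")))
  h <- harmonize_genes(x, y)
  expect_identical(rownames(h$x), rownames(h$y))
  expect_setequal(h$genes, c("B", "C"))
})
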