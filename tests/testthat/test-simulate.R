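test_that("signature gene sets are disjoint, sized as configured, baseline elsewhere", {
  cfg <- sim_config(n_genes = 100L, k_subtypes = 2L,
                    subtype_names = c("HGSOC", "CCOC"),
                    n_tumors_per_subtype = c(HGSOC = 4L, CCOC = 4L),
                    n_sig_genes_per_subtype = 10L, rng_seed = 1L)
  sig <- generate_signatures(cfg)
  sets <- sig$signature_genes
  expect_length(sets, 2)
  expect_length(sets[[1]], 10)
  expect_length(intersect(sets[[1]], sets[[2]]), 0)
  plain <- setdiff(sig$genes, unlist(sets))
  expect_length(plain, 80)
  # non-signature genes carry identical weight in both subtypes
  expect_equal(sig$signatures[plain, 1], sig$signatures[plain, 2])
  expect_true(all(sig$signatures >= 0))
})

test_that("degenerate logfc distribution gives exact fold changes", {
  cfg <- sim_config(n_genes = 80L, k_subtypes = 2L,
                    subtype_names = c("HGSOC", "CCOC"),
                    n_tumors_per_subtype = c(HGSOC = 4L, CCOC = 4L),
                    n_sig_genes_per_subtype = 8L,
                    logfc_mean = 2, logfc_sd = 0, rng_seed = 3L)
  sig <- generate_signatures(cfg)
  g <- sig$signature_genes$HGSOC
  ratio <- sig$signatures[g, "HGSOC"] / exp(sig$baseline_log[g])
  expect_equal(unname(ratio), rep(4, length(g)))
})

test_that("generator errors when signature sets cannot be disjoint", {
  cfg <- tiny_cfg()
  cfg$n_sig_genes_per_subtype <- 150L
  expect_error(generate_signatures(cfg), class = "eoclines_config_error")
})

test_that("identical config and seed reproduce the panel bit-for-bit", {
  cfg <- tiny_cfg(7L)
  s1 <- generate_signatures(cfg)
  s2 <- generate_signatures(cfg)
  expect_identical(s1$signatures, s2$signatures)
  l1 <- simulate_cell_lines(s1)
  l2 <- simulate_cell_lines(s2)
  expect_identical(l1$counts, l2$counts)
  t1 <- simulate_tumors(s1)
  t2 <- simulate_tumors(s2)
  expect_identical(t1$counts, t2$counts)
  b1 <- apply_batch_effects(l1)
  b2 <- apply_batch_effects(l2)
  expect_identical(b1$counts, b2$counts)
})

test_that("counts are non-negative integers with no missing values", {
  cfg <- tiny_cfg(11L)
  sig <- generate_signatures(cfg)
  for (panel in list(simulate_cell_lines(sig),
                     apply_batch_effects(simulate_tumors(sig)))) {
    expect_true(is.integer(panel$counts))
    expect_false(anyNA(panel$counts))
    expect_true(all(panel$counts >= 0))
    expect_identical(panel$metadata$sample_id, colnames(panel$counts))
  }
})

test_that("vanishing dispersion approaches the Poisson mean-variance relation", {
  cfg <- sim_config(n_genes = 1500L, k_subtypes = 2L,
                    subtype_names = c("HGSOC", "CCOC"),
                    n_tumors_per_subtype = c(HGSOC = 4L, CCOC = 4L),
                    n_cell_lines = 40L, n_sig_genes_per_subtype = 10L,
                    nb_dispersion = 0, library_size_logsd = 0, rng_seed = 5L)
  lines <- simulate_cell_lines(generate_signatures(cfg))
  idx <- lines$truth$true_subtype == "HGSOC"
  x <- lines$counts[, idx]
  m <- rowMeans(x)
  v <- apply(x, 1, var)
  keep <- m > 5
  expect_gt(sum(keep), 1000)
  expect_equal(median(v[keep] / m[keep]), 1, tolerance = 0.1)
})

test_that("signature genes are elevated by about the planted fold change", {
  cfg <- sim_config(n_genes = 800L, k_subtypes = 2L,
                    subtype_names = c("HGSOC", "CCOC"),
                    n_tumors_per_subtype = c(HGSOC = 4L, CCOC = 4L),
                    n_cell_lines = 40L, n_sig_genes_per_subtype = 30L,
                    logfc_mean = 2, logfc_sd = 0, sig_baseline_shift = 0,
                    nb_dispersion = 0.02, library_size_logsd = 0, rng_seed = 6L)
  sig <- generate_signatures(cfg)
  lines <- simulate_cell_lines(sig)
  own <- lines$truth$true_subtype == "HGSOC"
  g <- sig$signature_genes$HGSOC
  ratio <- rowMeans(lines$counts[g, own]) / rowMeans(lines$counts[g, !own])
  expect_equal(mean(ratio), 4, tolerance = 0.15)
})

test_that("full-purity tumors share the cell-line expression profile exactly", {
  cfg <- tiny_cfg(9L, purity_low = 1, purity_high = 1)
  sig <- generate_signatures(cfg)
  lines <- simulate_cell_lines(sig)
  tumors <- simulate_tumors(sig)
  li <- which(lines$truth$true_subtype == "HGSOC")[1]
  ti <- which(tumors$truth$true_subtype == "HGSOC")[1]
  expect_equal(lines$mu[, li] / sum(lines$mu[, li]),
               tumors$mu[, ti] / sum(tumors$mu[, ti]), tolerance = 1e-12)
})

test_that("half purity mixes subtype and stromal profiles as an arithmetic mean", {
  cfg <- tiny_cfg(10L, purity_low = 0.5, purity_high = 0.5)
  sig <- generate_signatures(cfg)
  tumors <- simulate_tumors(sig)
  i <- which(tumors$truth$true_subtype == "CCOC")[1]
  p_sub <- sig$signatures[, "CCOC"] / sum(sig$signatures[, "CCOC"])
  p_base <- exp(sig$baseline_log) / sum(exp(sig$baseline_log))
  expect_equal(tumors$mu[, i] / sum(tumors$mu[, i]),
               0.5 * p_sub + 0.5 * p_base, tolerance = 1e-12)
  expect_equal(tumors$truth$purity[i], 0.5)
})

test_that("lower purity lowers the correlation between tumors and pure same-subtype lines", {
  cors <- sapply(c(0.9, 0.6, 0.3), function(p) {
    cfg <- sim_config(n_genes = 300L, k_subtypes = 2L,
                      subtype_names = c("HGSOC", "CCOC"),
                      n_tumors_per_subtype = c(HGSOC = 50L, CCOC = 4L),
                      n_cell_lines = 8L, n_sig_genes_per_subtype = 100L,
                      logfc_mean = 3,
                      purity_low = p, purity_high = p, rng_seed = 12L)
    sig <- generate_signatures(cfg)
    lines <- simulate_cell_lines(sig)
    tumors <- simulate_tumors(sig)
    li <- which(lines$truth$true_subtype == "HGSOC")[1]
    ti <- tumors$truth$true_subtype == "HGSOC"
    mean(cor(lines$counts[, li], tumors$counts[, ti], method = "spearman"))
  })
  expect_true(all(diff(cors) < 0))
})

test_that("batch location effects have the configured magnitude and leave truth untouched", {
  cfg <- sim_config(n_genes = 2000L, k_subtypes = 3L,
                    subtype_names = c("HGSOC", "CCOC", "MOC"),
                    n_tumors_per_subtype = c(HGSOC = 4L, CCOC = 4L, MOC = 4L),
                    n_cell_lines = 24L, n_batches_cell_lines = 2L,
                    n_sig_genes_per_subtype = 20L,
                    batch_location_sd = 0.5, batch_scale_sd = 0,
                    library_size_logsd = 0, rng_seed = 13L)
  sig <- generate_signatures(cfg)
  lines <- simulate_cell_lines(sig)
  shifted <- apply_batch_effects(lines)
  b <- shifted$metadata$batch
  d <- rowMeans(log(shifted$mu[, b == "LB2"])) - rowMeans(log(shifted$mu[, b == "LB1"]))
  expect_equal(sd(d), 0.5, tolerance = 0.05)
  expect_identical(shifted$truth, lines$truth)
})

test_that("zero-magnitude batch effects reproduce the input counts exactly", {
  cfg <- tiny_cfg(14L, batch_location_sd = 0, batch_scale_sd = 0)
  lines <- simulate_cell_lines(generate_signatures(cfg))
  expect_identical(apply_batch_effects(lines)$counts, lines$counts)
})

test_that("a single batch introduces no relative shift", {
  cfg <- tiny_cfg(15L, n_batches_cell_lines = 1L)
  lines <- simulate_cell_lines(generate_signatures(cfg))
  expect_identical(apply_batch_effects(lines)$counts, lines$counts)
})

test_that("apply_batch_effects rejects missing batch labels", {
  cfg <- tiny_cfg(16L)
  lines <- simulate_cell_lines(generate_signatures(cfg))
  lines$metadata$batch[3] <- NA
  expect_error(apply_batch_effects(lines), class = "eoclines_input_error")
})

test_that("fixtures round-trip losslessly through both readers", {
  cfg <- tiny_cfg(17L)
  lines <- simulate_cell_lines(generate_signatures(cfg))
  dir <- withr::local_tempdir()
  write_fixture(lines, dir)
  tsv <- read_counts(file.path(dir, "counts.tsv"))
  mtx <- read_counts(file.path(dir, "counts.mtx"))
  expect_identical(tsv, lines$counts)
  expect_identical(mtx, lines$counts)
  meta <- read.delim(file.path(dir, "metadata.tsv"), stringsAsFactors = FALSE)
  expect_identical(meta, lines$metadata)
})

test_that("fixture writing is byte-deterministic", {
  cfg <- tiny_cfg(18L)
  lines <- simulate_cell_lines(generate_signatures(cfg))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(lines, d1)
  write_fixture(lines, d2)
  for (f in c("counts.tsv", "counts.mtx", "metadata.tsv", "truth.tsv"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})

test_that("a 3 x 2 toy matrix writes the expected file contents", {
  counts <- matrix(c(1L, 2L, 4L, 0L, 3L, 5L), nrow = 3,
                   dimnames = list(c("G1", "G2", "G3"), c("S1", "S2")))
  toy <- eoclines:::new_eoc_sim(
    counts,
    metadata = data.frame(sample_id = c("S1", "S2"), kind = "cell_line",
                          batch = "B1", annotation = "HGSOC"),
    truth = data.frame(sample_id = c("S1", "S2"), true_subtype = "HGSOC",
                       purity = NA_real_, similarity = 1),
    mu = counts * 1.0, dispersion = 0.1, count_seed = 1L,
    config = tiny_cfg())
  dir <- withr::local_tempdir()
  write_fixture(toy, dir)
  expect_identical(readLines(file.path(dir, "counts.tsv")),
                   c("gene_id\tS1\tS2", "G1\t1\t0", "G2\t2\t3", "G3\t4\t5"))
  expect_identical(readLines(file.path(dir, "counts.mtx")),
                   c("%%MatrixMarket matrix coordinate integer general",
                     "3 2 5", "1 1 1", "2 1 2", "3 1 4", "2 2 3", "3 2 5"))
})

test_that("planted separability strengthens with the planted effect size", {
  ari <- sapply(c(0.5, 1, 2), function(fc) {
    cfg <- tiny_cfg(21L, logfc_mean = fc)
    lines <- apply_batch_effects(simulate_cell_lines(generate_signatures(cfg)))
    V <- nmf_input(lines)
    rc <- run_consensus(V, 3, n_runs = 5, seed = 77)
    mclust::adjustedRandIndex(rc$labels, lines$truth$true_subtype)
  })
  expect_true(all(diff(ari) >= -1e-9))
  expect_gt(ari[3], 0.9)
})
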