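sim_probe_matrix <- function(n_probes, n_samples, seed) {
  set.seed(seed)
  matrix(rnorm(n_probes * n_samples, mean = 7), n_probes, n_samples,
         dimnames = list(sprintf("p%03d", seq_len(n_probes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

test_that("probe collapse keeps the max-mean probe per gene", {
  pm <- rbind(lo = rep(1, 4), hi = rep(2, 4))
  colnames(pm) <- paste0("s", 1:4)
  map <- data.frame(probe_id = c("lo", "hi"), gene_id = "G")
  out <- collapse_probes(pm, map)
  expect_equal(unname(out$values["G", ]), rep(2, 4))

  ## one probe per gene: identity up to relabeling
  pm2 <- sim_probe_matrix(5, 3, seed = 1)
  map2 <- data.frame(probe_id = rownames(pm2), gene_id = paste0("g", 1:5))
  out2 <- collapse_probes(pm2, map2)
  expect_equal(unname(out2$values[paste0("g", 1:5), ]), unname(pm2))

  ## random matrix vs per-gene argmax oracle
  pm3 <- sim_probe_matrix(200, 10, seed = 2)
  set.seed(3)
  map3 <- data.frame(probe_id = rownames(pm3),
                     gene_id = sample(sprintf("g%02d", 1:60), 200, replace = TRUE))
  out3 <- collapse_probes(pm3, map3)
  for (g in rownames(out3$values)) {
    probes <- map3$probe_id[map3$gene_id == g]
    means <- rowMeans(pm3[probes, , drop = FALSE])
    best <- sort(probes[means == max(means)])[1]
    expect_equal(unname(out3$values[g, ]), unname(pm3[best, ]))
  }
  expect_error(collapse_probes(pm3, data.frame(probe_id = "zzz", gene_id = "g")),
               "no probes")
})

test_that("a pure constant batch shift is removed exactly", {
  set.seed(4)
  mu <- rnorm(80, 7)
  pattern <- rnorm(16)
  vals <- outer(mu, rep(1, 16)) + outer(rep(1, 80), pattern)
  vals[, 9:16] <- vals[, 9:16] + 3
  dimnames(vals) <- list(sprintf("g%02d", 1:80), sprintf("s%02d", 1:16))
  x <- expression_set(vals, batch = rep(c("b1", "b2"), each = 8))
  xc <- correct_batches(x, protect = FALSE)
  diff <- rowMeans(xc$values[, 9:16]) - rowMeans(xc$values[, 1:8])
  expect_lt(max(abs(diff)), 1e-6)
})

test_that("single-batch input is returned unchanged and confounding errors", {
  sim <- simulate_expression(n_genes = 100, n_case = 6, n_control = 6,
                             module_size = 5, rng_seed = 5)
  x1 <- expression_set(sim$expression$values,
                       phenotype = sim$expression$phenotype,
                       batch = rep("b1", 12))
  expect_identical(correct_batches(x1)$values, x1$values)

  confounded <- expression_set(sim$expression$values,
                               phenotype = sim$expression$phenotype,
                               batch = ifelse(sim$expression$phenotype == "case",
                                              "b1", "b2"))
  expect_error(correct_batches(confounded, protect = TRUE), "confounded")
})

test_that("protected group effects survive batch adjustment", {
  sim <- simulate_expression(n_genes = 400, n_case = 14, n_control = 14,
                             module_size = 30, rho = 0, log2_effect = 2,
                             batch_design = list(n_batches = 2,
                                                 shift = c(0, 3)),
                             rng_seed = 6)
  xc <- correct_batches(sim$expression, protect = TRUE)
  ph <- xc$phenotype
  est <- rowMeans(xc$values[sim$truth$module_genes, ph == "case"]) -
    rowMeans(xc$values[sim$truth$module_genes, ph == "control"])
  expect_lt(abs(mean(est) - 2) / 2, 0.1)
  ## residual batch separation should be negligible relative to the shift
  bd <- rowMeans(xc$values[, xc$batch == "b2"]) -
    rowMeans(xc$values[, xc$batch == "b1"])
  expect_lt(mean(abs(bd)), 0.3)
})

test_that("batch adjustment agrees with the reference ComBat implementation", {
  skip_if_not_installed("sva")
  sim <- simulate_expression(n_genes = 300, n_case = 10, n_control = 10,
                             module_size = 20, log2_effect = 1,
                             batch_design = list(n_batches = 2,
                                                 shift = c(0, 2),
                                                 scale = c(1, 1.3)),
                             rng_seed = 7)
  x <- sim$expression
  mine <- correct_batches(x, protect = TRUE)$values
  ref <- sva::ComBat(dat = x$values, batch = factor(x$batch),
                     mod = stats::model.matrix(~ factor(x$phenotype)))
  expect_gt(cor(as.vector(mine), as.vector(ref)), 0.999)
  expect_lt(mean(abs(mine - ref)), 0.1)
})

test_that("IQR filtering keeps the top fraction deterministically", {
  vals <- rbind(a = c(0, 1, 2, 3), b = c(0, 2, 4, 6), c = c(0, 3, 6, 9),
                d = c(0, 4, 8, 12))
  colnames(vals) <- paste0("s", 1:4)
  x <- expression_set(vals)
  kept <- iqr_filter(x, 0.5)
  expect_equal(rownames(kept$values), c("c", "d"))
  expect_identical(iqr_filter(x, 1)$values, x$values)

  ## sample reordering and joint affine rescaling do not change the gene set
  sim <- simulate_expression(n_genes = 200, n_case = 8, n_control = 8,
                             module_size = 10, rng_seed = 8)
  x <- sim$expression
  perm <- sample(ncol(x$values))
  k1 <- rownames(iqr_filter(x, 0.4)$values)
  k2 <- rownames(iqr_filter(expression_set(x$values[, perm]), 0.4)$values)
  expect_identical(k1, k2)
  k3 <- rownames(iqr_filter(expression_set(2.5 * x$values + 1), 0.4)$values)
  expect_identical(k1, k3)
})

test_that("matrix and sample sheet round-trip through the TSV writer", {
  sim <- simulate_expression(n_genes = 50, n_case = 5, n_control = 5,
                             module_size = 5,
                             batch_design = list(n_batches = 2,
                                                 shift = c(0, 1)),
                             rng_seed = 9)
  f <- withr::local_tempfile(fileext = ".tsv")
  ss <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(sim$expression, f, sample_sheet = ss)
  back <- read_expression_matrix(f, sample_sheet = ss)
  expect_equal(back$values, sim$expression$values, tolerance = 1e-12)
  expect_equal(back$phenotype, sim$expression$phenotype)
  expect_equal(back$batch, sim$expression$batch)
})
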