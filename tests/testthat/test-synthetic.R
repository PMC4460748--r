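test_that("generators are pure functions of their seed", {
  g1 <- simulate_genome(n_genes = 80, seed = 5)
  g2 <- simulate_genome(n_genes = 80, seed = 5)
  expect_identical(g1, g2)
  g3 <- simulate_genome(n_genes = 80, seed = 6)
  expect_false(identical(g1$genes$start, g3$genes$start))

  s1 <- simulate_expression(n_genes = 100, n_case = 6, n_control = 6,
                            module_size = 10, rng_seed = 3)
  s2 <- simulate_expression(n_genes = 100, n_case = 6, n_control = 6,
                            module_size = 10, rng_seed = 3)
  expect_identical(s1$expression$values, s2$expression$values)

  tg <- g1$genes$gene_id[1:10]
  p1 <- simulate_peaks(g1, tg, seed = 7)
  p2 <- simulate_peaks(g1, tg, seed = 7)
  expect_identical(p1$mark1$peaks, p2$mark1$peaks)
})

test_that("a single-gene genome writes valid GFF3", {
  g <- simulate_genome(n_genes = 1, seed = 9)
  expect_equal(nrow(g$genes), 1L)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(g, f)
  back <- read_gene_models(f, "gff3")
  expect_equal(back$genes$gene_id, g$genes$gene_id)
  expect_equal(nrow(back$exons), nrow(g$exons))
})

test_that("genome structure honours its invariants and parameters", {
  g <- simulate_genome(n_genes = 2000, coding_fraction = 0.31, seed = 13)
  ## coding fraction within binomial 99% bounds
  phat <- mean(g$genes$biotype == "coding")
  expect_lt(abs(phat - 0.31), qnorm(0.995) * sqrt(0.31 * 0.69 / 2000))
  ## genes non-overlapping per chromosome
  for (ch in unique(g$genes$chrom)) {
    gg <- g$genes[g$genes$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    expect_true(all(gg$start[-1] > gg$end[-nrow(gg)]))
  }
  ## transcripts per gene 1..3, exons per transcript 1..8
  expect_true(all(table(g$transcripts$gene_id) %in% 1:3))
  expect_true(all(table(g$exons$transcript_id) %in% 1:8))
  ## infeasible packing errors
  expect_error(simulate_genome(n_genes = 100, chrom_length = 1e4, seed = 1),
               "infeasible")
})

test_that("full co-occupancy yields one co-enriched region per target", {
  g <- simulate_genome(n_genes = 120, seed = 17)
  set.seed(18)
  tg <- sample(g$genes$gene_id, 15)
  pk <- simulate_peaks(g, tg, n_background_peaks = 0, co_occupancy_rate = 1,
                       seed = 19)
  co <- intersect_peaksets(pk$mark1, pk$mark2)
  expect_equal(nrow(co$peaks), 15L)
  expect_setequal(target_genes(seq2gene(co, build_index(g))) |>
                    intersect(tg), tg)

  ## rate 0, background only: cross-mark intersection is (near) absent
  pk0 <- simulate_peaks(g, character(0), n_background_peaks = 40,
                        co_occupancy_rate = 0, seed = 20)
  co0 <- intersect_peaksets(pk0$mark1, pk0$mark2)
  expect_lte(nrow(co0$peaks), 2L)
})

test_that("planted module genes correlate with the seed at the planted level", {
  sim <- simulate_expression(rng_seed = 21)  # default scenario
  x <- sim$expression$values
  ph <- sim$expression$phenotype
  ## estimate rho on group-centred data (removes the planted case shift)
  xc <- x
  xc[, ph == "case"] <- x[, ph == "case"] - rowMeans(x[, ph == "case"])
  xc[, ph == "control"] <- x[, ph == "control"] - rowMeans(x[, ph == "control"])
  mod <- setdiff(sim$truth$module_genes, sim$truth$seed_gene)
  rs <- cor(t(xc[mod, ]), xc[sim$truth$seed_gene, ])
  expect_lt(abs(mean(rs) - 0.7), 0.05)
  ## non-module genes are null
  other <- setdiff(rownames(x), sim$truth$module_genes)[1:200]
  r0 <- cor(t(xc[other, ]), xc[sim$truth$seed_gene, ])
  expect_lt(abs(mean(r0)), 0.05)
})

test_that("a null generator yields only chance-level modules", {
  ## Under the null the chance overlap sits near the hypergeometric baseline
  ## n^2/N = 16.7 but is inflated by the data-sharing between the two
  ## statistics (a gene's correlation with the seed co-varies with its group
  ## contrast through the seed's realized contrast), so the bound is loose.
  sizes <- vapply(1:3, function(k) {
    sim <- simulate_expression(n_genes = 600, n_case = 20, n_control = 20,
                               module_size = 2, rho = 0, log2_effect = 0,
                               rng_seed = 22 + k)
    fit <- pgnet(sim$expression, sim$truth$seed_gene, "case", "control",
                 n_top = 100, B = 19, rng_seed = 24)
    length(fit$genes)
  }, numeric(1))
  expect_lt(mean(sizes), 40)
  expect_true(all(sizes < 60))

  ## near-deterministic planted signal is recovered almost perfectly
  sim2 <- simulate_expression(n_genes = 300, n_case = 10, n_control = 10,
                              module_size = 20, rho = 0.99, log2_effect = 3,
                              sigma = 0.5, rng_seed = 25)
  fit2 <- pgnet(sim2$expression, sim2$truth$seed_gene, "case", "control",
                n_top = 20, B = 99, rng_seed = 26)
  expect_gte(length(intersect(fit2$genes, sim2$truth$module_genes)), 18)
})

test_that("fixture directories are complete and re-readable", {
  d <- withr::local_tempdir()
  paths <- simulate_fixture(d, n_genes = 120, n_targets = 15,
                            module_size = 10, n_case = 8, n_control = 8,
                            n_sets = 5, seed = 27)
  expect_true(all(file.exists(paths)))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_length(truth$target_genes, 15)
  g <- read_gene_models(paths[["genome"]], "gff3")
  expect_equal(nrow(g$genes), 120L)
  x <- read_expression_matrix(paths[["expr"]], sample_sheet = paths[["samples"]])
  expect_equal(dim(x$values), c(120L, 16L))
  expect_true(truth$seed_gene %in% rownames(x$values))
  col <- read_gmt(paths[["gmt"]])
  expect_true("PLANTED_MODULE_SET" %in% names(col$sets))
  expect_true(all(truth$module_genes %in% col$sets$PLANTED_MODULE_SET))
})
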