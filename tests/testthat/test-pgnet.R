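## prefix-set oracle for the overlap step function
oracle_curve <- function(a, b, n_max) {
  vapply(seq_len(n_max), function(n)
    length(intersect(a[seq_len(n)], b[seq_len(n)])), integer(1))
}

test_that("the overlap step function matches prefix-set counting", {
  a <- c("g1", "g2", "g3"); b <- c("g2", "g1", "g3")
  cv <- overlap_curve(a, b, n_max = 3)
  expect_equal(cv$top, c(0L, 2L, 3L))
  expect_equal(overlap_curve(a, a, 3)$top, 1:3)

  set.seed(1)
  for (rep in 1:10) {
    u <- sprintf("g%03d", 1:50)
    x <- sample(u); y <- sample(u)
    cv <- overlap_curve(x, y, n_max = 50)
    expect_equal(cv$top, oracle_curve(x, y, 50))
    expect_equal(cv$bottom, oracle_curve(rev(x), rev(y), 50))
    ## O(n) nondecreasing, O(n) <= n, O(N) = N
    expect_true(all(diff(cv$top) >= 0))
    expect_true(all(cv$top <= cv$n))
    expect_equal(cv$top[50], 50L)
  }
  expect_error(overlap_curve(c("a", "b"), c("a", "c"), 2), "offending")
})

test_that("the null overlap expectation matches hypergeometric enumeration", {
  ci <- expected_overlap_ci(100, 10)
  expect_equal(ci$mean, 1.0)
  ciN <- expected_overlap_ci(30, 30)
  expect_equal(c(ciN$mean, ciN$lo95, ciN$hi95), c(30, 30, 30))

  ## N=20, n=5: exact pmf by counting permutations of set memberships
  N <- 20; n <- 5
  pmf <- vapply(0:n, function(k)
    choose(n, k) * choose(N - n, n - k) / choose(N, n), numeric(1))
  cdf <- cumsum(pmf)
  ci2 <- expected_overlap_ci(N, n)
  expect_equal(ci2$mean, sum((0:n) * pmf))
  expect_equal(ci2$lo95, (0:n)[which(cdf >= 0.025)[1]])
  expect_equal(ci2$hi95, (0:n)[which(cdf >= 0.975)[1]])
})

test_that("the similarity score is the weighted overlap sum", {
  u <- sprintf("g%02d", 1:10)
  set.seed(2)
  a <- sample(u); b <- sample(u)
  ## direct summation by hand
  for (beta in c(0, 0.1, 1)) {
    o <- oracle_curve(a, b, 10)
    expect_equal(similarity_score(a, b, beta = beta, n_max = 10),
                 sum(exp(-beta * (1:10)) * o))
  }
  ## beta = 0: unweighted; identical lists: closed form sum e^{-bn} n
  expect_equal(similarity_score(a, b, beta = 0, n_max = 10),
               sum(oracle_curve(a, b, 10)))
  expect_equal(similarity_score(a, a, beta = 0.3, n_max = 10),
               sum(exp(-0.3 * (1:10)) * (1:10)))
})

test_that("identical lists give the minimal possible empirical p", {
  u <- sprintf("g%03d", 1:40)
  for (B in c(19, 99)) {
    res <- permutation_pvalue(u, u, B = B, n_max = 20, seed = 3)
    expect_equal(res$empirical_p, 1 / (B + 1))
  }
})

test_that("the seeded permutation p converges to exhaustive enumeration on 4 genes", {
  u <- c("a", "b", "c", "d")
  set.seed(4)
  b_list <- sample(u)
  beta <- 0.25; n_max <- 4
  ## exact null: all 24 orderings of list b
  perms <- matrix(c(t(expand.grid(1:4, 1:4, 1:4, 1:4))), ncol = 4, byrow = TRUE)
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  obs <- similarity_score(u, b_list, beta = beta, n_max = n_max)
  null <- apply(perms, 1, function(ord)
    similarity_score(u, u[ord], beta = beta, n_max = n_max))
  p_exact <- mean(null >= obs)
  res <- permutation_pvalue(u, b_list, B = 10000, beta = beta, n_max = n_max,
                            seed = 5)
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(res$empirical_p - p_exact), 3 * se + 2 / 10001)
  ## reproducibility under the same seed
  res2 <- permutation_pvalue(u, b_list, B = 10000, beta = beta, n_max = n_max,
                             seed = 5)
  expect_identical(res$empirical_p, res2$empirical_p)
})

test_that("biomodule extraction is rank-based and direction-aware", {
  set.seed(6)
  n <- 200
  stats <- data.frame(gene_id = sprintf("g%03d", 1:n),
                      ce_r = runif(n, -1, 1), de_stat = rnorm(n))
  class(stats) <- c("ranked_gene_stats", "data.frame")
  m1 <- extract_biomodule(stats, n_top = 40, B = 50, rng_seed = 7)
  ## invariant under strictly monotone transforms of either statistic
  stats2 <- stats
  stats2$ce_r <- tanh(stats$ce_r * 3)
  stats2$de_stat <- exp(stats$de_stat)
  m2 <- extract_biomodule(stats2, n_top = 40, B = 50, rng_seed = 7)
  expect_identical(m1$genes, m2$genes)
  expect_identical(m1$similarity$top$score, m2$similarity$top$score)

  ## perfectly concordant stats fill the module; anti-concordant empty it
  conc <- data.frame(gene_id = stats$gene_id, ce_r = seq_len(n) / n,
                     de_stat = seq_len(n))
  full <- extract_biomodule(conc, n_top = 40, B = 19)
  expect_length(full$genes, 40)
  anti <- conc; anti$de_stat <- -anti$de_stat
  none <- extract_biomodule(anti, n_top = 40, B = 19)
  expect_length(none$genes, 0)
  expect_error(extract_biomodule(conc, n_top = 500), "exceeds")

  ## down-negative direction finds a module planted in the negative tails
  neg <- conc
  neg$ce_r <- -neg$ce_r; neg$de_stat <- -neg$de_stat
  dn <- extract_biomodule(neg, n_top = 40, direction = "down-negative", B = 19)
  expect_length(dn$genes, 40)
})

test_that("permutation p is calibrated under the null for independent lists", {
  set.seed(8)
  u <- sprintf("g%03d", 1:300)
  ps <- vapply(1:60, function(i)
    permutation_pvalue(sample(u), sample(u), B = 99, n_max = 100,
                       seed = i)$empirical_p, numeric(1))
  rr <- mean(ps <= 0.05)
  ## super-uniformity within Monte-Carlo error
  expect_lt(rr, 0.05 + 3 * sqrt(0.05 * 0.95 / 60))
  expect_gt(mean(ps), 0.35)
})

test_that("pgnet recovers a planted module and its methods run", {
  sim <- simulate_expression(n_genes = 400, n_case = 12, n_control = 12,
                             module_size = 25, rho = 0.8, log2_effect = 1.5,
                             rng_seed = 9)
  fit <- pgnet(sim$expression, seed_gene = sim$truth$seed_gene,
               group_a = "case", group_b = "control", n_top = 60, B = 199,
               rng_seed = 10)
  jac <- length(intersect(fit$genes, sim$truth$module_genes)) /
    length(union(fit$genes, sim$truth$module_genes))
  expect_gt(jac, 0.4)
  expect_lt(fit$similarity$top$empirical_p, 0.05)
  expect_true(sim$truth$seed_gene %in% fit$genes)

  expect_output(print(fit), "biomodule")
  s <- summary(fit)
  expect_s3_class(s, "summary.pgnet")
  expect_output(print(s), "similarity")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))

  f <- withr::local_tempfile(fileext = ".tsv")
  write_biomodule(fit, f)
  back <- read.delim(f)
  expect_setequal(back$gene_id, fit$genes)
  expect_true(file.exists(paste0(f, ".curve.tsv")))
})

test_that("two fits with the same seed are identical", {
  sim <- simulate_expression(n_genes = 200, n_case = 8, n_control = 8,
                             module_size = 10, rng_seed = 11)
  f1 <- pgnet(sim$expression, sim$truth$seed_gene, "case", "control",
              n_top = 50, B = 99, rng_seed = 12)
  f2 <- pgnet(sim$expression, sim$truth$seed_gene, "case", "control",
              n_top = 50, B = 99, rng_seed = 12)
  expect_identical(f1$genes, f2$genes)
  expect_identical(f1$similarity$top$null_scores, f2$similarity$top$null_scores)
})
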