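## Biomodule discovery: similarity of two ordered gene lists (seed-gene
## co-expression vs case-control differential expression), tested by
## permutation, and extraction of the jointly top-ranked gene module.

#' Order gene ids by a statistic
#'
#' Produces a deterministic full ordering of the gene universe, most
#' extreme (direction-of-interest) value first, ties broken by gene id.
#'
#' @param ids character vector of gene ids.
#' @param stat numeric statistic, parallel to `ids`.
#' @param decreasing order with the largest statistic first (default TRUE).
#' @return Character vector: `ids` reordered.
#' @export
ordered_list <- function(ids, stat, decreasing = TRUE) {
  stopifnot(length(ids) == length(stat), !anyDuplicated(ids))
  ids[.order_by(if (decreasing) -xtfrm(stat) else xtfrm(stat), id = ids)]
}

.check_universe <- function(a, b) {
  if (length(a) != length(b) || !setequal(a, b)) {
    bad <- c(setdiff(a, b), setdiff(b, a))
    .stopf("ordered lists must share one gene universe; offending ids: %s",
           paste(utils::head(unique(bad), 10), collapse = ", "))
  }
}

## ranks of the shared universe in each list, aligned on list a's ids
.aligned_ranks <- function(a, b) {
  list(ra = seq_along(a), rb = match(a, b))
}

## O(n) for n = 1..n_max from two aligned rank vectors: a gene is in both
## top-n prefixes iff max(rank_a, rank_b) <= n.
.prefix_overlap <- function(ra, rb, n_max) {
  m <- pmax(ra, rb)
  m <- m[m <= n_max]
  cumsum(tabulate(m, nbins = n_max))
}

#' Overlap step function of two ordered lists
#'
#' O(n) is the size of the intersection of the two top-n prefixes, for
#' n = 1..n_max; the same statistic computed from the list bottoms is
#' returned alongside.
#'
#' @param a,b character vectors: two orderings of the same gene universe.
#' @param n_max largest prefix size (default 150).
#' @return Object of class `overlap_curve`: data.frame with columns `n`,
#'   `top`, `bottom`, plus the hypergeometric null expectation `expected`
#'   and its 2.5%/97.5% quantiles `lo95`, `hi95`.
#' @export
overlap_curve <- function(a, b, n_max = 150) {
  .check_universe(a, b)
  N <- length(a)
  if (n_max < 1 || n_max > N) .stopf("n_max must be in 1..%d", N)
  r <- .aligned_ranks(a, b)
  top <- .prefix_overlap(r$ra, r$rb, n_max)
  bottom <- .prefix_overlap(N + 1L - r$ra, N + 1L - r$rb, n_max)
  ns <- seq_len(n_max)
  ci <- expected_overlap_ci(N, ns)
  out <- data.frame(n = ns, top = top, bottom = bottom,
                    expected = ci$mean, lo95 = ci$lo95, hi95 = ci$hi95)
  class(out) <- c("overlap_curve", "data.frame")
  out
}

#' Null expectation and 95% interval of the prefix overlap
#'
#' Under independent orderings of a universe of size N, the overlap of two
#' top-n prefixes is Hypergeometric(N, n, n), with mean n^2/N.
#'
#' @param N universe size.
#' @param n prefix rank(s), 1 <= n <= N (vectorised).
#' @return data.frame with columns `n`, `mean`, `lo95`, `hi95`.
#' @export
expected_overlap_ci <- function(N, n) {
  if (any(n < 1 | n > N)) .stopf("ranks must lie in 1..N")
  data.frame(n = n, mean = n^2 / N,
             lo95 = stats::qhyper(0.025, m = n, n = N - n, k = n),
             hi95 = stats::qhyper(0.975, m = n, n = N - n, k = n))
}

#' Weighted ordered-list similarity score
#'
#' Exponentially down-weighted sum of the overlap step function:
#' `score = sum_{n=1}^{n_max} exp(-beta * n) * O(n)`, computed on the list
#' tops (`direction = "top"`) or bottoms. `beta = 0` gives the unweighted
#' sum of overlaps.
#'
#' @inheritParams overlap_curve
#' @param beta decay rate of the rank weights (default `1/n_max`, e-fold
#'   decay at the rank threshold).
#' @param direction `"top"` or `"bottom"`.
#' @return Numeric scalar score.
#' @export
similarity_score <- function(a, b, beta = 1 / n_max, n_max = 150,
                             direction = c("top", "bottom")) {
  direction <- match.arg(direction)
  if (beta < 0) .stopf("beta must be >= 0")
  .check_universe(a, b)
  N <- length(a)
  r <- .aligned_ranks(a, b)
  if (direction == "bottom") {
    r$ra <- N + 1L - r$ra
    r$rb <- N + 1L - r$rb
  }
  o <- .prefix_overlap(r$ra, r$rb, n_max)
  sum(exp(-beta * seq_len(n_max)) * o)
}

#' Permutation test of ordered-list similarity
#'
#' The null distribution of the similarity score is generated by uniformly
#' permuting the order of list `b` (equivalent in distribution to permuting
#' both lists) `B` times; the empirical p-value uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (B + 1)` so it is never zero.
#'
#' @inheritParams similarity_score
#' @param B number of permutations (default 1000).
#' @param seed optional RNG seed for reproducibility.
#' @return Object of class `similarity_result`: list with `score`,
#'   `empirical_p`, `n_permutations`, `direction`, `beta`, `n_max`, `seed`,
#'   and the vector of `null_scores`.
#' @export
permutation_pvalue <- function(a, b, B = 1000, beta = 1 / n_max, n_max = 150,
                               seed = NULL, direction = c("top", "bottom")) {
  direction <- match.arg(direction)
  if (B < 1) .stopf("B must be >= 1")
  .check_universe(a, b)
  N <- length(a)
  r <- .aligned_ranks(a, b)
  if (direction == "bottom") {
    r$ra <- N + 1L - r$ra
    r$rb <- N + 1L - r$rb
  }
  w <- exp(-beta * seq_len(n_max))
  obs <- sum(w * .prefix_overlap(r$ra, r$rb, n_max))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  null_scores <- vapply(seq_len(B), function(i) {
    rb <- sample.int(N)
    sum(w * .prefix_overlap(r$ra, rb, n_max))
  }, numeric(1))
  p <- (1 + sum(null_scores >= obs)) / (B + 1)
  structure(list(score = obs, empirical_p = p, n_permutations = B,
                 direction = direction, beta = beta, n_max = n_max,
                 seed = seed, null_scores = null_scores),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("ordered-list similarity (%s ranks): score = %.4g, empirical p = %.4g (B = %d)\n",
              x$direction, x$score, x$empirical_p, x$n_permutations))
  invisible(x)
}

#' Extract a biomodule from ranked gene statistics
#'
#' Orders the gene universe by seed co-expression (`ce_r`) and by
#' differential expression (`de_stat`) and intersects the two top-`n_top`
#' prefixes. Direction `"up-positive"` (default) takes positive correlation
#' and up-regulation as the tops of the lists; `"down-negative"` reverses
#' both. The two directions' ordered-list similarities are tested separately
#' by permutation and reported separately, since concordance typically
#' exists among top ranks only.
#'
#' @param stats a [gene_rank_stats()] data.frame.
#' @param n_top rank threshold defining the module (default 150).
#' @param direction `"up-positive"` or `"down-negative"`.
#' @param B permutations for the similarity test (default 1000).
#' @param beta weight decay for the similarity score (default `1/n_top`).
#' @param rng_seed optional seed for the permutation null.
#' @return Object of class `biomodule`: list with `genes` (sorted ids in
#'   both prefixes), `n_top`, `direction`, `seed_gene`, `similarity` (list
#'   of `similarity_result` for `top` and `bottom`), `curve` (an
#'   [overlap_curve()]), and the two orderings `list_ce`, `list_de`.
#' @export
extract_biomodule <- function(stats, n_top = 150,
                              direction = c("up-positive", "down-negative"),
                              B = 1000, beta = 1 / n_top, rng_seed = NULL) {
  direction <- match.arg(direction)
  need <- c("gene_id", "ce_r", "de_stat")
  if (!all(need %in% names(stats)))
    .stopf("stats must carry columns %s", paste(need, collapse = ", "))
  if (n_top > nrow(stats))
    .stopf("n_top (%d) exceeds the gene universe (%d)", n_top, nrow(stats))
  up <- direction == "up-positive"
  list_ce <- ordered_list(stats$gene_id, stats$ce_r, decreasing = up)
  list_de <- ordered_list(stats$gene_id, stats$de_stat, decreasing = up)
  genes <- sort(intersect(list_ce[seq_len(n_top)], list_de[seq_len(n_top)]))
  sim_top <- permutation_pvalue(list_ce, list_de, B = B, beta = beta,
                                n_max = n_top, seed = rng_seed,
                                direction = "top")
  sim_bottom <- permutation_pvalue(list_ce, list_de, B = B, beta = beta,
                                   n_max = n_top,
                                   seed = if (is.null(rng_seed)) NULL else
                                     rng_seed + 1L,
                                   direction = "bottom")
  structure(list(genes = genes, n_top = n_top, direction = direction,
                 seed_gene = attr(stats, "seed_gene"),
                 similarity = list(top = sim_top, bottom = sim_bottom),
                 curve = overlap_curve(list_ce, list_de, n_max = n_top),
                 list_ce = list_ce, list_de = list_de),
            class = "biomodule")
}

#' @export
print.biomodule <- function(x, ...) {
  cat(sprintf("biomodule: %d genes in both top-%d prefixes (%s)\n",
              length(x$genes), x$n_top, x$direction))
  if (!is.null(x$seed_gene)) cat(sprintf("  seed gene: %s\n", x$seed_gene))
  cat(sprintf("  similarity: top p = %.4g, bottom p = %.4g (B = %d)\n",
              x$similarity$top$empirical_p, x$similarity$bottom$empirical_p,
              x$similarity$top$n_permutations))
  invisible(x)
}

## ---------------------------------------------------------------------------
## pgnet: the one-call model fit

#' Fit a phenotype-genotype network (biomodule) model
#'
#' The two-list procedure in one call: computes seed-gene co-expression and
#' case-control moderated-t statistics for every gene
#' ([gene_rank_stats()]), orders the universe by each, tests the similarity
#' of the two orderings by a permutation test of the weighted prefix
#' overlap, and extracts the biomodule — the genes in the top `n_top` ranks
#' of both orderings ([extract_biomodule()]).
#'
#' @inheritParams gene_rank_stats
#' @inheritParams extract_biomodule
#' @return Object of class `pgnet`: a `biomodule` plus the per-gene `stats`
#'   table and the matched `call`. Methods: `print`, `summary`, `plot`
#'   (overlap step function with the hypergeometric null band).
#' @examples
#' sim <- simulate_expression(n_genes = 300, n_case = 10, n_control = 10,
#'                            module_size = 20, rho = 0.8, log2_effect = 2,
#'                            rng_seed = 1)
#' fit <- pgnet(sim$expression, seed_gene = sim$truth$seed_gene,
#'              group_a = "case", group_b = "control", n_top = 50,
#'              B = 200, rng_seed = 1)
#' print(fit)
#' @export
pgnet <- function(x, seed_gene, group_a, group_b, group = NULL, n_top = 150,
                  direction = c("up-positive", "down-negative"), B = 1000,
                  beta = 1 / n_top, rng_seed = NULL, q_method = "bh") {
  direction <- match.arg(direction)
  stats <- gene_rank_stats(x, seed_gene, group_a, group_b, group = group,
                           q_method = q_method)
  fit <- extract_biomodule(stats, n_top = n_top, direction = direction,
                           B = B, beta = beta, rng_seed = rng_seed)
  fit$stats <- stats
  fit$call <- match.call()
  class(fit) <- c("pgnet", "biomodule")
  fit
}

#' @export
print.pgnet <- function(x, ...) {
  cat("Call: ")
  print(x$call)
  NextMethod()
}

#' @method summary pgnet
#' @export
summary.pgnet <- function(object, ...) {
  s <- object$stats
  mod <- s[s$gene_id %in% object$genes, , drop = FALSE]
  out <- list(call = object$call, n_genes = nrow(s),
              seed_gene = object$seed_gene, n_top = object$n_top,
              direction = object$direction, module = object$genes,
              module_stats = mod[order(mod$de_p), , drop = FALSE],
              similarity = object$similarity)
  class(out) <- "summary.pgnet"
  out
}

#' @export
print.summary.pgnet <- function(x, ...) {
  cat("Call: ")
  print(x$call)
  cat(sprintf("universe: %d genes; seed gene: %s; rank threshold: %d (%s)\n",
              x$n_genes, x$seed_gene, x$n_top, x$direction))
  cat(sprintf("biomodule: %d genes\n", length(x$module)))
  cat(sprintf("similarity: top score %.4g (p = %.4g), bottom score %.4g (p = %.4g)\n",
              x$similarity$top$score, x$similarity$top$empirical_p,
              x$similarity$bottom$score, x$similarity$bottom$empirical_p))
  cat("module genes (by DE p-value):\n")
  print(utils::head(x$module_stats, 20), row.names = FALSE, digits = 3)
  if (nrow(x$module_stats) > 20) cat("  ...\n")
  invisible(x)
}

#' Plot the overlap step function of a biomodule fit
#'
#' Draws the observed top-rank (and optionally bottom-rank) overlap O(n)
#' against the hypergeometric null expectation `n^2/N` with its 95% band.
#'
#' @param x a `pgnet` or `biomodule` object.
#' @param bottom also draw the bottom-rank overlap (default TRUE).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @method plot biomodule
#' @export
plot.biomodule <- function(x, bottom = TRUE, ...) {
  cv <- x$curve
  graphics::plot(cv$n, cv$top, type = "s", lwd = 2,
                 xlab = "rank n", ylab = "overlap O(n)",
                 ylim = range(0, cv$top, cv$bottom, cv$hi95), ...)
  graphics::polygon(c(cv$n, rev(cv$n)), c(cv$lo95, rev(cv$hi95)),
                    col = grDevices::adjustcolor("orange", 0.3), border = NA)
  graphics::lines(cv$n, cv$expected, col = "orange", lwd = 2)
  if (bottom) graphics::lines(cv$n, cv$bottom, type = "s", col = "grey50")
  graphics::legend("topleft", bty = "n", lwd = 2,
                   col = c("black", if (bottom) "grey50", "orange"),
                   legend = c("top ranks", if (bottom) "bottom ranks",
                              "null expectation (95% band)"))
  invisible(x)
}

#' @method plot pgnet
#' @export
plot.pgnet <- function(x, ...) plot.biomodule(x, ...)

#' Write a biomodule and its overlap curve
#'
#' Writes the module gene table (with per-gene statistics when available)
#' and the overlap step function as TSV files.
#'
#' @param x a `biomodule` or `pgnet` object.
#' @param path module TSV path; the curve goes to `<path>.curve.tsv`.
#' @return `path`, invisibly.
#' @export
write_biomodule <- function(x, path) {
  stopifnot(inherits(x, "biomodule"))
  tab <- if (!is.null(x$stats))
    x$stats[x$stats$gene_id %in% x$genes, , drop = FALSE]
  else data.frame(gene_id = x$genes, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(x$curve), paste0(path, ".curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
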