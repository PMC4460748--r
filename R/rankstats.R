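## Per-gene statistics feeding biomodule discovery: moderated-t differential
## expression, seed-gene Pearson co-expression, FDR q-values.

#' Moderated two-sample t-statistics
#'
#' Empirical-Bayes moderated t: per-gene residual variances are shrunk
#' toward a common prior. Writing s2_g for the pooled two-sample variance
#' with d_g = n_a + n_b - 2 residual df, the prior (d0, s0^2) is estimated
#' by the method of moments on log s2_g (using the digamma/trigamma moments
#' of log chi-square), the posterior variance is
#' s2_tilde = (d0 s0^2 + d_g s2_g) / (d0 + d_g), and
#' t = logfc / (s_tilde * sqrt(1/n_a + 1/n_b)) on d0 + d_g df. When the
#' observed variances are more dispersed than any chi-square (d0 -> 0) the
#' statistic approaches the ordinary t; when they are less dispersed
#' (d0 -> Inf) all genes share s0^2.
#'
#' @param x an `expression_set` (log2 values) with phenotype labels, or a
#'   plain matrix (then `group` must be given).
#' @param group_a,group_b the two phenotype labels to contrast; `group_a`
#'   is the case group, so `logfc = mean(group_a) - mean(group_b)`.
#' @param group optional per-sample labels when `x` is a matrix.
#' @param prior_df prior degrees of freedom d0: `NULL` (default) estimates
#'   them from the data; a fixed value (e.g. 0 for the ordinary-t limit or
#'   `Inf` for fully pooled variances) overrides the estimate.
#' @return data.frame with one row per gene: `gene_id`, `t`, `logfc`, `p`,
#'   `df_total`, `flagged` (TRUE for genes with zero variance in both
#'   groups, reported with p = 1 when the fold change is also zero).
#' @export
moderated_t <- function(x, group_a, group_b, group = NULL, prior_df = NULL) {
  if (inherits(x, "expression_set")) {
    m <- x$values
    group <- x$phenotype
  } else m <- as.matrix(x)
  if (is.null(group)) .stopf("sample group labels are required")
  ja <- which(group == group_a)
  jb <- which(group == group_b)
  if (length(ja) < 2L || length(jb) < 2L)
    .stopf("each group needs >= 2 samples (got %d and %d)",
           length(ja), length(jb))
  na <- length(ja); nb <- length(jb)
  ma <- rowMeans(m[, ja, drop = FALSE])
  mb <- rowMeans(m[, jb, drop = FALSE])
  logfc <- ma - mb
  ssa <- rowSums((m[, ja, drop = FALSE] - ma)^2)
  ssb <- rowSums((m[, jb, drop = FALSE] - mb)^2)
  dg <- na + nb - 2L
  s2 <- (ssa + ssb) / dg
  sh <- .squeeze_var(s2, dg, prior_df = prior_df)
  se <- sqrt(sh$s2_post * (1 / na + 1 / nb))
  df_total <- dg + sh$d0
  t <- ifelse(se > 0, logfc / se, ifelse(logfc == 0, 0, sign(logfc) * Inf))
  p <- if (is.finite(df_total)) 2 * stats::pt(-abs(t), df = df_total)
  else 2 * stats::pnorm(-abs(t))
  flagged <- s2 == 0
  p[flagged & logfc == 0] <- 1
  data.frame(gene_id = rownames(m), t = t, logfc = logfc, p = p,
             df_total = rep(df_total, length(t)), flagged = flagged,
             row.names = NULL, stringsAsFactors = FALSE)
}

## Moments estimate of the scaled inverse chi-square prior for gene-wise
## variances (d0, s0^2) and the posterior (shrunken) variances.
.squeeze_var <- function(s2, dg, prior_df = NULL) {
  ok <- s2 > 0
  if (!any(ok))
    return(list(d0 = Inf, s0_2 = 0, s2_post = rep(0, length(s2))))
  z <- log(s2[ok])
  e <- z - digamma(dg / 2) + log(dg / 2)
  e_bar <- mean(e)
  n_ok <- length(e)
  if (!is.null(prior_df)) {
    if (prior_df == 0)
      return(list(d0 = 0, s0_2 = exp(e_bar), s2_post = s2))
    if (is.infinite(prior_df))
      return(list(d0 = Inf, s0_2 = exp(e_bar),
                  s2_post = rep(exp(e_bar), length(s2))))
    s0_2 <- exp(e_bar + digamma(prior_df / 2) - log(prior_df / 2))
    return(list(d0 = prior_df, s0_2 = s0_2,
                s2_post = (prior_df * s0_2 + dg * s2) / (prior_df + dg)))
  }
  ev <- if (n_ok > 1L)
    mean((e - e_bar)^2) * n_ok / (n_ok - 1L) - trigamma(dg / 2)
  else -1
  if (is.finite(ev) && ev > 0) {
    d0 <- 2 * .trigamma_inverse(ev)
    s0_2 <- exp(e_bar + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s0_2 + dg * s2) / (d0 + dg)
  } else {
    d0 <- Inf
    s0_2 <- exp(e_bar)
    s2_post <- rep(s0_2, length(s2))
  }
  list(d0 = d0, s0_2 = s0_2, s2_post = s2_post)
}

#' Co-expression with a seed gene
#'
#' Pearson correlation of every gene with the seed gene across all samples,
#' with the p-value from the exact t transform `t = r sqrt((n-2)/(1-r^2))`
#' on n - 2 df. Zero-variance genes get `r = NA`, `p = 1`.
#'
#' @param x an `expression_set` or matrix (log2 values).
#' @param seed_gene gene id present in the matrix.
#' @return data.frame with columns `gene_id`, `r`, `p`; the seed's own row
#'   has `r = 1`.
#' @export
seed_correlation <- function(x, seed_gene) {
  m <- if (inherits(x, "expression_set")) x$values else as.matrix(x)
  if (!seed_gene %in% rownames(m))
    .stopf("seed gene '%s' not found in the expression matrix", seed_gene)
  n <- ncol(m)
  if (n < 3L) .stopf("correlation needs >= 3 samples")
  s <- m[seed_gene, ]
  r <- suppressWarnings(as.vector(stats::cor(t(m), s)))
  r[rownames(m) == seed_gene] <- 1
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(r) >= 1] <- 0
  p[is.na(r)] <- 1
  data.frame(gene_id = rownames(m), r = r, p = p, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' False discovery rate q-values
#'
#' Benjamini-Hochberg q-values, optionally rescaled by Storey's null
#' proportion estimate `pi0 = min(1, mean(p > lambda) / (1 - lambda))` at a
#' fixed `lambda = 0.5`, so Storey q-values are genewise no larger than BH.
#'
#' @param p vector of p-values in \[0, 1\].
#' @param method `"bh"` (default) or `"storey"`.
#' @param lambda tuning point for the Storey pi0 estimate (default 0.5).
#' @return Numeric vector of q-values, same order as `p`.
#' @export
qvalues <- function(p, method = c("bh", "storey"), lambda = 0.5) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) .stopf("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, mean(p > lambda, na.rm = TRUE) / (1 - lambda))
    q <- pmin(1, q * pi0)
  }
  q
}

#' Combined per-gene ranking statistics
#'
#' Computes the two orderable statistics used for biomodule discovery —
#' case-control moderated-t differential expression and Pearson
#' co-expression with a seed gene — together with their p- and q-values.
#'
#' @inheritParams moderated_t
#' @param seed_gene gene id used as the co-expression seed.
#' @param q_method q-value method passed to [qvalues()].
#' @return data.frame of class `ranked_gene_stats` with columns `gene_id`,
#'   `de_stat`, `logfc`, `de_p`, `de_q`, `ce_r`, `ce_p`, `ce_q`.
#' @export
gene_rank_stats <- function(x, seed_gene, group_a, group_b, group = NULL,
                            q_method = "bh") {
  de <- moderated_t(x, group_a, group_b, group = group)
  ce <- seed_correlation(x, seed_gene)
  stopifnot(identical(de$gene_id, ce$gene_id))
  out <- data.frame(gene_id = de$gene_id, de_stat = de$t, logfc = de$logfc,
                    de_p = de$p, de_q = qvalues(de$p, q_method),
                    ce_r = ce$r, ce_p = ce$p, ce_q = qvalues(ce$p, q_method),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "seed_gene") <- seed_gene
  attr(out, "groups") <- c(group_a, group_b)
  class(out) <- c("ranked_gene_stats", "data.frame")
  out
}

#' Select significantly differential genes
#'
#' Applies the joint q-value and fold-change thresholds
#' (default Q < 0.05 and FC >= 2 or <= 0.5, with FC = 2^logfc).
#'
#' @param stats a [gene_rank_stats()] data.frame (needs `gene_id`, `logfc`,
#'   `de_q`).
#' @param q_max q-value threshold (default 0.05).
#' @param fc_min minimum fold change on the natural scale (default 2).
#' @return List with sorted gene id vectors `up` and `down`.
#' @export
select_de_genes <- function(stats, q_max = 0.05, fc_min = 2) {
  fc <- 2^stats$logfc
  up <- stats$gene_id[stats$de_q < q_max & fc >= fc_min]
  down <- stats$gene_id[stats$de_q < q_max & fc <= 1 / fc_min]
  list(up = sort(up), down = sort(down))
}
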