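## Expression-matrix preprocessing: probe collapse, empirical-Bayes batch
## adjustment, IQR filtering. Values are log2-scale intensities throughout.

#' Construct an expression set
#'
#' @param values numeric genes x samples matrix (log2 scale) with gene ids
#'   as rownames and sample ids as colnames.
#' @param phenotype optional per-sample group labels (character/factor),
#'   recycled against columns or named by sample id.
#' @param batch optional per-sample batch labels.
#' @return Object of class `expression_set`: list with `values`,
#'   `phenotype`, `batch`.
#' @export
expression_set <- function(values, phenotype = NULL, batch = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .stopf("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) .stopf("duplicate gene ids")
  if (anyDuplicated(colnames(values))) .stopf("duplicate sample ids")
  if (!all(is.finite(values))) .stopf("expression values must be finite")
  align <- function(v, what) {
    if (is.null(v)) return(NULL)
    v <- stats::setNames(as.character(v),
                         if (!is.null(names(v))) names(v) else colnames(values))
    if (!all(colnames(values) %in% names(v)))
      .stopf("%s labels missing for some samples", what)
    v[colnames(values)]
  }
  structure(list(values = values,
                 phenotype = align(phenotype, "phenotype"),
                 batch = align(batch, "batch")),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression_set: %d genes x %d samples", nrow(x$values),
              ncol(x$values)))
  if (!is.null(x$phenotype))
    cat(sprintf("; groups: %s",
                paste(sprintf("%s=%d", names(table(x$phenotype)),
                              table(x$phenotype)), collapse = ", ")))
  if (!is.null(x$batch))
    cat(sprintf("; %d batch(es)", length(unique(x$batch))))
  cat("\n")
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$values)

#' Read an expression matrix from TSV
#'
#' Expects genes in rows, a header of sample ids, and the gene id in the
#' first column.
#'
#' @param path matrix TSV path.
#' @param sample_sheet optional path to a 3-column TSV
#'   (`sample_id`, `group`, `batch`) attaching phenotype and batch labels.
#' @return An [expression_set()].
#' @export
read_expression_matrix <- function(path, sample_sheet = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  phenotype <- batch <- NULL
  if (!is.null(sample_sheet)) {
    ss <- utils::read.delim(sample_sheet, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "group", "batch") %in% names(ss)))
      .stopf("sample sheet needs columns sample_id, group, batch")
    phenotype <- stats::setNames(ss$group, ss$sample_id)
    batch <- stats::setNames(as.character(ss$batch), ss$sample_id)
  }
  expression_set(m, phenotype = phenotype, batch = batch)
}

#' Write an expression set to TSV
#'
#' @param x an `expression_set`.
#' @param path matrix TSV path.
#' @param sample_sheet optional path for the sample sheet
#'   (`sample_id`, `group`, `batch`).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, sample_sheet = NULL) {
  stopifnot(inherits(x, "expression_set"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sample_sheet)) {
    ss <- data.frame(sample_id = colnames(x$values),
                     group = if (is.null(x$phenotype)) NA else x$phenotype,
                     batch = if (is.null(x$batch)) "b1" else x$batch,
                     stringsAsFactors = FALSE)
    utils::write.table(ss, sample_sheet, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Collapse probes to genes by maximum mean expression
#'
#' For each gene, keeps the single probe with the largest row mean (ties
#' broken by probe id in lexical order); probes without a mapping are
#' dropped.
#'
#' @param probe_matrix numeric probes x samples matrix with probe rownames.
#' @param map data.frame with columns `probe_id`, `gene_id` (many probes to
#'   one gene), or a named character vector probe_id -> gene_id.
#' @param phenotype,batch optional sample labels passed through to the
#'   result.
#' @return An [expression_set()] with one row per mapped gene.
#' @export
collapse_probes <- function(probe_matrix, map, phenotype = NULL, batch = NULL) {
  probe_matrix <- as.matrix(probe_matrix)
  if (is.null(rownames(probe_matrix))) .stopf("probe matrix needs rownames")
  if (is.data.frame(map)) {
    map <- stats::setNames(as.character(map$gene_id), map$probe_id)
  }
  probes <- intersect(rownames(probe_matrix), names(map))
  if (!length(probes)) .stopf("no probes in the matrix are mapped to genes")
  gene_of <- map[probes]
  means <- rowMeans(probe_matrix[probes, , drop = FALSE])
  ord <- order(gene_of, -means, probes, method = "radix")
  keep <- probes[ord][!duplicated(gene_of[ord])]
  out <- probe_matrix[keep, , drop = FALSE]
  rownames(out) <- gene_of[keep]
  expression_set(out, phenotype = phenotype, batch = batch)
}

## Inverse of the trigamma function by Newton iteration (monotone problem).
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

#' Empirical-Bayes batch adjustment
#'
#' Parametric location-scale batch adjustment: per gene, data are
#' standardized against a batch-free fit, per-batch additive effects (gamma)
#' and multiplicative effects (delta^2) are estimated and shrunk toward
#' common priors — normal for gamma, inverse-gamma for delta^2, with prior
#' hyperparameters estimated by the method of moments across genes — and the
#' shrunken effects are removed. With `protect = TRUE` (default) the
#' phenotype is carried as a covariate so genuine group differences are not
#' absorbed into the batch terms; this requires the design not to confound
#' batch with phenotype.
#'
#' Degenerate priors are handled exactly: when the batch effects are
#' identical across genes (prior variance zero) the common effect is removed
#' without shrinkage residue, so a pure constant shift between batches is
#' eliminated to machine precision.
#'
#' @param x an `expression_set` with `batch` labels (and `phenotype` labels
#'   if `protect` is on).
#' @param protect include phenotype as a protected covariate (default TRUE).
#' @param scale adjust multiplicative (variance) batch effects as well as
#'   additive ones (default TRUE).
#' @return An `expression_set` of the same shape with batch effects removed.
#' @export
correct_batches <- function(x, protect = TRUE, scale = TRUE) {
  stopifnot(inherits(x, "expression_set"))
  if (is.null(x$batch)) .stopf("expression set carries no batch labels")
  batch <- factor(x$batch)
  n_batches <- nlevels(batch)
  if (n_batches == 1L) return(x)  # nothing to adjust
  if (any(table(batch) < 2L)) .stopf("every batch needs >= 2 samples")

  Y <- x$values
  n <- ncol(Y)
  Z <- stats::model.matrix(~ 0 + batch)           # n x B one-hot
  if (protect) {
    if (is.null(x$phenotype)) .stopf("protect = TRUE requires phenotype labels")
    ph <- factor(x$phenotype)
    X <- if (nlevels(ph) > 1L) stats::model.matrix(~ ph)[, -1L, drop = FALSE]
    else matrix(0, n, 0)
    if (qr(cbind(Z, X))$rank < ncol(Z) + ncol(X))
      .stopf("batch is confounded with phenotype; effects are inestimable")
  } else {
    X <- matrix(0, n, 0)
  }

  ## per-gene OLS on [batch one-hot | protected covariates]
  W <- cbind(Z, X)
  fit <- t(solve(crossprod(W), crossprod(W, t(Y))))   # genes x (B + q)
  gamma_hat_raw <- fit[, seq_len(n_batches), drop = FALSE]
  cov_fx <- if (ncol(X)) fit[, -seq_len(n_batches), drop = FALSE] %*% t(X)
  else matrix(0, nrow(Y), n)

  ## grand (batch-size weighted) mean and pooled variance of the
  ## batch-and-covariate-free residuals
  nb <- as.numeric(table(batch))
  alpha <- drop(gamma_hat_raw %*% (nb / n))
  resid <- Y - t(W %*% t(fit))
  s2 <- rowSums(resid^2) / (n - qr(W)$rank)
  s2[s2 <= 0] <- min(s2[s2 > 0], 1e-8)
  sd_pool <- sqrt(s2)

  ## standardized data with covariate effects removed
  Zs <- (Y - cov_fx - alpha) / sd_pool

  out <- Zs
  for (b in levels(batch)) {
    j <- which(batch == b)
    g_hat <- rowMeans(Zs[, j, drop = FALSE])
    d_hat <- apply(Zs[, j, drop = FALSE], 1L, stats::var)
    if (!scale) d_hat <- rep(1, length(d_hat))

    ## normal prior on gamma: moments across genes
    g_bar <- mean(g_hat)
    t2 <- stats::var(g_hat)
    ## inverse-gamma prior on delta^2: moments across genes
    d_bar <- mean(d_hat)
    d_var <- stats::var(d_hat)

    nj <- length(j)
    if (!scale || d_var < 1e-12) {
      d_star <- rep(if (scale) d_bar else 1, length(d_hat))
      g_star <- if (t2 < 1e-12) rep(g_bar, length(g_hat)) else
        (t2 * nj * g_hat + d_star * g_bar) / (t2 * nj + d_star)
    } else {
      a_prior <- (2 * d_var + d_bar^2) / d_var
      b_prior <- (d_bar * d_var + d_bar^3) / d_var
      ## joint posterior modes by fixed-point iteration (standard EB scheme)
      g_star <- g_hat
      d_star <- d_hat
      sum2 <- function(g) rowSums((Zs[, j, drop = FALSE] - g)^2)
      for (it in 1:200) {
        g_new <- if (t2 < 1e-12) rep(g_bar, length(g_hat)) else
          (t2 * nj * g_hat + d_star * g_bar) / (t2 * nj + d_star)
        d_new <- (0.5 * sum2(g_new) + b_prior) / (nj / 2 + a_prior - 1)
        if (max(abs(g_new - g_star), abs(d_new - d_star)) < 1e-10) {
          g_star <- g_new; d_star <- d_new; break
        }
        g_star <- g_new; d_star <- d_new
      }
    }
    d_star[d_star <= 0] <- 1e-12
    out[, j] <- (Zs[, j, drop = FALSE] - g_star) /
      if (scale) sqrt(d_star) else 1
  }

  adj <- out * sd_pool + alpha + cov_fx
  expression_set(adj, phenotype = x$phenotype, batch = x$batch)
}

#' Keep the most variable genes by interquartile range
#'
#' Retains the `ceiling(keep_fraction * nrow)` genes with the largest IQR
#' across samples (type-7 linearly interpolated quantiles), ties broken by
#' gene id. The default keeps the most variable half.
#'
#' @param x an `expression_set` with at least 2 samples.
#' @param keep_fraction fraction of genes to keep, in (0, 1] (default 0.5).
#' @return An `expression_set` restricted to the retained genes, original
#'   row order preserved.
#' @export
iqr_filter <- function(x, keep_fraction = 0.5) {
  stopifnot(inherits(x, "expression_set"))
  if (keep_fraction <= 0 || keep_fraction > 1)
    .stopf("keep_fraction must be in (0, 1]")
  if (ncol(x$values) < 2L) .stopf("IQR filtering needs >= 2 samples")
  iqr <- apply(x$values, 1L, stats::IQR, type = 7)
  k <- ceiling(keep_fraction * nrow(x$values))
  ord <- order(-iqr, rownames(x$values), method = "radix")
  keep <- sort(ord[seq_len(k)])
  expression_set(x$values[keep, , drop = FALSE], phenotype = x$phenotype,
                 batch = x$batch)
}
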