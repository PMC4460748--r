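## Seeded synthetic generators for every pipeline input, with ground truth
## attached. All generators are pure functions of (parameters, seed): the
## same call reproduces the same objects bit for bit.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a toy genome annotation
#'
#' Places non-overlapping genes sequentially along chromosomes with
#' exponential intergenic gaps and gamma-distributed gene lengths. Each gene
#' carries 1-3 transcripts (the first spanning the whole gene) with 1-8
#' non-overlapping exons; a fraction of genes is flagged coding. The default
#' density (one gene per ~160 kb) mirrors a mammalian genome.
#'
#' @param n_genes number of genes (default 500).
#' @param n_chroms number of chromosomes (default 3).
#' @param mean_gene_len mean gene length in bp (default 30000).
#' @param mean_gap mean intergenic gap in bp (default 130000).
#' @param coding_fraction fraction of coding genes (default 0.31, the
#'   coding share typical of region-linked gene sets).
#' @param seed RNG seed.
#' @param chrom_length optional fixed chromosome length; an error is raised
#'   if the simulated genes do not fit.
#' @return An [annotation_set()]; attribute `"chrom_lengths"` records the
#'   simulated chromosome extents.
#' @export
simulate_genome <- function(n_genes = 500, n_chroms = 3,
                            mean_gene_len = 30000, mean_gap = 130000,
                            coding_fraction = 0.31, seed = 1,
                            chrom_length = NULL) {
  stopifnot(n_genes >= 1, n_chroms >= 1, mean_gene_len > 0, mean_gap > 0)
  .with_seed(seed, {
    per_chrom <- rep(n_genes %/% n_chroms, n_chroms)
    extra <- n_genes %% n_chroms
    if (extra) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
    genes <- transcripts <- exons <- list()
    gid <- 0L
    chrom_lengths <- stats::setNames(numeric(n_chroms),
                                     paste0("chr", seq_len(n_chroms)))
    for (ci in seq_len(n_chroms)) {
      ch <- paste0("chr", ci)
      cursor <- 0L
      for (k in seq_len(per_chrom[ci])) {
        gid <- gid + 1L
        gap <- max(1000L, as.integer(round(stats::rexp(1, 1 / mean_gap))))
        len <- max(1500L, as.integer(round(stats::rgamma(1, shape = 2,
                                                         scale = mean_gene_len / 2))))
        g_start <- cursor + gap
        g_end <- g_start + len - 1L
        if (!is.null(chrom_length) && g_end > chrom_length)
          .stopf("infeasible packing: %d genes do not fit in %d bp on %s",
                 per_chrom[ci], chrom_length, ch)
        cursor <- g_end
        id <- sprintf("SYNG%05d", gid)
        strand <- sample(c("+", "-"), 1L)
        genes[[gid]] <- data.frame(
          gene_id = id, gene_name = sprintf("gene%d", gid),
          biotype = if (stats::runif(1) < coding_fraction) "coding" else "noncoding",
          chrom = ch, start = g_start, end = g_end, strand = strand,
          stringsAsFactors = FALSE)
        n_tx <- sample.int(3L, 1L)
        for (ti in seq_len(n_tx)) {
          tid <- sprintf("SYNT%05d.%d", gid, ti)
          if (ti == 1L) {
            ts <- g_start; te <- g_end
          } else {
            ts <- g_start + sample.int(max(1L, len %/% 4L), 1L)
            te <- g_end - sample.int(max(1L, len %/% 4L), 1L)
            if (te - ts < 400L) { ts <- g_start; te <- g_end }
          }
          tlen <- te - ts + 1L
          n_ex <- min(sample.int(8L, 1L), max(1L, tlen %/% 400L))
          if (n_ex == 1L) {
            ex <- data.frame(start = ts, end = te)
          } else {
            cuts <- sort(sample(seq.int(ts + 1L, te - 1L), 2L * n_ex - 2L))
            lo <- c(ts, cuts[seq(2L, length(cuts), by = 2L)] + 1L)
            hi <- c(cuts[seq(1L, length(cuts), by = 2L)], te)
            ex <- data.frame(start = lo, end = hi)
          }
          transcripts[[length(transcripts) + 1L]] <- data.frame(
            transcript_id = tid, gene_id = id, chrom = ch,
            start = ts, end = te, strand = strand, stringsAsFactors = FALSE)
          exons[[length(exons) + 1L]] <- data.frame(
            exon_id = sprintf("%s:E%d", tid, seq_len(nrow(ex))),
            transcript_id = tid, gene_id = id, chrom = ch,
            start = ex$start, end = ex$end, stringsAsFactors = FALSE)
        }
      }
      chrom_lengths[ch] <- cursor + mean_gap
    }
    out <- annotation_set(do.call(rbind, genes), do.call(rbind, transcripts),
                          do.call(rbind, exons))
    attr(out, "chrom_lengths") <- chrom_lengths
    out
  })
}

#' Simulate co-occupancy peak sets for two chromatin marks
#'
#' For every planted target gene, a pair of overlapping peaks (one per
#' mark) is placed near the gene's TSS (promoter-biased, always within the
#' search radius). Background peaks are placed uniformly along the
#' chromosomes; a background peak of mark 1 is mirrored by an overlapping
#' mark-2 peak with probability `co_occupancy_rate`, otherwise mark 2
#' receives an independently placed background peak. Defaults model
#' stringent peak calls: a modest number of mark-specific noise peaks with
#' low incidental cross-mark overlap.
#'
#' @param genome an [annotation_set()] (typically from [simulate_genome()]).
#' @param target_genes gene ids to receive co-occurring peaks (must exist
#'   in `genome`).
#' @param n_background_peaks background (noise) peaks per mark (default 25).
#' @param radius search radius the planted peaks must respect (default
#'   150000).
#' @param co_occupancy_rate probability that a background peak co-occurs in
#'   both marks (default 0.1).
#' @param peak_halfwidth peak half-width in bp (default 500).
#' @param seed RNG seed.
#' @return List with `mark1`, `mark2` ([peak_set()]s) and `truth` (list:
#'   `target_genes` and the generator parameters).
#' @export
simulate_peaks <- function(genome, target_genes, n_background_peaks = 25,
                           radius = 150000, co_occupancy_rate = 0.1,
                           peak_halfwidth = 500, seed = 1) {
  stopifnot(inherits(genome, "annotation_set"))
  target_genes <- unique(as.character(target_genes))
  if (!all(target_genes %in% genome$genes$gene_id))
    .stopf("target genes absent from the genome: %s",
           paste(utils::head(setdiff(target_genes, genome$genes$gene_id), 5),
                 collapse = ", "))
  chrom_lengths <- attr(genome, "chrom_lengths")
  if (is.null(chrom_lengths)) {
    mx <- tapply(genome$genes$end, genome$genes$chrom, max)
    chrom_lengths <- stats::setNames(as.numeric(mx) + 100000, names(mx))
  }
  .with_seed(seed, {
    hw <- peak_halfwidth
    mk <- function(ch, ctr) {
      ctr <- pmax(ctr, hw + 1)
      data.frame(chrom = ch, start = as.integer(ctr - hw),
                 end = as.integer(ctr + hw), stringsAsFactors = FALSE)
    }
    p1 <- list(); p2 <- list(); planted <- list()
    ## planted co-occurring peaks at target promoters
    for (gid in target_genes) {
      tx <- genome$transcripts[genome$transcripts$gene_id == gid, ][1L, ]
      tss <- if (tx$strand == "-") tx$end else tx$start
      ctr <- tss + round(stats::rnorm(1, 0, 500))
      ch <- tx$chrom
      a <- mk(ch, ctr)
      b <- mk(ch, ctr + round(stats::rnorm(1, 0, hw / 2)))
      p1[[length(p1) + 1L]] <- a
      p2[[length(p2) + 1L]] <- b
      planted[[length(planted) + 1L]] <- data.frame(
        chrom = ch, start = min(a$start, b$start), end = max(a$end, b$end),
        gene_id = gid, stringsAsFactors = FALSE)
    }
    ## uniform background
    chs <- names(chrom_lengths)
    if (n_background_peaks > 0) {
      for (i in seq_len(n_background_peaks)) {
        ch <- sample(chs, 1L, prob = chrom_lengths / sum(chrom_lengths))
        ctr <- stats::runif(1, hw + 1, chrom_lengths[[ch]] - hw)
        p1[[length(p1) + 1L]] <- mk(ch, ctr)
        if (stats::runif(1) < co_occupancy_rate) {
          p2[[length(p2) + 1L]] <- mk(ch, ctr + round(stats::rnorm(1, 0, hw / 2)))
        } else {
          ch2 <- sample(chs, 1L, prob = chrom_lengths / sum(chrom_lengths))
          p2[[length(p2) + 1L]] <- mk(ch2, stats::runif(1, hw + 1,
                                                        chrom_lengths[[ch2]] - hw))
        }
      }
    }
    d1 <- do.call(rbind, p1); d2 <- do.call(rbind, p2)
    list(mark1 = peak_set(d1$chrom, d1$start, d1$end, label = "mark1"),
         mark2 = peak_set(d2$chrom, d2$start, d2$end, label = "mark2"),
         truth = list(target_genes = target_genes,
                      planted_regions = do.call(rbind, planted),
                      n_background_peaks = n_background_peaks,
                      co_occupancy_rate = co_occupancy_rate,
                      radius = radius, seed = seed))
  })
}

#' Simulate an expression matrix with a planted biomodule
#'
#' Gaussian log2-intensity model (microarray-like). Each sample carries a
#' latent seed signal `z ~ N(0, 1)`; the seed gene is `sigma * z` plus
#' `log2_effect` in cases, module genes are
#' `sigma * (rho * z + sqrt(1 - rho^2) * noise)` plus `log2_effect` in
#' cases, and all other genes are independent `sigma`-scaled noise. Every
#' gene receives its own baseline level (`N(7, 1)`), and optional additive
#' (and multiplicative) batch effects can be layered on top.
#'
#' @param n_genes number of genes (default 2000).
#' @param n_case,n_control group sizes (defaults 28 and 24, the case and
#'   control totals of the motivating cohort).
#' @param module_size number of planted module genes including the seed
#'   (default 40); ignored when `module_genes` is given.
#' @param module_genes optional explicit module gene ids.
#' @param seed_gene optional seed gene id (must belong to the module;
#'   default: the first module gene).
#' @param rho planted correlation of module genes with the seed signal,
#'   in \[0, 1) (default 0.7).
#' @param log2_effect case-group shift on the seed and module genes in
#'   log2 units (default 1.0).
#' @param sigma noise standard deviation (default 1).
#' @param gene_ids optional explicit gene ids (length `n_genes`); default
#'   `G00001..`.
#' @param batch_design optional list describing batch structure:
#'   `n_batches` (default 2), `shift` (additive per-batch offsets),
#'   `scale` (multiplicative per-batch residual scaling, default all 1),
#'   `assignment` (optional explicit per-sample batch labels; default
#'   interleaves batches within each group so batch is not confounded with
#'   phenotype).
#' @param rng_seed RNG seed.
#' @return List with `expression` (an [expression_set()] with phenotype
#'   `"case"`/`"control"` and batch labels when a design is given) and
#'   `truth` (class `synthetic_truth`: planted module, seed gene,
#'   parameters, seed).
#' @export
simulate_expression <- function(n_genes = 2000, n_case = 28, n_control = 24,
                                module_size = 40, module_genes = NULL,
                                seed_gene = NULL, rho = 0.7,
                                log2_effect = 1.0, sigma = 1,
                                batch_design = NULL, rng_seed = 1,
                                gene_ids = NULL) {
  if (rho < 0 || rho >= 1) .stopf("rho must lie in [0, 1)")
  if (is.null(gene_ids)) gene_ids <- sprintf("G%05d", seq_len(n_genes))
  if (length(gene_ids) != n_genes) .stopf("gene_ids must have length n_genes")
  if (is.null(module_genes)) module_genes <- gene_ids[seq_len(module_size)]
  if (!all(module_genes %in% gene_ids)) .stopf("module genes must be gene ids")
  if (is.null(seed_gene)) seed_gene <- module_genes[1L]
  if (!seed_gene %in% module_genes)
    .stopf("the seed gene must belong to the module")
  n <- n_case + n_control
  samples <- sprintf("S%03d", seq_len(n))
  phenotype <- stats::setNames(rep(c("case", "control"), c(n_case, n_control)),
                               samples)
  .with_seed(rng_seed, {
    z <- stats::rnorm(n)
    case <- as.numeric(phenotype == "case")
    vals <- matrix(stats::rnorm(n_genes * n, sd = sigma), n_genes, n,
                   dimnames = list(gene_ids, samples))
    mod_idx <- match(setdiff(module_genes, seed_gene), gene_ids)
    for (i in mod_idx)
      vals[i, ] <- sigma * (rho * z + sqrt(1 - rho^2) * stats::rnorm(n)) +
        log2_effect * case
    vals[seed_gene, ] <- sigma * z + log2_effect * case
    baseline <- stats::rnorm(n_genes, mean = 7, sd = 1)
    vals <- vals + baseline

    batch <- NULL
    if (!is.null(batch_design)) {
      nb <- if (!is.null(batch_design$n_batches)) batch_design$n_batches else 2L
      shift <- if (!is.null(batch_design$shift)) batch_design$shift else
        rep(0, nb)
      scl <- if (!is.null(batch_design$scale)) batch_design$scale else
        rep(1, nb)
      if (!is.null(batch_design$assignment)) {
        batch <- stats::setNames(as.character(batch_design$assignment), samples)
      } else {
        ## interleave batches within each phenotype group
        lab <- paste0("b", seq_len(nb))
        batch <- stats::setNames(
          c(rep_len(lab, n_case), rep_len(lab, n_control)), samples)
      }
      bi <- match(batch, paste0("b", seq_len(nb)))
      for (j in seq_len(n)) {
        mu <- baseline
        vals[, j] <- mu + (vals[, j] - mu) * scl[bi[j]] + shift[bi[j]]
      }
    }
    truth <- structure(list(module_genes = sort(module_genes),
                            seed_gene = seed_gene,
                            params = list(n_genes = n_genes, n_case = n_case,
                                          n_control = n_control, rho = rho,
                                          log2_effect = log2_effect,
                                          sigma = sigma,
                                          batch_design = batch_design),
                            rng_seed = rng_seed),
                       class = "synthetic_truth")
    list(expression = expression_set(vals, phenotype = phenotype,
                                     batch = batch),
         truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d module genes (seed %s), rho = %.2f, log2 effect = %.2f, seed = %d\n",
              length(x$module_genes), x$seed_gene, x$params$rho,
              x$params$log2_effect, x$rng_seed))
  invisible(x)
}

#' Write a complete synthetic fixture directory
#'
#' Generates a coherent set of pipeline inputs — genome annotation, two
#' peak sets with planted co-occupancy at target genes, an expression
#' matrix over the same gene ids with a planted biomodule drawn from the
#' peak targets, a sample sheet, a gene-set collection containing one
#' module-enriched set, and the ground truth — and writes them as plain
#' text files (`genome.gff3`, `mark1.bed`, `mark2.bed`, `expr.tsv`,
#' `samples.tsv`, `sets.gmt`, `truth.json`).
#'
#' @param dir output directory (created if needed).
#' @param n_genes genome and matrix size (default 500).
#' @param n_targets planted co-occupancy target genes (default 50).
#' @param module_size planted biomodule size (default 40), taken from the
#'   peak target genes.
#' @param n_case,n_control expression group sizes (defaults 28 and 24).
#' @param n_sets decoy gene sets in the collection (default 20).
#' @param with_batches add a two-batch design with a +2 shift (default
#'   TRUE).
#' @param seed RNG seed governing every generator.
#' @return Named character vector of written file paths, invisibly;
#'   attribute `"truth"` carries the in-memory truth list.
#' @export
simulate_fixture <- function(dir, n_genes = 500, n_targets = 50,
                             module_size = 40, n_case = 28, n_control = 24,
                             n_sets = 20, with_batches = TRUE, seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  genome <- simulate_genome(n_genes = n_genes, seed = seed)
  gene_ids <- genome$genes$gene_id
  targets <- .with_seed(seed + 1L, sample(gene_ids, n_targets))
  pk <- simulate_peaks(genome, targets, seed = seed + 2L)
  module <- sort(targets[seq_len(min(module_size, n_targets))])
  sim <- simulate_expression(
    n_genes = n_genes, n_case = n_case, n_control = n_control,
    module_genes = module, seed_gene = module[1L],
    batch_design = if (with_batches) list(n_batches = 2, shift = c(0, 2))
    else NULL,
    rng_seed = seed + 3L, gene_ids = gene_ids)
  expr <- sim$expression

  sets <- .with_seed(seed + 4L, {
    s <- lapply(seq_len(n_sets), function(i)
      sample(gene_ids, sample(30:80, 1L)))
    names(s) <- sprintf("RANDOM_SET_%02d", seq_len(n_sets))
    s$PLANTED_MODULE_SET <- unique(c(module,
                                     sample(setdiff(gene_ids, module), 30)))
    s
  })
  collection <- gene_set_collection(sets,
                                    description = rep("synthetic", length(sets)))

  paths <- c(genome = file.path(dir, "genome.gff3"),
             mark1 = file.path(dir, "mark1.bed"),
             mark2 = file.path(dir, "mark2.bed"),
             expr = file.path(dir, "expr.tsv"),
             samples = file.path(dir, "samples.tsv"),
             gmt = file.path(dir, "sets.gmt"),
             truth = file.path(dir, "truth.json"))
  write_gene_models(genome, paths[["genome"]])
  write_peaks(pk$mark1, paths[["mark1"]])
  write_peaks(pk$mark2, paths[["mark2"]])
  write_expression_matrix(expr, paths[["expr"]],
                          sample_sheet = paths[["samples"]])
  write_gmt(collection, paths[["gmt"]])
  truth <- list(target_genes = sort(targets), module_genes = module,
                seed_gene = module[1L], enriched_set = "PLANTED_MODULE_SET",
                seed = seed)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  attr(paths, "truth") <- truth
  invisible(paths)
}
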