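## End-to-end pipeline: peaks -> seq2gene -> expression preprocessing ->
## ranking statistics -> biomodule -> enrichment, with a reproducibility
## manifest.

.default_config <- function() {
  list(radius = 150000, promoter_halfwidth = 2000, n_top = 150,
       permutations = 1000, q_max = 0.05, fc_min = 2,
       enrich_p_max = 0.001, enrich_min_count = 6, keep_fraction = 0.5,
       coding_only = FALSE, nearest_only = FALSE, correct_batch = TRUE,
       protect_phenotype = TRUE, rng_seed = 1)
}

#' Validate a pipeline configuration
#'
#' Fills defaults and checks that every referenced input exists before any
#' computation starts.
#'
#' @param config a named list, or a path to a JSON/YAML file holding one.
#'   Required fields: `mark1`, `mark2` (peak BED files), `gff` (gene
#'   models), `expression` (matrix TSV), `samples` (sample sheet TSV),
#'   `gmt` (gene sets), `seed_gene`, `group_a`, `group_b`, `out_dir`.
#'   Optional fields with defaults: `radius` (150000),
#'   `promoter_halfwidth` (2000), `n_top` (150), `permutations` (1000),
#'   `q_max` (0.05), `fc_min` (2), `enrich_p_max` (0.001),
#'   `enrich_min_count` (6), `keep_fraction` (0.5), `coding_only`,
#'   `nearest_only`, `correct_batch`, `protect_phenotype`, `rng_seed`.
#' @return The completed configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) .stopf("config error: file not found: %s", config)
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        .stopf("config error: YAML config requires the yaml package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(.default_config(), config)
  need <- c("mark1", "mark2", "gff", "expression", "samples", "gmt",
            "seed_gene", "group_a", "group_b", "out_dir")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    .stopf("config error: missing field(s): %s", paste(miss, collapse = ", "))
  for (f in c("mark1", "mark2", "gff", "expression", "samples", "gmt"))
    if (!file.exists(cfg[[f]]))
      .stopf("config error: input '%s' not found: %s", f, cfg[[f]])
  cfg
}

#' Run the full integrative pipeline
#'
#' Executes the stages in order — read and intersect the two peak sets,
#' link co-enriched regions to candidate target genes, preprocess the
#' expression matrix (batch adjustment, IQR filter), compute the ranking
#' statistics, extract the biomodule with its permutation test, and test
#' the module for gene-set enrichment against the restricted background —
#' writing each stage's output plus a manifest into `out_dir`. The seed
#' gene is always retained through the variability filter. A rerun with
#' the same configuration reproduces the same outputs.
#'
#' @param config see [validate_config()].
#' @return Invisibly, a list with the stage results (`regions`,
#'   `seq2gene`, `targets`, `expression`, `fit`, `de_genes`,
#'   `enrichment`) and the `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  regions <- step("peaks", {
    m1 <- read_peaks(cfg$mark1, "bed3", label = "mark1")
    m2 <- read_peaks(cfg$mark2, "bed3", label = "mark2")
    r <- intersect_peaksets(m1, m2)
    write_peaks(r, out("co_enriched.bed"))
    r
  })

  s2g <- step("seq2gene", {
    index <- build_index(read_gene_models(cfg$gff, "gff3"))
    r <- seq2gene(regions, index, promoter_halfwidth = cfg$promoter_halfwidth,
                  radius = cfg$radius, coding_only = cfg$coding_only,
                  nearest_only = cfg$nearest_only)
    write_seq2gene(r, out("links.tsv"))
    r
  })
  targets <- target_genes(s2g)
  writeLines(targets, out("target_genes.txt"))

  expr <- step("expression", {
    x <- read_expression_matrix(cfg$expression, sample_sheet = cfg$samples)
    if (cfg$correct_batch && !is.null(x$batch) &&
        length(unique(x$batch)) > 1L)
      x <- correct_batches(x, protect = cfg$protect_phenotype)
    filtered <- iqr_filter(x, keep_fraction = cfg$keep_fraction)
    if (!cfg$seed_gene %in% rownames(filtered$values)) {
      keep <- union(rownames(filtered$values), cfg$seed_gene)
      filtered <- expression_set(x$values[keep[order(match(keep, rownames(x$values)))], ,
                                          drop = FALSE],
                                 phenotype = x$phenotype, batch = x$batch)
    }
    write_expression_matrix(filtered, out("expr_preprocessed.tsv"))
    filtered
  })

  fit <- step("biomodule", {
    f <- pgnet(expr, seed_gene = cfg$seed_gene, group_a = cfg$group_a,
               group_b = cfg$group_b, n_top = cfg$n_top,
               B = cfg$permutations, rng_seed = cfg$rng_seed)
    utils::write.table(f$stats, out("rank_stats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_biomodule(f, out("biomodule.tsv"))
    f
  })
  de <- select_de_genes(fit$stats, q_max = cfg$q_max, fc_min = cfg$fc_min)

  enr <- step("enrichment", {
    collection <- read_gmt(cfg$gmt)
    e <- enrich(fit$genes, collection, assay_genes = rownames(expr$values),
                p_max = cfg$enrich_p_max, min_count = cfg$enrich_min_count)
    write_enrichment(e, out("enrichment.tsv"))
    write_enrichment(e, out("enrichment_all.tsv"), all = TRUE)
    e
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("biomodules")),
    r_version = R.version.string,
    config = cfg[order(names(cfg))],
    inputs = lapply(cfg[c("mark1", "mark2", "gff", "expression", "samples",
                          "gmt")],
                    function(p) list(path = p,
                                     md5 = unname(tools::md5sum(p)))),
    results = list(n_co_enriched_regions = nrow(regions$peaks),
                   frac_regions_linked = s2g$summary$frac_linked,
                   coding_fraction = s2g$summary$coding_fraction,
                   n_target_genes = length(targets),
                   n_genes_after_filter = nrow(expr$values),
                   module_size = length(fit$genes),
                   similarity_p_top = fit$similarity$top$empirical_p,
                   similarity_p_bottom = fit$similarity$bottom$empirical_p,
                   n_up = length(de$up), n_down = length(de$down),
                   n_enriched_sets = nrow(enr)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(regions = regions, seq2gene = s2g, targets = targets,
                 expression = expr, fit = fit, de_genes = de,
                 enrichment = enr, manifest = manifest))
}
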