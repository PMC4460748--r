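## Gene-set over-representation with the restricted ("true") background:
## only genes present in both the assay and the collection form the
## universe of the 2x2 table.

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (member gene ids; duplicates
#'   within a set are removed).
#' @param description optional character vector of per-set descriptions.
#' @param category optional character vector of per-set categories.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL, category = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    .stopf("gene sets must have unique names")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0L)) .stopf("gene sets must be non-empty")
  nm <- names(sets)
  fill <- function(v) {
    if (is.null(v)) return(stats::setNames(rep(NA_character_, length(nm)), nm))
    stats::setNames(rep_len(as.character(v), length(nm)), nm)
  }
  structure(list(sets = sets, description = fill(description),
                 category = fill(category)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, sizes %d..%d, %d distinct genes\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets)),
              length(unique(unlist(x$sets)))))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a GMT gene-set file
#'
#' GMT lines are tab-separated: set name, description, then member gene
#' ids. Duplicate members within a set are dropped.
#'
#' @param path GMT file path.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) .stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    .stopf("%s: line %d: GMT needs >= 3 tab-separated fields (name, description, members)",
           path, keep[which(nf < 3L)[1L]])
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  gene_set_collection(sets,
                      description = vapply(fields, `[[`, character(1), 2L))
}

#' Write a gene-set collection as GMT
#'
#' @param x a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  desc <- ifelse(is.na(x$description), "na", x$description)
  writeLines(vapply(seq_along(x$sets), function(i) {
    paste(c(names(x$sets)[i], desc[i], x$sets[[i]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Conditional hypergeometric gene-set enrichment
#'
#' Over-representation of a gene module in each set of a collection,
#' conditioned on the restricted background: the universe N of the 2x2
#' table is the intersection of the assay genes with the union of all
#' collection members, and both the module and each set are intersected
#' with that background before testing. The p-value is the upper
#' hypergeometric tail P(X >= a) (identical to the one-sided Fisher exact
#' p on the same table); the odds ratio is `a*d / (b*c)` with the
#' Haldane-Anscombe 0.5 correction applied only when a zero cell occurs
#' (and `Inf` when the table shows perfect association, b = c = 0).
#'
#' @param module character vector of module gene ids (must be measured,
#'   i.e. a subset of `assay_genes`).
#' @param collection a [gene_set_collection()].
#' @param assay_genes character vector of all genes covered by the
#'   experiment.
#' @param p_max significance threshold on the filter statistic
#'   (default 0.001).
#' @param min_count minimum overlap count to report (default 6, i.e.
#'   count > 5).
#' @param filter_on `"p"` (default) filters on the raw hypergeometric p;
#'   `"q"` on the BH q-value.
#' @return Object of class `enrichment_result`: a data.frame (sorted by p)
#'   with columns `set`, `category`, `description`, `size` (full set size),
#'   `size_bg` (background-restricted size K), `count` (overlap a),
#'   `module_size` (m), `background` (N), `p`, `q` (BH across all tested
#'   sets), `odds_ratio`. Attribute `"all"` carries the unfiltered table.
#' @export
enrich <- function(module, collection, assay_genes, p_max = 0.001,
                   min_count = 6, filter_on = c("p", "q")) {
  stopifnot(inherits(collection, "gene_set_collection"))
  filter_on <- match.arg(filter_on)
  module <- unique(as.character(module))
  assay_genes <- unique(as.character(assay_genes))
  if (!all(module %in% assay_genes))
    .stopf("module genes must be a subset of the assay genes")
  background <- intersect(assay_genes, unique(unlist(collection$sets)))
  N <- length(background)
  if (N == 0L) .stopf("empty background: no assay gene appears in the collection")
  mod_bg <- intersect(module, background)
  m <- length(mod_bg)

  rows <- lapply(names(collection$sets), function(nm) {
    members <- collection$sets[[nm]]
    K <- length(intersect(members, background))
    a <- length(intersect(mod_bg, members))
    p <- stats::phyper(a - 1, K, N - K, m, lower.tail = FALSE)
    b <- K - a; cc <- m - a; d <- N - K - m + a
    or <- if (b == 0 && cc == 0) Inf
    else if (a == 0 || b == 0 || cc == 0 || d == 0)
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    else (a * d) / (b * cc)
    data.frame(set = nm, category = collection$category[[nm]],
               description = collection$description[[nm]],
               size = length(members), size_bg = K, count = a,
               module_size = m, background = N, p = p, odds_ratio = or,
               stringsAsFactors = FALSE)
  })
  all_res <- do.call(rbind, rows)
  all_res$q <- qvalues(all_res$p, method = "bh")
  all_res <- all_res[order(all_res$p, all_res$set, method = "radix"), ,
                     drop = FALSE]
  rownames(all_res) <- NULL
  stat <- if (filter_on == "p") all_res$p else all_res$q
  out <- all_res[stat <= p_max & all_res$count >= min_count, , drop = FALSE]
  rownames(out) <- NULL
  out <- out[, c("set", "category", "description", "size", "size_bg",
                 "count", "module_size", "background", "p", "q",
                 "odds_ratio")]
  attr(out, "all") <- all_res
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: %d set(s) pass the threshold (of %d tested; background N = %d)\n",
              nrow(x), nrow(attr(x, "all")),
              if (nrow(attr(x, "all"))) attr(x, "all")$background[1L] else 0L))
  if (nrow(x))
    print(as.data.frame(x)[, c("set", "size_bg", "count", "p", "q",
                               "odds_ratio")],
          row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write an enrichment table as TSV
#'
#' @param x an `enrichment_result`.
#' @param path output path.
#' @param all write the unfiltered table instead of the thresholded one.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(x, path, all = FALSE) {
  stopifnot(inherits(x, "enrichment_result"))
  tab <- if (all) attr(x, "all") else as.data.frame(x)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
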