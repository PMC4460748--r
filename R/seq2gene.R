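## seq2gene: link genomic regions to candidate target genes on both sides.
##
## Each region is classified against the annotation index. Per gene only the
## highest-priority category is kept (exonic > promoter > intronic >
## intergenic); intergenic links are emitted for genes on both sides of the
## region within the search radius, regardless of gene strand — the
## long-range regulation rationale: enhancers act over large distances and
## independently of orientation, and several may target the same gene.

.CATEGORIES <- c("exonic", "promoter", "intronic", "intergenic")

#' Classify one region against the annotation
#'
#' Links a genomic region to every gene within `radius` bp on either side
#' and assigns each link the highest-priority category that applies:
#' `exonic` (region overlaps an exon of the gene), `promoter` (region
#' overlaps the window of `promoter_halfwidth` bp around a transcript TSS),
#' `intronic` (region inside the gene span but touching no exon or
#' promoter), `intergenic` (non-overlapping gene within the radius).
#'
#' @param index an [build_index()] annotation index.
#' @param chrom,start,end the region (1-based inclusive).
#' @param promoter_halfwidth half-width in bp of the promoter window around
#'   each transcript TSS (default 2000, i.e. TSS +/- 2 kb).
#' @param radius search radius in bp on each side (default 150000).
#' @param nearest_only if `TRUE`, intergenic links are restricted to the
#'   nearest gene(s) instead of all genes within the radius.
#' @return data.frame with one row per linked gene: `gene_id`, `gene_name`,
#'   `biotype`, `category`, `distance` (signed bp, 0 for overlap), ordered
#'   by gene start then gene id.
#' @export
classify_region <- function(index, chrom, start, end,
                            promoter_halfwidth = 2000, radius = 150000,
                            nearest_only = FALSE) {
  stopifnot(inherits(index, "annotation_index"))
  if (promoter_halfwidth < 0) .stopf("promoter_halfwidth must be >= 0")
  if (radius < 0) .stopf("radius must be >= 0")
  cand <- query_radius(index, chrom, start, end, radius = radius)
  empty <- data.frame(gene_id = character(0), gene_name = character(0),
                      biotype = character(0), category = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(cand)) return(empty)

  g <- index$set$genes
  gi <- match(cand$gene_id, g$gene_id)
  category <- character(nrow(cand))

  ## exon hits for the whole region, grouped by gene
  ex_ids <- query_overlaps(index, chrom, start, end, level = "exon")
  ex_genes <- unique(index$set$exons$gene_id[
    match(ex_ids, index$set$exons$exon_id)])

  for (k in seq_len(nrow(cand))) {
    gid <- cand$gene_id[k]
    if (gid %in% ex_genes) {
      category[k] <- "exonic"
      next
    }
    tx <- index$tx_by_gene[[gid]]
    pr_lo <- tx$tss - promoter_halfwidth
    pr_hi <- tx$tss + promoter_halfwidth
    if (any(pr_lo <= end & pr_hi >= start)) {
      category[k] <- "promoter"
    } else if (cand$distance[k] == 0) {
      category[k] <- "intronic"
    } else {
      category[k] <- "intergenic"
    }
  }

  out <- data.frame(gene_id = cand$gene_id,
                    gene_name = g$gene_name[gi],
                    biotype = g$biotype[gi],
                    category = category,
                    distance = cand$distance,
                    stringsAsFactors = FALSE)
  if (nearest_only) {
    inter <- out$category == "intergenic"
    if (any(inter)) {
      dmin <- min(abs(out$distance[inter]))
      out <- out[!inter | abs(out$distance) == dmin, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

#' Link a set of regions to candidate target genes
#'
#' Applies [classify_region()] to every region of a peak set (typically the
#' co-enriched regions from [intersect_peaksets()]) and summarises the
#' mapping: the fraction of regions with at least one linked gene, the
#' fraction of distinct linked genes that are coding, and per-category link
#' counts. Summary fractions are computed over all links before any
#' `coding_only` filtering.
#'
#' @param regions a [peak_set()].
#' @param index an annotation index.
#' @inheritParams classify_region
#' @param coding_only if `TRUE`, links to noncoding genes are dropped from
#'   the returned link table (after the summary is computed).
#' @return Object of class `seq2gene`: list with `links` (data.frame:
#'   `chrom`, `start`, `end`, `region`, `gene_id`, `gene_name`, `category`,
#'   `distance`, `biotype`), `summary` (list: `n_regions`, `n_linked`,
#'   `frac_linked`, `coding_fraction`, `category_counts`) and `params`.
#' @export
seq2gene <- function(regions, index, promoter_halfwidth = 2000,
                     radius = 150000, coding_only = FALSE,
                     nearest_only = FALSE) {
  stopifnot(inherits(regions, "peak_set"), inherits(index, "annotation_index"))
  if (nrow(index$set$genes) == 0L) .stopf("empty annotation")
  p <- regions$peaks
  if (!nrow(p)) .stopf("empty region set")
  res <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    li <- classify_region(index, p$chrom[i], p$start[i], p$end[i],
                          promoter_halfwidth = promoter_halfwidth,
                          radius = radius, nearest_only = nearest_only)
    if (nrow(li)) {
      li$chrom <- p$chrom[i]; li$start <- p$start[i]; li$end <- p$end[i]
      li$region <- sprintf("%s:%d-%d", p$chrom[i], p$start[i], p$end[i])
      res[[i]] <- li
    }
  }
  linked <- !vapply(res, is.null, logical(1))
  links <- if (any(linked)) do.call(rbind, res[linked]) else
    data.frame(gene_id = character(0), gene_name = character(0),
               biotype = character(0), category = character(0),
               distance = numeric(0), chrom = character(0),
               start = integer(0), end = integer(0), region = character(0),
               stringsAsFactors = FALSE)
  links <- links[, c("chrom", "start", "end", "region", "gene_id",
                     "gene_name", "category", "distance", "biotype")]
  rownames(links) <- NULL

  linked_genes <- unique(links$gene_id)
  coding_fraction <- if (length(linked_genes))
    mean(index$set$genes$biotype[match(linked_genes,
                                       index$set$genes$gene_id)] == "coding")
  else NA_real_
  summary <- list(
    n_regions = nrow(p),
    n_linked = sum(linked),
    frac_linked = sum(linked) / nrow(p),
    n_genes = length(linked_genes),
    coding_fraction = coding_fraction,
    category_counts = vapply(.CATEGORIES,
                             function(cc) sum(links$category == cc),
                             integer(1))
  )
  if (coding_only) links <- links[links$biotype == "coding", , drop = FALSE]
  rownames(links) <- NULL
  structure(list(links = links, summary = summary,
                 params = list(promoter_halfwidth = promoter_halfwidth,
                               radius = radius, coding_only = coding_only,
                               nearest_only = nearest_only)),
            class = "seq2gene")
}

#' @export
print.seq2gene <- function(x, ...) {
  s <- x$summary
  cat(sprintf("seq2gene: %d regions, %.1f%% linked to %d genes (%.1f%% coding)\n",
              s$n_regions, 100 * s$frac_linked, s$n_genes,
              100 * s$coding_fraction))
  cat("  links by category:",
      paste(sprintf("%s=%d", names(s$category_counts), s$category_counts),
            collapse = ", "), "\n")
  invisible(x)
}

#' @method summary seq2gene
#' @export
summary.seq2gene <- function(object, ...) {
  out <- object$summary
  out$params <- object$params
  class(out) <- "summary.seq2gene"
  out
}

#' @export
print.summary.seq2gene <- function(x, ...) {
  cat(sprintf("regions: %d; linked: %d (%.3f)\n", x$n_regions, x$n_linked,
              x$frac_linked))
  cat(sprintf("distinct linked genes: %d; coding fraction: %.3f\n",
              x$n_genes, x$coding_fraction))
  cat("category counts:\n")
  print(x$category_counts)
  cat(sprintf("radius=%d bp, promoter halfwidth=%d bp\n",
              x$params$radius, x$params$promoter_halfwidth))
  invisible(x)
}

#' Candidate target genes of a seq2gene result
#'
#' @param x a `seq2gene` object.
#' @return Sorted character vector of distinct linked gene ids.
#' @export
target_genes <- function(x) {
  stopifnot(inherits(x, "seq2gene"))
  sort(unique(x$links$gene_id))
}

#' Write seq2gene links and summary
#'
#' Writes the link table as TSV and the mapping summary as JSON.
#'
#' @param x a `seq2gene` object.
#' @param path output TSV path; the summary goes to `<path>.summary.json`.
#' @return `path`, invisibly.
#' @export
write_seq2gene <- function(x, path) {
  stopifnot(inherits(x, "seq2gene"))
  utils::write.table(x$links, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  s <- x$summary
  s$category_counts <- as.list(s$category_counts)
  jsonlite::write_json(s, paste0(path, ".summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
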