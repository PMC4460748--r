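## Independent brute-force oracles used to validate the bisection index,
## the segment intersection and the region classifier. These deliberately
## use naive linear scans / pairwise loops, not the package's search paths.

## linear scan for features overlapping [qs, qe]
oracle_overlaps <- function(set, level, chrom, qs, qe) {
  tab <- switch(level,
                gene = data.frame(id = set$genes$gene_id, chrom = set$genes$chrom,
                                  start = set$genes$start, end = set$genes$end),
                transcript = data.frame(id = set$transcripts$transcript_id,
                                        chrom = set$transcripts$chrom,
                                        start = set$transcripts$start,
                                        end = set$transcripts$end),
                exon = data.frame(id = set$exons$exon_id, chrom = set$exons$chrom,
                                  start = set$exons$start, end = set$exons$end))
  hit <- tab$chrom == chrom & tab$start <= qe & tab$end >= qs
  h <- tab[hit, , drop = FALSE]
  h$id[order(h$start, h$id, method = "radix")]
}

## linear scan for genes within radius, with signed reference-strand distance
oracle_radius <- function(set, chrom, qs, qe, radius) {
  g <- set$genes[set$genes$chrom == chrom, , drop = FALSE]
  d <- ifelse(g$end < qs, g$end - qs, ifelse(g$start > qe, g$start - qe, 0))
  keep <- abs(d) <= radius
  out <- data.frame(gene_id = g$gene_id[keep], distance = d[keep])
  out[order(g$start[keep], out$gene_id, method = "radix"), , drop = FALSE]
}

## O(n*m) pairwise segment intersection of two peak sets, merged
oracle_intersect <- function(a, b) {
  pa <- a$peaks; pb <- b$peaks
  segs <- list()
  for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(pb))) {
    if (pa$chrom[i] != pb$chrom[j]) next
    s <- max(pa$start[i], pb$start[j]); e <- min(pa$end[i], pb$end[j])
    if (s <= e) segs[[length(segs) + 1L]] <- data.frame(chrom = pa$chrom[i],
                                                       start = s, end = e)
  }
  if (!length(segs)) return(data.frame(chrom = character(0), start = integer(0),
                                       end = integer(0)))
  d <- do.call(rbind, segs)
  d <- d[order(d$chrom, d$start, d$end), , drop = FALSE]
  out <- d[1, , drop = FALSE]
  for (k in seq_len(nrow(d))[-1]) {
    last <- nrow(out)
    if (d$chrom[k] == out$chrom[last] && d$start[k] <= out$end[last] + 1L) {
      out$end[last] <- max(out$end[last], d$end[k])
    } else out <- rbind(out, d[k, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

## exhaustive per-gene region classifier (mirrors the documented category
## priority without any index machinery)
oracle_classify <- function(set, chrom, qs, qe, hw, radius) {
  res <- list()
  for (k in seq_len(nrow(set$genes))) {
    g <- set$genes[k, ]
    if (g$chrom != chrom) next
    d <- if (g$end < qs) g$end - qs else if (g$start > qe) g$start - qe else 0
    if (abs(d) > radius) next
    ex <- set$exons[set$exons$gene_id == g$gene_id, , drop = FALSE]
    tx <- set$transcripts[set$transcripts$gene_id == g$gene_id, , drop = FALSE]
    cat_ <- if (any(ex$start <= qe & ex$end >= qs)) "exonic"
    else if (any(tx$tss - hw <= qe & tx$tss + hw >= qs)) "promoter"
    else if (d == 0) "intronic" else "intergenic"
    res[[length(res) + 1L]] <- data.frame(gene_id = g$gene_id, category = cat_,
                                          distance = d, g_start = g$start,
                                          stringsAsFactors = FALSE)
  }
  if (!length(res)) return(data.frame(gene_id = character(0),
                                      category = character(0),
                                      distance = numeric(0)))
  d <- do.call(rbind, res)
  d <- d[order(d$g_start, d$gene_id, method = "radix"), c("gene_id", "category",
                                                          "distance")]
  rownames(d) <- NULL
  d
}

## tiny hand-written annotation: two genes on chr1, one on chr2
toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    gene_name = c("alpha", "beta", "gamma"),
    biotype = c("coding", "noncoding", "coding"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000L, 50000L, 2000L),
    end = c(9000L, 60000L, 8000L),
    strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  transcripts <- data.frame(
    transcript_id = c("tA1", "tB1", "tC1"),
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000L, 50000L, 2000L),
    end = c(9000L, 60000L, 8000L),
    strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  exons <- data.frame(
    exon_id = c("eA1", "eA2", "eB1", "eC1"),
    transcript_id = c("tA1", "tA1", "tB1", "tC1"),
    gene_id = c("gA", "gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(1000L, 6000L, 50000L, 2000L),
    end = c(2000L, 9000L, 60000L, 8000L), stringsAsFactors = FALSE)
  annotation_set(genes, transcripts, exons)
}

## build genes realizing a 2x2 table (N, K, m, a) and run enrich on it
enrich_p_for_table <- function(N, K, m, a) {
  genes <- sprintf("g%03d", seq_len(N))
  set_k <- genes[seq_len(K)]
  module <- c(genes[seq_len(a)],
              if (m > a) genes[K + seq_len(m - a)])
  col <- gene_set_collection(list(S = set_k, FILL = genes))
  res <- enrich(module, col, genes, p_max = 1, min_count = 0)
  res$p[res$set == "S"]
}

## random query intervals over a simulated genome
random_queries <- function(set, n, seed) {
  set.seed(seed)
  chroms <- unique(set$genes$chrom)
  span_max <- max(set$genes$end)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = s <- sample.int(span_max, n, replace = TRUE),
             end = s + sample.int(50000L, n, replace = TRUE))
}
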