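## Gene-model parsing and the bisection-searchable annotation index.
##
## All coordinates inside the package are 1-based inclusive (the GFF
## convention used by ENSEMBL annotation). BED input is converted on read.

#' Construct an annotation set
#'
#' Bundles gene, transcript and exon tables into a validated annotation set.
#' Most users will call [read_gene_models()] or [simulate_genome()] instead
#' of this constructor.
#'
#' @param genes data.frame with columns `gene_id`, `gene_name`, `biotype`
#'   (`"coding"` or `"noncoding"`), `chrom`, `start`, `end`, `strand`.
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`.
#' @param exons data.frame with columns `exon_id`, `transcript_id`,
#'   `gene_id`, `chrom`, `start`, `end`.
#'
#' @details The transcription start site of each transcript is derived from
#'   its strand: the span start on `+` (and unstranded) transcripts, the span
#'   end on `-`. Validation enforces: unique gene ids, every gene having at
#'   least one transcript, every transcript at least one exon, exons inside
#'   their transcript span and non-overlapping, and gene spans covering their
#'   transcripts.
#'
#' @return An object of class `annotation_set`: a list with elements
#'   `genes`, `transcripts`, `exons` (exons sorted within transcript).
#' @export
annotation_set <- function(genes, transcripts, exons) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)

  .check_intervals(genes$chrom, genes$start, genes$end, "gene")
  .check_intervals(transcripts$chrom, transcripts$start, transcripts$end,
                   "transcript")
  .check_intervals(exons$chrom, exons$start, exons$end, "exon")

  if (anyDuplicated(genes$gene_id))
    .stopf("duplicate gene_id in annotation: %s",
           paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
                 collapse = ", "))
  if (anyDuplicated(transcripts$transcript_id))
    .stopf("duplicate transcript_id in annotation")
  if (!all(transcripts$gene_id %in% genes$gene_id))
    .stopf("transcript references unknown gene_id")
  if (!all(exons$transcript_id %in% transcripts$transcript_id))
    .stopf("exon references unknown transcript_id")

  if (is.null(genes$gene_name)) genes$gene_name <- genes$gene_id
  if (is.null(genes$biotype)) genes$biotype <- "coding"
  genes$biotype <- ifelse(genes$biotype %in% c("coding", "protein_coding"),
                          "coding", "noncoding")
  if (is.null(exons$exon_id))
    exons$exon_id <- paste0(exons$transcript_id, ":E",
                            stats::ave(seq_len(nrow(exons)),
                                       exons$transcript_id, FUN = seq_along))
  if (is.null(exons$gene_id))
    exons$gene_id <- transcripts$gene_id[match(exons$transcript_id,
                                               transcripts$transcript_id)]

  ## strand-aware TSS
  transcripts$tss <- ifelse(transcripts$strand == "-",
                            transcripts$end, transcripts$start)

  ## every gene >= 1 transcript, every transcript >= 1 exon
  orphan_g <- setdiff(genes$gene_id, transcripts$gene_id)
  if (length(orphan_g))
    .stopf("gene(s) without transcripts: %s",
           paste(utils::head(orphan_g, 5), collapse = ", "))
  orphan_t <- setdiff(transcripts$transcript_id, exons$transcript_id)
  if (length(orphan_t))
    .stopf("transcript(s) without exons: %s",
           paste(utils::head(orphan_t, 5), collapse = ", "))

  ## exon containment and non-overlap within transcript
  tx_of <- match(exons$transcript_id, transcripts$transcript_id)
  bad <- exons$start < transcripts$start[tx_of] |
    exons$end > transcripts$end[tx_of]
  if (any(bad))
    .stopf("exon outside its transcript span: %s",
           paste(utils::head(exons$exon_id[bad], 5), collapse = ", "))
  exons <- exons[.order_by(exons$transcript_id, exons$start, id = exons$exon_id), ,
                 drop = FALSE]
  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (ii in by_tx) {
    if (length(ii) > 1L &&
        any(exons$start[ii][-1L] <= exons$end[ii][-length(ii)]))
      .stopf("overlapping exons within transcript %s",
             exons$transcript_id[ii[1L]])
  }

  ## gene span must cover all of its transcripts
  g_of <- match(transcripts$gene_id, genes$gene_id)
  bad <- transcripts$start < genes$start[g_of] |
    transcripts$end > genes$end[g_of]
  if (any(bad))
    .stopf("transcript outside its gene span: %s",
           paste(utils::head(transcripts$transcript_id[bad], 5), collapse = ", "))

  rownames(genes) <- rownames(transcripts) <- rownames(exons) <- NULL
  structure(list(genes = genes, transcripts = transcripts, exons = exons),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d genes (%d coding), %d transcripts, %d exons on %d chromosome(s)\n",
              nrow(x$genes), sum(x$genes$biotype == "coding"),
              nrow(x$transcripts), nrow(x$exons),
              length(unique(x$genes$chrom))))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Readers / writers

#' Read gene models from GFF3 or GTF
#'
#' Parses an ENSEMBL-style annotation file into an [annotation_set()].
#' Attribute keys `ID`/`Parent` (GFF3) or `gene_id`/`transcript_id` (GTF) are
#' used to link features; `gene_biotype` or `biotype` supply the biotype
#' (`protein_coding` is mapped to `"coding"`, everything else to
#' `"noncoding"`). When a file carries no explicit `gene` (or transcript)
#' rows, spans are derived as the union of child features.
#'
#' @param path path to the annotation file.
#' @param fmt `"gff3"` or `"gtf"`.
#' @return An `annotation_set`.
#' @export
read_gene_models <- function(path, fmt = c("gff3", "gtf")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) .stopf("annotation file not found: %s", path)

  ## cheap structural pre-check so malformed lines are reported by number
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L))
    .stopf("%s: line %d: expected 9 tab-separated fields, found %d",
           path, body[which(nf != 9L)[1L]], nf[nf != 9L][1L])

  gr <- rtracklayer::import(path, format = if (fmt == "gff3") "gff3" else "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$strand[!df$strand %in% c("+", "-")] <- "."
  df$type <- as.character(df$type)

  first_chr <- function(x) {
    if (is.null(x)) return(NULL)
    vapply(x, function(v) if (length(v)) as.character(v[[1L]]) else NA_character_,
           character(1))
  }
  bio_col <- if (!is.null(df$gene_biotype)) df$gene_biotype else df$biotype

  if (fmt == "gff3") {
    ids <- as.character(df$ID)
    parents <- first_chr(df$Parent)
    gene_rows <- df$type %in% c("gene")
    tx_rows <- df$type %in% c("mRNA", "transcript")
    ex_rows <- df$type == "exon"
    genes <- data.frame(gene_id = ids[gene_rows],
                        gene_name = if (!is.null(df$Name))
                          ifelse(is.na(df$Name[gene_rows]), ids[gene_rows],
                                 df$Name[gene_rows]) else ids[gene_rows],
                        biotype = if (!is.null(bio_col))
                          ifelse(is.na(bio_col[gene_rows]), "coding",
                                 bio_col[gene_rows]) else "coding",
                        chrom = df$seqnames[gene_rows],
                        start = df$start[gene_rows], end = df$end[gene_rows],
                        strand = df$strand[gene_rows],
                        stringsAsFactors = FALSE)
    transcripts <- data.frame(transcript_id = ids[tx_rows],
                              gene_id = parents[tx_rows],
                              chrom = df$seqnames[tx_rows],
                              start = df$start[tx_rows], end = df$end[tx_rows],
                              strand = df$strand[tx_rows],
                              stringsAsFactors = FALSE)
    exons <- data.frame(transcript_id = parents[ex_rows],
                        chrom = df$seqnames[ex_rows],
                        start = df$start[ex_rows], end = df$end[ex_rows],
                        stringsAsFactors = FALSE)
    if (!is.null(df$ID) && any(!is.na(ids[ex_rows])))
      exons$exon_id <- ids[ex_rows]
    exons$gene_id <- transcripts$gene_id[match(exons$transcript_id,
                                               transcripts$transcript_id)]
  } else {
    gene_rows <- df$type == "gene"
    tx_rows <- df$type %in% c("transcript", "mRNA")
    ex_rows <- df$type == "exon"
    exons <- data.frame(transcript_id = df$transcript_id[ex_rows],
                        gene_id = df$gene_id[ex_rows],
                        chrom = df$seqnames[ex_rows],
                        start = df$start[ex_rows], end = df$end[ex_rows],
                        stringsAsFactors = FALSE)
    if (any(tx_rows)) {
      transcripts <- data.frame(transcript_id = df$transcript_id[tx_rows],
                                gene_id = df$gene_id[tx_rows],
                                chrom = df$seqnames[tx_rows],
                                start = df$start[tx_rows],
                                end = df$end[tx_rows],
                                strand = df$strand[tx_rows],
                                stringsAsFactors = FALSE)
    } else {
      transcripts <- do.call(rbind, lapply(split(exons, exons$transcript_id),
        function(e) data.frame(transcript_id = e$transcript_id[1L],
                               gene_id = e$gene_id[1L], chrom = e$chrom[1L],
                               start = min(e$start), end = max(e$end),
                               strand = ".", stringsAsFactors = FALSE)))
      str_map <- df$strand[ex_rows][match(transcripts$transcript_id,
                                          df$transcript_id[ex_rows])]
      transcripts$strand <- str_map
    }
    if (any(gene_rows)) {
      genes <- data.frame(gene_id = df$gene_id[gene_rows],
                          gene_name = if (!is.null(df$gene_name))
                            ifelse(is.na(df$gene_name[gene_rows]),
                                   df$gene_id[gene_rows],
                                   df$gene_name[gene_rows])
                          else df$gene_id[gene_rows],
                          biotype = if (!is.null(bio_col))
                            ifelse(is.na(bio_col[gene_rows]), "coding",
                                   bio_col[gene_rows]) else "coding",
                          chrom = df$seqnames[gene_rows],
                          start = df$start[gene_rows], end = df$end[gene_rows],
                          strand = df$strand[gene_rows],
                          stringsAsFactors = FALSE)
    } else {
      genes <- do.call(rbind, lapply(split(transcripts, transcripts$gene_id),
        function(t) data.frame(gene_id = t$gene_id[1L],
                               gene_name = t$gene_id[1L], biotype = "coding",
                               chrom = t$chrom[1L], start = min(t$start),
                               end = max(t$end), strand = t$strand[1L],
                               stringsAsFactors = FALSE)))
      if (!is.null(bio_col)) {
        bm <- bio_col[match(genes$gene_id, df$gene_id)]
        genes$biotype <- ifelse(is.na(bm), "coding", bm)
      }
    }
  }
  annotation_set(genes, transcripts, exons)
}

#' Write gene models as GFF3
#'
#' Emits gene/transcript/exon records with `ID`/`Parent` links,
#' `gene_biotype` and `Name` attributes, suitable for re-reading with
#' [read_gene_models()].
#'
#' @param x an `annotation_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(x, path) {
  stopifnot(inherits(x, "annotation_set"))
  g <- x$genes; t <- x$transcripts; e <- x$exons
  gl <- sprintf("%s\tbiomodules\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;gene_biotype=%s",
                g$chrom, g$start, g$end, g$strand, g$gene_id, g$gene_name,
                ifelse(g$biotype == "coding", "protein_coding", "noncoding"))
  tl <- sprintf("%s\tbiomodules\ttranscript\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                t$chrom, t$start, t$end, t$strand, t$transcript_id, t$gene_id)
  tx_strand <- t$strand[match(e$transcript_id, t$transcript_id)]
  el <- sprintf("%s\tbiomodules\texon\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                e$chrom, e$start, e$end, tx_strand, e$exon_id, e$transcript_id)
  ## group children under parents for readability
  ord <- .order_by(g$chrom, g$start, id = g$gene_id)
  out <- c("##gff-version 3")
  for (i in ord) {
    gid <- g$gene_id[i]
    out <- c(out, gl[i], tl[t$gene_id == gid], el[e$gene_id == gid])
  }
  writeLines(out, path)
  invisible(path)
}

#' Write flat exon and transcript lookup tables
#'
#' Writes the two TSV tables used for bisection search (`transcript.table`:
#' one row per transcript with its TSS; `exon.table`: one row per exon),
#' both keyed by stable feature ids.
#'
#' @param x an `annotation_set`.
#' @param dir output directory (created if missing).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_annotation_tables <- function(x, dir) {
  stopifnot(inherits(x, "annotation_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tpath <- file.path(dir, "transcript.table")
  epath <- file.path(dir, "exon.table")
  utils::write.table(x$transcripts[, c("transcript_id", "gene_id", "chrom",
                                       "start", "end", "strand", "tss")],
                     tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$exons[, c("exon_id", "transcript_id", "gene_id",
                                 "chrom", "start", "end")],
                     epath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(transcript.table = tpath, exon.table = epath))
}

## ---------------------------------------------------------------------------
## Bisection index

## One searchable table: features of one kind on one chromosome, sorted by
## (start, id), with the running maximum of ends enabling a two-sided
## bisection (findInterval) overlap query.
.make_tab <- function(chrom, start, end, id) {
  out <- list()
  for (ch in sort(unique(chrom))) {
    k <- which(chrom == ch)
    o <- k[.order_by(start[k], id = id[k])]
    out[[ch]] <- list(start = start[o], end = end[o], id = id[o],
                      cmax = cummax(end[o]))
  }
  out
}

## All features overlapping [qs, qe] (closed intervals, shared bp >= 1).
## Bisection: starts sorted ascending -> last candidate via findInterval on
## qe; cmax nondecreasing -> first candidate whose running-max end reaches qs.
.tab_query <- function(tab, ch, qs, qe) {
  t <- tab[[ch]]
  if (is.null(t)) return(integer(0))
  hi <- findInterval(qe, t$start)
  if (hi == 0L) return(integer(0))
  lo <- findInterval(qs - 1L, t$cmax) + 1L
  if (lo > hi) return(integer(0))
  cand <- lo:hi
  cand[t$end[cand] >= qs]
}

#' Build a bisection-searchable annotation index
#'
#' Creates per-chromosome sorted arrays of gene, transcript and exon
#' intervals, queried by binary search. Query results are identical to a
#' linear scan over the full tables.
#'
#' @param x an `annotation_set`.
#' @return An object of class `annotation_index`.
#' @export
build_index <- function(x) {
  stopifnot(inherits(x, "annotation_set"))
  if (nrow(x$genes) == 0L) .stopf("cannot index an empty annotation set")
  if (anyDuplicated(x$genes$gene_id)) .stopf("duplicate gene_id in annotation")
  structure(list(
    set = x,
    gene = .make_tab(x$genes$chrom, x$genes$start, x$genes$end, x$genes$gene_id),
    transcript = .make_tab(x$transcripts$chrom, x$transcripts$start,
                           x$transcripts$end, x$transcripts$transcript_id),
    exon = .make_tab(x$exons$chrom, x$exons$start, x$exons$end, x$exons$exon_id),
    tx_by_gene = split(x$transcripts, x$transcripts$gene_id),
    ex_by_gene = split(x$exons, x$exons$gene_id)
  ), class = "annotation_index")
}

#' @export
print.annotation_index <- function(x, ...) {
  cat(sprintf("annotation_index over %d genes / %d transcripts / %d exons\n",
              nrow(x$set$genes), nrow(x$set$transcripts), nrow(x$set$exons)))
  invisible(x)
}

#' Query features overlapping a region
#'
#' @param index an `annotation_index`.
#' @param chrom,start,end the query region (1-based inclusive).
#' @param level `"gene"`, `"transcript"` or `"exon"`.
#' @return Character vector of feature ids overlapping the region (closed
#'   intervals; a single shared base pair counts), ordered by feature start
#'   then id. A chromosome absent from the index yields an empty vector.
#' @export
query_overlaps <- function(index, chrom, start, end,
                           level = c("gene", "transcript", "exon")) {
  stopifnot(inherits(index, "annotation_index"))
  level <- match.arg(level)
  .check_intervals(chrom, start, end, "query region")
  t <- index[[level]][[chrom]]
  idx <- .tab_query(index[[level]], chrom, start, end)
  if (!length(idx)) return(character(0))
  t$id[idx]
}

#' Find genes within a radius of a region
#'
#' Returns every gene whose span (or TSS, see `distance_from`) lies within
#' `radius` bp of the query region on either side, independent of gene
#' strand. Distances are signed in reference orientation: 0 for overlap,
#' negative for genes left (upstream) of the region, positive for genes to
#' the right.
#'
#' @inheritParams query_overlaps
#' @param radius maximum gap in bp (default 150000, the search radius used
#'   for region-to-gene linking).
#' @param distance_from `"span"` (default): gap between the region and the
#'   gene span; `"tss"`: gap between the region and the gene's strand-aware
#'   span start.
#' @return data.frame with columns `gene_id` and `distance`, ordered by gene
#'   start then id.
#' @export
query_radius <- function(index, chrom, start, end, radius = 150000,
                         distance_from = c("span", "tss")) {
  stopifnot(inherits(index, "annotation_index"))
  distance_from <- match.arg(distance_from)
  if (radius < 0) .stopf("radius must be >= 0")
  .check_intervals(chrom, start, end, "query region")
  t <- index$gene[[chrom]]
  if (is.null(t))
    return(data.frame(gene_id = character(0), distance = numeric(0)))
  if (distance_from == "span") {
    idx <- .tab_query(index$gene, chrom, max(1, start - radius), end + radius)
    if (!length(idx))
      return(data.frame(gene_id = character(0), distance = numeric(0)))
    d <- .signed_gap(start, end, t$start[idx], t$end[idx])
  } else {
    g <- index$set$genes
    gi <- match(t$id, g$gene_id)
    tss <- ifelse(g$strand[gi] == "-", g$end[gi], g$start[gi])
    d_all <- .signed_gap(start, end, tss, tss)
    idx <- which(abs(d_all) <= radius)
    d <- d_all[idx]
  }
  keep <- abs(d) <= radius
  data.frame(gene_id = t$id[idx][keep], distance = d[keep],
             stringsAsFactors = FALSE)
}
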