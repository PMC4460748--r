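test_that("GFF3 and GTF readers parse minimal files with the right conventions", {
  gff <- c("##gff-version 3",
           "chr1\tsrc\tgene\t100\t900\t.\t+\t.\tID=g1;Name=one;gene_biotype=protein_coding",
           "chr1\tsrc\tmRNA\t100\t900\t.\t+\t.\tID=t1;Parent=g1",
           "chr1\tsrc\texon\t100\t300\t.\t+\t.\tID=e1;Parent=t1",
           "chr1\tsrc\texon\t500\t900\t.\t+\t.\tID=e2;Parent=t1")
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, f)
  set <- read_gene_models(f, "gff3")
  expect_equal(c(nrow(set$genes), nrow(set$transcripts), nrow(set$exons)),
               c(1L, 1L, 2L))
  expect_equal(set$genes$biotype, "coding")
  expect_equal(set$transcripts$tss, 100L)

  ## GTF with two genes on opposite strands: the minus-strand TSS is the end
  gtf <- c(paste0("chr1\tsrc\tgene\t100\t900\t.\t+\t.\t",
                  'gene_id "gp"; gene_biotype "protein_coding";'),
           paste0("chr1\tsrc\ttranscript\t100\t900\t.\t+\t.\t",
                  'gene_id "gp"; transcript_id "tp";'),
           paste0("chr1\tsrc\texon\t100\t900\t.\t+\t.\t",
                  'gene_id "gp"; transcript_id "tp";'),
           paste0("chr1\tsrc\tgene\t2000\t3000\t.\t-\t.\t",
                  'gene_id "gm"; gene_biotype "lincRNA";'),
           paste0("chr1\tsrc\ttranscript\t2000\t3000\t.\t-\t.\t",
                  'gene_id "gm"; transcript_id "tm";'),
           paste0("chr1\tsrc\texon\t2000\t3000\t.\t-\t.\t",
                  'gene_id "gm"; transcript_id "tm";'))
  f2 <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf, f2)
  set2 <- read_gene_models(f2, "gtf")
  expect_equal(nrow(set2$genes), 2L)
  tm <- set2$transcripts[set2$transcripts$gene_id == "gm", ]
  expect_equal(tm$tss, tm$end)
  expect_equal(set2$genes$biotype[set2$genes$gene_id == "gm"], "noncoding")
})

test_that("malformed and inconsistent annotation is rejected with useful errors", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chr1\tsrc\tgene\t100"), f)
  expect_error(read_gene_models(f, "gff3"), "line 2")

  toy <- toy_annotation()
  bad_exons <- toy$exons
  bad_exons$end[1] <- 99999L  # outside tA1
  expect_error(annotation_set(toy$genes, toy$transcripts, bad_exons),
               "outside its transcript")
  dup <- toy$genes[c(1, 1, 2, 3), ]
  expect_error(annotation_set(dup, toy$transcripts, toy$exons),
               "duplicate gene_id")
})

test_that("a simulated genome round-trips through the GFF3 writer and reader", {
  g <- simulate_genome(n_genes = 150, seed = 7)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(g, f)
  g2 <- read_gene_models(f, "gff3")
  norm <- function(s) {
    list(genes = s$genes[order(s$genes$gene_id), c("gene_id", "gene_name",
                                                   "biotype", "chrom", "start",
                                                   "end", "strand")],
         tx = s$transcripts[order(s$transcripts$transcript_id),
                            c("transcript_id", "gene_id", "chrom", "start",
                              "end", "strand", "tss")],
         ex = s$exons[order(s$exons$exon_id),
                      c("exon_id", "transcript_id", "gene_id", "chrom",
                        "start", "end")])
  }
  a <- norm(g); b <- norm(g2)
  rownames(a$genes) <- rownames(b$genes) <- NULL
  rownames(a$tx) <- rownames(b$tx) <- NULL
  rownames(a$ex) <- rownames(b$ex) <- NULL
  expect_equal(a, b)
})

test_that("bisection queries equal linear-scan results on fuzzed genomes", {
  g <- simulate_genome(n_genes = 300, n_chroms = 4, seed = 11)
  idx <- build_index(g)
  qs <- random_queries(g, 300, seed = 12)
  for (level in c("gene", "transcript", "exon")) {
    for (i in seq_len(nrow(qs))) {
      got <- query_overlaps(idx, qs$chrom[i], qs$start[i], qs$end[i], level)
      want <- oracle_overlaps(g, level, qs$chrom[i], qs$start[i], qs$end[i])
      expect_identical(got, want)
    }
  }
})

test_that("radius queries match the oracle, and radius 0 equals gene overlap", {
  g <- simulate_genome(n_genes = 250, n_chroms = 3, seed = 21)
  idx <- build_index(g)
  qs <- random_queries(g, 150, seed = 22)
  for (i in seq_len(nrow(qs))) {
    r <- sample(c(0L, 10000L, 150000L), 1L)
    got <- query_radius(idx, qs$chrom[i], qs$start[i], qs$end[i], radius = r)
    want <- oracle_radius(g, qs$chrom[i], qs$start[i], qs$end[i], r)
    expect_equal(got$gene_id, want$gene_id)
    expect_equal(got$distance, want$distance)
    if (r == 0L)
      expect_identical(sort(got$gene_id),
                       sort(query_overlaps(idx, qs$chrom[i], qs$start[i],
                                           qs$end[i], "gene")))
  }
})

test_that("radius queries are monotone in the radius and empty off-index", {
  g <- simulate_genome(n_genes = 100, seed = 31)
  idx <- build_index(g)
  qs <- random_queries(g, 50, seed = 32)
  for (i in seq_len(nrow(qs))) {
    r1 <- query_radius(idx, qs$chrom[i], qs$start[i], qs$end[i], radius = 20000)
    r2 <- query_radius(idx, qs$chrom[i], qs$start[i], qs$end[i], radius = 150000)
    expect_true(all(r1$gene_id %in% r2$gene_id))
  }
  expect_equal(nrow(query_radius(idx, "chrUn", 1, 1000, radius = 1e6)), 0L)
  expect_length(query_overlaps(idx, "chrUn", 1, 1000, "gene"), 0L)
})

test_that("signed distances follow reference orientation on a toy case", {
  toy <- toy_annotation()
  idx <- build_index(toy)
  ## gA ends at 9000; query 100 kb to its right
  q <- query_radius(idx, "chr1", 109000, 110000, radius = 150000)
  expect_true("gA" %in% q$gene_id)
  expect_equal(q$distance[q$gene_id == "gA"], -100000)
  q2 <- query_radius(idx, "chr1", 109000, 110000, radius = 50000)
  expect_false("gA" %in% q2$gene_id)
})

test_that("flat annotation tables are written keyed by feature id", {
  toy <- toy_annotation()
  d <- withr::local_tempdir()
  paths <- write_annotation_tables(toy, d)
  tt <- read.delim(paths[["transcript.table"]])
  et <- read.delim(paths[["exon.table"]])
  expect_equal(sort(tt$transcript_id), sort(toy$transcripts$transcript_id))
  expect_equal(sort(et$exon_id), sort(toy$exons$exon_id))
  expect_true(all(c("tss", "gene_id") %in% names(tt)))
})
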