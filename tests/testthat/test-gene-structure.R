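# Promoter extraction and exon-intron-UTR summaries.

simple_annotation <- function() {
  genome_annotation(data.frame(
    seqid = "chr1",
    type = c("gene", "mRNA", "exon", "exon", "CDS", "CDS"),
    start = c(3001, 3001, 3001, 3501, 3051, 3501),
    end = c(3800, 3800, 3200, 3800, 3200, 3700),
    strand = "+",
    ID = c("g1", "g1.t1", NA, NA, NA, NA),
    Parent = c(NA, "g1", "g1.t1", "g1.t1", "g1.t1", "g1.t1")
  ))
}

test_that("plus-strand promoter windows use [start - upstream, start - 1]", {
  ann <- simple_annotation()
  genome <- stats::setNames(random_contig(10000), "chr1")
  p <- extract_promoters(ann, genome, "g1")
  expect_equal(p$start, 1001)
  expect_equal(p$end, 3000)
  expect_equal(p$length, 2000)
  expect_false(p$truncated)
  expect_equal(p$sequence, unname(substr(genome, 1001, 3000)))
})

test_that("windows are clamped and flagged at contig boundaries, never padded", {
  ann <- genome_annotation(data.frame(
    seqid = "chr1", type = "gene", start = 500, end = 900, strand = "+",
    ID = "g_edge", Parent = NA))
  genome <- stats::setNames(random_contig(2000), "chr1")
  p <- extract_promoters(ann, genome, "g_edge")
  expect_equal(c(p$start, p$end, p$length), c(1, 499, 499))
  expect_true(p$truncated)
  # gene starting at base 1: empty window, truncated
  ann1 <- genome_annotation(data.frame(
    seqid = "chr1", type = "gene", start = 1, end = 300, strand = "+",
    ID = "g_first", Parent = NA))
  p1 <- extract_promoters(ann1, genome, "g_first")
  expect_equal(p1$sequence, "")
  expect_true(p1$truncated)
})

test_that("minus-strand promoters are the reverse complement downstream of the gene end", {
  genome_seq <- random_contig(5000)
  genome <- stats::setNames(genome_seq, "chr1")
  ann <- genome_annotation(data.frame(
    seqid = "chr1", type = "gene", start = 1000, end = 2000, strand = "-",
    ID = "g_minus", Parent = NA))
  p <- extract_promoters(ann, genome, "g_minus", upstream = 300)
  expect_equal(c(p$start, p$end), c(2001, 2300))
  expect_equal(p$sequence, oracle_revcomp(substr(genome_seq, 2001, 2300)))
})

test_that("unknown genes and contigs give per-gene notes without aborting", {
  ann <- simple_annotation()
  genome <- stats::setNames(random_contig(10000), "chrX")
  p <- extract_promoters(ann, genome, c("nope", "g1"))
  expect_equal(nrow(p), 2)
  expect_match(p$note[1], "not found")
  expect_match(p$note[2], "seqid absent")
  expect_true(all(is.na(p$sequence)))
})

test_that("promoter windows abut the gene 5' end on 100 random annotations", {
  set.seed(61)
  for (i in 1:100) {
    m <- random_gene_model()
    contig_len <- m$gene_end + sample(500:3000, 1)
    genome_seq <- random_contig(contig_len)
    genome <- stats::setNames(genome_seq, "chr1")
    up <- sample(c(200, 2000), 1)
    p <- extract_promoters(m$annotation, genome, m$gene_id, upstream = up)
    if (m$strand == "+") {
      expect_equal(p$end, m$gene_start - 1)  # no gap, no overlap
      expect_equal(p$start, max(1, m$gene_start - up))
      expect_equal(p$sequence, substr(genome_seq, p$start, p$end))
    } else {
      expect_equal(p$start, m$gene_end + 1)
      expect_equal(p$end, min(contig_len, m$gene_end + up))
      expect_equal(p$sequence,
                   oracle_revcomp(substr(genome_seq, p$start, p$end)))
    }
    expect_equal(p$truncated, p$length < up)
    # reverse-complement involution: mirroring the contig and annotation
    # yields the identical promoter sequence
    mirror <- function(x) contig_len - x + 1
    feats <- as.data.frame(m$annotation)
    new_start <- mirror(feats$end); new_end <- mirror(feats$start)
    feats$start <- new_start; feats$end <- new_end
    feats$strand <- ifelse(feats$strand == "+", "-", "+")
    genome_rc <- stats::setNames(oracle_revcomp(genome_seq), "chr1")
    p_rc <- extract_promoters(genome_annotation(feats), genome_rc,
                              m$gene_id, upstream = up)
    expect_equal(p_rc$sequence, p$sequence)
  }
})

test_that("structure summary counts CDS, introns and UTR segments", {
  ann <- simple_annotation()
  s <- structure_summary(ann, "g1.t1")
  expect_equal(s$length, 800)
  expect_equal(s$cds_segments, 2)
  expect_equal(s$introns, 1)
  expect_equal(s$utr_segments, 2) # 5' exon head + 3' exon tail
  expect_equal(s$utr_source, "derived")
  # single-exon fully coding transcript: (1, 0, 0)
  ann2 <- genome_annotation(data.frame(
    seqid = "c", type = c("gene", "mRNA", "exon", "CDS"),
    start = c(1, 1, 1, 1), end = c(300, 300, 300, 300), strand = "+",
    ID = c("g", "t", NA, NA), Parent = c(NA, "g", "t", "t")))
  s2 <- structure_summary(ann2, "t")
  expect_equal(c(s2$cds_segments, s2$introns, s2$utr_segments), c(1, 0, 0))
  # annotated UTR features win over derivation
  ann3 <- genome_annotation(data.frame(
    seqid = "c", type = c("gene", "mRNA", "exon", "CDS", "five_prime_UTR",
                          "three_prime_UTR"),
    start = c(1, 1, 1, 51, 1, 281), end = c(300, 300, 300, 280, 50, 300),
    strand = "+", ID = c("g", "t", NA, NA, NA, NA),
    Parent = c(NA, "g", "t", "t", "t", "t")))
  s3 <- structure_summary(ann3, "t")
  expect_equal(s3$utr_segments, 2)
  expect_equal(s3$utr_source, "annotated")
  # transcript with no exon/CDS children is flagged, not an abort
  ann4 <- genome_annotation(data.frame(
    seqid = "c", type = c("gene", "mRNA"), start = 1, end = 100,
    strand = "+", ID = c("g", "t"), Parent = c(NA, "g")))
  s4 <- structure_summary(ann4, "t")
  expect_match(s4$note, "no exon or CDS")
  expect_true(is.na(s4$cds_segments))
})

test_that("a five-exon fully spanned transcript with terminal UTR exons counts 5/4/2", {
  starts <- c(1, 201, 401, 601, 801)
  ends <- c(100, 300, 500, 700, 900)
  # CDS spans exons 1-5 partially: head of exon 1 and tail of exon 5 are UTR
  cds_s <- c(51, 201, 401, 601, 801)
  cds_e <- c(100, 300, 500, 700, 850)
  ann <- genome_annotation(data.frame(
    seqid = "c",
    type = c("gene", "mRNA", rep("exon", 5), rep("CDS", 5)),
    start = c(1, 1, starts, cds_s), end = c(900, 900, ends, cds_e),
    strand = "+",
    ID = c("g", "t", rep(NA, 10)), Parent = c(NA, "g", rep("t", 10))))
  s <- structure_summary(ann, "t")
  expect_equal(s$cds_segments, 5)
  expect_equal(s$introns, 4)
  expect_equal(s$utr_segments, 2)
})

test_that("structure counts match the per-base interval oracle on random models", {
  set.seed(62)
  for (i in 1:60) {
    m <- random_gene_model()
    s <- structure_summary(m$annotation, m$transcript_id)
    o <- oracle_structure_counts(m$exons, m$cds)
    expect_equal(s$introns, o$introns)
    expect_equal(s$cds_segments, nrow(m$cds))
    expect_equal(s$utr_segments, o$utr_segments)
    expect_equal(s$length, m$gene_end - m$gene_start + 1)
    # intron count is exon count minus one whenever exons exist
    expect_equal(s$introns, nrow(m$exons) - 1)
  }
})

test_that("annotations round-trip through GFF3 via rtracklayer", {
  ann <- simple_annotation()
  path <- withr::local_tempfile(fileext = ".gff3")
  df <- as.data.frame(ann)
  lines <- c("##gff-version 3", vapply(seq_len(nrow(df)), function(i) {
    attrs <- character(0)
    if (!is.na(df$ID[i])) attrs <- c(attrs, paste0("ID=", df$ID[i]))
    if (!is.na(df$Parent[i])) attrs <- c(attrs, paste0("Parent=", df$Parent[i]))
    paste(df$seqid[i], "test", df$type[i], df$start[i], df$end[i], ".",
          df$strand[i], ".", paste(attrs, collapse = ";"), sep = "\t")
  }, character(1)))
  writeLines(lines, path)
  back <- read_annotation(path)
  s1 <- structure_summary(ann, "g1.t1")
  s2 <- structure_summary(back, "g1.t1")
  expect_equal(s1, s2)
  # default transcript selection: first mRNA per gene
  s3 <- structure_summary(back)
  expect_equal(s3$transcript, "g1.t1")
  # BED-style segments
  segs <- structure_segments(back, "g1.t1")
  expect_equal(nrow(segs), 4)
  expect_equal(segs$start, c(3001, 3501, 3051, 3501) - 1) # 0-based starts
  expect_equal(segs$end, c(3200, 3800, 3200, 3700))       # exclusive ends
})
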