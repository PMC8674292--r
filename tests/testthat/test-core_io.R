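test_that("genome reading normalises case, enforces uniqueness and alphabet", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 description text", "acgt", ">chr2", "NNAA"), fa)
  g <- read_genome(fa)
  expect_equal(names(g), c("chr1", "chr2"))
  expect_equal(as.character(g[["chr1"]]), "ACGT")

  writeLines(c(">a", "ACGT", ">a", "ACGT"), fa)
  expect_error(read_genome(fa), "duplicate contig")

  writeLines(c(">a", "ACRT"), fa)
  expect_error(read_genome(fa), "non-ACGTN")
})

test_that("strand-aware fetch returns reverse complement on the minus strand", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
  expect_equal(fetch_seq(g, "chr1", 0, 2, "+"), "AC")
  expect_equal(fetch_seq(g, "chr1", 0, 2, "-"), "GT")
  expect_error(fetch_seq(g, "chr1", 0, 5), "out of bounds")
  expect_error(fetch_seq(g, "chrX", 0, 2), "unknown contig")
})

test_that("GTF parsing shifts 1-based inclusive coordinates to 0-based half-open", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\tCDS\t150\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'),
    gtf)
  a <- read_annotation(gtf, "gtf", source = "test")
  expect_equal(a$exons$start, c(99L, 300L))
  expect_equal(a$exons$end, c(200L, 400L))
  expect_equal(a$cds$start, 149L)
  # round trip through the GTF writer is the identity
  out <- withr::local_tempfile(fileext = ".gtf")
  write_annotation_gtf(a, out)
  b <- read_annotation(out, "gtf", source = "test")
  expect_equal(b$exons, a$exons)
  expect_equal(b$cds, a$cds)
})

test_that("BED12 blocks become exons at chromStart + blockStarts", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste(c("chr1", 99, 400, "tx1", 0, "+", 99, 400, "0",
                     2, "101,100,", "0,201,"), collapse = "\t"), bed)
  a <- read_annotation(bed, "bed12")
  expect_equal(a$exons$start, c(99L, 300L))
  expect_equal(a$exons$end, c(200L, 400L))
})

test_that("intron derivation is strand-aware and supports per-gene union", {
  df <- data.frame(
    type = "exon",
    transcript_id = rep(c("t1", "t2", "t3"), times = c(2, 3, 2)),
    gene_id = rep(c("gA", "gA", "gB"), times = c(2, 3, 2)),
    contig = "chr1",
    strand = rep(c("+", "+", "-"), times = c(2, 3, 2)),
    start = c(0, 200, 0, 200, 500, 1000, 1400),
    end = c(100, 300, 100, 300, 600, 1100, 1500),
    stringsAsFactors = FALSE)
  anno <- psiexon:::build_transcript_set(df, "t")
  per_tx <- derive_introns(anno, per_gene_union = FALSE)
  # t1 and t2 share intron [100, 200); t2 adds [300, 500)
  expect_equal(sum(per_tx$donor == 100 & per_tx$acceptor == 200), 2L)
  un <- derive_introns(anno, per_gene_union = TRUE)
  expect_equal(sum(un$donor == 100 & un$acceptor == 200), 1L)
  # minus-strand ordinals count from the genomically rightmost intron
  gB <- un[un$gene_id == "gB", ]
  expect_equal(gB$donor, 1100)
  expect_equal(gB$ordinal, 1L)
  # single-exon transcripts yield no introns
  single <- psiexon:::build_transcript_set(
    data.frame(type = "exon", transcript_id = "s", gene_id = "s",
               contig = "chr1", strand = "+", start = 0, end = 50,
               stringsAsFactors = FALSE), "t")
  expect_equal(nrow(derive_introns(single)), 0L)
})

test_that("junction dialects convert correctly and reject malformed input", {
  sj <- withr::local_tempfile(fileext = ".tab")
  writeLines(c("chr1\t101\t200\t1\t1\t0\t57\t3\t40",
               "chr1\t501\t700\t0\t0\t0\t12\t0\t38"), sj)
  jt <- read_junctions(sj, "sj_tab", sample_id = "s1")
  expect_equal(jt$donor, c(100L, 500L))
  expect_equal(jt$acceptor, c(200L, 700L))
  expect_equal(jt$strand, c("+", "."))   # code 0 = undefined, kept as '.'
  expect_equal(jt$count, c(57L, 12L))

  # generic TSV round trip
  out <- withr::local_tempfile(fileext = ".tsv")
  write_junctions(jt, out)
  jt2 <- read_junctions(out, "tsv")
  expect_equal(jt2, jt)

  dup <- rbind(jt, jt[1, ])
  expect_error(psiexon:::validate_junctions(dup), "duplicate")
  bad <- jt; bad$acceptor[1] <- bad$donor[1]
  expect_error(psiexon:::validate_junctions(bad), "acceptor <= donor")
})

test_that("undefined junction strands resolve against the unique containing gene", {
  df <- data.frame(type = "exon", transcript_id = "t1", gene_id = "g1",
                   contig = "chr1", strand = "-",
                   start = c(0, 500), end = c(100, 600),
                   stringsAsFactors = FALSE)
  anno <- psiexon:::build_transcript_set(df, "t")
  jt <- data.frame(contig = "chr1", donor = c(100L, 5000L),
                   acceptor = c(500L, 6000L), strand = ".",
                   sample_id = "s1", count = c(5L, 5L),
                   stringsAsFactors = FALSE)
  expect_message(res <- resolve_junction_strands(jt, anno), "excluded")
  expect_equal(nrow(res), 1L)
  expect_equal(res$strand, "-")
})
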