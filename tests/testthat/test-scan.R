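test_that("planted pseudoexons are recovered with exact boundaries on both strands", {
  cfg <- sim_config(seed = 31, n_genes = 6)
  sim <- simulate_genome(cfg, n_plants = 10,
                         plant_classes = c("pass", "short", "long", "weak",
                                           "annotated"))
  sc <- scan_introns(sim$genome, sim$introns, sim$acceptor_model,
                     annos = sim$anno)
  m <- merge(sim$truth, sc, by = c("contig", "strand", "start", "end"))
  expect_equal(nrow(m), nrow(sim$truth))          # every plant found
  expect_equal(m$passes_filters, m$expect_pass)
  dec <- m[!m$expect_pass, ]
  expect_equal(dec$fail_reason, dec$expect_reason)
  # scan scores equal the scores frozen at generation time
  expect_equal(m$acceptor_score.y, m$acceptor_score.x, tolerance = 1e-10)
  # both strands exercised
  expect_setequal(unique(m$strand), c("+", "-"))
  # every exon candidate obeys the AGA|GTAAG boundary invariant
  pass <- sc[sc$passes_filters, ]
  for (i in seq_len(nrow(pass))) {
    exon <- fetch_seq(sim$genome, pass$contig[i], pass$start[i], pass$end[i],
                      pass$strand[i])
    expect_equal(substr(exon, nchar(exon) - 2, nchar(exon)), "AGA")
    after <- if (pass$strand[i] == "+") {
      fetch_seq(sim$genome, pass$contig[i], pass$end[i], pass$end[i] + 5, "+")
    } else {
      fetch_seq(sim$genome, pass$contig[i], pass$start[i] - 5, pass$start[i], "-")
    }
    expect_equal(after, "GTAAG")
  }
  # primary flags: one per motif occurrence among passing candidates
  byocc <- split(pass$primary, paste(pass$contig, pass$strand, pass$motif_pos))
  expect_true(all(vapply(byocc, sum, numeric(1)) == 1))
})

test_that("a motif-free corpus yields no candidates", {
  cfg <- sim_config(seed = 77, n_genes = 2)
  sim <- simulate_genome(cfg, n_plants = 0)
  sc <- scan_introns(sim$genome, sim$introns, sim$acceptor_model,
                     annos = sim$anno)
  expect_equal(nrow(sc), 0L)
})

test_that("annotation re-evaluation distinguishes exact twins from shared single sites", {
  cfg <- sim_config(seed = 13, n_genes = 4)
  sim <- simulate_genome(cfg, n_plants = 2, plant_classes = c("pass", "pass"))
  sc <- scan_introns(sim$genome, sim$introns, sim$acceptor_model)
  pl <- sim$truth[1, ]
  i <- which(sc$start == pl$start & sc$end == pl$end)
  expect_false(sc$annotated[i])

  # exact-interval twin transcript -> annotated, excluded from passing set
  base <- rbind(
    transform(merge(sim$anno$exons, sim$anno$transcripts, by = "transcript_id"),
              type = "exon"),
    transform(merge(sim$anno$cds, sim$anno$transcripts, by = "transcript_id"),
              type = "CDS"))
  twin <- data.frame(type = "exon", transcript_id = "twin.t", gene_id = pl$gene_id,
                     contig = pl$contig, strand = pl$strand,
                     start = pl$start, end = pl$end, stringsAsFactors = FALSE)
  anno2 <- psiexon:::build_transcript_set(rbind(base, twin), "withtwin")
  sc2 <- annotate_candidates(sc, anno2)
  expect_true(sc2$annotated[i])
  expect_false(sc2$passes_filters[i])
  expect_match(sc2$fail_reason[i], "annotated")

  # sharing only the acceptor boundary leaves the candidate unannotated
  half <- twin; half$transcript_id <- "half.t"
  if (pl$strand == "+") half$end <- half$end + 9L else half$start <- half$start - 9L
  anno3 <- psiexon:::build_transcript_set(rbind(base, half), "half")
  sc3 <- annotate_candidates(sc, anno3)
  expect_false(sc3$annotated[i])
  expect_true(sc3$passes_filters[i])
})

test_that("exon-terminal dinucleotide census counts internal exons strand-aware", {
  # 11-exon plus-strand gene: 10 internal donors, 3 of them ending GA
  ends <- c(rep("GA", 3), rep("AG", 7))
  exlen <- 30L
  parts <- character(0); starts <- integer(0); pos <- 0L
  for (i in 1:11) {
    body <- paste(rep("C", exlen - 2), collapse = "")
    term <- if (i <= 10) ends[i] else "CC"
    starts <- c(starts, pos)
    parts <- c(parts, paste0(body, term))
    pos <- pos + exlen
    if (i < 11) { parts <- c(parts, paste(rep("T", 50), collapse = "")); pos <- pos + 50L }
  }
  g <- Biostrings::DNAStringSet(c(chr1 = paste(parts, collapse = "")))
  anno <- psiexon:::build_transcript_set(data.frame(
    type = "exon", transcript_id = "t1", gene_id = "g1", contig = "chr1",
    strand = "+", start = starts, end = starts + exlen,
    stringsAsFactors = FALSE), "ref")
  cen <- exon_end_dinucleotide_census(anno, g)
  expect_equal(sum(cen$count), 10L)   # terminal exon excluded
  expect_equal(cen$percent[cen$dinucleotide == "GA"], 30)
  expect_equal(cen$percent[cen$dinucleotide == "AG"], 70)
  expect_true(cen$canonical[cen$dinucleotide == "AG"])

  # the mirrored minus-strand gene gives the identical census
  gm <- Biostrings::DNAStringSet(c(chr1 = revcomp(as.character(g[[1]]))))
  glen <- length(g[[1]])
  anno_m <- psiexon:::build_transcript_set(data.frame(
    type = "exon", transcript_id = "t1", gene_id = "g1", contig = "chr1",
    strand = "-", start = glen - (starts + exlen), end = glen - starts,
    stringsAsFactors = FALSE), "ref")
  cen_m <- exon_end_dinucleotide_census(anno_m, gm)
  expect_equal(cen_m, cen)
})
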