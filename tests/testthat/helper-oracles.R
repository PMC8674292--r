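# Independent oracles and fixture builders shared by the suite. The
# oracles use only elementary arithmetic (choose(), direct enumeration),
# never the code paths they check.

# Two-sided Fisher exact P for the 2x2 table [[a, b], [c, d]] (rows =
# inclusion/exclusion, columns = the two groups) by exhaustive enumeration
# over all tables with the observed margins: sum of the probabilities of
# tables no more probable than the observed one (relative tolerance as in
# the classical definition).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  supp <- max(0, c1 - r2):min(c1, r1)
  logp <- lchoose(r1, supp) + lchoose(r2, c1 - supp) - lchoose(r1 + r2, c1)
  probs <- exp(logp)
  p0 <- exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(r1 + r2, c1))
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# Exact two-sided rank-sum P by exhaustive enumeration of all
# choose(n1+n2, n1) assignments of the pooled ranks to group 1 (no ties
# assumed). Statistic is the Mann-Whitney U of group 1.
ranksum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- colSums(matrix(sort(r)[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  p_le <- mean(us <= u_obs); p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Pooled-variance two-sample t-test oracle (textbook formulas).
t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# A one-event fixture whose pooled Fisher table is exactly
# [[a, b], [c, d]]: one sample per group, both inclusion junctions at the
# inclusion count so their mean equals it.
fisher_fixture <- function(a, b, c, d) {
  ev <- data.frame(event_id = "e1", kind = "CE", contig = "chr1",
                   strand = "+", exon_start = 200L, exon_end = 264L,
                   inc1_donor = 100L, inc1_acceptor = 200L,
                   inc2_donor = 264L, inc2_acceptor = 400L,
                   exc_donor = 100L, exc_acceptor = 400L,
                   stringsAsFactors = FALSE)
  jt <- rbind(
    data.frame(contig = "chr1", donor = c(100L, 264L, 100L),
               acceptor = c(200L, 400L, 400L), strand = "+",
               sample_id = "sA", count = c(a, a, c)),
    data.frame(contig = "chr1", donor = c(100L, 264L, 100L),
               acceptor = c(200L, 400L, 400L), strand = "+",
               sample_id = "sB", count = c(b, b, d)))
  mf <- data.frame(sample_id = c("sA", "sB"), group = c("A", "B"),
                   replicate = c(1L, 1L))
  list(event = ev, junctions = jt, manifest = mf)
}

# Hand-built event catalogue + junction table for threshold tests: one CE
# event per row of `spec`, with identical inclusion-junction counts per
# sample so supports are exact integers.
make_event_fixture <- function(spec) {
  # spec: data.frame(id, incA1..incAn, excA1.., incB1.., excB1..) given as
  # lists of per-sample (inc, exc) counts for control and treated
  events <- list(); jrows <- list()
  off <- 0L
  for (i in seq_len(nrow(spec))) {
    u <- off + 100L; s <- off + 200L; e <- off + 264L; v <- off + 400L
    events[[i]] <- data.frame(
      event_id = spec$id[i], kind = "CE", contig = "chr1", strand = "+",
      exon_start = s, exon_end = e,
      inc1_donor = u, inc1_acceptor = s, inc2_donor = e, inc2_acceptor = v,
      exc_donor = u, exc_acceptor = v, stringsAsFactors = FALSE)
    cts <- spec$counts[[i]]   # list(sample_id=, inc=, exc=)
    for (ct in cts) {
      jrows[[length(jrows) + 1L]] <- data.frame(
        contig = "chr1", donor = c(u, e, u), acceptor = c(s, v, v),
        strand = "+", sample_id = ct$sample_id,
        count = c(ct$inc, ct$inc, ct$exc), stringsAsFactors = FALSE)
    }
    off <- off + 1000L
  }
  list(events = do.call(rbind, events), junctions = do.call(rbind, jrows))
}

# Tiny hand-built genome/annotation for NMD truth tables: one plus-strand
# gene, two exons flanking one intron with a freely writable insert region.
# Returns genome, annotation and a planting helper returning the exon
# interval of an inserted sequence.
make_toy_nmd_gene <- function(strand = "+", intron_len = 400L) {
  exon1 <- paste0("GGGGGGGGGG", "ATG",
                  paste(rep("GCT", 20), collapse = ""))   # CDS starts at 10
  exon2 <- paste0(paste(rep("GCA", 10), collapse = ""), "TAA",
                  "CCCCCCCCCC")
  intron_core <- paste(rep("C", intron_len - 26L), collapse = "")
  intron <- paste0("GTAAGT", intron_core, "TTTTTTTTTTTTTTTTTCAG")
  gene <- paste0(exon1, intron, exon2)
  pad <- paste(rep("G", 50), collapse = "")
  if (strand == "+") {
    seqs <- paste0(pad, gene, pad)
  } else {
    seqs <- paste0(pad, psiexon::revcomp(gene), pad)
  }
  glen <- nchar(gene)
  e1 <- c(50L, 50L + nchar(exon1))
  i1 <- c(e1[2], e1[2] + nchar(intron))
  e2 <- c(i1[2], i1[2] + nchar(exon2))
  flip <- function(iv) c(100L + glen - iv[2], 100L + glen - iv[1])
  if (strand == "-") { tmp <- e1; e1 <- flip(e2); i1 <- flip(i1); e2 <- flip(tmp) }
  # on the minus strand exon1 (biological first) is genomically rightmost
  if (strand == "-") { b1 <- e2; b2 <- e1 } else { b1 <- e1; b2 <- e2 }
  cds1 <- if (strand == "+") c(b1[1] + 10L, b1[2]) else c(b1[1], b1[2] - 10L)
  cds2 <- if (strand == "+") c(b2[1], b2[1] + 33L) else c(b2[2] - 33L, b2[2])
  anno <- psiexon:::build_transcript_set(data.frame(
    type = c("exon", "exon", "CDS", "CDS"),
    transcript_id = "t1", gene_id = "g1", contig = "chr1", strand = strand,
    start = c(b1[1], b2[1], cds1[1], cds2[1]),
    end = c(b1[2], b2[2], cds1[2], cds2[2]),
    stringsAsFactors = FALSE), "toy")
  genome <- Biostrings::DNAStringSet(c(chr1 = seqs))

  # plant `body` into the intron so the insert's biological start sits
  # `frame_offset` coding bases after the last exon1 codon boundary; the
  # exon is preceded by ag and followed by gt so it is a clean insert
  plant <- function(body, bio_offset = 60L) {
    stopifnot(nchar(body) + bio_offset + 10L < intron_len)
    s <- as.character(genome[[1]])
    cass <- paste0("AG", body, "GT")
    if (strand == "+") {
      lo <- i1[1] + bio_offset
      substr(s, lo + 1L, lo + nchar(cass)) <- cass
      exon <- c(lo + 2L, lo + 2L + nchar(body))
    } else {
      lo <- i1[2] - bio_offset - nchar(cass)
      substr(s, lo + 1L, lo + nchar(cass)) <- psiexon::revcomp(cass)
      exon <- c(lo + 2L, lo + 2L + nchar(body))
    }
    list(genome = Biostrings::DNAStringSet(c(chr1 = s)),
         exon = data.frame(contig = "chr1", strand = strand,
                           start = exon[1], end = exon[2]))
  }
  list(genome = genome, anno = anno, plant = plant,
       exon1 = b1, exon2 = b2, intron = i1,
       cds_len_exon1 = if (strand == "+") b1[2] - b1[1] - 10L else b1[2] - b1[1] - 10L)
}

# non-stop codon-aligned filler of length n for a given frame offset:
# ensures no stop codon appears in the insert when read at frame_shift
# coding bases into a codon
no_stop_body <- function(n) {
  paste(rep("C", n), collapse = "")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# Synthetic score-table directory in the published maximum-entropy layout:
# deterministic rank-derived values so expected scores are hand-computable.
write_synthetic_maxent_dir <- function(dir, donor = TRUE, acceptor = TRUE) {
  dir.create(dir, showWarnings = FALSE)
  if (donor) {
    writeLines(format((0.5 + seq_len(4^7) / 4^7), digits = 12),
               file.path(dir, "me2x5"))
  }
  if (acceptor) {
    lens <- c(7, 7, 7, 7, 7, 3, 4, 3, 4)
    for (i in seq_len(9)) {
      writeLines(format(1 + seq_len(4^lens[i]) / (10 * 4^lens[i]), digits = 12),
                 file.path(dir, paste0("me2x3acc", i)))
    }
  }
  dir
}

# base-4 rank (A=0 C=1 G=2 T=3, first base most significant), 1-based
b4rank <- function(s) {
  v <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T")) - 1L
  sum(v * 4^(rev(seq_along(v)) - 1)) + 1L
}
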