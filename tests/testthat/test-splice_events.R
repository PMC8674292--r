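three_exon_anno <- function() {
  psiexon:::build_transcript_set(data.frame(
    type = "exon", transcript_id = "t1", gene_id = "g1", contig = "chr1",
    strand = "+", start = c(0, 200, 400), end = c(100, 264, 500),
    stringsAsFactors = FALSE), "ref")
}

test_that("catalogue discovers annotated CEs, novel CEs and A3SS events", {
  anno <- three_exon_anno()
  jt <- data.frame(contig = "chr1",
                   donor = c(100L, 264L, 100L),
                   acceptor = c(200L, 400L, 400L),
                   strand = "+", sample_id = "s1", count = 10L,
                   stringsAsFactors = FALSE)
  ev <- build_event_catalog(jt, anno)
  ce <- ev[ev$kind == "CE", ]
  expect_equal(nrow(ce), 1L)
  expect_equal(c(ce$exon_start, ce$exon_end), c(200L, 264L))
  expect_true(ce$acc_ann.ref && ce$don_ann.ref)
  expect_equal(ce$gene_id, "g1")

  # novel exon x = [150, 180) inside intron 1, both junctions + skip observed
  jt2 <- rbind(jt, data.frame(contig = "chr1", donor = c(100L, 180L),
                              acceptor = c(150L, 200L), strand = "+",
                              sample_id = "s1", count = 5L))
  ev2 <- build_event_catalog(jt2, anno)
  nov <- ev2[ev2$kind == "CE" & ev2$exon_start == 150 & ev2$exon_end == 180, ]
  expect_equal(nrow(nov), 1L)
  expect_false(nov$acc_ann.ref || nov$don_ann.ref)

  # two junctions sharing a donor with different acceptors, no bridge: A3SS
  jt3 <- data.frame(contig = "chr1", donor = 100L,
                    acceptor = c(200L, 230L), strand = "+",
                    sample_id = "s1", count = 10L, stringsAsFactors = FALSE)
  ev3all <- build_event_catalog(jt3, anno)
  ev3 <- ev3all[ev3all$kind != "CE", ]   # the annotated CE is co-discovered
  expect_equal(ev3$kind, "A3SS")
  # the shorter intron retains more exon: it is the inclusion junction
  expect_equal(ev3$inc1_acceptor, 200L)
  expect_equal(ev3$exc_acceptor, 230L)
  # same topology on the minus strand is an alternative 5'ss
  anno_m <- psiexon:::build_transcript_set(data.frame(
    type = "exon", transcript_id = "t1", gene_id = "g1", contig = "chr1",
    strand = "-", start = c(0, 200, 400), end = c(100, 264, 500),
    stringsAsFactors = FALSE), "ref")
  jt3m <- transform(jt3, strand = "-")
  ev3m <- build_event_catalog(jt3m, anno_m)
  expect_equal(ev3m$kind[ev3m$kind != "CE"], "A5SS")
})

test_that("PSI follows the averaged-inclusion formula with the denominator floor", {
  fx <- fisher_fixture(0, 0, 0, 0)
  ev <- fx$event
  jt <- data.frame(contig = "chr1", donor = c(100L, 264L, 100L),
                   acceptor = c(200L, 400L, 400L), strand = "+",
                   sample_id = "s1", count = c(30L, 50L, 60L),
                   stringsAsFactors = FALSE)
  # inclusion support = mean(30, 50) = 40; PSI = 100*40/(40+60)
  expect_equal(compute_psi(ev, jt, "s1"), 40)
  # denominator below 20 -> NA
  jt$count <- c(5L, 9L, 12L)   # inc = 7, denom = 19
  expect_true(is.na(compute_psi(ev, jt, "s1")))
  jt$count <- c(5L, 11L, 12L)  # inc = 8, denom = 20
  expect_false(is.na(compute_psi(ev, jt, "s1")))
  # all inclusion, no skip
  jt$count <- c(20L, 20L, 0L)
  expect_equal(compute_psi(ev, jt, "s1"), 100)
})

test_that("Fisher event test matches exhaustive enumeration and flags degeneracy", {
  for (tab in list(c(5, 5, 5, 5), c(0, 20, 20, 0), c(12, 3, 4, 11),
                   c(1, 0, 50, 49))) {
    fx <- fisher_fixture(tab[1], tab[2], tab[3], tab[4])
    res <- fisher_event_test(fx$event, fx$junctions, fx$manifest, "A", "B")
    expect_equal(res$p, fisher_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
  }
  fx <- fisher_fixture(5, 5, 5, 5)
  expect_equal(fisher_event_test(fx$event, fx$junctions, fx$manifest,
                                 "A", "B")$p, 1)
  # empty exclusion row margin
  fx <- fisher_fixture(10, 10, 0, 0)
  res <- fisher_event_test(fx$event, fx$junctions, fx$manifest, "A", "B")
  expect_true(res$degenerate)
  expect_equal(res$p, 1)
})

test_that("calls respect both thresholds and are antisymmetric under group swap", {
  psi <- data.frame(event_id = c("a", "b", "c", "d"),
                    dpsi = c(25, 25, -30, NA),
                    p = c(1e-4, 0.01, 1e-5, 1e-9))
  res <- call_regulated_events(psi)
  expect_equal(res$call, c("Inc", "NC", "Skp", "NC"))
  expect_equal(res$call_reason[4], "undefined_dpsi")

  # swapping groups mirrors calls and leaves P unchanged
  spec <- data.frame(id = sprintf("e%02d", 1:6))
  set.seed(7)
  spec$counts <- lapply(1:6, function(i) {
    pc <- sample(c(5, 40), 1); pt <- pc + sample(c(-30, 0, 30), 1)
    lapply(1:4, function(k) {
      grp_t <- k > 2
      p <- max(0, min(100, if (grp_t) pt else pc))
      list(sample_id = c("c1", "c2", "t1", "t2")[k],
           inc = round(4 * p), exc = round(4 * (100 - p)))
    })
  })
  fx <- make_event_fixture(spec)
  mf <- data.frame(sample_id = c("c1", "c2", "t1", "t2"),
                   group = rep(c("ctrl", "trt"), each = 2),
                   replicate = rep(1:2, 2))
  fwd <- psi_table(fx$events, fx$junctions, mf, "ctrl", "trt")
  rev <- psi_table(fx$events, fx$junctions, mf, "trt", "ctrl")
  expect_equal(fwd$p, rev$p, tolerance = 1e-12)
  expect_equal(fwd$dpsi, -rev$dpsi, tolerance = 1e-12)
  map <- c(Inc = "Skp", Skp = "Inc", NC = "NC")
  expect_equal(unname(map[fwd$call]), rev$call)
})

test_that("psiExon classification extracts strand-aware windows and status", {
  # exon [100, 164) on the plus strand: length 64, donor window = 3 exonic
  # bases 161..163 plus 6 intronic bases 164..169
  set.seed(3)
  s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = s))
  anno <- psiexon:::build_transcript_set(data.frame(
    type = "exon", transcript_id = "t1", gene_id = "g1", contig = "chr1",
    strand = "+", start = c(0, 250), end = c(60, 330),
    stringsAsFactors = FALSE), "ref")
  events <- data.frame(event_id = "ev1", kind = "CE", contig = "chr1",
                       strand = "+", exon_start = 100L, exon_end = 164L,
                       inc1_donor = 60L, inc1_acceptor = 100L,
                       inc2_donor = 164L, inc2_acceptor = 250L,
                       exc_donor = 60L, exc_acceptor = 250L,
                       acc_ann.ref = FALSE, don_ann.ref = FALSE,
                       gene_id = "g1", gene_ambiguous = FALSE,
                       stringsAsFactors = FALSE)
  psi <- data.frame(event_id = "ev1", call = "Inc", basal_psi = 0.7)
  px <- classify_psiexons(events, psi, anno, genome)
  expect_equal(px$length, 64L)
  expect_equal(px$donor9, substr(s, 162, 170))       # 0-based [161, 170)
  expect_equal(px$acceptor23, substr(s, 81, 103))    # 0-based [80, 103)
  expect_true(px$is_psiexon)

  # an exon with both splice sites annotated in one source is not a psiExon
  events$acc_ann.ref <- TRUE; events$don_ann.ref <- TRUE
  px2 <- classify_psiexons(events, psi, anno, genome)
  expect_false(px2$is_psiexon)
})
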