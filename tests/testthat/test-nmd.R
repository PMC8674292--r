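test_that("NMD truth table over length x stop-content matches the definition", {
  toy <- make_toy_nmd_gene("+")
  # frame at the insertion point is 0 (exon 1 contributes 63 coding bases),
  # so a codon-aligned TAA inside the insert is an in-frame PTC
  with_stop <- function(n) paste0(strrep("C", 30), "TAA", strrep("C", n - 33))
  cases <- expand.grid(len = c(63L, 64L, 72L, 75L), stop = c(TRUE, FALSE))
  for (i in seq_len(nrow(cases))) {
    L <- cases$len[i]
    body <- if (cases$stop[i]) with_stop(L) else no_stop_body(L)
    pl <- toy$plant(body)
    call <- classify_nmd(pl$exon, toy$anno, pl$genome)
    expect_equal(call$frameshift, L %% 3 != 0, info = paste("len", L))
    if (L %% 3 == 0) {
      expect_equal(call$ptc, cases$stop[i], info = paste("len", L, cases$stop[i]))
      expect_equal(call$is_nmd, cases$stop[i])
    } else {
      expect_true(call$is_nmd)   # frameshift alone suffices
    }
  }
})

test_that("NMD classification is strand-invariant for mirrored constructions", {
  for (stop_inside in c(TRUE, FALSE)) {
    body <- if (stop_inside) paste0(strrep("C", 30), "TAA", strrep("C", 42))
            else no_stop_body(75L)
    tp <- make_toy_nmd_gene("+"); tm <- make_toy_nmd_gene("-")
    pp <- tp$plant(body); pm <- tm$plant(body)
    cp <- classify_nmd(pp$exon, tp$anno, pp$genome)
    cm <- classify_nmd(pm$exon, tm$anno, pm$genome)
    expect_equal(cp$frameshift, cm$frameshift)
    expect_equal(cp$ptc, cm$ptc)
    expect_equal(cp$is_nmd, cm$is_nmd)
  }
})

test_that("frameshift implies NMD regardless of sequence content", {
  toy <- make_toy_nmd_gene("+")
  set.seed(19)
  for (rep in 1:10) {
    L <- sample(setdiff(10:100, seq(12, 99, by = 3)), 1)
    body <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                         prob = c(.3, .25, .25, .2)), collapse = "")
    pl <- toy$plant(body)
    call <- classify_nmd(pl$exon, toy$anno, pl$genome)
    expect_true(call$frameshift)
    expect_true(call$is_nmd)
  }
})

test_that("insertions outside introns error; upstream-of-start insertions are non-coding", {
  toy <- make_toy_nmd_gene("+")
  # not inside any intron of the transcript
  bad <- data.frame(contig = "chr1", strand = "+", start = 10L, end = 40L)
  expect_error(classify_nmd(bad, toy$anno, toy$genome), "intron")

  # a 5'UTR-hosted intron: move the CDS start downstream of the intron
  exdf <- data.frame(
    type = c("exon", "exon", "CDS"),
    transcript_id = "t2", gene_id = "g2", contig = "chr1", strand = "+",
    start = c(toy$exon1[1], toy$exon2[1], toy$exon2[1] + 3L),
    end = c(toy$exon1[2], toy$exon2[2], toy$exon2[1] + 33L),
    stringsAsFactors = FALSE)
  anno2 <- psiexon:::build_transcript_set(exdf, "toy2")
  pl <- toy$plant(no_stop_body(75L))
  call <- classify_nmd(pl$exon, anno2, pl$genome, transcript_id = "t2")
  expect_false(call$is_nmd)
  expect_equal(call$reason, "non-coding insertion")
})

test_that("rank-sum shift test matches exhaustive enumeration and detects shifts", {
  set.seed(23)
  # exact-enumeration agreement for 10 vs 10 (no ties)
  for (rep in 1:3) {
    lfc <- round(rnorm(20), 6)
    expr <- data.frame(gene_id = sprintf("g%03d", 1:20), log2fc = lfc,
                       fdr = 0.5, base_mean = 100)
    genes <- expr$gene_id[sample(20, 10)]
    res <- lfc_shift_test(expr, genes)
    expect_equal(res$p, ranksum_oracle(expr$log2fc[expr$gene_id %in% genes],
                                       expr$log2fc[!expr$gene_id %in% genes]),
                 tolerance = 1e-12)
  }
  # planted -1 shift on a 40-gene set in a 1000-gene table is detected
  expr <- data.frame(gene_id = sprintf("g%04d", 1:1000),
                     log2fc = rnorm(1000, 0, 0.5), fdr = 0.5, base_mean = 100)
  hosts <- sprintf("g%04d", 1:40)
  expr$log2fc[1:40] <- expr$log2fc[1:40] - 1
  res <- lfc_shift_test(expr, hosts)
  expect_lt(res$p, 0.05)
  expect_lt(res$median_shift, 0)
  # a random null draw is not significant in this seeded fixture
  res0 <- lfc_shift_test(transform(expr, log2fc = rnorm(1000, 0, 0.5)),
                         sample(expr$gene_id, 40))
  expect_gt(res0$p, 0.05)
  expect_error(lfc_shift_test(expr, expr$gene_id[1:2]), "too small")
})

test_that("volcano classification uses fold (not log-fold) thresholds", {
  expr <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                     log2fc = c(-1, -1, 0.4, 1, 2),
                     fdr = c(0.01, 0.10, 0.001, 0.01, NA),
                     base_mean = 100)
  res <- volcano_classify(expr)
  # 2^0.4 ~ 1.32 < 1.5: significant FDR alone does not make an "up" call
  expect_equal(res$label, c("down", "NC", "NC", "up", "NC"))
  expect_equal(res$label_reason[5], "missing_fdr")
})
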