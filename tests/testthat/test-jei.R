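jei_fixture <- function(rows) {
  do.call(rbind, lapply(rows, function(r) {
    data.frame(contig = "chr1", donor = r[[1]], acceptor = r[[2]],
               strand = "+", sample_id = r[[3]], count = r[[4]],
               stringsAsFactors = FALSE)
  }))
}

intron1 <- data.frame(intron_id = "i1", gene_id = "g", transcript_id = NA,
                      contig = "chr1", strand = "+", donor = 1000L,
                      acceptor = 2000L, ordinal = 1L,
                      stringsAsFactors = FALSE)

test_that("JEI follows the shared-splice-site definition", {
  # only the exact junction: full splicing regardless of depth
  jt <- jei_fixture(list(list(1000L, 2000L, "s1", 57L)))
  expect_equal(compute_jei(jt, intron1, "s1"), 100)

  # exact 80 + cryptic acceptor sharing the donor 20 -> 80%
  jt <- jei_fixture(list(list(1000L, 2000L, "s1", 80L),
                         list(1000L, 1500L, "s1", 20L)))
  expect_equal(compute_jei(jt, intron1, "s1"), 80)

  # cryptic paths on both sides -> 60%
  jt <- jei_fixture(list(list(1000L, 2000L, "s1", 60L),
                         list(1000L, 1500L, "s1", 20L),
                         list(1400L, 2000L, "s1", 20L)))
  expect_equal(compute_jei(jt, intron1, "s1"), 60)

  # junctions touching neither splice site are excluded from the denominator
  jt <- jei_fixture(list(list(1000L, 2000L, "s1", 60L),
                         list(1200L, 1500L, "s1", 40L)))
  expect_equal(compute_jei(jt, intron1, "s1"), 100)

  # undefined (not zero) when no read uses either splice site
  expect_true(is.na(compute_jei(jt, intron1, "s2")))
})

test_that("adding a splice-site-sharing junction never increases JEI", {
  set.seed(11)
  for (rep in 1:25) {
    exact <- sample(10:200, 1)
    jt <- jei_fixture(list(list(1000L, 2000L, "s1", exact)))
    prev <- compute_jei(jt, intron1, "s1")
    for (extra in 1:3) {
      alt <- if (runif(1) < 0.5) list(1000L, sample(1100:1900, 1), "s1", sample(1:50, 1))
             else list(sample(1100:1900, 1), 2000L, "s1", sample(1:50, 1))
      jt2 <- rbind(jt, jei_fixture(list(alt)))
      jt2 <- jt2[!duplicated(jt2[, 1:5]), ]
      cur <- compute_jei(jt2, intron1, "s1")
      expect_lte(cur, prev + 1e-12)
      jt <- jt2; prev <- cur
    }
  }
})

test_that("group comparison matches the pooled-variance t oracle and thresholds", {
  mk <- function(jeis, samples) {
    do.call(rbind, lapply(seq_along(jeis), function(i) {
      jei_fixture(list(list(1000L, 2000L, samples[i], round(10 * jeis[i])),
                       list(1000L, 1500L, samples[i], round(10 * (100 - jeis[i])))))
    }))
  }
  mf <- data.frame(sample_id = c("c1", "c2", "c3", "t1", "t2", "t3"),
                   group = rep(c("DMSO", "drug"), each = 3),
                   replicate = rep(1:3, 2))
  ctrl <- c(100, 98, 99); trt <- c(60, 62, 61)
  jt <- rbind(mk(ctrl, c("c1", "c2", "c3")), mk(trt, c("t1", "t2", "t3")))
  res <- compare_jei_groups(jt, intron1, mf, control = "DMSO", treated = "drug")
  orc <- t_oracle(ctrl, trt)
  expect_equal(res$reduction_pct, 100 * (1 - mean(trt) / mean(ctrl)),
               tolerance = 1e-12)
  expect_equal(res$t, orc$t, tolerance = 1e-12)
  expect_equal(res$p, orc$p, tolerance = 1e-12)
  expect_true(res$flagged)

  # significant but below the 25% reduction threshold: not flagged
  trt2 <- c(80, 79, 81)
  jt2 <- rbind(mk(ctrl, c("c1", "c2", "c3")), mk(trt2, c("t1", "t2", "t3")))
  res2 <- compare_jei_groups(jt2, intron1, mf, control = "DMSO", treated = "drug")
  expect_lt(res2$p, 0.05)
  expect_lt(res2$reduction_pct, 25)
  expect_false(res2$flagged)
})

test_that("degenerate and untestable group comparisons are marked, not guessed", {
  mf <- data.frame(sample_id = c("c1", "c2", "t1", "t2"),
                   group = rep(c("DMSO", "drug"), each = 2),
                   replicate = rep(1:2, 2))
  mk1 <- function(smp, jei) {
    jei_fixture(list(list(1000L, 2000L, smp, round(10 * jei)),
                     list(1000L, 1500L, smp, round(10 * (100 - jei)))))
  }
  # both groups constant and equal: t = 0, P = 1, no flag
  jt <- rbind(mk1("c1", 90), mk1("c2", 90), mk1("t1", 90), mk1("t2", 90))
  res <- compare_jei_groups(jt, intron1, mf, control = "DMSO", treated = "drug")
  expect_equal(res$t, 0); expect_equal(res$p, 1); expect_false(res$flagged)
  # constant but unequal: P = 0 with degeneracy flag
  jt <- rbind(mk1("c1", 90), mk1("c2", 90), mk1("t1", 50), mk1("t2", 50))
  res <- compare_jei_groups(jt, intron1, mf, control = "DMSO", treated = "drug")
  expect_equal(res$p, 0); expect_true(res$degenerate)
  # a group with < 2 defined JEIs is untestable
  jt <- rbind(mk1("c1", 90), mk1("c2", 90), mk1("t1", 50))
  res <- compare_jei_groups(jt, intron1, mf, control = "DMSO", treated = "drug")
  expect_true(res$untestable)
})
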