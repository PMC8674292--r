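test_that("PWM training matches hand-computed log-odds and consensus behaviour", {
  # 3-site training set, pseudocount 1: score is the sum over positions of
  # log2((count + 1) / (n + 4) / 0.25)
  train <- c("CAGGTAAGT", "CAGGTAAGT", "AAGGTAAGT")
  m <- train_pwm_fallback(train, "donor9", pseudocount = 1, min_sites = 3)
  hand <- function(w) {
    sum(vapply(seq_len(9), function(j) {
      b <- substr(w, j, j)
      cnt <- sum(substr(train, j, j) == b)
      log2(((cnt + 1) / (3 + 4)) / 0.25)
    }, numeric(1)))
  }
  for (w in c("CAGGTAAGT", "AAGGTAAGT", "TTTTTTTTT", "ACGTACGTA")) {
    expect_equal(score_site(m, w), hand(w), tolerance = 1e-12)
  }

  # consensus-trained model: consensus attains the maximum, any single
  # substitution strictly decreases the score
  cons <- "CAGGTAAGT"
  mc <- train_pwm_fallback(rep(cons, 60), "donor9")
  sc0 <- score_site(mc, cons)
  for (j in 1:9) for (b in setdiff(c("A", "C", "G", "T"), substr(cons, j, j))) {
    w <- cons; substr(w, j, j) <- b
    expect_lt(score_site(mc, w), sc0)
  }
})

test_that("PWM scores are additive across single-position differences", {
  set.seed(5)
  train <- vapply(1:80, function(i) {
    paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE, prob = c(.4, .1, .4, .1)),
          collapse = "")
  }, character(1))
  m <- train_pwm_fallback(train, "donor9")
  lod <- m$data$lod
  for (rep in 1:20) {
    w <- paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE), collapse = "")
    j <- sample(9, 1)
    b <- sample(setdiff(c("A", "C", "G", "T"), substr(w, j, j)), 1)
    w2 <- w; substr(w2, j, j) <- b
    expect_equal(score_site(m, w) - score_site(m, w2),
                 lod[substr(w, j, j), j] - lod[b, j], tolerance = 1e-12)
  }
})

test_that("scoring contract: determinism, length checks, N handling", {
  m <- train_pwm_fallback(rep("CAGGTAAGT", 60), "donor9")
  expect_identical(score_site(m, "GAGGTAAGT"), score_site(m, "GAGGTAAGT"))
  expect_error(score_site(m, "CAGGTAAG"), "length")
  expect_true(is.na(score_site(m, "CAGGTANGT")))
  expect_error(train_pwm_fallback(rep("CAGGTAAGT", 10), "donor9"), "too few")
})

test_that("maximum-entropy table backend reproduces the published combination rules", {
  dir <- withr::local_tempdir()
  write_synthetic_maxent_dir(dir)
  don <- load_maxent_tables(dir, "donor9")
  w <- "CAGGTAAGT"
  rest <- paste0(substr(w, 1, 3), substr(w, 6, 9))
  cons <- (0.9896 * 0.9884) / (0.23 * 0.27)   # G at +1, T at +2
  expected <- log2(cons * (0.5 + b4rank(rest) / 4^7))
  expect_equal(score_site(don, w), expected, tolerance = 1e-10)

  acc <- load_maxent_tables(dir, "acceptor23")
  w3 <- "TTTTTTTTTTCTTTTTTTAGGCT"
  rest3 <- paste0(substr(w3, 1, 18), substr(w3, 21, 23))
  lens <- c(7, 7, 7, 7, 7, 3, 4, 3, 4)
  off <- c(0, 7, 14, 4, 11, 4, 7, 11, 14)
  tv <- vapply(1:9, function(i) {
    sub <- substr(rest3, off[i] + 1, off[i] + lens[i])
    1 + b4rank(sub) / (10 * 4^lens[i])
  }, numeric(1))
  cons3 <- (0.9903 * 0.9905) / (0.27 * 0.23)  # A, G at the -2/-1 AG
  expected3 <- log2(cons3 * prod(tv[1:5]) / prod(tv[6:9]))
  expect_equal(score_site(acc, w3), expected3, tolerance = 1e-10)

  # missing or truncated tables are load errors naming the file
  dir2 <- withr::local_tempdir()
  expect_error(load_maxent_tables(dir2, "donor9"), "me2x5")
  writeLines("0.5", file.path(dir2, "me2x5"))
  expect_error(load_maxent_tables(dir2, "donor9"), "truncated")
})

test_that("PWM model TSV serialisation round-trips", {
  m <- train_pwm_fallback(rep(c("CAGGTAAGT", "AAGGTAAGT"), 30), "donor9")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pwm_model(m, f)
  m2 <- read_pwm_model(f)
  expect_equal(m2$site_kind, "donor9")
  expect_equal(m2$data$lod, m$data$lod, tolerance = 1e-12)
  ws <- c("CAGGTAAGT", "TTTTTTTTT")
  expect_equal(score_site(m2, ws), score_site(m, ws), tolerance = 1e-12)
})

test_that("window extraction helpers honour strand and boundaries", {
  g <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 30), collapse = "")))
  # plus-strand exon [20, 40): donor window = [37, 46), acceptor = [0, 23)
  expect_equal(donor_window(g, "chr1", "+", 20, 40),
               fetch_seq(g, "chr1", 37, 46, "+"))
  expect_equal(acceptor_window(g, "chr1", "+", 20, 40),
               fetch_seq(g, "chr1", 0, 23, "+"))
  # mirrored minus-strand exon gives the reverse-complement windows
  expect_equal(donor_window(g, "chr1", "-", 80, 100),
               fetch_seq(g, "chr1", 74, 83, "-"))
  # truncation at the contig end yields NA, not an error
  expect_true(is.na(donor_window(g, "chr1", "+", 100, 118)))
  expect_true(is.na(acceptor_window(g, "chr1", "+", 10, 40)))
})
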