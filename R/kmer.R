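# K-mer enrichment at 5' splice sites: compares k-mer (k = 4-6) occurrence
# frequencies between two exon groups (e.g. compound-included vs no-change)
# in fixed windows around the donor site and reports a signed significance
# score SS = -S * log10(P), S = +1 for enrichment in group 1, -1 for
# depletion, with P from a two-sided Fisher exact test of one k-mer vs all
# other k-mers.

#' Extract fixed 5'ss windows for a set of exons
#'
#' Standard windows are `"exonic"` (positions -4..-1, the last four exonic
#' bases) and `"intronic"` (+1..+6, the first six intronic bases), both in
#' biological orientation; a custom window is given as
#' `c(from, to)` positions relative to the donor boundary (negative =
#' exonic, positive = intronic, no zero). Exons whose window crosses a
#' contig end are skipped and counted.
#'
#' @param exons data.frame with contig, strand, exon_start (or start),
#'   exon_end (or end).
#' @param genome `DNAStringSet`.
#' @param window `"exonic"`, `"intronic"`, or `c(from, to)`.
#' @return Character vector of window sequences; attribute `n_skipped`
#'   counts exons skipped at contig boundaries.
#' @export
extract_ss_windows <- function(exons, genome, window = "intronic") {
  if (is.character(window)) {
    window <- switch(window, exonic = c(-4L, -1L), intronic = c(1L, 6L),
                     stop("unknown window label: ", window))
  }
  stopifnot(length(window) == 2, window[1] <= window[2],
            all(window != 0))
  st <- if ("exon_start" %in% names(exons)) exons$exon_start else exons$start
  en <- if ("exon_end" %in% names(exons)) exons$exon_end else exons$end
  rel <- function(p) if (p < 0) p else p - 1L   # no position zero
  a <- rel(window[1]); b <- rel(window[2])
  out <- character(0); skipped <- 0L
  for (i in seq_len(nrow(exons))) {
    ctg <- exons$contig[i]; strand <- exons$strand[i]
    len <- length(genome[[ctg]])
    if (strand == "+") {
      lo <- en[i] + a; hi <- en[i] + b + 1L
      if (lo < 0 || hi > len) { skipped <- skipped + 1L; next }
      out <- c(out, fetch_seq(genome, ctg, lo, hi, "+"))
    } else {
      lo <- st[i] - b - 1L; hi <- st[i] - a
      if (lo < 0 || hi > len) { skipped <- skipped + 1L; next }
      out <- c(out, fetch_seq(genome, ctg, lo, hi, "-"))
    }
  }
  attr(out, "n_skipped") <- skipped
  out
}

count_kmers <- function(windows, k) {
  windows <- windows[nchar(windows) >= k]
  if (!length(windows)) return(integer(0))
  kmers <- unlist(lapply(windows, function(w) {
    substring(w, seq_len(nchar(w) - k + 1), seq_len(nchar(w) - k + 1) + k - 1)
  }))
  table(kmers)
}

#' Signed k-mer enrichment between two window sets
#'
#' For each k-mer observed in either group, a 2x2 table of its occurrence
#' count vs all other k-mer occurrences in the two groups is tested with a
#' two-sided Fisher exact test. Overlapping occurrences are counted (for
#' the 4-base exonic window with k = 4 this coincides with per-window
#' presence). Windows shorter than k are skipped. SS is 0 when the table
#' is degenerate.
#'
#' @param group1,group2 Character vectors of window sequences.
#' @param k K-mer size (4-6 typical).
#' @return data.frame: kmer, n1, n2, total1, total2, p, S, SS; sorted by
#'   decreasing |SS|.
#' @export
kmer_significance <- function(group1, group2, k) {
  if (!length(group1) || !length(group2)) stop("both groups must be non-empty")
  c1 <- count_kmers(group1, k); c2 <- count_kmers(group2, k)
  t1 <- sum(c1); t2 <- sum(c2)
  kmers <- sort(union(names(c1), names(c2)))
  rows <- lapply(kmers, function(km) {
    n1 <- if (km %in% names(c1)) as.integer(c1[[km]]) else 0L
    n2 <- if (km %in% names(c2)) as.integer(c2[[km]]) else 0L
    tab <- matrix(c(n1, t1 - n1, n2, t2 - n2), nrow = 2)
    degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    p <- if (degenerate) 1 else stats::fisher.test(tab)$p.value
    s <- if (n1 / t1 >= n2 / t2) 1L else -1L
    ss <- if (degenerate) 0 else -s * log10(p)
    # -S*log10(P): positive exactly when the k-mer is relatively enriched
    # in group 1 (log10 P <= 0)
    data.frame(kmer = km, n1 = n1, n2 = n2, total1 = t1, total2 = t2,
               p = p, S = s, SS = ss, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-abs(out$SS), out$kmer), , drop = FALSE]
}

#' K-mer enrichment over the standard 5'ss windows
#'
#' Runs [kmer_significance()] for each window label and k, concatenating
#' results with window/k columns — the tabular counterpart of a splice-site
#' enrichment heat map.
#'
#' @param exons1,exons2 Exon data.frames (group 1 vs group 2).
#' @param genome `DNAStringSet`.
#' @param ks K-mer sizes (default 4:6).
#' @param windows Window labels (default exonic and intronic).
#' @return data.frame with window, k prepended to [kmer_significance()]
#'   columns.
#' @export
kmer_enrichment_scan <- function(exons1, exons2, genome, ks = 4:6,
                                 windows = c("exonic", "intronic")) {
  out <- list()
  for (w in windows) {
    w1 <- extract_ss_windows(exons1, genome, w)
    w2 <- extract_ss_windows(exons2, genome, w)
    for (k in ks) {
      if (k > min(nchar(c(w1, w2)))) next   # window shorter than k
      res <- kmer_significance(w1, w2, k)
      res <- cbind(window = w, k = k, res)
      out[[length(out) + 1L]] <- res
    }
  }
  do.call(rbind, out)
}

#' Position frequency matrix of a window set
#'
#' Per-position base counts and frequencies for logo-style summaries
#' (rendering itself is out of scope; the matrix is written as TSV).
#'
#' @param windows Character vector of equal-length sequences.
#' @return data.frame: position, base, count, freq.
#' @export
position_frequency_matrix <- function(windows) {
  stopifnot(length(windows) > 0, length(unique(nchar(windows))) == 1)
  len <- nchar(windows[1])
  m <- matrix(unlist(strsplit(windows, "")), ncol = len, byrow = TRUE)
  rows <- lapply(seq_len(len), function(j) {
    cnt <- tabulate(match(m[, j], BASES), nbins = 4L)
    data.frame(position = j, base = BASES, count = cnt,
               freq = cnt / length(windows), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
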