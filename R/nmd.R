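# NMD-psiExon classification: a psiExon is NMD-inducing when its inclusion
# in the mature mRNA introduces a premature termination codon, causes a
# frameshift, or both. The 50-nucleotide exon-junction rule is deliberately
# NOT applied by default; classification follows the literal PTC-or-
# frameshift definition (available for exploration via `ejc_rule`).

STOP_CODONS <- c("TAA", "TAG", "TGA")

spliced_exon_seqs <- function(anno, genome, tid) {
  e <- anno$exons[anno$exons$transcript_id == tid, , drop = FALSE]
  e <- e[order(e$start), , drop = FALSE]
  meta <- anno$transcripts[anno$transcripts$transcript_id == tid, ]
  if (meta$strand == "-") e <- e[rev(seq_len(nrow(e))), , drop = FALSE]
  list(meta = meta, exons = e,
       seqs = vapply(seq_len(nrow(e)), function(i) {
         fetch_seq(genome, meta$contig, e$start[i], e$end[i], meta$strand)
       }, character(1)))
}

codons <- function(s) {
  n <- nchar(s) %/% 3
  if (n == 0) return(character(0))
  substring(s, 3 * (seq_len(n) - 1) + 1, 3 * seq_len(n))
}

#' Classify an included exon for nonsense-mediated decay
#'
#' The exon's sequence is spliced into the host transcript at its genomic
#' position (it must lie inside one intron of the transcript), translation
#' proceeds from the annotated start codon, and the exon is classified:
#' `frameshift` when its length is not divisible by 3; `ptc` when a stop
#' codon occurs within the inserted exon in the reading frame at the
#' insertion point or — for frameshifted insertions — anywhere downstream
#' of the insertion before the transcript's original stop; `is_nmd` =
#' `frameshift OR ptc`. Insertions upstream of the start codon are
#' non-coding and never NMD.
#'
#' @param exon list or one-row data.frame with contig, strand, start, end
#'   (0-based half-open genomic interval).
#' @param anno `transcript_set` holding the host transcript with CDS.
#' @param genome `DNAStringSet`.
#' @param transcript_id Host transcript; default picks the longest
#'   CDS-bearing transcript whose intron contains the exon.
#' @param ejc_rule Apply the 50-nt exon-junction rule to PTC calls
#'   (default `FALSE`; classification then follows the literal
#'   PTC-or-frameshift definition).
#' @return list: event coordinates, transcript_id, frameshift, ptc,
#'   is_nmd, stop_offset_in_exon (0-based offset of the first introduced
#'   stop within the exon, NA if none there), first_stop_tx_pos (0-based
#'   position of the first stop codon in the modified mRNA), frame_at_insertion,
#'   reason.
#' @export
classify_nmd <- function(exon, anno, genome, transcript_id = NULL,
                         ejc_rule = FALSE) {
  exon <- as.list(exon)
  cds_tx <- unique(anno$cds$transcript_id)
  if (is.null(transcript_id)) {
    # host = longest CDS-bearing transcript with an intron containing the exon
    best <- NULL; best_len <- -1
    for (tid in cds_tx) {
      e <- anno$exons[anno$exons$transcript_id == tid, , drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      meta <- anno$transcripts[anno$transcripts$transcript_id == tid, ]
      if (meta$contig != exon$contig || meta$strand != exon$strand) next
      if (nrow(e) < 2) next
      gaps_ok <- any(e$end[-nrow(e)] <= exon$start & e$start[-1] >= exon$end)
      if (!gaps_ok) next
      clen <- sum(with(anno$cds[anno$cds$transcript_id == tid, ], end - start))
      if (clen > best_len) { best <- tid; best_len <- clen }
    }
    if (is.null(best)) stop("exon not within an intron of any CDS-bearing transcript")
    transcript_id <- best
  }
  tx <- spliced_exon_seqs(anno, genome, transcript_id)
  e <- tx$exons   # transcription order
  # verify exon lies in an intron of this transcript (genomic order check)
  eg <- e[order(e$start), , drop = FALSE]
  slot <- which(eg$end[-nrow(eg)] <= exon$start & eg$start[-1] >= exon$end)
  if (!length(slot)) stop("exon not within an intron of transcript ", transcript_id)

  exon_seq <- fetch_seq(genome, exon$contig, exon$start, exon$end, exon$strand)
  exon_len <- exon$end - exon$start
  frameshift <- exon_len %% 3 != 0

  # mature mRNA with the exon inserted, in transcription order
  eg2 <- rbind(eg[seq_len(slot), c("start", "end")],
               data.frame(start = exon$start, end = exon$end),
               eg[(slot + 1):nrow(eg), c("start", "end")])
  if (tx$meta$strand == "-") eg2 <- eg2[rev(seq_len(nrow(eg2))), , drop = FALSE]
  mrna <- paste0(vapply(seq_len(nrow(eg2)), function(i) {
    fetch_seq(genome, tx$meta$contig, eg2$start[i], eg2$end[i], tx$meta$strand)
  }, character(1)), collapse = "")

  # genomic -> transcript coordinate (0-based) in the modified mRNA
  tx_pos <- function(gpos_start) {
    # gpos_start: 0-based genomic coordinate of the biological first base
    off <- 0L
    for (i in seq_len(nrow(eg2))) {
      w <- eg2$end[i] - eg2$start[i]
      inside <- gpos_start >= eg2$start[i] && gpos_start < eg2$end[i]
      if (inside) {
        within <- if (tx$meta$strand == "+") gpos_start - eg2$start[i]
                  else eg2$end[i] - 1L - gpos_start
        return(off + within)
      }
      off <- off + w
    }
    NA_integer_
  }
  cds <- anno$cds[anno$cds$transcript_id == transcript_id, , drop = FALSE]
  start_codon_g <- if (tx$meta$strand == "+") min(cds$start) else max(cds$end) - 1L
  cds_start_tx <- tx_pos(start_codon_g)
  exon_first_g <- if (exon$strand == "+") exon$start else exon$end - 1L
  exon_start_tx <- tx_pos(exon_first_g)

  if (exon_start_tx < cds_start_tx) {
    return(list(contig = exon$contig, strand = exon$strand,
                start = exon$start, end = exon$end,
                transcript_id = transcript_id, frameshift = FALSE,
                ptc = FALSE, is_nmd = FALSE,
                stop_offset_in_exon = NA_integer_,
                first_stop_tx_pos = NA_integer_,
                frame_at_insertion = NA_integer_,
                reason = "non-coding insertion"))
  }

  orf <- substr(mrna, cds_start_tx + 1L, nchar(mrna))
  cods <- codons(orf)
  stop_idx <- which(cods %in% STOP_CODONS)
  first_stop_tx <- if (length(stop_idx)) cds_start_tx + 3L * (stop_idx[1] - 1L)
                   else NA_integer_
  frame_at_insertion <- (exon_start_tx - cds_start_tx) %% 3L

  exon_tx_lo <- exon_start_tx; exon_tx_hi <- exon_start_tx + exon_len - 1L
  stop_in_exon <- !is.na(first_stop_tx) &&
    first_stop_tx + 2L >= exon_tx_lo && first_stop_tx <= exon_tx_hi

  # position the original stop would occupy in the modified transcript
  if (frameshift) {
    ptc <- !is.na(first_stop_tx) && first_stop_tx < orig_stop_in_modified(
      anno, genome, tx, eg, slot, exon_len, tx_pos, transcript_id)
  } else {
    ptc <- stop_in_exon
  }
  if (ejc_rule && ptc && !is.na(first_stop_tx)) {
    # PTC must lie >50 nt upstream of the last exon-exon junction; eg2 is
    # already in transcription order so its last row is the 3'-most exon
    last_junction_tx <- nchar(mrna) - (eg2$end[nrow(eg2)] - eg2$start[nrow(eg2)])
    ptc <- (first_stop_tx + 2L) < (last_junction_tx - 50L)
  }
  stop_offset <- if (stop_in_exon) as.integer(max(0L, first_stop_tx - exon_tx_lo))
                 else NA_integer_
  list(contig = exon$contig, strand = exon$strand,
       start = exon$start, end = exon$end,
       transcript_id = transcript_id,
       frameshift = frameshift, ptc = ptc,
       is_nmd = frameshift || ptc,
       stop_offset_in_exon = stop_offset,
       first_stop_tx_pos = first_stop_tx,
       frame_at_insertion = frame_at_insertion,
       reason = "")
}

orig_stop_in_modified <- function(anno, genome, tx, eg, slot, exon_len,
                                  tx_pos, transcript_id) {
  # transcript position (in the MODIFIED mRNA) of the original stop codon:
  # the original ORF's stop shifts downstream by the exon length when the
  # insertion precedes it
  cds <- anno$cds[anno$cds$transcript_id == transcript_id, , drop = FALSE]
  stop_g <- if (tx$meta$strand == "+") max(cds$end) - 1L else min(cds$start)
  p <- tx_pos(stop_g)
  if (is.na(p)) Inf else p
}

#' Classify many exons for NMD
#' @param exons data.frame with contig, strand, start, end (and optionally
#'   event_id).
#' @inheritParams classify_nmd
#' @return data.frame of calls, one row per exon.
#' @export
classify_nmd_batch <- function(exons, anno, genome, ejc_rule = FALSE) {
  rows <- lapply(seq_len(nrow(exons)), function(i) {
    r <- tryCatch(classify_nmd(exons[i, ], anno, genome, ejc_rule = ejc_rule),
                  error = function(e) NULL)
    if (is.null(r)) {
      r <- list(contig = exons$contig[i], strand = exons$strand[i],
                start = exons$start[i], end = exons$end[i],
                transcript_id = NA_character_, frameshift = NA, ptc = NA,
                is_nmd = NA, stop_offset_in_exon = NA_integer_,
                first_stop_tx_pos = NA_integer_,
                frame_at_insertion = NA_integer_, reason = "no host transcript")
    }
    if ("event_id" %in% names(exons)) r <- c(list(event_id = exons$event_id[i]), r)
    as.data.frame(r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read an externally computed differential-expression table
#'
#' TSV with header `gene_id, log2fc, fdr, base_mean` (extra columns kept).
#' One row per gene; FDR must lie in \[0, 1\] where present.
#'
#' @param path Path to the TSV.
#' @return data.frame.
#' @export
read_expression_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "fdr", "base_mean")
  if (!all(need %in% names(x))) {
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(x$gene_id)) stop("duplicate gene_id in expression table")
  if (any(!is.na(x$fdr) & (x$fdr < 0 | x$fdr > 1))) stop("FDR outside [0,1]")
  x
}

#' Rank-sum test of a gene set's expression shift
#'
#' Two-sided Wilcoxon rank-sum test of the log2 fold changes of gene set
#' `genes` against all other genes in the table; exact null when the
#' smaller group has <= 20 genes and there are no ties, normal
#' approximation with tie correction otherwise. Also returns the empirical
#' CDF of each group for plotting.
#'
#' @param expr Expression table (gene_id, log2fc, ...).
#' @param genes Character vector of gene ids (the NMD-host set); must have
#'   >= 3 members present in the table.
#' @return list(statistic, p, n_set, n_rest, median_shift, cdf) where cdf
#'   is a data.frame(group, log2fc, ecdf).
#' @export
lfc_shift_test <- function(expr, genes) {
  inset <- expr$gene_id %in% genes
  x <- expr$log2fc[inset]; y <- expr$log2fc[!inset]
  if (length(x) < 3) stop("gene set too small: ", length(x))
  if (!length(y)) stop("empty complement")
  exact <- min(length(x), length(y)) <= 20 &&
    !any(duplicated(c(x, y)))
  wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                           correct = !exact)
  ec <- rbind(
    data.frame(group = "set", log2fc = sort(x),
               ecdf = seq_along(x) / length(x)),
    data.frame(group = "all_other_genes", log2fc = sort(y),
               ecdf = seq_along(y) / length(y)))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_set = length(x), n_rest = length(y),
       median_shift = stats::median(x) - stats::median(y),
       cdf = ec)
}

#' Volcano-style expression classification
#'
#' `down` when fold change < 1/`fold_threshold` and FDR < `fdr_threshold`;
#' `up` when fold change > `fold_threshold` and FDR < threshold; otherwise
#' `NC`. Genes with missing FDR are `NC` with reason `"missing_fdr"`.
#'
#' @param expr Expression table with log2fc and fdr.
#' @param fold_threshold Fold-change threshold (default 1.5).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @return The table with columns `label` and `label_reason` appended.
#' @export
volcano_classify <- function(expr, fold_threshold = 1.5, fdr_threshold = 0.05) {
  fold <- 2^expr$log2fc
  lab <- rep("NC", nrow(expr))
  reason <- rep("", nrow(expr))
  miss <- is.na(expr$fdr)
  reason[miss] <- "missing_fdr"
  sig <- !miss & expr$fdr < fdr_threshold
  lab[sig & fold < 1 / fold_threshold] <- "down"
  lab[sig & fold > fold_threshold] <- "up"
  expr$label <- lab
  expr$label_reason <- reason
  expr
}
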