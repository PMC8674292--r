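# Genome-wide discovery of putative GA-psiExons: intronic exon candidates
# whose 5'ss is the fixed noncanonical AGA|gtaag motif (exon ends ...AGA,
# intron begins GTAAG) and whose upstream 3'ss scores above threshold.
# The search runs on the biological sense strand of each host intron only:
# pseudoexon inclusion requires the host pre-mRNA's orientation.

#' Scan annotated introns for AGAgtaag pseudoexon candidates
#'
#' For every occurrence of `motif` (default `AGAGTAAG`, the last three
#' exonic bases followed by the first five intronic bases) on the sense
#' strand of an intron, every upstream AG dinucleotide defines a candidate
#' acceptor: the candidate exon runs from the base after the AG through the
#' final A of the motif's AGA, and the acceptor's 23-mer window (20 intronic
#' + 3 exonic bases) is scored with `acceptor_model`. Candidates are
#' enumerated for exon lengths from 2 to `max_len + 10` so that
#' near-threshold decoys are reported with verdicts rather than silently
#' dropped; `passes_filters` requires `min_len <= length <= max_len`,
#' acceptor score > `min_acceptor_score`, and no annotation match.
#' Candidates whose acceptor window would cross the intron boundary are
#' skipped with reason `"window_truncated"`. Per motif occurrence the
#' best-scoring passing candidate is marked `primary` (ties to the shorter
#' exon). Candidates are deduplicated by (contig, strand, interval).
#'
#' @param genome `DNAStringSet`.
#' @param introns Intron table from [derive_introns()].
#' @param acceptor_model A `splice_site_model` of kind `acceptor23`.
#' @param annos Optional `transcript_set` (or list) for annotation status;
#'   when omitted all candidates count as unannotated.
#' @param min_len,max_len Exon length filter bounds (defaults 6, 200).
#' @param min_acceptor_score Acceptor score threshold (default 2.3).
#' @param motif Donor motif, exonic part in upper case position only by
#'   convention; must end with the 5 intronic bases (default "AGAGTAAG").
#' @param exonic_bases Number of exonic bases at the start of `motif`
#'   (default 3).
#' @return data.frame of candidates: contig, strand, start, end (0-based
#'   half-open genomic), length, gene_id, intron_id, intron_ordinal,
#'   acceptor23, acceptor_score, annotated, passes_filters, fail_reason,
#'   primary, backend.
#' @export
scan_introns <- function(genome, introns, acceptor_model, annos = NULL,
                         min_len = 6, max_len = 200,
                         min_acceptor_score = 2.3,
                         motif = "AGAGTAAG", exonic_bases = 3L) {
  stopifnot(inherits(acceptor_model, "splice_site_model"),
            acceptor_model$site_kind == "acceptor23")
  bnd <- if (!is.null(annos)) boundary_sets(annotation_list(annos))
  motif <- toupper(motif)
  mlen <- nchar(motif)
  out <- list()
  for (i in seq_len(nrow(introns))) {
    intr <- introns[i, ]
    iseq <- fetch_seq(genome, intr$contig, intr$donor, intr$acceptor,
                      intr$strand)   # biological orientation
    ilen <- nchar(iseq)
    hits <- gregexpr(motif, iseq, fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    for (p in as.integer(hits)) {
      # biological positions (1-based within intron); exon ends at the last
      # exonic base of the motif
      exon_end_b <- p + exonic_bases - 1L
      if (p + mlen - 1L > ilen) next   # intronic part must stay intronic
      # candidate acceptors: AG dinucleotides upstream; exon starts at q+2
      # (1-based), exon length = exon_end_b - (q+2) + 1
      for (L in 2:(max_len + 10L)) {
        q <- exon_end_b - L - 1L       # AG at biological positions q, q+1
        if (q < 1L) break
        if (substr(iseq, q, q + 1L) != "AG") next
        exon_start_b <- q + 2L
        win_start <- q - 18L           # 23-mer: 18 tract + AG + 3 exonic
        reason <- character(0)
        win <- NA_character_; sc <- NA_real_
        if (win_start < 1L) {
          reason <- "window_truncated"
        } else {
          win <- substr(iseq, win_start, win_start + 22L)
          sc <- score_site(acceptor_model, win)
        }
        # genomic coordinates of exon [start, end), strand-aware
        if (intr$strand == "+") {
          g_start <- intr$donor + exon_start_b - 1L
          g_end <- intr$donor + exon_end_b
        } else {
          g_end <- intr$acceptor - (exon_start_b - 1L)
          g_start <- intr$acceptor - exon_end_b
        }
        annotated <- FALSE
        if (!is.null(bnd)) {
          for (b in bnd) {
            if (paste(intr$contig, intr$strand, g_start, g_end) %in% b$exons) {
              annotated <- TRUE
            } else {
              left_ann <- paste(intr$contig, intr$strand, g_start) %in% b$starts
              right_ann <- paste(intr$contig, intr$strand, g_end) %in% b$ends
              if (left_ann && right_ann) annotated <- TRUE
            }
          }
        }
        if (L < min_len) reason <- c(reason, "too_short")
        if (L > max_len) reason <- c(reason, "too_long")
        if (!is.na(sc) && sc <= min_acceptor_score) reason <- c(reason, "weak_acceptor")
        if (is.na(sc) && !"window_truncated" %in% reason) reason <- c(reason, "unscorable")
        if (annotated) reason <- c(reason, "annotated")
        out[[length(out) + 1L]] <- data.frame(
          contig = intr$contig, strand = intr$strand,
          start = g_start, end = g_end, length = L,
          gene_id = intr$gene_id, intron_id = intr$intron_id,
          intron_ordinal = intr$ordinal,
          motif_pos = if (intr$strand == "+") intr$donor + p - 1L else
            intr$acceptor - p,
          acceptor23 = win, acceptor_score = sc,
          annotated = annotated,
          passes_filters = length(reason) == 0L,
          fail_reason = paste(reason, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(), strand = character(),
                      start = integer(), end = integer(), length = integer(),
                      gene_id = character(), intron_id = character(),
                      intron_ordinal = integer(), motif_pos = integer(),
                      acceptor23 = character(), acceptor_score = numeric(),
                      annotated = logical(), passes_filters = logical(),
                      fail_reason = character(), primary = logical(),
                      backend = character()))
  }
  cand <- do.call(rbind, out)
  # deduplicate by (contig, strand, interval)
  cand <- cand[!duplicated(paste(cand$contig, cand$strand, cand$start, cand$end)),
               , drop = FALSE]
  # primary = best-scoring passing candidate per motif occurrence
  cand$primary <- FALSE
  key <- paste(cand$contig, cand$strand, cand$motif_pos)
  for (k in unique(key[cand$passes_filters])) {
    idx <- which(key == k & cand$passes_filters)
    best <- idx[order(-cand$acceptor_score[idx], cand$length[idx])][1]
    cand$primary[best] <- TRUE
  }
  cand$backend <- acceptor_model$backend
  rownames(cand) <- NULL
  cand
}

#' Re-evaluate candidate annotation status against annotation sources
#'
#' A candidate is annotated when its exon interval exactly matches an
#' annotated exon in any source, or when both of its splice sites match
#' annotated exon boundaries in any single source. Filter verdicts and
#' fail reasons are updated accordingly.
#'
#' @param candidates Output of [scan_introns()].
#' @param annos `transcript_set` or list of them.
#' @return The candidates with `annotated`, `passes_filters`, `fail_reason`
#'   refreshed.
#' @export
annotate_candidates <- function(candidates, annos) {
  bnd <- boundary_sets(annotation_list(annos))
  ann <- rep(FALSE, nrow(candidates))
  for (b in bnd) {
    exact <- paste(candidates$contig, candidates$strand,
                   candidates$start, candidates$end) %in% b$exons
    both <- (paste(candidates$contig, candidates$strand, candidates$start) %in% b$starts) &
      (paste(candidates$contig, candidates$strand, candidates$end) %in% b$ends)
    ann <- ann | exact | both
  }
  candidates$annotated <- ann
  # rebuild verdicts: strip/add the "annotated" reason
  reasons <- strsplit(candidates$fail_reason, ",", fixed = TRUE)
  reasons <- lapply(seq_along(reasons), function(i) {
    r <- setdiff(reasons[[i]], c("annotated", ""))
    if (ann[i]) r <- c(r, "annotated")
    r
  })
  candidates$fail_reason <- vapply(reasons, paste, character(1), collapse = ",")
  candidates$passes_filters <- lengths(reasons) == 0L
  candidates
}

#' Census of exon-terminal dinucleotides at the 5'ss
#'
#' Counts the last two exonic bases (positions -2, -1 relative to the
#' donor site, biological orientation) of every internal exon — an exon
#' possessing a downstream intron in transcription order. AG is the
#' canonical terminus; GA marks the noncanonical class responsive to
#' splicing modifiers.
#'
#' @param anno A `transcript_set`.
#' @param genome `DNAStringSet`.
#' @return data.frame: dinucleotide, count, percent, canonical; all 16
#'   dinucleotides present.
#' @export
exon_end_dinucleotide_census <- function(anno, genome) {
  din <- character(0)
  for (tid in unique(anno$exons$transcript_id)) {
    e <- anno$exons[anno$exons$transcript_id == tid, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2) next
    meta <- anno$transcripts[anno$transcripts$transcript_id == tid, ]
    for (i in seq_len(nrow(e))) {
      has_down <- if (meta$strand == "+") i < nrow(e) else i > 1
      if (!has_down) next
      d <- if (meta$strand == "+") {
        fetch_seq(genome, meta$contig, e$end[i] - 2, e$end[i], "+")
      } else {
        fetch_seq(genome, meta$contig, e$start[i], e$start[i] + 2, "-")
      }
      din <- c(din, d)
    }
  }
  all16 <- as.vector(outer(BASES, BASES, paste0))
  cnt <- table(factor(din, levels = all16))
  data.frame(dinucleotide = all16,
             count = as.integer(cnt),
             percent = if (length(din)) 100 * as.integer(cnt) / length(din)
                       else rep(0, 16),
             canonical = all16 == "AG",
             stringsAsFactors = FALSE)
}

#' Write scan candidates as BED6
#'
#' Score column is the acceptor score x 100, truncated toward zero.
#'
#' @param candidates Scan output.
#' @param path Output path.
#' @param passing_only Write only candidates passing all filters (default
#'   `TRUE`).
#' @export
write_scan_bed <- function(candidates, path, passing_only = TRUE) {
  x <- if (passing_only) candidates[candidates$passes_filters, , drop = FALSE]
       else candidates
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   x$contig, x$start, x$end,
                   paste0(x$intron_id, ".cand", seq_len(nrow(x))),
                   ifelse(is.na(x$acceptor_score), 0L,
                          as.integer(trunc(x$acceptor_score * 100))),
                   x$strand)
  writeLines(lines, path)
  invisible(path)
}
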