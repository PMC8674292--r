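# Splice-site strength models. Two backends score fixed windows around the
# exon/intron boundary:
#   donor9     9-mer, positions -3..+6  (3 exonic + 6 intronic bases)
#   acceptor23 23-mer, positions -20..+3 (20 intronic + 3 exonic bases)
# "maxent-tables" loads the published maximum-entropy score tables from
# their distributed file layout and reproduces the published scorer's
# log2-odds; "pwm-fallback" is a position weight matrix trained from
# annotated sites, so fully self-contained corpora can be scored without
# third-party tables. Scores from both backends are log2 odds against a
# background model.

SS_WINDOW_LEN <- c(donor9 = 9L, acceptor23 = 23L)
BASES <- c("A", "C", "G", "T")

# background and boundary-consensus base frequencies used by the published
# maximum-entropy scorer (donor: +1/+2 = GT; acceptor: AG at -2/-1)
MAXENT_BGD <- c(A = 0.27, C = 0.23, G = 0.23, T = 0.27)
MAXENT_DONOR_CONS1 <- c(A = 0.0040, C = 0.0032, G = 0.9896, T = 0.0032)
MAXENT_DONOR_CONS2 <- c(A = 0.0034, C = 0.0039, G = 0.0042, T = 0.9884)
MAXENT_ACC_CONS1 <- c(A = 0.9903, C = 0.0032, G = 0.0034, T = 0.0030)
MAXENT_ACC_CONS2 <- c(A = 0.0027, C = 0.0037, G = 0.9905, T = 0.0030)

new_ss_model <- function(site_kind, backend, data, meta = list()) {
  structure(list(site_kind = site_kind, backend = backend, data = data,
                 meta = meta),
            class = "splice_site_model")
}

#' @export
print.splice_site_model <- function(x, ...) {
  cat("splice_site_model: ", x$site_kind, " [", x$backend, "]\n", sep = "")
  invisible(x)
}

seq_to_index <- function(seqs) {
  # base-4 rank of an ACGT string, A=0 C=1 G=2 T=3, first base most significant
  n <- nchar(seqs[1])
  m <- matrix(match(unlist(strsplit(seqs, "")), BASES) - 1L,
              ncol = n, byrow = TRUE)
  as.integer(m %*% (4L ^ ((n - 1L):0L))) + 1L
}

#' Load published maximum-entropy splice-site score tables
#'
#' Reads the distributed table layout of the published maximum-entropy
#' scorer. For the donor model the directory must contain `me2x5` (one
#' score per line for each 7-mer over the non-consensus positions, in
#' base-4 A<C<G<T order, optionally accompanied by `splice5sequences`
#' giving the ordering explicitly). For the acceptor model it must contain
#' `me2x3acc1` .. `me2x3acc9`, the nine factor tables of the acceptor
#' maximum-entropy decomposition (lengths 7,7,7,7,7,3,4,3,4 nt).
#'
#' @param path Directory holding the table files.
#' @param site_kind `"donor9"` or `"acceptor23"`.
#' @return A `splice_site_model` with backend `"maxent-tables"`.
#' @export
load_maxent_tables <- function(path, site_kind = c("donor9", "acceptor23")) {
  site_kind <- match.arg(site_kind)
  read_tab <- function(fname, expected_len) {
    f <- file.path(path, fname)
    if (!file.exists(f)) stop("missing score table file: ", f)
    v <- as.numeric(readLines(f))
    if (length(v) != expected_len || anyNA(v)) {
      stop("truncated or malformed score table: ", f,
           " (expected ", expected_len, " numeric lines)")
    }
    v
  }
  if (site_kind == "donor9") {
    scores <- read_tab("me2x5", 4^7)
    sf <- file.path(path, "splice5sequences")
    if (file.exists(sf)) {
      seqs <- toupper(readLines(sf))
      seqs <- seqs[nzchar(seqs)]
      if (length(seqs) != 4^7) stop("malformed splice5sequences in ", path)
      scores[seq_to_index(seqs)] <- scores  # reorder to base-4 rank
    }
    new_ss_model("donor9", "maxent-tables", list(me2x5 = scores),
                 meta = list(source = path))
  } else {
    lens <- c(7L, 7L, 7L, 7L, 7L, 3L, 4L, 3L, 4L)
    tabs <- lapply(seq_len(9), function(i) read_tab(paste0("me2x3acc", i), 4^lens[i]))
    new_ss_model("acceptor23", "maxent-tables",
                 list(tabs = tabs, lens = lens), meta = list(source = path))
  }
}

#' Train a position-weight-matrix fallback splice-site model
#'
#' Per-position log2 odds of base frequency (with additive pseudocount)
#' against a uniform 0.25 background; a window's score is the sum over
#' positions. Used where the published tables cannot be redistributed,
#' e.g. on synthetic corpora.
#'
#' @param windows Character vector of training windows (all ACGT, all the
#'   correct length for `site_kind`).
#' @param site_kind `"donor9"` or `"acceptor23"`.
#' @param pseudocount Additive pseudocount (default 1).
#' @param min_sites Minimum number of training sites (default 50).
#' @param background Background base probability (default uniform 0.25).
#' @return A `splice_site_model` with backend `"pwm-fallback"`.
#' @export
train_pwm_fallback <- function(windows, site_kind = c("donor9", "acceptor23"),
                               pseudocount = 1, min_sites = 50,
                               background = 0.25) {
  site_kind <- match.arg(site_kind)
  len <- SS_WINDOW_LEN[[site_kind]]
  windows <- toupper(windows)
  if (length(windows) < min_sites) {
    stop("too few training sites: ", length(windows), " < ", min_sites)
  }
  if (any(nchar(windows) != len)) stop("training window of wrong length")
  if (any(grepl("[^ACGT]", windows))) stop("non-ACGT base in training windows")
  m <- matrix(unlist(strsplit(windows, "")), ncol = len, byrow = TRUE)
  counts <- vapply(seq_len(len), function(j) {
    tabulate(match(m[, j], BASES), nbins = 4L)
  }, integer(4))
  lod <- log2(((counts + pseudocount) /
               (length(windows) + 4 * pseudocount)) / background)
  dimnames(lod) <- list(BASES, paste0("p", seq_len(len)))
  new_ss_model(site_kind, "pwm-fallback", list(lod = lod),
               meta = list(n_sites = length(windows), pseudocount = pseudocount,
                           background = background))
}

#' Score splice-site windows
#'
#' Deterministic log2-odds score for each window. Windows must be exactly
#' the model's length and must be supplied pre-oriented (biological 5'->3'
#' sequence); windows containing non-ACGT characters score `NA`.
#'
#' @param model A `splice_site_model`.
#' @param windows Character vector of windows.
#' @return Numeric vector of scores (`NA` where a window contains N).
#' @export
score_site <- function(model, windows) {
  stopifnot(inherits(model, "splice_site_model"))
  len <- SS_WINDOW_LEN[[model$site_kind]]
  windows <- toupper(windows)
  if (any(nchar(windows) != len)) {
    stop("window length must be ", len, " for ", model$site_kind)
  }
  ok <- !grepl("[^ACGT]", windows)
  out <- rep(NA_real_, length(windows))
  if (!any(ok)) return(out)
  w <- windows[ok]
  out[ok] <- switch(model$backend,
    "pwm-fallback" = {
      m <- matrix(match(unlist(strsplit(w, "")), BASES), ncol = len, byrow = TRUE)
      vapply(seq_len(nrow(m)), function(i) {
        sum(model$data$lod[cbind(m[i, ], seq_len(len))])
      }, numeric(1))
    },
    "maxent-tables" = {
      if (model$site_kind == "donor9") maxent_score5(model, w)
      else maxent_score3(model, w)
    },
    stop("unknown backend: ", model$backend)
  )
  out
}

maxent_score5 <- function(model, w) {
  b4 <- substr(w, 4, 4); b5 <- substr(w, 5, 5)
  cons <- (MAXENT_DONOR_CONS1[b4] * MAXENT_DONOR_CONS2[b5]) /
    (MAXENT_BGD[b4] * MAXENT_BGD[b5])
  rest <- paste0(substr(w, 1, 3), substr(w, 6, 9))
  log2(cons * model$data$me2x5[seq_to_index(rest)])
}

maxent_score3 <- function(model, w) {
  b19 <- substr(w, 19, 19); b20 <- substr(w, 20, 20)
  cons <- (MAXENT_ACC_CONS1[b19] * MAXENT_ACC_CONS2[b20]) /
    (MAXENT_BGD[b19] * MAXENT_BGD[b20])
  rest <- paste0(substr(w, 1, 18), substr(w, 21, 23))
  # offsets of the nine factor subsequences within the 21-mer rest
  off <- c(0L, 7L, 14L, 4L, 11L, 4L, 7L, 11L, 14L)
  lens <- model$data$lens
  sc <- vapply(seq_len(9), function(i) {
    sub <- substr(rest, off[i] + 1L, off[i] + lens[i])
    model$data$tabs[[i]][seq_to_index(sub)]
  }, numeric(length(w)))
  sc <- matrix(sc, nrow = length(w))
  me <- (sc[, 1] * sc[, 2] * sc[, 3] * sc[, 4] * sc[, 5]) /
    (sc[, 6] * sc[, 7] * sc[, 8] * sc[, 9])
  log2(cons * me)
}

#' Serialise / restore a PWM fallback model as TSV
#'
#' The matrix is written with a `#` header recording site kind, training
#' size, pseudocount and background, so provenance travels with the file.
#'
#' @param model A `splice_site_model` with backend `"pwm-fallback"`.
#' @param path Output (input) path.
#' @return `write_pwm_model`: the path, invisibly; `read_pwm_model`: the
#'   restored model.
#' @export
write_pwm_model <- function(model, path) {
  stopifnot(model$backend == "pwm-fallback")
  hdr <- sprintf("# psiexon pwm-fallback site_kind=%s n_sites=%d pseudocount=%g background=%g",
                 model$site_kind, model$meta$n_sites, model$meta$pseudocount,
                 model$meta$background)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(model$data$lod, con, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_pwm_model
#' @export
read_pwm_model <- function(path) {
  hdr <- readLines(path, n = 1)
  get <- function(k) sub(paste0(".*", k, "="), "", hdr)
  kind <- sub(" .*", "", get("site_kind"))
  lod <- as.matrix(utils::read.table(path, sep = "\t", skip = 1, header = TRUE,
                                     row.names = 1, check.names = FALSE))
  new_ss_model(kind, "pwm-fallback", list(lod = lod),
               meta = list(n_sites = as.integer(sub(" .*", "", get("n_sites"))),
                           pseudocount = as.numeric(sub(" .*", "", get("pseudocount"))),
                           background = as.numeric(sub(" .*", "", get("background")))))
}

# ---- window extraction -----------------------------------------------------

#' Extract the 9-mer donor window of an exon, strand-aware
#'
#' The donor (5'ss) window spans the last 3 exonic and first 6 intronic
#' bases in biological orientation. Returns `NA` when the window runs past
#' a contig end.
#'
#' @param genome `DNAStringSet`.
#' @param contig,strand Exon location.
#' @param exon_start,exon_end 0-based half-open exon interval.
#' @return Character scalar (or `NA_character_`).
#' @export
donor_window <- function(genome, contig, strand, exon_start, exon_end) {
  len <- length(genome[[contig]])
  if (strand == "+") {
    if (exon_end - 3 < 0 || exon_end + 6 > len) return(NA_character_)
    fetch_seq(genome, contig, exon_end - 3, exon_end + 6, "+")
  } else {
    if (exon_start - 6 < 0 || exon_start + 3 > len) return(NA_character_)
    fetch_seq(genome, contig, exon_start - 6, exon_start + 3, "-")
  }
}

#' Extract the 23-mer acceptor window of an exon, strand-aware
#'
#' The acceptor (3'ss) window spans the last 20 intronic and first 3 exonic
#' bases in biological orientation.
#'
#' @inheritParams donor_window
#' @return Character scalar (or `NA_character_`).
#' @export
acceptor_window <- function(genome, contig, strand, exon_start, exon_end) {
  len <- length(genome[[contig]])
  if (strand == "+") {
    if (exon_start - 20 < 0 || exon_start + 3 > len) return(NA_character_)
    fetch_seq(genome, contig, exon_start - 20, exon_start + 3, "+")
  } else {
    if (exon_end - 3 < 0 || exon_end + 20 > len) return(NA_character_)
    fetch_seq(genome, contig, exon_end - 3, exon_end + 20, "-")
  }
}

#' Collect annotated splice-site training windows from an annotation
#'
#' Donor windows come from every exon with a downstream intron and acceptor
#' windows from every exon with an upstream intron (transcription order).
#' Windows truncated by contig ends or containing N are dropped.
#'
#' @param anno A `transcript_set`.
#' @param genome `DNAStringSet`.
#' @return list(donor9 = character vector, acceptor23 = character vector).
#' @export
annotated_ss_windows <- function(anno, genome) {
  don <- character(0); acc <- character(0)
  for (tid in unique(anno$exons$transcript_id)) {
    e <- anno$exons[anno$exons$transcript_id == tid, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2) next
    meta <- anno$transcripts[anno$transcripts$transcript_id == tid, ]
    for (i in seq_len(nrow(e))) {
      has_down <- if (meta$strand == "+") i < nrow(e) else i > 1
      has_up <- if (meta$strand == "+") i > 1 else i < nrow(e)
      if (has_down) {
        don <- c(don, donor_window(genome, meta$contig, meta$strand,
                                   e$start[i], e$end[i]))
      }
      if (has_up) {
        acc <- c(acc, acceptor_window(genome, meta$contig, meta$strand,
                                      e$start[i], e$end[i]))
      }
    }
  }
  keep <- function(x) x[!is.na(x) & !grepl("[^ACGT]", x)]
  list(donor9 = keep(don), acceptor23 = keep(acc))
}
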