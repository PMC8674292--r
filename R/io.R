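#' @import methods
#' @importFrom stats setNames
NULL

# Internal coordinate convention: 0-based, half-open [start, end) on the
# genomic forward strand, for every interval in the package (exons, introns,
# junctions, scan candidates).  1-based inclusive dialects (GTF, SJ tab) are
# converted at the I/O boundary and nowhere else.

#' Read a genome FASTA
#'
#' Loads a (plain or gzipped) FASTA file into a `DNAStringSet`, keyed by the
#' first whitespace-delimited token of each header, with sequences
#' upper-cased. Only A/C/G/T/N are accepted after normalisation.
#'
#' @param path Path to a FASTA file.
#' @return A `Biostrings::DNAStringSet` with unique contig names.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate contig names in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  if (any(Biostrings::width(seqs) == 0L)) stop("empty contig in ", path)
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  af <- Biostrings::alphabetFrequency(seqs)
  bad <- rowSums(af[, setdiff(colnames(af), c("A", "C", "G", "T", "N")),
                    drop = FALSE]) > 0
  if (any(bad)) {
    ctg <- names(seqs)[which(bad)[1]]
    s <- as.character(seqs[[which(bad)[1]]])
    pos <- regexpr("[^ACGTN]", s)
    stop("non-ACGTN character in contig ", ctg, " at position ", pos)
  }
  seqs
}

#' Fetch a genomic interval, strand-aware
#'
#' Returns the sequence of `[start, end)` (0-based half-open) on the given
#' contig; for `strand == "-"` the reverse complement is returned, i.e. the
#' sequence in biological (5' to 3') orientation.
#'
#' @param genome A `DNAStringSet` from [read_genome()].
#' @param contig Contig name.
#' @param start,end 0-based half-open interval bounds.
#' @param strand `"+"` or `"-"`.
#' @return A character scalar.
#' @export
fetch_seq <- function(genome, contig, start, end, strand = "+") {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  len <- length(genome[[contig]])
  if (start < 0 || end > len || start >= end) {
    stop("interval [", start, ",", end, ") out of bounds for ", contig,
         " (length ", len, ")")
  }
  s <- Biostrings::subseq(genome[[contig]], start + 1L, end)
  if (identical(strand, "-")) s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Reverse-complement a nucleotide string
#' @param x Character vector of ACGTN strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

new_transcript_set <- function(transcripts, exons, cds, source) {
  structure(list(transcripts = transcripts, exons = exons, cds = cds,
                 source = source),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set [", x$source, "]: ", nrow(x$transcripts),
      " transcripts, ", nrow(x$exons), " exons, ",
      nrow(x$cds), " CDS segments\n", sep = "")
  invisible(x)
}

#' Read a transcript annotation
#'
#' Parses GTF, GFF3 or BED12 into a `transcript_set`: per-transcript exon
#' and CDS intervals in the internal 0-based half-open convention. Several
#' annotation files (e.g. RefSeq-, Ensembl- and UCSC-style sets) may be
#' loaded separately and tagged by `source` for annotation-status queries.
#'
#' @param path Path to the annotation file.
#' @param dialect One of `"gtf"`, `"gff3"`, `"bed12"`.
#' @param source Free-text tag naming the annotation source; defaults to the
#'   file name.
#' @return A `transcript_set` with elements `transcripts` (transcript_id,
#'   gene_id, contig, strand), `exons` (transcript_id, start, end), `cds`
#'   (transcript_id, start, end), `source`.
#' @export
read_annotation <- function(path, dialect = c("gtf", "gff3", "bed12"),
                            source = basename(path)) {
  dialect <- match.arg(dialect)
  if (dialect == "bed12") return(read_annotation_bed12(path, source))
  gr <- rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  tid <- as.character(md$transcript_id)
  if (all(is.na(tid)) && "Parent" %in% names(md)) {
    tid <- vapply(md$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
                  character(1))
    tid <- sub("^transcript:", "", tid)
  }
  gid <- if ("gene_id" %in% names(md)) as.character(md$gene_id) else tid
  keep <- type %in% c("exon", "CDS")
  df <- data.frame(
    type = type[keep],
    transcript_id = tid[keep],
    gene_id = gid[keep],
    contig = as.character(GenomicRanges::seqnames(gr))[keep],
    strand = as.character(GenomicRanges::strand(gr))[keep],
    start = GenomicRanges::start(gr)[keep] - 1L,   # 1-based incl -> 0-based half-open
    end = GenomicRanges::end(gr)[keep],
    stringsAsFactors = FALSE
  )
  if (any(is.na(df$transcript_id))) stop("records without transcript_id in ", path)
  build_transcript_set(df, source)
}

read_annotation_bed12 <- function(path, source) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(S4Vectors::mcols(gr)$blocks)) stop("BED input lacks 12-column block structure: ", path)
  rows <- lapply(seq_along(gr), function(i) {
    blocks <- S4Vectors::mcols(gr)$blocks[[i]]
    chrom_start <- GenomicRanges::start(gr)[i] - 1L
    data.frame(
      type = "exon",
      transcript_id = as.character(S4Vectors::mcols(gr)$name[i]),
      gene_id = as.character(S4Vectors::mcols(gr)$name[i]),
      contig = as.character(GenomicRanges::seqnames(gr))[i],
      strand = as.character(GenomicRanges::strand(gr))[i],
      start = chrom_start + IRanges::start(blocks) - 1L,  # block starts are 1-based within gr
      end = chrom_start + IRanges::end(blocks),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  ts <- S4Vectors::mcols(gr)$thick
  if (!is.null(ts)) {
    # the thick span covers introns; the CDS is its intersection with each
    # block (exon)
    th <- data.frame(name = as.character(S4Vectors::mcols(gr)$name),
                     start = IRanges::start(ts) - 1L, end = IRanges::end(ts))
    cds <- df
    cds$type <- "CDS"
    i <- match(cds$transcript_id, th$name)
    cds$start <- pmax(cds$start, th$start[i])
    cds$end <- pmin(cds$end, th$end[i])
    cds <- cds[cds$end > cds$start, , drop = FALSE]
    df <- rbind(df, cds)
  }
  build_transcript_set(df, source)
}

build_transcript_set <- function(df, source) {
  ex <- df[df$type == "exon", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  ex <- ex[order(ex$transcript_id, ex$start), , drop = FALSE]
  # validate per transcript: sorted, non-overlapping
  for (tx in split(ex, ex$transcript_id)) {
    if (nrow(tx) > 1 && any(tx$start[-1] < tx$end[-nrow(tx)])) {
      stop("overlapping/malformed exons in transcript ", tx$transcript_id[1])
    }
  }
  tr <- unique(ex[, c("transcript_id", "gene_id", "contig", "strand")])
  if (anyDuplicated(tr$transcript_id)) {
    stop("transcript spans multiple contigs/strands: ",
         tr$transcript_id[duplicated(tr$transcript_id)][1])
  }
  # CDS within exon union
  if (nrow(cds)) {
    exs <- split(ex, ex$transcript_id)
    for (i in seq_len(nrow(cds))) {
      e <- exs[[cds$transcript_id[i]]]
      if (is.null(e) ||
          !any(cds$start[i] >= e$start & cds$end[i] <= e$end)) {
        stop("CDS outside exons for transcript ", cds$transcript_id[i])
      }
    }
  }
  rownames(ex) <- rownames(cds) <- rownames(tr) <- NULL
  new_transcript_set(
    tr,
    ex[, c("transcript_id", "start", "end")],
    if (nrow(cds)) cds[order(cds$transcript_id, cds$start),
                       c("transcript_id", "start", "end")]
    else data.frame(transcript_id = character(), start = integer(), end = integer()),
    source
  )
}

#' Derive introns from transcript models
#'
#' One intron per gap between consecutive exons of each transcript. With
#' `per_gene_union = TRUE`, introns identical in coordinates are collapsed
#' within each gene. Ordinal indices count in transcription order, i.e. from
#' the genomically rightmost intron for minus-strand genes.
#'
#' @param anno A `transcript_set`.
#' @param per_gene_union Collapse identical introns shared by transcripts of
#'   one gene (default `TRUE`).
#' @return data.frame: intron_id, gene_id, transcript_id, contig, strand,
#'   donor (0-based first intronic base), acceptor (one past the last
#'   intronic base), ordinal. `donor < acceptor` always; on the minus strand
#'   the genomic-left coordinate is biologically the 3'ss.
#' @export
derive_introns <- function(anno, per_gene_union = TRUE) {
  stopifnot(inherits(anno, "transcript_set"))
  out <- list()
  for (tid in unique(anno$exons$transcript_id)) {
    e <- anno$exons[anno$exons$transcript_id == tid, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2) next
    meta <- anno$transcripts[anno$transcripts$transcript_id == tid, ]
    don <- e$end[-nrow(e)]
    acc <- e$start[-1]
    n <- length(don)
    ord <- if (meta$strand == "-") rev(seq_len(n)) else seq_len(n)
    out[[tid]] <- data.frame(
      gene_id = meta$gene_id, transcript_id = tid,
      contig = meta$contig, strand = meta$strand,
      donor = don, acceptor = acc, ordinal = ord,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(intron_id = character(), gene_id = character(),
                      transcript_id = character(), contig = character(),
                      strand = character(), donor = integer(),
                      acceptor = integer(), ordinal = integer()))
  }
  ix <- do.call(rbind, out)
  rownames(ix) <- NULL
  if (per_gene_union) {
    key <- paste(ix$gene_id, ix$contig, ix$donor, ix$acceptor)
    first <- !duplicated(key)
    ix <- ix[first, , drop = FALSE]
    # re-rank ordinals within gene in transcription order
    ix <- ix[order(ix$gene_id, ix$donor), , drop = FALSE]
    ix$ordinal <- unlist(lapply(split(seq_len(nrow(ix)), ix$gene_id), function(i) {
      n <- length(i)
      if (ix$strand[i[1]] == "-") rev(seq_len(n)) else seq_len(n)
    })[unique(ix$gene_id)], use.names = FALSE)
    ix$transcript_id <- NA_character_
  }
  ix$intron_id <- paste0(ifelse(is.na(ix$transcript_id), ix$gene_id,
                                ix$transcript_id), ".i", ix$ordinal)
  rownames(ix) <- NULL
  ix[, c("intron_id", "gene_id", "transcript_id", "contig", "strand",
         "donor", "acceptor", "ordinal")]
}

#' Read a splice-junction count table
#'
#' Two dialects are supported. `"sj_tab"` is the 9-column spliced-aligner
#' layout (contig, intron first base 1-based, intron last base 1-based,
#' strand code 0/1/2, motif, annotated flag, unique reads, multimapping
#' reads, overhang); the unique-read column is used as the count and one
#' file holds one sample, named by `sample_id`. `"tsv"` is the generic
#' 6-column layout (contig, donor, acceptor, strand, sample_id, count)
#' already in the internal 0-based half-open convention.
#'
#' @param path Path to the junction file.
#' @param dialect `"sj_tab"` or `"tsv"`.
#' @param sample_id Sample name for the `sj_tab` dialect.
#' @return data.frame: contig, donor, acceptor, strand, sample_id, count.
#' @export
read_junctions <- function(path, dialect = c("tsv", "sj_tab"), sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "sj_tab") {
    if (is.null(sample_id)) stop("sample_id required for sj_tab dialect")
    x <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("contig", "first", "last", "strand_code",
                                         "motif", "annotated", "unique", "multi",
                                         "overhang"),
                           colClasses = c("character", rep("integer", 8)))
    jt <- data.frame(
      contig = x$contig,
      donor = x$first - 1L,
      acceptor = x$last,
      strand = c("."[1], "+", "-")[x$strand_code + 1L],
      sample_id = sample_id,
      count = x$unique,
      stringsAsFactors = FALSE
    )
  } else {
    jt <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = c("character", "integer", "integer",
                                           "character", "character", "integer"))
    names(jt) <- c("contig", "donor", "acceptor", "strand", "sample_id", "count")
  }
  validate_junctions(jt)
}

validate_junctions <- function(jt) {
  if (any(jt$count < 0)) stop("negative junction counts")
  if (any(jt$acceptor <= jt$donor)) {
    bad <- which(jt$acceptor <= jt$donor)[1]
    stop("acceptor <= donor at ", jt$contig[bad], ":", jt$donor[bad])
  }
  key <- paste(jt$contig, jt$donor, jt$acceptor, jt$strand, jt$sample_id)
  if (anyDuplicated(key)) {
    stop("duplicate (junction, sample) rows: ", key[duplicated(key)][1])
  }
  rownames(jt) <- NULL
  jt
}

#' Write a junction table in the generic 6-column TSV dialect
#' @param jt Junction data.frame.
#' @param path Output path.
#' @export
write_junctions <- function(jt, path) {
  utils::write.table(jt[, c("contig", "donor", "acceptor", "strand",
                            "sample_id", "count")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample manifest (TSV with header sample_id, group, replicate)
#' @param path Path to the manifest.
#' @return data.frame with columns sample_id, group, replicate.
#' @export
read_manifest <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("character", "character", "integer"))
  names(m) <- c("sample_id", "group", "replicate")
  if (anyDuplicated(m$sample_id)) stop("duplicate sample_id in manifest")
  m
}

#' Resolve undefined junction strands against gene models
#'
#' Junctions with strand `"."` inherit the strand of the unique gene whose
#' intron-containing span covers them; junctions contained in genes on both
#' strands (or in none) are dropped, and the number dropped is reported via
#' a message.
#'
#' @param jt Junction data.frame.
#' @param anno A `transcript_set`.
#' @return The junction table with strands resolved.
#' @export
resolve_junction_strands <- function(jt, anno) {
  und <- which(jt$strand == ".")
  if (!length(und)) return(jt)
  spans <- do.call(rbind, lapply(split(anno$exons, anno$exons$transcript_id),
    function(e) {
      data.frame(transcript_id = e$transcript_id[1],
                 start = min(e$start), end = max(e$end))
    }))
  spans <- merge(spans, anno$transcripts, by = "transcript_id")
  drop <- logical(length(und))
  for (k in seq_along(und)) {
    i <- und[k]
    hit <- spans$contig == jt$contig[i] &
      spans$start <= jt$donor[i] & spans$end >= jt$acceptor[i]
    st <- unique(spans$strand[hit])
    if (length(st) == 1) jt$strand[i] <- st else drop[k] <- TRUE
  }
  if (any(drop)) {
    message(sum(drop), " undefined-strand junction(s) with ambiguous or no ",
            "gene containment excluded")
    jt <- jt[-und[drop], , drop = FALSE]
  }
  rownames(jt) <- NULL
  jt
}

#' Write a transcript_set as GTF
#'
#' Emits exon and CDS features with gene_id/transcript_id attributes,
#' converting back to the 1-based inclusive GTF convention.
#'
#' @param anno A `transcript_set`.
#' @param path Output path.
#' @export
write_annotation_gtf <- function(anno, path) {
  fmt <- function(df, type) {
    meta <- anno$transcripts[match(df$transcript_id, anno$transcripts$transcript_id), ]
    sprintf('%s\tpsiexon\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            meta$contig, type, df$start + 1L, df$end, meta$strand,
            meta$gene_id, df$transcript_id)
  }
  lines <- c(fmt(anno$exons, "exon"),
             if (nrow(anno$cds)) fmt(anno$cds, "CDS"))
  writeLines(lines, path)
  invisible(path)
}
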