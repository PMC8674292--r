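# Synthetic-data generator: multi-gene genomes with planted AGAgtaag
# pseudoexons of known coordinates and acceptor-strength class, junction
# count tables sampled at specified inclusion levels, and assay fixtures
# with known truth. Every output is reproducible byte-for-byte from
# (config, seed), and every plant is recorded in a truth manifest.

rand_seq <- function(n, probs = c(A = 0.28, C = 0.22, G = 0.22, T = 0.28)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

rand_seq_no_motif <- function(n, motif = "AGAGTAAG", max_tries = 200, ...) {
  for (i in seq_len(max_tries)) {
    s <- rand_seq(n, ...)
    if (!grepl(motif, s, fixed = TRUE)) return(s)
  }
  stop("could not generate motif-free sequence of length ", n)
}

pyrimidine_tract <- function(n) {
  paste(sample(c("C", "T"), n, replace = TRUE, prob = c(0.45, 0.55)),
        collapse = "")
}

rand_codons <- function(n) {
  ok <- setdiff(as.vector(outer(as.vector(outer(BASES, BASES, paste0)),
                                BASES, paste0)), STOP_CODONS)
  paste(sample(ok, n, replace = TRUE), collapse = "")
}

#' Simulation configuration
#'
#' Defaults mirror the statistical structure of a targeted splicing study:
#' a handful of multi-exon genes on both strands, introns long enough to
#' host pseudoexons, consensus GT..AG splice sites with polypyrimidine
#' acceptor tracts, and annotated CDS so NMD calls are decidable.
#'
#' @param seed Master seed (integer < 2^31).
#' @param n_genes Number of genes.
#' @param n_exons Exons per gene (scalar or range).
#' @param exon_len,intron_len Length ranges (min, max).
#' @param minus_strand_genes Indices of genes placed on the minus strand;
#'   default alternates.
#' @param spacer Intergenic spacer length.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 4L, n_exons = 4L,
                       exon_len = c(90L, 150L), intron_len = c(350L, 500L),
                       minus_strand_genes = NULL, spacer = 150L) {
  if (is.null(minus_strand_genes)) {
    minus_strand_genes <- seq(2L, n_genes, by = 2L)
  }
  structure(list(seed = as.integer(seed), n_genes = n_genes,
                 n_exons = n_exons, exon_len = exon_len,
                 intron_len = intron_len,
                 minus_strand_genes = minus_strand_genes, spacer = spacer),
            class = "sim_config")
}

# Build one gene in biological orientation. Returns gene sequence plus
# exon/cds intervals in gene-local biological coordinates.
build_gene <- function(config, gid) {
  ne <- if (length(config$n_exons) > 1) {
    sample(config$n_exons[1]:config$n_exons[2], 1)
  } else config$n_exons
  elen <- sample(config$exon_len[1]:config$exon_len[2], ne, replace = TRUE)
  ilen <- sample(config$intron_len[1]:config$intron_len[2], ne - 1,
                 replace = TRUE)
  M <- sum(elen)
  utr5 <- 12L; utr3 <- 12L
  cds_len <- M - utr5 - utr3
  cds_len <- cds_len - (cds_len %% 3L)
  n_cod <- cds_len %/% 3L - 2L
  mrna <- paste0(rand_seq_no_motif(utr5), "ATG", rand_codons(n_cod), "TAA",
                 rand_seq_no_motif(M - utr5 - cds_len))
  stopifnot(nchar(mrna) == M)
  # split mRNA into exons, interleave introns
  parts <- character(0)
  exons <- data.frame(start = integer(ne), end = integer(ne))
  pos <- 0L; mpos <- 0L
  for (i in seq_len(ne)) {
    ex <- substr(mrna, mpos + 1L, mpos + elen[i])
    exons$start[i] <- pos; exons$end[i] <- pos + elen[i]
    parts <- c(parts, ex)
    pos <- pos + elen[i]; mpos <- mpos + elen[i]
    if (i < ne) {
      core <- rand_seq_no_motif(ilen[i] - 6L - 20L)
      intr <- paste0("GTAAGT", core, pyrimidine_tract(17L), "CAG")
      parts <- c(parts, intr)
      pos <- pos + ilen[i]
    }
  }
  list(gene_id = gid, seq = paste(parts, collapse = ""),
       exons = exons, cds = c(start = utr5, end = utr5 + cds_len),
       mrna_len = M)
}

# map a gene-local biological interval [a, b) to genomic coordinates
bio_to_genomic <- function(a, b, offset, gene_len, strand) {
  if (strand == "+") c(offset + a, offset + b)
  else c(offset + gene_len - b, offset + gene_len - a)
}

#' Simulate a genome with planted pseudoexons
#'
#' Generates the genes of `config`, trains an acceptor PWM on the
#' annotated 3' splice sites of the simulated annotation, then plants
#' pseudoexon cassettes (polypyrimidine tract + AG, exon body ending AGA,
#' GTAAG) inside introns. Each plant's class controls its expected scan
#' verdict: `"pass"` (length within bounds, acceptor rejection-sampled
#' until it scores above threshold), `"short"` (length 5), `"long"`
#' (length 201), `"weak"` (acceptor rejection-sampled to score at or below
#' threshold), `"annotated"` (a passing plant whose interval is added to
#' the annotation as a single-exon twin transcript). Plant classes recycle
#' over `n_plants`. Cassette replacement is length-preserving, so all
#' annotation coordinates remain valid.
#'
#' @param config A [sim_config()].
#' @param n_plants Number of planted pseudoexons.
#' @param plant_classes Character vector of classes, recycled (default
#'   `"pass"`).
#' @param plant_len Body length of passing/weak plants (default 64).
#' @param acceptor_threshold Score threshold separating strong from weak
#'   acceptors (default 2.3).
#' @param max_attempts Rejection-sampling cap per plant (default 1000).
#' @return list: genome (`DNAStringSet`), anno (`transcript_set`), introns
#'   (per-gene union), acceptor_model, donor_model, truth (data.frame:
#'   plant_id, class, contig, strand, start, end, length, intron_id,
#'   intron_donor, intron_acceptor, acceptor_score, expect_pass,
#'   expect_reason).
#' @export
simulate_genome <- function(config, n_plants = 0L, plant_classes = "pass",
                            plant_len = 64L, acceptor_threshold = 2.3,
                            max_attempts = 1000L) {
  set.seed(config$seed)
  genes <- lapply(seq_len(config$n_genes), function(i) {
    build_gene(config, sprintf("g%02d", i))
  })
  # place two genes per contig
  per_contig <- 2L
  placements <- list(); contigs <- list()
  for (i in seq_along(genes)) {
    ci <- (i - 1L) %/% per_contig + 1L
    ctg <- sprintf("chr%d", ci)
    strand <- if (i %in% config$minus_strand_genes) "-" else "+"
    gseq <- genes[[i]]$seq
    if (strand == "-") gseq <- revcomp(gseq)
    prev <- if (length(contigs) >= ci) contigs[[ci]] else ""
    offset <- nchar(prev) + config$spacer
    contigs[[ci]] <- paste0(prev, rand_seq_no_motif(config$spacer), gseq)
    placements[[i]] <- list(contig = ctg, strand = strand, offset = offset,
                            gene_len = nchar(genes[[i]]$seq))
  }
  contigs <- lapply(contigs, function(s) paste0(s, rand_seq_no_motif(config$spacer)))
  names(contigs) <- sprintf("chr%d", seq_along(contigs))

  # annotation in genomic coordinates
  ex_rows <- list(); cds_rows <- list(); tr_rows <- list()
  for (i in seq_along(genes)) {
    g <- genes[[i]]; pl <- placements[[i]]
    tid <- paste0(g$gene_id, ".t1")
    tr_rows[[i]] <- data.frame(transcript_id = tid, gene_id = g$gene_id,
                               contig = pl$contig, strand = pl$strand,
                               stringsAsFactors = FALSE)
    ex_rows[[i]] <- do.call(rbind, lapply(seq_len(nrow(g$exons)), function(k) {
      gc <- bio_to_genomic(g$exons$start[k], g$exons$end[k], pl$offset,
                           pl$gene_len, pl$strand)
      data.frame(transcript_id = tid, start = gc[1], end = gc[2])
    }))
    # CDS split across exons
    cds_rows[[i]] <- do.call(rbind, lapply(seq_len(nrow(g$exons)), function(k) {
      # mRNA span of exon k
      mst <- sum(g$exons$end[seq_len(k - 1)] - g$exons$start[seq_len(k - 1)])
      men <- mst + (g$exons$end[k] - g$exons$start[k])
      lo <- max(g$cds["start"], mst); hi <- min(g$cds["end"], men)
      if (lo >= hi) return(NULL)
      # back to gene-local biological coords
      a <- g$exons$start[k] + (lo - mst); b <- g$exons$start[k] + (hi - mst)
      gc <- bio_to_genomic(a, b, pl$offset, pl$gene_len, pl$strand)
      data.frame(transcript_id = tid, start = gc[1], end = gc[2])
    }))
  }
  anno <- new_transcript_set(
    do.call(rbind, tr_rows),
    do.call(rbind, ex_rows)[, c("transcript_id", "start", "end")],
    do.call(rbind, cds_rows)[, c("transcript_id", "start", "end")],
    "simulated")
  anno <- build_transcript_set(
    rbind(transform(merge(anno$exons, anno$transcripts, by = "transcript_id"),
                    type = "exon"),
          transform(merge(anno$cds, anno$transcripts, by = "transcript_id"),
                    type = "CDS")),
    "simulated")
  genome <- Biostrings::DNAStringSet(unlist(contigs))

  # splice-site models trained on the simulated annotation
  wins <- annotated_ss_windows(anno, genome)
  acc_model <- train_pwm_fallback(wins$acceptor23, "acceptor23",
                                  min_sites = min(50, length(wins$acceptor23)))
  don_model <- train_pwm_fallback(wins$donor9, "donor9",
                                  min_sites = min(50, length(wins$donor9)))

  introns <- derive_introns(anno)
  truth <- data.frame()
  twin_rows <- list()
  if (n_plants > 0) {
    classes <- rep_len(plant_classes, n_plants)
    # spread plants over introns round-robin
    ord <- order(introns$contig, introns$donor)
    hosts <- introns[rep_len(ord, n_plants), , drop = FALSE]
    contig_chars <- lapply(as.character(genome), identity)
    for (pi in seq_len(n_plants)) {
      cls <- classes[pi]
      host <- hosts[pi, ]
      L <- switch(cls, short = 5L, long = 201L, plant_len)
      ilen <- host$acceptor - host$donor
      cas_len <- 20L + L + 5L
      margin <- 30L
      if (cas_len + 2 * margin > ilen) {
        stop("intron ", host$intron_id, " too short for a length-", L, " plant")
      }
      # biological offset of cassette start within the intron
      pos <- margin + ((pi * 37L) %% max(1L, ilen - cas_len - 2L * margin))
      body <- paste0(rand_seq_no_motif(L - 3L), "AGA")
      if (L == 5L) body <- paste0(rand_seq_no_motif(2L), "AGA")
      target_pass <- !(cls == "weak")
      sc <- NA_real_; acc_region <- NULL
      for (att in seq_len(max_attempts)) {
        acc_region <- if (target_pass) {
          paste0(pyrimidine_tract(18L), "AG")
        } else {
          paste0(rand_seq(18L, c(A = 0.45, C = 0.05, G = 0.45, T = 0.05)), "AG")
        }
        win <- paste0(acc_region, substr(body, 1L, 3L))
        sc <- score_site(acc_model, win)
        if ((target_pass && sc > acceptor_threshold) ||
            (!target_pass && sc <= acceptor_threshold)) break
        if (att == max_attempts) {
          stop("could not reach acceptor class ", cls, " in ",
               max_attempts, " attempts")
        }
      }
      cassette <- paste0(acc_region, body, "GTAAG")
      # biological intron coordinates -> genomic replacement
      strand <- host$strand
      if (strand == "+") {
        g_lo <- host$donor + pos
        repl <- cassette
      } else {
        g_lo <- host$acceptor - pos - cas_len
        repl <- revcomp(cassette)
      }
      ctg <- host$contig
      s <- contig_chars[[ctg]]
      substr(s, g_lo + 1L, g_lo + cas_len) <- repl
      contig_chars[[ctg]] <- s
      ex_bio_start <- pos + 20L
      gc <- if (strand == "+") {
        c(host$donor + ex_bio_start, host$donor + ex_bio_start + L)
      } else {
        c(host$acceptor - ex_bio_start - L, host$acceptor - ex_bio_start)
      }
      expect_reason <- switch(cls, short = "too_short", long = "too_long",
                              weak = "weak_acceptor", annotated = "annotated",
                              "")
      truth <- rbind(truth, data.frame(
        plant_id = sprintf("plant%03d", pi), class = cls,
        contig = ctg, strand = strand, start = gc[1], end = gc[2],
        length = L, gene_id = host$gene_id, intron_id = host$intron_id,
        intron_donor = host$donor, intron_acceptor = host$acceptor,
        acceptor_score = sc, expect_pass = cls %in% c("pass"),
        expect_reason = expect_reason, stringsAsFactors = FALSE))
      if (cls == "annotated") {
        twin_rows[[length(twin_rows) + 1L]] <- data.frame(
          type = "exon",
          transcript_id = sprintf("%s.twin%03d", host$gene_id, pi),
          gene_id = host$gene_id, contig = ctg, strand = strand,
          start = gc[1], end = gc[2], stringsAsFactors = FALSE)
      }
    }
    genome <- Biostrings::DNAStringSet(unlist(contig_chars))
    names(genome) <- names(contig_chars)
  }
  if (length(twin_rows)) {
    base <- rbind(
      transform(merge(anno$exons, anno$transcripts, by = "transcript_id"),
                type = "exon"),
      transform(merge(anno$cds, anno$transcripts, by = "transcript_id"),
                type = "CDS"))
    anno <- build_transcript_set(rbind(base, do.call(rbind, twin_rows)),
                                 "simulated")
  }
  list(genome = genome, anno = anno, introns = introns,
       acceptor_model = acc_model, donor_model = don_model,
       truth = truth, config = config)
}

#' Simulate junction counts for planted events
#'
#' For each planted event and sample: total junction depth `depth`;
#' inclusion-junction reads drawn binomially with probability
#' `2 p / (1 + p)` for true inclusion fraction `p` (the junction-level
#' expectation: an included transcript contributes reads to two inclusion
#' junctions, a skipped one to a single skip junction), split evenly
#' across the two inclusion junctions with the +/-1 remainder alternating
#' deterministically; the remaining reads go to the skip junction. Introns
#' without events receive constitutive junction counts.
#'
#' @param sim Output of [simulate_genome()].
#' @param psi_control,psi_treated True inclusion percent per planted event
#'   (recycled over plants).
#' @param n_control,n_treated Replicates per group.
#' @param depth Event junction depth per sample.
#' @param constitutive_depth Depth of event-free constitutive junctions.
#' @param seed Seed for count sampling.
#' @param groups Group labels c(control, treated).
#' @return list(junctions, manifest, event_truth).
#' @export
simulate_junction_counts <- function(sim, psi_control = 1, psi_treated = 60,
                                     n_control = 3L, n_treated = 3L,
                                     depth = 1000L, constitutive_depth = 200L,
                                     seed = sim$config$seed + 1L,
                                     groups = c("DMSO", "treated")) {
  set.seed(seed)
  plants <- sim$truth
  if (any(psi_control < 0 | psi_control > 100) ||
      any(psi_treated < 0 | psi_treated > 100)) stop("truePSI outside [0,100]")
  manifest <- data.frame(
    sample_id = c(sprintf("c%d", seq_len(n_control)),
                  sprintf("t%d", seq_len(n_treated))),
    group = c(rep(groups[1], n_control), rep(groups[2], n_treated)),
    replicate = c(seq_len(n_control), seq_len(n_treated)),
    stringsAsFactors = FALSE)
  pc <- rep_len(psi_control, nrow(plants))
  pt <- rep_len(psi_treated, nrow(plants))
  rows <- list()
  event_introns <- character(0)
  if (nrow(plants)) {
    for (i in seq_len(nrow(plants))) {
      pl <- plants[i, ]
      event_introns <- c(event_introns, pl$intron_id)
      for (si in seq_len(nrow(manifest))) {
        smp <- manifest$sample_id[si]
        p <- (if (manifest$group[si] == groups[1]) pc[i] else pt[i]) / 100
        p_read <- 2 * p / (1 + p)
        inc <- stats::rbinom(1L, depth, p_read)
        exc <- depth - inc
        first_extra <- (i + si) %% 2L == 0L
        c1 <- inc %/% 2L + as.integer(inc %% 2L == 1L && first_extra)
        c2 <- inc - c1
        rows[[length(rows) + 1L]] <- data.frame(
          contig = pl$contig,
          donor = c(pl$intron_donor, pl$end, pl$intron_donor),
          acceptor = c(pl$start, pl$intron_acceptor, pl$intron_acceptor),
          strand = pl$strand, sample_id = smp,
          count = c(if (pl$strand == "+") c(c1, c2) else c(c2, c1), exc),
          stringsAsFactors = FALSE)
      }
    }
  }
  quiet <- sim$introns[!sim$introns$intron_id %in% event_introns, , drop = FALSE]
  for (i in seq_len(nrow(quiet))) {
    q <- quiet[i, ]
    for (smp in manifest$sample_id) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = q$contig, donor = q$donor, acceptor = q$acceptor,
        strand = q$strand, sample_id = smp,
        count = stats::rpois(1L, constitutive_depth), stringsAsFactors = FALSE)
    }
  }
  jt <- do.call(rbind, rows)
  jt <- jt[jt$count > 0 | TRUE, , drop = FALSE]  # keep zeros: explicit support
  rownames(jt) <- NULL
  et <- if (nrow(plants)) {
    cbind(plants[, c("plant_id", "contig", "strand", "start", "end",
                     "intron_id", "intron_donor", "intron_acceptor")],
          true_psi_control = pc, true_psi_treated = pt)
  } else plants
  list(junctions = validate_junctions(jt), manifest = manifest,
       event_truth = et)
}

#' Simulate an amplicon-style junction table with one cryptic junction
#'
#' Emulates a targeted panel over one intron: each sample's reads split
#' between the exact annotated junction and a cryptic junction sharing the
#' intron's donor, at a per-sample cryptic fraction, so the intron's JEI is
#' `100 * (1 - f)` up to count rounding.
#'
#' @param intron One intron row.
#' @param cryptic_frac Named numeric vector: fraction per sample id.
#' @param depth Reads per intron per sample.
#' @param cryptic_offset Acceptor offset of the cryptic junction inside the
#'   intron (default: mid-intron).
#' @return Junction data.frame.
#' @export
simulate_cryptic_junctions <- function(intron, cryptic_frac, depth = 500L,
                                       cryptic_offset = NULL) {
  if (is.null(cryptic_offset)) {
    cryptic_offset <- (intron$acceptor - intron$donor) %/% 2L
  }
  rows <- lapply(names(cryptic_frac), function(smp) {
    cr <- round_half_up(cryptic_frac[[smp]] * depth)
    data.frame(contig = intron$contig,
               donor = intron$donor,
               acceptor = c(intron$acceptor, intron$donor + cryptic_offset),
               strand = intron$strand, sample_id = smp,
               count = c(depth - cr, cr), stringsAsFactors = FALSE)
  })
  jt <- do.call(rbind, rows)
  jt <- jt[jt$count > 0, , drop = FALSE]
  rownames(jt) <- NULL
  jt
}

#' Simulate assay fixtures with known truth
#'
#' ECL duplicate signals around specified true lowering percentages
#' (multiplicative log-normal noise), qPCR Ct records consistent with true
#' percent-of-vehicle levels at stated efficiencies, and a receiver
#' concentration series encoding an exact apparent permeability.
#'
#' @param seed Seed.
#' @param lowering Named numeric: true percent lowering per group; must
#'   include `vehicle = 0`.
#' @param n_animals Animals per group.
#' @param noise_sd Log-scale signal noise (0 = exact).
#' @param qpcr_percent_true Named numeric: true percent-of-vehicle mRNA per
#'   group.
#' @param efficiency Shared amplification efficiency E.
#' @param papp_true True Papp (cm/s).
#' @param vr,area,c0 Permeability assay geometry.
#' @return list(ecl, qpcr, perm, truth).
#' @export
simulate_quant_fixtures <- function(seed = 1L,
                                    lowering = c(vehicle = 0, low = 30, high = 60),
                                    n_animals = 5L, noise_sd = 0,
                                    qpcr_percent_true = c(vehicle = 100, treated = 40),
                                    efficiency = 1,
                                    papp_true = 4.42478e-5,
                                    vr = 0.5, area = 1.13, c0 = 10) {
  set.seed(seed)
  base_t <- 2000; base_n <- 1500
  ecl <- do.call(rbind, lapply(names(lowering), function(grp) {
    do.call(rbind, lapply(seq_len(n_animals), function(a) {
      lev <- 1 - lowering[[grp]] / 100
      data.frame(
        animal_id = sprintf("%s_%02d", grp, a), group = grp,
        target = base_t * lev * exp(stats::rnorm(2, 0, noise_sd)),
        normaliser = base_n * exp(stats::rnorm(2, 0, noise_sd)),
        stringsAsFactors = FALSE)
    }))
  }))
  rownames(ecl) <- NULL
  qpcr <- do.call(rbind, lapply(names(qpcr_percent_true), function(grp) {
    lev <- qpcr_percent_true[[grp]] / 100
    do.call(rbind, lapply(seq_len(3L), function(a) {
      data.frame(sample_id = sprintf("%s_%d", grp, a), group = grp,
                 norm_ct = 20,
                 target_ct = 25 - log(lev) / log(1 + efficiency),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(qpcr) <- NULL
  times <- c(0, 1800, 3600)
  slope <- papp_true * area * c0 / vr
  perm <- list(times = times, receiver_conc = slope * times,
               vr = vr, area = area, c0 = c0)
  list(ecl = ecl, qpcr = qpcr, perm = perm,
       truth = list(lowering = lowering,
                    qpcr_percent = qpcr_percent_true,
                    efficiency = efficiency, papp = papp_true))
}

#' Write a simulated corpus to a directory
#'
#' Emits genome.fa, annotation.gtf, junctions.tsv, manifest.tsv, truth.tsv
#' and acceptor_model.tsv — the complete plain-text input set for a
#' pipeline run.
#'
#' @param sim Output of [simulate_genome()].
#' @param jc Output of [simulate_junction_counts()] (optional).
#' @param dir Output directory (created).
#' @return The directory, invisibly.
#' @export
write_sim_corpus <- function(sim, jc = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_annotation_gtf(sim$anno, file.path(dir, "annotation.gtf"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_pwm_model(sim$acceptor_model, file.path(dir, "acceptor_model.tsv"))
  if (!is.null(jc)) {
    write_junctions(jc$junctions, file.path(dir, "junctions.tsv"))
    utils::write.table(jc$manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
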