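# Alternative-splicing event catalogue and PSI statistics.
#
# Events follow the cassette-exon / alternative-5'ss / alternative-3'ss
# taxonomy. A CE event has two inclusion junctions (upstream donor -> exon
# acceptor, exon donor -> downstream acceptor) and one exclusion (skip)
# junction; A5SS/A3SS events have one junction per isoform. Discovery is
# junction-driven with annotation as scaffold: annotated internal exons
# seed CE events, and unannotated CE events require both flanking
# junctions plus the bridging skip junction to be observed.

round_half_up <- function(x) floor(x + 0.5)

unique_junctions <- function(junctions) {
  u <- unique(junctions[junctions$count > 0,
                        c("contig", "donor", "acceptor", "strand")])
  rownames(u) <- NULL
  u
}

annotation_list <- function(anno) {
  if (inherits(anno, "transcript_set")) list(anno) else anno
}

# exon boundary sets per source for annotation-status lookup
boundary_sets <- function(annos) {
  lapply(annos, function(a) {
    ex <- merge(a$exons, a$transcripts, by = "transcript_id")
    list(source = a$source,
         starts = unique(paste(ex$contig, ex$strand, ex$start)),
         ends = unique(paste(ex$contig, ex$strand, ex$end)),
         exons = unique(paste(ex$contig, ex$strand, ex$start, ex$end)))
  })
}

gene_spans <- function(annos) {
  ex <- do.call(rbind, lapply(annos, function(a) {
    merge(a$exons, a$transcripts, by = "transcript_id")
  }))
  sp <- do.call(rbind, lapply(split(ex, ex$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], contig = g$contig[1],
               strand = g$strand[1], start = min(g$start), end = max(g$end),
               stringsAsFactors = FALSE)
  }))
  rownames(sp) <- NULL
  sp
}

#' Build the alternative-splicing event catalogue
#'
#' CE events arise from annotated internal exons and from unannotated exon
#' intervals `[s, e)` for which junctions `(u, s)`, `(e, v)` and the
#' bridging skip `(u, v)` are all observed. Junction pairs sharing one
#' coordinate (and not already part of a CE) yield A5SS/A3SS events,
#' strand-aware: a varying genomic-right end is an alternative 3'ss on the
#' plus strand and an alternative 5'ss on the minus strand, and vice versa.
#' Events with zero observed reads across all samples are dropped. Each
#' event records, per annotation source, whether its 3'ss and 5'ss match an
#' annotated exon boundary, and is assigned to the gene whose span contains
#' it (ambiguous containment flagged).
#'
#' @param junctions Junction data.frame.
#' @param annos A `transcript_set` or list of them (first = scaffold).
#' @return data.frame of events; inclusion junctions in columns
#'   `inc1_donor/inc1_acceptor` (upstream, genomic order), `inc2_*`
#'   (downstream; NA for A5SS/A3SS where `inc1` is the sole inclusion
#'   junction), exclusion junction in `exc_*`; per-source annotation flags
#'   in `acc_ann.<source>` / `don_ann.<source>`.
#' @export
build_event_catalog <- function(junctions, annos) {
  annos <- annotation_list(annos)
  uj <- unique_junctions(junctions)
  bnd <- boundary_sets(annos)
  spans <- gene_spans(annos)

  events <- list()
  for (grp in split(uj, paste(uj$contig, uj$strand))) {
    contig <- grp$contig[1]; strand <- grp$strand[1]
    jkey <- paste(grp$donor, grp$acceptor)
    # --- CE from observed junction triples
    for (i in seq_len(nrow(grp))) {
      u <- grp$donor[i]; v <- grp$acceptor[i]          # candidate skip
      ups <- grp[grp$donor == u & grp$acceptor < v, , drop = FALSE]
      downs <- grp[grp$acceptor == v & grp$donor > u, , drop = FALSE]
      if (!nrow(ups) || !nrow(downs)) next
      for (s in ups$acceptor) for (e in downs$donor) {
        if (s >= e) next
        events[[length(events) + 1L]] <- data.frame(
          kind = "CE", contig = contig, strand = strand,
          exon_start = s, exon_end = e,
          inc1_donor = u, inc1_acceptor = s,
          inc2_donor = e, inc2_acceptor = v,
          exc_donor = u, exc_acceptor = v, stringsAsFactors = FALSE)
      }
    }
    # --- CE from annotated internal exons (flanks may be partly unobserved)
    for (a in annos) {
      ex <- merge(a$exons, a$transcripts, by = "transcript_id")
      ex <- ex[ex$contig == contig & ex$strand == strand, , drop = FALSE]
      for (tid in unique(ex$transcript_id)) {
        e3 <- ex[ex$transcript_id == tid, , drop = FALSE]
        e3 <- e3[order(e3$start), , drop = FALSE]
        if (nrow(e3) < 3) next
        for (k in 2:(nrow(e3) - 1)) {
          events[[length(events) + 1L]] <- data.frame(
            kind = "CE", contig = contig, strand = strand,
            exon_start = e3$start[k], exon_end = e3$end[k],
            inc1_donor = e3$end[k - 1], inc1_acceptor = e3$start[k],
            inc2_donor = e3$end[k], inc2_acceptor = e3$start[k + 1],
            exc_donor = e3$end[k - 1], exc_acceptor = e3$start[k + 1],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  ce <- if (length(events)) unique(do.call(rbind, events)) else
    data.frame(kind = character(), contig = character(), strand = character(),
               exon_start = integer(), exon_end = integer(),
               inc1_donor = integer(), inc1_acceptor = integer(),
               inc2_donor = integer(), inc2_acceptor = integer(),
               exc_donor = integer(), exc_acceptor = integer())

  # --- A5SS / A3SS from junction pairs sharing one end
  ce_pair_keys <- character(0)
  if (nrow(ce)) {
    ce_pair_keys <- c(
      paste(ce$contig, ce$strand, ce$inc1_donor, ce$inc1_acceptor,
            ce$exc_donor, ce$exc_acceptor),
      paste(ce$contig, ce$strand, ce$inc2_donor, ce$inc2_acceptor,
            ce$exc_donor, ce$exc_acceptor))
  }
  aev <- list()
  for (grp in split(uj, paste(uj$contig, uj$strand))) {
    contig <- grp$contig[1]; strand <- grp$strand[1]
    shared <- list(
      list(by = "donor", vary = "acceptor"),
      list(by = "acceptor", vary = "donor"))
    for (sh in shared) {
      for (val in unique(grp[[sh$by]])) {
        g2 <- grp[grp[[sh$by]] == val, , drop = FALSE]
        if (nrow(g2) < 2) next
        g2 <- g2[order(g2[[sh$vary]]), , drop = FALSE]
        for (i in seq_len(nrow(g2) - 1)) for (j in (i + 1):nrow(g2)) {
          # shorter intron = inclusion (retains more exonic sequence)
          lens <- g2$acceptor[c(i, j)] - g2$donor[c(i, j)]
          inc <- c(i, j)[which.min(lens)]; exc <- c(i, j)[which.max(lens)]
          pk <- paste(contig, strand, g2$donor[inc], g2$acceptor[inc],
                      g2$donor[exc], g2$acceptor[exc])
          if (pk %in% ce_pair_keys) next
          vary_right <- sh$vary == "acceptor"
          kind <- if (vary_right == (strand == "+")) "A3SS" else "A5SS"
          aev[[length(aev) + 1L]] <- data.frame(
            kind = kind, contig = contig, strand = strand,
            exon_start = NA_integer_, exon_end = NA_integer_,
            inc1_donor = g2$donor[inc], inc1_acceptor = g2$acceptor[inc],
            inc2_donor = NA_integer_, inc2_acceptor = NA_integer_,
            exc_donor = g2$donor[exc], exc_acceptor = g2$acceptor[exc],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  ev <- rbind(ce, if (length(aev)) unique(do.call(rbind, aev)))
  if (!nrow(ev)) return(cbind(ev, event_id = character(0)))

  # drop events with zero observed reads on every junction
  obs <- paste(uj$contig, uj$strand, uj$donor, uj$acceptor)
  has_reads <- vapply(seq_len(nrow(ev)), function(i) {
    ks <- c(paste(ev$contig[i], ev$strand[i], ev$inc1_donor[i], ev$inc1_acceptor[i]),
            paste(ev$contig[i], ev$strand[i], ev$inc2_donor[i], ev$inc2_acceptor[i]),
            paste(ev$contig[i], ev$strand[i], ev$exc_donor[i], ev$exc_acceptor[i]))
    any(ks %in% obs)
  }, logical(1))
  ev <- ev[has_reads, , drop = FALSE]

  # annotation status of the biological 3'ss and 5'ss per source
  for (b in bnd) {
    # genomic-left boundary of the variable region
    left <- ifelse(ev$kind == "CE", ev$exon_start,
                   pmax(ev$inc1_donor, ev$exc_donor))
    right <- ifelse(ev$kind == "CE", ev$exon_end,
                    pmin(ev$inc1_acceptor, ev$exc_acceptor))
    left_ann <- paste(ev$contig, ev$strand, left) %in% b$starts
    right_ann <- paste(ev$contig, ev$strand, right) %in% b$ends
    acc <- ifelse(ev$strand == "+", left_ann, right_ann)   # biological 3'ss
    don <- ifelse(ev$strand == "+", right_ann, left_ann)   # biological 5'ss
    ev[[paste0("acc_ann.", b$source)]] <- acc
    ev[[paste0("don_ann.", b$source)]] <- don
  }

  # gene assignment by span containment
  lo <- pmin(ev$inc1_donor, ev$exc_donor, na.rm = TRUE)
  hi <- pmax(ev$inc1_acceptor, ev$exc_acceptor, na.rm = TRUE)
  ev$gene_id <- NA_character_; ev$gene_ambiguous <- FALSE
  for (i in seq_len(nrow(ev))) {
    hit <- spans$contig == ev$contig[i] & spans$strand == ev$strand[i] &
      spans$start <= lo[i] & spans$end >= hi[i]
    g <- spans$gene_id[hit]
    if (length(g)) {
      ev$gene_id[i] <- g[1]
      ev$gene_ambiguous[i] <- length(g) > 1
    }
  }
  ev <- ev[order(ev$contig, ev$exc_donor, ev$exc_acceptor, ev$kind), , drop = FALSE]
  ev$event_id <- sprintf("ev%04d", seq_len(nrow(ev)))
  rownames(ev) <- NULL
  ev[, c("event_id", setdiff(names(ev), "event_id"))]
}

junction_count <- function(junctions, sample, contig, strand, donor, acceptor) {
  if (is.na(donor)) return(NA_real_)
  i <- junctions$sample_id == sample & junctions$contig == contig &
    junctions$donor == donor & junctions$acceptor == acceptor &
    (junctions$strand == strand | junctions$strand == ".")
  sum(junctions$count[i])
}

event_supports <- function(event, junctions, sample) {
  incs <- c(junction_count(junctions, sample, event$contig, event$strand,
                           event$inc1_donor, event$inc1_acceptor),
            junction_count(junctions, sample, event$contig, event$strand,
                           event$inc2_donor, event$inc2_acceptor))
  incs <- incs[!is.na(incs)]
  exc <- junction_count(junctions, sample, event$contig, event$strand,
                        event$exc_donor, event$exc_acceptor)
  list(inc = mean(incs), exc = exc)
}

#' Percent spliced in (PSI) of one event in one sample
#'
#' Inclusion support is the arithmetic mean of the inclusion-junction read
#' counts (two junctions for CE, one for A5SS/A3SS); exclusion support is
#' the exclusion-junction count. PSI = 100 * inc / (inc + exc), reported as
#' `NA` when the denominator (inc + exc) is below `min_denominator`.
#'
#' @param event One catalogue row.
#' @param junctions Junction data.frame.
#' @param sample Sample id.
#' @param min_denominator Minimum read support (default 20).
#' @return Percent in \[0, 100\] or `NA_real_`.
#' @export
compute_psi <- function(event, junctions, sample, min_denominator = 20) {
  s <- event_supports(event, junctions, sample)
  if (s$inc + s$exc < min_denominator) return(NA_real_)
  100 * s$inc / (s$inc + s$exc)
}

#' Fisher exact test of one event between two groups
#'
#' Builds the 2x2 read-count table with rows inclusion/exclusion and
#' columns the two groups, biological replicates combined: per-sample
#' inclusion supports (averaged across the event's inclusion junctions) are
#' summed over a group's samples and rounded half-up to integers, likewise
#' exclusion supports. Two-sided P. A table with an empty row or column
#' margin is degenerate and reported as P = 1.
#'
#' @param event One catalogue row.
#' @param junctions Junction data.frame.
#' @param manifest Sample manifest.
#' @param groupA,groupB Group labels (columns of the 2x2 table).
#' @return list(p, table, degenerate).
#' @export
fisher_event_test <- function(event, junctions, manifest, groupA, groupB) {
  pool <- function(grp) {
    ss <- manifest$sample_id[manifest$group == grp]
    sup <- lapply(ss, function(s) event_supports(event, junctions, s))
    c(inc = round_half_up(sum(vapply(sup, `[[`, numeric(1), "inc"))),
      exc = round_half_up(sum(vapply(sup, `[[`, numeric(1), "exc"))))
  }
  a <- pool(groupA); b <- pool(groupB)
  tab <- matrix(c(a["inc"], a["exc"], b["inc"], b["exc"]), nrow = 2,
                dimnames = list(c("inc", "exc"), c(groupA, groupB)))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (degenerate) 1 else stats::fisher.test(tab)$p.value
  list(p = p, table = tab, degenerate = degenerate)
}

#' PSI statistics for every event between two conditions
#'
#' Per-sample PSI, group means (NA excluded), basal PSI (control mean),
#' delta PSI (treated - control), Fisher two-sided P on pooled replicate
#' counts, and the Inc/Skp/NC call.
#'
#' @param events Event catalogue.
#' @param junctions Junction data.frame.
#' @param manifest Sample manifest.
#' @param control,treated Group labels.
#' @param min_denominator PSI denominator floor (default 20).
#' @param dpsi_threshold,p_threshold Call thresholds (defaults 20, 0.001).
#' @return data.frame: event_id, kind, per-sample `psi.<sample>` columns,
#'   psi_control, psi_treated, basal_psi, dpsi, p, degenerate, call,
#'   call_reason.
#' @export
psi_table <- function(events, junctions, manifest, control, treated,
                      min_denominator = 20, dpsi_threshold = 20,
                      p_threshold = 0.001) {
  sc <- manifest$sample_id[manifest$group == control]
  st <- manifest$sample_id[manifest$group == treated]
  rows <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    psis <- vapply(c(sc, st), function(s) {
      compute_psi(ev, junctions, s, min_denominator)
    }, numeric(1))
    pc <- psis[seq_along(sc)]; pt <- psis[length(sc) + seq_along(st)]
    mc <- if (all(is.na(pc))) NA_real_ else mean(pc, na.rm = TRUE)
    mt <- if (all(is.na(pt))) NA_real_ else mean(pt, na.rm = TRUE)
    ft <- fisher_event_test(ev, junctions, manifest, control, treated)
    out <- data.frame(event_id = ev$event_id, kind = ev$kind,
                      stringsAsFactors = FALSE)
    out[paste0("psi.", c(sc, st))] <- as.list(psis)
    out$psi_control <- mc; out$psi_treated <- mt
    out$basal_psi <- mc
    out$dpsi <- mt - mc
    out$p <- ft$p; out$degenerate <- ft$degenerate
    out
  })
  res <- do.call(rbind, rows)
  call_regulated_events(res, dpsi_threshold, p_threshold)
}

#' Call compound-regulated events from PSI statistics
#'
#' `Inc` when delta PSI > threshold and P < threshold, `Skp` when delta PSI
#' < -threshold and P < threshold, otherwise `NC`. Events whose delta PSI is
#' undefined (an all-NA group) are `NC` with reason `"undefined_dpsi"`.
#'
#' @param psi data.frame with columns dpsi, p (e.g. from [psi_table()]).
#' @param dpsi_threshold,p_threshold Thresholds (defaults 20, 0.001).
#' @return The input with columns `call` and `call_reason` appended.
#' @export
call_regulated_events <- function(psi, dpsi_threshold = 20, p_threshold = 0.001) {
  call <- rep("NC", nrow(psi))
  reason <- rep("", nrow(psi))
  und <- is.na(psi$dpsi)
  reason[und] <- "undefined_dpsi"
  ok <- !und & psi$p < p_threshold
  call[ok & psi$dpsi > dpsi_threshold] <- "Inc"
  call[ok & psi$dpsi < -dpsi_threshold] <- "Skp"
  psi$call <- call
  psi$call_reason <- reason
  psi
}

#' Inc/Skp ratio among called cassette exons
#' @param psi Called PSI table.
#' @return list(n_inc, n_skp, ratio).
#' @export
inc_skp_ratio <- function(psi) {
  ce <- psi[psi$kind == "CE", , drop = FALSE]
  n_inc <- sum(ce$call == "Inc"); n_skp <- sum(ce$call == "Skp")
  list(n_inc = n_inc, n_skp = n_skp,
       ratio = if (n_skp > 0) n_inc / n_skp else NA_real_)
}

#' Classify included cassette exons as psiExons
#'
#' For each Inc-called CE event, records the annotation status of its 3'ss
#' and 5'ss against every supplied annotation source and extracts the
#' 9-mer donor and 23-mer acceptor windows strand-aware. An exon is a
#' psiExon when no single source annotates both of its splice sites, i.e.
#' at least one splice site is unannotated in every source.
#'
#' @param events Event catalogue.
#' @param psi Called PSI table for the same events.
#' @param annos `transcript_set` or list of them.
#' @param genome `DNAStringSet`.
#' @return data.frame: event_id, exon interval, length, donor9/acceptor23
#'   windows (`NA` when truncated by a contig end), per-source annotation
#'   columns, n_sources_fully_annotated, basal_psi, is_psiexon.
#' @export
classify_psiexons <- function(events, psi, annos, genome) {
  annos <- annotation_list(annos)
  inc <- merge(events[events$kind == "CE", , drop = FALSE],
               psi[psi$call == "Inc", c("event_id", "basal_psi")],
               by = "event_id")
  if (!nrow(inc)) {
    return(data.frame(event_id = character(), exon_start = integer(),
                      exon_end = integer(), length = integer(),
                      donor9 = character(), acceptor23 = character(),
                      basal_psi = numeric(), is_psiexon = logical()))
  }
  src <- vapply(annos, `[[`, character(1), "source")
  fully <- rep(0L, nrow(inc))
  for (s in src) {
    both <- inc[[paste0("acc_ann.", s)]] & inc[[paste0("don_ann.", s)]]
    fully <- fully + as.integer(both)
  }
  inc$n_sources_fully_annotated <- fully
  inc$is_psiexon <- fully == 0L
  inc$length <- inc$exon_end - inc$exon_start
  inc$donor9 <- vapply(seq_len(nrow(inc)), function(i) {
    donor_window(genome, inc$contig[i], inc$strand[i],
                 inc$exon_start[i], inc$exon_end[i])
  }, character(1))
  inc$acceptor23 <- vapply(seq_len(nrow(inc)), function(i) {
    acceptor_window(genome, inc$contig[i], inc$strand[i],
                    inc$exon_start[i], inc$exon_end[i])
  }, character(1))
  rownames(inc) <- NULL
  inc[, c("event_id", "contig", "strand", "exon_start", "exon_end", "length",
          "donor9", "acceptor23",
          grep("^(acc|don)_ann\\.", names(inc), value = TRUE),
          "n_sources_fully_annotated", "basal_psi", "is_psiexon")]
}

#' Summary statistics of a psiExon set
#' @param px Output of [classify_psiexons()].
#' @return list(n, median_basal_psi, median_length).
#' @export
psiexon_summary <- function(px) {
  px <- px[px$is_psiexon, , drop = FALSE]
  list(n = nrow(px),
       median_basal_psi = stats::median(px$basal_psi, na.rm = TRUE),
       median_length = stats::median(px$length))
}

#' Write psiExon records as BED6 (0-based half-open)
#' @param px psiExon records.
#' @param path Output path.
#' @export
write_psiexon_bed <- function(px, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   px$contig, px$exon_start, px$exon_end, px$event_id,
                   ifelse(is.na(px$basal_psi), 0L,
                          as.integer(round(px$basal_psi * 10))),
                   px$strand)
  writeLines(lines, path)
  invisible(path)
}
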