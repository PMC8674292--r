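#!/usr/bin/env Rscript
# Stage 3: alternative-splicing events from the corpus junction tables.
# Catalogue discovery, per-sample PSI, Fisher testing on pooled replicate
# counts, Inc/Skp calling at (|dPSI| > 20, P < 0.001), and psiExon
# classification of the included exons.

suppressPackageStartupMessages(library(psiexon))
stopifnot(dir.exists("results/corpus"))   # run 01_simulate_corpus.R first

genome <- read_genome("results/corpus/genome.fa")
anno <- read_annotation("results/corpus/annotation.gtf", "gtf",
                        source = "simulated")
jt <- read_junctions("results/corpus/junctions.tsv", "tsv")
mf <- read_manifest("results/corpus/manifest.tsv")
truth <- read.table("results/corpus/truth.tsv", header = TRUE, sep = "\t")

events <- build_event_catalog(jt, anno)
psi <- psi_table(events, jt, mf, control = "DMSO", treated = "treated")
px <- classify_psiexons(events, psi, anno, genome)

write.table(events, "results/events.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(psi, "results/psi.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(px, "results/psiexons.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
if (any(px$is_psiexon)) {
  write_psiexon_bed(px[px$is_psiexon, ], "results/psiexons.bed")
}

r <- inc_skp_ratio(psi)
s <- psiexon_summary(px)
cat("Event catalogue:", nrow(events), "events (",
    paste(names(table(events$kind)), table(events$kind), collapse = ", "), ")\n")
cat("Calls:", sum(psi$call == "Inc"), "Inc,", sum(psi$call == "Skp"),
    "Skp,", sum(psi$call == "NC"), "NC; Inc/Skp ratio:",
    ifelse(is.na(r$ratio), "undefined (no Skp)", round(r$ratio, 2)), "\n")
cat("psiExons among Inc cassette exons:", s$n,
    "| median basal PSI:", round(s$median_basal_psi, 2),
    "% | median length:", s$median_length, "bp\n")

# every planted pseudoexon sampled at 1% -> 60% inclusion should be an
# Inc-called psiExon with recovered coordinates
found <- merge(truth, px, by.x = c("contig", "strand", "start", "end"),
               by.y = c("contig", "strand", "exon_start", "exon_end"))
cat("Planted exons recovered as Inc-called cassette exons:", nrow(found),
    "of", nrow(truth), "(the annotated twin is Inc but, correctly, not a psiExon)\n")
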