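#!/usr/bin/env Rscript
# Stage 4: genome-wide scan for putative GA-psiExons. Every AGAGTAAG donor
# motif inside an annotated intron is tested against upstream AG acceptors
# scored with the trained acceptor model; passing candidates need length
# 6-200, acceptor score > 2.3 and no annotation match. Also emits the
# exon-terminal dinucleotide census (the GA class the compounds act on).

suppressPackageStartupMessages(library(psiexon))
stopifnot(dir.exists("results/corpus"))

genome <- read_genome("results/corpus/genome.fa")
anno <- read_annotation("results/corpus/annotation.gtf", "gtf",
                        source = "simulated")
acc_model <- read_pwm_model("results/corpus/acceptor_model.tsv")
introns <- derive_introns(anno)
truth <- read.table("results/corpus/truth.tsv", header = TRUE, sep = "\t")

cand <- scan_introns(genome, introns, acc_model, annos = anno)
write.table(cand, "results/scan.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write_scan_bed(cand, "results/scan.bed")

cat("Scanned", nrow(introns), "introns:", nrow(cand),
    "acceptor candidates at", length(unique(paste(cand$contig, cand$motif_pos))),
    "motif occurrences\n")
cat("Passing candidates:", sum(cand$passes_filters),
    "| primary (one per motif):", sum(cand$primary), "\n")

m <- merge(truth, cand, by = c("contig", "strand", "start", "end"))
cat("Planted-truth agreement:", sum(m$passes_filters == m$expect_pass),
    "of", nrow(truth), "verdicts correct\n")
print(table(class = m$class, verdict = ifelse(m$passes_filters, "pass", "fail")))

cen <- exon_end_dinucleotide_census(anno, genome)
write.table(cen, "results/exon_end_census.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Exon-terminal dinucleotides: AG (canonical)",
    sprintf("%.1f%%,", cen$percent[cen$dinucleotide == "AG"]),
    "GA", sprintf("%.1f%%\n", cen$percent[cen$dinucleotide == "GA"]))
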