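#!/usr/bin/env Rscript
# Stage 1: build the synthetic study corpus. A multi-gene genome on both
# strands with pseudoexons planted inside introns (strong and deliberately
# defective ones), junction counts for a DMSO-vs-compound contrast at low
# basal and high treated inclusion, and assay fixtures with known truth.

suppressPackageStartupMessages(library(psiexon))

dir.create("results/corpus", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 20260924L, n_genes = 8)
sim <- simulate_genome(cfg, n_plants = 8,
                       plant_classes = c("pass", "pass", "pass", "pass",
                                         "short", "long", "weak", "annotated"))
jc <- simulate_junction_counts(sim, psi_control = 1, psi_treated = 60,
                               n_control = 3, n_treated = 3, depth = 1000)
write_sim_corpus(sim, jc, "results/corpus")
qf <- simulate_quant_fixtures(seed = 20260924L, noise_sd = 0.1)
write.table(qf$ecl, "results/corpus/ecl.csv", sep = ",", quote = FALSE,
            row.names = FALSE)
write.table(qf$qpcr, "results/corpus/qpcr.csv", sep = ",", quote = FALSE,
            row.names = FALSE)

cat("Corpus written to results/corpus/:\n")
cat(" genome:", sum(Biostrings::width(sim$genome)), "bases on",
    length(sim$genome), "contigs\n")
cat(" genes:", nrow(sim$anno$transcripts), "transcripts;",
    nrow(sim$introns), "introns\n")
cat(" plants:", nrow(sim$truth), "(",
    sum(sim$truth$expect_pass), "expected to pass scan filters )\n")
cat(" junction rows:", nrow(jc$junctions), "across",
    nrow(jc$manifest), "samples\n")
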