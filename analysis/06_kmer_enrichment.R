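#!/usr/bin/env Rscript
# Stage 6: k-mer enrichment at the 5'ss of included vs unchanged exons.
# The planted pseudoexons all carry the AGA|GTAAG donor, so the exonic
# -4..-1 window should enrich A-rich/GA-terminal k-mers and the intronic
# +1..+6 window GTAAG-containing k-mers, relative to annotated NC exons.

suppressPackageStartupMessages(library(psiexon))
stopifnot(file.exists("results/psi.tsv"))

genome <- read_genome("results/corpus/genome.fa")
events <- read.table("results/events.tsv", header = TRUE, sep = "\t")
psi <- read.table("results/psi.tsv", header = TRUE, sep = "\t")

inc <- events[events$kind == "CE" &
              events$event_id %in% psi$event_id[psi$call == "Inc"], ]
nc <- events[events$kind == "CE" &
             events$event_id %in% psi$event_id[psi$call == "NC"], ]
cat("Comparing", nrow(inc), "Inc vs", nrow(nc), "NC cassette exons\n")

enr <- kmer_enrichment_scan(inc, nc, genome, ks = 4:6)
write.table(enr, "results/kmer_enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
top <- enr[enr$window == "intronic" & enr$k == 5, ][1:5, ]
cat("Top intronic 5-mers by |SS| (SS = -S * log10 P):\n")
print(top[, c("kmer", "n1", "n2", "p", "S", "SS")], row.names = FALSE)

# position frequency matrix of the Inc donor windows (logo-style summary)
win <- extract_ss_windows(inc, genome, c(-4L, 6L))
pfm <- position_frequency_matrix(win)
write.table(pfm, "results/inc_donor_pfm.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Donor-window position frequency matrix written for", length(win),
    "Inc exons (positions -4..+6)\n")
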