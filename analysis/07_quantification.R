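#!/usr/bin/env Rscript
# Stage 7: assay quantification arithmetic on the simulated fixtures —
# ECL protein lowering per animal and group, efficiency-corrected qPCR
# percent-of-vehicle, transwell Papp with both efflux metrics, and Kp,uu.

suppressPackageStartupMessages(library(psiexon))
stopifnot(file.exists("results/corpus/ecl.csv"))

ecl <- read.csv("results/corpus/ecl.csv")
low <- ecl_lowering(ecl, vehicle = "vehicle")
write.table(low$per_animal, "results/ecl_lowering_animals.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(low$per_group, "results/ecl_lowering_groups.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("ECL lowering (target/normaliser x1000 vs vehicle grand mean):\n")
print(transform(low$per_group, mean_lowering = round(mean_lowering, 1),
                sem = round(sem, 1)), row.names = FALSE)

qp <- read.csv("results/corpus/qpcr.csv")
qres <- qpcr_percent(qp, e_target = 1, e_norm = 1, vehicle = "vehicle")
write.table(qres, "results/qpcr_percent.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nqPCR percent of vehicle, (1+E)^-Ct with E = 1, GAPDH-normalised:\n")
agg <- aggregate(percent_of_vehicle ~ group, qres, mean)
print(transform(agg, percent_of_vehicle = round(percent_of_vehicle, 1)),
      row.names = FALSE)

# permeability: a low-efflux compound profile (B->A close to A->B)
fx <- simulate_quant_fixtures(seed = 20260924L)
p_ab <- papp(fx$perm$times, fx$perm$receiver_conc, fx$perm$vr, fx$perm$area,
             fx$perm$c0)
p_ba <- 1.25 * p_ab
em <- efflux_metrics(p_ab, p_ba)
cat(sprintf("\nPapp(A->B) = %.5e cm/s; Papp(B->A) = %.5e cm/s\n", p_ab, p_ba))
cat(sprintf("net efflux (difference, as defined) = %.3e; conventional ratio = %.2f\n",
            em$as_printed, em$conventional_ratio))
cat(sprintf("Kp,uu example (Cbrain 2, fu,b 0.05, Cplasma 1, fu,p 0.1) = %.2f\n",
            kpuu(2, 1, 0.05, 0.1)))
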