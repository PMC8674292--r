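# psiexon

Junction-level analysis of small-molecule **splicing modifiers** that
lower a target gene by activating a premature-stop **pseudoexon
(psiExon)**. Some compounds stabilise U1 snRNP recognition of
noncanonical 5' splice sites whose exon ends `GA` instead of `AG`
(signature motif `AGA|gtaag`); the included pseudoexon carries a
premature termination codon and/or frameshift, and nonsense-mediated
decay (NMD) then degrades the mRNA. This package implements, as tested
reusable R functions, the complete downstream analysis such a study
needs, exercisable end-to-end on synthetic data with known ground truth.

It is written for computational biologists working with splice-junction
counts from a spliced aligner (plus genome FASTA and GTF/GFF3/BED12
annotations) and for DMPK analysts handling the accompanying assay
arithmetic.

## What it computes

| Stage | Statistic |
|---|---|
| Amplicon panels | **JEI**, the junction expression index: `100 × n(exact intron junction) / Σ n(junctions using either splice site)`; group comparison by two-sided Student's *t*, flagged at >25% reduction and P < 0.05 |
| RNA-seq events | **PSI** with averaged inclusion-junction support, `NA` below a 20-read denominator; two-sided Fisher exact test on pooled replicate counts; `Inc`/`Skp` calls at ΔPSI > 20 (< −20) and P < 0.001 |
| psiExons | Annotation status of both splice sites against any number of sources; psiExon = no source annotates both |
| Splice-site strength | Maximum-entropy score tables (published layout, user-supplied) or a trainable PWM fallback; 9-mer donors, 23-mer acceptors, log2 odds |
| Genome scan | All `AGAgtaag` donors inside annotated introns with upstream scored acceptors; pass = length 6–200 nt, acceptor score > 2.3, unannotated |
| NMD | PTC-or-frameshift classification of an exon spliced into its host transcript |
| Motifs | Signed k-mer significance `SS = −S·log10 P` around the 5'ss; position frequency matrices |
| Assays | ECL percent protein lowering, `(1+E)^−Ct` qPCR quantification, transwell `Papp = (dCr/dt)·Vr/(A·C0)` with both efflux metrics, and `Kp,uu` |

A synthetic-data module generates genomes with planted pseudoexons
(including single-violation decoys), junction tables sampled at chosen
inclusion levels, and assay fixtures — every stage is testable offline.

## Worked example

```r
library(psiexon)

cfg <- sim_config(seed = 42, n_genes = 4)
sim <- simulate_genome(cfg, n_plants = 4,
                       plant_classes = c("pass", "short", "long", "weak"))
jc  <- simulate_junction_counts(sim, psi_control = 1, psi_treated = 60)

events <- build_event_catalog(jc$junctions, sim$anno)
psi    <- psi_table(events, jc$junctions, jc$manifest, "DMSO", "treated")
psi[psi$call == "Inc", c("event_id", "psi_control", "psi_treated", "dpsi", "p", "call")]
#>   event_id psi_control psi_treated     dpsi p call
#> 1   ev0001   0.9768289    59.84736 58.87053 0  Inc
#> 3   ev0003   0.9765546    58.90479 57.92823 0  Inc
#> 5   ev0005   0.9263892    60.40652 59.48013 0  Inc
#> 6   ev0006   1.0271491    62.36478 61.33763 0  Inc
```

Four planted exons, sampled at 1% basal and 60% treated inclusion, come
back as `Inc` calls with ΔPSI ≈ +59 and Fisher P below double precision.
The genome scan then recovers the same plants from sequence alone:

```r
sc <- scan_introns(sim$genome, sim$introns, sim$acceptor_model, annos = sim$anno)
merge(sim$truth, sc, by = c("contig", "strand", "start", "end"))[,
  c("plant_id", "class", "passes_filters", "fail_reason")]
#>   plant_id class passes_filters   fail_reason
#> 1 plant004  weak          FALSE weak_acceptor
#> 2 plant003  long          FALSE      too_long
#> 3 plant001  pass           TRUE
#> 4 plant002 short          FALSE     too_short
```

The passing plant is reported with exact boundaries (exon ends `AGA`,
intron continues `GTAAG`); each decoy fails exactly the filter it was
built to violate. `classify_nmd()` on the recovered exon reports
`frameshift TRUE, ptc TRUE, is_nmd TRUE` — a 64-nt insert with an
introduced stop.

The `analysis/` directory holds the same workflow as numbered narrative
drivers (`01_simulate_corpus.R` … `07_quantification.R`), each writing
its tables under `results/`.

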