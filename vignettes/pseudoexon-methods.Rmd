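---
title: "Methods: junction statistics, pseudoexon discovery and assay arithmetic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction statistics, pseudoexon discovery and assay arithmetic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`psiexon` analyses the splicing signature of small-molecule splicing
modifiers that lower a target gene's expression by activating a
*pseudoexon* (psiExon): an intronic segment, normally invisible to the
spliceosome, whose inclusion in the mature mRNA introduces a premature
termination codon and/or a frameshift, routing the transcript into
nonsense-mediated decay (NMD). The compound class of interest stabilises
U1 snRNP binding at noncanonical donors whose exon ends in `GA` rather
than `AG` — the signature motif is `AGA|gtaag` (three exonic bases, five
intronic). Everything downstream of read alignment is implemented here:
the inputs are junction count tables (spliced-aligner output), genome
FASTA, one or more transcript annotations, and assay measurement tables.

All genomic intervals inside the package are 0-based half-open on the
forward strand; 1-based dialects (GTF, the 9-column junction tab format)
are converted once at the I/O boundary. On the minus strand the
genomic-left coordinate of an intron is biologically its 3' splice site;
every sequence-facing function re-orients windows to biological 5'→3'.

# Junction expression index (JEI)

For an annotated intron with donor $d$ and acceptor $a$,

$$\mathrm{JEI} = 100 \times
  \frac{n(d \to a)}{\sum_{j:\, \text{donor}(j)=d \,\vee\, \text{acceptor}(j)=a} n(j)},$$

the percent of junction reads supporting exactly the annotated intron
among all reads using either of its splice sites. 100% means fully
canonical splicing; cryptic-exon inclusion or alternative splice-site use
pulls it down. Three deliberate choices:

* The JEI is computed *per sample* and groups are compared on per-sample
  values — a *t* test over biological replicates requires per-replicate
  values, so group JEI is the mean of sample JEIs, not a pooled-count
  ratio.
* The group test is the classical pooled-variance two-sample Student's
  *t* (two-sided); the unequal-variance form is available via
  `pooled_variance = FALSE`. An intron is flagged as a compound-induced
  event at reduction > 25% *and* P < 0.05.
* Junctions fully inside the intron that touch neither splice site are
  excluded from the denominator: the definition names only junctions
  using the intron's 5'ss or 3'ss.

Degenerate data are labelled, never guessed: fewer than two defined JEIs
in a group makes the intron `untestable`; two constant equal groups give
t = 0, P = 1; constant unequal groups give P = 0 with a `degenerate`
flag. A JEI with an empty denominator is `NA`, never silently 0.

# PSI, event testing and calls

Events follow the cassette-exon (CE) / alternative 5'ss / alternative
3'ss taxonomy. Discovery is junction-driven with the annotation as
scaffold: annotated internal exons always seed CE events, and a novel CE
`[s, e)` requires all three junctions `(u, s)`, `(e, v)` and the bridging
skip `(u, v)` to be observed. Junction pairs sharing one coordinate (and
not already explained by a CE) become A5SS/A3SS events; which class is
strand-dependent, and the shorter-intron junction — the isoform retaining
more exonic sequence — is taken as the inclusion isoform.

Percent spliced in uses the averaged-inclusion reading: inclusion support
is the arithmetic mean of the inclusion-junction counts (two junctions
for CE, one for the A events), exclusion support the skip count, and

$$\mathrm{PSI} = 100 \times \frac{\bar n_{\mathrm{inc}}}
  {\bar n_{\mathrm{inc}} + n_{\mathrm{exc}}},$$

reported as `NA` whenever the denominator is below 20 reads, the
stability floor for a junction-based percentage. Group PSI averages the
per-sample values with `NA` excluded; ΔPSI is treated minus control.

The significance test is a two-sided Fisher exact test on the 2×2 table
(rows inclusion/exclusion, columns the two groups) with biological
replicates combined: per-sample supports are summed within group and
rounded half-up, since an exact test needs integer counts and averaging
the two CE inclusion junctions produces halves. Events are called `Inc`
at ΔPSI > 20 and P < 0.001, `Skp` at ΔPSI < −20 and P < 0.001, else
`NC`; both thresholds are strict inequalities and exactly-at-threshold
events stay `NC`. No multiplicity correction is applied — the fixed
P < 0.001 cutoff is itself the selection rule, so reported P values are
selection scores, not FDR-controlled estimates.

An Inc-called cassette exon is a **psiExon** when no single annotation
source annotates both of its splice sites. With several sources loaded
(RefSeq-, Ensembl-, UCSC-style), each is consulted independently;
`n_sources_fully_annotated` records how many know the exon completely.

# Splice-site models

Two scoring backends share one contract: a donor window is 9 nt
(−3..+6), an acceptor window 23 nt (−20..+3), both supplied in
biological orientation, and scores are log2 odds.

* **maxent-tables** reads the published maximum-entropy score tables in
  their distributed layout (`me2x5` (+ `splice5sequences`) for donors;
  `me2x3acc1..9` for acceptors) and reproduces the published combination
  rules: a consensus-odds factor over the two near-invariant boundary
  bases times the table terms (a single 7-mer lookup for donors; the
  five-over-four factor product for acceptors). The tables are
  third-party and user-supplied, never bundled; the loader's mechanics
  are verified against synthetic table directories generated in code.
* **pwm-fallback** is a position weight matrix trained from annotated
  splice sites: per-position log2 of base frequency (additive
  pseudocount, default 1) over a uniform 0.25 background, summed over
  positions. It keeps every pipeline stage — including the genome scan —
  self-contained on synthetic corpora.

The scan threshold (below) applies to whichever backend is configured;
because the scale is only comparable within a backend, the backend name
is recorded in all outputs. Windows containing `N` score `NA` and are
flagged, never imputed.

# Genome-wide GA-psiExon scan

Within each annotated intron, on the host gene's sense strand only
(pseudoexon inclusion requires the pre-mRNA's orientation), every
occurrence of `AGAGTAAG` marks a putative donor: the candidate exon ends
with the `AGA`, the `GTAAG` stays intronic. Every upstream `AG`
dinucleotide then defines a candidate acceptor; its 23-mer window (18
tract bases + `AG` + 3 exonic bases) is scored. A candidate **passes**
when its length is 6–200 nt, the acceptor scores above 2.3, and the exon
is unannotated — meaning its interval matches no annotated exon exactly
and no single source annotates both splice sites.

Enumeration deliberately extends past the filter bounds (lengths 2 to
`max_len + 10`), so near-miss candidates appear in the output with an
explicit failure reason (`too_short`, `too_long`, `weak_acceptor`,
`annotated`, `window_truncated`) instead of vanishing. Acceptors whose
window would cross the intron boundary are skipped with a reason. Since
one motif can have several passing acceptors and the counting unit is
ambiguous, all candidates are reported and a `primary` flag marks the
best-scoring passing acceptor per motif occurrence (ties to the shorter
exon); both "per candidate" and "per occurrence" counts are therefore
available. Candidates are deduplicated by (contig, strand, interval)
across overlapping transcripts.

# NMD classification

The classifier follows the literal definition: a psiExon is
NMD-inducing when its inclusion introduces a PTC, causes a frameshift
(length not divisible by 3), or both. The exon is spliced into its host
transcript — by default the longest CDS-bearing transcript with an
intron containing it, and the choice is recorded — and translation
proceeds from the annotated start. For in-frame insertions the PTC must
lie inside the inserted exon; for frameshifted insertions any stop ahead
of the original stop counts (the call is already NMD via the frameshift;
the scan only refines the reported stop position). Insertions upstream
of the start codon are non-coding and never NMD. The 50-nt
exon-junction rule is *not* applied by default — fidelity to the stated
definition — but is available via `ejc_rule = TRUE` for exploration.

Host-gene expression consequences are tested on an externally computed
differential-expression table (the negative-binomial fitting itself is
out of scope and consumed as input): a two-sided Wilcoxon rank-sum test
of the NMD-host genes' log2 fold changes against all other genes, exact
for small tie-free sets, normal approximation with tie correction
otherwise. The volcano classifier labels genes at fold change beyond
1.5× with FDR < 5%, on the fold scale (a log2 fold change of 0.4 is
1.32×, below threshold however small its FDR).

# K-mer enrichment

For two exon groups (typically Inc vs NC), fixed windows around the 5'ss
(−4..−1 exonic, +1..+6 intronic) are compared per k-mer (k = 4–6) with a
two-sided Fisher exact test of one k-mer against all others, and
reported as the signed significance score
$\mathrm{SS} = -S \log_{10} P$ with $S = +1$ for relative enrichment in
group 1. Occurrences are counted overlapping (for the 4-base window with
k = 4 this equals presence/absence). Scores are a ranking device and are
not multiplicity-corrected. The side convention of the Fisher test is
recorded in the output; swapping the groups negates every SS exactly.

# Assay arithmetic

* **Protein lowering (ECL):** per animal, mean duplicate target signal
  over mean duplicate normaliser signal × 1000; fold change against the
  vehicle group's grand mean ratio; lowering = (1 − fold) × 100. The
  vehicle group's mean lowering is 0 by construction — an identity the
  tests assert exactly. The white-blood-cell variant runs on raw target
  means without a normaliser.
* **qPCR:** abundance $(1+E)^{-C_t}$ per amplicon, target normalised to
  the housekeeping amplicon, expressed as percent of the vehicle-group
  mean — the efficiency-generalised 2^−ΔΔCt. When E is not supplied it
  is estimated from a dilution series as $E = 10^{-1/\text{slope}} - 1$.
  E outside (0, 1.2] is rejected.
* **Permeability:** $P_{app} = (dC_r/dt) \cdot V_r / (A \cdot C_0)$,
  the receiver slope by least squares (difference quotient for two
  points), default area 1.13 cm² (12-well insert). The net efflux metric
  is emitted in *both* forms — the difference
  $P_{app}^{B \to A} - P_{app}^{A \to B}$ exactly as the source
  arithmetic defines it, and the conventional quotient — labelled and
  unprivileged, because the defined difference is plausibly a typo for
  the customary ratio and silently correcting source arithmetic is worse
  than reporting both. The percent-recovery formula is referenced by the
  assay description but never printed, so it is not implemented; the
  donor volume is carried in the record for users who supply their own.
* **Brain partitioning:**
  $K_{p,uu} = C_{brain} f_{u,b} / (C_{plasma} f_{u,p})$.

# The synthetic corpus

`simulate_genome()` builds multi-exon genes on both strands with
consensus `GT..AG` introns (polypyrimidine acceptor tracts) and annotated
CDS so NMD calls are decidable, then plants pseudoexon cassettes
(`tract+AG | body…AGA | GTAAG`) inside introns by length-preserving
replacement, so annotation coordinates never shift. Acceptor strength is
*rejection-sampled against the same PWM the scan will use* — pyrimidine-
rich tracts for passing plants, purine-rich for weak decoys — and the
achieved score is frozen into the truth manifest, so planted class and
scan verdict are compared on identical footing. Decoy classes violate
exactly one filter each: length 5, length 201, acceptor ≤ 2.3, or an
exact-interval annotated twin transcript. Intron cores and UTR filler
are re-drawn until free of accidental `AGAGTAAG`, so a zero-plant corpus
scans clean.

Junction counts model the junction-level read expectation: a transcript
including the exon contributes reads to *two* inclusion junctions, a
skipping transcript to one skip junction, so with true inclusion
fraction $p$ a junction read falls on an inclusion junction with
probability $2p/(1+p)$. Total event depth is fixed, inclusion reads are
binomial at that probability, split evenly across the two inclusion
junctions with the ±1 remainder alternating deterministically. Under the
averaged-inclusion PSI formula this makes the estimator unbiased for
$p$ (at depth 1000 and PSI 30% the standard error is ≈1.3 points).
Quantification fixtures encode their truth exactly at zero noise
(log-normal signal noise optional); the permeability series is exactly
collinear so the encoded Papp is recovered to machine precision.

What the generator does **not** emulate: read-level artefacts (mapping
bias, overhang filters, sequencing error), expression heterogeneity
across genes, intron retention, or correlated biological replicate
structure. Passing tests therefore demonstrate correctness of the
statistics and the discovery logic under the stated sampling model, not
robustness to alignment pathology on real data.

# Problem sizes and numerical choices

The shipped analyses and tests use deliberately small corpora — 2–8
genes for most stages and a 34-gene genome (~102 introns) for the scan
recall study, junction depths of 400–10,000, 500 replicate draws for PSI
recovery, and 1,000 sampled tables for the Fisher-oracle comparison —
sizes at which every oracle is exhaustively computable while each stage
still exercises both strands and all decoy classes. Fisher agreement is
asserted to 1e−12 against direct enumeration with the classical
relative-tolerance tie rule; rounding of pooled supports is half-up
(`floor(x + 0.5)`), avoiding banker's rounding surprises; PSI/JEI
undefinedness is always explicit `NA` with a reason, and every
degenerate statistical input (empty margins, constant groups, missing
FDR) has a defined, flagged output rather than an error or a silent
default.

# Known limitations

* Event discovery enumerates junction triples; on dense real junction
  sets this is quadratic per skip junction and would need indexing for
  genome-scale inputs.
* The PWM fallback scores on a different scale than the
  maximum-entropy tables; the 2.3 scan threshold is calibrated for the
  latter, so fallback-based scans are meaningful for planted-truth
  recovery, not for absolute strength claims on real genomes.
* NMD classification uses one host transcript (longest CDS); genes
  whose isoforms disagree about the hosting intron are resolved by that
  choice, which the output records.
* The A5SS/A3SS inclusion convention (shorter intron = inclusion) is a
  package convention; callers comparing against other tools should check
  the sign of ΔPSI for A events.
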