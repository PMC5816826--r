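---
title: "Models and methods behind misspR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind misspR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misspR)
```

misspR implements an effector-discovery workflow for ectomycorrhizal
fungi: it catalogues the secretome, selects mycorrhiza-induced small
secreted proteins (MiSSPs), places genes in genome compartments from
flanking intergenic region lengths, and quantifies gene presence–absence
polymorphism across a panel of re-sequenced strains. This vignette
explains each model, the thresholds that drive it, the synthetic data that
exercises it, and the numerical choices made where the design was open.

## Secretome cataloguing

Secreted proteins (those carrying a signal peptide; prediction itself is
upstream of this package) are partitioned into five *disjoint* classes:
CAZymes, lipases, proteases, SSPs and other SPs. SSP status is a pure size
rule — strictly shorter than `ssp_max_len = 300` amino acids — while the
enzymatic classes come from annotation. Since a 220-aa CAZyme satisfies
both definitions and the published class counts are disjoint (they sum to
the secretome total), we resolve overlaps by precedence
CAZyme > lipase > protease > SSP > otherSP: an enzymatic annotation is
more specific than a length cutoff. The partition property (class counts
always sum to the input size) is enforced by construction and tested.

MiSSP candidates are SSPs whose linear fold change in the
symbiosis-versus-free-living-mycelium contrast strictly exceeds
`missp_fold = 2.5` (computed as `2^log2fc > 2.5`). The packaged candidate
table contains one row (protein 664950, log2FC 1.21, i.e. 2.31-fold) that
sits below this rule while being part of the recorded 22-candidate set;
we treat the packaged table as authoritative for the candidate list and
keep the rule strict, so `select_missps()` returns 21 of those 22 rows.
This discrepancy is surfaced rather than patched: the selection rule is a
contract, the table is data.

Cysteine content is reported as `100 * n_C / length_aa` rounded to two
decimals. For one recorded 58-aa protein a printed value of 3.51% implies
a denominator of 57 (probably a stop-codon or signal-peptide handling
difference); we keep the plain definition and accept a possible
0.1-point discrepancy on such rows.

## Expression states

Normalization uses the textbook definitions: FPKM is
`count * 1e9 / (library_size * length_bp)` and TPM rescales
length-normalized rates to a per-sample sum of one million. A gene is
*expressed* in a condition when its replicate-mean FPKM strictly exceeds
`expressed_fpkm = 1`; a gene is *regulated* in a contrast when
`|log2FC| > 1` and FDR `< 0.05`. The FDR procedure is Benjamini–Hochberg
(the conventional default of the DE engines this workflow consumes
tables from); `bh_adjust()` validates its input and is property-tested
against a literal step-up implementation.

Host preference compares condition-mean FPKM between two hosts: a
transcript is host-*specific* only when the other host shows exactly zero
expression, host-*preferential* when the larger/smaller ratio strictly
exceeds `host_fold = 5`, and *shared* otherwise (two zeros are shared).
Class enrichment among up- (and separately down-) regulated genes uses
the one-sided hypergeometric tail `P(X >= k)` — the enrichment direction
of Fisher's exact test — with the classified secretome as universe,
computed exactly via `phyper()` and cross-checked against term-by-term
enumeration for small universes.

`simple_de_test()` is deliberately labelled a stand-in: median-of-ratios
size factors (geometric-mean reference, genes containing zeros excluded
from the median), log2 fold changes of normalized group means with a
pseudocount of 1, two-sided Welch t-tests on `log2(normalized + 1)`, and
BH adjustment. It exists so that synthetic counts can be scored without a
full RNA-seq engine; it has no dispersion shrinkage or independent
filtering, and at the study's minimum of three replicates its power is
modest — the planted-recovery evaluation below therefore uses five
replicates, where it recovers over 80% of planted four-fold changes.

## Two-speed genome architecture

For every gene we measure the flanking intergenic region (FIR) on each
side as the number of bases strictly between adjacent gene spans
(`start_next − end_prev − 1`; abutting genes give 0, overlapping ones are
clamped to 0 with a warning). The upstream gap is the 5′ FIR for a
`+`-strand gene and the 3′ FIR for a `−`-strand gene. Genes at contig
edges get an undefined FIR on the edge side — we do not substitute the
distance to the contig end, because a contig break carries no repeat
information — and a gene is still classifiable from its single defined
flank. Two invariances pin this definition down: translation of all
coordinates and mirror-reversal of a contig (with strand flips) leave
every (5′, 3′) pair unchanged.

A gene is assigned to the gene-sparse repeat-rich compartment (GSR) when
its 5′ and/or 3′ FIR strictly exceeds `gsr_cutoff_bp = 6495` bp, to the
gene-dense repeat-poor compartment (GDR) when every defined FIR is at or
below the cutoff, and is unassigned when neither flank is defined. The
cutoff's provenance (a fit to one genome's FIR distribution) is not
reproducible here, so it is a configurable constant defaulting to the
published value. The density heatmap bins log10(FIR) at width 0.1
(the published analysis says only "log(length)"); zero-length FIRs go in
the first bin, and overlays (mean log2FC or FPKM per bin) are averaged
over member genes. Compartment composition per secretome class reuses the
same exact hypergeometric machinery; expression differences between
compartments use a two-sided Mann–Whitney test (exact for small untied
samples via `wilcox.test`, otherwise the tie-corrected normal
approximation).

## Presence–absence polymorphism

Strain panels are scored from 12-column tabular alignment hit tables.
The best hit is the lowest e-value, ties broken by greatest HSP length,
remaining ties by input order (deterministic). Absence is called when the
deletion — the uncovered complement of the merged query intervals —
spans strictly more than `absence_deletion_frac = 90%` of the gene, i.e.
covered fraction < 0.10. The published rule speaks of a "deletion event
overlapping >90% of the gene"; coverage complement over merged HSPs is
the only hit-table-computable equivalent, and intermediate coverage
(10–90%) is "present" under the strict rule but visible in the evidence
output for manual review.

Strain similarity uses Jaccard distances
`d = 1 − |intersection| / |union|` over gene rows; a pair of all-absent
profiles has an empty union and is assigned distance 0 (indistinguishable
on this data), with a logged message. Principal coordinates analysis
Gower-double-centers `−D²/2` and keeps eigenvalues above `1e-10`, scaling
eigenvectors by the square root of their eigenvalue; negative eigenvalues
are reported and dropped, with no Lingoes/Cailliez correction — the
correction behaviour of the commercial package used for the original
ordination is unknown, so we prefer the transparent option.

One-way PERMANOVA follows Anderson's formulation:
`SS_total = Σ_{i<j} d²_ij / N`, `SS_within = Σ_g Σ_{i<j∈g} d²_ij / n_g`,
`pseudo-F = ((SS_T − SS_W)/(a−1)) / (SS_W/(N−a))`. The permutation null
is unrestricted label permutation; all distinct assignments are
enumerated when there are at most 10,000 of them (p is then exact),
otherwise random permutations are drawn (default 9,999, the published
setting) and p uses the `(1 + b)/(1 + m)` estimator so it can never be
zero. F-ties are counted with a `1e-12` tolerance. Conservation classes
polarize presence against outgroup species: `core` (all strains, all
outgroups), `genus_conserved` (all strains, missing in ≥1 outgroup),
`dispersed` (missing in ≥1 strain). PERMANOVA on unbalanced tiny panels
(factor levels with one member) is fragile; the package computes it but
the caller should read small-level results with care.

## What the synthetic data emulates — and what it does not

`sim_config()` fixes the study conditions for the generator. Genes
(uniform 300–3,000 bp) are laid without overlap on contigs; each contig
carries one repeat-rich block at its end holding ~`frac_gsr = 30%` of its
genes, and a gap is drawn from the sparse log-normal component only when
both flanking genes belong to the repeat block (so a block edge gene
keeps one long flank, and blocks hold at least two genes). The two
components have medians 200 bp and 20,000 bp with `sdlog = 0.5` — a 100×
separation straddling the 6,495-bp cutoff. Nothing about the real FIR
distribution beyond its bimodal heatmap is published, so this
parametrization is a stand-in chosen to be realistic for a repeat-invaded
fungal genome, not an estimate.

Counts are negative binomial (dispersion 0.1, log-normal baseline means)
for free-living mycelium and two ECM conditions, three replicates by
default as in the study; a `de_fraction` of genes per secretome class is
induced by `planted_lfc` log2 units in both ECM conditions. Strain panels
delete genes at the clade level (probability `deletion_rate`, optionally
per clade), flip strain-private calls at `strain_noise_rate = 2%`, and
delete outgroup genes independently at 30%; retained genes emit one
full-span high-identity hit, deleted genes emit nothing or a residual
hit covering ~8% of the gene. Hit tables are generated directly rather
than by simulating sequences and aligning, because every decision rule
here operates on hit geometry, not alignment internals.

Determinism is file-level: one RNG stream per generator, seeded from the
master seed plus a fixed offset, so identical configurations give
byte-identical GFF3, count and hit-table outputs.

Passing the planted-truth tests therefore shows that the *decision rules*
recover clean structure; it does not show robustness to fragmented
assemblies, partial hits near the 10% boundary, mapping biases, or
overdispersion beyond the NB model — real-data caveats the original
analyses handled by manual curation and PCR validation, which are out of
scope here.

## Problem sizes and evaluation settings

The packaged evaluations use sizes chosen to make the statistical
properties measurable while staying comfortable on a laptop: 2,000-gene
genomes for compartment-label recovery (observed agreement ≥95% under
the 100×-separated mixture), 12-strain panels of 50 genes for exact
deletion recovery, 500 null panels at 199 permutations each for the
PERMANOVA type-I check (the discrete permutation p is exactly calibrated
at α = 0.05 when `(1+b)/(1+199) ≤ 0.05`), and 2,000 genes × 5 replicates
for stand-in DE recall. The acceptance script
(`scripts/acceptance.R`) re-runs the fixture statistics and the recovery
evaluations from scratch under a caller-supplied seed.

## Known limitations

* The GDR/GSR cutoff is taken as given; no mixture fit is performed.
* `simple_de_test()` is not a substitute for a dispersion-modelling DE
  engine at low replication.
* Negative PCO eigenvalues are dropped, so non-Euclidean distance
  structure is only reported, not embedded.
* Conservation classes assume outgroup hit tables of quality comparable
  to the strain panel.
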