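# misspR

Ectomycorrhizal fungi negotiate symbiosis with their host trees partly
through **mycorrhiza-induced small secreted proteins (MiSSPs)** — candidate
effectors that are up-regulated in symbiotic root tips relative to
free-living mycelium. misspR provides the downstream computational toolkit
for a MiSSP discovery study: it is written for researchers who already have
gene annotations, secretome annotations, differential-expression tables and
BLAST-style hit tables, and who need the rule-based cataloguing, genome
architecture and presence–absence analyses that turn those inputs into
effector candidates and evolutionary signal.

## What it computes

* **Secretome catalogue** — partitions signal-peptide-bearing proteins into
  five disjoint classes (SSP < 300 aa, CAZyme, lipase, protease, other SP;
  enzymatic annotation takes precedence over the size rule), per-protein
  statistics (size, signal-peptide length, cysteine %), strict
  `2^log2FC > 2.5` MiSSP selection, and reciprocal duplication pairs.
* **Expression states** — FPKM/TPM, expressed calls (mean FPKM > 1),
  regulation calls (|log2FC| > 1 and BH-FDR < 0.05), 5-fold host-preference
  calls, one-sided hypergeometric class enrichment, and Venn-region
  overlaps between systems. A documented stand-in DE test (median-of-ratios
  size factors + Welch t on log-normalized counts) scores synthetic data.
* **Two-speed genome architecture** — strand-aware 5′/3′ flanking
  intergenic regions (FIRs, `start_next − end_prev − 1`), log10-binned 2D
  density heatmaps with expression overlays, and GDR/GSR compartment calls:
  a gene is **GSR** (gene-sparse, repeat-rich) when its 5′ and/or 3′ FIR
  exceeds 6,495 bp.
* **Presence–absence polymorphism** — best hit by lowest e-value then
  greatest HSP length; absence when the deletion covers > 90 % of the gene
  (merged-HSP coverage < 0.10); Jaccard distances
  `d = 1 − |x∧y|/|x∨y|`; principal coordinates (Gower double-centering of
  −D²/2); one-way PERMANOVA,
  `F = ((SS_T − SS_W)/(a−1)) / (SS_W/(N−a))`, with exhaustive label
  enumeration when feasible and the `(1+b)/(1+m)` permutation estimator
  otherwise; conservation classes (core / genus-conserved / dispersed)
  against outgroup species.
* **Synthetic study generator** — bipartite genomes with a two-component
  log-normal intergenic mixture, negative-binomial counts with planted
  fold changes, and clade-structured deletion panels emitted as 12-column
  hit tables, all with exported ground truth and byte-identical
  reproducibility under a fixed seed.

## Worked example

The packaged fixtures hold the 22-candidate MiSSP table and the recorded
presence–absence statements for 16 isolates plus two outgroup species:

```r
library(misspR)
fx  <- load_fixtures()
cat <- classify_secretome(data.frame(protein_id = fx$table1$protein_id,
                                     length_aa = fx$table1$size_aa,
                                     has_signal_peptide = TRUE))
sel <- select_missps(data.frame(gene_id = fx$table1$protein_id,
                                log2fc = fx$table1$lfc_semisterile_pine),
                     cat)
head(sel, 3)
#>   gene_id log2fc fold_change
#> 1  698167   8.21    296.1122
#> 2  660401   8.08    270.5966
#> 3  680403   7.88    235.5680
```

The top candidate (698167, a Six1-like protein) is induced ~296-fold in
pine root tips. Conservation against the outgroups and the clade signal
in the presence–absence patterns:

```r
conservation_classes(fx$presence)$counts
#>            core genus_conserved       dispersed
#>               2               6              14

d   <- jaccard_distances(fx$presence$calls[, !fx$presence$is_outgroup])
res <- permanova(d, fx$strain_metadata$clade, n_perm = 999, seed = 1)
#> clade: pseudo-F = 14.640, p = 0.001 (999 permutations)
```

Two candidates are conserved everywhere, six are fixed in the species but
missing from an outgroup, and fourteen show presence–absence polymorphism
among isolates — polymorphism that the phylogenetic clade explains
(p = 0.001), consistent with effector evolution through gene gain/loss.

A full synthetic run (`run_pipeline(list(seed = 1))`, or
`Rscript inst/scripts/missp-pipeline.R all --seed 1 --outdir out/`)
exercises every stage against planted truth and writes stage outputs plus
a JSON report.

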