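# Packaged fixtures

- `missp_table1.tsv` — the curated table of the 22 MiSSP candidates
  (protein id, putative function, size, signal-peptide length, cysteine
  percentage, presence in other Dothideomycetes, log2 fold changes in the
  semi-sterile pine system and the in-vitro pine/poplar systems, tissue
  flags, reciprocal duplication partners). Note one candidate (664950,
  log2FC 1.21 = 2.31-fold) sits below the 2.5-fold selection rule; the
  table is authoritative for the 22-candidate list.
- `secretome_class_counts.tsv` — the five published secretome class counts
  (sum 595).
- `missp_presence_statements.tsv` — 22 candidates x (16 isolates + 2
  outgroup species, *Glonium stellatum* and *Lepidopterella palustris*),
  binary presence. Only the gene-level conservation statements are of
  record (2 genes present everywhere; 6 present in all isolates but
  missing in at least one outgroup; 14 missing in at least one isolate;
  isolates 1-3 carrying all 22). Individual cells not fixed by those
  statements are SYNTHETIC completions chosen to be consistent with them;
  strain ids are synthetic labels.
- `strain_metadata_synthetic.tsv` — SYNTHETIC isolate metadata with the
  recorded factor structure (3 phylogenetic clades, 4 countries, 4 forest
  types: *Picea abies* Pa, *Pinus sylvestris* Ps, *Fagus sylvatica* Fs,
  mixed Mx).
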