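# dgetag

Tag-based digital gene expression (DGE) profiling against a reference
transcriptome, for transcriptomics studies that count SAGE-style
restriction tags instead of full reads. The motivating design: a
non-model plant under cold stress, one clean-tag library per condition
(a control plus 12 h / 24 h / 48 h treatments), a de novo transcriptome
as the mapping reference, and no biological replicates — so differential
expression rests on an exact conditional test between two libraries of
known sizes.

The package implements the whole chain as tested functions:

* **Reference tag database** — every CATG (NlaIII) site with ≥ 17 nt
  downstream yields a 21-nt tag (CATG + 17 nt, the MmeI cut length), on
  both strands (`extract_reference_tags()`).
* **Tag mapping** — exact-first, then 1-mismatch; tags whose best-tier
  hits span ≥ 2 genes are discarded as ambiguous; unambiguous counts are
  normalized to transcripts per million clean tags,
  `tpm = count / library_size × 10⁶` (`map_tags()`, `normalize_tpm()`).
* **Differential expression** — the Audic–Claverie conditional
  p(y|x) = (N₂/N₁)^y (x+y)! / (x! y! (1+N₂/N₁)^(x+y+1)), two-sided via
  the doubled smaller tail with each direction evaluated under its own
  library orientation (exactly swap-symmetric), BH-adjusted per
  comparison; significant = FDR ≤ 0.001 & |log₂ratio| ≥ 1, plus a
  sub-2-fold "difference" tier at p ≤ 0.01 (`ac_pvalue()`, `de_test()`).
* **Time-course sets** — three-way Venn partitions per direction,
  shared percentages, novel genes (zero control tags, expressed under
  treatment) (`venn_partition()`, `detect_novel()`).
* **GO-slim enrichment** — minimal OBO parsing, nearest-slim-ancestor
  mapping (map2slim semantics), hypergeometric upper-tail tests
  (`read_obo()`, `map_to_slim()`, `hypergeom_enrich()`).
* **Forward simulator** — transcriptomes with controllable CATG density,
  designated per-time-point fold changes, 3′-most-site tag capture,
  per-base substitution error and dirty-tag filtering, for ground-truth
  validation of every stage (`generate_transcriptome()`, `make_truth()`,
  `simulate_tag_library()`); `run_pipeline()` drives all stages.

The methods vignette (`vignettes/tag-dge-methods.Rmd`) documents the
model, the numerics and the design decisions.

## Worked example

The numbered scripts under `analysis/` run the full study shape on
simulated data (2,000 genes, four libraries of 500,000 tags, seed 42)
and write their tables under `results/analysis/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_build_reference.R
Rscript analysis/03_map_tags.R
Rscript analysis/04_differential_expression.R
Rscript analysis/05_timecourse_sets.R
Rscript analysis/06_go_enrichment.R
```

Output of a run (abridged):

```
simulated 2000 transcripts (mean length 829 nt)
library control  497935 clean tags (9283 distinct), 2065 dirty reads removed, 160 genes unobservable
reference: 2000 genes, 1866 with CATG sites (93.3%), 32837 reference tags
control  mapped 99.27% of distinct tags (99.99% of copies); ...
12h    169 significant (117 up / 52 down), 125 difference-tier, 2000 genes tested
24h    150 significant (96 up / 54 down), 100 difference-tier, 2000 genes tested
48h    169 significant (111 up / 58 down), 134 difference-tier, 2000 genes tested
DE union across the time course: 303 genes (205 up, 98 down)
common to all three time points: 16 up (7.8% of 205), 12 down (12.2% of 98)
novel genes per treatment: 12h=16, 24h=9, 48h=11; expressed at all three: 3
recovery 12h   sensitivity 0.804 (152/189), precision 0.899 (152/169)
```

Reading it: of 2,000 simulated genes, 1,866 carry a usable CATG site
(the rest are invisible to the assay — 160 of them were expressed);
~99% of distinct clean tags map because the simulated reference is
complete, unlike real assemblies; each treatment-vs-control comparison
calls 150–170 genes significant at FDR ≤ 0.001 with ≥ 2-fold change;
the three DE lists overlap into a 303-gene union with 16 genes
upregulated at every time point; and comparison against the simulation
truth shows ~80% sensitivity and ~90% precision at this depth. The same
computations are available in one call as
`run_pipeline(pipeline_config(...))`.

Equivalent one-off calls:

```r
library(dgetag)
ac_pvalue(x = 5, N1 = 4810000, y = 50, N2 = 4490000)  # 4.362287e-11
shared_percentage(457, 3178)                          # 14.4
normalize_tpm(3, 4810000)                             # 0.6237006
```

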