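---
title: "Methods: tag-based digital gene expression profiling with dgetag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tag-based digital gene expression profiling with dgetag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgetag)
```

## The assay and the model

Digital gene expression (DGE) tag profiling is a SAGE-style counting assay.
Poly(A)+ cDNA is digested with NlaIII, which cuts at every CATG; the
3′-most fragment of each transcript is retained on oligo-dT beads, and
MmeI — whose recognition site is engineered into the adaptor–CATG
junction — cuts 17 bp downstream. Each transcript molecule is thereby
reduced to a single 21-nt tag (CATG + 17 nt) taken at the 3′-most CATG
site, and tag counts proxy transcript abundance. A transcript with no
CATG site at least 17 nt from its 3′ end is invisible to the assay; in
the reference transcriptomes this pipeline targets, a substantial
minority of genes (here typically 5–10% of simulated transcripts, ~19%
of unigenes in the motivating dataset) fall in that class.

`dgetag` implements the full downstream analysis as tested, reusable
functions, and pairs it with a forward simulator of the chemistry so the
whole chain can be exercised against a known ground truth. The package is
organised as an analysis: the numbered scripts under `analysis/` walk the
pipeline stage by stage on simulated data and write their tables under
`results/analysis/`, while every computation lives in the package
namespace where the test suite can reach it.

## Reference tag database

`extract_reference_tags()` scans each transcript for CATG occurrences
with at least 17 nt downstream and records the 21-mer, on the sense
strand and — identically — on the reverse complement. CATG is
palindromic, so an antisense tag's site coincides with a sense-strand
motif; positions are stored 0-based on the sense strand. All usable sites
are indexed, not only the 3′-most one: observed libraries contain tags
from internal sites whenever digestion or bead capture is imperfect, and
the multi-tags-per-gene ratio of real reference databases (about 3 tags
per gene with sites) is only explicable if every site counts. The sense
3′-most tag is flagged for diagnostics and for the simulator. Sites whose
21-mer contains N are skipped rather than wildcard-expanded: an N-bearing
tag cannot be matched under a 1-mismatch budget without inflating
ambiguity.

Whether antisense tag hits should contribute to a gene's expression level
is not settled; `map_tags()` tabulates them separately and excludes them
from gene totals by default (`include_antisense = TRUE` reverses this).

## Tag mapping

Observed clean tags are assigned by best-hit precedence: exact matches
first, and only tags with no exact match are considered at Hamming
distance 1. A tag whose best-tier matches hit two or more distinct genes
is *ambiguous* and its count is discarded entirely — expression rests on
unambiguous clean tags, with no fractional splitting. Because both
observed and reference tags begin with CATG, a distance-1 pair can differ
only within the 17-nt extension; the implementation enumerates that
51-variant neighbourhood and performs exact lookups. The contract is
semantic, not structural: the test suite requires the results to equal an
all-pairs Hamming-distance oracle exactly, so the index could be swapped
for a partitioned lookup without touching any test.

TPM (transcripts per million clean tags) divides a gene's unambiguous tag
count by the *total* clean-tag count of the library — not the mapped
total — and scales by 10^6, following the standard definition for this
assay.

## The Audic–Claverie exact test

For a tag counted $x$ times among $N_1$ clean tags, the conditional
distribution of its count $y$ among $N_2$ tags in a second library (flat
prior on the unknown rate) is

$$p(y \mid x) \;=\; \left(\frac{N_2}{N_1}\right)^{\!y}
\frac{(x+y)!}{x!\,y!\,\bigl(1+\tfrac{N_2}{N_1}\bigr)^{x+y+1}},$$

a negative binomial in $y$ with size $x+1$ and success probability
$N_1/(N_1+N_2)$. The one-sided evidence for enrichment in library 2 is
the upper tail $P(Y \ge y \mid x)$; the evidence for depletion is,
symmetrically, the upper tail of the same family with the libraries
exchanged, $P(X \ge x \mid y)$. The two-sided p-value doubles the smaller
of the two and caps at 1.

Computing each direction under its own orientation is a deliberate
choice: it makes the p-value *exactly* invariant under swapping
$(x, N_1) \leftrightarrow (y, N_2)$, which a doubled lower/upper tail
taken from a single orientation is not (the two orientations' point
masses differ by a factor $N_2/N_1$). The construction coincides with the
doubled-tail conditional binomial test on $x$ given $x+y$.

Numerics: everything is evaluated in log space with `lgamma` — library
sizes in the millions overflow factorials immediately. Each tail keeps
full relative precision on both branches: the complement $1 -
P(\text{lower})$ is used only when the result is at least 0.5, and small
upper tails are summed directly term by term until the terms are
negligible (relative cutoff $10^{-17}$ past the distribution mode). The
test suite checks agreement with naive direct summation to $10^{-10}$
relative over a deep grid, and against the closed-form incomplete-beta
identity $P(Y \ge y \mid x) = I_{r/(1+r)}(y, x+1)$ to $10^{-12}$.

The test has no dispersion parameter: the design it serves is one
library per condition, so biological replication is out of scope, and
calls should be read as "incompatible with equal sampling rates", not as
replicated biology.

## Multiple testing and the two significance tiers

P-values are adjusted by the Benjamini–Hochberg step-up procedure
(`p.adjust(method = "BH")`), controlling the error ratio $Q = V/R$ —
the expected fraction of false positives $V$ among $R$ rejections.
Adjustment is performed within each treatment-vs-control comparison
separately, matching per-comparison DE lists. Two tiers are reported:

* **significant** — FDR ≤ 0.001 and $|\log_2 \text{ratio}| \ge 1$
  (at least a 2-fold TPM change);
* **difference** — not significant, TPM fold ratio strictly between 1
  and 2, with $p \le 0.01$ and FDR ≤ 0.001: reproducible but sub-2-fold
  shifts. The "between 1 and 2" range is read as exclusive at both ends,
  leaving the tiers disjoint.

The counts keep their true zeros for the test itself; only the
$\log_2$ ratio replaces zero TPMs by a floor (default 0.001 TPM) so that
genes absent from one library — novel genes in particular — get a
finite, large-magnitude fold change instead of an infinity.

## Time-course sets and novel genes

`venn_partition()` splits three gene sets into the seven disjoint regions
and asserts, on every call, that the regions are pairwise disjoint and
jointly exhaust the union. Per-direction totals count a gene once per
direction, so a gene upregulated at 12 h and downregulated at 48 h
contributes to both totals — which is why up + down union sizes can
exceed the distinct DE count. `shared_percentage()` rounds half-up (base
R's banker's rounding would turn e.g. 14.45 into 14.4).

A **novel gene** is operationalized as: zero unambiguous tags in the
control and at least `min_count` (default 1) in a treatment library.
This is an expression-based reading — "not expressed before, expressed
now" — and is a package decision, flagged here deliberately: a
transcript-annotation-based reading ("no database hit") would be a
different analysis and is not implemented.

## GO-slim mapping and enrichment

The ontology reader is a minimal OBO subset parser: `[Term]` stanzas with
`id`, `name`, `namespace` and `is_a` only; `part_of` and other
relationship types are ignored, obsolete terms are skipped, and the
`is_a` graph is verified acyclic (Kahn topological sort) before use.
This is sufficient for slim mapping and avoids full OBO semantics.

Slim lifting follows the nearest-slim-ancestor-or-self rule per `is_a`
path, as the classic map2slim tool documents it: a term that is itself in
the slim maps to itself only; otherwise it maps to the union of its
parents' slim images. A slim term on one path therefore shields its own
ancestors along that path, while distinct paths keep their own nearest
slim terms (a diamond with both shoulders in the slim maps to both), and
ties are kept rather than broken arbitrarily.

Enrichment of a slim term with $K$ of $M$ population genes and $k$ of
$n$ study genes is the hypergeometric upper tail $P(X \ge k)$, summed
term by term in log space. No multiple-testing adjustment is applied by
default (the upstream convention reports raw hypergeometric p); an
optional flag appends a BH column. The population defaults to all genes
with at least one slim mapping; all reference genes is the documented
alternative, and neither is asserted as canonical.

## The forward simulator

The simulator defines the study conditions the tests run under:

* **Transcriptome** — `n_genes` sequences with geometric-like lengths
  (minimum 60 nt), heavy-tailed like real unigene length distributions;
  defaults of 789 nt mean length match the motivating assembly. The
  background is i.i.d. uniform A/C/G/T *scrubbed* of incidental CATG
  motifs, with CATG injected at a Poisson rate of `catg_density` sites
  per kb (default 10/kb, chosen so that ~93% of transcripts carry at
  least one site, near the 81% seen in the real reference; a uniform
  background alone would give ~3.9 sites/kb). Because CATG cannot
  overlap itself and injection cannot create new motifs at overlapping
  offsets, the realized motif count is exactly the injected count —
  `catg_density = 0` yields motif-free sequences by construction.
* **Truth** — each gene is designated up, down, novel or null
  (defaults 10% / 5% / 1% / rest, near the motivating study's ~9% DE
  rate); affected genes are active in a uniformly drawn non-empty subset
  of the three treatments, which is what produces realistic Venn overlap
  structure. Fold changes are $2^u$, $u \sim U(1, 3)$ (reciprocal for
  down), so every designated effect is at least 2-fold. Baseline
  abundances are log-normal (meanlog 0, sdlog 1). Novel genes have
  baseline 0 and switch on at a log-normal abundance in their active
  treatments.
* **Libraries** — exactly `depth` tags are drawn multinomially with
  weights baseline × fold change; each tag is its gene's 3′-most usable
  tag (a site closer than 17 nt to the 3′ end falls back to the next one
  upstream; an optional `partial_digestion` probability exposes fallback
  to internal sites and defaults to 0). Substitution errors are applied
  per base, uniformly over the 21 positions and 3 alternative bases
  (default rate 0.001, the dominant Illumina error mode at this read
  length; no indels, no quality scores). Reads whose CATG anchor is
  corrupted no longer satisfy the clean-tag definition and are removed,
  mirroring the upstream dirty-tag filter; `library_size` is the
  remaining clean-tag count and the emitted total is preserved as
  `n_emitted = library_size + n_dirty`.
* **Seeds** — every stochastic step takes one integer seed and restores
  the RNG state afterwards; identical inputs give byte-identical outputs.

What the simulator does *not* emulate — and what passing tests therefore
do not show about real data: PCR duplication, adaptor artefacts,
quality-score-correlated errors, indels, partial 3′-bias beyond the
single-site capture rule, expression correlation between genes, and
biological replication. Mapped fractions on simulated libraries run near
99% because the reference is complete and error rates are low; the ~70%
mapped fraction of real libraries reflects incomplete assemblies,
polymorphism and higher error — a gap in realism, not a bug.

## Problem sizes and numerical choices

The analysis scripts use 2,000 genes at 500,000 tags per library — a
deliberate desk-scale stand-in for the 4.5–5 million-tag libraries of the
motivating study, keeping a full run around half a minute. The test
suite's calibration checks use 2,000 null genes in two 100,000-tag
libraries over 50 replicates (empirical type-I rate ≈ 0.040 at
p ≤ 0.05 — slightly conservative, as doubled-tail exact tests are —
and zero significant calls in all 50 null replicates), and the recovery
check plants 25 four-fold up and 25 four-fold down genes among 500 at
1,000,000 tags. Keeping the DE fraction modest there matters:
multinomial sampling renormalizes composition, so with (say) 20% of a
library's mass inflated 4-fold the *observed* TPM ratio of a true 4-fold
gene is pushed toward 2.5; at the 10% used, observed ratios stay within
±0.2 of the designated effect, and recovered $\log_2$ ratios land within
±0.5 of truth for well over 90% of calls.

Tie-breaks and degenerate inputs: equal TPMs are `not_de` regardless of
p; a mapping tie across genes at the best tier is discarded, never split;
an empty transcriptome, a duplicate gene id, a zero library size, a
malformed tag row, a cyclic ontology and a study set outside its
population are all hard errors naming the offending record.

## Known limitations

One library per condition means no dispersion estimation; the exact test
will call small consistent differences at deep coverage that replicated
designs would absorb into biological variance. Ambiguous-tag discard
biases against recently duplicated gene families sharing 21-mers.
3′-most-site capture means alternative 3′ ends of one gene collapse or
split tags in ways the one-sequence-per-unigene reference cannot
represent. The novel-gene definition is sampling-depth dependent: a gene
at 0.5 TPM is "novel" or not depending on whether the control library
happened to sample it.
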