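---
title: "Detecting graft-mobile mRNAs and integrating them with differential omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting graft-mobile mRNAs and integrating them with differential omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftmobile)
library(dplyr)
```

## The problem

When a cucumber scion (*Cucumis sativus*, `Csa`) is grafted onto a pumpkin
rootstock (*Cucurbita moschata*, `Cmo`) — or the reverse — some mRNAs cross
the graft junction through the phloem and accumulate in the other species'
tissue. Because the two species diverged millions of years ago, homologous
transcripts differ at many substitution sites, so a short read sequenced
from a graft tissue can be assigned to its species of origin by the alleles
it carries at those sites. A read with pumpkin alleles found in cucumber
tissue of a heterograft is evidence of transport.

`graftmobile` implements the full computational chain around this idea for a
two-species, four-graft (`Csa/Csa`, `Csa/Cmo`, `Cmo/Csa`, `Cmo/Cmo`),
two-tissue (first leaf of the scion, root of the rootstock), two-condition
(control vs 6-h chilling at 4 °C), three-replicate design:

1. **Origin assignment and mobility calling** from per-sample reads,
2. **Direction and chilling-response classification** of mobile transcripts,
3. the **Δ2 − Δ1 difference-of-differences statistic** for differentially
   expressed genes (DEGs) and differentially intense metabolites (DIMs),
4. **metabolite fold-change filtering, clustering and PCA**, and
5. **integration** of mobile mRNAs, DEGs and DIMs into correlation and
   pathway networks.

A synthetic-data generator with planted ground truth supplies every input,
so the pipeline is testable end to end without any sequencing archive.

## Origin assignment

For each homolog pair the *diagnostic sites* are the aligned positions where
the two species carry different bases (`find_diagnostic_sites()`; pairs are
generated without indels, so position *i* faces position *i*). A read is
located by scanning both homologs for a window within `max_mismatch`
(default 1) mismatches — implemented with a pigeonhole seed index: a read
with at most *m* mismatches must match one of *m + 1* disjoint seeds
exactly, so exact seed lookup yields a complete candidate set that is then
verified by full-length mismatch counting. Ties are broken deterministically
by (mismatches, pair, offset).

The verdict per read:

* **origin A / origin B** — all covered diagnostic sites carry one species'
  alleles;
* **ambiguous** — covered sites conflict (excluded from all counts, never
  split fractionally);
* **uninformative** — the read covers no diagnostic site;
* **unmapped** — no window fits within tolerance.

A covered site whose read base matches *neither* allele is treated as a
sequencing-error observation and dropped from the vote; unanimity is
required over the remaining covered sites. The strictly literal alternative
(any neither-allele site makes the read ambiguous) would discard every read
with an error at a diagnostic site and buys no specificity, since such a
read still carries unanimous evidence at its other sites.

## Mobility calling

`call_mobile_transcripts()` calls a transcript mobile into a heterograft
tissue when:

1. at least `min_reads` (default 5) foreign-origin reads are found summed
   over replicates,
2. it is detected in at least `min_replicates` (default 2) replicates, and
3. the matched homograft background does not exceed `max_background`.

The background is the count of reads in the destination tissue's own-species
homograft (same tissue, same condition) that are nevertheless assigned to
the foreign species. A true mapping artifact is systematic: it produces
background on the scale of the resident sequencing depth (tens of reads at
depth 20 × 3 replicates). A sequencing error, by contrast, can forge at most
the occasional single foreign read — a read whose only covered diagnostic
site is flipped to the foreign allele is indistinguishable from a genuinely
mobile read, and at typical settings (depth 20, 3 replicates, error rate
0.005, ~1.5 diagnostic sites per 150-bp window at 1% divergence) the
expected number of such reads per transcript and destination is about 0.03,
while two or more would be a ~5 × 10⁻⁴ event. `max_background = 1` therefore
separates the two failure modes cleanly: it tolerates the single stray
error-flip that a zero-tolerance veto would let destroy a genuine mobility
call, while still vetoing anything systematic (a background of 3 reads, for
example, is always vetoed). Set `max_background = 0` to restore the strict
screen when reads are error-free.

## Direction and chilling-response classes

Direction is defined relative to the transcript's origin species and is one
record per transcript per condition, aggregated over destination tissues:
found only where the origin species is the scion → `scion_to_rootstock`;
only where it is the rootstock → `rootstock_to_scion`; both reciprocal
grafts → `bidirectional`. Comparing the two conditions over the union of
mobile transcripts yields four mutually exclusive categories:
`chilling_induced`, `chilling_reduced`, `direction_changed`,
`direction_maintained`.

`summarize_directions()` reports percentages rounded half-up to one decimal,
the convention under which 3324 of 3500 prints as 95.0, 40 of 3500 as 1.1,
136 of 3500 as 3.9, 95 of 247 as 38.5 and 4 of 247 as 1.6. (148 of 247 is
59.92 and prints as 59.9 under this rule; no half-up rule produces 60.0, so
that single published figure is not reproducible by rounding alone.)

## The Δ2 − Δ1 statistic

For a feature in one tissue, with the heterograft in which the feature's
species occupies that tissue and the matching homograft:

* Δ1 = log2(het + c) − log2(homo + c) under control,
* Δ2 = the same contrast under chilling,
* statistic = Δ2 − Δ1; calls are `up` above +2 and `down` below −2.

Replicates are aggregated by the arithmetic mean before the log (median
available via `aggregate`). The pseudocount `c` (default 1) guards zeros.
Two readings of "fold difference" circulate — a ratio and a subtraction —
and computing the subtraction in log2 space makes them the same thing: the
±2 cutoff is then a 4-fold change in the ratio of ratios. A raw-space mode
(`log_space = FALSE`) is provided for sensitivity checks only; its threshold
applies to raw abundance differences and is not comparable. The rule is a
pure threshold by construction; no p-value layer is added, because adding
one would change the method rather than implement it. DEG and DIM calling
share this single code path (`call_degs()`, `call_dims()`).

## Metabolite filtering, clustering, PCA

`select_cluster_set()` computes, per metabolite and per graft × tissue, the
chilling/control intensity ratio `R` and `Z = log2(R)`. The default
retention rule is the literal one — `Zmin > 2` or `Zmax < −2`, i.e. *every*
contrast at least 4-fold in the same direction — which is unusually strict;
the likely-intended variant (`Zmax > 2` or `Zmin < −2`, *any* contrast
4-fold) is available as `rule = "lenient"`. Metabolites whose control
aggregate is zero with pseudocount 0 have an undefined ratio and are
excluded with a message, and contaminated sample groups can be removed with
an explicit `exclude` list rather than silently dropped.

Min–max normalization is the textbook `(x − min)/(max − min)`, with a hard
error on constant vectors. Clustering (`cluster_metabolites()`, default
k = 8) is agglomerative with Euclidean distance and average linkage — the
convention is fixed here for reproducibility because heat-map web tools do
not document theirs. `pca_summary()` is column-centred, unscaled PCA with a
fixed sign convention (each component oriented so its largest-magnitude
loading is positive) so that scores and loadings are reproducible run to
run; it reports explained-variance fractions and the top-k positive and
negative loadings per component.

## Integration

* **Orthology**: every cross-species pair is scored by global alignment
  (match +1, mismatch −1, gap −2 via `Biostrings::pairwiseAlignment`); the
  best B hit per A sequence is kept, then duplicates are resolved to the
  highest-scoring pair per B id (ties to the lexicographically smallest A
  id), yielding a one-to-one map. BLAST-style local search would add
  heuristics without adding information at this scale.
* **Correlation**: each feature's profile is its heterograft-vs-homograft
  log2 fold change per (combination, tissue, condition) contrast
  (`log2fc_profiles()`). A species' genes contribute the four contrasts of
  the tissues that species occupies; metabolites contribute all eight; the
  Pearson correlation runs over the shared keys (≥ `min_points`, default 4),
  and edges are kept at |cor| ≥ 0.95. With only four shared points the null
  rate of |cor| ≥ 0.95 is a few percent, so these edges are a screen, not an
  inference; a replicate-level correlation mode was considered and rejected
  because replicate pairing across omics platforms is arbitrary.
* **Enrichment**: hypergeometric upper tail per pathway with
  Benjamini–Hochberg adjustment — the standard over-representation test,
  fixed here because no test is otherwise specified.
* **Network**: `build_network()` emits `mobile–deg` edges (mobile
  transcript's ortholog is a DEG and shares ≥1 pathway id) and `deg–dim`
  edges (correlation edges whose endpoints are called DEG/DIM), exported as
  SIF and TSV.

## The synthetic-data generator

The generator emulates the study conditions: homolog pairs at a configurable
substitution rate (default 1% over 1000-b transcripts, ~10 diagnostic sites
per pair, with at least one substitution forced because real cross-species
homologs are never identical); 150-b forward-strand reads at Poisson depth
(default mean 20) with independent per-base substitution errors; the full
4 × 2 × 2 × 3 sample design; lognormal baselines with multiplicative
lognormal replicate noise (`noise_sd`, log2 units) for FPKM and ion
intensities — both are positive, right-skewed measures; and planted truth
for mobile transcripts (`mobility_plan`, reads per replicate), Δ2 − Δ1
effects, transcript–metabolite correlations (a metabolite's fold-change
profile mirrors ±1 × a gene's profile) and pathway enrichment. Effects are
planted in pseudocount-adjusted log2 space, so noiseless tables round-trip
exactly through the statistic.

What it deliberately does **not** model: indels and paralogy (the origin
assigner is alignment-free by design), isoforms, 3′ coverage or library-prep
bias, strandedness, pooling variance within a replicate (each replicate is
one unit, though the real experiment pools ~10 seedlings), or
platform-specific metabolomics artifacts. Passing tests therefore
demonstrate correctness of the computational chain under this generative
model, not performance on archived sequencing data, where alignment,
multi-mapping and annotation error dominate.

## Numerical and scale choices

Coordinates are 0-based half-open internally. Percentages round half-up to
one decimal. All generator randomness flows from a single integer seed
(identical config + seed ⇒ byte-identical artifacts). The test suite and the
acceptance script run the read-level pipeline at 30 homolog pairs × 1000 b ×
depth 20 (about 29 000 reads per run) with 8 planted mobile transcripts at
30 reads per replicate, and the tabular pipeline at 500 genes / 300
metabolites — sizes chosen so every planted signal is recoverable with
wide statistical margin while a full run stays interactive on a laptop.

## Known limitations

* The origin assigner requires equal-length, indel-free homolog pairs; real
  references need an upstream alignment step it does not provide.
* `min_reads`, `min_replicates` and `max_background` are explicit
  configuration, not estimates of any published pipeline's internal values,
  which are not printed anywhere.
* Four-point correlation profiles make |cor| ≥ 0.95 a weak filter (see
  above); treat `deg–dim` edges as candidates.
* The literal `Zmin/Zmax` retention rule passes only metabolites responding
  ≥4-fold in every graft; use `rule = "lenient"` when that is too strict for
  a data set.
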