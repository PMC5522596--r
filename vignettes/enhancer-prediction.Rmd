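---
title: "Predicting intergenic enhancers from chromatin accessibility, H3K9ac and DNA methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting intergenic enhancers from chromatin accessibility, H3K9ac and DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhscan)
```

## The model

Active plant enhancers are expected to coincide with three chromatin
signals: accessible chromatin (DNase I hypersensitive sites, DHSs),
enrichment of histone H3 lysine-9 acetylation (H3K9ac), and low DNA
methylation in the CG and CHG sequence contexts. `enhscan` implements a
three-step integration over two contrasted tissues (here labelled
V2-IST, the inner stem of a V2-stage maize seedling, and husk, the soft
inner husk leaf):

1. **Consensus peaks.** Per-replicate DHS and H3K9ac peak calls are
   collapsed with a reciprocal overlap rule: a pair of peaks is retained
   only when the overlap covers at least 70% of *both* peak lengths
   (`consensus_peaks()`). With three replicates, the first two are
   integrated and the result is chained against the third. The retained
   interval is the union of the passing pair — a conservative choice,
   since candidate integration downstream only asks for one-basepair
   overlaps.
2. **Low and unmethylated regions (LUMRs).** Per-cytosine methylation
   frequencies are segmented independently in the CG and CHG contexts
   into maximal runs of covered sites below 20% methylation
   (`segment_low_methylation()`), the two context-wise sets are
   intersected (`combine_lumr()`), and any region whose mean methylation
   over 100-bp fixed windows reaches 20% is removed
   (`filter_mean_methylation()`). CHH methylation is not used for
   prediction (it is globally low, about 2% in maize) but is carried
   through for profiling.
3. **Candidates.** A LUMR becomes an enhancer candidate in a tissue when
   it overlaps at least one consensus DHS *and* one consensus H3K9ac
   region of that tissue while touching no exonic, intronic or promoter
   base (`integrate_candidates()`). Candidate coordinates are the LUMR
   coordinates. A candidate found in exactly one tissue is
   tissue-specific; one found in both is shared, and the identity
   `union = specific_1 + specific_2 + shared` holds exactly because the
   LUMR substrate is tissue-independent.

Candidates are then ranked by tissue contrast: for each candidate the
largest per-basepair signed difference between the two tissues' signal
tracks is computed separately for DNase and H3K9ac, the two descending
ranks are summed, and candidates are re-ranked on the sum
(`rank_candidates()`). Candidate ids combine the tissue initial with the
final rank (V2, H1233, ...). A permutation null — position-wise sums of
independent uniform permutations of 1..N, re-sorted — provides a p-value
per rank position (`rank_permutation_p()`).

## Genome partition

`partition_genome()` assigns every base to exactly one class: exon
(annotated exons including UTRs), intron (genic minus exon — intronic TE
bases count as intron), promoter (1 kb upstream to 200 bp downstream of
the TSS, strand-aware, minus genic bases), flanking (4 kb upstream of
the promoter and 5 kb downstream of the TTS), TE (remaining intergenic
TE bases) and distal. Where definitions overlap, precedence is
exon > intron > promoter > flanking > TE > distal; the gene-proximal
classes win so that "TE" means intergenic TE space away from regulatory
flanks. Features are counted per class at their midpoint
(`classify_features()`): the published distributions count each region
once but do not say how straddlers are resolved, so the midpoint rule is
this package's choice.

## Orientation, profiles and categories

H3K9ac is often enriched on only one side of a DHS. `orient_dhs()`
computes mean H3K9ac over the 300-bp flanks on either side and defines
the higher side as the 3' end (rows needing a flip are marked; exact
ties keep their orientation and are flagged). A DHS is *eligible* when
its higher flank reaches 0.5 RPM and *asymmetric* when the high/low
ratio is at least 2. The flank statistic is a mean over the 300-bp
window rather than a point value 300 bp away: on stepwise tracks a point
estimate is fragile, a window mean is not. Flank means do not exclude
bases inside neighbouring DHSs.

`build_profile_matrix()` produces heatmap input: 20-bp fixed bins over
±1-kb flanks and 50 equal-occupancy bins over the scaled feature body
(defaults chosen here; features shorter than the bin count are linearly
interpolated per basepair). `kmeans_categories()` clusters the H3K9ac
rows with k-means (k = 4, seeded, k-means++-like multi-start via
`nstart`), then relabels clusters by descending mean enrichment so that
category 1 is the strongest — a deterministic proxy for the published
"top to bottom" heatmap order, which is display-dependent. The same row
order and labels are reused for the companion matrices (DNase,
methylation contexts, TE presence, transcripts). TSS-side profiling
(k = 3, oriented by gene strand, seeded random DHS sampling) reuses the
same operations with different arguments.

`expression_bins()` reproduces the expression-binned metaprofiles: bin 0
holds genes under 1 RPKM; the remaining genes split into six equal-count
bins by ascending RPKM; `gene_metaprofile()` averages scaled gene-body
profiles per bin.

## Target linking

Enhancers are assumed to regulate their nearest flanking gene on either
side (`nearest_flanking()`, by genomic coordinate, gene strand ignored).
For a tissue-specific candidate, a flanking gene is linked when it is
significantly differentially expressed with the higher expression in the
candidate's tissue; for a shared candidate, when it is expressed in both
tissues. The expression floor for "expressed" is 1 RPKM — the only floor
the source data define (the boundary of expression bin 0); this is an
operationalisation, not a published constant. Candidates fall into
`one_gene`, `both_genes` or `unlinked` categories that partition each
specificity class.

## TE and motif statistics

The TE family test asks whether enhancer-containing TEs concentrate in
particular families. The baseline is the TE annotation after resolving
nested insertions (inner elements fully contained in another TE are
excluded; the outermost span is kept — the published analysis cites a
tool without stating its rule, so this transparent rule is documented
as ours), dropping TEs inside introns, and requiring length > 635 bp so
that a short candidate can still be 80% contained. A candidate is a
"TE-enhancer" when at least 80% of its length lies within a single TE
(`te_containment()`). With K enhancer-containing TEs among M baseline
elements, a family with `M_f` members and `k_f` containing members gets
`p = P(Binomial(K, M_f/M) >= k_f)`, Bonferroni-corrected over families
with `k_f >= 1` (`family_enrichment()`).

`motif_scan()` counts exact occurrences of the site II motif GGCCCA and
its reverse complement TGGGCC (overlapping matches included);
`motif_enrichment()` compares the fraction of candidates containing the
motif with length-matched random intergenic windows.
`permutation_enrichment()` places length-preserved features uniformly at
random within the uniquely mappable mask (non-overlapping, by rejection
with a retry cap — whether shuffled features may overlap is not
specified anywhere authoritative, so non-overlapping placement is this
package's choice) and reports add-one empirical p-values,
`(1 + b)/(n + 1)`, so p is never exactly zero and "no null permutation
reached the observed value" reads as p < 1/n.

### Conservative p-values and calibration

Rank sums and overlap counts are discrete statistics with heavy ties,
so empirical p-values built from "less than or equal" counts are
conservative (super-uniform under the null) — a property of the
estimator, not a bug. Both `rank_permutation_p()` and
`permutation_enrichment()` therefore also expose the Lancaster mid-p
variant (half weight on ties), which is the appropriate quantity when
*calibration* against Uniform(0, 1) is being assessed; the reported
inference p-values remain the conservative ones. The test suite checks
calibration with one mid-p value per independent null dataset, because
p-values within one dataset share the same observed draw and are
strongly dependent.

## The synthetic data generator

`generate_synthetic_data()` emits a complete, truth-annotated input
bundle: two 1-Mb chromosomes with about 200 genes; 60 planted intergenic
enhancers (10 V2-IST-only, 35 husk-only, 15 shared — roughly the
published proportions at desk scale), each combining a methylation
valley (900–1400 bp at 5% mean methylation), a DHS (300–500 bp) and an
H3K9ac region on one side only; background loci carrying only one or two
of the three features (unmethylated-only, DHS-only, H3K9ac-only, and
accessible-but-methylated loci) so that the integration logic is
genuinely exercised; promoter peaks at expressed genes; five TE families
over the LTR/TIR/helitron superfamilies with one family wrapped around
eight enhancers (about ten times the baseline rate); an expression table
whose differential-expression flags match the planted tissue patterns;
a mappability mask with excluded blocks; and GGCCCA planted in 60% of
enhancer DHSs.

Numeric choices and what they emulate:

* Methylation background is Beta-distributed around means 0.86 (CG),
  0.74 (CHG) and 0.02 (CHH) — the genome-wide averages of the system
  being emulated — with planted valleys at mean 0.05 and a small CHH
  bump at valley 5' edges (mCHH marks boundaries between lowly and
  highly methylated space). The Beta concentration (60) was set by a
  design calculation, not tuning: at mean 0.05 the probability that a
  single valley site crosses the 20% segmentation threshold is
  negligible, so sampling noise does not fragment planted valleys.
* Replicate peaks get uniform ±30-bp boundary jitter. Planted peak
  widths (DHS ≥ 300 bp) were likewise chosen by a prior Monte Carlo of
  the reciprocal-70% rule under this jitter: pass probability per peak
  is ≥ 0.999 at 300 bp, versus ≈ 0.91–0.96 at 200 bp.
* Dropout (rate 0.05) models a replicate-specific peak-calling miss: per
  planted locus and tissue, with probability 0.05 the peak of one
  randomly chosen assay disappears from one randomly chosen replicate.
  Because the consensus rule requires every replicate, each dropout
  event removes that locus from that tissue's candidate set, giving an
  expected recall of about 0.95 for tissue-specific enhancers and
  > 0.99 for shared ones. (Applying 5% dropout independently to every
  replicate of every assay would drive expected recall to about 0.81,
  inconsistent with the intended operating point of the noise model.)
* The one-sided H3K9ac plateau straddles one DHS boundary by 50 bp so
  that it always intersects the LUMR regardless of methylation-site
  spacing, and the opposite side carries the same plateau at 1/fold of
  the height (default fold 4), so the orientation flank means have an
  exact, known ratio.
* The motif is planted in 60% of enhancers: with candidate lengths
  around 1 kb, random sequence alone gives a ~35–40% background hit
  rate, so the planted fraction reproduces the observed roughly twofold
  enrichment regime rather than an unrealistically clean signal.

What the generator does **not** emulate: read-level noise (inputs are
already-processed peak calls and tracks), realistic repeat landscapes
and copy-number structure, chromatin-state autocorrelation along the
genome, partial methylation gradients at region boundaries, or
enhancer–promoter interactions beyond nearest-flanking-gene regulation.
Passing the planted-truth tests therefore demonstrates that the
integration, ranking, linking and enrichment logic is correct under the
stated model — not that the thresholds would be optimal on real
sequencing data.

## Degenerate inputs, ties and numeric conventions

* All coordinates are 0-based half-open internally (BED convention);
  GFF3 is converted on read. Interval algebra is strand-blind.
* A boundary case in the source description is contradictory: regions
  are "20% or lower" methylated yet "more than or equal to 20%" is
  filtered out. Segmentation uses strict `< 0.20` per site; the windowed
  mean filter drops `>= 0.20`; regions scoring within 0.02 of the
  ceiling are flagged in the output.
* Rank ties break deterministically by DNase rank, then chromosome,
  then start. k-means clusters are relabelled by descending mean.
  Orientation ties keep and are flagged.
* Percentages round half-away-from-zero (`percent()`): banker's rounding
  would fail to reproduce printed values such as 22% from 38/175.
* Genes without annotated exons are treated as single-exon with a
  warning; regions with no covered methylation site survive the mean
  filter (they cannot be contradicted) with a warning; empty replicate
  peak sets yield an empty consensus with a warning.
* The permutation p-value construction for rank sums is ambiguous in its
  source between per-rank-position and per-candidate nulls; this package
  implements and documents the per-rank-position reading as the only
  mode, and the "largest difference" is the per-basepair maximum on the
  step track rather than a windowed mean.
* The union row of the region-overlap table counts merged regions, which
  is why it can be smaller than the sum of the tissue rows.

## Problem sizes

The bundled synthetic study runs at two 1-Mb chromosomes, ~200 genes,
60 planted enhancers, 1000 permutations for p-values (tests scale this
down to 50–200 where the p-values themselves are not under test), and
calibration experiments of 250–300 independent datasets. A full
noise-free pipeline run completes in well under a minute on one CPU.

## Limitations

Two tissues only (the specificity logic is binary by design); no
chromatin-interaction data for target assignment, so linking is strictly
nearest-flanking-gene and repressive regulation is out of scope; motif
analysis is exact-match (no PWM scanning or de-novo discovery);
mappability masks, peak calls, methylation calls and differential
expression flags are inputs, not computed; and the ranking's two feature
contrasts are known not to correlate well with each other, so ranks
order candidates for follow-up rather than measure activity.
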