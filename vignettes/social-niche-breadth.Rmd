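---
title: "Social niche breadth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Social niche breadth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snb)
```

## The idea

Niche breadth — the range of conditions under which an organism can live —
is hard to quantify for microbes because it requires an objective
definition of "the environment". This package takes the community a
microorganism lives in as that definition: its *social* niche. The social
niche breadth (SNB) of a taxon is the mean pairwise compositional
dissimilarity of the samples in which it is detected,

$$\mathrm{SNB} = \frac{\sum_{i=1}^{n}\sum_{j=1}^{n} d_{ij},\; i \neq j}{n^2 - n},$$

where $n$ is the number of samples carrying the taxon and $d_{ij}$ a
pairwise community dissimilarity. A taxon found only in compositionally
similar communities is a *social specialist* (low SNB); a taxon found in
dissimilar communities is a *social generalist* (high SNB). Because the
matrix is symmetric the ordered-pair mean above equals the mean over
unordered pairs, which is what `snb_score()` computes.

The default dissimilarity — Spearman's rank correlation of taxon
abundances at the rank order, converted by $0.5 - \rho/2$, with strict
unknown handling — is the configuration used for all downstream analyses;
every other choice (ten measures, seven ranks, three unknown-handling
approaches) remains available through `dissim_config()`.

## From raw profiles to a dissimilarity matrix

**Cleaning and selection.** Profiles are read from a lineage-by-sample TSV
(`read_profiles()`). `clean_profiles()` removes eukaryotic, mitochondrial,
chloroplast and superkingdom-unclassified entries and recomputes the total
prokaryotic read count, the denominator of all relative abundances.
`select_samples()` keeps samples with at least 50,000 reads annotated at
superkingdom and strictly less than 10% eukaryotic reads, then caps each
annotated biome at 1,000 samples by seeded uniform subsampling (sample ids
are sorted before drawing, so the selection does not depend on input
order).

**Rank projection and unknowns.** `project_to_rank()` aggregates a profile
to one rank under three approaches: (1) fall back to the first classified
rank below, else above; (2) strict — only taxa classified at the rank; (3)
as (1), but from-above fallbacks are removed pairwise when present in both
samples of a comparison, because for those taxa it is unknown whether they
are the same at the rank of interest. Fallback keys carry `from-below:` /
`from-above:` prefixes so they can never collide with genuine rank keys.
Taxa with fewer than 5 reads at the rank are removed *after* aggregation
and *per rank*, so a sample's included read total may differ between
ranks; an absolute read floor (not a relative one) keeps the deepest
attainable resolution.

**Measures.** Pairs are aligned over the union of their taxa
(`align_pair()`); taxa present in only one sample get abundance zero in
the other, except for the Aitchison distance, which cannot handle zeros.
There, pseudocounts in read units are added to every union taxon: one read
in the sample with the larger read sum ($N_1$) and $N_2/N_1$ reads in the
other — the smallest relative abundance an undetected taxon could have
had. Counts are then closed, CLR-transformed per sample, and the Euclidean
distance taken. The three correlation measures (Pearson, Spearman,
tie-corrected Kendall $\tau_b$) are mapped to $[0,1]$ by
$0.5 - \mathrm{coefficient}/2$; Bray–Curtis, Jaccard and Sørensen–Dice
follow their usual forms. The abundance-weighted Jaccard is the Ružička
dissimilarity $1 - \sum_i \min(x_i,y_i) / \sum_i \max(x_i,y_i)$ — a
documented design choice, since several weighted variants circulate. The
correlation measures act on relative abundances; rank-based measures are
insensitive to this, Pearson is not, which is flagged here rather than
asserted as the only defensible reading.

**UniFrac.** Both UniFrac variants are earth-mover distances over the rank
taxonomy with unit branch lengths (`emd_unifrac()`). Taxa unclassified at
the target rank but classified below are placed at an artificial node at
the target depth derived from their first classified rank below (unique
per classification, at the right distance from the root); taxa with
nothing at or below the rank sit at their first classified rank above. On
a tree the EMD has an exact form — the summed absolute subtree mass
difference over all edges — which is what is computed; the tests verify it
against an enumerative minimum-cost-flow oracle. The result is normalized
by the tree diameter at the rank ($2\times$ depth), a pair-independent
bound: a per-pair bound was rejected because it saturates every
single-taxon pair at 1 and destroys monotonicity in tree distance.

**Degenerate cases.** Samples with no taxon at a rank are removed there.
For correlation measures, samples whose rank profile is constant
(including single-taxon samples) are removed at matrix construction —
their self-correlation is undefined — and recorded in the
`removed_samples` attribute. Pairs whose taxon union holds a single taxon
are set to dissimilarity 0 regardless of abundances. Residual degenerate
pairs (possible only after approach-3 key removal) fall back to 0 for
identical vectors and to the chance level 0.5 otherwise, with a warning.
All values are clamped to $[0,1]$ at a $10^{-12}$ floating-point
tolerance.

## Presence, scores and null models

A taxon is present in a sample when its relative abundance — reads
including all subtaxa over total prokaryotic reads — is at least
$10^{-4}$; the threshold is inclusive, and taxa present in fewer than 5
usable samples are not scored. `snb_table()` scores taxa at every rank of
their lineage independently and annotates local dominance (mean relative
abundance over the taxon's samples), the normalized Shannon entropy of its
abundances across those samples (renormalized to sum 1, divided by
$\ln N$; undefined at $N=1$), and the number of annotated biomes.

Because high-ranking taxa intrinsically occur in more samples, raw SNB is
only comparable within a rank. `modified_z()` therefore standardizes per
rank: $(\mathrm{SNB} - \mathrm{median}) / (1.4826 \times \mathrm{MAD})$,
the constant making robust scores comparable to standard-deviation
z-scores. A rank with zero MAD yields an `NA` sentinel — reporting 0 would
wrongly claim median-typicality.

`isnb()` provides the imaginary-taxon reference distributions: SNB of
taxa planted in random sample subsets of a given size, in whole biomes, in
biome halves, or in biome pairs. Permutations draw uniformly without
replacement; per-permutation seeds derive from the master seed by counter,
so distributions are reproducible and independent of evaluation order.

## Diversity and PERMANOVA

Hill numbers of order $q \in \{0,1,2\}$ (richness, exponential Shannon,
inverse Simpson) are computed per sample on strict rank-order projections
thresholded at $10^{-4}$. Alpha diversity of a sample set is by default
the arithmetic mean of per-sample effective numbers — consistent with the
order-0 definition as the mean number of taxa — with the alternative
(effective number of the mean entropy) behind `method =
"effective_mean"`, since the convention for $q \geq 1$ is genuinely open.
Gamma diversity pools the per-sample relative abundance vectors with equal
sample weights; beta is $\gamma/\alpha$. Group-wise summaries exclude
groups of fewer than 3 samples. The taxon-level entropy vector is
renormalized before the Shannon computation so the statistic is
scale-free — also an open convention, decided here for scale invariance.

`permanova()` partitions squared dissimilarities in the usual one-way
design, reports the pseudo-$F$, a permutation p-value with the $+1$
correction (avoiding $p = 0$ and matching reference implementations), and
$R^2 = F / (F + (N-G)/(G-1))$, with $R^2 = 1$ in the infinite-$F$ limit of
perfectly separated groups.

## Genomes, pan-genomes, GSEA

Genome records pass the quality rule
$\mathrm{completeness} - 5 \times \mathrm{contamination} \geq 70$
(boundary inclusive) and are size-corrected by
$s = 100/(\mathrm{completeness} + \mathrm{contamination})$. A function
belongs to a species when at least 50% of its genomes contain it
(inclusive, so 1 of 2 counts); genomes with $\leq 20$ unique functions are
discarded for subsystem names, gene ontologies and pathways but not for
subsystem subclasses. Aggregation to higher ranks is either plain (mean
and sd over all daughter species) or taxonomy-corrected (recursive mean
over immediate daughters), the latter removing the skew from species-rich
subclades. Pan-genome openness is the pan-genome size over the mean
per-species functional size; under the majority rule a species' functional
genome *is* its pan-genome at the function level, so the two circulating
definitions of the denominator coincide. The 3-species permuted variant
(1,000 seeded subsets, `NA` below 3 species) corrects for the tendency of
species-rich taxa to accumulate functions. Genus growth rates average
species means rather than pooling genomes — consistent with the size
aggregation — with the pooled variant exposed.

GSEA uses the classical Kolmogorov–Smirnov running sum ($p = 0$: equal hit
increments), with an explicit tie rule (positive extreme wins on equal
magnitude) applied identically in the implementation, the null generator
and the test oracles. Significance comes from gene-set (member)
permutations: NES divides ES by the mean same-signed null, p-values use
the same-signed tail with the $+1$ correction, and the FDR compares pooled
normalized nulls against observed scores per sign with a monotonicity
cleanup, per functional universe (matching the one-universe-per-table
reporting convention). Ranked lists break score ties lexicographically by
genus id so results are deterministic. Sets smaller than 3 genera or
spanning the whole universe are skipped as degenerate.

## Association analyses

`within_sample_correlation()` and `within_family_correlation()` compute
one Spearman correlation per unit between SNB and a feature, with a floor
of 5 genera per unit (stated for families, applied to samples for
symmetry; configurable). `alpha_binned_regression()` fits one OLS line of
mean genome size on SNB per sample and summarizes slopes by
alpha-diversity bin (mean and IQR) — the computation behind the two
contrasting strategies: in low-diversity habitats
($\alpha \leq 11$, inclusive) genome size rises with niche breadth, in
high-diversity habitats it falls. `strategy_split()` implements the three
stratifications with their exact boundaries: specialists are strictly
below SNB 0.35; the diversity split is inclusive at 11; the within-sample
split takes the bottom/top quartile. `coding_density_test()` is a
one-tailed two-sample t-test (specialists lower); Welch's unequal-variance
form is the default as the safer choice where only "t-test" is specified,
with Student's form behind `var_equal = TRUE`.

## The synthetic generator

`generate_collection()` draws a Dirichlet-multinomial world: each biome
has a centroid over its taxa (background weights from a gamma draw with
shape `biome_centroid_concentration`, planted taxa at fixed weight
`planted_weight`), each sample a Dirichlet draw around its centroid at
precision `within_biome_concentration`, and reads a multinomial of depth
`reads_per_sample`. Specialists receive centroid mass in one biome,
generalists in all; a configurable fraction of background lineages is
truncated at a random rank to emulate the unclassified taxa that motivate
the unknown-handling approaches. Planted taxa stay fully classified so
their scores are defined at every rank.

The defaults — 4 biomes × 30 samples, 30 background taxa per biome, 8
specialists and 8 generalists at centroid weight 0.02, precision 50,
$10^5$ reads, 20% truncation — were fixed up front as a plausible
desk-scale miniature of a many-biome survey: planted taxa sit two orders
of magnitude above the $10^{-4}$ detection limit in their home biomes, and
biome centroids are distinct enough that biome identity dominates
community composition. `generate_two_regime()` varies richness instead (5
background taxa in two biomes, 60 in the other two, so first-order alpha
diversity falls clearly on either side of the 11 split) and assigns genus
genome sizes by role (2 Mb low-diversity specialists, 4 Mb generalists,
8 Mb high-diversity specialists). `generate_genomes()` builds genome
records whose observed sizes are deflated by completeness and inflated by
contamination — so the correction recovers the truth — and function sets
with a genus core plus per-species accessory draws; accessory turnover 0
makes every pan-genome exactly closed, and the generalist turnover default
(0.8 vs 0.2) makes generalist pan-genomes more open by construction.

The generator is a stand-in, not a claim about real data: it does not
reproduce empirical taxon frequency spectra, read-depth variation,
compositional zero-inflation beyond multinomial sampling, or biome
hierarchies. Passing the planted-recovery tests shows the estimator ranks
known-dissimilar occupancy patterns correctly under the stated model, not
that any particular real taxon is a specialist.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on the
120-sample default world (5–20 seeded replicates), 200-pair brute-force
oracle sweeps per measure, and permutation counts of $10^3$–$2\times10^4$
— sizes chosen so a complete run stays a coffee-break affair on one core
while keeping Monte-Carlo error well below the tested margins. Scores are
clamped at $10^{-12}$, the correlation undefined-cases are excluded rather
than imputed, derived seeds stay below $2^{31}$, and every randomized
routine funnels through one seed-restoring helper so library calls never
disturb the caller's RNG stream.

## Known limitations

* Replicate-genome deduplication uses a metadata proxy (species, size,
  function-set hash), not concatenated sequences.
* Clade ages and growth rates are consumed as tables; no inference.
* The full 150-variant measure benchmark harness exists through
  `dissim_config()`, but no published ranking is reproduced here.
* UniFrac branch lengths are the unit-branch taxonomy, not a calibrated
  phylogeny.
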