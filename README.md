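# snb — social niche breadth scores for microbial taxa

Generalist microbes survive in many environments; specialists are
restricted to few. Quantifying that distinction from sequencing surveys
has been hampered by arbitrary habitat labels: whether a taxon looks like
a generalist depends on how the submitter chose to name the biome. This
package sidesteps habitat definitions by treating the *community* a taxon
lives in as its environment. The **social niche breadth (SNB)** of a taxon
is the mean pairwise compositional dissimilarity of the samples in which
it is detected:

```
SNB = Σᵢ Σⱼ d_ij, i ≠ j  /  (n² − n)
```

with `n` the samples carrying the taxon and `d_ij` by default the
Spearman-based dissimilarity `0.5 − ρ/2` of taxon abundances at the rank
order. Low SNB = social specialist (always the same neighbours); high SNB
= social generalist. The package is aimed at microbial ecologists working
with large collections of taxonomic profiles (MGnify-style lineage ×
sample count tables) and genome metadata tables.

It implements the complete supporting workflow:

* profile reading, cleaning, and seeded per-biome subsampling;
* ten ecological dissimilarity measures (Aitchison with paired
  pseudocounts, Bray–Curtis, Sørensen–Dice, Jaccard, Ružička-weighted
  Jaccard, Pearson, Spearman, Kendall τ_b, and earth-mover UniFrac over
  the rank taxonomy, weighted and unweighted) under three
  unknown-handling approaches;
* presence calling at a 10⁻⁴ relative-abundance detection limit, SNB
  scoring, per-rank robust z standardization, and imaginary-taxon (iSNB)
  null models;
* Hill-number alpha/beta/gamma diversity (orders 0–2) and PERMANOVA;
* genome quality filtering and completeness/contamination size
  correction, majority-rule species function sets, plain and
  taxonomy-corrected aggregation, pan-genome size and openness (all
  species and 3-species permuted);
* classical Kolmogorov–Smirnov gene set enrichment over genus pan-genomes
  with gene-set permutation, NES and FDR;
* the association analyses linking SNB to dominance, growth rate, genome
  size and coding density, including the alpha-binned genome-size
  regressions and strategy splits;
* a fully seeded synthetic-data generator with planted specialists and
  generalists, so every analysis is testable without downloads.

## Worked example

Generate the default synthetic world (4 biomes × 30 samples, 8 planted
specialists, 8 planted generalists), score every order-rank taxon, and
summarize community structure:

```r
library(snb)

sim <- generate_collection(synthetic_config(seed = 1))
x   <- clean_profiles(sim$collection)
D   <- pairwise_matrix(x, dissim_config("spearman", "order", 2, 5))
tab <- snb_table(x, D = D, ranks = "order")

tr <- sim$truth
tab[match(tr$order_key[c(1, 2, 9, 10)], tab$taxon),
    c("name", "n_samples", "snb", "z", "dominance", "entropy")]
#>      name n_samples   snb      z dominance entropy
#>  OrdSpec1        30 0.246  0.360    0.0183   0.894
#>  OrdSpec2        30 0.238  0.116    0.0200   0.847
#>   OrdGen1       119 0.659 12.694    0.0210   0.923
#>   OrdGen2       120 0.659 12.694    0.0184   0.916
```

The planted specialists (confined to one biome of 30 samples) score ~0.24
— they live in mutually similar communities — while the planted
generalists, present in essentially all 120 samples across 4 biomes,
score ~0.66. The modified z column standardizes within the rank, the
dominance column is each taxon's mean relative abundance where present,
and the entropy column shows how evenly that abundance is spread.

```r
hill_diversity(x, q = 1)
#>   q alpha beta gamma n_samples
#> 1 1 15.94 3.97 63.26       120

permanova(D, setNames(x$metadata$biome, x$metadata$sample_id),
          n_perm = 99, seed = 2)
#> <permanova> F = 335.5  R2 = 0.8967  p = 0.01  ( 120 samples, 4 groups, 99 permutations )
```

A sample holds on average ~16 effective orders, the pooled collection ~63,
i.e. ~4 effective distinct communities — and biome identity explains ~90%
of the dissimilarity structure, which is exactly what the generator
planted.

A thin command-line front end is available in
`inst/scripts/snb-cli.R` (`synth`, `dissim`, `score` subcommands). The
methods vignette (`vignettes/social-niche-breadth.Rmd`) documents every
model choice, default and known limitation.

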