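# Builders for small collections used across test files.

make_profile <- function(sid, ...) {
  v <- c(...)
  taxonomic_profile(sid, v)
}

# random rank profiles for the oracle-equivalence sweeps: two samples over
# a partially shared taxon pool, 3-10 taxa each
random_pair <- function(seed, min_taxa = 3, max_taxa = 10) {
  set.seed(seed)
  pool <- sprintf("Bacteria;P;C;O%d", 1:12)
  ta <- sample(pool, sample(min_taxa:max_taxa, 1))
  tb <- sample(pool, sample(min_taxa:max_taxa, 1))
  a <- taxonomic_profile("a",
                         setNames(as.numeric(sample(5:500, length(ta))), ta))
  b <- taxonomic_profile("b",
                         setNames(as.numeric(sample(5:500, length(tb))), tb))
  list(a = a, b = b)
}

# a tiny fully-classified collection from a named list of count vectors
collection_from_counts <- function(counts, lineages, biome = NULL) {
  profiles <- lapply(names(counts), function(sid) {
    v <- counts[[sid]]
    taxonomic_profile(sid, setNames(v[v > 0], lineages[v > 0]))
  })
  md <- data.frame(sample_id = names(counts),
                   biome = if (is.null(biome)) "root:Test" else biome,
                   stringsAsFactors = FALSE)
  profile_collection(profiles, md)
}

fixture_lineages <- sprintf("Bacteria;PhyA;ClsA;Ord%d;Fam%d;Gen%d;Sp%d",
                            1:6, 1:6, 1:6, 1:6)
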