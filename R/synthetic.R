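#' Configuration of the synthetic microbiome generator
#'
#' The generator emulates the statistical structure the niche-breadth
#' analyses rely on: multiple biomes with characteristic community
#' centroids, per-sample Dirichlet-multinomial read sampling, planted
#' specialist taxa (restricted to one biome) and generalist taxa (present
#' in every biome's centroid), hierarchical taxonomy with partially
#' unclassified lineages. Planted taxa are fully classified so their scores
#' are defined at every rank.
#'
#' @param n_biomes number of biomes, default 4.
#' @param samples_per_biome samples per biome, default 30.
#' @param taxa_per_biome background taxa per biome (scalar or vector of
#'   length `n_biomes`), default 30.
#' @param n_specialists planted specialists, assigned to biomes round-robin,
#'   default 8.
#' @param n_generalists planted generalists (in all biomes), default 8.
#' @param biome_centroid_concentration gamma shape for background centroid
#'   weights (scalar or per-biome); small values give uneven communities.
#'   Default 0.5.
#' @param within_biome_concentration Dirichlet precision of samples around
#'   their biome centroid (scalar or per-biome), default 50.
#' @param planted_weight centroid relative abundance of each planted taxon,
#'   default 0.02.
#' @param reads_per_sample multinomial read depth, default 1e5.
#' @param unclassified_fraction fraction of background lineages truncated at
#'   a random rank (emulating unclassified taxa), default 0.2.
#' @param seed master seed, default 1.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_biomes = 4L, samples_per_biome = 30L,
                             taxa_per_biome = 30L, n_specialists = 8L,
                             n_generalists = 8L,
                             biome_centroid_concentration = 0.5,
                             within_biome_concentration = 50,
                             planted_weight = 0.02,
                             reads_per_sample = 1e5,
                             unclassified_fraction = 0.2, seed = 1L) {
  taxa_per_biome <- rep_len(taxa_per_biome, n_biomes)
  biome_centroid_concentration <-
    rep_len(biome_centroid_concentration, n_biomes)
  within_biome_concentration <-
    rep_len(within_biome_concentration, n_biomes)
  stopifnot(n_biomes >= 1, samples_per_biome >= 1, all(taxa_per_biome >= 1),
            n_specialists >= 0, n_generalists >= 0,
            all(biome_centroid_concentration > 0),
            all(within_biome_concentration > 0), reads_per_sample >= 1,
            unclassified_fraction >= 0, unclassified_fraction < 1)
  spec_per_biome <- sum(rep_len(seq_len(n_biomes), max(n_specialists, 1L))
                        == 1L) * (n_specialists > 0)
  planted_share <- planted_weight * (n_generalists + spec_per_biome)
  if (planted_share >= 0.9)
    stop("infeasible config: planted taxa claim ",
         round(planted_share, 2), " of the centroid mass", call. = FALSE)
  structure(list(n_biomes = as.integer(n_biomes),
                 samples_per_biome = as.integer(samples_per_biome),
                 taxa_per_biome = as.integer(taxa_per_biome),
                 n_specialists = as.integer(n_specialists),
                 n_generalists = as.integer(n_generalists),
                 biome_centroid_concentration = biome_centroid_concentration,
                 within_biome_concentration = within_biome_concentration,
                 planted_weight = planted_weight,
                 reads_per_sample = as.integer(reads_per_sample),
                 unclassified_fraction = unclassified_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

planted_lineage <- function(kind, i, biome = NULL) {
  if (kind == "specialist")
    sprintf("Bacteria;Phy%d;Cls%d;OrdSpec%d;FamSpec%d;SpecGenus%d;SpecSp%d",
            biome, biome, i, i, i, i)
  else
    sprintf("Bacteria;PhyGen;ClsGen;OrdGen%d;FamGen%d;GenGenus%d;GenSp%d",
            i, i, i, i)
}

#' Generate a synthetic profile collection with planted niche structure
#'
#' @param cfg a [synthetic_config()].
#' @return list with `collection` (a `profile_collection`) and `truth`
#'   (data frame: `name`, `role`, `biome`, `order_key`, `genus_key`,
#'   `lineage` for every planted taxon). Fully reproducible from
#'   `cfg$seed`.
#' @export
generate_collection <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    spec_biome <- if (cfg$n_specialists)
      rep_len(seq_len(cfg$n_biomes), cfg$n_specialists) else integer(0)
    specialists <- if (cfg$n_specialists)
      vapply(seq_len(cfg$n_specialists), function(i)
        planted_lineage("specialist", i, spec_biome[i]), "") else character(0)
    generalists <- if (cfg$n_generalists)
      vapply(seq_len(cfg$n_generalists), function(i)
        planted_lineage("generalist", i), "") else character(0)
    profiles <- list()
    md_rows <- list()
    for (b in seq_len(cfg$n_biomes)) {
      nb <- cfg$taxa_per_biome[b]
      bg_full <- sprintf(
        "Bacteria;Phy%d;Cls%d;OrdB%dT%d;FamB%dT%d;GenB%dT%d;SpB%dT%d",
        b, b, b, seq_len(nb), b, seq_len(nb), b, seq_len(nb), b, seq_len(nb))
      # truncate a fraction of background lineages at a random rank
      trunc <- runif(nb) < cfg$unclassified_fraction
      depth <- ifelse(trunc, sample(1:6, nb, replace = TRUE), 7L)
      bg <- vapply(seq_len(nb), function(t) {
        parts <- strsplit(bg_full[t], ";", fixed = TRUE)[[1]]
        paste(parts[seq_len(depth[t])], collapse = ";")
      }, "")
      planted_b <- c(specialists[spec_biome == b], generalists)
      w_bg <- rgamma(nb, shape = cfg$biome_centroid_concentration[b])
      w_bg <- w_bg / sum(w_bg) *
        (1 - cfg$planted_weight * length(planted_b))
      centroid <- c(w_bg, rep(cfg$planted_weight, length(planted_b)))
      lineages <- c(bg, planted_b)
      for (s in seq_len(cfg$samples_per_biome)) {
        sid <- sprintf("B%d_S%02d", b, s)
        p <- rgamma(length(centroid),
                    shape = cfg$within_biome_concentration[b] * centroid)
        if (sum(p) == 0) p <- centroid
        counts <- as.numeric(rmultinom(1L, cfg$reads_per_sample,
                                       p / sum(p)))
        keep <- counts > 0
        profiles[[sid]] <- taxonomic_profile(
          sid, setNames(counts[keep], lineages[keep]))
        md_rows[[sid]] <- data.frame(
          sample_id = sid, biome = sprintf("root:Synthetic:Biome%d", b),
          experiment_type = "metagenomic", stringsAsFactors = FALSE)
      }
    }
    truth <- data.frame(
      name = c(sprintf("SpecGenus%d", seq_len(cfg$n_specialists)),
               sprintf("GenGenus%d", seq_len(cfg$n_generalists))),
      role = c(rep("specialist", cfg$n_specialists),
               rep("generalist", cfg$n_generalists)),
      biome = c(spec_biome, rep(NA_integer_, cfg$n_generalists)),
      lineage = c(specialists, generalists),
      stringsAsFactors = FALSE)
    L <- parse_lineage(truth$lineage)
    truth$order_key <- path_to_rank(L, rank_index("order"))
    truth$genus_key <- path_to_rank(L, rank_index("genus"))
    list(collection = profile_collection(profiles,
                                         do.call(rbind, md_rows)),
         truth = truth)
  })
}

#' Generate genome records for the planted genera
#'
#' Per planted genus, species genomes are drawn with role-dependent true
#' sizes; observed sizes are scaled by the genome's completeness and
#' contamination so that [corrected_size()] recovers the truth. Function
#' sets (universe `subsystem_subclass`) consist of a genus core plus a
#' per-species accessory draw from a genus pool whose size grows with the
#' role's accessory `turnover`: at turnover 0 every species set is
#' identical (closed pan-genome, openness 1); generalists default to a
#' higher turnover than specialists, so their pan-genomes are more open by
#' construction. Optionally one marker function is planted in all
#' generalist genera for signal-recovery checks.
#'
#' @param truth truth table from [generate_collection()].
#' @param n_species species per genus, default 5.
#' @param genomes_per_species genomes per species, default 2.
#' @param core_size genus core function count, default 300.
#' @param accessory_size per-species accessory function count, default 100.
#' @param turnover named vector of accessory turnover in `[0, 1]` per role,
#'   default `c(specialist = 0.2, generalist = 0.8)`.
#' @param size_mean named vector of true genome size (bp) per role, default
#'   `c(specialist = 2.5e6, generalist = 4.5e6)`.
#' @param size_sd between-species size standard deviation, default 2e5.
#' @param density_mean coding density (CDS per bp) per role, default
#'   `c(specialist = 8.8e-4, generalist = 9.6e-4)`.
#' @param density_sd genome-level coding density standard deviation,
#'   default 2e-5.
#' @param size_by_genus optional named vector overriding `size_mean` per
#'   genus name.
#' @param marker add the `MARKER_generalist` function to generalist genera,
#'   default `TRUE`.
#' @param seed seed, default 1.
#' @return list with `genomes` (metadata data frame as for
#'   [read_genomes()]) and `functions` (long table: `genome_id`,
#'   `universe`, `function_id`).
#' @export
generate_genomes <- function(truth, n_species = 5L, genomes_per_species = 2L,
                             core_size = 300L, accessory_size = 100L,
                             turnover = c(specialist = 0.2,
                                          generalist = 0.8),
                             size_mean = c(specialist = 2.5e6,
                                           generalist = 4.5e6),
                             size_sd = 2e5,
                             density_mean = c(specialist = 8.8e-4,
                                              generalist = 9.6e-4),
                             density_sd = 2e-5,
                             size_by_genus = NULL, marker = TRUE,
                             seed = 1L) {
  with_seed(seed, {
    meta <- list()
    funs <- list()
    for (g in seq_len(nrow(truth))) {
      genus <- truth$name[g]
      role <- truth$role[g]
      tv <- turnover[[role]]
      pool_n <- accessory_size + round(3 * tv * accessory_size)
      pool <- sprintf("%s_acc%d", genus, seq_len(pool_n))
      core <- sprintf("%s_core%d", genus, seq_len(core_size))
      mu <- if (!is.null(size_by_genus) && genus %in% names(size_by_genus))
        size_by_genus[[genus]] else size_mean[[role]]
      for (sp in seq_len(n_species)) {
        true_size <- rnorm(1, mu, size_sd)
        accessory <- sample(pool, accessory_size)
        fset <- c(core, accessory)
        if (marker && role == "generalist")
          fset <- c(fset, "MARKER_generalist")
        sp_lineage <- sub("[^;]+$", sprintf("%s_sp%d", genus, sp),
                          truth$lineage[g])
        for (k in seq_len(genomes_per_species)) {
          gid <- sprintf("%s_sp%d_g%d", genus, sp, k)
          comp <- runif(1, 82, 100)
          cont <- runif(1, 0, 3)
          obs_size <- true_size * (comp + cont) / 100
          meta[[gid]] <- data.frame(
            genome_id = gid, lineage = sp_lineage, completeness = comp,
            contamination = cont, size_bp = obs_size,
            n_cds = obs_size *
              max(rnorm(1, density_mean[[role]], density_sd), 1e-5),
            gc = runif(1, 35, 65),
            growth_rate = rnorm(1, if (role == "generalist") 8 else 3, 0.5),
            stringsAsFactors = FALSE)
          funs[[gid]] <- data.frame(
            genome_id = gid, universe = "subsystem_subclass",
            function_id = fset, stringsAsFactors = FALSE)
        }
      }
    }
    list(genomes = do.call(rbind, c(meta, list(make.row.names = FALSE))),
         functions = do.call(rbind, c(funs, list(make.row.names = FALSE))))
  })
}

#' Two-regime study conditions: genome size vs niche breadth by diversity
#'
#' Builds a collection in which the first half of the biomes have low
#' richness (few background taxa, so first-order alpha diversity falls
#' below the low/high split) and the second half high richness, and assigns
#' genus genome sizes by ecological role: specialists of low-diversity
#' biomes get small genomes, generalists intermediate ones, specialists of
#' high-diversity biomes the largest — the two contrasting niche range
#' strategies. Within a low-diversity sample, genome size then increases
#' with niche breadth; within a high-diversity sample it decreases.
#'
#' @param seed master seed.
#' @param low_size,gen_size,high_size true genome sizes (bp) of low-
#'   diversity specialists, generalists, and high-diversity specialists.
#' @return list with `collection`, `truth` (with a `regime` column) and
#'   `size_by_genus` (named vector of true sizes).
#' @export
generate_two_regime <- function(seed = 1L, low_size = 2e6, gen_size = 4e6,
                                high_size = 8e6) {
  cfg <- synthetic_config(
    n_biomes = 4L, samples_per_biome = 30L,
    taxa_per_biome = c(5L, 5L, 60L, 60L),
    n_specialists = 8L, n_generalists = 8L,
    biome_centroid_concentration = c(0.7, 0.7, 2, 2),
    within_biome_concentration = c(80, 80, 80, 80),
    planted_weight = 0.02, unclassified_fraction = 0.1, seed = seed)
  sim <- generate_collection(cfg)
  truth <- sim$truth
  truth$regime <- ifelse(truth$role == "generalist", "generalist",
                         ifelse(truth$biome <= 2L, "low_diversity",
                                "high_diversity"))
  size_by_genus <- setNames(
    ifelse(truth$regime == "generalist", gen_size,
           ifelse(truth$regime == "low_diversity", low_size, high_size)),
    truth$name)
  list(collection = sim$collection, truth = truth,
       size_by_genus = size_by_genus)
}

#' The package's canonical tiny worked example
#'
#' A deterministic 5-sample, 6-taxon collection (all taxa fully classified
#' to species) small enough that its dissimilarities, niche-breadth scores
#' and diversity numbers can be recomputed by hand or by the brute-force
#' oracles in the test suite. Samples s1 and s2 are proportional (their
#' Spearman dissimilarity is 0), s3 is disjoint from s1 at the order rank,
#' and s5 is a low-depth sample.
#'
#' @return a `profile_collection`.
#' @export
worked_fixture <- function() {
  lin <- sprintf("Bacteria;PhyA;ClsA;Ord%d;Fam%d;Gen%d;Sp%d", 1:6, 1:6,
                 1:6, 1:6)
  counts <- list(
    s1 = c(500, 300, 200, 0, 0, 0),
    s2 = c(250, 150, 100, 0, 0, 0),
    s3 = c(0, 0, 0, 400, 400, 200),
    s4 = c(100, 0, 0, 300, 600, 0),
    s5 = c(0, 60, 40, 0, 0, 0))
  profiles <- lapply(names(counts), function(sid) {
    v <- counts[[sid]]
    taxonomic_profile(sid, setNames(v[v > 0], lin[v > 0]))
  })
  md <- data.frame(sample_id = names(counts),
                   biome = c("root:Host", "root:Host", "root:Aquatic",
                             "root:Aquatic", "root:Host"),
                   experiment_type = "amplicon", stringsAsFactors = FALSE)
  profile_collection(profiles, md)
}
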