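#' Assemble a genome metadata table
#'
#' Normalizes a genome metadata data frame (or TSV path) into the layout the
#' aggregation functions expect, parsing the species-level lineage into rank
#' columns. Required columns: `genome_id`, `lineage`, `completeness`,
#' `contamination`, `size_bp`, `n_cds`; optional: `gc`, `growth_rate`.
#'
#' @param meta data frame or TSV path.
#' @return data frame with the rank columns of [TAX_RANKS] appended.
#' @export
read_genomes <- function(meta) {
  if (is.character(meta)) meta <- read.delim(meta, stringsAsFactors = FALSE)
  need <- c("genome_id", "lineage", "completeness", "contamination",
            "size_bp", "n_cds")
  miss <- setdiff(need, colnames(meta))
  if (length(miss))
    stop("genome table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(meta$genome_id))
    stop("duplicate genome ids", call. = FALSE)
  cbind(meta, as.data.frame(parse_lineage(meta$lineage),
                            stringsAsFactors = FALSE))
}

#' Quality-filter genomes on completeness and contamination
#'
#' A genome is retained iff `completeness - 5 * contamination >= 70`
#' (boundary inclusive). Records with missing estimates are rejected and
#' reported in the `rejected` attribute.
#'
#' @param genomes data frame from [read_genomes()].
#' @param min_score quality floor, default 70.
#' @return filtered data frame.
#' @export
quality_filter <- function(genomes, min_score = 70) {
  ok_fields <- !is.na(genomes$completeness) & !is.na(genomes$contamination)
  score <- genomes$completeness - 5 * genomes$contamination
  keep <- ok_fields & score >= min_score
  out <- genomes[keep, , drop = FALSE]
  attr(out, "rejected") <- data.frame(
    genome_id = genomes$genome_id[!keep],
    reason = ifelse(ok_fields[!keep], "quality-below-threshold",
                    "missing-quality-fields"))
  out
}

#' Correct genome size estimates for completeness and contamination
#'
#' Multiplies base pair and coding-sequence counts by the scaling factor
#' `s = 100 / (completeness + contamination)`, so an incomplete genome is
#' scaled up and a contaminated one down.
#'
#' @param genomes data frame with `completeness`, `contamination`,
#'   `size_bp`, `n_cds`.
#' @return the data frame with `size_bp_corrected` and `n_cds_corrected`
#'   columns added.
#' @export
corrected_size <- function(genomes) {
  denom <- genomes$completeness + genomes$contamination
  if (any(denom == 0, na.rm = TRUE))
    stop("completeness + contamination is zero for: ",
         paste(genomes$genome_id[denom == 0], collapse = ", "),
         call. = FALSE)
  s <- 100 / denom
  genomes$size_bp_corrected <- genomes$size_bp * s
  genomes$n_cds_corrected <- genomes$n_cds * s
  genomes
}

#' Drop duplicated genome records
#'
#' Sequence-level replicate detection needs the DNA itself; as a metadata
#' proxy, records identical in (species lineage, genome size, function-set
#' hash) are collapsed to one, with a warning naming the dropped ids.
#'
#' @param genomes data frame from [read_genomes()].
#' @param functions long-format function table (`genome_id`, `universe`,
#'   `function_id`) used for the hash; may be `NULL`.
#' @return deduplicated genomes data frame.
#' @export
dedup_genomes <- function(genomes, functions = NULL) {
  hash <- rep("", nrow(genomes))
  if (!is.null(functions)) {
    sets <- split(paste(functions$universe, functions$function_id),
                  functions$genome_id)
    h <- vapply(sets, function(s) paste(sort(unique(s)), collapse = "\r"),
                "")
    hash <- unname(h[match(genomes$genome_id, names(h))])
    hash[is.na(hash)] <- ""
  }
  key <- paste(genomes$lineage, genomes$size_bp, hash, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    warning("dropped ", sum(dup), " duplicate genome record(s): ",
            paste(genomes$genome_id[dup], collapse = ", "))
  genomes[!dup, , drop = FALSE]
}

FUNCTION_UNIVERSES <- c("subsystem_name", "subsystem_subclass",
                        "gene_ontology", "pathway")

#' Species-level functional profiles under the majority rule
#'
#' A function belongs to a species if at least 50% of the species' genomes
#' contain it (inclusive). Genomes with `<= discard_max` unique functions in
#' the universe are discarded first — the rule applies to subsystem names,
#' gene ontologies and pathways, but not to subsystem subclasses.
#'
#' @param genomes quality-filtered data frame from [read_genomes()].
#' @param functions long-format table (`genome_id`, `universe`,
#'   `function_id`).
#' @param universe one of `subsystem_name`, `subsystem_subclass`,
#'   `gene_ontology`, `pathway`.
#' @param discard_max sparse-genome cutoff, default 20.
#' @return list with `sets` (named list: species lineage -> function id
#'   vector) and `table` (data frame `species`, `n_genomes`,
#'   `functional_size`).
#' @export
species_functional_profile <- function(genomes, functions,
                                       universe = "subsystem_subclass",
                                       discard_max = 20L) {
  universe <- match.arg(universe, FUNCTION_UNIVERSES)
  fn <- functions[functions$universe == universe, , drop = FALSE]
  per_genome <- lapply(split(fn$function_id, fn$genome_id), unique)
  if (universe != "subsystem_subclass")
    per_genome <- per_genome[lengths(per_genome) > discard_max]
  genomes <- genomes[genomes$genome_id %in% names(per_genome), ,
                     drop = FALSE]
  if (!nrow(genomes)) stop("no genomes left in universe ", universe,
                           call. = FALSE)
  by_species <- split(genomes$genome_id, genomes$lineage)
  sets <- lapply(by_species, function(gids) {
    tab <- table(unlist(per_genome[gids]))
    names(tab)[tab / length(gids) >= 0.5]
  })
  list(sets = sets,
       table = data.frame(species = names(by_species),
                          n_genomes = lengths(by_species),
                          functional_size = lengths(sets),
                          stringsAsFactors = FALSE))
}

#' Aggregate species-level values to a higher rank
#'
#' Plain mode averages over all daughter species of the taxon (and reports
#' the standard deviation over species). Taxonomy-corrected mode instead
#' averages recursively over the immediate daughter ranks — the value of a
#' family is the mean over its genera, each genus the mean over its species
#' — which removes the skew caused by species-rich subclades.
#'
#' @param species_df data frame with one row per species: the rank columns
#'   of [TAX_RANKS] (at least down to `species`) plus numeric value columns.
#' @param rank target rank (above species).
#' @param value_cols names of the numeric columns to aggregate.
#' @param taxonomy_corrected use the recursive mean, default `FALSE`.
#' @return data frame: `taxon` (name at the rank), `n_species`, then
#'   `mean_*` and (plain mode) `sd_*` per value column.
#' @export
taxon_aggregate <- function(species_df, rank, value_cols,
                            taxonomy_corrected = FALSE) {
  ri <- rank_index(rank)
  if (ri >= rank_index("species"))
    stop("rank must be above species", call. = FALSE)
  species_df <- species_df[!is.na(species_df[[rank]]), , drop = FALSE]
  if (!nrow(species_df)) stop("no species classified at rank ", rank,
                              call. = FALSE)
  n_sp <- tapply(species_df$species, species_df[[rank]],
                 function(s) length(unique(s)))
  if (!taxonomy_corrected) {
    out <- data.frame(taxon = names(n_sp), n_species = as.integer(n_sp),
                      stringsAsFactors = FALSE)
    for (v in value_cols) {
      out[[paste0("mean_", v)]] <-
        as.numeric(tapply(species_df[[v]], species_df[[rank]], mean))
      out[[paste0("sd_", v)]] <-
        as.numeric(tapply(species_df[[v]], species_df[[rank]], sd))
    }
    rownames(out) <- NULL
    return(out)
  }
  # recursive mean over immediate daughters: walk from species up to the
  # target rank, averaging each rank into its parent
  cur <- species_df
  for (k in rev(seq(ri + 1L, rank_index("species")))) {
    parent_cols <- TAX_RANKS[seq_len(k - 1L)]
    key <- do.call(paste, c(cur[parent_cols], sep = "\r"))
    agg <- aggregate(cur[value_cols], by = list(.key = key), FUN = mean)
    first <- cur[!duplicated(key), parent_cols, drop = FALSE]
    first <- first[match(agg$.key, unique(key)), , drop = FALSE]
    cur <- cbind(first, agg[value_cols])
  }
  out <- data.frame(taxon = cur[[rank]],
                    n_species = as.integer(n_sp[cur[[rank]]]),
                    stringsAsFactors = FALSE)
  for (v in value_cols) out[[paste0("mean_", v)]] <- cur[[v]]
  rownames(out) <- NULL
  out
}

#' Pan-genome size and openness of a set of species
#'
#' The pan-genome is the union of the species' function sets; openness is
#' the pan-genome size divided by the mean per-species functional size, so
#' 1 means a fully closed pan-genome (all species identical). In
#' `permuted_3` mode the two quantities are means over random subsets of
#' three daughter species, correcting for the tendency of species-rich taxa
#' to have large pan-genomes; taxa with fewer than three species get `NA`.
#'
#' @param sets list of function-id vectors, one per species.
#' @param mode `"all"` or `"permuted_3"`.
#' @param n_perm random subsets in permuted mode, default 1000.
#' @param seed seed for the subsets.
#' @return data frame with `pan_size`, `openness`, `n_species`, `mode`.
#' @export
pan_genome <- function(sets, mode = c("all", "permuted_3"), n_perm = 1000L,
                       seed = 1L) {
  mode <- match.arg(mode)
  sets <- lapply(sets, unique)
  k <- length(sets)
  if (!k) stop("no species sets", call. = FALSE)
  if (mode == "all") {
    pan <- length(unique(unlist(sets)))
    return(data.frame(pan_size = pan,
                      openness = pan / mean(lengths(sets)),
                      n_species = k, mode = mode))
  }
  if (k < 3L)
    return(data.frame(pan_size = NA_real_, openness = NA_real_,
                      n_species = k, mode = mode))
  res <- vapply(seq_len(n_perm), function(b) {
    pick <- with_seed(derive_seed(seed, b), sample.int(k, 3L))
    sub <- sets[pick]
    pan <- length(unique(unlist(sub)))
    c(pan, pan / mean(lengths(sub)))
  }, numeric(2))
  data.frame(pan_size = mean(res[1, ]), openness = mean(res[2, ]),
             n_species = k, mode = mode)
}

#' Per-taxon genome and pan-genome feature table
#'
#' Convenience wrapper joining [taxon_aggregate()] on corrected genome sizes
#' with [pan_genome()] (both all-species and 3-species-permuted) per taxon
#' at a rank.
#'
#' @param species_df species-level data frame (see [taxon_aggregate()])
#'   with `size_bp_corrected` and `n_cds_corrected` columns.
#' @param sets named list: species lineage -> function set.
#' @param rank target rank.
#' @param n_perm permutations for the 3-species mode.
#' @param seed seed.
#' @return data frame, one row per taxon.
#' @export
taxon_genome_features <- function(species_df, sets, rank, n_perm = 1000L,
                                  seed = 1L) {
  base <- taxon_aggregate(species_df, rank,
                          c("size_bp_corrected", "n_cds_corrected"))
  species_df <- species_df[!is.na(species_df[[rank]]), , drop = FALSE]
  by_taxon <- split(species_df$lineage, species_df[[rank]])
  pans <- lapply(base$taxon, function(tx) {
    s <- sets[intersect(by_taxon[[tx]], names(sets))]
    if (!length(s))
      return(data.frame(pan_size = NA_real_, openness = NA_real_,
                        pan_size_3 = NA_real_, openness_3 = NA_real_,
                        mean_functional_size = NA_real_,
                        sd_functional_size = NA_real_))
    all <- pan_genome(s, "all")
    p3 <- pan_genome(s, "permuted_3", n_perm = n_perm, seed = seed)
    data.frame(pan_size = all$pan_size, openness = all$openness,
               pan_size_3 = p3$pan_size, openness_3 = p3$openness,
               mean_functional_size = mean(lengths(s)),
               sd_functional_size = sd(lengths(s)))
  })
  cbind(base, do.call(rbind, pans))
}

#' Aggregate maximal growth rates to species and genus
#'
#' Species rate is the mean over its genomes; the genus rate averages the
#' species means (species-first, mirroring the size aggregation), or pools
#' all genomes directly with `variant = "pooled"`.
#'
#' @param genomes data frame from [read_genomes()] with a `growth_rate`
#'   column (`NA` allowed).
#' @param variant `"species_mean"` (default) or `"pooled"`.
#' @return list with `species` and `genus` data frames.
#' @export
growth_rate_aggregate <- function(genomes,
                                  variant = c("species_mean", "pooled")) {
  variant <- match.arg(variant)
  g <- genomes[!is.na(genomes$growth_rate), , drop = FALSE]
  if (!nrow(g)) stop("no growth rates available", call. = FALSE)
  sp <- aggregate(list(growth_rate = g$growth_rate),
                  by = list(species = g$lineage, genus = g$genus),
                  FUN = mean)
  gen <- if (variant == "species_mean") {
    aggregate(list(growth_rate = sp$growth_rate),
              by = list(genus = sp$genus), FUN = mean)
  } else {
    aggregate(list(growth_rate = g$growth_rate),
              by = list(genus = g$genus), FUN = mean)
  }
  list(species = sp, genus = gen[!is.na(gen$genus), , drop = FALSE])
}
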