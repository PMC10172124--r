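#' Presence calls of taxa across samples at a rank
#'
#' A taxon is considered present (alive and growing) in a sample if its
#' relative abundance — reads assigned to the taxon including all its
#' subtaxa, divided by the sample's total prokaryotic reads — is at least
#' `threshold`. The threshold is inclusive, reading "at least".
#'
#' @param x a cleaned `profile_collection`.
#' @param rank one of [TAX_RANKS].
#' @param threshold detection limit, default `1e-4`.
#' @return logical matrix (taxa x samples) of class `presence_matrix`, with
#'   attribute `rel_abundance` holding the underlying relative abundances.
#'   Taxa present in zero samples are omitted.
#' @export
presence_matrix <- function(x, rank, threshold = 1e-4) {
  ri <- rank_index(rank)
  ids <- sample_ids(x)
  per_sample <- lapply(x$profiles, function(p) {
    L <- parse_lineage(names(p$counts))
    at <- !is.na(L[, ri])
    if (!any(at)) return(setNames(numeric(0), character(0)))
    key <- path_to_rank(L[at, , drop = FALSE], ri)
    agg <- tapply(p$counts[at], key, sum)
    setNames(as.numeric(agg) / p$total_reads, names(agg))
  })
  taxa <- unique(unlist(lapply(per_sample, names)))
  R <- matrix(0, length(taxa), length(ids), dimnames = list(taxa, ids))
  for (j in seq_along(ids)) {
    v <- per_sample[[j]]
    if (length(v)) R[names(v), j] <- v
  }
  P <- R >= threshold
  keep <- rowSums(P) > 0L
  structure(P[keep, , drop = FALSE],
            class = c("presence_matrix", "matrix", "array"),
            rel_abundance = R[keep, , drop = FALSE],
            rank = rank, threshold = threshold)
}

#' Social niche breadth of a sample set
#'
#' The SNB of a taxon found in samples `i = 1..n` is the mean pairwise
#' dissimilarity `sum(d_ij, i != j) / (n^2 - n)`; because the matrix is
#' symmetric this equals the mean over unordered pairs, which is what is
#' computed.
#'
#' @param ids sample ids the taxon is present in (n >= 2).
#' @param D a `dissim_matrix` covering those samples.
#' @return SNB value.
#' @export
snb_score <- function(ids, D) {
  ids <- unique(ids)
  if (length(ids) < 2L)
    stop("SNB undefined for fewer than 2 samples", call. = FALSE)
  if (!all(ids %in% rownames(D)))
    stop("samples missing from dissimilarity matrix: ",
         paste(setdiff(ids, rownames(D)), collapse = ", "), call. = FALSE)
  sub <- D[ids, ids]
  mean(sub[upper.tri(sub)])
}

#' SNB table for all taxa of a collection
#'
#' Scores every taxon at the requested ranks: presence is called per rank at
#' the detection `threshold`, taxa present in fewer than `min_samples`
#' usable samples are removed, and each remaining taxon's SNB is the mean
#' pairwise dissimilarity of its samples under `D` (by default the published
#' configuration: Spearman at rank order, approach 2). Local dominance (mean
#' relative abundance over the taxon's samples), normalized Shannon entropy
#' of its relative abundances across those samples, the number of annotated
#' biomes it occurs in, and the per-rank modified z score are annotated.
#'
#' @param x a cleaned `profile_collection`.
#' @param D optional precomputed `dissim_matrix`; computed from `config`
#'   when `NULL`.
#' @param config a [dissim_config()] used when `D` is `NULL`.
#' @param ranks ranks to score, default all seven.
#' @param threshold detection limit, default `1e-4`.
#' @param min_samples minimum presence count, default 5.
#' @param sample_subset optional sample ids restricting the analysis (for
#'   hierarchical subset runs such as marine- or human-only scores).
#' @return data frame of class `snb_table` with columns `taxon` (lineage
#'   path key), `name`, `rank`, `n_samples`, `snb`, `dominance`, `entropy`,
#'   `n_biomes`, `z`.
#' @export
snb_table <- function(x, D = NULL, config = dissim_config(),
                      ranks = TAX_RANKS, threshold = 1e-4,
                      min_samples = 5L, sample_subset = NULL) {
  if (!length(x$profiles)) stop("empty collection", call. = FALSE)
  if (!is.null(sample_subset)) x <- subset_samples(x, sample_subset)
  if (is.null(D)) D <- pairwise_matrix(x, config)
  usable <- intersect(sample_ids(x), rownames(D))
  biome <- setNames(x$metadata$biome, x$metadata$sample_id)
  res <- lapply(ranks, function(rk) {
    P <- presence_matrix(x, rk, threshold)
    R <- attr(P, "rel_abundance")
    P <- P[, intersect(colnames(P), usable), drop = FALSE]
    rows <- lapply(rownames(P), function(tx) {
      ids <- colnames(P)[P[tx, ]]
      if (length(ids) < min_samples) return(NULL)
      ra <- R[tx, ids]
      v <- ra / sum(ra)
      ent <- if (length(ids) >= 2L) -sum(v * log(v)) / log(length(ids))
             else NA_real_
      parts <- strsplit(tx, ";", fixed = TRUE)[[1]]
      data.frame(taxon = tx, name = parts[length(parts)], rank = rk,
                 n_samples = length(ids), snb = snb_score(ids, D),
                 dominance = mean(ra), entropy = ent,
                 n_biomes = length(unique(biome[ids])),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(taxon = character(0), name = character(0),
                      rank = character(0), n_samples = integer(0),
                      snb = numeric(0), dominance = numeric(0),
                      entropy = numeric(0), n_biomes = integer(0))
  rownames(out) <- NULL
  out <- modified_z(out)
  class(out) <- c("snb_table", "data.frame")
  attr(out, "config") <- attr(D, "config")
  attr(out, "threshold") <- threshold
  out
}

#' Per-rank modified z scores
#'
#' Robust standardization of SNB within each taxonomic rank: the number of
#' median absolute deviations from the rank median, divided by the constant
#' 1.4826 so scores are comparable to standard-deviation z scores. Positive
#' z marks taxa that are relatively generalist for their rank, negative z
#' relatively specialist. When the rank MAD is zero the z score is
#' undefined and reported as `NA` (a zero would wrongly claim
#' median-typicality).
#'
#' @param records data frame with columns `rank` and `snb`.
#' @return the same data frame with a `z` column (re)filled.
#' @export
modified_z <- function(records) {
  records$z <- NA_real_
  for (rk in unique(records$rank)) {
    i <- records$rank == rk
    if (sum(i) < 2L) next
    x <- records$snb[i]
    med <- median(x)
    mad_raw <- median(abs(x - med))
    if (mad_raw > 0) records$z[i] <- (x - med) / (1.4826 * mad_raw)
  }
  records
}

#' SNB null models: imaginary taxa
#'
#' Computes the SNB of imaginary taxa (iSNB) planted in chosen sample sets,
#' the reference distributions against which real scores are read:
#'
#' * `random_subsets`: for each requested subset size, `n_perm` uniform
#'   draws of that many samples (without replacement).
#' * `biome_full`: one imaginary taxon present in all samples of each biome.
#' * `biome_half`: `n_perm` draws of half the samples of each biome.
#' * `biome_pairs`: one imaginary taxon per unordered pair of biomes,
#'   present in all their samples.
#'
#' @param D a `dissim_matrix`.
#' @param mode one of `random_subsets`, `biome_full`, `biome_half`,
#'   `biome_pairs`.
#' @param metadata data frame with `sample_id` and `biome` (biome modes).
#' @param sizes integer vector of subset sizes (`random_subsets` mode).
#' @param n_perm permutations per condition, default 100.
#' @param seed master seed; per-permutation seeds are derived by counter.
#' @return data frame with columns `condition`, `size`, `perm`, `snb`.
#' @export
isnb <- function(D, mode = c("random_subsets", "biome_full", "biome_half",
                             "biome_pairs"),
                 metadata = NULL, sizes = NULL, n_perm = 100L, seed = 1L) {
  mode <- match.arg(mode)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  ids <- rownames(D)
  if (mode == "random_subsets") {
    if (is.null(sizes)) stop("sizes required for random_subsets",
                             call. = FALSE)
    if (any(sizes > length(ids)))
      stop("subset size exceeds sample count", call. = FALSE)
    rows <- list()
    k <- 0L
    for (s in sizes) for (b in seq_len(n_perm)) {
      k <- k + 1L
      picked <- with_seed(derive_seed(seed, k), sample(ids, s))
      rows[[k]] <- data.frame(condition = "random", size = s, perm = b,
                              snb = snb_score(picked, D))
    }
    return(do.call(rbind, rows))
  }
  if (is.null(metadata))
    stop("metadata required for biome modes", call. = FALSE)
  biome <- setNames(metadata$biome, metadata$sample_id)[ids]
  groups <- split(ids, biome)
  groups <- groups[lengths(groups) >= 2L]
  if (mode == "biome_full") {
    return(do.call(rbind, lapply(names(groups), function(b)
      data.frame(condition = b, size = length(groups[[b]]), perm = 1L,
                 snb = snb_score(groups[[b]], D)))))
  }
  if (mode == "biome_half") {
    groups <- groups[lengths(groups) >= 4L]
    rows <- list()
    k <- 0L
    for (b in names(groups)) {
      h <- floor(length(groups[[b]]) / 2)
      for (p in seq_len(n_perm)) {
        k <- k + 1L
        picked <- with_seed(derive_seed(seed, k), sample(groups[[b]], h))
        rows[[k]] <- data.frame(condition = b, size = h, perm = p,
                                snb = snb_score(picked, D))
      }
    }
    return(do.call(rbind, rows))
  }
  # biome_pairs
  bn <- names(groups)
  if (length(bn) < 2L) stop("need at least 2 biomes", call. = FALSE)
  pairs <- combn(bn, 2L)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    members <- c(groups[[pairs[1, k]]], groups[[pairs[2, k]]])
    data.frame(condition = paste(pairs[1, k], pairs[2, k], sep = "+"),
               size = length(members), perm = 1L,
               snb = snb_score(members, D))
  }))
}

#' Write an SNB table as TSV
#' @param tab an `snb_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snb_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
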