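#' Project a taxonomic profile to a single rank
#'
#' Aggregates a profile's entries to taxon keys at a target rank under one of
#' three approaches for taxa not classified at that rank:
#'
#' * approach `1`: fall back to the first classified rank below; if there is
#'   none, to the first classified rank above. Fallback keys carry a
#'   provenance tag (`from-below:`/`from-above:` prefixes) so they never
#'   collide with genuine rank keys.
#' * approach `2` (strict): only taxa classified at the rank are kept.
#' * approach `3`: as approach 1, but from-above fallback keys are only
#'   resolved pairwise — [align_pair()] removes them when present in both
#'   samples of a comparison.
#'
#' After aggregation, keys supported by fewer than `min_reads` reads are
#' removed; because this is applied per rank, a sample's included read total
#' may differ between ranks.
#'
#' @param p a [taxonomic_profile()].
#' @param rank one of [TAX_RANKS].
#' @param approach 1, 2 or 3 (default 2, the published configuration).
#' @param min_reads per-taxon read floor after aggregation, default 5.
#' @return object of class `rank_profile`: list with `sample_id`, `rank`,
#'   `approach`, `counts` (named by taxon key = lineage path to the rank) and
#'   `tags` (`"exact"`, `"from-below"` or `"from-above"` per key).
#' @export
project_to_rank <- function(p, rank, approach = 2L, min_reads = 5L) {
  ri <- rank_index(rank)
  approach <- as.integer(approach)
  stopifnot(approach %in% 1:3)
  L <- parse_lineage(names(p$counts))
  deep <- deepest_rank(L)
  key <- character(nrow(L))
  tag <- character(nrow(L))
  at_rank <- !is.na(L[, ri])
  key[at_rank] <- path_to_rank(L[at_rank, , drop = FALSE], ri)
  tag[at_rank] <- "exact"
  below <- !at_rank & deep > ri
  if (any(below)) {
    key[below] <- paste0("from-below:",
                         lineage_string(L[below, , drop = FALSE]))
    tag[below] <- "from-below"
  }
  above <- !at_rank & !below & deep >= 1L
  if (any(above)) {
    key[above] <- paste0("from-above:",
                         lineage_string(L[above, , drop = FALSE]))
    tag[above] <- "from-above"
  }
  if (approach == 2L) {
    use <- at_rank
  } else {
    use <- at_rank | below | above
  }
  counts <- p$counts[use]
  keys <- key[use]
  tags <- tag[use]
  if (length(counts)) {
    agg <- tapply(counts, keys, sum)
    tags <- tags[match(names(agg), keys)]
    keep <- agg >= min_reads
    counts <- setNames(as.numeric(agg[keep]), names(agg)[keep])
    tags <- setNames(tags[keep], names(agg)[keep])
  } else {
    counts <- setNames(numeric(0), character(0))
    tags <- setNames(character(0), character(0))
  }
  structure(list(sample_id = p$sample_id, rank = rank, approach = approach,
                 min_reads = min_reads, counts = counts, tags = tags),
            class = "rank_profile")
}

#' @export
print.rank_profile <- function(x, ...) {
  cat("<rank_profile> sample", x$sample_id, "rank", x$rank,
      "approach", x$approach, "-", length(x$counts), "taxa\n")
  invisible(x)
}

# Project every sample; returns list of rank_profile keyed by sample id.
project_collection <- function(x, rank, approach = 2L, min_reads = 5L) {
  lapply(x$profiles, project_to_rank, rank = rank, approach = approach,
         min_reads = min_reads)
}

# Count matrix (taxa x samples) from a list of rank profiles, with the tag
# vector for the row keys. Samples with zero taxa at the rank are dropped
# (ids recorded in attribute "empty_samples").
rank_count_matrix <- function(rps) {
  empty <- vapply(rps, function(rp) length(rp$counts) == 0L, TRUE)
  dropped <- names(rps)[empty]
  rps <- rps[!empty]
  keys <- unique(unlist(lapply(rps, function(rp) names(rp$counts))))
  M <- matrix(0, length(keys), length(rps),
              dimnames = list(keys, names(rps)))
  tags <- setNames(rep(NA_character_, length(keys)), keys)
  for (j in seq_along(rps)) {
    M[names(rps[[j]]$counts), j] <- rps[[j]]$counts
    tags[names(rps[[j]]$tags)] <- rps[[j]]$tags
  }
  structure(M, tags = tags, empty_samples = dropped)
}
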