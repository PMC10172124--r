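# Earth-mover UniFrac over the rank taxonomy with unit branch lengths.
#
# The tree is the taxonomy itself: root -> superkingdom -> ... -> species,
# every edge of length 1. Taxa unclassified at the target rank but classified
# below are placed at an artificial node at the target depth derived from
# their first classified rank below (unique per such classification, at the
# appropriate distance from the root); taxa with no classification at or
# below the rank are placed at their first classified rank above.

# Placement path (root-ward name vector) for each lineage row, at target
# rank index ri. Internal unclassified ranks get placeholders keyed by the
# first classified rank below, so lineages sharing that classification share
# the placeholder.
placement_paths <- function(L, ri) {
  deep <- deepest_rank(L)
  lapply(seq_len(nrow(L)), function(i) {
    r <- L[i, ]
    named <- which(!is.na(r))
    if (!length(named)) return(NULL)
    depth <- if (deep[i] >= ri) ri else deep[i]
    path <- character(depth)
    for (k in seq_len(depth)) {
      if (!is.na(r[k])) {
        path[k] <- r[k]
      } else {
        below <- named[named > k]
        anchor <- if (length(below)) r[min(below)] else r[max(named)]
        path[k] <- paste0("?", TAX_RANKS[k], "|", anchor)
      }
    }
    path
  })
}

#' Place a profile on the rank taxonomy for UniFrac
#'
#' @param p a [taxonomic_profile()].
#' @param rank target rank.
#' @param min_reads per-node read floor after aggregation, default 5.
#' @return object of class `unifrac_placement`: `node_paths` (list of name
#'   vectors from the root) and `counts` per node.
#' @export
unifrac_placement <- function(p, rank, min_reads = 5L) {
  ri <- rank_index(rank)
  L <- parse_lineage(names(p$counts))
  paths <- placement_paths(L, ri)
  ok <- !vapply(paths, is.null, TRUE)
  ids <- vapply(paths[ok], paste, "", collapse = "|")
  counts <- tapply(p$counts[ok], ids, sum)
  keep <- counts >= min_reads
  upaths <- paths[ok][match(names(counts)[keep], ids)]
  structure(list(sample_id = p$sample_id, rank = rank,
                 node_paths = upaths,
                 counts = setNames(as.numeric(counts[keep]),
                                   names(counts)[keep])),
            class = "unifrac_placement")
}

# Tree distance between two placement paths (unit branches).
path_distance <- function(pa, pb) {
  la <- length(pa); lb <- length(pb)
  common <- 0L
  for (k in seq_len(min(la, lb))) {
    if (pa[k] == pb[k]) common <- k else break
  }
  la + lb - 2L * common
}

#' Earth-mover UniFrac dissimilarity between two placed samples
#'
#' Computes the earth-mover distance between the two samples' abundance
#' masses over the taxonomy tree (exact on a tree: the summed absolute
#' subtree mass difference over all edges), normalized to `[0, 1]` by the
#' maximum attainable flow distance at the target rank (the tree diameter
#' `2 * depth`, since unit-branch placements are at most that far apart).
#' The weighted variant moves relative-abundance mass, the unweighted
#' variant uniform presence mass.
#'
#' @param pa,pb `unifrac_placement` objects at the same rank.
#' @param weighted use relative abundances (`TRUE`) or presence (`FALSE`).
#' @return dissimilarity in `[0, 1]`.
#' @export
emd_unifrac <- function(pa, pb, weighted = TRUE) {
  stopifnot(inherits(pa, "unifrac_placement"),
            inherits(pb, "unifrac_placement"), pa$rank == pb$rank)
  if (!length(pa$counts) || !length(pb$counts))
    stop(errorCondition("empty placement", class = "snb_undefined_pair"))
  mass <- function(pl) {
    if (weighted) pl$counts / sum(pl$counts)
    else setNames(rep(1 / length(pl$counts), length(pl$counts)),
                  names(pl$counts))
  }
  ma <- mass(pa); mb <- mass(pb)
  ids <- union(names(ma), names(mb))
  if (length(ids) <= 1L) return(0)
  paths <- c(pa$node_paths, pb$node_paths)
  names(paths) <- c(names(pa$counts), names(pb$counts))
  paths <- paths[!duplicated(names(paths))][ids]
  diff <- setNames(numeric(length(ids)), ids)
  diff[names(ma)] <- diff[names(ma)] + ma
  diff[names(mb)] <- diff[names(mb)] - mb
  # propagate subtree mass differences root-ward; every traversed edge of
  # length 1 contributes |subtree difference|
  node_diff <- new.env(parent = emptyenv())
  for (id in ids) {
    key <- paste(paths[[id]], collapse = "|")
    node_diff[[key]] <- (if (is.null(node_diff[[key]])) 0 else
      node_diff[[key]]) + diff[[id]]
  }
  emd <- 0
  repeat {
    keys <- ls(node_diff)
    if (!length(keys)) break
    depths <- lengths(strsplit(keys, "|", fixed = TRUE))
    d <- max(depths)
    for (key in keys[depths == d]) {
      v <- node_diff[[key]]
      emd <- emd + abs(v)
      if (d > 1L) {
        parts <- strsplit(key, "|", fixed = TRUE)[[1]]
        pkey <- paste(parts[-d], collapse = "|")
        node_diff[[pkey]] <- (if (is.null(node_diff[[pkey]])) 0 else
          node_diff[[pkey]]) + v
      }
      rm(list = key, envir = node_diff)
    }
  }
  if (emd == 0) return(0)
  # normalize by the tree diameter at the target rank (two placements can
  # be at most 2 * depth apart), so values are comparable on the 0-1 scale
  clamp01(emd / (2 * rank_index(pa$rank)))
}

# Pairwise UniFrac matrix for a collection (dispatch target of
# pairwise_matrix()).
unifrac_matrix <- function(x, config) {
  weighted <- config$measure == "weighted_unifrac"
  placements <- lapply(x$profiles, unifrac_placement, rank = config$rank,
                       min_reads = config$min_reads)
  empty <- vapply(placements, function(p) length(p$counts) == 0L, TRUE)
  removed <- setNames(rep("empty-at-rank", sum(empty)),
                      names(placements)[empty])
  placements <- placements[!empty]
  ids <- names(placements)
  n <- length(ids)
  if (n < 2L)
    stop("fewer than 2 usable samples at rank ", config$rank, call. = FALSE)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- emd_unifrac(placements[[i]], placements[[j]],
                                      weighted = weighted)
  structure(D, class = c("dissim_matrix", "matrix", "array"),
            config = config, removed_samples = removed)
}
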