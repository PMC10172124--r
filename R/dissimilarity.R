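SNB_MEASURES <- c("aitchison", "bray_curtis", "sorensen_dice", "jaccard",
                  "weighted_jaccard", "kendall_tau_b", "pearson", "spearman",
                  "unweighted_unifrac", "weighted_unifrac")

CORRELATION_MEASURES <- c("pearson", "spearman", "kendall_tau_b")
UNIFRAC_MEASURES <- c("unweighted_unifrac", "weighted_unifrac")

#' Configuration of a pairwise dissimilarity computation
#'
#' A config fully determines a dissimilarity matrix: the measure, the
#' taxonomic rank, the unknown-handling approach and the per-taxon read
#' floor. The published niche-breadth configuration is Spearman at rank
#' order with approach 2 and a 5-read floor — the default.
#'
#' @param measure one of `aitchison`, `bray_curtis`, `sorensen_dice`,
#'   `jaccard`, `weighted_jaccard`, `kendall_tau_b`, `pearson`, `spearman`,
#'   `unweighted_unifrac`, `weighted_unifrac`.
#' @param rank one of [TAX_RANKS]. UniFrac measures are conventionally run
#'   at species, family or class; other ranks trigger a warning unless
#'   `allow_any_unifrac_rank` is `TRUE`.
#' @param approach unknown-handling approach (see [project_to_rank()]);
#'   ignored by the UniFrac measures, which use their own tree placement.
#' @param min_reads per-taxon read floor, default 5.
#' @param allow_any_unifrac_rank suppress the UniFrac rank warning.
#' @return object of class `dissim_config`.
#' @export
dissim_config <- function(measure = "spearman", rank = "order",
                          approach = 2L, min_reads = 5L,
                          allow_any_unifrac_rank = FALSE) {
  measure <- match.arg(measure, SNB_MEASURES)
  rank_index(rank)
  if (measure %in% UNIFRAC_MEASURES &&
      !rank %in% c("species", "family", "class") && !allow_any_unifrac_rank)
    warning("UniFrac measures are conventionally computed at species, ",
            "family or class; got rank ", rank)
  structure(list(measure = measure, rank = rank,
                 approach = as.integer(approach),
                 min_reads = as.integer(min_reads)),
            class = "dissim_config")
}

clamp01 <- function(x, tol = 1e-12) {
  if (is.na(x)) return(x)
  if (abs(x) < tol) return(0)
  if (abs(x - 1) < tol) return(1)
  x
}

#' Convert a correlation coefficient to a dissimilarity
#'
#' Computes `0.5 - coefficient/2` so that perfect positive correlation maps
#' to 0 and perfect negative correlation to 1. Spearman uses average ranks;
#' the Kendall variant is the tie-corrected tau-b.
#'
#' @param v1,v2 abundance vectors of equal length (>= 2).
#' @param kind `"pearson"`, `"spearman"` or `"kendall_tau_b"`.
#' @return dissimilarity in `[0, 1]`.
#' @export
correlation_dissimilarity <- function(v1, v2, kind = "spearman") {
  kind <- match.arg(kind, CORRELATION_MEASURES)
  if (length(v1) != length(v2) || length(v1) < 2L)
    stop("vectors must have equal length >= 2", call. = FALSE)
  method <- c(pearson = "pearson", spearman = "spearman",
              kendall_tau_b = "kendall")[kind]
  if (sd(v1) == 0 || sd(v2) == 0)
    stop(errorCondition("correlation undefined for a constant vector",
                        class = "snb_undefined_correlation"))
  clamp01(0.5 - cor(v1, v2, method = method) / 2)
}

#' Set-based and abundance-based dissimilarities
#'
#' `jaccard` and `sorensen_dice` act on presence/absence; `weighted_jaccard`
#' is the Ruzicka dissimilarity `1 - sum(min)/sum(max)`; `bray_curtis` is
#' `sum(|x - y|) / sum(x + y)`. The two abundance-weighted measures expect
#' relative abundances.
#'
#' @param v1,v2 non-negative vectors of equal length, not both all-zero.
#' @param kind `"sorensen_dice"`, `"jaccard"`, `"weighted_jaccard"` or
#'   `"bray_curtis"`.
#' @return dissimilarity in `[0, 1]`.
#' @export
set_dissimilarity <- function(v1, v2, kind) {
  kind <- match.arg(kind, c("sorensen_dice", "jaccard", "weighted_jaccard",
                            "bray_curtis"))
  if (all(v1 == 0) && all(v2 == 0))
    stop(errorCondition("both vectors all-zero",
                        class = "snb_undefined_pair"))
  d <- switch(kind,
    jaccard = 1 - sum(v1 > 0 & v2 > 0) / sum(v1 > 0 | v2 > 0),
    sorensen_dice = 1 - 2 * sum(v1 > 0 & v2 > 0) /
      (sum(v1 > 0) + sum(v2 > 0)),
    weighted_jaccard = 1 - sum(pmin(v1, v2)) / sum(pmax(v1, v2)),
    bray_curtis = sum(abs(v1 - v2)) / sum(v1 + v2))
  clamp01(d)
}

#' Aitchison distance between two rank profiles
#'
#' Compositional (CLR/Euclidean) distance over the union of the two samples'
#' taxa. Because the transform cannot handle zeros, paired pseudocounts are
#' added in read units before closing the composition: one read per union
#' taxon in the sample with the larger read sum (`N1`), and `N2/N1` reads in
#' the other (`N2 <= N1`), i.e. the smallest relative abundance an undetected
#' taxon could have had. Counts are then converted to relative abundances,
#' centred log-ratio transformed per sample, and the Euclidean distance
#' returned.
#'
#' @param ca,cb named numeric count vectors over each sample's taxa at the
#'   rank (as in a `rank_profile`'s `counts`).
#' @return non-negative distance.
#' @export
aitchison_distance <- function(ca, cb) {
  keys <- union(names(ca), names(cb))
  if (!length(keys))
    stop(errorCondition("empty union", class = "snb_undefined_pair"))
  x <- setNames(numeric(length(keys)), keys)
  y <- x
  x[names(ca)] <- ca
  y[names(cb)] <- cb
  na <- sum(x); nb <- sum(y)
  if (na >= nb) {
    x <- x + 1
    y <- y + nb / na
  } else {
    y <- y + 1
    x <- x + na / nb
  }
  lx <- log(x / sum(x))
  ly <- log(y / sum(y))
  clrx <- lx - mean(lx)
  clry <- ly - mean(ly)
  sqrt(sum((clrx - clry)^2))
}

#' Align two rank profiles over the union of their taxa
#'
#' Builds the paired abundance vectors a dissimilarity measure consumes:
#' taxa present in only one sample get abundance zero in the other (all
#' measures except Aitchison, which adds pseudocounts instead). Under
#' approach 3, keys that were placed by from-above fallback and occur in
#' *both* samples are removed from the pair, because for those taxa it is
#' unknown whether they are the same at the rank of interest. Relative
#' abundances divide by the per-sample sum over the included taxa.
#'
#' @param a,b `rank_profile` objects at the same rank and approach.
#' @param config a [dissim_config()].
#' @return list with `keys`, raw counts `ca`, `cb` and relative abundances
#'   `ra`, `rb`.
#' @export
align_pair <- function(a, b, config = dissim_config()) {
  stopifnot(a$rank == b$rank, a$approach == b$approach)
  keys <- union(names(a$counts), names(b$counts))
  if (!length(keys))
    stop(errorCondition("both profiles empty at the rank",
                        class = "snb_undefined_pair"))
  ca <- setNames(numeric(length(keys)), keys)
  cb <- ca
  ca[names(a$counts)] <- a$counts
  cb[names(b$counts)] <- b$counts
  if (config$approach == 3L) {
    drop <- startsWith(keys, "from-above:") & ca > 0 & cb > 0
    if (any(drop)) {
      keys <- keys[!drop]; ca <- ca[!drop]; cb <- cb[!drop]
    }
    if (!length(keys))
      stop(errorCondition("pair empty after conditional removal",
                          class = "snb_undefined_pair"))
  }
  list(keys = keys, ca = ca, cb = cb,
       ra = if (sum(ca) > 0) ca / sum(ca) else ca,
       rb = if (sum(cb) > 0) cb / sum(cb) else cb)
}

# Dissimilarity of one aligned pair under a (non-UniFrac) measure. The
# single-union-taxon rule (d = 0) is applied by the caller.
pair_dissimilarity <- function(al, measure) {
  if (measure == "aitchison")
    return(aitchison_distance(al$ca[al$ca > 0], al$cb[al$cb > 0]))
  if (measure %in% CORRELATION_MEASURES)
    return(correlation_dissimilarity(al$ra, al$rb, measure))
  set_dissimilarity(al$ra, al$rb, measure)
}

#' All pairwise dissimilarities between the samples of a collection
#'
#' Projects every sample to the configured rank, removes samples with no
#' taxon at that rank and — for the correlation measures — samples whose
#' rank profile is constant (their self-correlation is undefined), then
#' computes the full symmetric matrix. Pairs whose taxon union contains a
#' single taxon are set to 0 regardless of abundances.
#'
#' @param x a `profile_collection` (cleaned).
#' @param config a [dissim_config()].
#' @return a numeric matrix of class `dissim_matrix` with sample ids as
#'   dimnames; attributes `config` and `removed_samples` (ids dropped at
#'   this rank, with the reason).
#' @export
pairwise_matrix <- function(x, config = dissim_config()) {
  if (config$measure %in% UNIFRAC_MEASURES)
    return(unifrac_matrix(x, config))
  rps <- project_collection(x, config$rank, config$approach,
                            config$min_reads)
  M <- rank_count_matrix(rps)
  removed <- setNames(rep("empty-at-rank",
                          length(attr(M, "empty_samples"))),
                      attr(M, "empty_samples"))
  if (config$measure %in% CORRELATION_MEASURES && ncol(M)) {
    const <- vapply(seq_len(ncol(M)), function(j) {
      v <- M[M[, j] > 0, j]
      length(v) < 2L || sd(v) == 0
    }, TRUE)
    removed <- c(removed,
                 setNames(rep("constant-profile", sum(const)),
                          colnames(M)[const]))
    M <- M[, !const, drop = FALSE]
  }
  ids <- colnames(M)
  n <- length(ids)
  if (n < 2L)
    stop("fewer than 2 usable samples at rank ", config$rank, call. = FALSE)
  tags <- attr(M, "tags")
  from_above <- startsWith(rownames(M), "from-above:")
  csum <- colSums(M)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  warned <- FALSE
  for (i in seq_len(n - 1L)) {
    xi <- M[, i]
    for (j in (i + 1L):n) {
      yj <- M[, j]
      sel <- xi > 0 | yj > 0
      if (config$approach == 3L)
        sel <- sel & !(from_above & xi > 0 & yj > 0)
      k <- sum(sel)
      if (k <= 1L) next  # single-union-taxon rule: d = 0
      ca <- xi[sel]; cb <- yj[sel]
      d <- if (config$measure == "aitchison") {
        aitchison_distance(ca[ca > 0], cb[cb > 0])
      } else if (config$measure %in% CORRELATION_MEASURES) {
        if (sd(ca) == 0 || sd(cb) == 0) {
          # degenerate pair surviving sample-level screening (possible only
          # after approach-3 removal): identical vectors are similar, else
          # fall back to the chance level of the correlation scale
          if (!warned) {
            warning("degenerate correlation pair(s); using 0/0.5 fallback")
            warned <- TRUE
          }
          if (isTRUE(all.equal(ca / sum(ca), cb / sum(cb)))) 0 else 0.5
        } else {
          correlation_dissimilarity(ca / sum(ca), cb / sum(cb),
                                    config$measure)
        }
      } else {
        set_dissimilarity(ca / sum(ca), cb / sum(cb), config$measure)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  structure(D, class = c("dissim_matrix", "matrix", "array"),
            config = config, removed_samples = removed)
}

#' @export
print.dissim_matrix <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<dissim_matrix>", nrow(x), "samples,", cfg$measure, "at rank",
      cfg$rank, "approach", cfg$approach, "\n")
  invisible(x)
}

#' Write a dissimilarity matrix as TSV
#' @param D a `dissim_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dissim_matrix <- function(D, path) {
  out <- data.frame(sample_id = rownames(D), as.data.frame(unclass(D)),
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
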