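# Per-sample relative abundance vectors at a rank for diversity work:
# strict (approach 2) aggregation, detection threshold on relative abundance
# against total prokaryotic reads, then renormalized to sum 1. Samples with
# nothing left are dropped with a warning.
diversity_vectors <- function(x, rank = "order", threshold = 1e-4) {
  P <- presence_matrix(x, rank, threshold)
  R <- attr(P, "rel_abundance")
  R[!P] <- 0
  keep <- colSums(R) > 0
  if (any(!keep))
    warning("excluded ", sum(!keep), " sample(s) with no taxon at rank ",
            rank, " after the relative abundance threshold")
  R <- R[, keep, drop = FALSE]
  sweep(R, 2L, colSums(R), "/")
}

# Effective number of taxa of one probability vector at order q.
hill_number <- function(p, q) {
  p <- p[p > 0]
  if (q == 0) return(length(p))
  if (q == 1) return(exp(-sum(p * log(p))))
  if (q == 2) return(1 / sum(p^2))
  stop("diversity order must be 0, 1 or 2", call. = FALSE)
}

#' Per-sample (alpha) Hill diversity
#'
#' Effective numbers of taxa at diversity order `q` for every sample:
#' richness (`q = 0`), the exponential of Shannon entropy (`q = 1`) or the
#' inverse Simpson concentration (`q = 2`). Alpha diversity of the set is by
#' default the arithmetic mean of the per-sample effective numbers,
#' consistent with the zeroth-order definition (the mean number of taxa
#' found in a set of samples); `method = "effective_mean"` instead averages
#' entropies/concentrations before converting to an effective number.
#'
#' @param x a cleaned `profile_collection`.
#' @param q diversity order, 0, 1 or 2.
#' @param rank rank for the strict projection, default `"order"`.
#' @param threshold relative abundance detection limit, default `1e-4`.
#' @param method `"mean_effective"` (default) or `"effective_mean"`.
#' @return list with `per_sample` (named vector) and `alpha` (the mean).
#' @export
hill_alpha <- function(x, q = 1, rank = "order", threshold = 1e-4,
                       method = c("mean_effective", "effective_mean")) {
  method <- match.arg(method)
  R <- diversity_vectors(x, rank, threshold)
  per <- apply(R, 2L, hill_number, q = q)
  alpha <- if (method == "mean_effective" || q == 0) {
    mean(per)
  } else if (q == 1) {
    exp(mean(log(per)))
  } else {
    1 / mean(1 / per)
  }
  list(per_sample = per, alpha = alpha)
}

#' Alpha, beta and gamma Hill diversity of a sample set
#'
#' Gamma diversity is the effective number of taxa of the pooled community:
#' the per-sample relative abundance vectors are summed (equivalently
#' averaged, weighting samples equally) and renormalized. Beta diversity is
#' `gamma / alpha`, the effective number of distinct communities.
#'
#' @inheritParams hill_alpha
#' @return data frame with one row: `q`, `alpha`, `beta`, `gamma`,
#'   `n_samples`.
#' @export
hill_diversity <- function(x, q = 1, rank = "order", threshold = 1e-4,
                           method = c("mean_effective", "effective_mean")) {
  method <- match.arg(method)
  R <- diversity_vectors(x, rank, threshold)
  per <- apply(R, 2L, hill_number, q = q)
  alpha <- if (method == "mean_effective" || q == 0) mean(per)
           else if (q == 1) exp(mean(log(per)))
           else 1 / mean(1 / per)
  pooled <- rowMeans(R)
  gamma <- hill_number(pooled / sum(pooled), q)
  data.frame(q = q, alpha = alpha, beta = gamma / alpha, gamma = gamma,
             n_samples = ncol(R))
}

#' Diversity by sample group
#'
#' Applies [hill_diversity()] to each group of samples (for example each
#' annotated biome); groups with fewer than `min_samples` samples are
#' excluded from the analysis.
#'
#' @param x a cleaned `profile_collection`.
#' @param groups named vector mapping sample id to group label; defaults to
#'   the metadata biome.
#' @param q diversity order.
#' @param min_samples minimum group size, default 3.
#' @param ... passed to [hill_diversity()].
#' @return data frame with one row per retained group.
#' @export
diversity_by_group <- function(x, groups = NULL, q = 1, min_samples = 3L,
                               ...) {
  if (is.null(groups))
    groups <- setNames(x$metadata$biome, x$metadata$sample_id)
  split_ids <- split(sample_ids(x), groups[sample_ids(x)])
  split_ids <- split_ids[lengths(split_ids) >= min_samples]
  out <- do.call(rbind, lapply(names(split_ids), function(g) {
    d <- hill_diversity(subset_samples(x, split_ids[[g]]), q = q, ...)
    cbind(group = g, d)
  }))
  rownames(out) <- NULL
  out
}

#' Local dominance and cross-sample entropy of one taxon
#'
#' Local dominance is the taxon's mean relative abundance across the
#' samples in which it is present (at the detection threshold). The Shannon
#' entropy (base e) of its relative abundances across those `N` samples —
#' renormalized to sum 1 — measures how even its occurrence is and is
#' normalized by `ln(N)` to `[0, 1]`; it is undefined (`NA`) for `N = 1`.
#'
#' @param taxon taxon key (lineage path at the rank, as in
#'   [presence_matrix()] rownames).
#' @param x a cleaned `profile_collection`.
#' @param rank rank of the taxon key.
#' @param threshold detection limit, default `1e-4`.
#' @return data frame with `taxon`, `n_samples`, `dominance`, `entropy`.
#' @export
taxon_distribution <- function(taxon, x, rank, threshold = 1e-4) {
  P <- presence_matrix(x, rank, threshold)
  if (!taxon %in% rownames(P))
    stop("taxon not present anywhere: ", taxon, call. = FALSE)
  ra <- attr(P, "rel_abundance")[taxon, P[taxon, ]]
  n <- length(ra)
  ent <- if (n >= 2L) {
    v <- ra / sum(ra)
    -sum(v * log(v)) / log(n)
  } else NA_real_
  data.frame(taxon = taxon, n_samples = n, dominance = mean(ra),
             entropy = ent)
}

#' Permutational multivariate analysis of variance on a dissimilarity matrix
#'
#' One-way PERMANOVA: the total sum of squared dissimilarities is
#' partitioned into within- and between-group parts, giving the pseudo-F
#' statistic `F = (SS_between/(G-1)) / (SS_within/(N-G))`. The coefficient
#' of determination is computed as `R^2 = F / (F + (N-G)/(G-1))`, and the
#' p value by permuting group labels: `p = (#{F_perm >= F} + 1)/(n_perm + 1)`.
#'
#' @param D a `dissim_matrix` (or plain symmetric matrix with dimnames).
#' @param groups named vector mapping sample id to group label.
#' @param n_perm number of permutations, default 99.
#' @param seed seed for the permutations.
#' @return list of class `permanova_result`: `pseudo_F`, `R2`, `p_value`,
#'   `n_samples`, `n_groups`, `n_permutations`.
#' @export
permanova <- function(D, groups, n_perm = 99L, seed = 1L) {
  ids <- rownames(D)
  g <- as.character(groups[ids])
  if (anyNA(g)) stop("groups missing for some samples", call. = FALSE)
  if (length(unique(g)) < 2L)
    stop("PERMANOVA needs at least 2 groups", call. = FALSE)
  N <- length(ids)
  G <- length(unique(g))
  D2 <- unclass(D)^2
  f_stat <- function(lab) {
    ss_total <- sum(D2[upper.tri(D2)]) / N
    ss_within <- 0
    for (lv in unique(lab)) {
      i <- lab == lv
      if (sum(i) < 2L) next
      sub <- D2[i, i]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / sum(i)
    }
    ((ss_total - ss_within) / (G - 1)) / (ss_within / (N - G))
  }
  F_obs <- f_stat(g)
  perm_ge <- 0L
  for (b in seq_len(n_perm)) {
    gp <- with_seed(derive_seed(seed, b), sample(g))
    if (f_stat(gp) >= F_obs) perm_ge <- perm_ge + 1L
  }
  structure(list(pseudo_F = F_obs,
                 R2 = permanova_r2(F_obs, N, G),
                 p_value = (perm_ge + 1) / (n_perm + 1),
                 n_samples = N, n_groups = G, n_permutations = n_perm),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("<permanova> F =", signif(x$pseudo_F, 4), " R2 =", signif(x$R2, 4),
      " p =", x$p_value, " (", x$n_samples, "samples,", x$n_groups,
      "groups,", x$n_permutations, "permutations )\n")
  invisible(x)
}

#' Coefficient of determination from a pseudo-F statistic
#'
#' `R^2 = F / (F + (N - G)/(G - 1))` for `N` samples in `G` groups.
#'
#' @param F pseudo-F statistic.
#' @param N number of samples.
#' @param G number of groups.
#' @return R squared in `[0, 1]`.
#' @export
permanova_r2 <- function(F, N, G)
  ifelse(is.finite(F), F / (F + (N - G) / (G - 1)), 1)
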