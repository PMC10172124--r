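#' Build a strictly ordered ranked list
#'
#' Sorts items by score, descending; ties are broken by item identifier
#' (lexicographic) so the ordering is deterministic.
#'
#' @param scores named numeric vector (names are item ids, e.g. genera).
#' @return object of class `ranked_list`: list with `items` and `scores` in
#'   rank order.
#' @export
ranked_list <- function(scores) {
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop("scores must be uniquely named", call. = FALSE)
  ord <- order(-scores, names(scores))
  structure(list(items = names(scores)[ord], scores = unname(scores[ord])),
            class = "ranked_list")
}

#' Classical Kolmogorov-Smirnov enrichment score
#'
#' Running-sum statistic over the ranked list: walking down the list, the
#' sum increases by `1/Nh` at each member ("hit") of the set and decreases
#' by `1/(N - Nh)` at each non-member. With weight exponent `p = 0` every
#' hit counts equally (the classical KS statistic); with `p > 0` hits are
#' weighted by `|score|^p`. The enrichment score is the signed maximum
#' deviation of the running sum from zero; when the positive and negative
#' extremes tie in magnitude, the positive one is reported.
#'
#' @param ranked a [ranked_list()] (or named score vector).
#' @param members item ids forming the set; must be a non-empty proper
#'   subset of the ranked universe.
#' @param p_exponent hit weight exponent, default 0 (classical KS).
#' @return enrichment score in `[-1, 1]`.
#' @export
enrichment_score <- function(ranked, members, p_exponent = 0) {
  if (!inherits(ranked, "ranked_list")) ranked <- ranked_list(ranked)
  hit <- ranked$items %in% members
  N <- length(hit)
  Nh <- sum(hit)
  if (Nh == 0L || Nh == N)
    stop(errorCondition("set is empty or spans the whole universe",
                        class = "snb_degenerate_set"))
  if (p_exponent == 0) {
    w <- rep(1, N)
  } else {
    w <- abs(ranked$scores)^p_exponent
  }
  step <- ifelse(hit, w / sum(w[hit]), -1 / (N - Nh))
  running <- cumsum(step)
  top <- max(running)
  bottom <- min(running)
  # on an exact magnitude tie the positive deviation is reported
  if (top >= -bottom) top else bottom
}

# ES of a random set given sorted hit positions; O(Nh) closed form of the
# running sum extrema (classical KS only).
es_from_positions <- function(pos, N) {
  Nh <- length(pos)
  i <- seq_len(Nh)
  top <- max(i / Nh - (pos - i) / (N - Nh))
  bottom <- min((i - 1) / Nh - (pos - i) / (N - Nh))
  if (top >= -bottom) top else bottom
}

#' Permutation significance of enrichment scores
#'
#' For each set, a null distribution of enrichment scores is built from
#' `n_perm` random member sets of identical size (gene-set permutation).
#' The normalized enrichment score divides the observed ES by the mean of
#' the same-signed null scores; the p value is the same-signed null tail
#' (with the +1 correction); the FDR compares each normalized score against
#' the pooled normalized null distribution, separately for the positive and
#' negative sides, with the observed-score denominator and a monotonicity
#' cleanup.
#'
#' @param ranked a [ranked_list()] (or named score vector).
#' @param sets named list of member-id vectors.
#' @param n_perm permutations per set size, default 1000.
#' @param seed master seed.
#' @param min_size,max_frac sets with fewer members than `min_size` or
#'   covering at least `max_frac` of the universe are skipped (degenerate
#'   KS); skipped ids are recorded in the `skipped` attribute.
#' @return data frame of class `gsea_result`: `set`, `size`, `ES`, `NES`,
#'   `p_value`, `FDR`, sorted by NES (descending).
#' @export
gsea <- function(ranked, sets, n_perm = 1000L, seed = 1L, min_size = 3L,
                 max_frac = 1) {
  if (!inherits(ranked, "ranked_list")) ranked <- ranked_list(ranked)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  N <- length(ranked$items)
  sizes <- vapply(sets, function(m) sum(ranked$items %in% m), 0L)
  ok <- sizes >= min_size & sizes < ceiling(max_frac * N) & sizes < N
  skipped <- names(sets)[!ok]
  sets <- sets[ok]
  sizes <- sizes[ok]
  if (!length(sets)) stop("no usable sets", call. = FALSE)
  # one null per distinct set size, shared across sets of that size
  null_by_size <- list()
  for (k in unique(sizes)) {
    null_by_size[[as.character(k)]] <- vapply(seq_len(n_perm), function(b) {
      pos <- sort(with_seed(derive_seed(seed, k * n_perm + b),
                            sample.int(N, k)))
      es_from_positions(pos, N)
    }, 0)
  }
  es <- vapply(names(sets), function(s)
    enrichment_score(ranked, sets[[s]]), 0)
  norm_one <- function(e, null) {
    pos_mean <- mean(null[null >= 0])
    neg_mean <- mean(abs(null[null < 0]))
    if (e >= 0) {
      if (!is.finite(pos_mean) || pos_mean == 0) NA_real_ else e / pos_mean
    } else {
      if (!is.finite(neg_mean) || neg_mean == 0) NA_real_ else e / neg_mean
    }
  }
  nes <- numeric(length(es))
  pval <- numeric(length(es))
  null_nes_pool <- c()
  for (k in unique(sizes)) {
    null <- null_by_size[[as.character(k)]]
    null_nes_pool <- c(null_nes_pool,
                       vapply(null, norm_one, 0, null = null))
  }
  for (i in seq_along(es)) {
    null <- null_by_size[[as.character(sizes[i])]]
    nes[i] <- norm_one(es[i], null)
    if (es[i] >= 0) {
      same <- null[null >= 0]
      pval[i] <- (sum(same >= es[i]) + 1) / (length(same) + 1)
    } else {
      same <- null[null < 0]
      pval[i] <- (sum(same <= es[i]) + 1) / (length(same) + 1)
    }
  }
  fdr <- rep(NA_real_, length(nes))
  pos_null <- null_nes_pool[!is.na(null_nes_pool) & null_nes_pool >= 0]
  neg_null <- null_nes_pool[!is.na(null_nes_pool) & null_nes_pool < 0]
  pos_obs <- which(!is.na(nes) & nes >= 0)
  neg_obs <- which(!is.na(nes) & nes < 0)
  for (i in pos_obs) {
    num <- mean(pos_null >= nes[i])
    den <- mean(nes[pos_obs] >= nes[i])
    fdr[i] <- min(1, num / den)
  }
  for (i in neg_obs) {
    num <- mean(neg_null <= nes[i])
    den <- mean(nes[neg_obs] <= nes[i])
    fdr[i] <- min(1, num / den)
  }
  # FDR monotone in |NES| within each sign
  if (length(pos_obs)) {
    ord <- pos_obs[order(-nes[pos_obs])]
    fdr[ord] <- cummin(fdr[ord])
  }
  if (length(neg_obs)) {
    ord <- neg_obs[order(nes[neg_obs])]
    fdr[ord] <- cummin(fdr[ord])
  }
  out <- data.frame(set = names(sets), size = as.integer(sizes), ES = es,
                    NES = nes, p_value = pval, FDR = fdr,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$NES), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gsea_result", "data.frame")
  attr(out, "skipped") <- skipped
  out
}

#' GSEA of genus pan-genomes along the niche-breadth axis
#'
#' Runs [gsea()] with the two rankings used to characterize niche range
#' strategies: all genera sorted by SNB (`all_by_snb`, comparing social
#' specialists with social generalists), or only specialist genera
#' (`SNB < specialist_cutoff`, strict) sorted by the mean alpha diversity
#' of the samples in which they are found (`specialists_by_alpha`,
#' comparing low- with high-diversity specialists). Positive enrichment
#' scores mark functions enriched towards the top of the ranking (high SNB
#' resp. high alpha); both directions are reported through the sign.
#'
#' @param snb_genus data frame with columns `name` (genus) and `snb`
#'   (typically the genus rows of an [snb_table()]); for
#'   `specialists_by_alpha` also `mean_alpha`.
#' @param pan_membership named list: function id -> vector of genera whose
#'   pan-genome contains the function.
#' @param mode `"all_by_snb"` or `"specialists_by_alpha"`.
#' @param specialist_cutoff SNB cutoff, default 0.35.
#' @param ... passed to [gsea()] (`n_perm`, `seed`, `min_size`).
#' @return a `gsea_result` data frame.
#' @export
run_pan_gsea <- function(snb_genus, pan_membership,
                         mode = c("all_by_snb", "specialists_by_alpha"),
                         specialist_cutoff = 0.35, ...) {
  mode <- match.arg(mode)
  universe <- intersect(snb_genus$name,
                        unique(unlist(pan_membership)))
  df <- snb_genus[snb_genus$name %in% universe, , drop = FALSE]
  if (!nrow(df)) stop("no genera shared between SNB table and pan-genomes",
                      call. = FALSE)
  if (mode == "all_by_snb") {
    scores <- setNames(df$snb, df$name)
  } else {
    df <- df[df$snb < specialist_cutoff, , drop = FALSE]
    if (!nrow(df)) stop("no specialist genera below cutoff ",
                        specialist_cutoff, call. = FALSE)
    if (is.null(df$mean_alpha))
      stop("specialists_by_alpha mode needs a mean_alpha column",
           call. = FALSE)
    scores <- setNames(df$mean_alpha, df$name)
  }
  gsea(ranked_list(scores), pan_membership, ...)
}
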