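#' Spearman correlation between SNB and a feature within samples
#'
#' For every sample, the genera present in it are correlated (Spearman)
#' between their SNB and a feature — either a static per-genus value (named
#' vector, e.g. mean corrected genome size) or a per-genus-per-sample value
#' (matrix genera x samples, e.g. local relative abundance). Samples with
#' fewer than `min_genera` genera carrying both values are skipped and
#' counted.
#'
#' @param x a cleaned `profile_collection`.
#' @param snb_genus genus rows of an [snb_table()] (columns `taxon`, `name`,
#'   `snb`).
#' @param feature named numeric vector (per genus) or numeric matrix with
#'   genus rownames and sample-id colnames.
#' @param threshold presence detection limit, default `1e-4`.
#' @param min_genera correlation floor, default 5.
#' @return data frame of one row per retained sample: `unit`, `biome`, `n`,
#'   `rho`, `p`; skipped sample count in attribute `n_skipped`.
#' @export
within_sample_correlation <- function(x, snb_genus, feature,
                                      threshold = 1e-4, min_genera = 5L) {
  P <- presence_matrix(x, "genus", threshold)
  snb_by_taxon <- setNames(snb_genus$snb, snb_genus$taxon)
  genus_name <- setNames(snb_genus$name, snb_genus$taxon)
  taxa <- intersect(rownames(P), names(snb_by_taxon))
  biome <- setNames(x$metadata$biome, x$metadata$sample_id)
  rows <- list()
  skipped <- 0L
  for (sid in colnames(P)) {
    present <- taxa[P[taxa, sid]]
    g <- genus_name[present]
    fv <- if (is.matrix(feature)) {
      if (!sid %in% colnames(feature)) rep(NA_real_, length(g))
      else feature[match(g, rownames(feature)), sid]
    } else {
      feature[match(g, names(feature))]
    }
    sv <- snb_by_taxon[present]
    ok <- is.finite(fv) & is.finite(sv)
    if (sum(ok) < min_genera) {
      skipped <- skipped + 1L
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(sv[ok], fv[ok], method = "spearman"))
    rows[[sid]] <- data.frame(unit = sid, biome = unname(biome[sid]),
                              n = sum(ok), rho = unname(ct$estimate),
                              p = ct$p.value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(unit = character(0), biome = character(0),
                      n = integer(0), rho = numeric(0), p = numeric(0))
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}

#' Spearman correlation between SNB and a feature within families
#'
#' One correlation per family over its genera, for families with at least
#' `min_genera` genera carrying both SNB and the feature. Families whose
#' genera have constant SNB or feature values (undefined correlation) are
#' skipped with the reason recorded.
#'
#' @param snb_genus genus rows of an [snb_table()]; the family of each genus
#'   is read from its `taxon` lineage path.
#' @param feature named numeric vector per genus name.
#' @param min_genera floor, default 5.
#' @return data frame: `unit` (family), `n`, `rho`, `p`; skipped families
#'   with reasons in attribute `skipped`.
#' @export
within_family_correlation <- function(snb_genus, feature, min_genera = 5L) {
  L <- parse_lineage(snb_genus$taxon)
  fam <- L[, "family"]
  rows <- list()
  skipped <- list()
  for (f in unique(fam[!is.na(fam)])) {
    i <- which(!is.na(fam) & fam == f)
    sv <- snb_genus$snb[i]
    fv <- feature[match(snb_genus$name[i], names(feature))]
    ok <- is.finite(fv) & is.finite(sv)
    if (sum(ok) < min_genera) {
      skipped[[f]] <- "below-genus-floor"
      next
    }
    if (sd(sv[ok]) == 0 || sd(fv[ok]) == 0) {
      skipped[[f]] <- "constant-values"
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(sv[ok], fv[ok], method = "spearman"))
    rows[[f]] <- data.frame(unit = f, n = sum(ok),
                            rho = unname(ct$estimate), p = ct$p.value,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(unit = character(0), n = integer(0), rho = numeric(0),
                      p = numeric(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- unlist(skipped)
  out
}

#' Per-sample genome-size regressions, summarized by alpha-diversity bin
#'
#' For each sample, an ordinary least squares line of mean genome size on
#' SNB is fitted across the genera present; samples are then binned by
#' their first-order alpha diversity (rank order) and the mean and
#' interquartile range of the per-sample slopes and intercepts reported per
#' bin. This is the computation behind the two-regime contrast: a positive
#' mean slope in low-diversity habitats, a negative one in high-diversity
#' habitats.
#'
#' @param x a cleaned `profile_collection`.
#' @param snb_genus genus rows of an [snb_table()].
#' @param genome_size named numeric vector: genus name -> mean genome size.
#' @param bin_edges breaks over alpha diversity (passed to [cut()]),
#'   e.g. `c(0, 11, Inf)`.
#' @param threshold presence detection limit, default `1e-4`.
#' @param min_genera minimum genera with genome data per sample, default 3.
#' @return list with `per_sample` (sample, alpha, bin, slope, intercept, n)
#'   and `per_bin` (bin, n_samples, mean/IQR of slope and intercept).
#' @export
alpha_binned_regression <- function(x, snb_genus, genome_size, bin_edges,
                                    threshold = 1e-4, min_genera = 3L) {
  alpha <- hill_alpha(x, q = 1, rank = "order",
                      threshold = threshold)$per_sample
  P <- presence_matrix(x, "genus", threshold)
  snb_by_taxon <- setNames(snb_genus$snb, snb_genus$taxon)
  genus_name <- setNames(snb_genus$name, snb_genus$taxon)
  taxa <- intersect(rownames(P), names(snb_by_taxon))
  rows <- list()
  for (sid in intersect(colnames(P), names(alpha))) {
    present <- taxa[P[taxa, sid]]
    sv <- snb_by_taxon[present]
    gv <- genome_size[match(genus_name[present], names(genome_size))]
    ok <- is.finite(sv) & is.finite(gv)
    if (sum(ok) < min_genera || sd(sv[ok]) == 0) next
    fit <- coef(lm(gv[ok] ~ sv[ok]))
    rows[[sid]] <- data.frame(sample = sid, alpha = unname(alpha[sid]),
                              intercept = unname(fit[1]),
                              slope = unname(fit[2]), n = sum(ok),
                              stringsAsFactors = FALSE)
  }
  per_sample <- do.call(rbind, rows)
  if (is.null(per_sample))
    stop("no sample had enough genera with genome data", call. = FALSE)
  rownames(per_sample) <- NULL
  per_sample$bin <- cut(per_sample$alpha, breaks = bin_edges,
                        include.lowest = TRUE)
  per_bin <- do.call(rbind, lapply(levels(per_sample$bin), function(b) {
    sub <- per_sample[per_sample$bin == b, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    data.frame(bin = b, n_samples = nrow(sub),
               mean_slope = mean(sub$slope), iqr_slope = IQR(sub$slope),
               mean_intercept = mean(sub$intercept),
               iqr_intercept = IQR(sub$intercept))
  }))
  rownames(per_bin) <- NULL
  list(per_sample = per_sample, per_bin = per_bin)
}

#' Label genera as specialists or generalists
#'
#' Three stratification modes:
#' * `snb_cutoff`: specialist iff `snb < cutoff` (strict; default 0.35), all
#'   others generalist.
#' * `alpha_cutoff`: `low_diversity` iff the mean alpha diversity of the
#'   genus' samples is `<= cutoff` (inclusive; default 11), else
#'   `high_diversity`.
#' * `within_sample_quantile`: per sample, the bottom quantile of genera by
#'   SNB are specialists, the top quantile generalists, the rest
#'   intermediate (default quantile 0.25).
#'
#' @param snb_genus genus rows of an [snb_table()]; `alpha_cutoff` mode
#'   needs a `mean_alpha` column.
#' @param mode one of the three modes.
#' @param cutoff cutoff value; defaults per mode (0.35, 11, 0.25).
#' @param x collection, required for `within_sample_quantile`.
#' @param threshold presence threshold for the quantile mode.
#' @return `snb_cutoff`/`alpha_cutoff`: the input with a `label` column.
#'   `within_sample_quantile`: long data frame (sample, taxon, name, snb,
#'   label).
#' @export
strategy_split <- function(snb_genus,
                           mode = c("snb_cutoff", "alpha_cutoff",
                                    "within_sample_quantile"),
                           cutoff = NULL, x = NULL, threshold = 1e-4) {
  mode <- match.arg(mode)
  if (mode == "snb_cutoff") {
    if (is.null(cutoff)) cutoff <- 0.35
    snb_genus$label <- ifelse(snb_genus$snb < cutoff, "specialist",
                              "generalist")
    return(snb_genus)
  }
  if (mode == "alpha_cutoff") {
    if (is.null(cutoff)) cutoff <- 11
    if (is.null(snb_genus$mean_alpha))
      stop("alpha_cutoff mode needs a mean_alpha column", call. = FALSE)
    snb_genus$label <- ifelse(snb_genus$mean_alpha <= cutoff,
                              "low_diversity", "high_diversity")
    return(snb_genus)
  }
  if (is.null(cutoff)) cutoff <- 0.25
  if (is.null(x)) stop("within_sample_quantile mode needs the collection",
                       call. = FALSE)
  P <- presence_matrix(x, "genus", threshold)
  snb_by_taxon <- setNames(snb_genus$snb, snb_genus$taxon)
  taxa <- intersect(rownames(P), names(snb_by_taxon))
  rows <- list()
  for (sid in colnames(P)) {
    present <- taxa[P[taxa, sid]]
    if (!length(present)) next
    sv <- snb_by_taxon[present]
    k <- floor(length(sv) * cutoff)
    ord <- order(sv, present)
    label <- rep("intermediate", length(sv))
    if (k >= 1L) {
      label[ord[seq_len(k)]] <- "specialist"
      label[ord[seq(length(sv) - k + 1L, length(sv))]] <- "generalist"
    }
    rows[[sid]] <- data.frame(sample = sid, taxon = present,
                              name = snb_genus$name[
                                match(present, snb_genus$taxon)],
                              snb = unname(sv), label = label,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean alpha diversity of the samples a genus is found in
#'
#' The sorting key of the specialist GSEA and the `alpha_cutoff` split:
#' per genus, the mean first-order alpha diversity (rank order) over the
#' samples where the genus is present at the detection threshold.
#'
#' @param x a cleaned `profile_collection`.
#' @param snb_genus genus rows of an [snb_table()].
#' @param threshold detection limit, default `1e-4`.
#' @return the input with a `mean_alpha` column added.
#' @export
genus_mean_alpha <- function(x, snb_genus, threshold = 1e-4) {
  alpha <- hill_alpha(x, q = 1, rank = "order",
                      threshold = threshold)$per_sample
  P <- presence_matrix(x, "genus", threshold)
  snb_genus$mean_alpha <- vapply(snb_genus$taxon, function(tx) {
    if (!tx %in% rownames(P)) return(NA_real_)
    ids <- intersect(colnames(P)[P[tx, ]], names(alpha))
    if (!length(ids)) return(NA_real_)
    mean(alpha[ids])
  }, 0)
  snb_genus
}

#' One-tailed t-test on coding density between strategy groups
#'
#' Tests whether coding density (coding sequences per base pair) is lower in
#' low-diversity specialists than in social generalists: a one-tailed
#' two-sample t-test with alternative "specialists < generalists". Welch's
#' unequal-variance form is the default; Student's pooled form is available
#' via `var_equal`.
#'
#' @param specialists,generalists numeric vectors of coding density per
#'   genus (each of length >= 2).
#' @param var_equal use the pooled-variance Student test, default `FALSE`.
#' @return `htest` object from [stats::t.test()].
#' @export
coding_density_test <- function(specialists, generalists,
                                var_equal = FALSE) {
  if (length(specialists) < 2L || length(generalists) < 2L)
    stop("both groups need at least 2 values", call. = FALSE)
  t.test(specialists, generalists, alternative = "less",
         var.equal = var_equal)
}
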