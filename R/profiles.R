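#' Construct a taxonomic profile
#'
#' A taxonomic profile holds the read counts of one sample, keyed by canonical
#' lineage string (see [lineage_string()]). Counts are reads assigned to the
#' terminal (deepest classified) taxon of each lineage; a high-ranking taxon's
#' total therefore is the sum over all entries sharing its path prefix.
#'
#' @param sample_id sample identifier.
#' @param counts named numeric vector of read counts (names are lineage
#'   strings); zero counts are dropped.
#' @param total_reads total prokaryotic reads; defaults to `sum(counts)`.
#' @return object of class `taxonomic_profile`.
#' @export
taxonomic_profile <- function(sample_id, counts, total_reads = sum(counts)) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be named by lineage string", call. = FALSE)
  counts <- counts[counts > 0]
  if (anyDuplicated(names(counts)))
    counts <- tapply(counts, names(counts), sum)[unique(names(counts))]
  structure(list(sample_id = as.character(sample_id),
                 counts = counts,
                 total_reads = as.numeric(total_reads)),
            class = "taxonomic_profile")
}

#' @export
print.taxonomic_profile <- function(x, ...) {
  cat("<taxonomic_profile> sample", x$sample_id, "-",
      length(x$counts), "lineages,", x$total_reads, "reads\n")
  invisible(x)
}

#' Bundle taxonomic profiles with sample metadata
#'
#' @param profiles list of [taxonomic_profile()] objects with unique sample
#'   ids.
#' @param metadata data frame with at least `sample_id` and `biome`;
#'   `experiment_type` defaults to `"unknown"`. If `NULL`, minimal metadata is
#'   created. Columns `n_annotated_reads` (reads classified at superkingdom,
#'   before cleaning) and `fraction_eukaryotic` are computed from the
#'   profiles when absent; they drive [select_samples()].
#' @return object of class `profile_collection`.
#' @export
profile_collection <- function(profiles, metadata = NULL) {
  ids <- vapply(profiles, function(p) p$sample_id, "")
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ", paste(unique(ids[duplicated(ids)]),
                                         collapse = ", "), call. = FALSE)
  names(profiles) <- ids
  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = ids, biome = "root:Unknown",
                           experiment_type = "unknown",
                           stringsAsFactors = FALSE)
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (!all(ids %in% metadata$sample_id))
    stop("metadata missing for samples: ",
         paste(setdiff(ids, metadata$sample_id), collapse = ", "),
         call. = FALSE)
  metadata <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  if (is.null(metadata$experiment_type)) metadata$experiment_type <- "unknown"
  if (is.null(metadata$n_annotated_reads) ||
      is.null(metadata$fraction_eukaryotic)) {
    stats <- lapply(profiles, function(p) {
      L <- parse_lineage(names(p$counts))
      sk <- L[, "superkingdom"]
      ann <- sum(p$counts[!is.na(sk)])
      euk <- sum(p$counts[!is.na(sk) & sk == "Eukaryota"])
      c(ann = ann, euk = euk)
    })
    ann <- vapply(stats, `[[`, 0, "ann")
    if (is.null(metadata$n_annotated_reads))
      metadata$n_annotated_reads <- unname(ann)
    if (is.null(metadata$fraction_eukaryotic))
      metadata$fraction_eukaryotic <-
        unname(ifelse(ann > 0, vapply(stats, `[[`, 0, "euk") / ann, 0))
  }
  structure(list(profiles = profiles, metadata = metadata),
            class = "profile_collection")
}

#' @export
print.profile_collection <- function(x, ...) {
  cat("<profile_collection>", length(x$profiles), "samples,",
      length(unique(x$metadata$biome)), "biomes\n")
  invisible(x)
}

#' @export
length.profile_collection <- function(x) length(x$profiles)

#' Sample ids of a collection
#' @param x a `profile_collection`.
#' @return character vector of sample ids.
#' @export
sample_ids <- function(x) names(x$profiles)

#' Subset a collection to a set of samples
#' @param x a `profile_collection`.
#' @param ids sample ids to keep.
#' @return a `profile_collection` with the requested samples, in `ids` order.
#' @export
subset_samples <- function(x, ids) {
  missing <- setdiff(ids, sample_ids(x))
  if (length(missing))
    stop("unknown sample ids: ", paste(missing, collapse = ", "),
         call. = FALSE)
  profile_collection(x$profiles[ids],
                     x$metadata[match(ids, x$metadata$sample_id), ,
                                drop = FALSE])
}

#' Read taxonomic profiles from a TSV matrix
#'
#' Expects rows = lineages, columns = samples, first column named `lineage`.
#' An optional row whose lineage field is `total_prokaryotic_reads` supplies
#' per-sample totals (mirroring profile tables whose header carries the total
#' prokaryotic read counts); otherwise totals default to column sums. Zero
#' cells are dropped. Lineages lacking a superkingdom classification are
#' parsed but flagged in the `flagged_lineages` attribute (with their row
#' numbers) for [clean_profiles()].
#'
#' @param path path to the TSV file.
#' @param metadata optional data frame passed to [profile_collection()], or a
#'   path read with [read_sample_metadata()].
#' @param delim lineage rank delimiter, default `";"`.
#' @return a `profile_collection`.
#' @export
read_profiles <- function(path, metadata = NULL, delim = ";") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- tryCatch(
    read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse profile table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!nrow(tab) || ncol(tab) < 2L)
    stop("profile table '", path,
         "' is empty or lacks sample columns", call. = FALSE)
  lin <- as.character(tab[[1L]])
  samples <- colnames(tab)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample ids in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  tot_row <- which(lin == "total_prokaryotic_reads")
  totals <- NULL
  if (length(tot_row)) {
    totals <- as.numeric(tab[tot_row[1L], -1L])
    tab <- tab[-tot_row, , drop = FALSE]
    lin <- lin[-tot_row]
  }
  L <- parse_lineage(lin, delim = delim)
  flagged <- which(is.na(L[, "superkingdom"]))
  canon <- lineage_string(L)
  profiles <- lapply(seq_along(samples), function(j) {
    cnt <- as.numeric(tab[[j + 1L]])
    cnt[is.na(cnt)] <- 0
    keep <- cnt > 0
    taxonomic_profile(samples[j], setNames(cnt[keep], canon[keep]),
                      total_reads = if (is.null(totals)) sum(cnt[keep])
                                    else totals[j])
  })
  if (is.character(metadata)) metadata <- read_sample_metadata(metadata)
  out <- profile_collection(profiles, metadata)
  attr(out, "flagged_lineages") <-
    if (length(flagged)) setNames(flagged, lin[flagged]) else integer(0)
  out
}

#' Read sample metadata from a TSV file
#'
#' @param path TSV with columns `sample_id`, `biome` and optionally
#'   `experiment_type`, `n_annotated_reads`, `fraction_eukaryotic`.
#' @return data frame.
#' @export
read_sample_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  if (is.null(md$sample_id) || is.null(md$biome))
    stop("metadata must have sample_id and biome columns", call. = FALSE)
  md
}

#' Remove non-prokaryotic and unclassified-superkingdom entries
#'
#' Drops entries classified as Eukaryota, entries whose lineage names a
#' mitochondrion or chloroplast at any rank, and entries with no
#' superkingdom classification; total prokaryotic reads are recomputed.
#'
#' @param p a [taxonomic_profile()].
#' @return cleaned `taxonomic_profile`. If nothing survives, a warning of
#'   class `snb_empty_sample` is signalled and an empty profile returned.
#' @export
clean_profile <- function(p) {
  L <- parse_lineage(names(p$counts))
  organelle <- apply(L, 1L, function(r)
    any(grepl("mitochondri|chloroplast", r, ignore.case = TRUE), na.rm = TRUE))
  keep <- !is.na(L[, "superkingdom"]) &
    L[, "superkingdom"] != "Eukaryota" & !organelle
  counts <- p$counts[keep]
  if (!length(counts))
    warning(warningCondition(
      paste0("sample ", p$sample_id, " is empty after cleaning"),
      class = "snb_empty_sample"))
  taxonomic_profile(p$sample_id,
                    if (length(counts)) counts else
                      setNames(numeric(0), character(0))[0],
                    total_reads = sum(counts))
}

#' Clean every profile of a collection
#'
#' Applies [clean_profile()] to each sample; samples left empty are removed
#' with a message. Cleaning is idempotent.
#'
#' @param x a `profile_collection`.
#' @return cleaned `profile_collection`.
#' @export
clean_profiles <- function(x) {
  cleaned <- lapply(x$profiles, function(p)
    withCallingHandlers(clean_profile(p),
                        snb_empty_sample = function(w)
                          invokeRestart("muffleWarning")))
  empty <- vapply(cleaned, function(p) length(p$counts) == 0L, TRUE)
  if (any(empty))
    message("removed ", sum(empty), " sample(s) empty after cleaning: ",
            paste(names(cleaned)[empty], collapse = ", "))
  profile_collection(cleaned[!empty],
                     x$metadata[!empty, , drop = FALSE])
}

#' Filter and subsample a collection the way the study selected samples
#'
#' Keeps samples with at least `min_reads` reads annotated at superkingdom
#' and strictly less than `max_euk` of those classified as eukaryotic, then
#' caps each annotated biome at `per_biome_cap` samples by uniform random
#' subsampling. Sample ids are sorted before drawing so the selection is
#' reproducible given the seed regardless of input order.
#'
#' @param x a `profile_collection` (metadata must carry `n_annotated_reads`
#'   and `fraction_eukaryotic`; both are filled automatically at
#'   construction).
#' @param min_reads minimum annotated reads, default 50000.
#' @param max_euk maximum eukaryotic read fraction (exclusive), default 0.10.
#' @param per_biome_cap maximum samples per biome, default 1000; `Inf`
#'   disables capping (then no randomness is used).
#' @param seed integer seed for the biome subsampling.
#' @return filtered `profile_collection`.
#' @export
select_samples <- function(x, min_reads = 50000, max_euk = 0.10,
                           per_biome_cap = 1000, seed = 1L) {
  md <- x$metadata
  keep <- md$n_annotated_reads >= min_reads & md$fraction_eukaryotic < max_euk
  ids <- md$sample_id[keep]
  biomes <- md$biome[keep]
  if (is.finite(per_biome_cap)) {
    picked <- with_seed(seed, {
      unlist(lapply(sort(unique(biomes)), function(b) {
        bi <- sort(ids[biomes == b])
        if (length(bi) > per_biome_cap) sample(bi, per_biome_cap) else bi
      }), use.names = FALSE)
    })
    ids <- ids[ids %in% picked]
  }
  subset_samples(x, ids)
}
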