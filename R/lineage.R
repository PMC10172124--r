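#' Taxonomic ranks used throughout the package
#'
#' The seven ranks of the reference taxonomy, ordered from superkingdom to
#' species. All rank arguments in the package must be one of these.
#'
#' @export
TAX_RANKS <- c("superkingdom", "phylum", "class", "order", "family",
               "genus", "species")

rank_index <- function(rank) {
  i <- match(rank, TAX_RANKS)
  if (is.na(i)) stop("unknown taxonomic rank: ", rank, call. = FALSE)
  i
}

#' Parse lineage strings into a rank matrix
#'
#' Accepts two dialects: prefixed MGnify-style lineages
#' (`"sk__Bacteria;p__Proteobacteria;..."`, with `sk`/`k`/`d` mapping to
#' superkingdom) and plain positional paths (`"Bacteria;Proteobacteria"`).
#' Unnamed (unclassified) ranks are encoded as `NA`, never as empty-string
#' taxa. A leading `root` token is dropped.
#'
#' @param x character vector of lineage strings.
#' @param delim field delimiter between ranks, default `";"`.
#' @return character matrix with one row per input string and the seven
#'   columns of [TAX_RANKS]; `NA` where a rank is unclassified.
#' @export
parse_lineage <- function(x, delim = ";") {
  x <- as.character(x)
  out <- matrix(NA_character_, length(x), 7L,
                dimnames = list(names(x), TAX_RANKS))
  if (!length(x)) return(out)
  prefix_map <- c(sk = 1L, k = 1L, d = 1L, p = 2L, c = 3L, o = 4L,
                  f = 5L, g = 6L, s = 7L)
  parts <- strsplit(x, delim, fixed = TRUE)
  for (i in seq_along(parts)) {
    toks <- trimws(parts[[i]])
    if (length(toks) && tolower(toks[1]) == "root") toks <- toks[-1]
    if (!length(toks)) next
    m <- regmatches(toks, regexec("^([a-z]{1,2})__(.*)$", toks))
    prefixed <- vapply(m, length, 0L) == 3L
    if (any(prefixed)) {
      for (j in which(prefixed)) {
        ri <- prefix_map[m[[j]][2]]
        if (!is.na(ri) && nzchar(m[[j]][3])) out[i, ri] <- m[[j]][3]
      }
    } else {
      n <- min(length(toks), 7L)
      vals <- toks[seq_len(n)]
      vals[!nzchar(vals)] <- NA_character_
      out[i, seq_len(n)] <- vals
    }
  }
  out
}

#' Canonical lineage strings from a rank matrix
#'
#' Inverse of [parse_lineage()] for the plain dialect: ranks joined by `";"`,
#' internal unclassified ranks kept as empty fields, trailing unclassified
#' ranks dropped.
#'
#' @param mat character matrix as returned by [parse_lineage()].
#' @return character vector of canonical lineage strings.
#' @export
lineage_string <- function(mat) {
  apply(mat, 1L, function(r) {
    named <- which(!is.na(r) & nzchar(r))
    if (!length(named)) return("")
    r <- r[seq_len(max(named))]
    r[is.na(r)] <- ""
    paste(r, collapse = ";")
  })
}

deepest_rank <- function(mat) {
  apply(mat, 1L, function(r) {
    named <- which(!is.na(r) & nzchar(r))
    if (!length(named)) 0L else max(named)
  })
}

# Path key of a lineage up to rank index ri (inclusive); NA internal ranks
# become empty fields. Used as the taxon identity at that rank.
path_to_rank <- function(mat, ri) {
  sub <- mat[, seq_len(ri), drop = FALSE]
  sub[is.na(sub)] <- ""
  apply(sub, 1L, paste, collapse = ";")
}
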