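# Independent brute-force oracles. These deliberately avoid the package's
# computation paths: ranks are assigned by sorting, correlations use the
# textbook sum formulas, and the earth-mover distance is solved by direct
# minimum-cost search on enumerated flows.

oracle_rank <- function(x) {
  # average ranks via sorting, no call to rank()
  o <- order(x)
  r <- numeric(length(x))
  i <- 1L
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[o[j + 1L]] == x[o[i]]) j <- j + 1L
    r[o[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - sum(x) / n) * (y - sum(y) / n)) /
    sqrt(sum((x - sum(x) / n)^2) * sum((y - sum(y) / n)^2))
}

oracle_spearman_d <- function(x, y)
  0.5 - oracle_pearson(oracle_rank(x), oracle_rank(y)) / 2

oracle_pearson_d <- function(x, y) 0.5 - oracle_pearson(x, y) / 2

oracle_kendall_d <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[i] - x[j])
    b <- sign(y[i] - y[j])
    if (a == 0 && b == 0) next
    if (a == 0) tx <- tx + 1
    else if (b == 0) ty <- ty + 1
    else if (a == b) conc <- conc + 1
    else disc <- disc + 1
  }
  tau <- (conc - disc) /
    sqrt((conc + disc + tx) * (conc + disc + ty))
  0.5 - tau / 2
}

oracle_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)
oracle_jaccard <- function(x, y)
  1 - sum(x > 0 & y > 0) / sum(x > 0 | y > 0)
oracle_dice <- function(x, y)
  1 - 2 * sum(x > 0 & y > 0) / (sum(x > 0) + sum(y > 0))
oracle_ruzicka <- function(x, y) 1 - sum(pmin(x, y)) / sum(pmax(x, y))

# step-by-step Aitchison: pseudocounts in read units, close, clr, euclid
oracle_aitchison <- function(ca, cb) {
  keys <- union(names(ca), names(cb))
  x <- sapply(keys, function(k) if (k %in% names(ca)) ca[[k]] else 0)
  y <- sapply(keys, function(k) if (k %in% names(cb)) cb[[k]] else 0)
  if (sum(x) >= sum(y)) {
    pseudo_x <- 1; pseudo_y <- sum(y) / sum(x)
  } else {
    pseudo_y <- 1; pseudo_x <- sum(x) / sum(y)
  }
  x <- x + pseudo_x; y <- y + pseudo_y
  px <- x / sum(x); py <- y / sum(y)
  cx <- log(px) - mean(log(px))
  cy <- log(py) - mean(log(py))
  sqrt(sum((cx - cy)^2))
}

# brute-force earth-mover distance between two mass vectors over nodes with
# a full pairwise ground-distance matrix, by LP (enumeration over vertex
# solutions via the transportation simplex is overkill at this size; use a
# fine-grained greedy-exchange search validated by lpSolve-free total
# enumeration on <= 3 sources). For the tiny trees in the tests an exact
# answer comes from the north-west-corner + improvement over all
# permutations of source/sink orderings.
oracle_emd <- function(ma, mb, dist) {
  src <- which(ma > mb + 1e-15)
  snk <- which(mb > ma + 1e-15)
  sup <- ma[src] - mb[src]
  dem <- mb[snk] - ma[snk]
  if (!length(src)) return(0)
  best <- Inf
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  for (ps in perms(seq_along(src))) for (pd in perms(seq_along(snk))) {
    s <- sup[ps]; d <- dem[pd]
    cost <- 0
    i <- j <- 1L
    while (i <= length(s) && j <= length(d)) {
      f <- min(s[i], d[j])
      cost <- cost + f * dist[src[ps[i]], snk[pd[j]]]
      s[i] <- s[i] - f; d[j] <- d[j] - f
      if (s[i] <= 1e-15) i <- i + 1L
      if (j <= length(d) && d[j] <= 1e-15) j <- j + 1L
    }
    best <- min(best, cost)
  }
  best
}

# GSEA running sum computed literally, step by step; an exact magnitude
# tie between the positive and negative extreme reports the positive one
oracle_es <- function(ranked_items, members) {
  hit <- ranked_items %in% members
  nh <- sum(hit)
  nm <- length(ranked_items) - nh
  running <- 0
  top <- bottom <- 0
  for (i in seq_along(ranked_items)) {
    running <- running + if (hit[i]) 1 / nh else -1 / nm
    if (running > top) top <- running
    if (running < bottom) bottom <- running
  }
  if (top >= -bottom) top else bottom
}

# PERMANOVA pseudo-F by direct sum-of-squares decomposition
oracle_permanova_f <- function(D, labels) {
  N <- nrow(D)
  G <- length(unique(labels))
  sst <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) sst <- sst + D[i, j]^2
  sst <- sst / N
  ssw <- 0
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    acc <- 0
    if (length(idx) >= 2)
      for (a in 1:(length(idx) - 1)) for (b in (a + 1):length(idx))
        acc <- acc + D[idx[a], idx[b]]^2
    ssw <- ssw + acc / length(idx)
  }
  ((sst - ssw) / (G - 1)) / (ssw / (N - G))
}
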