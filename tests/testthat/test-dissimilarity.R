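spearman_cfg <- dissim_config("spearman", "order", 2, 5)

test_that("correlation dissimilarities hit their closed-form endpoints", {
  v <- c(0.5, 0.3, 0.2)
  expect_equal(correlation_dissimilarity(v, 2 * v, "spearman"), 0)
  expect_equal(correlation_dissimilarity(v, rev(sort(v)), "spearman"), 0)
  expect_equal(correlation_dissimilarity(c(1, 2, 3), c(9, 5, 1), "spearman"),
               1)
  expect_equal(correlation_dissimilarity(c(1, 2, 3), c(2, 4, 6), "pearson"),
               0)
  # hand-ranked oracle on the spec's example vectors
  v1 <- c(0.5, 0.3, 0.2); v2 <- c(0.2, 0.5, 0.3)
  expect_equal(correlation_dissimilarity(v1, v2, "spearman"),
               oracle_spearman_d(v1, v2), tolerance = 1e-12)
  expect_error(correlation_dissimilarity(c(1, 1, 1), c(1, 2, 3)),
               class = "snb_undefined_correlation")
})

test_that("set measures match their definitions on simple sets", {
  x <- c(0.6, 0.4, 0)
  expect_equal(set_dissimilarity(x, x, "jaccard"), 0)
  expect_equal(set_dissimilarity(x, x, "sorensen_dice"), 0)
  expect_equal(set_dissimilarity(c(1, 0), c(0, 1), "jaccard"), 1)
  expect_equal(set_dissimilarity(c(1, 0), c(0, 1), "bray_curtis"), 1)
  y <- c(0.2, 0.4, 0.4)
  expect_equal(set_dissimilarity(x, y, "bray_curtis"), oracle_bray(x, y))
  expect_error(set_dissimilarity(c(0, 0), c(0, 0), "jaccard"),
               class = "snb_undefined_pair")
})

test_that("Aitchison distance follows the paired-pseudocount recipe", {
  ca <- c(A = 150, B = 50)
  cb <- c(A = 60, B = 40)
  # N1 = 200 >= N2 = 100: +1 read in a, +0.5 reads in b
  expect_equal(aitchison_distance(ca, cb), oracle_aitchison(ca, cb),
               tolerance = 1e-12)
  expect_equal(aitchison_distance(ca, cb), aitchison_distance(cb, ca))
  expect_equal(aitchison_distance(ca, ca), 0)
  # manual recomputation of the same example, fully spelled out
  a <- c(151, 51); b <- c(60.5, 40.5)
  clr <- function(v) log(v / sum(v)) - mean(log(v / sum(v)))
  expect_equal(aitchison_distance(ca, cb),
               sqrt(sum((clr(a) - clr(b))^2)), tolerance = 1e-12)
})

test_that("pair alignment zero-fills and approach 3 removes shared fallbacks", {
  pa <- make_profile("a", c("Bacteria;P;C;O1" = 80, "Bacteria;P" = 20))
  pb <- make_profile("b", c("Bacteria;P;C;O2" = 50, "Bacteria;P" = 30))
  cfg1 <- dissim_config("spearman", "order", 1)
  r1a <- project_to_rank(pa, "order", 1)
  r1b <- project_to_rank(pb, "order", 1)
  al1 <- align_pair(r1a, r1b, cfg1)
  expect_true("from-above:Bacteria;P" %in% al1$keys)
  cfg3 <- dissim_config("spearman", "order", 3)
  r3a <- project_to_rank(pa, "order", 3)
  r3b <- project_to_rank(pb, "order", 3)
  al3 <- align_pair(r3a, r3b, cfg3)
  expect_false("from-above:Bacteria;P" %in% al3$keys)
  # disjoint sets produce complementary zeros
  expect_equal(unname(al3$ca[al3$keys == "Bacteria;P;C;O2"]), 0)
  expect_equal(unname(al3$cb[al3$keys == "Bacteria;P;C;O1"]), 0)
  # identical profiles align to identical vectors
  ali <- align_pair(r1a, r1a, cfg1)
  expect_identical(ali$ra, ali$rb)
})

test_that("every measure matches its brute-force oracle on random pairs", {
  oracles <- list(
    spearman = function(x, y) oracle_spearman_d(x, y),
    pearson = function(x, y) oracle_pearson_d(x, y),
    kendall_tau_b = function(x, y) oracle_kendall_d(x, y),
    bray_curtis = oracle_bray,
    jaccard = oracle_jaccard,
    sorensen_dice = oracle_dice,
    weighted_jaccard = oracle_ruzicka)
  for (seed in 1:25) {
    pr <- random_pair(seed)
    x <- profile_collection(list(pr$a, pr$b))
    ra <- project_to_rank(pr$a, "order", 2)
    rb <- project_to_rank(pr$b, "order", 2)
    al <- align_pair(ra, rb, spearman_cfg)
    for (m in names(oracles)) {
      d_pkg <- pairwise_matrix(x, dissim_config(m, "order", 2, 5))["a", "b"]
      d_or <- if (length(al$keys) == 1) 0 else oracles[[m]](al$ra, al$rb)
      expect_equal(d_pkg, d_or, tolerance = 1e-9,
                   label = paste(m, "seed", seed))
    }
    d_pkg <- pairwise_matrix(x, dissim_config("aitchison", "order", 2,
                                              5))["a", "b"]
    d_or <- if (length(al$keys) == 1) 0 else
      oracle_aitchison(ra$counts, rb$counts)
    expect_equal(d_pkg, d_or, tolerance = 1e-9,
                 label = paste("aitchison seed", seed))
  }
})

test_that("dissimilarity matrices are symmetric, zero-diagonal and bounded", {
  fx <- clean_profiles(worked_fixture())
  for (m in c("spearman", "pearson", "kendall_tau_b", "bray_curtis",
              "jaccard", "sorensen_dice", "weighted_jaccard", "aitchison")) {
    D <- pairwise_matrix(fx, dissim_config(m, "order", 2, 5))
    expect_identical(unclass(D), t(unclass(D)), label = m)
    expect_true(all(diag(D) == 0), label = m)
    expect_true(all(D >= 0), label = m)
    if (m != "aitchison") expect_true(all(D <= 1), label = m)
  }
})

test_that("three identical samples give an all-zero matrix", {
  cnt <- c("Bacteria;P;C;O1" = 70, "Bacteria;P;C;O2" = 30)
  x <- profile_collection(lapply(c("a", "b", "c"), make_profile, cnt))
  D <- pairwise_matrix(x, spearman_cfg)
  expect_true(all(D == 0))
})

test_that("pairs sharing exactly one union taxon are forced to zero", {
  x <- profile_collection(list(
    make_profile("a", c("Bacteria;P;C;O1" = 100)),
    make_profile("b", c("Bacteria;P;C;O1" = 55)),
    make_profile("c", c("Bacteria;P;C;O1" = 10, "Bacteria;P;C;O2" = 90))))
  D <- pairwise_matrix(x, dissim_config("bray_curtis", "order", 2, 5))
  expect_equal(D["a", "b"], 0)
  expect_gt(D["a", "c"], 0)
})

test_that("constant rank profiles are removed for correlation measures only", {
  x <- profile_collection(list(
    make_profile("flat", c("Bacteria;P;C;O1" = 50, "Bacteria;P;C;O2" = 50)),
    make_profile("a", c("Bacteria;P;C;O1" = 80, "Bacteria;P;C;O2" = 20)),
    make_profile("b", c("Bacteria;P;C;O1" = 30, "Bacteria;P;C;O2" = 70))))
  Ds <- pairwise_matrix(x, spearman_cfg)
  expect_false("flat" %in% rownames(Ds))
  expect_equal(unname(attr(Ds, "removed_samples")["flat"]),
               "constant-profile")
  Db <- pairwise_matrix(x, dissim_config("bray_curtis", "order", 2, 5))
  expect_true("flat" %in% rownames(Db))
})

test_that("spearman dissimilarity is invariant to monotone transforms and relabeling", {
  for (seed in 1:5) {
    pr <- random_pair(seed)
    ra <- project_to_rank(pr$a, "order", 2)
    rb <- project_to_rank(pr$b, "order", 2)
    al <- align_pair(ra, rb, spearman_cfg)
    if (length(al$keys) < 3 || sd(al$ra) == 0 || sd(al$rb) == 0) next
    d0 <- correlation_dissimilarity(al$ra, al$rb, "spearman")
    expect_equal(correlation_dissimilarity(al$ra^3, al$rb, "spearman"), d0)
    expect_equal(correlation_dissimilarity(al$ra, log1p(al$rb), "spearman"),
                 d0)
    # consistent relabeling of taxa in both samples
    perm <- sample(seq_along(al$keys))
    expect_equal(correlation_dissimilarity(al$ra[perm], al$rb[perm],
                                           "spearman"), d0)
  }
})

test_that("approach 1 and approach 2 agree on fully classified data", {
  fx <- clean_profiles(worked_fixture())
  D1 <- pairwise_matrix(fx, dissim_config("spearman", "order", 1))
  D2 <- pairwise_matrix(fx, dissim_config("spearman", "order", 2))
  expect_equal(unclass(D1), unclass(D2), ignore_attr = TRUE)
})

test_that("matrix TSV export round-trips", {
  fx <- clean_profiles(worked_fixture())
  D <- pairwise_matrix(fx, spearman_cfg)
  path <- tempfile(fileext = ".tsv")
  write_dissim_matrix(D, path)
  back <- read.delim(path, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), unclass(D),
               ignore_attr = TRUE, tolerance = 1e-12)
})
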