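test_that("lineage parsing handles both dialects and round-trips", {
  L <- parse_lineage(c("sk__Bacteria;p__Proteobacteria;c__;o__Rhizobiales",
                       "Bacteria;Firmicutes",
                       "Root;sk__Archaea",
                       ""))
  expect_equal(unname(L[1, c("superkingdom", "phylum", "order")]),
               c("Bacteria", "Proteobacteria", "Rhizobiales"))
  expect_true(is.na(L[1, "class"]))
  expect_equal(unname(L[2, 1:2]), c("Bacteria", "Firmicutes"))
  expect_equal(unname(L[3, 1]), "Archaea")
  expect_true(all(is.na(L[4, ])))
  expect_equal(lineage_string(L)[2], "Bacteria;Firmicutes")
  # internal unclassified rank survives as an empty field, not a taxon
  L2 <- parse_lineage("Bacteria;;ClsX")
  expect_equal(lineage_string(L2), "Bacteria;;ClsX")
  expect_true(is.na(L2[1, "phylum"]))
})

test_that("profile TSV reading round-trips counts and flags bad lineages", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("lineage\tsA\tsB",
               "total_prokaryotic_reads\t1000\t600",
               "Bacteria;PhyA;ClsA;Ord1\t700\t100",
               "Bacteria;PhyA;ClsA;Ord2\t300\t500",
               "NoRankHere\t0\t0"), tsv)
  # note: the flagged lineage has zero counts everywhere but is still
  # reported with its row number
  x <- read_profiles(tsv)
  expect_s3_class(x, "profile_collection")
  expect_equal(length(x), 2L)
  expect_equal(unname(x$profiles$sA$counts["Bacteria;PhyA;ClsA;Ord1"]), 700)
  expect_equal(x$profiles$sB$total_reads, 600)
  expect_equal(length(attr(x, "flagged_lineages")), 0L)

  writeLines(c("lineage\tsA", ";;MysteryClass\t50",
               "Bacteria\t100"), tsv)
  x2 <- read_profiles(tsv)
  expect_equal(length(attr(x2, "flagged_lineages")), 1L)

  writeLines(character(0), tsv)
  expect_error(read_profiles(tsv), "empty|parse")

  writeLines(c("lineage\tsA\tsA", "Bacteria\t1\t2"), tsv)
  expect_error(read_profiles(tsv), "duplicate")
})

test_that("cleaning removes non-prokaryotic entries and is idempotent", {
  p <- make_profile("s", c("Bacteria" = 900, "Eukaryota;Ascomycota" = 100))
  cp <- clean_profile(p)
  expect_equal(unname(cp$counts), 900)
  expect_equal(cp$total_reads, 900)
  # chloroplast under Bacteria/Cyanobacteria is removed
  p2 <- make_profile("s", c("Bacteria;Cyanobacteria;Chloroplast" = 50,
                            "Bacteria;Cyanobacteria;ClsX" = 150,
                            ";UnknownPhylum" = 30))
  cp2 <- clean_profile(p2)
  expect_equal(names(cp2$counts), "Bacteria;Cyanobacteria;ClsX")
  # all-prokaryotic profiles are untouched; cleaning twice changes nothing
  p3 <- make_profile("s", c("Archaea;Euryarchaeota" = 10, "Bacteria" = 20))
  expect_equal(clean_profile(p3)$counts, p3$counts)
  expect_equal(clean_profile(clean_profile(p2))$counts, cp2$counts)
  # empty-after-cleaning signals a typed condition
  expect_warning(clean_profile(make_profile("s", c("Eukaryota" = 5))),
                 class = "snb_empty_sample")
})

test_that("sample selection applies read and eukaryotic filters at the stated boundaries", {
  mk <- function(sid, n_bact, n_euk) {
    taxonomic_profile(sid, setNames(c(n_bact, n_euk),
                                    c("Bacteria", "Eukaryota"))[
                                      c(n_bact, n_euk) > 0])
  }
  x <- profile_collection(list(mk("a", 49999, 0), mk("b", 50000, 0),
                               mk("c", 60000, 0), mk("d", 88000, 12000)))
  sel <- select_samples(x, min_reads = 50000, max_euk = 0.10, seed = 1)
  # 49999 fails the inclusive >= 50000 floor; 12% eukaryotic fails < 10%
  expect_setequal(sample_ids(sel), c("b", "c"))
})

test_that("per-biome capping is seeded, reproducible and order-independent", {
  profiles <- lapply(sprintf("s%03d", 1:60), function(sid)
    taxonomic_profile(sid, c("Bacteria" = 60000)))
  md <- data.frame(sample_id = sprintf("s%03d", 1:60), biome = "root:One")
  x <- profile_collection(profiles, md)
  s1 <- select_samples(x, per_biome_cap = 40, seed = 11)
  s2 <- select_samples(x, per_biome_cap = 40, seed = 11)
  expect_equal(length(s1), 40L)
  expect_identical(sample_ids(s1), sample_ids(s2))
  # shuffled input order gives the same selected set
  xs <- profile_collection(profiles[rev(seq_along(profiles))],
                           md[rev(seq_len(nrow(md))), ])
  s3 <- select_samples(xs, per_biome_cap = 40, seed = 11)
  expect_setequal(sample_ids(s1), sample_ids(s3))
  # different seed gives a different subset, uncapped selection is
  # deterministic regardless of seed
  s4 <- select_samples(x, per_biome_cap = 40, seed = 12)
  expect_false(identical(sort(sample_ids(s1)), sort(sample_ids(s4))))
  expect_equal(length(select_samples(x, per_biome_cap = Inf, seed = 99)),
               60L)
})

test_that("rank projection implements the three unknown-handling approaches", {
  p <- make_profile("s", c(
    "Bacteria;PhyA;ClsA;Ord1;FamX" = 100,  # classified at order
    "Bacteria;PhyA;ClsA;Ord1;FamY" = 50,   # same order, other family
    "Bacteria;PhyA;ClsA;;FamZ" = 30,       # order unknown, family known
    "Bacteria;PhyA" = 20,                  # only high-rank classification
    "Bacteria;PhyA;ClsA;Ord2" = 4))        # below the 5-read floor
  r2 <- project_to_rank(p, "order", approach = 2)
  expect_equal(sort(names(r2$counts)), "Bacteria;PhyA;ClsA;Ord1")
  expect_equal(unname(r2$counts), 150)  # summed over sub-lineages
  r1 <- project_to_rank(p, "order", approach = 1)
  expect_setequal(names(r1$counts),
                  c("Bacteria;PhyA;ClsA;Ord1",
                    "from-below:Bacteria;PhyA;ClsA;;FamZ",
                    "from-above:Bacteria;PhyA"))
  expect_equal(unname(r1$tags["from-above:Bacteria;PhyA"]), "from-above")
  r3 <- project_to_rank(p, "order", approach = 3)
  expect_identical(sort(names(r3$counts)), sort(names(r1$counts)))
  # min_reads boundary: 4 reads at the rank are removed, 5 kept
  p5 <- make_profile("s", c("Bacteria;PhyA;ClsA;Ord9" = 5))
  expect_equal(unname(project_to_rank(p5, "order", 2)$counts), 5)
  # fully classified profile: approach 2 keeps every read
  pf <- make_profile("s", c("Bacteria;PhyA;ClsA;Ord1;Fam1;Gen1;Sp1" = 10,
                            "Bacteria;PhyA;ClsA;Ord2;Fam2;Gen2;Sp2" = 20))
  expect_equal(sum(project_to_rank(pf, "order", 2)$counts), 30)
})

test_that("strict projection never exceeds the profile's prokaryotic total", {
  for (seed in 1:10) {
    pr <- random_pair(seed)$a
    rp <- project_to_rank(pr, "order", approach = 2, min_reads = 5)
    expect_lte(sum(rp$counts), pr$total_reads)
  }
})
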