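mk_genomes <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(genome_id = r$id, lineage = r$lin,
               completeness = r$comp, contamination = r$cont,
               size_bp = r$size, n_cds = r$cds,
               stringsAsFactors = FALSE)))
  read_genomes(df)
}

test_that("quality filter applies the completeness - 5x contamination rule", {
  g <- mk_genomes(
    list(id = "g1", lin = "Bacteria;P;C;O;F;G;S1", comp = 90, cont = 4,
         size = 4e6, cds = 4000),   # 90 - 20 = 70: boundary, retained
    list(id = "g2", lin = "Bacteria;P;C;O;F;G;S1", comp = 80, cont = 3,
         size = 4e6, cds = 4000),   # 65: excluded
    list(id = "g3", lin = "Bacteria;P;C;O;F;G;S1", comp = 100, cont = 0,
         size = 4e6, cds = 4000),
    list(id = "g4", lin = "Bacteria;P;C;O;F;G;S1", comp = NA, cont = 1,
         size = 4e6, cds = 4000))
  out <- quality_filter(g)
  expect_setequal(out$genome_id, c("g1", "g3"))
  rej <- attr(out, "rejected")
  expect_equal(rej$reason[rej$genome_id == "g4"], "missing-quality-fields")
})

test_that("size correction scales by 100 / (completeness + contamination)", {
  g <- mk_genomes(
    list(id = "g1", lin = "Bacteria;P;C;O;F;G;S1", comp = 100, cont = 0,
         size = 2e6, cds = 2000),
    list(id = "g2", lin = "Bacteria;P;C;O;F;G;S1", comp = 50, cont = 0,
         size = 2e6, cds = 2000),
    list(id = "g3", lin = "Bacteria;P;C;O;F;G;S1", comp = 90, cont = 10,
         size = 2e6, cds = 2000))
  out <- corrected_size(g)
  expect_equal(out$size_bp_corrected, c(2e6, 4e6, 2e6))
  expect_equal(out$n_cds_corrected, c(2000, 4000, 2000))
  g0 <- mk_genomes(list(id = "g0", lin = "Bacteria;P;C;O;F;G;S1",
                        comp = 0, cont = 0, size = 1e6, cds = 1000))
  expect_error(corrected_size(g0), "zero")
})

test_that("species function sets follow the inclusive majority rule", {
  lin <- "Bacteria;P;C;O;F;G;S1"
  g <- mk_genomes(list(id = "a", lin = lin, comp = 95, cont = 1,
                       size = 4e6, cds = 4000),
                  list(id = "b", lin = lin, comp = 95, cont = 1,
                       size = 4e6, cds = 4000))
  fn <- data.frame(
    genome_id = c("a", "b", "a"),
    universe = "subsystem_subclass",
    function_id = c("shared", "shared", "only_a"))
  prof <- species_functional_profile(g, fn, "subsystem_subclass")
  # 1 of 2 genomes = 50%: inclusive, kept
  expect_setequal(prof$sets[[lin]], c("shared", "only_a"))
  # 1 of 3 genomes: dropped
  g3 <- rbind(g, mk_genomes(list(id = "c", lin = lin, comp = 95, cont = 1,
                                 size = 4e6, cds = 4000)))
  fn3 <- rbind(fn, data.frame(genome_id = "c",
                              universe = "subsystem_subclass",
                              function_id = "shared"))
  prof3 <- species_functional_profile(g3, fn3, "subsystem_subclass")
  expect_equal(prof3$sets[[lin]], "shared")
  # single genome: species set equals the genome set
  g1 <- g[1, ]
  prof1 <- species_functional_profile(g1, fn[fn$genome_id == "a", ],
                                      "subsystem_subclass")
  expect_setequal(prof1$sets[[lin]], c("shared", "only_a"))
})

test_that("sparse genomes are discarded except for subsystem subclasses", {
  lin <- "Bacteria;P;C;O;F;G;S1"
  g <- mk_genomes(list(id = "rich", lin = lin, comp = 95, cont = 1,
                       size = 4e6, cds = 4000),
                  list(id = "sparse", lin = lin, comp = 95, cont = 1,
                       size = 4e6, cds = 4000))
  fn <- rbind(
    data.frame(genome_id = "rich", universe = "pathway",
               function_id = sprintf("p%d", 1:25)),
    data.frame(genome_id = "sparse", universe = "pathway",
               function_id = sprintf("p%d", 1:20)),
    data.frame(genome_id = "rich", universe = "subsystem_subclass",
               function_id = sprintf("s%d", 1:10)),
    data.frame(genome_id = "sparse", universe = "subsystem_subclass",
               function_id = sprintf("s%d", 1:10)))
  # pathway universe: the 20-function genome is discarded, so the species
  # profile rests on the rich genome alone
  pw <- species_functional_profile(g, fn, "pathway")
  expect_equal(pw$table$n_genomes, 1L)
  expect_equal(pw$table$functional_size, 25L)
  # subsystem_subclass: no discard
  sc <- species_functional_profile(g, fn, "subsystem_subclass")
  expect_equal(sc$table$n_genomes, 2L)
})

test_that("taxon aggregation: plain vs taxonomy-corrected means", {
  # family with genus A (1 species, size 2) and genus B (3 species, size 4)
  sp <- data.frame(
    lineage = sprintf("Bacteria;P;C;O;FamX;%s;S%d",
                      c("GenA", "GenB", "GenB", "GenB"), 1:4),
    val = c(2, 4, 4, 4))
  sp <- cbind(sp, as.data.frame(parse_lineage(sp$lineage)))
  plain <- taxon_aggregate(sp, "family", "val")
  expect_equal(plain$mean_val, 3.5)
  expect_equal(plain$n_species, 4L)
  corr <- taxon_aggregate(sp, "family", "val", taxonomy_corrected = TRUE)
  expect_equal(corr$mean_val, 3.0)  # mean(mean(2), mean(4,4,4))
  # genus of one species: both modes return the species value
  one <- sp[1, ]
  expect_equal(taxon_aggregate(one, "genus", "val")$mean_val, 2)
  expect_equal(taxon_aggregate(one, "genus", "val", TRUE)$mean_val, 2)
  # identical species values have sd 0
  expect_equal(taxon_aggregate(sp[2:4, ], "genus", "val")$sd_val, 0)
})

test_that("pan-genome size and openness hit their closed forms", {
  same <- replicate(4, sprintf("f%d", 1:50), simplify = FALSE)
  pg <- pan_genome(same, "all")
  expect_equal(pg$openness, 1)
  expect_equal(pg$pan_size, 50)
  # pairwise-disjoint equal-size sets: openness = k
  disj <- lapply(0:3, function(i) sprintf("f%d", i * 50 + 1:50))
  pgd <- pan_genome(disj, "all")
  expect_equal(pgd$openness, 4)
  expect_equal(pgd$pan_size, 200)
})

test_that("permuted 3-species pan-genome matches exhaustive enumeration", {
  set.seed(77)
  sets <- lapply(1:5, function(i)
    unique(c(sprintf("core%d", 1:30),
             sample(sprintf("acc%d", 1:60), 25))))
  exact <- combn(5, 3, function(idx) {
    sub <- sets[idx]
    pan <- length(unique(unlist(sub)))
    c(pan, pan / mean(lengths(sub)))
  })
  res <- pan_genome(sets, "permuted_3", n_perm = 4000, seed = 3)
  expect_equal(res$pan_size, mean(exact[1, ]), tolerance = 0.02)
  expect_equal(res$openness, mean(exact[2, ]), tolerance = 0.02)
  # determinism and the <3-species sentinel
  res2 <- pan_genome(sets, "permuted_3", n_perm = 4000, seed = 3)
  expect_identical(res, res2)
  expect_true(is.na(pan_genome(sets[1:2], "permuted_3")$openness))
  # permuted openness cannot exceed the all-species openness here
  expect_lte(res$openness, pan_genome(sets, "all")$openness)
})

test_that("growth rates aggregate species-first", {
  g <- mk_genomes(
    list(id = "a1", lin = "Bacteria;P;C;O;F;GenZ;S1", comp = 95, cont = 0,
         size = 4e6, cds = 4000),
    list(id = "a2", lin = "Bacteria;P;C;O;F;GenZ;S1", comp = 95, cont = 0,
         size = 4e6, cds = 4000),
    list(id = "b1", lin = "Bacteria;P;C;O;F;GenZ;S2", comp = 95, cont = 0,
         size = 4e6, cds = 4000))
  g$growth_rate <- c(1, 3, 4)
  res <- growth_rate_aggregate(g)
  # species S1 mean (1+3)/2 = 2; genus mean of species means (2+4)/2 = 3
  expect_equal(sort(res$species$growth_rate), c(2, 4))
  expect_equal(res$genus$growth_rate, 3)
  # pooled variant averages genomes directly: (1+3+4)/3
  expect_equal(growth_rate_aggregate(g, "pooled")$genus$growth_rate,
               8 / 3)
})

test_that("duplicate genome records are collapsed with a warning", {
  g <- mk_genomes(
    list(id = "a", lin = "Bacteria;P;C;O;F;G;S1", comp = 95, cont = 0,
         size = 4e6, cds = 4000),
    list(id = "b", lin = "Bacteria;P;C;O;F;G;S1", comp = 95, cont = 0,
         size = 4e6, cds = 4000),
    list(id = "c", lin = "Bacteria;P;C;O;F;G;S1", comp = 95, cont = 0,
         size = 5e6, cds = 5000))
  fn <- data.frame(genome_id = c("a", "b", "c"),
                   universe = "subsystem_subclass",
                   function_id = "f1")
  expect_warning(out <- dedup_genomes(g, fn), "duplicate")
  expect_setequal(out$genome_id, c("a", "c"))
})
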