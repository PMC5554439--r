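test_that("generate_reference hits the target GC and is deterministic", {
  g <- generate_reference(10000, 0.5, seed = 1)
  expect_equal(nchar(g), 10000L)
  expect_true(grepl("^[ACGT]+$", g))
  gc <- sum(strsplit(g, "")[[1]] %in% c("G", "C")) / 10000
  expect_gt(gc, 0.45)
  expect_lt(gc, 0.55)
  expect_identical(g, generate_reference(10000, 0.5, seed = 1))
  expect_false(identical(g, generate_reference(10000, 0.5, seed = 2)))

  big <- generate_reference(2e6, 0.37, seed = 7)
  gc_big <- sum(strsplit(big, "")[[1]] %in% c("G", "C")) / 2e6
  expect_gt(gc_big, 0.36)
  expect_lt(gc_big, 0.38)

  expect_error(generate_reference(100, 0.5), "length")
  expect_error(generate_reference(10000, 1.2), "gc_fraction")
})

test_that("an all-zero config yields identical copies of the reference", {
  cfg <- population_config(
    reference_length = 20000L, clade_sizes = c(2L, 2L),
    ancestral_snps = 0L, fixed_snps_per_clade = c(0L, 0L),
    private_snps_per_clade = c(0L, 0L), shared_snps = 0L,
    singletons_per_genome = 0L, n_insertions = 0L, n_deletions = 0L,
    n_substitutions = 0L, ancestral_insertions = 0L,
    ancestral_deletions = 0L, island_spec = NULL, insertion_specs = NULL,
    crispr_spec = NULL, genes = FALSE, seed = 3L)
  sim <- simulate_population(cfg)
  expect_length(sim$genomes, 4L)
  expect_true(all(sim$genomes == sim$reference))
  expect_equal(nrow(sim$truth$snps), 0L)
})

test_that("clade-fixed SNPs land in exactly their clade, with forced classes", {
  cfg <- population_config(
    reference_length = 20000L, clade_sizes = c(2L, 2L),
    ancestral_snps = 0L, fixed_snps_per_clade = c(1L, 1L),
    private_snps_per_clade = c(0L, 0L), shared_snps = 0L,
    singletons_per_genome = 0L, n_insertions = 0L, n_deletions = 0L,
    n_substitutions = 0L, ancestral_insertions = 0L,
    ancestral_deletions = 0L, island_spec = NULL, insertion_specs = NULL,
    crispr_spec = NULL, genes = FALSE, seed = 5L)
  sim <- simulate_population(cfg)
  expect_equal(nrow(sim$truth$snps), 2L)
  expect_true(all(sim$truth$snps$class == "clade_fixed"))
  for (i in 1:2) {
    carriers <- sim$truth$snps$carriers[[i]]
    k <- sim$truth$snps$clade[i]
    expect_setequal(carriers,
                    sim$truth$clades$genome[sim$truth$clades$clade == k])
  }
})

test_that("simulation is deterministic and round-trips through its truth", {
  sim1 <- simulate_population(toy_config(seed = 21L))
  sim2 <- simulate_population(toy_config(seed = 21L))
  expect_identical(sim1$reference, sim2$reference)
  expect_identical(sim1$genomes, sim2$genomes)
  # independent reconstruction of each genome from the truth tables
  for (g in names(sim1$genomes)[c(1, 4, 6)]) {
    expect_identical(rebuild_genome_from_truth(sim1, g), sim1$genomes[[g]])
  }
})

test_that("planted classes are consistent with carrier sets and clades", {
  sim <- simulate_population(toy_config(seed = 9L))
  clades <- sim$truth$clades
  for (i in seq_len(nrow(sim$truth$snps))) {
    row <- sim$truth$snps[i, ]
    carriers <- row$carriers[[1]]
    cl <- unique(clades$clade[match(carriers, clades$genome)])
    switch(row$class,
           singleton = expect_length(carriers, 1L),
           private = {
             expect_gte(length(carriers), 2L)
             expect_length(cl, 1L)
             expect_lt(length(carriers),
                       sum(clades$clade == cl) + 1L)
           },
           clade_fixed = {
             expect_length(cl, 1L)
             expect_setequal(carriers, clades$genome[clades$clade == cl])
           },
           ancestral = expect_setequal(carriers, clades$genome),
           shared = expect_gt(length(cl), 1L))
  }
})

test_that("invalid configs are rejected", {
  expect_error(population_config(reference_length = 500L), "reference_length")
  expect_error(population_config(gc_fraction = 1.5), "gc_fraction")
  expect_error(toy_config(private_snps_per_clade = c(1L, 1L),
                          clade_sizes = c(3L, 2L)), "size >= 3")
  expect_error(population_config(ancestral_insertions = 50L), "ancestral")
  # overlapping features
  expect_error(population_config(
    insertion_specs = list(
      list(id = "a", position_frac = 0.5, length = 30000L,
           carriers = list(whole_clades = 1L, partial = list())),
      list(id = "b", position_frac = 0.52, length = 30000L,
           carriers = list(whole_clades = 1L, partial = list()))),
    island_spec = NULL, crispr_spec = NULL, genes = FALSE), "overlap")
})

test_that("simulated reads have the right count, content and error rate", {
  g <- generate_reference(10000, 0.5, seed = 2)
  expect_error(simulate_reads(g, coverage = 0, read_length = 100), "coverage")
  expect_error(simulate_reads(g, coverage = 5, read_length = 20000),
               "read_length")

  rs <- simulate_reads(g, coverage = 30, read_length = 100, error_rate = 0,
                       seed = 3)
  expect_equal(length(rs$reads), 3000L)
  expect_true(all(nchar(rs$reads) == 100L))
  # zero-error reads are exact substrings
  expect_true(all(vapply(rs$reads[1:50], grepl, logical(1), x = g,
                         fixed = TRUE)))

  rs2 <- simulate_reads(g, coverage = 30, read_length = 100,
                        error_rate = 0.01, seed = 3)
  mm <- sum(vapply(seq_along(rs2$reads), function(i) {
    sum(strsplit(rs2$reads[i], "")[[1]] != strsplit(rs$reads[i], "")[[1]])
  }, numeric(1)))
  # expected 3000 errors at 1%; generous binomial band
  expect_gt(mm, 2400)
  expect_lt(mm, 3600)
  expect_identical(
    rs2$reads,
    simulate_reads(g, 30, 100, error_rate = 0.01, seed = 3)$reads)
})

test_that("the default config plants the emulated population structure", {
  cfg <- population_config()
  expect_equal(sum(cfg$clade_sizes), 47L)
  expect_length(cfg$clade_sizes, 7L)
  n_snps <- cfg$ancestral_snps + sum(cfg$fixed_snps_per_clade) +
    sum(cfg$private_snps_per_clade) + cfg$shared_snps +
    sum(cfg$singletons_per_genome)
  expect_equal(n_snps, 119L)
  expect_equal(cfg$n_insertions + cfg$n_deletions, 31L)
  expect_equal(cfg$n_substitutions, 4L)
  expect_equal(sum(cfg$fixed_snps_per_clade) +
                 sum(cfg$private_snps_per_clade), 36L)
  expect_equal(cfg$island_spec$length, 33000L)
  expect_length(cfg$island_spec$patterns, 5L)  # plus intact = 6 patterns
  expect_equal(cfg$crispr_spec$n_arrays, 4L)
})
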