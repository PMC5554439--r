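make_matrix <- function(alleles, ref) {
  m <- list(alleles = alleles,
            sites = tibble::tibble(pos = as.integer(colnames(alleles)),
                                   ref = ref))
  class(m) <- "snp_matrix"
  m
}

test_that("allele classification follows the carrier-set definitions", {
  al <- rbind(a1 = c("G", "A", "G", "G"),
              a2 = c("A", "A", "G", "G"),
              b1 = c("A", "C", "G", "G"),
              b2 = c("A", "C", "G", "T"))
  colnames(al) <- c(10, 20, 30, 40)
  m <- make_matrix(al, ref = c("A", "A", "A", "A"))
  clades <- tibble::tibble(genome = c("a1", "a2", "b1", "b2"),
                           clade = c(1L, 1L, 2L, 2L))
  cl <- classify_alleles(m, clades)
  s <- cl$sites
  expect_equal(s$class, c("singleton", "private", "shared", "shared"))
  expect_equal(s$fixed_vs_reference, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(s$biallelic, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(s$clade[2], 2L)
  # site carried by a whole clade counts as that clade's unique fixed SNP
  expect_equal(cl$clade_summary$n_fixed_unique, c(0L, 1L))
  expect_error(classify_alleles(m, clades[1:3, ]), "clade")
})

test_that("classification tallies on a simulated population equal truth", {
  sim <- simulate_population(toy_config(seed = 13L))
  cmp <- compare_genomes(sim$genomes, sim$reference)
  cl <- classify_alleles(cmp$snp_matrix, sim$truth$clades)
  truth <- sim$truth$snps
  expected_class <- dplyr::case_when(
    truth$class == "singleton" ~ "singleton",
    truth$class %in% c("clade_fixed", "private") ~ "private",
    TRUE ~ "shared")
  got <- cl$sites[match(truth$pos, cl$sites$pos), ]
  expect_equal(got$class, expected_class)
  expect_equal(got$fixed_vs_reference, truth$class == "ancestral")
})

test_that("divergence reports both statistics on the stated scales", {
  al <- matrix(character(0), nrow = 2, ncol = 0,
               dimnames = list(c("a", "b"), NULL))
  m0 <- make_matrix(al, ref = character(0))
  expect_equal(divergence(m0, 1000)$d_total, 0)
  expect_error(divergence(m0, 0), "core_length")

  # 119 sites over 2 Mb of core genome
  al119 <- matrix("G", nrow = 2, ncol = 119,
                  dimnames = list(c("a", "b"), 1:119))
  m119 <- make_matrix(al119, ref = rep("A", 119))
  expect_equal(divergence(m119, 2e6)$d_total, 119 / 2e6)
  expect_equal(divergence(m119, 2e6)$d_total, 5.95e-5)

  # two genomes differing at 4 of 1000 core bp
  al4 <- rbind(a = c("G", "G", "G", "G"), b = c("A", "A", "A", "A"))
  colnames(al4) <- 1:4
  m4 <- make_matrix(al4, ref = rep("A", 4))
  expect_equal(divergence(m4, 1000)$d_pi, 0.004)
})

test_that("Tajima's D matches a from-scratch recomputation to 1e-10", {
  expect_error(tajimas_d(3, 5, 2), "n >= 4")
  expect_warning(d0 <- tajimas_d(10, 0, 0), "undefined")
  expect_true(is.na(d0))

  # oracle: compute pi, S and all constants independently from haplotypes
  oracle_d <- function(haps) {
    n <- nrow(haps)
    S <- sum(apply(haps, 2, function(x) length(unique(x)) > 1))
    pi <- 0
    np <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      pi <- pi + sum(haps[i, ] != haps[j, ])
      np <- np + 1
    }
    pi <- pi / np
    if (S == 0) return(NA_real_)
    a1 <- sum(1 / (1:(n - 1)))
    a2 <- sum(1 / (1:(n - 1))^2)
    b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    (pi - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
  }
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(4:10, 1)
    L <- sample(3:12, 1)
    haps <- matrix(sample(c("A", "G"), n * L, TRUE), n, L)
    S <- sum(apply(haps, 2, function(x) length(unique(x)) > 1))
    if (S == 0) next
    pi <- mean(utils::combn(n, 2, function(ix) {
      sum(haps[ix[1], ] != haps[ix[2], ])
    }))
    expect_equal(tajimas_d(n, S, pi), oracle_d(haps), tolerance = 1e-10)
  }

  # pi exactly at the Watterson expectation gives D = 0
  n <- 8; S <- 5
  a1 <- sum(1 / (1:(n - 1)))
  expect_equal(tajimas_d(n, S, S / a1), 0)

  # an excess of singletons drives D negative
  n <- 20; L <- 40
  haps <- matrix("A", n, L)
  for (j in 1:L) haps[sample(n, 1), j] <- "G"
  pi <- mean(utils::combn(n, 2, function(ix) {
    sum(haps[ix[1], ] != haps[ix[2], ])
  }))
  expect_lt(tajimas_d(n, L, pi), 0)
})

test_that("tajima_test computes per-clade and overall rows", {
  sim <- simulate_population(toy_config(seed = 17L))
  cmp <- compare_genomes(sim$genomes, sim$reference)
  tt <- tajima_test(cmp$snp_matrix, sim$truth$clades)
  expect_equal(tt$group, c("overall", "clade_1", "clade_2"))
  expect_equal(tt$n, c(6L, 3L, 3L))
  expect_true(is.na(tt$D[2]))  # n < 4 within a clade
  expect_false(is.na(tt$D[1]))
})

test_that("Nei-Gojobori site counting matches exhaustive enumeration", {
  ct <- Biostrings::GENETIC_CODE
  syn_fraction <- function(codon, pos) {
    b <- substr(codon, pos, pos)
    alts <- setdiff(c("A", "C", "G", "T"), b)
    mean(vapply(alts, function(a) {
      alt <- codon; substr(alt, pos, pos) <- a
      ct[[alt]] == ct[[codon]]
    }, logical(1)))
  }
  # TTT (Phe): third position one of three changes is synonymous
  expect_equal(syn_fraction("TTT", 3), 1 / 3)
  # ATG (Met): no synonymous change at any position
  expect_equal(sum(vapply(1:3, syn_fraction, numeric(1), codon = "ATG")), 0)

  # a random stop-free 300-codon gene: totals equal the 9-change oracle
  set.seed(4)
  codons <- sample(setdiff(names(ct), c("TAA", "TAG", "TGA")), 300, TRUE)
  gene_seq <- paste(codons, collapse = "")
  ref <- paste0(strrep("A", 10), gene_seq, strrep("A", 10))
  genes <- tibble::tibble(gene_id = "g1", start = 10L, end = 10L + 900L)
  al <- matrix(character(0), 2, 0, dimnames = list(c("x", "y"), NULL))
  m <- make_matrix(al, character(0))
  eff <- coding_effects(m, genes, ref)
  oracle_S <- sum(vapply(codons, function(cd) {
    sum(vapply(1:3, syn_fraction, numeric(1), codon = cd))
  }, numeric(1)))
  expect_equal(eff$totals$S_sites, oracle_S)
  expect_equal(eff$totals$N_sites + eff$totals$S_sites, 900)

  bad <- tibble::tibble(gene_id = "g2", start = 10L, end = 11L)
  expect_error(coding_effects(m, bad, ref), "divisible")
  stopg <- tibble::tibble(gene_id = "g3", start = 0L, end = 9L)
  expect_error(coding_effects(m, stopg, paste0("ATGTAACCC", ref)), "stop")
})

test_that("per-SNP effects classify substituted codons correctly", {
  # gene ATG AAA TGG TAT -> M K W Y
  ref <- paste0("CC", "ATGAAATGGTAT", "CC")
  genes <- tibble::tibble(gene_id = "g", start = 2L, end = 14L)
  al <- rbind(x = c("G", "A", "A"), y = c("A", "G", "A"))
  colnames(al) <- c(7, 10, 16)  # 0-based: AAA->AAG (syn), TGG->TAG (stop)
  m <- make_matrix(al, ref = c("A", "G", "C"))
  eff <- coding_effects(m, genes, ref)
  expect_equal(eff$per_snp$effect, c("synonymous", "nonsynonymous",
                                     "intergenic"))
  expect_equal(eff$per_snp$nonsense, c(FALSE, TRUE, FALSE))
})

test_that("dn/ds behaves on the worked examples", {
  expect_equal(dnds(10, 10, 100, 100), 1.0)
  expect_equal(dnds(0, 5, 100, 100), 0.0)
  expect_warning(r <- dnds(5, 0, 100, 100), "undefined")
  expect_true(is.na(r))
  expect_error(dnds(5, 5, 0, 100), "site counts")
  expect_equal(dnds(53, 41, 1.3e6, 3.6e5), (53 / 1.3e6) / (41 / 3.6e5))
})

test_that("multi-hit genes are reported with partitioned tallies", {
  ref <- paste0(strrep("C", 10),
                "ATGAAATGGTATAAAAAATGGATA",  # gene g1, 8 codons
                strrep("C", 10))
  genes <- tibble::tibble(gene_id = "g1", start = 10L, end = 34L)
  # three nonsynonymous sites fixed in both genomes (vs reference)
  al <- rbind(x = c("C", "C", "C"), y = c("C", "C", "C"))
  colnames(al) <- c(11, 14, 17)  # first codon positions -> nonsyn
  m <- make_matrix(al, ref = c("T", "A", "G"))
  clades <- tibble::tibble(genome = c("x", "y"), clade = c(1L, 1L))
  cl <- classify_alleles(m, clades)
  eff <- coding_effects(m, genes, ref)
  rep <- multi_hit_genes(eff, cl)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$partition, "fixed_vs_reference")
  expect_equal(c(rep$syn, rep$nonsyn, rep$indel), c(0L, 3L, 0L))

  # no gene with >= 2 mutations -> empty report
  m1 <- make_matrix(al[, 1, drop = FALSE], ref = "T")
  rep0 <- multi_hit_genes(coding_effects(m1, genes, ref),
                          classify_alleles(m1, clades))
  expect_equal(nrow(rep0), 0L)

  # indels in a gene count in the indel column of the variable partition
  indels <- tibble::tibble(genome = "x", pos = c(20L, 28L),
                           type = c("deletion", "insertion"))
  rep2 <- multi_hit_genes(eff, cl, indels)
  v <- rep2[rep2$partition == "variable", ]
  expect_equal(v$indel, 2L)
})
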