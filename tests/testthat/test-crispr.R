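plant_array <- function(genome, pos0, repeat_seq, spacers) {
  units <- character(2L * length(spacers) + 1L)
  units[seq(1, length(units), 2)] <- repeat_seq
  units[seq(2, length(units), 2)] <- spacers
  arr <- paste(units, collapse = "")
  paste0(substr(genome, 1, pos0), arr,
         substr(genome, pos0 + nchar(arr) + 1L, nchar(genome)))
}

test_that("random sequence yields no arrays across many seeds", {
  hits <- vapply(1:20, function(s) {
    g <- generate_reference(50000, 0.4, seed = 100 + s)
    nrow(detect_arrays(g))
  }, integer(1))
  expect_true(all(hits == 0L))
})

test_that("a planted array is recovered with exact coordinates and spacers", {
  g <- generate_reference(60000, 0.4, seed = 43)
  rep_seq <- generate_reference(1000, 0.5, seed = 44)
  rep_seq <- substr(rep_seq, 1, 30)
  spacers <- vapply(1:4, function(i) {
    substr(generate_reference(1000, 0.4, seed = 50 + i), 1, 35)
  }, character(1))
  g2 <- plant_array(g, 20000L, rep_seq, spacers)
  arr <- detect_arrays(g2)
  expect_equal(nrow(arr), 1L)
  expect_equal(arr$start, 20000L)
  expect_equal(arr$end, 20000L + 5L * 30L + 4L * 35L)
  expect_equal(arr$repeat_seq, rep_seq)
  expect_equal(arr$n_repeats, 5L)
  expect_equal(arr$spacers[[1]]$seq, spacers)
  # fewer than 3 repeats is not an array
  g3 <- plant_array(g, 40000L, substr(rep_seq, 1, 24), spacers[1])
  arr3 <- detect_arrays(g3)
  expect_false(any(arr3$start > 35000 & arr3$start < 45000))
})

test_that("multiple arrays sharing one repeat are all recovered", {
  g <- generate_reference(80000, 0.4, seed = 45)
  rep_seq <- substr(generate_reference(1000, 0.5, seed = 46), 1, 24)
  sp <- function(k) {
    vapply(1:6, function(i) {
      substr(generate_reference(1000, 0.4, seed = 900 + 10 * k + i), 1, 35)
    }, character(1))
  }
  g <- plant_array(g, 10000L, rep_seq, sp(1))
  g <- plant_array(g, 30000L, rep_seq, sp(2))
  g <- plant_array(g, 60000L, rep_seq, sp(3))
  arr <- detect_arrays(g)
  expect_equal(nrow(arr), 3L)
  expect_equal(arr$start, c(10000L, 30000L, 60000L))
  expect_true(all(arr$n_repeats == 7L))
})

test_that("Karlin-Altschul parameters match theory and simulation", {
  kp <- karlin_params(2L, -3L)
  # lambda solves the transcendental equation
  expect_equal(0.25 * exp(2 * kp$lambda) + 0.75 * exp(-3 * kp$lambda), 1,
               tolerance = 1e-10)
  # brute-force tally: expected number of >= S word-seeded segments in
  # random 12-mers versus K m n exp(-lambda S)
  set.seed(77)
  m <- 12L
  n_pairs <- 3000L
  s_cut <- 16L
  count <- 0L
  for (i in seq_len(n_pairs)) {
    a <- paste(sample(c("A", "C", "G", "T"), m, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), m, TRUE), collapse = "")
    h <- clonalpop:::seed_hits(a, b, 7L, 2L, -3L, s_cut)
    if (nrow(h) > 0L) count <- count + 1L
  }
  expected <- n_pairs * evalue(s_cut, m, m, kp)
  # asymptotic theory at finite n: agree within a factor of ~3
  expect_lt(count, 3 * expected + 5)
  expect_gt(count + 3, expected / 3)
})

test_that("spacer matching is calibrated at the e-value cutoff", {
  sp <- vapply(1:2, function(i) {
    substr(generate_reference(1000, 0.5, seed = 60 + i), 1, 35)
  }, character(1))
  names(sp) <- c("s1", "s2")
  # self-match: tiny e-value, full identity
  self <- match_spacers(sp["s1"], sp["s1"], exclude_self = FALSE)
  expect_equal(nrow(self), 1L)
  expect_lt(self$evalue, 1e-10)
  expect_equal(self$identity, 1.0)

  # random 35-mer pairs essentially never match at E <= 0.001
  set.seed(88)
  n_pairs <- 2000L
  hits <- 0L
  for (i in seq_len(n_pairs)) {
    a <- paste(sample(c("A", "C", "G", "T"), 35, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 35, TRUE), collapse = "")
    hits <- hits + nrow(match_spacers(c(q = a), c(s = b)))
  }
  # expected <= 2 * n_pairs * 0.001 (two strands); allow slack
  expect_lt(hits, 20L)
  expect_error(match_spacers(character(0), sp), "empty")
  expect_error(match_spacers(c(q = "ACGT"), sp), "19")
})

test_that("a spacer finds its protospacer at the planted coordinate", {
  g <- generate_reference(50000, 0.4, seed = 47)
  spacer <- substr(g, 30001, 30035)
  hits <- match_spacers(c(sp = spacer), c(genome = g), mode = "all")
  fwd <- hits[hits$strand == "+", ]
  expect_true(30000L %in% fwd$s_start)
  # reverse-complement search finds strandless protospacers
  hits_rc <- match_spacers(c(sp = clonalpop:::revcomp(spacer)),
                           c(genome = g), mode = "all")
  expect_true(30000L %in% hits_rc$s_start[hits_rc$strand == "-"])
})

test_that("matching is symmetric at the cutoff", {
  set.seed(91)
  base <- paste(sample(c("A", "C", "G", "T"), 35, TRUE), collapse = "")
  near <- mutate_at(base, c(5L, 20L))
  ab <- match_spacers(c(a = base), c(b = near))
  ba <- match_spacers(c(b = near), c(a = base))
  expect_equal(nrow(ab), nrow(ba))
  if (nrow(ab) > 0L) expect_equal(ab$score, ba$score)
})

test_that("self-targets exclude array loci and annotate planted elements", {
  g <- generate_reference(80000, 0.4, seed = 48)
  rep_seq <- substr(generate_reference(1000, 0.5, seed = 49), 1, 24)
  # one spacer copied from a 'plasmid' interior, rest random
  plasmid <- tibble::tibble(id = "plasmid", start = 50000L, end = 60000L)
  spacers <- c(substr(g, 55001, 55035),
               vapply(1:3, function(i) {
                 substr(generate_reference(1000, 0.4, seed = 70 + i), 1, 35)
               }, character(1)))
  g2 <- plant_array(g, 10000L, rep_seq, spacers)
  arr <- detect_arrays(g2, genome_id = "g")
  expect_equal(nrow(arr), 1L)
  st <- find_self_targets(arr, g2, elements = plasmid)
  expect_equal(nrow(st), 1L)
  expect_equal(st$target_annotation, "insertion element")
  expect_gt(st$s_start, 50000L)

  # with no planted protospacer there are no self-targets (array masked)
  g3 <- plant_array(g, 10000L, rep_seq, spacers[-1])
  arr3 <- detect_arrays(g3, genome_id = "g")
  st3 <- find_self_targets(arr3, g3, elements = plasmid)
  expect_equal(nrow(st3), 0L)
})

test_that("array conservation reports identical content across genomes", {
  g1 <- generate_reference(40000, 0.4, seed = 52)
  g2 <- mutate_at(g1, c(5000L, 25000L))  # SNPs outside the array
  rep_seq <- substr(generate_reference(1000, 0.5, seed = 53), 1, 24)
  spacers <- vapply(1:5, function(i) {
    substr(generate_reference(1000, 0.4, seed = 80 + i), 1, 35)
  }, character(1))
  arrs <- list(g1 = detect_arrays(plant_array(g1, 15000L, rep_seq, spacers)),
               g2 = detect_arrays(plant_array(g2, 15000L, rep_seq, spacers)))
  cons <- array_conservation(arrs)
  expect_true(cons$all_identical)
  # a genome with one divergent spacer breaks conservation
  spacers2 <- spacers
  spacers2[3] <- mutate_at(spacers2[3], 10L)
  arrs$g3 <- detect_arrays(plant_array(g1, 15000L, rep_seq, spacers2))
  expect_false(array_conservation(arrs)$all_identical)
})
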