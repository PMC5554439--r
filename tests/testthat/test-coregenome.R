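test_that("anchoring identical sequences yields one whole-genome anchor", {
  g <- generate_reference(20000, 0.4, seed = 1)
  ch <- find_anchors(g, g)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$ref_start, 0L)
  expect_equal(ch$ref_end, 20000L)
  expect_equal(ch$query_start, 0L)
  expect_equal(ch$query_end, 20000L)
})

test_that("a single SNP splits the chain into two anchors abutting it", {
  g <- generate_reference(20000, 0.4, seed = 2)
  q <- mutate_at(g, 9999L)
  ch <- find_anchors(g, q)
  expect_equal(nrow(ch), 2L)
  expect_equal(ch$ref_end[1], 9999L)
  expect_equal(ch$ref_start[2], 10000L)
  expect_error(find_anchors("", g), "empty")
  expect_error(find_anchors(g, q, min_match = 10), "min_match")
})

test_that("chain gaps localize planted SNPs and a large deletion", {
  g <- generate_reference(100000, 0.4, seed = 3)
  snp_pos <- seq(5000L, 50000L, by = 5000L)
  q <- mutate_at(g, snp_pos)
  q <- delete_span(q, 70000L, 2000L)
  ch <- find_anchors(g, q)
  gaps <- ch$ref_start[-1]
  # every planted SNP is an inter-anchor gap; the deletion gap is ~2 kb
  expect_true(all(snp_pos %in% (ch$ref_end)))
  widths <- ch$ref_start[-1] - ch$ref_end[-nrow(ch)]
  expect_equal(sum(widths >= 1900), 1L)
  big <- which(widths >= 1900)
  expect_lt(abs(ch$ref_end[big] - 70000L), 20L)
})

test_that("small-variant calls match what was planted", {
  g <- generate_reference(30000, 0.4, seed = 4)
  expect_equal(nrow(call_small_variants(g, g, find_anchors(g, g))), 0L)

  q <- mutate_at(g, 14999L, "G")
  ref_base <- substr(g, 15000, 15000)
  v <- call_small_variants(g, q, find_anchors(g, q))
  expect_equal(nrow(v), 1L)
  expect_equal(v$pos, 14999L)
  expect_equal(v$type, "snp")
  expect_equal(v$ref, ref_base)
  expect_equal(v$alt, "G")
})

test_that("population-scale variant recovery is exact against the truth", {
  sim <- simulate_population(toy_config(seed = 31L))
  cmp <- compare_genomes(sim$genomes, sim$reference)
  rec <- tidy(cmp$snp_matrix)
  rec <- rec[rec$is_alt, ]
  expect_setequal(paste(rec$pos, rec$allele, rec$genome),
                  truth_snp_triplets(sim$truth$snps))
  # indel and substitution events match the planted set too
  ev <- dplyr::distinct(cmp$variants[cmp$variants$type != "snp", ],
                        pos, type, ref, alt)
  tr <- sim$truth$indels
  expect_setequal(paste(ev$pos, ev$type, ev$ref, ev$alt),
                  paste(tr$pos, tr$type, tr$ref, tr$alt))
})

test_that("anchored calls equal a full dynamic-programming alignment", {
  # 8 kb pair with SNPs, indels and one multi-nucleotide substitution
  g <- generate_reference(8000, 0.4, seed = 5)
  q <- mutate_at(g, c(1000L, 3000L, 5000L))
  q <- delete_span(q, 6000L, 4L)
  q <- paste0(substr(q, 1, 2000), "ACGTA", substr(q, 2001, nchar(q)))
  impl <- call_small_variants(g, q, find_anchors(g, q))

  # oracle: one global DP alignment of the whole pair, decomposed by an
  # independent walker with its own left-normalization
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(q), Biostrings::DNAString(g), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = TRUE),
    gapOpening = 20, gapExtension = 10)
  ap <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  st <- ifelse(ap == "-", "del", ifelse(as_ == "-", "ins",
                                        ifelse(ap == as_, "m", "x")))
  r <- rle(st)
  rows <- list()
  pos <- 0L
  col <- 1L
  lshift_del <- function(p, refseq, dlen) {
    while (p > 0L && substr(refseq, p, p) ==
             substr(refseq, p + dlen, p + dlen)) p <- p - 1L
    p
  }
  for (k in seq_along(r$lengths)) {
    len <- r$lengths[k]
    cols <- col:(col + len - 1L)
    if (r$values[k] == "x") {
      rows[[length(rows) + 1L]] <- data.frame(
        pos = pos, type = if (len == 1L) "snp" else "substitution",
        ref = paste(as_[cols], collapse = ""),
        alt = paste(ap[cols], collapse = ""))
      pos <- pos + len
    } else if (r$values[k] == "del") {
      p2 <- lshift_del(pos, g, len)
      rows[[length(rows) + 1L]] <- data.frame(
        pos = p2, type = "deletion",
        ref = substr(g, p2 + 1L, p2 + len), alt = "")
      pos <- pos + len
    } else if (r$values[k] == "ins") {
      ins <- paste(ap[cols], collapse = "")
      p2 <- pos
      while (p2 > 0L && substr(g, p2, p2) == substr(ins, len, len)) {
        ins <- paste0(substr(ins, len, len), substr(ins, 1L, len - 1L))
        p2 <- p2 - 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(pos = p2, type = "insertion",
                                              ref = "", alt = ins)
    } else {
      pos <- pos + len
    }
    col <- col + len
  }
  oracle <- do.call(rbind, rows)
  expect_setequal(paste(impl$pos, impl$type, impl$ref, impl$alt),
                  paste(oracle$pos, oracle$type, oracle$ref, oracle$alt))
})

test_that("core blocks are the intersection of covered footprints", {
  g <- generate_reference(30000, 0.4, seed = 6)
  genomes <- c(a = g, b = g, c = g)
  chains <- lapply(names(genomes), function(id) {
    find_anchors(g, genomes[[id]], genome_id = id)
  })
  names(chains) <- names(genomes)
  blocks <- extract_core_blocks(chains, nchar(g),
                                vapply(genomes, nchar, integer(1)))
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$start, 0L)
  expect_equal(blocks$end, 30000L)

  # one genome missing a 5 kb island: blocks exclude it
  genomes2 <- c(a = g, b = delete_span(g, 10000L, 5000L), c = g)
  chains2 <- lapply(names(genomes2), function(id) {
    find_anchors(g, genomes2[[id]], genome_id = id)
  })
  names(chains2) <- names(genomes2)
  blocks2 <- extract_core_blocks(chains2, nchar(g),
                                 vapply(genomes2, nchar, integer(1)))
  expect_equal(nrow(blocks2), 2L)
  covered <- unlist(Map(seq, blocks2$start, blocks2$end - 1L))
  expect_false(any(covered %in% 10050:14950))
  # SNP-bearing genomes do not fragment blocks (small gaps are closed)
  genomes3 <- c(a = mutate_at(g, 15000L), b = g)
  chains3 <- lapply(names(genomes3), function(id) {
    find_anchors(g, genomes3[[id]], genome_id = id)
  })
  names(chains3) <- names(genomes3)
  blocks3 <- extract_core_blocks(chains3, nchar(g),
                                 vapply(genomes3, nchar, integer(1)))
  expect_equal(nrow(blocks3), 1L)
  expect_error(extract_core_blocks(chains3[1], nchar(g), 30000L), "2 genomes")
})

test_that("core plus variable intervals partition the reference", {
  sim <- simulate_population(toy_config(seed = 41L))
  cmp <- compare_genomes(sim$genomes, sim$reference)
  L <- nchar(sim$reference)
  state <- integer(L)
  mark <- function(s, e) state[(s + 1L):e] <<- state[(s + 1L):e] + 1L
  for (r in seq_len(nrow(cmp$blocks))) {
    mark(cmp$blocks$start[r], cmp$blocks$end[r])
  }
  expect_true(all(state <= 1L))  # blocks are disjoint
  # everything outside core blocks is attributable to a variant/gap zone
  # within 500 bp of a junction
  outside <- which(state == 0L) - 1L
  if (length(outside) > 0L) {
    near_feature <- vapply(outside, function(p) {
      any(abs(p - c(sim$truth$snps$pos, sim$truth$indels$pos)) <= 500L)
    }, logical(1))
    expect_true(all(near_feature))
  }
})

test_that("the SNP matrix is well formed and query-order symmetric", {
  expect_equal(ncol(build_snp_matrix(
    tibble::tibble(genome = character(), pos = integer(), type = character(),
                   ref = character(), alt = character(), length = integer()),
    tibble::tibble(start = 0L, end = 1000L), c("a", "b"))$alleles), 0L)

  v <- tibble::tibble(genome = c("a", "b"), pos = c(10L, 10L), type = "snp",
                      ref = "A", alt = c("G", "G"), length = 1L)
  m <- build_snp_matrix(v, tibble::tibble(start = 0L, end = 100L),
                        c("a", "b", "c"))
  expect_equal(dim(m$alleles), c(3L, 1L))
  expect_equal(unname(m$alleles[, 1]), c("G", "G", "A"))

  vbad <- tibble::tibble(genome = c("a", "a"), pos = c(10L, 10L),
                         type = "snp", ref = "A", alt = c("G", "T"),
                         length = 1L)
  expect_error(build_snp_matrix(vbad, tibble::tibble(start = 0L, end = 100L),
                                c("a")), "conflicting")

  # swapping identical genomes never changes the matrix
  sim <- simulate_population(toy_config(seed = 51L))
  cmp1 <- compare_genomes(sim$genomes, sim$reference)
  cmp2 <- compare_genomes(rev(sim$genomes), sim$reference)
  ord <- rownames(cmp1$snp_matrix$alleles)
  expect_identical(cmp1$snp_matrix$alleles,
                   cmp2$snp_matrix$alleles[ord, , drop = FALSE])
})

test_that("multi-scaffold queries are concatenated in reference order", {
  g <- generate_reference(30000, 0.4, seed = 8)
  scaffolds <- c(s2 = substr(g, 10001, 30000), s1 = substr(g, 1, 10000))
  ch <- find_anchors(g, scaffolds)
  v <- call_small_variants(g, scaffolds, ch)
  expect_equal(nrow(v), 0L)
  cov <- sum(ch$ref_end - ch$ref_start)
  expect_gte(cov, 29900L)
})
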