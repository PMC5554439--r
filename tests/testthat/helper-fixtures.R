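# Shared fixtures, all generated in code.

# A small two-clade population with a few variants of every class and no
# large features; fast enough to simulate inside individual tests.
toy_config <- function(seed = 7L, ...) {
  args <- list(
    reference_length = 60000L, gc_fraction = 0.4,
    clade_sizes = c(3L, 3L),
    ancestral_snps = 2L,
    fixed_snps_per_clade = c(1L, 2L),
    private_snps_per_clade = c(1L, 0L),
    shared_snps = 1L,
    singletons_per_genome = c(1L, 0L, 0L, 1L, 0L, 0L),
    n_insertions = 2L, n_deletions = 2L, n_substitutions = 1L,
    ancestral_insertions = 1L, ancestral_deletions = 1L,
    island_spec = NULL, insertion_specs = NULL, crispr_spec = NULL,
    genes = FALSE, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(population_config, args)
}

# Long-form (pos, alt allele, genome) triplets for a truth SNP table.
truth_snp_triplets <- function(truth_snps) {
  long <- tidyr::unnest(truth_snps[, c("pos", "alt", "carriers")],
                        "carriers")
  paste(long$pos, long$alt, long$carriers)
}

# Apply one genome's truth edits to the reference from scratch (test-local
# reimplementation, independent of the simulator's assembly path).
rebuild_genome_from_truth <- function(sim, genome) {
  ref <- sim$reference
  truth <- sim$truth
  edits <- list()
  for (i in seq_len(nrow(truth$snps))) {
    if (genome %in% truth$snps$carriers[[i]]) {
      edits[[length(edits) + 1L]] <- c(truth$snps$pos[i], 1L,
                                       truth$snps$alt[i])
    }
  }
  for (i in seq_len(nrow(truth$indels))) {
    if (genome %in% truth$indels$carriers[[i]]) {
      edits[[length(edits) + 1L]] <- c(truth$indels$pos[i],
                                       nchar(truth$indels$ref[i]),
                                       truth$indels$alt[i])
    }
  }
  ip <- truth$island_patterns
  if (nrow(ip) > 0L && nrow(truth$islands) > 0L) {
    pr <- ip$pairs[[match(genome, ip$genome)]]
    for (r in seq_len(nrow(pr))) {
      st <- truth$islands$start[1] + pr[r, 1]
      en <- truth$islands$start[1] + pr[r, 2]
      edits[[length(edits) + 1L]] <- c(st, en - st, "")
    }
  }
  for (i in seq_len(nrow(truth$insertions))) {
    if (!(genome %in% truth$insertions$carriers[[i]])) {
      st <- truth$insertions$start[i]
      en <- truth$insertions$end[i]
      edits[[length(edits) + 1L]] <- c(st, en - st, "")
    }
  }
  pos <- vapply(edits, function(e) as.integer(e[1]), integer(1))
  ord <- order(pos, decreasing = TRUE)
  out <- ref
  for (e in edits[ord]) {
    p <- as.integer(e[1]); w <- as.integer(e[2])
    out <- paste0(substr(out, 1L, p), e[3],
                  substr(out, p + w + 1L, nchar(out)))
  }
  out
}

# Mutate a string at given 0-based positions (cycling replacement base).
mutate_at <- function(seq, pos0, base = NULL) {
  for (p in pos0) {
    old <- substr(seq, p + 1L, p + 1L)
    new <- base %||% setdiff(c("A", "C", "G", "T"), old)[1]
    substr(seq, p + 1L, p + 1L) <- new
  }
  seq
}

delete_span <- function(seq, start0, width) {
  paste0(substr(seq, 1L, start0), substr(seq, start0 + width + 1L,
                                         nchar(seq)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
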