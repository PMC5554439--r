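# Synthetic clonal-population generator.
#
# Emulates the statistical structure of a near-clonal archaeal population
# sampled from two hot springs: ~47 genomes in 7 clades that differ from an
# ancestral reference by ~119 core SNPs (a mix of ancestrally fixed,
# clade-fixed, private, cross-clade shared and singleton alleles), ~31 small
# indels and 4 multi-nucleotide substitutions, one large genomic island with
# nested deletion patterns, two integrated plasmid-like elements, one
# integrated virus-like element, and four CRISPR arrays whose spacer content
# is identical across all genomes. Every planted feature is recorded in a
# ground-truth table so downstream recovery can be tested exactly.

#' Default deletion-pattern layout for the large genomic island
#'
#' Five non-trivial deletion patterns (plus the intact state) in island-local
#' coordinates, with clade-based genome assignment rules: two clades share the
#' pattern with two deletions, one clade shares a small central deletion, one
#' clade a large left-arm deletion, and two single genomes carry a near-total
#' and a total loss respectively.
#'
#' @return A list of pattern descriptions used by [population_config()].
#' @export
default_island_patterns <- function() {
  list(
    list(pairs = cbind(2000L, 14000L),
         assign = list(list(clade = 5L, members = "all_but_last"))),
    list(pairs = cbind(12000L, 15500L),
         assign = list(list(clade = 4L, members = "all_but_last"))),
    list(pairs = rbind(c(12000L, 15500L), c(20000L, 26000L)),
         assign = list(list(clade = 1L, members = "all"),
                       list(clade = 2L, members = "all"))),
    list(pairs = cbind(5000L, 30000L),
         assign = list(list(clade = 4L, members = "last"))),
    list(pairs = cbind(0L, 33000L),
         assign = list(list(clade = 3L, members = "last")))
  )
}

#' Default integrated mobile-element layout
#'
#' One virus-like element (17 kb, carried by five clades from one spring plus
#' a small clade from the other) and two plasmid-like elements (30 kb carried
#' by one two-member clade; 35 kb carried by a few members of two clades).
#' Elements are generated with a GC offset of +0.05 so their presence is
#' compositionally verifiable.
#'
#' @return A list of element specs used by [population_config()].
#' @export
default_insertion_specs <- function() {
  list(
    list(id = "virus_STIV", position_frac = 0.50, length = 17000L,
         carriers = list(whole_clades = 1:6, partial = list())),
    list(id = "plasmid_1", position_frac = 0.66, length = 30000L,
         carriers = list(whole_clades = 6L, partial = list())),
    list(id = "plasmid_2", position_frac = 0.84, length = 35000L,
         carriers = list(whole_clades = integer(0),
                         partial = list(list(clade = 1L, idx = 1:2),
                                        list(clade = 2L, idx = 1:3))))
  )
}

#' Default CRISPR array layout
#'
#' Four arrays per genome with a shared 24 bp repeat and eight 35 bp spacers
#' each, identical across all genomes. Three spacers are copied from planted
#' mobile elements or from a deleted island segment, so that spacer-vs-genome
#' search yields annotatable self-targets.
#'
#' @return A list describing the planted arrays.
#' @export
default_crispr_spec <- function() {
  list(n_arrays = 4L, n_spacers = 8L, repeat_length = 24L,
       spacer_length = 35L,
       position_fracs = c(0.10, 0.16, 0.22, 0.93),
       self_targets = list(
         list(array = 1L, spacer = 3L, source = "virus_STIV",
              offset = 5000L),
         list(array = 2L, spacer = 4L, source = "plasmid_1",
              offset = 8000L),
         list(array = 3L, spacer = 2L, source = "glyco_island",
              offset = 20500L)))
}

#' Configure a synthetic clonal population
#'
#' The defaults describe the full study-scale population: 47 genomes in 7
#' clades (sizes 6,6,5,5,5 from one spring; 2,18 from the other) carrying 119
#' core SNPs partitioned as 31 ancestrally fixed, 23 clade-fixed, 13 partial
#' private, 9 cross-clade shared (recombination-like) and 43 singletons;
#' 21 insertions, 10 deletions (6 and 9 of them ancestral) and 4
#' multi-nucleotide substitutions; one 33 kb island with six deletion
#' patterns; three integrated elements; and four identical CRISPR arrays.
#' The 500 kb reference length is a scaled coordinate system that preserves
#' all feature counts of the emulated population.
#'
#' @param reference_length Reference length in bp.
#' @param gc_fraction Target GC of the reference backbone.
#' @param clade_sizes Integer vector of clade sizes; genomes sum over it.
#' @param ancestral_snps SNPs fixed in every study genome vs the reference.
#' @param fixed_snps_per_clade SNPs fixed in (exactly) one whole clade.
#' @param private_snps_per_clade SNPs private to one clade, carried by at
#'   least 2 but not all members.
#' @param shared_snps SNPs whose carriers span two clades (recombination-like).
#' @param singletons_per_genome Integer (recycled) or vector of per-genome
#'   singleton SNP counts; `NULL` uses the study-scale default (more
#'   singletons in the first five clades than in the last two).
#' @param n_insertions,n_deletions,n_substitutions Small-variant counts
#'   (lengths 1-10 bp; substitutions 2-10 bp).
#' @param ancestral_insertions,ancestral_deletions How many of the indels are
#'   fixed in all study genomes.
#' @param island_spec Large-island spec (`NULL` for none): a list with `id`,
#'   `position_frac`, `length` and `patterns` (see
#'   [default_island_patterns()]).
#' @param insertion_specs List of integrated-element specs (`NULL` for none).
#' @param crispr_spec CRISPR array spec (`NULL` for none).
#' @param genes If `TRUE`, tile protein-coding genes over the non-feature
#'   reference (stop-free in frame) and plant coding SNPs with prescribed
#'   synonymous/nonsynonymous effects, including the multi-hit gene structure
#'   of the emulated population.
#' @param gene_length,intergenic_gap Gene tiling geometry in bp.
#' @param feature_buffer No small variant is planted within this distance of
#'   an island/element/array boundary.
#' @param min_spacing Minimum spacing between planted small variants (keeps
#'   anchoring unambiguous; the emulated SNP density is ~1 per 17 kb).
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A `population_config` list.
#' @export
population_config <- function(reference_length = 500000L,
                              gc_fraction = 0.37,
                              clade_sizes = c(6L, 6L, 5L, 5L, 5L, 2L, 18L),
                              ancestral_snps = 31L,
                              fixed_snps_per_clade = c(3L, 3L, 3L, 3L, 2L, 3L, 6L),
                              private_snps_per_clade = c(3L, 2L, 2L, 2L, 2L, 0L, 2L),
                              shared_snps = 9L,
                              singletons_per_genome = NULL,
                              n_insertions = 21L,
                              n_deletions = 10L,
                              n_substitutions = 4L,
                              ancestral_insertions = 6L,
                              ancestral_deletions = 9L,
                              island_spec = list(id = "glyco_island",
                                                 position_frac = 0.30,
                                                 length = 33000L,
                                                 patterns = default_island_patterns()),
                              insertion_specs = default_insertion_specs(),
                              crispr_spec = default_crispr_spec(),
                              genes = TRUE,
                              gene_length = 900L,
                              intergenic_gap = 120L,
                              feature_buffer = 150L,
                              min_spacing = 50L,
                              seed = 1L) {
  n_genomes <- sum(clade_sizes)
  n_clades <- length(clade_sizes)
  if (is.null(singletons_per_genome)) {
    if (identical(as.integer(clade_sizes), c(6L, 6L, 5L, 5L, 5L, 2L, 18L))) {
      singletons_per_genome <- c(rep(2L, 8L), rep(1L, 19L),
                                 rep(1L, 8L), rep(0L, 12L))
    } else {
      singletons_per_genome <- rep(1L, n_genomes)
    }
  }
  singletons_per_genome <- rep_len(as.integer(singletons_per_genome), n_genomes)
  cfg <- list(reference_length = as.integer(reference_length),
              gc_fraction = gc_fraction,
              n_genomes = n_genomes,
              clade_sizes = as.integer(clade_sizes),
              ancestral_snps = as.integer(ancestral_snps),
              fixed_snps_per_clade = rep_len(as.integer(fixed_snps_per_clade), n_clades),
              private_snps_per_clade = rep_len(as.integer(private_snps_per_clade), n_clades),
              shared_snps = as.integer(shared_snps),
              singletons_per_genome = singletons_per_genome,
              n_insertions = as.integer(n_insertions),
              n_deletions = as.integer(n_deletions),
              n_substitutions = as.integer(n_substitutions),
              ancestral_insertions = as.integer(ancestral_insertions),
              ancestral_deletions = as.integer(ancestral_deletions),
              island_spec = island_spec,
              insertion_specs = insertion_specs,
              crispr_spec = crispr_spec,
              genes = isTRUE(genes),
              gene_length = as.integer(gene_length),
              intergenic_gap = as.integer(intergenic_gap),
              feature_buffer = as.integer(feature_buffer),
              min_spacing = as.integer(min_spacing),
              seed = as.integer(seed))
  class(cfg) <- "population_config"
  validate_population_config(cfg)
  cfg
}

validate_population_config <- function(cfg) {
  if (cfg$reference_length < 1000L) abort("reference_length must be >= 1000")
  if (cfg$gc_fraction <= 0 || cfg$gc_fraction >= 1) {
    abort("gc_fraction must be in (0, 1)")
  }
  if (any(cfg$clade_sizes < 1L)) abort("clade sizes must be positive")
  counts <- c(cfg$ancestral_snps, cfg$fixed_snps_per_clade,
              cfg$private_snps_per_clade, cfg$shared_snps,
              cfg$singletons_per_genome, cfg$n_insertions, cfg$n_deletions,
              cfg$n_substitutions)
  if (any(counts < 0L)) abort("all planted-feature counts must be >= 0")
  if (cfg$ancestral_insertions > cfg$n_insertions ||
      cfg$ancestral_deletions > cfg$n_deletions) {
    abort("ancestral indel counts cannot exceed total indel counts")
  }
  bad <- cfg$private_snps_per_clade > 0L & cfg$clade_sizes < 3L
  if (any(bad)) {
    abort("private (non-fixed) SNPs need clades of size >= 3")
  }
  # planted large features must be disjoint within the reference
  iv <- feature_intervals(cfg)
  if (nrow(iv) > 0L) {
    if (any(iv$start < 0L) || any(iv$end > cfg$reference_length)) {
      abort("planted features fall outside the reference")
    }
    iv <- dplyr::arrange(iv, .data$start)
    if (nrow(iv) > 1L && any(iv$start[-1] < iv$end[-nrow(iv)])) {
      abort("planted feature coordinates overlap")
    }
  }
  invisible(cfg)
}

array_span <- function(spec) {
  (spec$n_spacers + 1L) * spec$repeat_length +
    spec$n_spacers * spec$spacer_length
}

# Reference-coordinate intervals of all reserved features (island, elements,
# CRISPR arrays), before buffering.
feature_intervals <- function(cfg) {
  rows <- list()
  L <- cfg$reference_length
  if (!is.null(cfg$island_spec)) {
    s <- cfg$island_spec
    st <- as.integer(round(s$position_frac * L))
    rows[[length(rows) + 1L]] <-
      tibble(id = s$id, type = "island", start = st, end = st + s$length)
  }
  for (s in cfg$insertion_specs %||% list()) {
    st <- as.integer(round(s$position_frac * L))
    rows[[length(rows) + 1L]] <-
      tibble(id = s$id, type = "element", start = st, end = st + s$length)
  }
  if (!is.null(cfg$crispr_spec)) {
    sp <- cfg$crispr_spec
    span <- array_span(sp)
    for (i in seq_len(sp$n_arrays)) {
      st <- as.integer(round(sp$position_fracs[i] * L))
      rows[[length(rows) + 1L]] <-
        tibble(id = paste0("crispr_", i), type = "array",
               start = st, end = st + span)
    }
  }
  if (length(rows) == 0L) {
    return(tibble(id = character(), type = character(),
                  start = integer(), end = integer()))
  }
  bind_rows(rows)
}

genome_labels <- function(clade_sizes) {
  k <- length(clade_sizes)
  springs <- if (k == 7L) c(rep("NG05", 5L), rep("GG12", 2L)) else rep("SIM", k)
  unlist(lapply(seq_len(k), function(i) {
    sprintf("%s_c%d_s%02d", springs[i], i, seq_len(clade_sizes[i]))
  }))
}

#' Generate a random reference genome
#'
#' @param length Sequence length in bp (>= 1000).
#' @param gc_fraction Target GC fraction, in (0, 1).
#' @param seed Integer seed; the same call is byte-identical across runs.
#' @return A single character string over A/C/G/T.
#' @examples
#' g <- generate_reference(10000, 0.5, seed = 1)
#' nchar(g)
#' @export
generate_reference <- function(length, gc_fraction, seed = 1L) {
  if (length < 1000) abort("length must be >= 1000")
  if (gc_fraction <= 0 || gc_fraction >= 1) abort("gc_fraction must be in (0,1)")
  local_seed(seed, rand_dna(as.integer(length), gc_fraction))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

# Tile genes over free intervals; returns tibble(gene_id, start, end),
# 0-based half-open, forward strand, length divisible by 3.
tile_genes <- function(free, gene_length, gap) {
  rows <- list()
  gi <- 0L
  for (r in seq_len(nrow(free))) {
    pos <- free$start[r] + gap
    while (pos + gene_length + gap <= free$end[r]) {
      gi <- gi + 1L
      rows[[gi]] <- tibble(gene_id = sprintf("gene_%04d", gi),
                           start = pos, end = pos + gene_length)
      pos <- pos + gene_length + gap
    }
  }
  if (gi == 0L) return(tibble(gene_id = character(), start = integer(),
                              end = integer()))
  bind_rows(rows)
}

# Replace every in-frame stop codon by a same-prefix non-stop codon
# (third base -> C turns TAA/TAG into TAC and TGA into TGC).
recode_stops <- function(reference, genes) {
  v <- strsplit(reference, "", fixed = TRUE)[[1]]
  for (r in seq_len(nrow(genes))) {
    g0 <- genes$start[r]
    n_codon <- (genes$end[r] - g0) %/% 3L
    starts <- g0 + 3L * (seq_len(n_codon) - 1L)
    codons <- paste0(v[starts + 1L], v[starts + 2L], v[starts + 3L])
    bad <- which(codons %in% STOP_CODONS)
    if (length(bad)) v[starts[bad] + 3L] <- "C"
  }
  paste(v, collapse = "")
}

# Largest-remainder allocation of n items to length(w) bins with weights w.
alloc_counts <- function(n, w) {
  if (n == 0L) return(rep(0L, length(w)))
  raw <- n * w / sum(w)
  out <- floor(raw)
  rem <- n - sum(out)
  if (rem > 0L) {
    ord <- order(raw - out, decreasing = TRUE)
    out[ord[seq_len(rem)]] <- out[ord[seq_len(rem)]] + 1L
  }
  as.integer(out)
}

#' Simulate a clonal genome population with full ground truth
#'
#' Builds the ancestral reference (carrying the island, all integrated
#' elements and the CRISPR arrays), then applies each genome's planted edits:
#' SNPs, small indels, multi-nucleotide substitutions, island deletion
#' patterns, and full-length element deletions for non-carriers. All truth
#' coordinates are 0-based half-open on the unedited reference.
#'
#' @param config A [population_config()].
#' @return A `population_sim` object: list with `reference` (character),
#'   `genomes` (named character vector), `truth` (list of tibbles: `snps`,
#'   `indels`, `islands`, `island_patterns`, `insertions`, `arrays`,
#'   `spacers`, `genes`, `clades`), and `config`.
#' @export
simulate_population <- function(config) {
  validate_population_config(config)
  local_seed(config$seed, simulate_population_impl(config))
}

simulate_population_impl <- function(cfg) {
  L <- cfg$reference_length
  ids <- genome_labels(cfg$clade_sizes)
  clade_of <- rep(seq_along(cfg$clade_sizes), cfg$clade_sizes)
  clades <- tibble(genome = ids, clade = clade_of)
  clade_members <- split(ids, clade_of)

  feats <- feature_intervals(cfg)
  reference <- rand_dna(L, cfg$gc_fraction)

  # splice compositionally distinct element sequences (GC + 0.05)
  ins_truth <- list()
  for (s in cfg$insertion_specs %||% list()) {
    st <- as.integer(round(s$position_frac * L))
    elem <- rand_dna(s$length, min(0.95, cfg$gc_fraction + 0.05))
    substr(reference, st + 1L, st + s$length) <- elem
    carriers <- unlist(c(
      clade_members[as.character(s$carriers$whole_clades)],
      lapply(s$carriers$partial, function(p) clade_members[[p$clade]][p$idx])
    ), use.names = FALSE)
    ins_truth[[length(ins_truth) + 1L]] <-
      tibble(id = s$id, start = st, end = st + s$length,
             carriers = list(sort(unique(carriers))))
  }
  insertions <- if (length(ins_truth)) bind_rows(ins_truth) else
    tibble(id = character(), start = integer(), end = integer(),
           carriers = list())

  # island interval (its content is native backbone sequence)
  island <- NULL
  if (!is.null(cfg$island_spec)) {
    st <- as.integer(round(cfg$island_spec$position_frac * L))
    island <- tibble(id = cfg$island_spec$id, start = st,
                     end = st + cfg$island_spec$length)
  }

  # CRISPR arrays: one shared repeat, per-array spacers; a few spacers are
  # copied from element/island interiors (protospacers -> self-targets)
  arrays <- tibble(array_id = character(), start = integer(),
                   end = integer(), repeat_seq = character(),
                   n_repeats = integer())
  spacers <- tibble(array_id = character(), spacer_idx = integer(),
                    start = integer(), end = integer(), seq = character(),
                    source = character())
  if (!is.null(cfg$crispr_spec)) {
    sp <- cfg$crispr_spec
    rep_seq <- rand_dna(sp$repeat_length, 0.5)
    spacer_seqs <- matrix("", nrow = sp$n_arrays, ncol = sp$n_spacers)
    src <- matrix(NA_character_, nrow = sp$n_arrays, ncol = sp$n_spacers)
    for (a in seq_len(sp$n_arrays)) {
      for (j in seq_len(sp$n_spacers)) {
        spacer_seqs[a, j] <- rand_dna(sp$spacer_length, cfg$gc_fraction)
      }
    }
    for (tg in sp$self_targets %||% list()) {
      origin <- if (!is.null(island) && tg$source == island$id) {
        island$start
      } else {
        hit <- insertions[insertions$id == tg$source, ]
        if (nrow(hit) == 0L) next
        hit$start[1]
      }
      pos <- origin + tg$offset
      spacer_seqs[tg$array, tg$spacer] <-
        substr(reference, pos + 1L, pos + sp$spacer_length)
      src[tg$array, tg$spacer] <- tg$source
    }
    for (a in seq_len(sp$n_arrays)) {
      st <- as.integer(round(sp$position_fracs[a] * L))
      units <- character(2L * sp$n_spacers + 1L)
      units[seq(1L, length(units), 2L)] <- rep_seq
      units[seq(2L, length(units), 2L)] <- spacer_seqs[a, ]
      arr <- paste(units, collapse = "")
      substr(reference, st + 1L, st + nchar(arr)) <- arr
      aid <- paste0("crispr_", a)
      arrays <- bind_rows(arrays, tibble(
        array_id = aid, start = st, end = st + nchar(arr),
        repeat_seq = rep_seq, n_repeats = sp$n_spacers + 1L))
      off <- st + sp$repeat_length
      for (j in seq_len(sp$n_spacers)) {
        spacers <- bind_rows(spacers, tibble(
          array_id = aid, spacer_idx = j, start = off,
          end = off + sp$spacer_length, seq = spacer_seqs[a, j],
          source = src[a, j]))
        off <- off + sp$spacer_length + sp$repeat_length
      }
    }
  }

  # gene tiling over non-feature space (buffered), then stop recoding
  buf <- cfg$feature_buffer
  blocked <- feats
  genes <- tibble(gene_id = character(), start = integer(), end = integer())
  if (cfg$genes) {
    free <- free_intervals(L, blocked, buf, edge = 200L)
    genes <- tile_genes(free, cfg$gene_length, cfg$intergenic_gap)
    reference <- recode_stops(reference, genes)
  }

  plan <- plan_variants(cfg, ids, clade_members)
  planted <- plant_variants(cfg, reference, plan, genes, blocked)
  reference <- planted$reference  # unchanged; kept for clarity
  snps <- planted$snps
  indels <- planted$indels

  # island deletion patterns
  island_patterns <- tibble(genome = ids, pattern = "A",
                            pairs = replicate(length(ids), matrix(integer(0), 0, 2),
                                              simplify = FALSE))
  if (!is.null(island)) {
    pat_specs <- cfg$island_spec$patterns %||% list()
    labels <- LETTERS[seq_along(pat_specs) + 1L]
    for (k in seq_along(pat_specs)) {
      ps <- pat_specs[[k]]
      members <- unlist(lapply(ps$assign, function(a) {
        mem <- clade_members[[a$clade]]
        switch(a$members,
               all = mem,
               all_but_last = mem[-length(mem)],
               last = mem[length(mem)],
               first = mem[1],
               abort("unknown pattern member rule"))
      }), use.names = FALSE)
      sel <- island_patterns$genome %in% members
      island_patterns$pattern[sel] <- labels[k]
      island_patterns$pairs[sel] <- replicate(sum(sel), ps$pairs,
                                              simplify = FALSE)
    }
  }

  # assemble each genome from its edits (applied right-to-left)
  genomes <- character(length(ids))
  names(genomes) <- ids
  for (g in ids) {
    ed <- list()
    keep <- map_lgl(snps$carriers, function(cs) g %in% cs)
    if (any(keep)) {
      ed[[1L]] <- tibble(pos = snps$pos[keep], ref = snps$ref[keep],
                         alt = snps$alt[keep])
    }
    keep <- map_lgl(indels$carriers, function(cs) g %in% cs)
    if (any(keep)) {
      ed[[length(ed) + 1L]] <- tibble(pos = indels$pos[keep],
                                      ref = indels$ref[keep],
                                      alt = indels$alt[keep])
    }
    if (!is.null(island)) {
      pr <- island_patterns$pairs[[match(g, island_patterns$genome)]]
      if (nrow(pr) > 0L) {
        st <- island$start + pr[, 1L]
        en <- island$start + pr[, 2L]
        ed[[length(ed) + 1L]] <- tibble(
          pos = st, ref = substring(reference, st + 1L, en), alt = "")
      }
    }
    for (r in seq_len(nrow(insertions))) {
      if (!(g %in% insertions$carriers[[r]])) {
        st <- insertions$start[r]; en <- insertions$end[r]
        ed[[length(ed) + 1L]] <- tibble(
          pos = st, ref = substr(reference, st + 1L, en), alt = "")
      }
    }
    edits <- if (length(ed)) bind_rows(ed) else
      tibble(pos = integer(), ref = character(), alt = character())
    genomes[[g]] <- apply_edits(reference, edits)
  }

  islands_truth <- if (is.null(island)) {
    tibble(id = character(), start = integer(), end = integer())
  } else island

  out <- list(reference = reference,
              genomes = genomes,
              truth = list(snps = snps, indels = indels,
                           islands = islands_truth,
                           island_patterns = island_patterns,
                           insertions = insertions,
                           arrays = arrays, spacers = spacers,
                           genes = genes, clades = clades),
              config = cfg)
  class(out) <- "population_sim"
  out
}

# Complement of blocked intervals (buffered) within [edge, L - edge).
free_intervals <- function(L, blocked, buf, edge = 200L) {
  if (nrow(blocked) == 0L) {
    return(tibble(start = edge, end = L - edge))
  }
  b <- dplyr::arrange(blocked, .data$start)
  starts <- c(edge, b$end + buf)
  ends <- c(b$start - buf, L - edge)
  keep <- ends > starts
  tibble(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

# Build the planting plan: one row per small variant with class, carriers,
# target effect and (possibly) a designated multi-hit gene.
plan_variants <- function(cfg, ids, clade_members) {
  rows <- list()
  add <- function(kind, class, effect, gene_slot, carriers, clade = NA_integer_,
                  length = 1L) {
    rows[[length(rows) + 1L]] <<- tibble(
      kind = kind, class = class, effect = effect, gene_slot = gene_slot,
      clade = clade, len = as.integer(length), carriers = list(carriers))
  }
  use_genes <- cfg$genes
  eff <- function(e) if (use_genes) e else NA_character_

  # --- SNPs ---
  # ancestral (fixed vs reference): two 3-hit genes, remainder mixed
  n_anc <- cfg$ancestral_snps
  spec_a <- min(3L, n_anc); spec_b <- min(3L, max(0L, n_anc - spec_a))
  if (use_genes) {
    for (i in seq_len(spec_a)) add("snp", "ancestral", "nonsyn", "gene_A", ids)
    for (i in seq_len(spec_b)) add("snp", "ancestral", "nonsyn", "gene_B", ids)
  }
  rest <- n_anc - if (use_genes) spec_a + spec_b else 0L
  cnt <- alloc_counts(rest, c(10, 10, 5))
  for (e in rep(c("syn", "nonsyn", "intergenic"), cnt)) {
    add("snp", "ancestral", eff(e), NA_character_, ids)
  }

  # clade-fixed: two 2-hit genes (in the clades with enough fixed SNPs)
  fixed <- cfg$fixed_snps_per_clade
  special_fixed <- list()
  if (use_genes && length(fixed) >= 7L && fixed[2L] >= 2L && fixed[7L] >= 2L) {
    special_fixed <- list(list(clade = 2L, gene = "gene_E"),
                          list(clade = 7L, gene = "gene_F"))
  }
  rest_fixed <- fixed
  for (k in seq_along(fixed)) {
    for (sfx in special_fixed) {
      if (sfx$clade == k) {
        for (i in 1:2) add("snp", "clade_fixed", "nonsyn", sfx$gene,
                           clade_members[[k]], clade = k)
        rest_fixed[k] <- rest_fixed[k] - 2L
      }
    }
  }
  # effects are allocated over the pooled class count, then dealt out to
  # clades in order, so the class-level effect totals are exact
  clade_seq <- rep(seq_along(rest_fixed), rest_fixed)
  cnt <- alloc_counts(length(clade_seq), c(8, 6, 5))
  effs <- rep(c("syn", "nonsyn", "intergenic"), cnt)
  for (i in seq_along(clade_seq)) {
    k <- clade_seq[i]
    add("snp", "clade_fixed", eff(effs[i]), NA_character_,
        clade_members[[k]], clade = k)
  }

  # private (>= 2 but not all members of one clade)
  clade_seq <- rep(seq_along(cfg$private_snps_per_clade),
                   cfg$private_snps_per_clade)
  cnt <- alloc_counts(length(clade_seq), c(6, 4, 3))
  effs <- rep(c("syn", "nonsyn", "intergenic"), cnt)
  for (i in seq_along(clade_seq)) {
    k <- clade_seq[i]
    mem <- clade_members[[k]]
    sizes <- 2:(length(mem) - 1L)
    sz <- sizes[sample.int(length(sizes), 1L)]
    add("snp", "private", eff(effs[i]), NA_character_, sample(mem, sz),
        clade = k)
  }

  # shared across two clades (recombination-like partial sharing)
  pair_cycle <- list(c(1L, 2L), c(1L, 5L), c(2L, 3L), c(4L, 5L), c(1L, 2L),
                     c(3L, 4L), c(2L, 5L), c(1L, 3L), c(2L, 4L))
  n_clades <- length(cfg$clade_sizes)
  cnt <- alloc_counts(cfg$shared_snps, c(4, 3, 2))
  effs <- rep(c("syn", "nonsyn", "intergenic"), cnt)
  for (i in seq_len(cfg$shared_snps)) {
    pr <- pair_cycle[[(i - 1L) %% length(pair_cycle) + 1L]]
    pr <- ((pr - 1L) %% n_clades) + 1L
    if (pr[1] == pr[2]) pr[2] <- (pr[2] %% n_clades) + 1L
    a <- clade_members[[pr[1]]]; b <- clade_members[[pr[2]]]
    carriers <- c(sample(a, min(2L, length(a))), sample(b, min(2L, length(b))))
    add("snp", "shared", eff(effs[i]), NA_character_, carriers)
  }

  # singletons: a 7-hit gene (one nonsense) across distinct genomes of the
  # first clades, remainder mixed
  budget <- setNames(cfg$singletons_per_genome, ids)
  if (use_genes) {
    donors <- names(budget)[budget >= 1L]
    donors <- head(donors, 7L)
    for (i in seq_along(donors)) {
      e <- if (i == 1L) "nonsense" else "nonsyn"
      add("snp", "singleton", e, "gene_C", donors[i])
      budget[donors[i]] <- budget[donors[i]] - 1L
    }
  }
  rest_sing <- sum(budget)
  cnt <- alloc_counts(rest_sing, c(13, 13, 10))
  effs <- rep(c("syn", "nonsyn", "intergenic"), cnt)
  carriers_sing <- rep(names(budget), budget)
  for (i in seq_along(carriers_sing)) {
    add("snp", "singleton", eff(effs[i]), NA_character_, carriers_sing[i])
  }

  # --- indels and substitutions ---
  n_var_ins <- cfg$n_insertions - cfg$ancestral_insertions
  n_var_del <- cfg$n_deletions - cfg$ancestral_deletions
  for (i in seq_len(cfg$ancestral_insertions)) {
    add("insertion", "ancestral", NA_character_, NA_character_, ids,
        length = sample(1:10, 1L))
  }
  for (i in seq_len(cfg$ancestral_deletions)) {
    add("deletion", "ancestral", NA_character_, NA_character_, ids,
        length = sample(1:10, 1L))
  }
  # the multi-hit gene also carries one variable deletion and one insertion
  gene_c_indels <- use_genes && n_var_ins >= 1L && n_var_del >= 1L
  if (gene_c_indels) {
    pool <- if (length(clade_members) >= 5L) {
      unlist(clade_members[1:min(5L, length(clade_members))], use.names = FALSE)
    } else ids
    add("deletion", "variable", NA_character_, "gene_C",
        sample(pool, 1L), length = sample(1:10, 1L))
    add("insertion", "variable", NA_character_, "gene_C",
        sample(pool, 1L), length = sample(1:10, 1L))
    n_var_ins <- n_var_ins - 1L
    n_var_del <- n_var_del - 1L
  }
  for (i in seq_len(n_var_ins)) {
    add("insertion", "variable", NA_character_, NA_character_,
        sample(ids, 1L), length = sample(1:10, 1L))
  }
  for (i in seq_len(n_var_del)) {
    add("deletion", "variable", NA_character_, NA_character_,
        sample(ids, 1L), length = sample(1:10, 1L))
  }
  for (i in seq_len(cfg$n_substitutions)) {
    add("substitution", "variable", NA_character_, NA_character_,
        sample(ids, 1L), length = sample(2:10, 1L))
  }

  if (length(rows) == 0L) {
    return(tibble(kind = character(), class = character(),
                  effect = character(), gene_slot = character(),
                  clade = integer(), len = integer(), carriers = list()))
  }
  bind_rows(rows)
}

# Resolve the plan to concrete positions and alleles on the reference.
plant_variants <- function(cfg, reference, plan, genes, blocked) {
  L <- cfg$reference_length
  buf <- cfg$feature_buffer
  spacing <- cfg$min_spacing
  free <- free_intervals(L, blocked, buf, edge = 200L)
  # intergenic = free minus genes
  intergenic <- free
  if (nrow(genes) > 0L) {
    gb <- dplyr::arrange(genes, .data$start)
    intergenic <- free_intervals(L, bind_rows(
      blocked[, c("start", "end")], gb[, c("start", "end")]), 0L, edge = 200L)
    # re-apply the feature buffer around blocked features only
    intergenic <- intersect_intervals(intergenic, free)
  }
  used <- numeric(0)
  ct <- codon_table()
  # designated multi-hit genes, spread across the gene set
  slot_ids <- c(gene_A = NA, gene_B = NA, gene_C = NA, gene_E = NA,
                gene_F = NA)
  if (nrow(genes) >= 5L) {
    picks <- round(seq(1L, nrow(genes), length.out = 7L))[2:6]
    slot_ids <- setNames(genes$gene_id[picks], names(slot_ids))
  }

  ok_spacing <- function(pos, width = 1L) {
    length(used) == 0L ||
      min(abs(outer(c(pos, pos + width - 1L), used, "-"))) >= spacing
  }
  sample_interval_pos <- function(iv, width) {
    w <- pmax(0L, iv$end - iv$start - width + 1L)
    if (sum(w) == 0L) abort("no room to plant a variant")
    r <- sample.int(nrow(iv), 1L, prob = w)
    iv$start[r] + sample.int(w[r], 1L) - 1L
  }

  snp_rows <- list(); indel_rows <- list()
  for (i in seq_len(nrow(plan))) {
    p <- plan[i, ]
    kind <- p$kind
    effect <- p$effect
    if (kind == "snp" && !is.na(effect) && effect != "intergenic") {
      # coding SNP with a prescribed effect
      placed <- FALSE
      for (try in 1:500) {
        gid <- if (!is.na(p$gene_slot)) slot_ids[[p$gene_slot]] else
          genes$gene_id[sample.int(nrow(genes), 1L)]
        if (is.na(gid)) abort("gene slots require gene tiling")
        gr <- genes[genes$gene_id == gid, ]
        n_codon <- (gr$end - gr$start) %/% 3L
        ci <- sample.int(n_codon, 1L)
        cstart <- gr$start + 3L * (ci - 1L)
        codon <- substr(reference, cstart + 1L, cstart + 3L)
        off <- sample.int(3L, 1L)
        pos <- cstart + off - 1L
        if (!ok_spacing(pos)) next
        refb <- substr(codon, off, off)
        alts <- setdiff(DNA_BASES, refb)
        good <- character(0)
        for (ab in alts) {
          alt_codon <- codon
          substr(alt_codon, off, off) <- ab
          aa0 <- ct[[codon]]; aa1 <- ct[[alt_codon]]
          hit <- switch(effect,
                        syn = aa1 == aa0,
                        nonsyn = aa1 != aa0 && aa1 != "*",
                        nonsense = aa1 == "*")
          if (hit) good <- c(good, ab)
        }
        if (length(good) == 0L) next
        ab <- if (length(good) == 1L) good else sample(good, 1L)
        snp_rows[[length(snp_rows) + 1L]] <- tibble(
          pos = pos, ref = refb, alt = ab, class = p$class,
          clade = p$clade, effect = effect, gene_id = gid,
          carriers = p$carriers)
        used <- c(used, pos)
        placed <- TRUE
        break
      }
      if (!placed) abort("failed to place a coding SNP with target effect")
    } else if (kind == "snp") {
      iv <- if (!is.na(effect) && effect == "intergenic") intergenic else free
      for (try in 1:500) {
        pos <- sample_interval_pos(iv, 1L)
        if (ok_spacing(pos)) break
        if (try == 500L) abort("failed to place a SNP")
      }
      refb <- substr(reference, pos + 1L, pos + 1L)
      ab <- sample(setdiff(DNA_BASES, refb), 1L)
      snp_rows[[length(snp_rows) + 1L]] <- tibble(
        pos = pos, ref = refb, alt = ab, class = p$class, clade = p$clade,
        effect = effect, gene_id = NA_character_, carriers = p$carriers)
      used <- c(used, pos)
    } else {
      # indel / substitution
      len <- p$len
      width <- len + 2L
      target_gene <- if (!is.na(p$gene_slot)) slot_ids[[p$gene_slot]] else NA
      for (try in 1:500) {
        if (!is.na(target_gene)) {
          gr <- genes[genes$gene_id == target_gene, ]
          pos <- gr$start + sample.int(gr$end - gr$start - width, 1L)
        } else {
          pos <- sample_interval_pos(free, width)
        }
        if (ok_spacing(pos, width)) break
        if (try == 500L) abort("failed to place an indel")
      }
      if (kind == "deletion") {
        ref_a <- substr(reference, pos + 1L, pos + len)
        nm <- normalize_indel(reference, pos, ref_a, "")
        row <- tibble(pos = nm$pos, type = "deletion", len = len,
                      ref = nm$ref, alt = "")
      } else if (kind == "insertion") {
        ins <- rand_dna(len, cfg$gc_fraction)
        nm <- normalize_indel(reference, pos, "", ins)
        row <- tibble(pos = nm$pos, type = "insertion", len = len,
                      ref = "", alt = nm$alt)
      } else {
        # substitution: every base differs from the reference, so the edit
        # is unambiguously one multi-nucleotide substitution, not SNPs
        ref_a <- substr(reference, pos + 1L, pos + len)
        rb <- strsplit(ref_a, "")[[1]]
        alt_a <- paste(vapply(rb, function(b) {
          sample(setdiff(DNA_BASES, b), 1L)
        }, character(1)), collapse = "")
        row <- tibble(pos = pos, type = "substitution", len = len,
                      ref = ref_a, alt = alt_a)
      }
      gid <- if (!is.na(target_gene)) target_gene else NA_character_
      indel_rows[[length(indel_rows) + 1L]] <- mutate(
        row, class = p$class, gene_id = gid, carriers = p$carriers)
      used <- c(used, row$pos, row$pos + max(1L, nchar(row$ref)) - 1L)
    }
  }

  snps <- if (length(snp_rows)) arrange(bind_rows(snp_rows), .data$pos) else
    tibble(pos = integer(), ref = character(), alt = character(),
           class = character(), clade = integer(), effect = character(),
           gene_id = character(), carriers = list())
  indels <- if (length(indel_rows)) arrange(bind_rows(indel_rows), .data$pos) else
    tibble(pos = integer(), type = character(), len = integer(),
           ref = character(), alt = character(), class = character(),
           gene_id = character(), carriers = list())
  list(reference = reference, snps = snps, indels = indels)
}

# Interval intersection on tibbles with start/end (0-based half-open).
intersect_intervals <- function(a, b) {
  ia <- IRanges::IRanges(a$start + 1L, a$end)
  ib <- IRanges::IRanges(b$start + 1L, b$end)
  ov <- IRanges::intersect(ia, ib)
  tibble(start = IRanges::start(ov) - 1L, end = IRanges::end(ov))
}

#' @export
print.population_sim <- function(x, ...) {
  cat("Synthetic clonal population\n")
  cat(sprintf("  reference: %s bp, %d genomes in %d clades\n",
              format(nchar(x$reference), big.mark = ","),
              length(x$genomes), length(x$config$clade_sizes)))
  cat(sprintf("  planted: %d SNPs, %d indels/substitutions, %d islands, %d elements, %d arrays\n",
              nrow(x$truth$snps), nrow(x$truth$indels),
              nrow(x$truth$islands), nrow(x$truth$insertions),
              nrow(x$truth$arrays)))
  invisible(x)
}

#' Simulate a sequencing read set from a genome
#'
#' Uniform single-end reads on the forward strand with i.i.d. substitution
#' errors; deletion typing downstream is strand-agnostic, so reverse-strand
#' sampling is deliberately omitted.
#'
#' @param genome Character string (or DNAString) to sample from.
#' @param coverage Target fold coverage (> 0).
#' @param read_length Read length in bp (<= genome length).
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param genome_id Optional label carried through to outputs.
#' @return A `read_set`: list with `reads` (character vector), `qual`
#'   (constant placeholder qualities), and the simulation parameters.
#' @export
simulate_reads <- function(genome, coverage, read_length, error_rate = 0,
                           seed = 1L, genome_id = "genome") {
  genome <- as_seq_chr(genome)[[1]]
  glen <- nchar(genome)
  if (coverage <= 0) abort("coverage must be > 0")
  if (read_length > glen) abort("read_length exceeds genome length")
  n_reads <- as.integer(round(coverage * glen / read_length))
  reads <- local_seed(seed, {
    starts <- sample.int(glen - read_length + 1L, n_reads, replace = TRUE)
    rd <- substring(genome, starts, starts + read_length - 1L)
    if (error_rate > 0) {
      n_err <- rbinom(n_reads, read_length, error_rate)
      mx <- max(n_err)
      k <- 1L
      while (k <= mx) {
        idx <- which(n_err >= k)
        ep <- sample.int(read_length, length(idx), replace = TRUE)
        old <- substr(rd[idx], ep, ep)
        new <- DNA_BASES[(match(old, DNA_BASES) +
                            sample.int(3L, length(idx), replace = TRUE) - 1L) %% 4L + 1L]
        substr(rd[idx], ep, ep) <- new
        k <- k + 1L
      }
    }
    rd
  })
  out <- list(genome_id = genome_id, reads = reads,
              qual = strrep("I", read_length), coverage = coverage,
              read_length = as.integer(read_length), error_rate = error_rate)
  class(out) <- "read_set"
  out
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d x %d bp reads from %s (%.0fx, error %.3g)\n",
              length(x$reads), x$read_length, x$genome_id, x$coverage,
              x$error_rate))
  invisible(x)
}
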