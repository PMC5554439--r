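# Anchored comparison of near-identical assemblies against a designated
# ancestral reference. Maximal exact matches unique in both sequences
# (k-mer seeded) are chained into the best collinear subset; small
# inter-anchor gaps are resolved into SNPs / indels / substitutions by
# pairwise alignment; large gaps feed the genomic-island module.

#' Anchor a query assembly to the reference
#'
#' Finds maximal exact matches that are unique in both sequences (seeded by
#' `min_match`-mers), then chains them into the collinear subset of highest
#' total length (weighted longest-increasing-subsequence on reference order;
#' ties resolved toward the smaller reference start). Multi-scaffold queries
#' are concatenated in reference-anchored order with 100 `N` spacers, which
#' can never anchor.
#'
#' @param reference,query Character strings or `DNAStringSet`s; a query with
#'   several records is treated as a multi-scaffold assembly.
#' @param min_match Minimum exact-match (and seed) length, >= 15. The default
#'   20 bp is effectively unique at the 2 Mb genome scale.
#' @param genome_id Label stored in the `genome` column.
#' @return A tibble with columns `genome`, `ref_start`, `ref_end`,
#'   `query_start`, `query_end` (0-based half-open), strictly increasing and
#'   non-overlapping on both coordinate systems.
#' @export
find_anchors <- function(reference, query, min_match = 20L,
                         genome_id = "query") {
  reference <- as_seq_chr(reference)
  if (length(reference) != 1L) abort("reference must be a single sequence")
  reference <- reference[[1]]
  query <- as_seq_chr(query)
  if (nchar(reference) == 0L || any(nchar(query) == 0L)) {
    abort("empty sequence")
  }
  if (min_match < 15L) abort("min_match must be >= 15")
  query <- concat_scaffolds(reference, query, min_match)
  ch <- cpp_anchor_chain(reference, query, as.integer(min_match))
  tibble(genome = genome_id, ref_start = ch$ref_start, ref_end = ch$ref_end,
         query_start = ch$query_start, query_end = ch$query_end)
}

# Concatenate multi-scaffold queries in reference-anchored order with 100-N
# spacers (which can never anchor); single sequences pass through.
concat_scaffolds <- function(reference, query, min_match = 20L) {
  query <- as_seq_chr(query)
  if (length(query) == 1L) return(query[[1]])
  ord <- order(map_dbl(query, function(sc) {
    ch <- cpp_anchor_chain(reference, sc, as.integer(min_match))
    if (nrow(ch) == 0L) Inf else ch$ref_start[1]
  }))
  paste(query[ord], collapse = strrep("N", 100L))
}

# All inter-anchor gaps of a chain (including sequence ends), classified by
# reference-side width: small (both sides <= max_small), intermediate
# (51-999 bp), island (>= island_min).
chain_gaps <- function(chain, ref_len, query_len, max_small = 50L,
                       island_min = 1000L) {
  rs <- c(chain$ref_start, ref_len)
  re <- c(0L, chain$ref_end)
  qs <- c(chain$query_start, query_len)
  qe <- c(0L, chain$query_end)
  g <- tibble(ref_start = re, ref_end = rs, query_start = qe, query_end = qs) %>%
    mutate(ref_width = .data$ref_end - .data$ref_start,
           query_width = .data$query_end - .data$query_start) %>%
    filter(.data$ref_width > 0L | .data$query_width > 0L)
  g %>% mutate(category = case_when(
    .data$ref_width <= max_small & .data$query_width <= max_small ~ "small",
    .data$ref_width >= island_min ~ "island",
    TRUE ~ "intermediate"))
}

# Decompose two aligned gap sequences into variant records; `gap_start` is
# the 0-based reference position of the gap.
decompose_gap <- function(ref_seq, query_seq, gap_start, reference) {
  if (identical(ref_seq, query_seq)) return(NULL)
  if (nchar(ref_seq) == 0L) {
    nm <- normalize_indel(reference, gap_start, "", query_seq)
    return(tibble(pos = nm$pos, type = "insertion", ref = "", alt = nm$alt,
                  length = nchar(nm$alt)))
  }
  if (nchar(query_seq) == 0L) {
    nm <- normalize_indel(reference, gap_start, ref_seq, "")
    return(tibble(pos = nm$pos, type = "deletion", ref = nm$ref, alt = "",
                  length = nchar(nm$ref)))
  }
  # steep gap costs: gaps are only opened to absorb the length difference,
  # so an equal-length mismatch run stays one substitution record
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query_seq), Biostrings::DNAString(ref_seq),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = TRUE),
    gapOpening = 20, gapExtension = 10)
  ap <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  state <- ifelse(ap == "-", "del", ifelse(as_ == "-", "ins",
                                           ifelse(ap == as_, "m", "x")))
  r <- rle(state)
  rows <- list()
  ref_pos <- gap_start
  col <- 1L
  for (k in seq_along(r$lengths)) {
    len <- r$lengths[k]
    cols <- col:(col + len - 1L)
    st <- r$values[k]
    if (st == "x") {
      rows[[length(rows) + 1L]] <- tibble(
        pos = ref_pos, type = if (len == 1L) "snp" else "substitution",
        ref = paste(as_[cols], collapse = ""),
        alt = paste(ap[cols], collapse = ""), length = len)
      ref_pos <- ref_pos + len
    } else if (st == "del") {
      nm <- normalize_indel(reference, ref_pos,
                            paste(as_[cols], collapse = ""), "")
      rows[[length(rows) + 1L]] <- tibble(pos = nm$pos, type = "deletion",
                                          ref = nm$ref, alt = "", length = len)
      ref_pos <- ref_pos + len
    } else if (st == "ins") {
      nm <- normalize_indel(reference, ref_pos, "",
                            paste(ap[cols], collapse = ""))
      rows[[length(rows) + 1L]] <- tibble(pos = nm$pos, type = "insertion",
                                          ref = "", alt = nm$alt, length = len)
    } else {
      ref_pos <- ref_pos + len
    }
    col <- col + len
  }
  bind_rows(rows)
}

#' Call small variants from an anchor chain
#'
#' Inter-anchor gaps of at most `max_small` bp on both sides are resolved by
#' global pairwise alignment into SNP, insertion, deletion and
#' multi-nucleotide substitution records (indels left-normalized against the
#' reference). Gaps of 51-999 bp on the reference side are reported in the
#' `"intermediate_deletions"` attribute and excluded from both the variant
#' set and island calling; reference gaps >= 1000 bp are left to
#' [build_absence_profiles()].
#'
#' @param reference,query The same sequences the chain was built from;
#'   multi-scaffold queries are concatenated in the same reference-anchored
#'   order as in [find_anchors()].
#' @param chain Anchor chain tibble from [find_anchors()].
#' @param max_small Largest gap (both sides) treated as small variation.
#' @return Tibble with `genome`, `pos` (0-based), `type`, `ref`, `alt`,
#'   `length`; attribute `intermediate_deletions` holds the side table.
#' @export
call_small_variants <- function(reference, query, chain, max_small = 50L) {
  reference <- as_seq_chr(reference)[[1]]
  query <- concat_scaffolds(reference, query, 20L)
  if (nrow(chain) > 0L &&
      (max(chain$ref_end) > nchar(reference) ||
       max(chain$query_end) > nchar(query))) {
    abort("chain does not fit the supplied sequences")
  }
  gid <- if (nrow(chain) > 0L) chain$genome[1] else "query"
  gaps <- chain_gaps(chain, nchar(reference), nchar(query), max_small)
  small <- filter(gaps, .data$category == "small")
  rows <- list()
  for (i in seq_len(nrow(small))) {
    rseq <- substr(reference, small$ref_start[i] + 1L, small$ref_end[i])
    qseq <- substr(query, small$query_start[i] + 1L, small$query_end[i])
    rows[[length(rows) + 1L]] <-
      decompose_gap(rseq, qseq, small$ref_start[i], reference)
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(pos = integer(), type = character(), ref = character(),
           alt = character(), length = integer())
  out <- arrange(mutate(out, genome = gid), .data$pos) %>%
    select("genome", "pos", "type", "ref", "alt", "length")
  attr(out, "intermediate_deletions") <-
    filter(gaps, .data$category == "intermediate") %>%
    mutate(genome = gid) %>%
    select("genome", "ref_start", "ref_end", "query_width")
  out
}

# Per-genome covered reference footprint: anchors plus closed small gaps.
chain_footprint <- function(chain, ref_len, query_len, max_small = 50L) {
  if (nrow(chain) == 0L) return(IRanges::IRanges())
  ir <- IRanges::IRanges(chain$ref_start + 1L, chain$ref_end)
  gaps <- chain_gaps(chain, ref_len, query_len, max_small)
  small <- filter(gaps, .data$category == "small",
                  .data$ref_start > 0L, .data$ref_end < ref_len)
  if (nrow(small) > 0L) {
    # closing a gap of zero reference width is a no-op on the footprint
    w <- small$ref_end > small$ref_start
    if (any(w)) {
      ir <- c(ir, IRanges::IRanges(small$ref_start[w] + 1L, small$ref_end[w]))
    }
  }
  IRanges::reduce(ir)
}

#' Extract core collinear blocks shared by all genomes
#'
#' Intersects the per-genome covered reference footprints (anchors with small
#' gaps closed, so isolated SNPs do not fragment blocks), splitting at any
#' genome's larger gap, and keeps blocks longer than `min_len`.
#'
#' @param chains Named list of anchor chains (one per genome).
#' @param ref_len Reference length in bp.
#' @param query_lens Named vector of query lengths (same names as `chains`).
#' @param min_len Minimum block length (strictly greater than; default 500).
#' @param max_small Small-gap closure threshold, as in
#'   [call_small_variants()].
#' @return Tibble of core blocks with `start`, `end` (0-based half-open).
#' @export
extract_core_blocks <- function(chains, ref_len, query_lens, min_len = 500L,
                                max_small = 50L) {
  if (length(chains) < 2L) abort("need at least 2 genomes")
  cov <- NULL
  for (g in names(chains)) {
    fp <- chain_footprint(chains[[g]], ref_len, query_lens[[g]], max_small)
    cov <- if (is.null(cov)) fp else IRanges::intersect(cov, fp)
  }
  cov <- cov[IRanges::width(cov) > min_len]
  tibble(start = IRanges::start(cov) - 1L, end = IRanges::end(cov))
}

#' Build the core SNP matrix
#'
#' One column per reference position carrying a SNP record inside a core
#' block; genomes without a record at a site carry the reference allele.
#'
#' @param variants Row-bound per-genome variant tibbles from
#'   [call_small_variants()].
#' @param blocks Core blocks from [extract_core_blocks()].
#' @param genomes Character vector of all genome ids (including genomes with
#'   no variants).
#' @return A `snp_matrix`: list with `alleles` (genomes x sites character
#'   matrix) and `sites` (tibble of `pos`, `ref`).
#' @export
build_snp_matrix <- function(variants, blocks, genomes) {
  snps <- filter(variants, .data$type == "snp")
  if (nrow(snps) > 0L && nrow(blocks) > 0L) {
    inb <- map_lgl(snps$pos, function(p) {
      any(p >= blocks$start & p < blocks$end)
    })
    snps <- snps[inb, ]
  } else if (nrow(blocks) == 0L) {
    snps <- snps[0, ]
  }
  dup <- snps %>% count(.data$genome, .data$pos) %>% filter(n > 1L)
  if (nrow(dup) > 0L) abort("conflicting alleles for a genome at one position")
  sites <- snps %>% distinct(.data$pos, .data$ref) %>% arrange(.data$pos)
  if (anyDuplicated(sites$pos)) {
    abort("conflicting reference alleles at one position")
  }
  alleles <- matrix(rep(sites$ref, each = length(genomes)),
                    nrow = length(genomes), ncol = nrow(sites),
                    dimnames = list(genomes, as.character(sites$pos)))
  if (nrow(snps) > 0L) {
    alleles[cbind(match(snps$genome, genomes),
                  match(snps$pos, sites$pos))] <- snps$alt
  }
  out <- list(alleles = alleles, sites = sites)
  class(out) <- "snp_matrix"
  out
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("snp_matrix: %d genomes x %d sites\n",
              nrow(x$alleles), ncol(x$alleles)))
  invisible(x)
}

#' @export
dim.snp_matrix <- function(x) dim(x$alleles)

#' Long (tidy) form of a SNP matrix
#'
#' @param x A `snp_matrix`.
#' @param ... Unused.
#' @return Tibble with `genome`, `pos`, `ref`, `allele`, `is_alt`.
#' @export
tidy.snp_matrix <- function(x, ...) {
  tibble(genome = rep(rownames(x$alleles), times = ncol(x$alleles)),
         pos = rep(x$sites$pos, each = nrow(x$alleles)),
         ref = rep(x$sites$ref, each = nrow(x$alleles)),
         allele = as.vector(x$alleles)) %>%
    mutate(is_alt = .data$allele != .data$ref)
}

#' Run the anchored comparison for a whole population
#'
#' Convenience wrapper: anchors every genome, calls small variants, extracts
#' core blocks and assembles the SNP matrix.
#'
#' @param genomes Named character vector (or DNAStringSet) of assemblies.
#' @param reference Reference sequence.
#' @param min_match Anchor seed length.
#' @return List with `chains`, `variants`, `intermediate`, `blocks`,
#'   `snp_matrix`.
#' @export
compare_genomes <- function(genomes, reference, min_match = 20L) {
  reference <- as_seq_chr(reference)[[1]]
  genomes <- as_seq_chr(genomes)
  if (is.null(names(genomes))) {
    names(genomes) <- sprintf("genome_%02d", seq_along(genomes))
  }
  chains <- imap(genomes, function(seq, id) {
    find_anchors(reference, seq, min_match, genome_id = id)
  })
  var_list <- imap(genomes, function(seq, id) {
    call_small_variants(reference, seq, chains[[id]])
  })
  variants <- bind_rows(var_list)
  intermediate <- bind_rows(map(var_list, attr, "intermediate_deletions"))
  blocks <- extract_core_blocks(chains, nchar(reference),
                                setNames(nchar(genomes), names(genomes)))
  m <- build_snp_matrix(variants, blocks, names(genomes))
  list(chains = chains, variants = variants, intermediate = intermediate,
       blocks = blocks, snp_matrix = m)
}
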