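# Variable-genome detection: reference intervals >= 1000 bp absent from at
# least one genome, filtered (absent from only a single genome -> dropped as
# likely misassembly) and merged into contiguous variable regions, with
# sequence-level presence verification.

#' Per-genome absence profiles from anchor chains
#'
#' Reference intervals with no anchor coverage whose reference-side gap is at
#' least `min_len` bp.
#'
#' @param chains Named list of anchor chains (one per genome, same
#'   reference).
#' @param ref_len Reference length in bp.
#' @param min_len Minimum reference-side gap width (default 1000).
#' @return Tibble with `genome`, `start`, `end` (0-based half-open), sorted
#'   and non-overlapping within each genome.
#' @export
build_absence_profiles <- function(chains, ref_len, min_len = 1000L) {
  bind_rows(imap(chains, function(ch, id) {
    qlen <- if (nrow(ch) > 0L) max(ch$query_end) else 0L
    g <- chain_gaps(ch, ref_len, qlen)
    g <- filter(g, .data$ref_width >= min_len)
    tibble(genome = id, start = g$ref_start, end = g$ref_end)
  }))
}

#' Call genomic islands and variable regions
#'
#' Candidate islands are maximal reference intervals with a constant set of
#' absent genomes (built by segmenting the union of all absence intervals at
#' every boundary). Islands missing from only a single genome are removed;
#' surviving islands shorter than `min_len` are dropped; islands separated
#' by at most `gap_tolerance` bp are grouped into variable regions.
#'
#' @param profiles Absence profiles from [build_absence_profiles()].
#' @param genomes Character vector of all genome ids (presence vectors span
#'   all of them, including genomes with empty profiles).
#' @param min_len Minimum island length (default 1000).
#' @param gap_tolerance Maximum gap between islands grouped into one
#'   variable region (default 100).
#' @param boundary_tolerance Absence-interval edges within this many bp
#'   across genomes are reconciled to their median before segmentation
#'   (default 20).
#' @return Tibble of islands: `island_id`, `region_id`, `start`, `end`,
#'   `n_absent`, `absent` (list of genome ids), `presence` (list of named
#'   logicals over all genomes).
#' @export
call_islands <- function(profiles, genomes, min_len = 1000L,
                         gap_tolerance = 100L, boundary_tolerance = 20L) {
  if (length(genomes) < 2L) abort("need at least 2 genomes")
  if (nrow(profiles) == 0L) {
    return(tibble(island_id = character(), region_id = character(),
                  start = integer(), end = integer(), n_absent = integer(),
                  absent = list(), presence = list()))
  }
  # reconcile boundaries: absence interval edges from different genomes that
  # agree within a few bp are one boundary (anchor extension at a deletion
  # junction can absorb chance-matching flank bases)
  bp <- sort(unique(c(profiles$start, profiles$end)))
  grp <- cumsum(c(TRUE, diff(bp) > boundary_tolerance))
  snapped <- round(tapply(bp, grp, stats::median))[grp]
  snap_map <- setNames(as.integer(snapped), bp)
  profiles$start <- snap_map[as.character(profiles$start)]
  profiles$end <- snap_map[as.character(profiles$end)]
  bp <- sort(unique(c(profiles$start, profiles$end)))
  seg <- tibble(start = bp[-length(bp)], end = bp[-1])
  seg$absent <- map2(seg$start, seg$end, function(s, e) {
    sort(unique(profiles$genome[profiles$start <= s & profiles$end >= e]))
  })
  seg <- seg[map_int(seg$absent, length) > 0L, ]
  if (nrow(seg) == 0L) {
    return(call_islands(profiles[0, ], genomes))
  }
  # merge adjacent segments with identical absentee sets
  merged <- list()
  cur <- seg[1, ]
  for (r in seq_len(nrow(seg))[-1]) {
    if (seg$start[r] == cur$end && setequal(seg$absent[[r]], cur$absent[[1]])) {
      cur$end <- seg$end[r]
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- seg[r, ]
    }
  }
  merged[[length(merged) + 1L]] <- cur
  isl <- bind_rows(merged) %>%
    mutate(n_absent = map_int(.data$absent, length)) %>%
    filter(.data$n_absent >= 2L, .data$end - .data$start >= min_len) %>%
    arrange(.data$start)
  if (nrow(isl) == 0L) {
    return(call_islands(profiles[0, ], genomes))
  }
  region <- cumsum(c(TRUE, isl$start[-1] - isl$end[-nrow(isl)] > gap_tolerance))
  isl %>%
    mutate(region_id = sprintf("region_%02d", region),
           island_id = sprintf("island_%03d", row_number()),
           presence = map(.data$absent, function(ab) {
             setNames(!(genomes %in% ab), genomes)
           })) %>%
    select("island_id", "region_id", "start", "end", "n_absent", "absent",
           "presence")
}

#' Island presence/absence matrix
#'
#' @param islands Island tibble from [call_islands()].
#' @param regions If `TRUE`, collapse islands to variable regions (a genome
#'   is scored present if it retains any member island).
#' @return Integer 0/1 matrix, islands (or regions) x genomes.
#' @export
island_presence_matrix <- function(islands, regions = FALSE) {
  if (nrow(islands) == 0L) return(matrix(integer(0), 0, 0))
  pm <- do.call(rbind, map(islands$presence, as.integer))
  colnames(pm) <- names(islands$presence[[1]])
  rownames(pm) <- islands$island_id
  if (regions) {
    pm <- do.call(rbind, lapply(split(seq_len(nrow(pm)), islands$region_id),
                                function(ix) {
                                  as.integer(colSums(pm[ix, , drop = FALSE]) > 0L)
                                }))
    colnames(pm) <- names(islands$presence[[1]])
  }
  pm
}

#' Verify island presence in a genome by local similarity
#'
#' Anchors the island sequence against the genome (with small gaps closed by
#' pairwise alignment) and scores aligned coverage and identity. The island
#' is called present when coverage >= `min_coverage` of its length at
#' identity >= `min_identity`; partial retention (e.g. one arm of a nested
#' deletion pattern) reports the realized coverage fraction.
#'
#' @param island_sequence Island sequence (>= 1000 bp).
#' @param genome Genome sequence to search.
#' @param min_coverage Minimum aligned fraction of the island (default 0.5).
#' @param min_identity Minimum identity over aligned columns (default 0.95).
#' @param min_match Anchor seed length.
#' @return One-row tibble: `present`, `coverage`, `identity`.
#' @export
verify_presence <- function(island_sequence, genome, min_coverage = 0.5,
                            min_identity = 0.95, min_match = 20L) {
  island_sequence <- as_seq_chr(island_sequence)[[1]]
  genome <- as_seq_chr(genome)[[1]]
  if (nchar(island_sequence) < 1000L) abort("island must be >= 1000 bp")
  if (nchar(genome) == 0L) abort("empty genome")
  chain <- find_anchors(island_sequence, genome, min_match)
  ilen <- nchar(island_sequence)
  if (nrow(chain) == 0L) {
    return(tibble(present = FALSE, coverage = 0, identity = NA_real_))
  }
  anchored <- sum(chain$ref_end - chain$ref_start)
  matched <- anchored
  aligned <- anchored
  gaps <- chain_gaps(chain, ilen, nchar(genome)) %>%
    filter(.data$category == "small",
           .data$ref_width > 0L, .data$query_width > 0L)
  for (i in seq_len(nrow(gaps))) {
    rseq <- substr(island_sequence, gaps$ref_start[i] + 1L, gaps$ref_end[i])
    qseq <- substr(genome, gaps$query_start[i] + 1L, gaps$query_end[i])
    cols <- max(nchar(rseq), nchar(qseq))
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(qseq), Biostrings::DNAString(rseq),
      type = "global")
    aligned <- aligned + cols
    matched <- matched + Biostrings::nmatch(al)
  }
  coverage <- aligned / ilen
  identity <- matched / aligned
  tibble(present = coverage >= min_coverage & identity >= min_identity,
         coverage = coverage, identity = identity)
}
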