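# Coverage-threshold deletion typing within a reference island: map each
# genome's reads to the island, call maximal runs where smoothed depth drops
# below 10x as (drop, recover) breakpoint pairs, and group genomes sharing
# breakpoint lists into labeled deletion patterns.

#' Compute per-base read coverage over an island reference
#'
#' Reads are placed by exact k-mer seeding with near-exact verification (at
#' most `max_mismatch` substitutions over the full read); this purpose-built
#' placer is adequate for the bundled read simulator, not a general aligner.
#' Unplaced reads are ignored.
#'
#' @param reads A `read_set` from [simulate_reads()], or a character vector
#'   of read sequences.
#' @param island_reference Island sequence to map against.
#' @param seed_k Seed length for placement.
#' @param max_mismatch Maximum substitutions tolerated per read.
#' @return A `coverage_vector`: list with `depth` (integer per base),
#'   `genome_id`, `n_reads`, `n_mapped`, `read_length`.
#' @export
compute_coverage <- function(reads, island_reference, seed_k = 20L,
                             max_mismatch = 3L) {
  island_reference <- as_seq_chr(island_reference)[[1]]
  gid <- "reads"
  read_length <- NA_integer_
  if (inherits(reads, "read_set")) {
    gid <- reads$genome_id
    read_length <- reads$read_length
    reads <- reads$reads
  }
  if (length(reads) == 0L || nchar(island_reference) == 0L) {
    abort("reads and island reference must be non-empty")
  }
  if (is.na(read_length)) read_length <- as.integer(nchar(reads[1]))
  hits <- cpp_place_reads(reads, island_reference, as.integer(seed_k),
                          as.integer(max_mismatch))
  L <- nchar(island_reference)
  mapped <- hits[, 1] >= 0L
  pos <- hits[mapped, 1]
  lens <- nchar(reads)[mapped]
  starts <- tabulate(pos + 1L, nbins = L)
  ends <- tabulate(pmin(pos + lens, L) + 1L, nbins = L + 1L)
  depth <- cumsum(starts - ends[seq_len(L)])
  out <- list(depth = as.integer(depth), genome_id = gid,
              n_reads = length(reads), n_mapped = sum(mapped),
              read_length = read_length)
  class(out) <- "coverage_vector"
  out
}

#' @export
print.coverage_vector <- function(x, ...) {
  cat(sprintf("coverage_vector: %s bp, mean depth %.1fx (%d/%d reads placed) [%s]\n",
              format(length(x$depth), big.mark = ","), mean(x$depth),
              x$n_mapped, x$n_reads, x$genome_id))
  invisible(x)
}

#' Call deletion breakpoints from a coverage vector
#'
#' Depth is median-filtered (window ~ 2 read lengths) to keep isolated
#' dips from fragmenting calls, then maximal runs with depth strictly below
#' `threshold` and length >= `min_span` are reported as (drop, recover)
#' pairs; depth exactly at the threshold does not count as deleted. A genome
#' lacking the whole island yields the single full-length pair.
#'
#' @param coverage A `coverage_vector` (or bare numeric depth vector).
#' @param threshold Depth threshold in fold coverage (default 10).
#' @param smooth_window Median filter window in bp (`NULL`: twice the read
#'   length, or 200 when unknown).
#' @param min_span Minimum deletion span reported (default 200 bp).
#' @param genome_id Label for bare numeric input.
#' @return Tibble with `genome`, `drop`, `recover` (0-based half-open).
#' @export
call_breakpoints <- function(coverage, threshold = 10, smooth_window = NULL,
                             min_span = 200L, genome_id = "reads") {
  if (threshold <= 0) abort("threshold must be > 0")
  if (inherits(coverage, "coverage_vector")) {
    depth <- coverage$depth
    genome_id <- coverage$genome_id
    if (is.null(smooth_window)) smooth_window <- 2L * coverage$read_length
  } else {
    depth <- coverage
    if (is.null(smooth_window)) smooth_window <- 200L
  }
  k <- odd_window(min(smooth_window, length(depth)))
  sm <- if (length(depth) > k) runmed(depth, k, endrule = "median") else depth
  low <- sm < threshold
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_span
  tibble(genome = genome_id, drop = starts[keep], recover = ends[keep])
}

#' Group genomes into deletion patterns
#'
#' Genomes whose breakpoint-pair lists match pairwise within `tolerance` bp
#' share a pattern. Patterns are labeled `A`, `B`, ... by descending group
#' size, then by leftmost breakpoint coordinate; the intact (no deletion)
#' state is a pattern like any other.
#'
#' @param calls Breakpoint calls (rows of [call_breakpoints()] output across
#'   genomes; genomes with no rows are intact).
#' @param genomes All genome ids, including intact ones.
#' @param tolerance Coordinate tolerance in bp (default 50).
#' @return Tibble with `genome`, `pattern`, `n_deletions`, `breakpoints`
#'   (list of two-column matrices).
#' @export
group_patterns <- function(calls, genomes, tolerance = 50L) {
  genomes <- sort(genomes)
  bp <- map(setNames(genomes, genomes), function(g) {
    rows <- calls[calls$genome == g, , drop = FALSE]
    rows <- rows[order(rows$drop), , drop = FALSE]
    cbind(drop = rows$drop, recover = rows$recover)
  })
  same <- function(a, b) {
    nrow(a) == nrow(b) && (nrow(a) == 0L || all(abs(a - b) <= tolerance))
  }
  group <- setNames(rep(NA_integer_, length(genomes)), genomes)
  reps <- list()
  for (g in genomes) {
    if (!is.na(group[[g]])) next
    gid <- length(reps) + 1L
    reps[[gid]] <- bp[[g]]
    for (h in genomes[is.na(group)]) {
      if (same(bp[[h]], reps[[gid]])) group[[h]] <- gid
    }
  }
  sizes <- tabulate(group, nbins = length(reps))
  leftmost <- map_dbl(reps, function(m) if (nrow(m) == 0L) Inf else min(m[, 1]))
  ord <- order(-sizes, leftmost)
  label_of <- integer(length(reps))
  label_of[ord] <- seq_along(ord)
  tibble(genome = genomes,
         pattern = LETTERS[label_of[group]],
         n_deletions = unname(map_int(bp, nrow)[genomes]),
         breakpoints = bp[genomes])
}

#' Type deletion patterns for a population of read sets
#'
#' Maps each genome's reads to the island reference, calls breakpoints and
#' groups patterns: the full coverage-based deletion typing workflow.
#'
#' @param read_sets Named list of `read_set` objects (one per genome).
#' @param island_reference Island sequence.
#' @param threshold,min_span,tolerance See [call_breakpoints()] and
#'   [group_patterns()].
#' @return List with `coverage` (named list), `calls`, `patterns`.
#' @export
type_island_deletions <- function(read_sets, island_reference, threshold = 10,
                                  min_span = 200L, tolerance = NULL) {
  covs <- imap(read_sets, function(rs, id) {
    compute_coverage(rs, island_reference)
  })
  calls <- bind_rows(imap(covs, function(cv, id) {
    out <- call_breakpoints(cv, threshold = threshold, min_span = min_span)
    out$genome <- id
    out
  }))
  if (is.null(tolerance)) {
    tolerance <- max(50L, covs[[1]]$read_length)
  }
  patterns <- group_patterns(calls, names(read_sets), tolerance)
  list(coverage = covs, calls = calls, patterns = patterns)
}
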