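# CRISPR array detection (CRT-like tandem-repeat search), spacer extraction,
# and spacer matching by word-seeded ungapped local alignment scored with
# Karlin-Altschul e-values (word size 7, match +2 / mismatch -3, no
# low-complexity filtering), mirroring a BLASTN short-word search.

#' Detect CRISPR arrays in a genome
#'
#' K-mer seeds recurring at CRISPR-like periods nominate a repeat unit
#' (maximal common substring around the seed pair, end-trimmed against
#' chance extension into spacers); arrays are chains of at least
#' `min_repeats` exact repeat copies separated by spacers of
#' `spacer_length_range` bp. Constraints follow the defaults of the standard
#' recognition tools: >= 3 repeat copies, repeat 19-38 bp, spacer 19-48 bp.
#'
#' @param genome Genome sequence.
#' @param genome_id Label carried into the output.
#' @param min_repeats Minimum repeat copies per array.
#' @param repeat_length_range,spacer_length_range Two-element integer ranges.
#' @param seed_k Seed k-mer length for the period scan.
#' @return Tibble of arrays: `genome`, `array_id`, `start`, `end`,
#'   `repeat_seq`, `n_repeats`, and `spacers` (list of tibbles with
#'   `spacer_idx`, `start`, `end`, `seq`).
#' @export
detect_arrays <- function(genome, genome_id = "genome", min_repeats = 3L,
                          repeat_length_range = c(19L, 38L),
                          spacer_length_range = c(19L, 48L),
                          seed_k = 8L) {
  genome <- as_seq_chr(genome)[[1]]
  if (nchar(genome) == 0L) abort("empty genome")
  raw <- cpp_detect_arrays(genome, as.integer(seed_k),
                           repeat_length_range[1], repeat_length_range[2],
                           spacer_length_range[1], spacer_length_range[2],
                           as.integer(min_repeats))
  if (length(raw) == 0L) {
    return(tibble(genome = character(), array_id = character(),
                  start = integer(), end = integer(),
                  repeat_seq = character(), n_repeats = integer(),
                  spacers = list()))
  }
  rows <- map(raw, function(a) {
    rl <- nchar(a$`repeat`)
    rs <- a$repeat_starts
    sp_start <- rs[-length(rs)] + rl
    sp_end <- rs[-1]
    tibble(start = a$start, end = a$end, repeat_seq = a$`repeat`,
           n_repeats = length(rs),
           spacers = list(tibble(
             spacer_idx = seq_along(sp_start),
             start = sp_start, end = sp_end,
             seq = substring(genome, sp_start + 1L, sp_end))))
  })
  bind_rows(rows) %>%
    arrange(.data$start) %>%
    mutate(genome = genome_id,
           array_id = sprintf("array_%02d", row_number())) %>%
    select("genome", "array_id", "start", "end", "repeat_seq", "n_repeats",
           "spacers")
}

#' Karlin-Altschul parameters for an ungapped match/mismatch score system
#'
#' `lambda` is the positive root of `sum(p_i p_j exp(lambda s_ij)) = 1`
#' under uniform base composition; `K` is computed from the Karlin-Altschul
#' lattice formula `K = delta lambda exp(-2 sigma) / (H (1 - exp(-lambda
#' delta)))` with `sigma = sum_j (1/j) (E[exp(lambda S_j); S_j < 0] +
#' P(S_j >= 0))` evaluated by direct binomial summation over the random-walk
#' step distribution.
#'
#' @param match,mismatch Match and mismatch scores (match > 0 > mismatch).
#' @param p_match Probability two random bases match (0.25 uniform).
#' @param max_terms Truncation of the sigma series (it converges
#'   geometrically).
#' @return List with `lambda`, `K`, `H`.
#' @export
karlin_params <- function(match = 2L, mismatch = -3L, p_match = 0.25,
                          max_terms = 400L) {
  if (match <= 0 || mismatch >= 0) abort("need match > 0 > mismatch")
  es <- p_match * match + (1 - p_match) * mismatch
  if (es >= 0) abort("expected step score must be negative")
  f <- function(l) {
    p_match * exp(l * match) + (1 - p_match) * exp(l * mismatch) - 1
  }
  lambda <- uniroot(f, c(1e-8, 10), tol = 1e-14)$root
  H <- lambda * (p_match * match * exp(lambda * match) +
                   (1 - p_match) * mismatch * exp(lambda * mismatch))
  delta <- gcd2(match, -mismatch)
  sigma <- 0
  for (j in seq_len(max_terms)) {
    a <- 0:j
    s <- a * match + (j - a) * mismatch
    w <- stats::dbinom(a, j, p_match)
    term <- sum(w * ifelse(s < 0, exp(lambda * s), 1))
    sigma <- sigma + term / j
    if (term / j < 1e-12) break
  }
  K <- delta * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * delta)))
  list(lambda = lambda, K = K, H = H)
}

gcd2 <- function(a, b) if (b == 0L) a else gcd2(b, a %% b)

#' E-value of an ungapped alignment score
#'
#' `E = K m n exp(-lambda S)` for search space `m x n`.
#'
#' @param score Alignment raw score.
#' @param m,n Query and subject lengths.
#' @param params Output of [karlin_params()].
#' @return Expected number of chance alignments at or above `score`.
#' @export
evalue <- function(score, m, n, params = karlin_params()) {
  params$K * m * n * exp(-params$lambda * score)
}

seed_hits <- function(qseq, sseq, word, match, mismatch, min_score) {
  df <- cpp_seed_extend(qseq, sseq, as.integer(word), as.integer(match),
                        as.integer(mismatch), as.integer(min_score))
  as_tibble(df)
}

#' Match spacers against other spacers or whole genomes
#'
#' Word-seeded (size 7) ungapped extension with match +2 / mismatch -3 and
#' no low-complexity masking; hits with Karlin-Altschul e-value at most
#' `e_cutoff` are reported. Spacer-vs-genome search is strandless (both the
#' spacer and its reverse complement are searched); for spacer-vs-spacer
#' pairs the better strand is reported.
#'
#' @param queries Named character vector of spacer sequences (>= 19 bp).
#' @param subjects Named character vector of subject sequences: other
#'   spacers, or one or more genomes.
#' @param e_cutoff E-value cutoff (default 0.001).
#' @param word,match,mismatch Seeding and scoring parameters.
#' @param mode `"all"` keeps every qualifying hit (genome search);
#'   `"best_strand"` keeps only the best hit per query/subject pair
#'   (spacer-vs-spacer).
#' @param exclude_self Drop pairs where query and subject names are equal.
#' @return Tibble: `query`, `subject`, `strand`, `q_start`, `q_end`,
#'   `s_start`, `s_end`, `length`, `identity`, `score`, `evalue`
#'   (subject coordinates 0-based half-open, forward strand).
#' @export
match_spacers <- function(queries, subjects, e_cutoff = 0.001, word = 7L,
                          match = 2L, mismatch = -3L,
                          mode = c("best_strand", "all"),
                          exclude_self = TRUE) {
  mode <- match.arg(mode)
  if (length(queries) == 0L) abort("empty query set")
  if (any(nchar(queries) < 19L)) abort("spacers must be >= 19 bp")
  if (is.null(names(queries))) {
    names(queries) <- sprintf("spacer_%03d", seq_along(queries))
  }
  if (is.null(names(subjects))) {
    names(subjects) <- sprintf("subject_%03d", seq_along(subjects))
  }
  kp <- karlin_params(match, mismatch)
  rows <- list()
  for (qn in names(queries)) {
    qseq <- queries[[qn]]
    qlen <- nchar(qseq)
    qrc <- revcomp(qseq)
    for (sn in names(subjects)) {
      if (exclude_self && identical(qn, sn)) next
      sseq <- subjects[[sn]]
      slen <- nchar(sseq)
      min_score <- max(word * match,
                       ceiling(log(kp$K * qlen * slen / e_cutoff) / kp$lambda))
      for (strand in c("+", "-")) {
        qq <- if (strand == "+") qseq else qrc
        h <- seed_hits(qq, sseq, word, match, mismatch, min_score)
        if (nrow(h) == 0L) next
        h <- h %>% mutate(
          query = qn, subject = sn, strand = strand,
          length = .data$q_end - .data$q_start,
          s_end = .data$s_start + .data$length,
          identity = .data$n_ident / .data$length,
          evalue = evalue(.data$score, qlen, slen, kp))
        if (strand == "-") {
          h <- h %>% mutate(q_start0 = qlen - .data$q_end,
                            q_end = qlen - .data$q_start,
                            q_start = .data$q_start0) %>%
            select(-"q_start0")
        }
        rows[[length(rows) + 1L]] <- h
      }
    }
  }
  out <- if (length(rows)) bind_rows(rows) else NULL
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble(query = character(), subject = character(),
                  strand = character(), q_start = integer(),
                  q_end = integer(), s_start = integer(), s_end = integer(),
                  length = integer(), identity = numeric(),
                  score = integer(), evalue = numeric()))
  }
  out <- out %>%
    filter(.data$evalue <= e_cutoff) %>%
    select("query", "subject", "strand", "q_start", "q_end", "s_start",
           "s_end", "length", "identity", "score", "evalue") %>%
    arrange(.data$query, .data$subject, .data$evalue)
  if (mode == "best_strand") {
    out <- out %>%
      group_by(.data$query, .data$subject) %>%
      arrange(desc(.data$score), .data$strand, .by_group = TRUE) %>%
      dplyr::slice(1L) %>%
      ungroup()
  }
  out
}

#' Flatten the spacers of a detected array set to a named vector
#'
#' @param arrays Array tibble from [detect_arrays()].
#' @return Named character vector (`<array_id>_sp<idx>` -> sequence).
#' @export
spacer_set <- function(arrays) {
  if (nrow(arrays) == 0L) return(character(0))
  sp <- bind_rows(map2(arrays$array_id, arrays$spacers, function(id, s) {
    mutate(s, array_id = id)
  }))
  setNames(sp$seq, paste0(sp$array_id, "_sp", sp$spacer_idx))
}

#' Find self-targeting spacers
#'
#' Matches every detected spacer against its own genome and reports hits
#' whose subject interval lies outside every detected array (the array loci
#' themselves necessarily match). When island / element intervals are
#' supplied, each self-target is annotated with the feature it falls in.
#'
#' @param arrays Array tibble from [detect_arrays()] for this genome.
#' @param genome The genome sequence the arrays were detected on.
#' @param islands Optional tibble (`id`, `start`, `end`) of genomic islands.
#' @param elements Optional tibble (`id`, `start`, `end`) of integrated
#'   elements.
#' @param e_cutoff E-value cutoff (default 0.001).
#' @return Tibble of self-targets with a `target_annotation` column
#'   (`"genomic island"`, `"insertion element"` or `"other"`).
#' @export
find_self_targets <- function(arrays, genome, islands = NULL,
                              elements = NULL, e_cutoff = 0.001) {
  genome <- as_seq_chr(genome)[[1]]
  sp <- spacer_set(arrays)
  if (length(sp) == 0L) {
    return(tibble(query = character(), s_start = integer(),
                  s_end = integer(), strand = character(),
                  identity = numeric(), evalue = numeric(),
                  target_annotation = character()))
  }
  gid <- if (nrow(arrays) > 0L) arrays$genome[1] else "genome"
  hits <- match_spacers(sp, setNames(genome, gid), e_cutoff = e_cutoff,
                        mode = "all", exclude_self = FALSE)
  in_array <- map_lgl(seq_len(nrow(hits)), function(i) {
    any(hits$s_start[i] < arrays$end & hits$s_end[i] > arrays$start)
  })
  hits <- hits[!in_array, , drop = FALSE]
  annotate <- function(s, e) {
    if (!is.null(elements) && nrow(elements) > 0L &&
        any(s < elements$end & e > elements$start)) return("insertion element")
    if (!is.null(islands) && nrow(islands) > 0L &&
        any(s < islands$end & e > islands$start)) return("genomic island")
    "other"
  }
  hits %>%
    mutate(target_annotation = map2_chr_safe(.data$s_start, .data$s_end,
                                             annotate)) %>%
    select("query", "s_start", "s_end", "strand", "identity", "evalue",
           "target_annotation")
}

map2_chr_safe <- function(a, b, f) {
  if (length(a) == 0L) return(character(0))
  vapply(seq_along(a), function(i) f(a[i], b[i]), character(1))
}

#' Compare CRISPR array content across genomes
#'
#' Builds a per-genome signature from ordered spacer content (arrays in
#' genomic order, spacers in array order) and reports whether all genomes
#' carry identical arrays.
#'
#' @param arrays_by_genome Named list of [detect_arrays()] results.
#' @return List with `table` (tibble: `genome`, `n_arrays`, `n_spacers`,
#'   `signature`) and `all_identical`.
#' @export
array_conservation <- function(arrays_by_genome) {
  tab <- bind_rows(imap(arrays_by_genome, function(arr, id) {
    sig <- paste(map_chr(arr$spacers, function(s) {
      paste(s$seq, collapse = "|")
    }), collapse = "||")
    tibble(genome = id, n_arrays = nrow(arr),
           n_spacers = sum(map_int(arr$spacers, nrow)), signature = sig)
  }))
  list(table = tab, all_identical = length(unique(tab$signature)) == 1L)
}
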