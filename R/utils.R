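# Internal helpers shared across modules.

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

# Random DNA string at a target GC fraction.
rand_dna <- function(n, gc_fraction) {
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

gc_content <- function(seq) {
  tab <- table(strsplit(seq, "", fixed = TRUE)[[1]])
  sum(tab[names(tab) %in% c("G", "C")]) / sum(tab[names(tab) %in% DNA_BASES])
}

# Coerce a DNAStringSet / DNAString / character to a named character vector.
as_seq_chr <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    out <- as.character(x)
  } else if (inherits(x, "DNAString")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- x
  } else {
    abort("sequences must be character, DNAString or DNAStringSet")
  }
  out
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# VCF-style left normalization of an indel against the full reference.
# `pos` is 0-based; deletions remove ref[pos, pos+len), insertions insert
# `alt` before ref[pos]. Returns list(pos, ref, alt).
normalize_indel <- function(reference, pos, ref_allele, alt_allele) {
  del_len <- nchar(ref_allele)
  ins_len <- nchar(alt_allele)
  if (del_len > 0L && ins_len == 0L) {
    while (pos > 0L &&
           substr(reference, pos, pos) ==
           substr(reference, pos + del_len, pos + del_len)) {
      pos <- pos - 1L
    }
    ref_allele <- substr(reference, pos + 1L, pos + del_len)
  } else if (ins_len > 0L && del_len == 0L) {
    ins <- alt_allele
    while (pos > 0L &&
           substr(reference, pos, pos) == substr(ins, ins_len, ins_len)) {
      ins <- paste0(substr(ins, ins_len, ins_len),
                    substr(ins, 1L, ins_len - 1L))
      pos <- pos - 1L
    }
    alt_allele <- ins
  }
  list(pos = pos, ref = ref_allele, alt = alt_allele)
}

# Apply edits to a reference string. `edits` is a tibble with 0-based `pos`,
# `ref` (text removed) and `alt` (text inserted); non-overlapping.
apply_edits <- function(reference, edits) {
  if (nrow(edits) == 0L) return(reference)
  edits <- dplyr::arrange(edits, .data$pos)
  ends <- edits$pos + nchar(edits$ref)
  if (any(edits$pos[-1] < ends[-length(ends)])) {
    abort("overlapping edits")
  }
  keep_start <- c(0L, ends)
  keep_end <- c(edits$pos, nchar(reference))
  pieces <- character(2L * nrow(edits) + 1L)
  pieces[seq(1L, length(pieces), by = 2L)] <-
    substring(reference, keep_start + 1L, keep_end)
  pieces[seq(2L, length(pieces), by = 2L)] <- edits$alt
  paste(pieces, collapse = "")
}

odd_window <- function(w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w + 1L else w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
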