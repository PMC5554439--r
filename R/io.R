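# Writers for the standard interchange formats: FASTA/FASTQ (Biostrings),
# VCF-like variant TSV (1-based), BED (0-based half-open), GFF3, relaxed
# PHYLIP, newick (ape), plus the simulator's truth tables and config.

#' Write sequences as FASTA
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(as_seq_chr(seqs)),
                              path)
  invisible(path)
}

#' Write a read set as FASTQ
#'
#' @param read_set A `read_set` from [simulate_reads()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(read_set, path) {
  n <- length(read_set$reads)
  reads <- Biostrings::DNAStringSet(read_set$reads)
  names(reads) <- sprintf("%s_read_%06d", read_set$genome_id, seq_len(n))
  Biostrings::writeXStringSet(
    reads, path, format = "fastq",
    qualities = Biostrings::BStringSet(rep(read_set$qual, n)))
  invisible(path)
}

#' Write small variants as a VCF-like TSV
#'
#' Columns CHROM, POS (1-based), REF, ALT, TYPE, GENOME. Indel rows are
#' anchored on the preceding base as in VCF.
#'
#' @param variants Variant tibble from [call_small_variants()].
#' @param path Output file.
#' @param chrom Chromosome label.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(variants, path, chrom = "reference") {
  out <- variants %>%
    mutate(CHROM = chrom, POS = .data$pos + 1L,
           REF = ifelse(.data$ref == "", ".", .data$ref),
           ALT = ifelse(.data$alt == "", ".", .data$alt),
           TYPE = .data$type, GENOME = .data$genome) %>%
    select("CHROM", "POS", "REF", "ALT", "TYPE", "GENOME")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param intervals Tibble with `start`, `end` and optionally a name column.
#' @param path Output file.
#' @param chrom Chromosome label.
#' @param name_col Column used for the BED name field, if present.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, chrom = "reference",
                      name_col = NULL) {
  nm <- if (!is.null(name_col) && name_col %in% names(intervals)) {
    intervals[[name_col]]
  } else "."
  out <- data.frame(chrom = chrom, start = intervals$start,
                    end = intervals$end, name = nm)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write the island presence/absence matrix as TSV
#'
#' @param islands Island tibble from [call_islands()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_presence_tsv <- function(islands, path) {
  pm <- island_presence_matrix(islands)
  write.table(data.frame(island = rownames(pm), pm, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an alignment in relaxed PHYLIP format
#'
#' @param aln A `DNAStringSet` (e.g. from [concat_snp_alignment()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alignment_phylip <- function(aln, path) {
  lines <- c(sprintf("%d %d", length(aln), Biostrings::width(aln)[1]),
             sprintf("%s  %s", names(aln), as.character(aln)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a tree in newick format
#'
#' @param tree An `ape::phylo`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

gff3_escape <- function(x) gsub("[;=,\t]", "_", x)

#' Write gene or CRISPR-array intervals as GFF3
#'
#' @param features Tibble with `start`, `end` (0-based half-open), an id
#'   column, and optionally `type`.
#' @param path Output file.
#' @param chrom Sequence label.
#' @param id_col Column holding feature ids.
#' @param type Feature type written to column 3 (default `"gene"`).
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, chrom = "reference",
                       id_col = "gene_id", type = "gene") {
  lines <- c("##gff-version 3",
             sprintf("%s\tclonalpop\t%s\t%d\t%d\t.\t+\t0\tID=%s",
                     chrom, type, features$start + 1L, features$end,
                     gff3_escape(features[[id_col]])))
  writeLines(lines, path)
  invisible(path)
}

#' Write CRISPR spacers as FASTA
#'
#' @param arrays Array tibble from [detect_arrays()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spacers_fasta <- function(arrays, path) {
  write_fasta(spacer_set(arrays), path)
}

#' Write spacer matches as a tabular TSV
#'
#' Mirrors tabular BLAST column order (query, subject, identity, length,
#' coordinates 1-based, score, e-value) plus a strand column.
#'
#' @param matches Match tibble from [match_spacers()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_matches_tsv <- function(matches, path) {
  out <- matches %>%
    mutate(pident = round(100 * .data$identity, 2),
           qstart = .data$q_start + 1L, qend = .data$q_end,
           sstart = .data$s_start + 1L, send = .data$s_end) %>%
    select("query", "subject", "pident", "length", "qstart", "qend",
           "sstart", "send", "strand", "score", "evalue")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

flatten_carriers <- function(tb) {
  if ("carriers" %in% names(tb)) {
    tb$carriers <- map_chr(tb$carriers, paste, collapse = ",")
  }
  tb
}

#' Write a simulated population to a run directory
#'
#' Emits the reference and one FASTA per genome, the ground-truth tables as
#' TSV, planted genes as GFF3, the clade map, and the config as YAML; the
#' config hash and seed are logged to `run_info.txt`.
#'
#' @param sim A `population_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(sim, dir) {
  dir.create(file.path(dir, "genomes"), recursive = TRUE,
             showWarnings = FALSE)
  write_fasta(c(reference = sim$reference), file.path(dir, "reference.fasta"))
  for (g in names(sim$genomes)) {
    write_fasta(sim$genomes[g], file.path(dir, "genomes",
                                          paste0(g, ".fasta")))
  }
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  for (nm in c("snps", "indels", "islands", "insertions", "spacers",
               "clades")) {
    tb <- flatten_carriers(sim$truth[[nm]])
    write.table(tb, file.path(tdir, paste0(nm, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  pat <- sim$truth$island_patterns %>%
    mutate(breakpoints = map_chr(.data$pairs, function(m) {
      paste(sprintf("%d-%d", m[, 1], m[, 2]), collapse = ",")
    })) %>%
    select("genome", "pattern", "breakpoints")
  write.table(pat, file.path(tdir, "island_patterns.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$arrays %>% select(-dplyr::any_of("spacers")),
              file.path(tdir, "arrays.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (nrow(sim$truth$genes) > 0L) {
    write_gff3(sim$truth$genes, file.path(dir, "genes.gff3"))
  }
  cfg <- sim$config
  yaml::write_yaml(cfg[!map_lgl(cfg, is.list)], file.path(dir, "config.yaml"))
  writeLines(sprintf("seed: %d\nconfig_hash: %s", cfg$seed, rlang::hash(cfg)),
             file.path(dir, "run_info.txt"))
  invisible(dir)
}

#' Write a coverage vector as bedGraph
#'
#' @param coverage A `coverage_vector`.
#' @param path Output file.
#' @param chrom Island label.
#' @return `path`, invisibly.
#' @export
write_coverage_bedgraph <- function(coverage, path, chrom = "island") {
  r <- rle(coverage$depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  write.table(data.frame(chrom, starts, ends, r$values), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
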