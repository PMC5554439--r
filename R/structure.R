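# Clonal structure: concatenated-SNP alignment export, distance-based tree
# (a declared stand-in for ML / recombination-aware inference, whose input
# files this module exports), allele-supported clade assignment, and the
# integrated report joining clades to island presence.

#' Concatenated core-SNP alignment
#'
#' One aligned sequence per genome over the SNP columns in reference order,
#' plus the reference row, suitable for export to external ML tools.
#'
#' @param m A `snp_matrix` with at least one site.
#' @param include_reference Add a `reference` row holding reference alleles.
#' @return A `Biostrings::DNAStringSet`.
#' @export
concat_snp_alignment <- function(m, include_reference = TRUE) {
  if (ncol(m$alleles) == 0L) abort("empty SNP matrix")
  seqs <- apply(m$alleles, 1L, paste, collapse = "")
  if (include_reference) {
    seqs <- c(seqs, reference = paste(m$sites$ref, collapse = ""))
  }
  Biostrings::DNAStringSet(seqs)
}

#' Neighbor-joining tree from the SNP matrix
#'
#' Pairwise Hamming distances over SNP columns (no per-site model: at
#' divergences around 1e-5, corrections are negligible), neighbor-joining,
#' rooted on the reference row, which stands for the ancestral strain.
#' Genomes are processed in lexicographic order so ties resolve
#' deterministically.
#'
#' @param m A `snp_matrix` with >= 3 genomes.
#' @param root_on_reference Root the tree on the ancestral reference row.
#' @return An `ape::phylo` tree.
#' @export
nj_tree <- function(m, root_on_reference = TRUE) {
  if (nrow(m$alleles) < 3L) abort("need at least 3 genomes")
  alle <- m$alleles[order(rownames(m$alleles)), , drop = FALSE]
  if (root_on_reference) {
    alle <- rbind(alle, reference = m$sites$ref)
  }
  d <- pairwise_snp_distances(alle)
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  if (root_on_reference) {
    tr <- ape::root(tr, outgroup = "reference", resolve.root = TRUE)
  }
  tr
}

#' Assign genomes to allele-supported clades
#'
#' Candidate clades are the monophyletic groups of the tree (the reference
#' tip and the trivial all-genome group excluded). A group's support is the
#' number of SNP sites whose carrier set equals the group exactly (alleles
#' fixed within and absent outside). Maximal disjoint groups with support
#' >= `min_support` become clades, processed largest-first; genomes left
#' over become singleton clades. This allele-based criterion replaces
#' bootstrap support.
#'
#' @param m A `snp_matrix`.
#' @param tree Tree over the matrix genomes (e.g. [nj_tree()]).
#' @param min_support Minimum supporting alleles per clade (default 1).
#' @return Tibble with `genome`, `clade` (integer, ordered by descending
#'   clade size), `support`.
#' @export
assign_clades <- function(m, tree, min_support = 1L) {
  genomes <- rownames(m$alleles)
  tips <- setdiff(tree$tip.label, "reference")
  if (!setequal(tips, genomes)) abort("tree leaves do not match the matrix")
  carriers <- map(seq_len(ncol(m$alleles)), function(j) {
    genomes[m$alleles[, j] != m$sites$ref[j]]
  })
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  groups <- map(parts, function(ix) setdiff(labs[ix], "reference"))
  groups <- unique(groups[map_int(groups, length) > 0L &
                            map_int(groups, length) < length(genomes)])
  support_of <- function(g) sum(map_lgl(carriers, setequal, y = g))
  ord <- order(-map_int(groups, length),
               map_chr(groups, function(g) sort(g)[1]))
  assigned <- character(0)
  clades <- list()
  for (g in groups[ord]) {
    if (length(intersect(g, assigned)) > 0L) next
    sup <- support_of(g)
    if (sup >= min_support) {
      clades[[length(clades) + 1L]] <- list(members = g, support = sup)
      assigned <- c(assigned, g)
    }
  }
  for (g in setdiff(genomes, assigned)) {
    clades[[length(clades) + 1L]] <- list(members = g,
                                          support = support_of(g))
  }
  ord <- order(-map_int(clades, function(cl) length(cl$members)),
               map_chr(clades, function(cl) sort(cl$members)[1]))
  bind_rows(imap(clades[ord], function(cl, k) {
    tibble(genome = sort(cl$members), clade = k, support = cl$support)
  })) %>% arrange(.data$clade, .data$genome)
}

#' Analyze a clonal genome population end to end
#'
#' Anchors every genome to the reference, calls small variants, extracts
#' core blocks, builds the SNP matrix, infers the tree and clades,
#' classifies alleles, computes divergence and Tajima's D, detects genomic
#' islands, and (when genes are supplied) Nei-Gojobori coding effects,
#' dn/ds and the multi-hit gene report.
#'
#' @param genomes Named character vector or `DNAStringSet` of assemblies.
#' @param reference Designated ancestral reference sequence.
#' @param genes Optional coding intervals (`gene_id`, `start`, `end`).
#' @param min_match Anchor seed length (default 20).
#' @param min_support Allele support required per clade (default 1).
#' @param island_min Minimum island length (default 1000).
#' @param gap_tolerance Island-to-region merge tolerance (default 100).
#' @return A `clonal_analysis` object; see [tidy.clonal_analysis()] and
#'   [glance.clonal_analysis()].
#' @export
analyze_population <- function(genomes, reference, genes = NULL,
                               min_match = 20L, min_support = 1L,
                               island_min = 1000L, gap_tolerance = 100L) {
  reference <- as_seq_chr(reference)[[1]]
  genomes <- as_seq_chr(genomes)
  cmp <- compare_genomes(genomes, reference, min_match)
  m <- cmp$snp_matrix
  core_length <- sum(cmp$blocks$end - cmp$blocks$start)
  tree <- NULL
  clades <- tibble(genome = names(genomes), clade = 1L, support = 0L)
  if (length(genomes) >= 3L && ncol(m$alleles) > 0L) {
    tree <- nj_tree(m)
    clades <- assign_clades(m, tree, min_support)
  }
  classification <- classify_alleles(m, clades)
  div <- divergence(m, core_length)
  taj <- tajima_test(m, clades)
  profiles <- build_absence_profiles(cmp$chains, nchar(reference), island_min)
  islands <- call_islands(profiles, names(genomes), island_min, gap_tolerance)
  effects <- NULL
  dnds_ratio <- NA_real_
  multi_hit <- NULL
  if (!is.null(genes) && nrow(genes) > 0L) {
    effects <- coding_effects(m, genes, reference)
    n_obs <- sum(effects$per_snp$effect == "nonsynonymous")
    s_obs <- sum(effects$per_snp$effect == "synonymous")
    dnds_ratio <- if (s_obs > 0L) {
      dnds(n_obs, s_obs, effects$totals$N_sites, effects$totals$S_sites)
    } else NA_real_
    multi_hit <- multi_hit_genes(effects, classification, cmp$variants)
  }
  out <- list(snp_matrix = m, variants = cmp$variants,
              intermediate = cmp$intermediate, blocks = cmp$blocks,
              chains = cmp$chains, core_length = core_length, tree = tree,
              clades = clades, classification = classification,
              divergence = div, tajima = taj, islands = islands,
              effects = effects, dnds = dnds_ratio, multi_hit = multi_hit,
              genomes = names(genomes))
  class(out) <- "clonal_analysis"
  out
}

#' @export
print.clonal_analysis <- function(x, ...) {
  g <- glance(x)
  cat("Clonal population analysis\n")
  cat(sprintf("  %d genomes, %d core SNP sites over %s bp of core genome\n",
              g$n_genomes, g$n_snps, format(g$core_length, big.mark = ",")))
  cat(sprintf("  divergence d_total = %.3g, d_pi = %.3g; Tajima's D = %.3f\n",
              g$d_total, g$d_pi, g$tajima_d))
  cat(sprintf("  %d clades; %d islands in %d variable regions",
              g$n_clades, g$n_islands, g$n_regions))
  if (!is.na(g$dnds)) cat(sprintf("; dn/ds = %.3f", g$dnds))
  cat("\n")
  invisible(x)
}

#' Tidy per-site table of a clonal analysis
#'
#' @param x A `clonal_analysis`.
#' @param ... Unused.
#' @return The per-site classification tibble, joined with coding effects
#'   when available.
#' @export
tidy.clonal_analysis <- function(x, ...) {
  sites <- x$classification$sites
  if (!is.null(x$effects)) {
    eff <- x$effects$per_snp %>%
      group_by(.data$pos) %>%
      summarise(gene_id = .data$gene_id[1],
                effect = paste(sort(unique(.data$effect)), collapse = ","),
                .groups = "drop")
    sites <- left_join(sites, eff, by = "pos")
  }
  sites
}

#' One-row summary of a clonal analysis
#'
#' @param x A `clonal_analysis`.
#' @param ... Unused.
#' @return A one-row tibble of the headline statistics.
#' @export
glance.clonal_analysis <- function(x, ...) {
  tibble(
    n_genomes = length(x$genomes),
    n_snps = ncol(x$snp_matrix$alleles),
    n_indels = nrow(distinct(
      filter(x$variants, .data$type %in% c("insertion", "deletion")),
      .data$pos, .data$type)),
    n_substitutions = nrow(distinct(
      filter(x$variants, .data$type == "substitution"),
      .data$pos, .data$type)),
    core_length = x$core_length,
    d_total = x$divergence$d_total,
    d_pi = x$divergence$d_pi,
    tajima_d = x$tajima$D[x$tajima$group == "overall"],
    n_clades = length(unique(x$clades$clade)),
    n_islands = nrow(x$islands),
    n_regions = length(unique(x$islands$region_id)),
    dnds = x$dnds)
}

#' Joined clade / island-presence report
#'
#' @param x A `clonal_analysis`.
#' @return Tibble with one row per genome x island: `genome`, `clade`,
#'   `island_id`, `region_id`, `present`.
#' @export
clade_island_report <- function(x) {
  if (nrow(x$islands) == 0L) {
    return(tibble(genome = character(), clade = integer(),
                  island_id = character(), region_id = character(),
                  present = logical()))
  }
  long <- bind_rows(pmap(list(x$islands$island_id, x$islands$region_id,
                              x$islands$presence),
                         function(iid, rid, pres) {
                           tibble(genome = names(pres), island_id = iid,
                                  region_id = rid, present = unname(pres))
                         }))
  left_join(long, x$clades[, c("genome", "clade")], by = "genome") %>%
    select("genome", "clade", "island_id", "region_id", "present") %>%
    arrange(.data$clade, .data$genome, .data$island_id)
}

#' Plot island presence against the clade structure
#'
#' Tile map of island presence (columns) per genome (rows, grouped by
#' clade), the package's rendering of the classic clade-by-island synthesis
#' figure.
#'
#' @param object A `clonal_analysis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clonal_analysis <- function(object, ...) {
  rep <- clade_island_report(object)
  if (nrow(rep) == 0L) abort("no islands to plot")
  ord <- object$clades %>% arrange(.data$clade, .data$genome)
  rep$genome <- factor(rep$genome, levels = rev(ord$genome))
  ggplot2::ggplot(rep, ggplot2::aes(x = .data$island_id, y = .data$genome,
                                    fill = .data$present)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "grey90"),
                               name = "present") +
    ggplot2::facet_grid(clade ~ region_id, scales = "free", space = "free") +
    ggplot2::labs(x = "genomic island", y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot an island coverage profile
#'
#' @param object A `coverage_vector`.
#' @param threshold Depth threshold drawn as a horizontal line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coverage_vector <- function(object, threshold = 10, ...) {
  df <- tibble(pos = seq_along(object$depth) - 1L, depth = object$depth)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                        color = "firebrick") +
    ggplot2::labs(x = "island position (bp)", y = "read depth",
                  title = object$genome_id) +
    ggplot2::theme_minimal(base_size = 9)
}
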