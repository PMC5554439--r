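# Population-genetic statistics on the core SNP matrix: allele
# classification (singleton / private / shared, with an orthogonal
# fixed-vs-reference flag), divergence, Tajima's D, Nei-Gojobori site
# counting and dn/ds, and the multi-hit gene report.

clade_vector <- function(clades, genomes) {
  if (is.data.frame(clades)) {
    v <- setNames(clades$clade, clades$genome)
  } else {
    v <- clades
  }
  if (!all(genomes %in% names(v))) {
    abort("every genome in the matrix needs a clade label")
  }
  v[genomes]
}

#' Classify core SNP alleles
#'
#' Each site is classified from its carrier set: `singleton` (exactly one
#' carrier), `private` (carriers confined to one clade, at least two of
#' them), otherwise `shared`. Sites where every study genome carries the
#' same alternate allele are additionally flagged `fixed_vs_reference` (the
#' flag is orthogonal to the class). Sites with more than one alternate allele
#' have `biallelic = FALSE` and are excluded from the biallelic tallies but
#' not from segregating-site counts.
#'
#' @param m A `snp_matrix`.
#' @param clades Tibble (`genome`, `clade`) or named vector of clade labels.
#' @return An `allele_classification`: list with per-site tibble `sites`,
#'   per-clade tibble `clade_summary`, and one-row `summary`.
#' @export
classify_alleles <- function(m, clades) {
  genomes <- rownames(m$alleles)
  cl <- clade_vector(clades, genomes)
  n <- length(genomes)
  sites <- m$sites
  ns <- nrow(sites)
  rows <- vector("list", ns)
  for (j in seq_len(ns)) {
    col <- m$alleles[, j]
    carriers <- genomes[col != sites$ref[j]]
    alts <- sort(unique(col[col != sites$ref[j]]))
    k <- length(carriers)
    cc <- unique(cl[carriers])
    class <- if (k == 1L) "singleton" else
      if (length(cc) == 1L && k >= 2L) "private" else "shared"
    rows[[j]] <- tibble(
      pos = sites$pos[j], ref = sites$ref[j],
      alt = paste(alts, collapse = ","),
      n_carriers = k, biallelic = length(alts) == 1L,
      class = class,
      fixed_vs_reference = k == n && length(alts) == 1L,
      clade = if (class == "private") cc[1] else NA_integer_,
      carriers = list(carriers))
  }
  sites_out <- bind_rows(rows)
  clade_ids <- sort(unique(cl))
  clade_summary <- map(clade_ids, function(k) {
    mem <- genomes[cl == k]
    fixed_unique <- sum(map_lgl(sites_out$carriers, function(cs) {
      setequal(cs, mem)
    }))
    tibble(clade = k, n_genomes = length(mem),
           n_fixed_unique = fixed_unique,
           n_private = sum(sites_out$class == "private" &
                             !is.na(sites_out$clade) & sites_out$clade == k &
                             sites_out$biallelic),
           n_singletons = sum(sites_out$class == "singleton" &
                                map_lgl(sites_out$carriers,
                                        function(cs) cs[1] %in% mem)))
  }) %>% bind_rows()
  informative <- sites_out$n_carriers >= 2L & !sites_out$fixed_vs_reference
  summary <- tibble(
    n_sites = ns,
    n_fixed_vs_reference = sum(sites_out$fixed_vs_reference),
    n_singleton = sum(sites_out$class == "singleton"),
    n_informative_biallelic = sum(informative & sites_out$biallelic),
    n_private_biallelic = sum(informative & sites_out$biallelic &
                                sites_out$class == "private"))
  out <- list(sites = sites_out, clade_summary = clade_summary,
              summary = summary, n_genomes = n)
  class(out) <- "allele_classification"
  out
}

#' @export
print.allele_classification <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "allele_classification: %d sites (%d fixed vs reference, %d singletons,\n  %d/%d informative biallelic sites private)\n",
    s$n_sites, s$n_fixed_vs_reference, s$n_singleton,
    s$n_private_biallelic, s$n_informative_biallelic))
  invisible(x)
}

#' @rdname classify_alleles
#' @param x An `allele_classification`.
#' @param ... Unused.
#' @export
tidy.allele_classification <- function(x, ...) x$sites

#' @rdname classify_alleles
#' @export
glance.allele_classification <- function(x, ...) x$summary

# Pairwise Hamming distances over SNP columns (counts of differing sites).
pairwise_snp_distances <- function(alleles) {
  n <- nrow(alleles)
  d <- matrix(0L, n, n, dimnames = list(rownames(alleles), rownames(alleles)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sum(alleles[i, ] != alleles[j, ])
    }
  }
  d
}

#' Core-genome divergence statistics
#'
#' Reports both the polymorphism density `d_total = P / L_core` (the number
#' of polymorphic core sites divided by the core genome size) and the mean
#' pairwise difference density `d_pi` (mean pairwise SNP-column differences
#' over all genome pairs, divided by the core genome size).
#'
#' @param m A `snp_matrix`.
#' @param core_length Core genome length in bp (> 0).
#' @return One-row tibble: `n_sites`, `core_length`, `d_total`, `d_pi`.
#' @export
divergence <- function(m, core_length) {
  if (core_length <= 0) abort("core_length must be > 0")
  P <- ncol(m$alleles)
  d <- pairwise_snp_distances(m$alleles)
  n <- nrow(m$alleles)
  mean_pair <- if (n < 2L) 0 else sum(d[upper.tri(d)]) / (n * (n - 1L) / 2L)
  tibble(n_sites = P, core_length = as.numeric(core_length),
         d_total = P / core_length, d_pi = mean_pair / core_length)
}

#' Tajima's D from summary inputs
#'
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the standard constants
#' `a1 = sum(1/i)`, `a2 = sum(1/i^2)` (i = 1..n-1), `b1 = (n+1)/(3(n-1))`,
#' `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`, `e2 = c2/(a1^2+a2)`.
#' `pi` is the mean pairwise difference count per alignment (not per site).
#'
#' @param n Number of sequences (>= 4).
#' @param S Number of segregating sites.
#' @param pi Mean pairwise difference count.
#' @return The D statistic; `NA` (with a warning) when `S = 0`, where the
#'   statistic is undefined.
#' @export
tajimas_d <- function(n, S, pi) {
  if (n < 4L) abort("Tajima's D requires n >= 4")
  if (S < 1L) {
    warn("S = 0: Tajima's D is undefined")
    return(NA_real_)
  }
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Tajima's D over the matrix, overall and per clade
#'
#' `pi` and `S` are computed over the concatenated core SNP columns
#' (monomorphic core positions contribute zero to both), within each group
#' of genomes.
#'
#' @param m A `snp_matrix`.
#' @param clades Optional clade labels; when given, one row per clade is
#'   added to the overall row.
#' @return Tibble with `group`, `n`, `S`, `pi`, `D` (`D` is `NA` for groups
#'   with `n < 4` or `S = 0`).
#' @export
tajima_test <- function(m, clades = NULL) {
  groups <- list(overall = rownames(m$alleles))
  if (!is.null(clades)) {
    cl <- clade_vector(clades, rownames(m$alleles))
    for (k in sort(unique(cl))) {
      groups[[paste0("clade_", k)]] <- rownames(m$alleles)[cl == k]
    }
  }
  bind_rows(imap(groups, function(mem, label) {
    sub <- m$alleles[mem, , drop = FALSE]
    S <- sum(apply(sub, 2L, function(col) length(unique(col)) > 1L))
    d <- pairwise_snp_distances(sub)
    n <- length(mem)
    pi <- if (n < 2L) 0 else sum(d[upper.tri(d)]) / (n * (n - 1L) / 2L)
    D <- if (n >= 4L && S >= 1L) tajimas_d(n, S, pi) else NA_real_
    tibble(group = label, n = n, S = S, pi = pi, D = D)
  }))
}

# Potential synonymous sites per codon: each of the 9 single-base changes
# contributes 1/3 of a site to its position; stops are NA (invalid in a
# reference frame).
codon_syn_sites <- function() {
  ct <- codon_table()
  out <- setNames(numeric(length(ct)), names(ct))
  for (cd in names(ct)) {
    if (ct[[cd]] == "*") { out[[cd]] <- NA_real_; next }
    s <- 0
    for (p in 1:3) {
      for (b in setdiff(DNA_BASES, substr(cd, p, p))) {
        alt <- cd
        substr(alt, p, p) <- b
        if (ct[[alt]] == ct[[cd]]) s <- s + 1 / 3
      }
    }
    out[[cd]] <- s
  }
  out
}

#' Nei-Gojobori site counting and per-SNP coding effects
#'
#' Potential synonymous site counts are computed per reference codon by
#' enumerating all nine single-base changes (standard genetic code, as used
#' for bacterial/archaeal protein genes); `N_sites + S_sites = 3 x codons`
#' by construction. Each SNP inside a gene is classified by substituting its
#' alternate base into the reference codon; changes creating a stop codon
#' count as nonsynonymous and are flagged `nonsense`. SNPs outside every
#' gene are `intergenic`.
#'
#' @param m A `snp_matrix`.
#' @param genes Tibble of forward-strand coding intervals (`gene_id`,
#'   `start`, `end`; 0-based half-open, lengths divisible by 3, no internal
#'   stop in the reference frame).
#' @param reference Reference sequence the matrix positions refer to.
#' @return A `coding_effects`: list with `totals` (one-row tibble `N_sites`,
#'   `S_sites`, `n_codons`), `per_snp`, `per_gene`, and the `genes` table.
#' @export
coding_effects <- function(m, genes, reference) {
  reference <- as_seq_chr(reference)[[1]]
  ct <- codon_table()
  syn_tbl <- codon_syn_sites()
  S_sites <- 0
  n_codons <- 0L
  for (r in seq_len(nrow(genes))) {
    g0 <- genes$start[r]; g1 <- genes$end[r]
    if ((g1 - g0) %% 3L != 0L) {
      abort(sprintf("gene %s length is not divisible by 3", genes$gene_id[r]))
    }
    starts <- seq(g0, g1 - 3L, by = 3L)
    codons <- substring(reference, starts + 1L, starts + 3L)
    if (any(codons %in% STOP_CODONS)) {
      abort(sprintf("gene %s has an in-frame stop codon", genes$gene_id[r]))
    }
    S_sites <- S_sites + sum(syn_tbl[codons])
    n_codons <- n_codons + length(codons)
  }
  N_sites <- 3 * n_codons - S_sites

  # classify every (site, alt) pair
  rows <- list()
  for (j in seq_len(nrow(m$sites))) {
    pos <- m$sites$pos[j]
    ref_b <- m$sites$ref[j]
    alts <- setdiff(unique(m$alleles[, j]), ref_b)
    hit <- which(genes$start <= pos & pos < genes$end)
    for (ab in alts) {
      if (length(hit) == 0L) {
        rows[[length(rows) + 1L]] <- tibble(
          pos = pos, ref = ref_b, alt = ab, gene_id = NA_character_,
          effect = "intergenic", nonsense = FALSE)
        next
      }
      g <- hit[1]
      off <- pos - genes$start[g]
      cstart <- genes$start[g] + 3L * (off %/% 3L)
      codon <- substr(reference, cstart + 1L, cstart + 3L)
      alt_codon <- codon
      substr(alt_codon, off %% 3L + 1L, off %% 3L + 1L) <- ab
      aa0 <- ct[[codon]]; aa1 <- ct[[alt_codon]]
      nonsense <- aa1 == "*"
      effect <- if (nonsense) "nonsynonymous" else
        if (aa0 == aa1) "synonymous" else "nonsynonymous"
      rows[[length(rows) + 1L]] <- tibble(
        pos = pos, ref = ref_b, alt = ab, gene_id = genes$gene_id[g],
        effect = effect, nonsense = nonsense)
    }
  }
  per_snp <- if (length(rows)) bind_rows(rows) else
    tibble(pos = integer(), ref = character(), alt = character(),
           gene_id = character(), effect = character(), nonsense = logical())
  per_gene <- per_snp %>%
    filter(!is.na(.data$gene_id)) %>%
    group_by(.data$gene_id) %>%
    summarise(syn = sum(.data$effect == "synonymous"),
              nonsyn = sum(.data$effect == "nonsynonymous"),
              nonsense = sum(.data$nonsense), .groups = "drop")
  out <- list(totals = tibble(N_sites = N_sites, S_sites = S_sites,
                              n_codons = n_codons),
              per_snp = per_snp, per_gene = per_gene, genes = genes)
  class(out) <- "coding_effects"
  out
}

#' @export
print.coding_effects <- function(x, ...) {
  cat(sprintf(
    "coding_effects: %s codons; %.4g nonsynonymous / %.4g synonymous sites\n  observed: %d nonsynonymous, %d synonymous, %d intergenic SNP alleles\n",
    format(x$totals$n_codons, big.mark = ","), x$totals$N_sites,
    x$totals$S_sites, sum(x$per_snp$effect == "nonsynonymous"),
    sum(x$per_snp$effect == "synonymous"),
    sum(x$per_snp$effect == "intergenic")))
  invisible(x)
}

#' dn/ds from observed counts and potential sites
#'
#' `(N_obs / N_sites) / (S_obs / S_sites)`, uncorrected proportions (no
#' multiple-hit correction; at divergences around 1e-5 the correction is
#' negligible).
#'
#' @param n_obs,s_obs Observed nonsynonymous / synonymous polymorphisms.
#' @param n_sites,s_sites Potential nonsynonymous / synonymous sites (> 0).
#' @return The ratio; `NA` (with a warning) when `s_obs = 0`.
#' @examples
#' dnds(53, 41, 1.3e6, 3.6e5)  # ~0.358
#' @export
dnds <- function(n_obs, s_obs, n_sites, s_sites) {
  if (n_sites <= 0 || s_sites <= 0) abort("site counts must be > 0")
  if (min(n_obs, s_obs) < 0) abort("observed counts must be >= 0")
  if (s_obs == 0) {
    warn("no synonymous polymorphisms: dn/ds is undefined")
    return(NA_real_)
  }
  (n_obs / n_sites) / (s_obs / s_sites)
}

#' Report genes hit by multiple mutations
#'
#' Genes with two or more mutations (SNPs and small indels), tallied as
#' (synonymous, nonsynonymous, indel) and partitioned into mutations fixed
#' against the reference versus variable within the population.
#'
#' @param effects A `coding_effects`.
#' @param classification An `allele_classification` from the same matrix.
#' @param indels Optional per-genome indel records (tibble with `genome`,
#'   `pos`, `type` containing `"insertion"`/`"deletion"` rows), as returned
#'   by [call_small_variants()].
#' @param min_hits Minimum mutations for a gene to be reported (default 2).
#' @return Tibble: `gene_id`, `partition`, `syn`, `nonsyn`, `nonsense`,
#'   `indel`, `n_mutations`.
#' @export
multi_hit_genes <- function(effects, classification, indels = NULL,
                            min_hits = 2L) {
  n_total <- classification$n_genomes
  fixed_pos <- classification$sites$pos[classification$sites$fixed_vs_reference]
  snp_rows <- effects$per_snp %>%
    filter(!is.na(.data$gene_id)) %>%
    mutate(partition = ifelse(.data$pos %in% fixed_pos,
                              "fixed_vs_reference", "variable"),
           kind = ifelse(.data$effect == "synonymous", "syn", "nonsyn"))
  genes <- effects$genes
  indel_rows <- NULL
  if (!is.null(indels) && nrow(indels) > 0L) {
    ev <- indels %>%
      filter(.data$type %in% c("insertion", "deletion")) %>%
      count(.data$pos, .data$type, name = "n_carriers")
    if (nrow(ev) > 0L) {
      gid <- map_chr(ev$pos, function(p) {
        hit <- which(genes$start <= p & p < genes$end)
        if (length(hit)) genes$gene_id[hit[1]] else NA_character_
      })
      indel_rows <- ev %>%
        mutate(gene_id = gid,
               partition = ifelse(.data$n_carriers >= n_total,
                                  "fixed_vs_reference", "variable"),
               kind = "indel") %>%
        filter(!is.na(.data$gene_id))
    }
  }
  all_rows <- bind_rows(
    snp_rows %>% select("gene_id", "partition", "kind") %>%
      mutate(nonsense = snp_rows$nonsense),
    if (!is.null(indel_rows)) {
      indel_rows %>% select("gene_id", "partition", "kind") %>%
        mutate(nonsense = FALSE)
    })
  if (is.null(all_rows) || nrow(all_rows) == 0L) {
    return(tibble(gene_id = character(), partition = character(),
                  syn = integer(), nonsyn = integer(), nonsense = integer(),
                  indel = integer(), n_mutations = integer()))
  }
  all_rows %>%
    group_by(.data$gene_id, .data$partition) %>%
    summarise(syn = sum(.data$kind == "syn"),
              nonsyn = sum(.data$kind == "nonsyn"),
              nonsense = sum(.data$nonsense),
              indel = sum(.data$kind == "indel"),
              n_mutations = dplyr::n(), .groups = "drop") %>%
    filter(.data$n_mutations >= min_hits) %>%
    arrange(.data$partition, desc(.data$n_mutations), .data$gene_id)
}
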