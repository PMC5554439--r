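---
title: "Comparative population genomics of near-clonal genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative population genomics of near-clonal genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalpop)
```

## The problem

Some microbial species — thermoacidophilic archaea such as *Sulfolobus
acidocaldarius* are the motivating case — show astonishingly little core-genome
diversity: tens of genomes sampled from isolated hot springs can differ from a
decades-old reference by only ~100 SNPs across ~2 Mb. At that divergence
(~5 × 10⁻⁵ substitutions per site), standard population-genomic tooling built
for divergent strains is both overkill and unreliable: read mappers and
whole-genome aligners are accurate, but their outputs need a purpose-built
layer to (i) separate the *core* genome (collinear blocks present in every
genome) from the *variable* genome (islands and integrated mobile elements),
(ii) classify the handful of segregating alleles by their carrier structure,
and (iii) resolve nested deletion patterns inside a single variable locus.

`clonalpop` implements that layer for assemblies that are all >95% identical
to a designated ancestral reference, plus a fully ground-truthed simulator so
that every stage can be validated end to end without access to any particular
sequencing dataset.

## Anchored comparison instead of full alignment

For near-identical genomes, full multiple alignment is unnecessary. Each
assembly is compared to the reference through **maximal exact matches that are
unique in both sequences**, seeded by 20-mers (`min_match = 20`; a random
20-mer is effectively unique at the 2 Mb scale, and anchors tolerate the
observed SNP density of roughly one variant per 17 kb). Anchors are chained by
a weighted longest-increasing-subsequence on reference order, ties toward the
smaller reference start, and trimmed so the chain is strictly collinear on
both coordinate systems.

Inter-anchor gaps are then classified by size:

* **≤ 50 bp on both sides** — resolved by global pairwise alignment
  (`Biostrings::pairwiseAlignment`) into SNPs, insertions, deletions and
  multi-nucleotide substitutions. Gap costs are deliberately steep
  (opening 20, extension 10 against match +2/mismatch −3) so that gaps are
  opened only to absorb the length difference between the two sides; an
  equal-length mismatch run therefore stays one substitution record rather
  than fragmenting into spurious indel/SNP mixtures. Indels are
  left-normalized against the reference (VCF convention), so calls are
  comparable across genomes regardless of homopolymer context.
* **51–999 bp on the reference side** — reported as "intermediate deletions"
  in a side table, excluded from SNP statistics and from island calling. The
  field convention defines islands at ≥ 1 kb and small variants at 1–10 bp;
  this band is genuinely ambiguous, and parking it in a side table keeps both
  downstream statistics clean.
* **≥ 1000 bp on the reference side** — handed to the island module.

**Core blocks** are the intersection of per-genome covered footprints, where a
footprint is the anchor chain with small gaps closed. Closing small gaps
matters: without it every SNP would split a block, the >500 bp length filter
would discard the fragments, and SNPs could never lie *inside* the core
genome. Blocks are split only at intermediate/island gaps and filtered to
length > 500 bp, mirroring the locally-collinear-block convention for
core-genome extraction.

Multi-scaffold assemblies are concatenated in reference-anchored order with
100-`N` spacers (which can never anchor) before chaining — the same
contiguation idea as reference-guided scaffolding tools.

## Allele classification and statistics

Every core SNP column is classified from its carrier set:

* `singleton` — exactly one carrier;
* `private` — carriers confined to one clade, at least two of them (alleles
  fixed in a whole clade are private and additionally counted as that clade's
  *unique fixed* support);
* `shared` — carriers spanning clades (recombination or homoplasy);
* orthogonally, a site where **every** genome carries the **same** alternate
  allele is flagged `fixed_vs_reference` — those record divergence on the stem
  lineage, not polymorphism structure.

Sites with more than one alternate allele keep their class but are excluded
from the *biallelic* tallies (they still count as segregating sites in S and
in π).

Divergence is reported two ways, because the two obvious definitions differ
and published tables do not always say which was used: `d_total = P / L_core`
(polymorphic sites over core length) and `d_pi` (mean pairwise difference
count over core length). Both are cheap; reporting both avoids guessing.

**Tajima's D** uses the standard constants (`a1, a2, b1, b2, c1, c2, e1, e2`)
with π computed over the concatenated SNP columns — monomorphic core positions
contribute zero to both π and S, so restricting to SNP columns is exact. D is
evaluated overall and per clade; within clades of n < 4 or with S = 0 the
statistic is undefined and reported as `NA`, never silently as 0.

**Nei–Gojobori site counting**: potential synonymous sites are computed per
reference codon by enumerating all nine single-base changes (each synonymous
change contributes 1/3 site), under the standard genetic code as it applies
to bacterial/archaeal protein genes. `N_sites + S_sites = 3 × codons` holds by
construction and is asserted in tests. Observed SNPs are classified by
substituting the alternate base into the reference codon; stop-creating
changes count as nonsynonymous and carry a `nonsense` flag. dn/ds is the raw
proportion ratio `(N_obs/N_sites)/(S_obs/S_sites)` with no multiple-hit
correction — at divergences near 10⁻⁵ the correction term is far below the
reporting precision.

The **multi-hit gene report** tallies genes with ≥ 2 mutations as
(synonymous, nonsynonymous, indel), partitioned into mutations fixed against
the reference versus variable within the population — the shape of the
classic "loci with multiple mutations" table.

## The variable genome

A genome's **absence profile** is the set of reference intervals ≥ 1000 bp
with no anchor coverage. Candidate islands are maximal intervals with a
constant absentee set, built by segmenting the union of all absence intervals
at every boundary. Two filters follow the established rules: islands missing
from only a single genome are removed (experience attributes most of those to
misassembly), and surviving islands within 100 bp of each other are grouped
into **variable regions** (whole-genome aligners tend to split one biological
region into several blocks).

One numerical subtlety: at a deletion junction, anchor extension absorbs any
flank bases that match by chance, so the same biological boundary can be
observed a few bp apart in different genomes. Boundaries within 20 bp are
therefore reconciled to their median before segmentation
(`boundary_tolerance`, a config key). Without this, a 1 bp jitter can split a
region or push a segment just below the 1 kb filter.

`verify_presence()` is the sequence-level cross-check: each island
representative is anchored against each genome and called present at
≥ 50% aligned coverage with ≥ 95% identity. These two thresholds are not from
any published protocol — they are chosen so that a genome retaining one arm
of a nested deletion pattern still registers the retained segment — and both
are exposed as arguments. Presence is evaluated on the forward strand only;
the simulator never inverts segments, and inversions are out of scope.

## Deletion typing from read coverage

Within a designated island, per-genome deletion breakpoints are read off the
coverage profile: reads are placed by exact 20-mer seeding with ≤ 3
mismatches over the full read (a purpose-built placer adequate for the
bundled simulator — explicitly not a general aligner), depth is
median-filtered with a window of twice the read length, and maximal runs with
depth **strictly below 10×** and length ≥ 200 bp become (drop, recover)
pairs. Depth exactly at 10× is not a deletion. The smoothing window and
minimum span are config keys: the 10× rule is the published procedure, but
raw per-base dips at SNPs would otherwise fragment calls, so some smoothing
choice is unavoidable and is made explicit here.

Genomes whose breakpoint lists agree pairwise within a tolerance (default:
one read length) share a **pattern**, labeled `A`, `B`, … by descending group
size then leftmost coordinate, with the intact state a pattern like any
other. On zero-error simulated reads at ≥ 20×, breakpoint localization error
stays within one read length (asserted in tests).

## CRISPR arrays and spacer matching

Array detection is a k-mer-seeded tandem-repeat search with the constraints
the standard recognition tools document as defaults: ≥ 3 repeat copies,
repeat 19–38 bp, spacer 19–48 bp. An 8-mer recurring at a CRISPR-like period
nominates a repeat unit (the maximal common substring around the seed pair);
because that extension can absorb a few chance-matching spacer bases, up to
three bases are trimmed from each end in search of the trim whose exact
occurrence chain has the most copies. All qualifying chains of the chosen
repeat become arrays, so several loci sharing one repeat — the usual case —
are all found. On random sequence the length constraints make the
false-positive rate effectively zero (tested over 20 seeds).

Spacer matching mirrors an ungapped BLASTN short-word search: word size 7, no
low-complexity masking, match +2 / mismatch −3, hits reported at
Karlin–Altschul e-value ≤ 0.001. The reward/penalty pair is not dictated by
any published setting at word size 7; +2/−3 is this package's recorded
choice. λ is solved from `Σ pᵢpⱼ exp(λ sᵢⱼ) = 1` under uniform composition
and K from the lattice-case formula with the σ series evaluated by direct
binomial summation; both are computed, not hard-coded, and are validated in
tests against a brute-force segment tally (λ ≈ 0.634, K ≈ 0.408 for the
default scores, in line with published ungapped BLASTN parameters). E-values
use raw sequence lengths, so cutoff behavior is calibrated rather than
bit-identical to any particular BLAST build. Spacer-vs-genome search is
strandless (protospacers have no orientation); spacer-vs-spacer search
reports the better strand. Self-targets are spacer-vs-own-genome hits falling
outside every detected array, annotated against supplied island/element
intervals.

## Clonal structure

The concatenated SNP alignment (plus the reference row) is exported as
FASTA/relaxed PHYLIP for external maximum-likelihood or
recombination-aware inference — those methods are intentionally delegated,
not reimplemented. The package's own tree is neighbor-joining on pairwise
Hamming distances over SNP columns (again, no per-site model: corrections
vanish at these divergences), rooted on the reference as the ancestral
proxy, with genomes processed in lexicographic order for deterministic
tie-breaking.

Clades are assigned by **allele support** rather than bootstrap: candidate
groups are the tree's monophyletic sets, a group's support is the number of
sites whose carrier set equals the group exactly, and maximal disjoint groups
with support ≥ 1 become clades (largest first; leftovers become singleton
clades). This is a different criterion from the bootstrap support used in
tree-inference pipelines and is documented as such; it is the natural
operationalization when the signal consists of a handful of clade-fixed
alleles.

## What the simulator emulates — and what it does not

`population_config()` defaults describe the emulated study population:

* 47 genomes in 7 clades (6, 6, 5, 5, 5 from one spring; 2 and 18 from the
  other);
* 119 core SNPs: 31 ancestrally fixed vs the reference, 23 clade-fixed, 13
  partial-private, 9 cross-clade shared (planted as recombination-like
  partial sharing between clade pairs, spread so no single pair accumulates
  enough homoplasy to distort the tree), 43 singletons (more in the
  first-spring clades than the second, 0–2 per genome);
* 21 insertions, 10 deletions (6 and 9 ancestral) and 4 substitutions of
  1–10 bp;
* coding structure: genes tiled at ~85% density, stop codons recoded in
  frame, SNP effects planted to give exactly 41 synonymous, 53
  nonsynonymous (one nonsense) and 25 intergenic changes, including the
  multi-hit genes (two 3-hit fixed genes, one gene with seven nonsynonymous
  singletons plus two indels, and two 2-hit clade-associated genes);
* one 33 kb island with six deletion patterns (intact; one two-deletion
  pattern shared by two clades; a small deletion shared by most of another
  clade; a large arm loss; a near-total and a total loss in single genomes);
* three integrated elements — a 17 kb virus-like and 30/35 kb plasmid-like
  stand-ins at +0.05 GC so presence verification is compositionally
  non-trivial;
* four CRISPR arrays (24 bp repeat, eight 35 bp spacers each) identical
  across all genomes, three spacers copied from element/island interiors so
  self-target search has planted positives.

The emitted ancestral reference **carries** the island and all elements;
non-carrier genomes realize them as full-length deletions. With a single
designated reference this is the only coordinate system in which all four
variable regions coexist, and it matches how an alignment-based analysis
perceives integrated elements.

The default reference length is 500 kb: a scaled coordinate system that
keeps every *count* at study scale while keeping a full pipeline run on one
CPU in the low minutes. Divergence densities are correspondingly ~4× the
real-data values; all recovery tests compare counts and memberships, which
are scale-free. Edits are planted at least 50 bp apart (real SNP spacing is
~17 kb) and outside a 150 bp buffer around features, so anchoring is
unambiguous by construction; indels in the truth tables are left-normalized
with the same convention the caller uses, which is what makes *exact* truth
comparison meaningful.

What the simulator does **not** model: recombination tracts (shared alleles
are planted directly), sequencing-error structure beyond uniform
substitutions, quality-score realism, reverse-strand reads (coverage typing
is strand-agnostic), genome rearrangements and inversions, and assembly
error. Passing the recovery tests therefore demonstrates the pipeline's
correctness on clean near-clonal assemblies, not robustness to misassembly —
the single-genome island filter exists precisely because real pipelines meet
that problem.

## Numerical and design choices, collected

* Coordinates are 0-based half-open internally; written reports use 1-based
  positions (variant TSV) or BED conventions as appropriate.
* Anchor chaining ties break toward the smaller reference start; NJ input
  order is lexicographic; pattern labels order by size then coordinate —
  every pipeline stage is deterministic for a fixed seed.
* `S = 0` (Tajima), `s_obs = 0` (dn/ds) and `n < 4` produce explicit `NA`s
  with warnings, never silent zeros.
* Genes with frame violations or in-frame reference stops are errors, not
  warnings: silent frame corruption would bias site counts.
* The per-criterion problem sizes used by the test suite: toy populations of
  6 genomes at 60 kb for exact-recovery unit tests; 6 kb pairs for the
  full-DP oracle; 50 kb toys for the island brute-force oracle; and one
  47-genome, 500 kb run (25× reads, 101 bp, 0.2% error) for the end-to-end
  recovery checks. These sizes are the package's validation design; the
  same code paths run unchanged at 2 Mb.

## Limitations

* The anchor layer assumes near-identity (>95%); at larger divergences
  unique 20-mer anchors thin out and a true aligner should replace it.
* Island boundaries are reported as maximal intervals with per-genome
  realized sub-intervals; reconciling partially overlapping absences across
  genomes beyond the boundary-median rule is not attempted.
* The NJ tree is a distance-based stand-in, declared non-equivalent to
  maximum-likelihood or recombination-aware inference; the package exports
  their input files instead.
* E-values are calibrated against theory, not against any specific BLAST
  build's effective-length corrections.
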