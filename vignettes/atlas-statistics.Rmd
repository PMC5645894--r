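---
title: "Atlas statistics: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas statistics: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlaskit)
```

`atlaskit` implements the comparative layer of a multi-tissue,
multi-stage RNA-seq expression atlas: tens of cDNA libraries, one per
tissue/stage combination, typically without biological replicates. This
vignette is the package's own account of the statistics it computes, the
parameters that matter, and the design choices made where more than one
reasonable convention exists.

## Library-correlated genes

For each gene the FPKM values across the $L$ libraries are standardized,
$z_i = (x_i - \mu)/s$, and the gene is called *correlated* with library
$i$ when $z_i > 1.5$ and $x_i > 1$, both strict inequalities
(`call_correlated_genes()`). The two thresholds play different roles: the
z cut demands that the library stand out against the gene's own
cross-library profile, while the FPKM cut removes genes whose "signal"
is a fluctuation around zero expression.

Two conventions are deliberately pinned down:

* **Standard deviation.** The sample formula (denominator $n-1$) is the
  default, matching the common spreadsheet/statistics default for small
  $n$; `sd_type = "population"` is available because the definition in
  the field's usage does not always say which is meant. For the worked
  row $(50, 1, 1, 1, 1, 1)$ the two give $z_1 = 2.04$ and $2.24$; both
  clear the 1.5 threshold, so set membership rarely hinges on the choice.
* **Constant genes.** A gene with zero spread gets $z = 0$ everywhere
  and is never correlated with anything; the alternative
  ($0/0 \to$ NaN) silently poisons downstream set arithmetic.

Useful identities that the tests exercise as properties: non-constant
z-rows have mean 0 and sd 1 to $10^{-9}$; multiplying a gene's row by a
positive constant leaves its z-row unchanged, so membership can move only
through the FPKM filter; raising either threshold can only shrink sets.

## Pairwise library similarity

Two libraries with correlated-gene sets of sizes $x$ and $y$ among $n$
genes, sharing $c$ genes, are compared by the exact hypergeometric upper
tail $P(\text{overlap} \ge c)$ (`overlap_pvalue()`). The probability is
Bonferroni-corrected by the number of ordered pairs $m = L^2$ — for 67
libraries, $m = 4489$ — and expressed as the mapping score
$-\log_{10}(mP)$ floored at 0 (`mapping_score()`); scores above 10 reject
independence, and the plotting layer is $\log_2(\text{score})$.

Numerical decisions:

* **Log-gamma evaluation.** The factorial form of the tail overflows
  double precision near $n = 170$. Every term is therefore computed as a
  sum of `lchoose` values and the tail accumulated by log-sum-exp;
  correctness is checked against an exact prime-factorization rational
  oracle for all small problems and against `phyper` at realistic sizes.
* **Underflow-free scores.** `overlap_pvalue(..., log10p = TRUE)` keeps
  the tail in log10 space, so a mapping score of 10 000 is representable
  even though $10^{-10000}$ is not. `similarity_matrix()` uses this path
  throughout.
* **Symmetry.** The tail is mathematically symmetric in $x, y$; floating
  point is not. Arguments are put in canonical order internally so the
  matrix is exactly symmetric.
* **$m = L^2$, not $\binom{L}{2}$.** The correction family includes both
  orders and the self-pairs, matching how these atlases count their
  pairwise comparisons. Corrected probabilities are capped at 1, giving
  score $\ge 0$.
* **Diagonal and zeros.** Self-comparisons are computed like any pair
  ($c = x = y$), so each diagonal cell is its row's maximum.
  $\log_2(\text{score})$ is undefined at score 0; those cells are
  exported as missing rather than $-\infty$.

The null calibration deserves a note: with sets of 100 among 2000 genes,
the smallest overlap whose tail drops below 0.05 is 10, and
$P(\text{overlap} \ge 10) = 0.0248$. The discrete test is therefore
conservative — the rejection rate at nominal 0.05 is about 0.025, not
0.05 — and the test suite asserts agreement with this exact discrete
rate rather than with the nominal level.

## Coverage strata

Per-base depth is normalized to BPKM, $d \cdot 10^9 / D$ where $D$ is the
library's total mapped bases (`bpkm_normalize()`): the number of bases
mapped onto that base out of one billion mapped bases, which makes
libraries of different depth comparable. All bases are ranked by BPKM
descending and cut into 19 groups whose cumulative spans double: group 1
is the top 400 bases, group $g$ ends at rank $400 \cdot 2^{g-1}$
(`group_boundary()`; groups 1–4 end at 3 200, 1–6 at 12 800, 1–12 at
819 200). `stratify()` reports each group's mean BPKM and share of all
aligned bases, plus an explicit remainder (bases beyond rank
$400 \cdot 2^{18}$ and all zero-depth bases) rather than padding it into
group 19 — shares plus remainder always sum to 1.

* **Ties.** Bases with equal BPKM are ordered by (scaffold id, position),
  a stated deterministic rule. Group shares and means are in fact
  tie-invariant (tied bases carry equal mass), but the rule makes the
  full ranking reproducible.
* **Streaming sort.** Only nonzero-depth positions are sorted; zero bases
  all tie at BPKM 0, so only their count matters. The contract — results
  identical to a whole-genome sort — is enforced in the tests against a
  naive full-sort oracle on megabase tracks.
* **Scaffold filter.** Scaffolds under 200 000 bases are removed before
  stratification (`filter_scaffolds()`, strict `<`), because short
  scaffolds concentrate rRNA/mitochondrial signal; totals are recomputed
  after filtering.

`annotation_coverage()` computes strand-agnostic interval unions per
feature class on 1-based inclusive coordinates (the GTF convention); gene
spans are the maximum distance between a gene's exon edges, derived from
exon records when no explicit gene rows are given.
`regress_coverage()` fits covered-fraction on aligned bases by ordinary
least squares separately for single-end and paired-end libraries —
sequencing mode is a real covariate for coverage breadth — and reports
per-library residuals for outlier inspection.

## Composition classifiers

`longest_orf_length()` scans all six frames. The default mode requires an
ATG start and lets an ORF run off the 3' end without a stop; `"edge"`
mode additionally opens a frame at the sequence edge without ATG, for
fragments whose start lies outside the assembled sequence. Codons
containing `N` translate to an unknown residue inside an ORF but cannot
serve as a start. Genes classify by precedence mitochondrial → rRNA →
coding (ORF strictly over 100 residues) → noncoding (`classify_gene()`);
the precedence encodes that scaffold assignment is stronger evidence than
ORF content.

Hit titles classify by the first matching keyword group in priority order
(rRNA, mitochondrion, phage, *M. sexta*, *E. coli*, *Oryza*, others), via
case-insensitive literal substring matching — dots in "e.coli" are
literal, and the bare token "sexta" does match any title containing it,
which is accepted as the rule's literal reading. The priority order means
a "*Manduca sexta* 18S ribosomal RNA" title lands in rRNA, not
*M. sexta*.

`adjust_library_sizes()` exposes the FPKM rescaling implied by excluding
contaminating reads from a library's mapped total: with excluded fraction
$f$, remaining FPKM values scale by $1/(1-f)$, preserving within-library
order. It is left optional and applied, when wanted, before the
expression module.

## Codon usage

Genome-based usage sums codons over in-frame CDS (`count_codons_cds()`;
a length not divisible by 3 is an error naming the record, never a silent
truncation; codons containing ambiguity codes are dropped and tallied).
Transcriptome-based usage weights each transcript's longest-ORF codon
counts by its FPKM per library, normalizes to percentages per library,
and averages those percentages unweighted across libraries
(`transcriptome_usage()`) — the average-of-percentages convention, not
pooled counts, so a deep library does not dominate the mean. Libraries
with all-zero weighted counts are flagged and excluded from the mean.

Stop codons: a complete CDS includes its stop, so genome-based counts
include stops; ORF-based transcriptome counting reflects whatever counts
the caller supplies (the synthetic generator records its terminator, and
`aggregate_by_aa()` reports stops separately under `"*"` so either
convention conserves mass). `correlate_trna()` correlates amino-acid
usage with tRNA gene counts across the 20 standard amino acids — the
amino-acid level is the right one, since codon-level counts are decoupled
from tRNA gene numbers by wobble pairing.

## The synthetic atlas generators

The generators exist to give every downstream stage a planted ground
truth; they are first-class, tested code.

* `generate_fpkm_matrix()` draws per-gene baseline log-FPKM from
  $\mathcal{N}(1, 1.5^2)$ (natural log) — heavy-tailed and strictly
  positive, the qualitative shape of real FPKM distributions — plants a
  disjoint 5% of genes as markers per tissue at an 8-fold effect in the
  tissue's libraries, and adds per-cell log-normal noise with sd 0.3.
  The default design is 10 tissues × 4 stages = 40 libraries. The
  *home-library fraction* (1/10 here) is the operative design quantity:
  with z-score calling, a marker's z margin depends on what fraction of
  libraries carry the elevated value, so a desk-scale design must keep
  that fraction small, as in a real atlas where any one tissue
  contributes only a few of the libraries.
* `generate_depth_track()` spreads a requested total of aligned bases
  over ranks as a truncated discrete power law ($r^{-1.2}$ by default),
  floor-rounded with the remainder assigned to top ranks so the total is
  exact, then shuffles positions. One parameter reproduces the dominance
  of the top coverage strata.
* `generate_transcriptome()` emits complete ATG-to-stop ORFs with sense
  codons drawn from a 64-weight vector, recording realized counts.
* `generate_hit_table()` embeds category keywords in randomized-case
  titles with keyword-free flanking words.

What the generators do **not** emulate: read-level noise, splice
structure, library-size or GC artifacts, shared markers between tissues,
correlated contamination across libraries, and any organism-specific
expression values. Passing the recovery and round-trip tests therefore
demonstrates that the statistics behave as specified under their own
model assumptions — not that any particular organism's published values
are reproduced. In particular, the census of correlated genes on a real
deposited expression table depends on that table and is only checked
when the spreadsheet is supplied externally.

## Problem sizes and determinism

The test suite runs synthetic atlases of 2 000 genes × 40 libraries,
depth tracks up to a megabase with up to $10^7$ aligned bases, a
1 000-replicate null-calibration simulation, and exhaustive
oracle sweeps for the overlap tail at $n \le 30$ — sizes chosen so the
statistical properties are measurable with comfortable margins while the
whole suite runs in well under a minute. Every stochastic step takes an
explicit integer seed, runs in a local RNG scope (the caller's
`.Random.seed` is untouched), and is bit-reproducible for a given seed.

## Known limitations

* The correlated-gene definition has no replicate-aware error model; it
  is a descriptive cut, and its thresholds (1.5, 1) are conventions, not
  fitted quantities.
* Bonferroni over $L^2$ ordered pairs is conservative twice over
  (dependence between pairs, and double-counting of unordered pairs).
* `cluster_order()` provides a deterministic average-linkage ordering
  under correlation distance for heatmap export; it is not a clustering
  inference and assigns no group labels.
* The ORF scanner is a uniform-rule reimplementation of what dedicated
  translators do with more context (e.g. coding-potential models); the
  strict >100-residue rule inherits their main failure mode for short
  coding genes.
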