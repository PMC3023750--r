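---
title: "Methods: profile mining with traitscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profile mining with traitscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitscan)
```

## The problem

Some gene systems — uncommon cofactors, boutique modification pathways,
nutrient-utilization cassettes — are sparsely and sporadically distributed
across prokaryote genomes. Their distribution (the *phylogenetic profile*:
a YES/NO vector over a genome collection) is a powerful query: proteins
whose homologs concentrate in exactly the trait-positive genomes are
candidate members of, or dependents on, the system. `traitscan`
implements three connected analyses around this idea:

1. **Partial Phylogenetic Profiling (PPP)** — per-protein optimal-cutoff
   enrichment scoring of ranked similarity hit lists against a profile.
2. **SIMBAL-style subsequence mapping** — the same scoring applied to
   every window of a probe protein against a trait-partitioned training
   set, localizing *which part* of the protein carries the association.
3. **Six-frame short-ORF scanning** — recovery of small, often uncalled
   precursor peptide genes by their strongly conserved C-terminal motif.

## The PPP score

For one protein, take its similarity hit list sorted by non-increasing
score. Every score cutoff defines a prefix of the list; for a prefix let
$n$ be the number of distinct genomes hit, $y$ the number of those that
are trait-positive, and *depth* the number of protein hits traversed (a
genome hit by several paralogs counts once in $n$ but each hit counts in
depth). Under the null that genomes are hit independently of the trait,
$y \sim \mathrm{Binomial}(n, p)$ with $p$ the profile prevalence. The
protein's score is

$$ S \;=\; \min_{\text{cutoffs}} \; \log_{10} P(X \ge y \mid n, p), $$

the log10 binomial upper-tail probability at the best cutoff. Scores are
$\le 0$; more negative is more surprising. Three conventions matter and
are fixed here:

* **Upper tail, not point mass.** The published score tables this package
  reproduces are consistent with the upper-tail form to ≤ 0.005 log10
  units once the prevalence is calibrated (below); the point-probability
  form misses several rows by 0.01–0.015.
* **Tie blocks are atomic.** Equal-score hits cannot be separated by any
  cutoff, so candidate cutoffs are tie-block boundaries only. Ties in the
  input keep their input order (stable sort) for reproducibility.
* **Shallower cutoff wins score ties,** reporting the most parsimonious
  family; the empty prefix (score 0) is a legal outcome. The query's
  self-hit and genome are counted (configurable), matching reference
  tables whose perfect rows include the query's own genome.

The tail is computed in log space (log-gamma binomial coefficients,
log-sum-exp over tail terms), since interesting scores live far below
double-precision underflow; two identities hold exactly, $S(y{=}0) = 0$
and $S(y{=}n) = n \log_{10} p$. The perfect-prefix identity is also how a
reference table with unknown profile composition can be calibrated: a
printed perfect row $(n, n)$ with score $S$ fixes $p = 10^{S/n}$, and the
package's `phylo_profile(..., override_prevalence =)` accepts that value.
`scripts/acceptance.R` uses exactly this construction.

No multiple-testing correction over cutoff depth is applied; none is
evident in the reference tables, and ranked comparison within one genome
is unaffected by a depth-dependent monotone correction only if all lists
have similar length, so we leave the raw tail probability visible.

## SIMBAL-style window mapping

A protein family is split into TRUE/FALSE partitions by the trait label
of each member's genome of origin — not by any property of the sequences.
Each partition is thinned (fragments shorter than half the partition
median removed, then greedy dereplication so no kept pair exceeds 80%
global-alignment identity; "greater than 80%" is strict, so pairs at
exactly 80% are kept). Every subsequence window of a probe is then scored
like a PPP query against the combined training set, with two differences:
each training **sequence** is its own profile unit (the training set is
already dereplicated; no genome collapsing), and the null prevalence is
$p_t = |\mathrm{TRUE}| / (|\mathrm{TRUE}| + |\mathrm{FALSE}|)$. Scores
are displayed as $-\log_{10}$ tails, so they are $\ge 0$ and hotter is
larger, matching the sign convention of published heat-map apex scores
(positive) versus PPP tables (negative).

The window grid defaults to `min_len = 8`, `len_step = 4`, `pos_step = 2`
plus the full-length apex window: sizes 8 and 12 are where published maps
resolve their finest features, and the steps trade resolution for runtime
(both are exposed). The apex score equals the full-length PPP-style score
by construction — the suite asserts this identity on independent code
paths. Note that window scores are *not* monotone in window length: a
longer window is a different query with its own hit ranking.

Similarity inside window scoring comes from the package's own
Smith–Waterman kernel (BLOSUM62, affine gaps 11/1, a gap of length $L$
costing $11 + L$): raw scores are used directly for ranking without
bit-score conversion, because the cutoff walk consumes only the ordering
and tie structure, not score magnitudes. Exact local alignment has no
word-size or compositional heuristics to tune, which matters for 8–20
residue windows. Mapping a hot window onto a homolog of known structure
is reduced to reporting the homolog interval aligned to the window under
global alignment, with gapped positions flagged.

## Short-ORF and motif scanning

`six_frame_orfs()` enumerates maximal start-to-stop ORFs on all six
frames under genetic code 11 (bacterial/archaeal), with `ATG/GTG/TTG`
starts translated as M in start position, codons containing `N`
translating to `X` (never start/stop), and ORFs lacking a terminal
in-frame stop excluded. Coordinates are 1-based inclusive forward-strand
and include the stop codon; every emitted ORF re-translates to its
reported peptide (asserted in the suite). Default peptide length bounds
20–120 aa bracket reported short precursor predictions (34–78 residues)
with margin. The most upstream qualifying start per stop is reported
because start-site predictions for such peptides are unreliable;
`all_starts = TRUE` adds the nested alternatives.

`scan_cterm_motif()` matches a residue pattern (uppercase literal, `x`
wildcard) anchored at, or within `max_distance` of, the C-terminus.
`column_conservation()` supplies per-column dominant residue/fraction and
invariant flags for alignments of recovered peptides, with ties on the
dominant residue resolved alphabetically (deterministic output).

## The synthetic data generator

No sequence accessions accompany the reference analyses, so validation is
property-based on generated collections whose statistical structure is the
one the method assumes. The defaults, chosen once as a desk-scale portrait
of a real collection:

* **40 genomes in 10 clades of 4; trait prevalence 0.10** (4 positive
  genomes, each in a different clade). The 10% prevalence is the regime of
  a sparsely distributed cofactor among ~1450 genomes; sporadic placement
  across clades is what makes such profiles informative. A 3% preset
  mirrors rarer systems but at 40 genomes would leave 1–2 positive
  genomes, where enrichment cannot separate signal from a single lucky
  background hit (the best planted score is $K \log_{10} K/N$, and with
  the self-hit counted a background protein ties it with probability
  $\approx 1$ across a 200-protein genome when $K \le 2$); use it with
  larger collections.
* **Marker cluster** (3 families, 1 copy in all and only trait-positive
  genomes), **dependent families** (4 families, 1–6 copies per positive
  genome, absent elsewhere), each member carrying an invariant 15-residue
  **diagnostic window**, and a **sister clade** present in every genome
  that shares the dependent ancestor everywhere *except* that window —
  so outside the window dependent and sister members are exchangeable,
  and the window is the only trait-diagnostic subsequence.
* **Background families** (186, one copy per genome) with within-clade
  identity 0.90 over between-clade identity 0.65, giving background hit
  lists the clade-local structure real paralog-free families have.
* **Precursor genes** (30–45 aa, conserved 23-residue tail, invariant
  C-terminal `CGVY`, seven of the last eight tail positions invariant)
  embedded in 2 kb contigs of trait-positive genomes behind an in-frame
  upstream stop; decoy genes with a shuffled suffix in every genome.
* Substitutions are planted at exactly `round(n(1 - t))` positions with
  BLOSUM62-weighted replacements, so realized identity equals the target
  to within half a position. (Bernoulli per-site mutation would scatter
  realized identity by several percent at typical lengths, making the
  generator's own contracts unverifiable.) No indels are simulated, and
  there is no phylogeny beyond the two-level clade structure — passing
  tests therefore say nothing about alignment-induced rank noise or deep
  tree correlation in real data; they validate the scoring machinery,
  not BLAST.

All randomness flows from one spec seed; identical specs give
byte-identical bundles. Model-based hit tables (`synth_hit_lists()`)
score within-homology-group pairs as $2 L \cdot \mathrm{identity}$ plus
Gaussian noise (sd 2), with a handful of low-scoring cross-group hits, so
PPP runs without any aligner; the built-in aligner route is exercised
separately and the two routes are asserted to agree.

## Numerical and design notes

* Binomial tails: log-sum-exp over at most $n - y + 1$ terms; point
  masses normalize to 1 within 1e−12 up to $n = 200$.
* Exact score ties in the cutoff walk resolve to the shallower depth by
  scanning candidates in depth order; the $y{=}n$ shortcut makes equal
  perfect prefixes bit-identical, so this tie-break is exact, not
  float-fragile.
* The SW kernel is scored-only, linear-memory, with a per-query position
  profile; it matches `Biostrings::pairwiseAlignment` and an independent
  full-matrix DP oracle exactly on integer scoring schemes.
* Dereplication identity is matches over all alignment columns (PID1 of
  a global alignment, end gaps counted), the strictest of the common
  definitions; greedy scan order is input order, so representative choice
  is deterministic.
* `max_depth` never splits a tie block: a block straddling the cap is
  simply not an admissible cutoff.
* Heat-map maxima (`max_window()`) break score ties toward the shortest,
  then leftmost window — the most localized statement of the signal.

## Problem sizes used by the test suite

The suite validates the cutoff walk against exhaustive oracles on 1,000
random hit lists (length ≤ 200) and 200 random windows, the SW kernel
against a quadratic DP oracle on 200 random pairs (length ≤ 60), planted
PPP/ORF recovery on the default 40-genome spec, and SIMBAL window
localization across 20 generator seeds, asserting recovery in ≥ 90% of
them. These sizes were chosen as the smallest at which the distributional
claims above are meaningfully exercised.

## Known limitations

* Scores are raw tail probabilities, not E-values; comparing scores
  *across* genomes with very different proteome sizes needs care.
* The built-in aligner is exact but quadratic; collection-scale all-vs-all
  searching is out of scope (precomputed tabular hits are the intended
  input at scale).
* The generator does not emulate indels, codon usage, or realistic
  phylogenies; see above for what that implies about test scope.
* Automatic selection of "the" diagnostic site from a heat map is not
  attempted: the grid and its maximum are reported, interpretation is the
  analyst's.
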