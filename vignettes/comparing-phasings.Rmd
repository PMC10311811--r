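---
title: "Comparing haplotype-assembly outputs without a reference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing haplotype-assembly outputs without a reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapcompare)
```

## The problem

Diploid haplotype assembly reconstructs, from sequencing reads, which
alleles at heterozygous SNVs lie together on each chromosome copy. Tools
report *phase blocks*: maximal sets of SNVs whose relative phase the tool
asserts jointly, with no claim about phase between blocks. True haplotypes
for a sample are rarely available, and even curated "gold standard" call
sets may cover only a fraction of the positions a tool infers from raw
reads — at 40% position overlap, haplotype-level accuracy against such a
standard is not a meaningful number. `hapcompare` therefore evaluates
tools *against each other*: a reference-free, pairwise, block-by-block
comparison.

## The comparison procedure

One result acts as reference (HA1) and the comparison walks its blocks in
order.

**Pairing.** The counterpart of an HA1 block is the unique HA2 block
sharing at least one SNV position. Tools do not publish how their blocks
correspond, so the pairing rule is a design choice of this package: unique
positional overlap, with both zero overlap and multiple overlap mapped to
"no usable counterpart". The rule is deterministic, symmetric in spirit
(both failure modes mean the block structures genuinely differ), and
reproduces the familiar per-block table in which a block whose SNV counts
differ is simply marked `NA`.

**Site matching.** A paired block is *comparable* only when both blocks
cover identical ordered position lists — strictly stronger than equal SNV
counts. Equal counts over different positions cannot be allele-compared
meaningfully; on outputs derived from a common input VCF the two readings
coincide anyway, because tools index the same variant set.

**Switch distance.** For comparable blocks, form the agreement vector
$a_i = \mathbf{1}[h^{(2)}_i = h^{(1)}_i]$ over sites in position order,
where $h^{(k)}_i$ is the allele tool $k$ assigns to the first haplotype.
The switch distance is the number of transitions
$\#\{i : a_i \ne a_{i+1}\}$. Because a phasing is an equivalence class
under swapping the two haplotype rows, a constant agreement vector (all
agree *or* all disagree) is a perfect match; each transition is one
position at which the chromosome assignment must be exchanged, and the
transition count is exactly the minimum number of such suffix switches
(the package's test suite checks this against an exhaustive search over
all switch sequences on thousands of random block pairs).

**Aggregation.** A block disagrees unless it is comparable with switch
distance 0. The block disagreement rate divides by HA1's block count, the
SNV disagreement rate sums HA1's sites in disagreeing blocks and divides
by HA1's SNV total — both denominators belong to HA1, so the comparison
matrix is intentionally asymmetric. Twelve switch metrics decompose the
same comparison: block counts, SNV counts, and mean SNVs per block in the
three categories (`sw = 0`, `sw = NA`, `sw > 0`), total switches, SNVs
per switch, and switches per block; the last two are computed over
`sw > 0` blocks only. Uncomparable blocks — including those with no
usable counterpart — fall in the `sw = NA` category, which is why
`disagree_blocks = blk_w_NAsw + blk_w_sw` always holds.

## Normalization

Every comparison assumes canonical inputs, produced by
`normalize_phasing()`:

* unphased (`"-"`) sites removed — all SNV counts in summaries and
  comparisons are counts of *phased* sites;
* blocks left with fewer than two sites removed: a singleton block
  asserts no phase relative to anything and carries no comparable
  information (after this step the minimum block size is 2, which is also
  what published per-tool summaries show across all tools);
* sites sorted by position within blocks, blocks sorted by first
  position, and 1-based coordinates (SDhaP's 0-based output is shifted on
  read).

Because canonical order is imposed here, comparisons are invariant to how
an input file happened to be sorted — tools variously sort by block ID or
by SNV position, and the package's tests verify that both orderings of
the same result give identical comparison output. Normalization also
rejects a position appearing in two blocks, which indicates a corrupt
file.

## Numerical conventions

* **Quantiles** (Q1/median/Q3 of SNVs-per-block) use linear interpolation
  between order statistics (`stats::quantile()` type 7, the common
  statistical-software default). No published convention exists for these
  tables; one convention is declared and used everywhere.
* **Percentages and means** are rendered to two decimals, rounded half
  *away from zero* (`round_half_up()`), matching how comparison tables
  are conventionally printed; base R's round-half-to-even would render
  some cells differently. Machine-readable TSV output never contains
  thousands separators; the human-readable matrix cells do.
* **Ratios with empty denominators are `NA`, never 0**: "no disagreement
  blocks" and "zero switches per disagreement block" are different
  statements.
* **Degenerate inputs**: empty results are an error where a summary would
  be meaningless (`phasing_summary()`, `position_overlap()`) and legal
  where emptiness is a valid answer (parsing an empty file, filtering
  everything away). Homozygous or multi-allelic genotypes are rejected at
  the model boundary — the analysis is defined over biallelic
  heterozygous SNVs only; phased-VCF reading skips and counts such
  records instead of failing, since real VCFs contain them.
* One `phasing` object covers one chromosome; mixing is rejected.

A note on one published per-tool summary: a mean of 17.69 SNVs/block is
printed for a result with 178,523 SNVs in 10,132 blocks, but
178,523/10,132 = 17.62. `phasing_summary()` computes
`mean = total_snvs / total_blocks`; the discrepancy lies in the printed
table, not in the convention.

## Filtering analyses

**Position restriction.** `filter_to_positions()` keeps only sites in a
given set, then re-applies the singleton rule. This is how a long-block
tool's output is restricted to the positions other tools inferred before
a "proper" comparison — with the caveat, visible in the package's own
output, that cutting sites out of long blocks fragments their switch
structure and can *increase* downstream switch counts.

**Depth filtering.** The DP levels of sequencing studies (DP1/DP15/DP30 =
≥1×/≥15×/≥30×) filter BAM reads. This package operates at the
fragment-file level — the nearest desk-scale equivalent — masking
variants whose fragment coverage falls below the threshold and removing
fragments left covering fewer than two variants (a read linking one site
is not haplotype-informative). Whether an upstream pipeline removes whole
reads or masks positions is underdetermined; the mask-then-drop rule is
declared, not inferred, and the operation is monotone in the threshold.
Base qualities are parsed and validated but unused: filtering here is by
coverage only.

## The synthetic generator

`simulate_truth()` draws strictly increasing positions with geometric
gaps (default mean 900 bp ≈ one het SNV per kilobase of a human
chromosome) and i.i.d. uniform first-haplotype alleles with complementary
second haplotype. `derive_phasing()` then emulates one tool's view of
that truth:

* **Block structure**: sizes drawn from 2–10 with geometric-decay weights
  (decay 0.45, giving a mean near 3 SNVs/block and a heavy mass at 2–3,
  the shape short-read phasing outputs show), plus a rare
  (`long_block_fraction = 0.002`) Poisson-sized long block
  (`long_block_size = 500`) standing in for the occasional
  thousands-of-SNVs block some tools emit. Independent segmentation
  sampling plus per-gap extra breaks (`extra_block_break_prob = 0.02`)
  give two derivations differing boundaries; passing one derivation's
  segmentation to another forces shared boundaries.
* **Switch errors**: per within-block gap, with probability
  `switch_prob` (default 0.01) the phase flips *from that site onward* —
  the classic switch-error model, chosen because it is exactly the event
  the transition-counting switch distance detects. Each block also gets a
  random global orientation, which the comparison must (and does) ignore.
* **Missingness**: sites dropped with `drop_site_prob` (0.02), emitted
  unphased with `unphase_prob` (0.01) — the two mechanisms by which real
  tools end up with differing SNV sets.

Every event lands in an **injection log** (per site: block, cumulative
flip state, dropped, unphased). `expected_metrics()` predicts the entire
comparison from two logs alone: at a common position the tools agree
exactly when their flip states are equal, so the truth alleles cancel and
the prediction never touches the comparison code. The suite asserts exact
equality between pipeline output and log prediction on every seed tried —
the module's central guarantee — and recovers injected switch
probabilities (0.01–0.1) within three binomial standard errors from
runs with at least 10,000 gaps.

What the generator does *not* emulate: read-level errors and genotyping
error (corruptions are injected at the site level, not derived from
simulated reads), linkage between missingness and coverage, reference
bias, indels, or multi-sample VCFs. Passing tests therefore demonstrate
the correctness of the comparison machinery under the stated error model,
not any claim about how real tools behave on real reads.

## Problem sizes

The test suite and acceptance script run at sizes a laptop handles in
seconds: oracle equivalence on 1,000 random block pairs of ≤10 sites
(the exhaustive switch-search oracle is exponential in block length),
metric conservation on 100 random pairs, switch-rate recovery on
20,000-site truths (≈14,000 within-block gaps), exact log-oracle
agreement on 5,000-site full-corruption runs, and the printed-table
convention checks on a constructed 115,215-SNV / 32,150-block result.
The comparison core is vectorized (grouped operations over a site table,
not per-block loops) and handles the tens of thousands of blocks of a
whole-chromosome comparison directly.

## Known limitations

* Diploid, biallelic SNVs only; polyploid phasing, indels and genotype
  likelihoods are out of scope.
* Block pairing is positional; a pathological output in which one tool's
  block interleaves with several of another's collapses to `NA` rather
  than attempting a many-to-many alignment.
* Mismatch/flip-error decompositions and MEC scores — used by individual
  tools' own papers — are not computed; the package's contract is the
  block/SNV disagreement rates and the 12 switch metrics.
* Depth filtering approximates read-level DP filtering at the fragment
  level (see above).
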