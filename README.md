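# hapcompare

Reference-free pairwise comparison of diploid haplotype-assembly outputs.

Haplotype assembly (HA) tools — HapCUT2, MixSIH, PEATH, WhatsHap, SDhaP,
MAtCHap and friends — reconstruct the two haplotypes of a diploid sample
from sequencing reads, emitting *phase blocks* of biallelic heterozygous
SNVs. True haplotypes are rarely available, so a practical way to evaluate
such tools is to compare them against each other: pick one output as the
reference (HA1), walk it block by block, and ask how often the second
output (HA2) tells the same phasing story. `hapcompare` implements that
comparison for anyone benchmarking phasing tools or sanity-checking a
phasing pipeline, together with the file parsing, filtering, summaries and
a fully instrumented synthetic-data generator needed to do it end to end.

## The comparison model

For each HA1 block, the *counterpart* is the unique HA2 block sharing at
least one SNV position (no counterpart, or several, means the block cannot
be compared and counts as a disagreement). When the two blocks cover
identical ordered positions, their distance is the **switch distance**:
with agreement indicators `a_i = [HA2 allele == HA1 allele]` over the
block's sites in position order, the switch count is the number of
transitions

```
sw = #{ i : a_i != a_(i+1) }
```

— the minimum number of positions at which the two chromosome assignments
must be exchanged for the phasings to match, invariant to swapping either
block's haplotype pair (a global swap is the same biological phasing).
A block *agrees* when its counterpart has the same sites and `sw = 0`.

Each ordered pair (HA1, HA2) is summarized by

* block disagreement: `#disagreeing blocks / #HA1 blocks`,
* SNV disagreement: `#HA1 SNVs in disagreeing blocks / #HA1 SNVs`,
* twelve switch metrics — block counts, SNV counts and SNVs-per-block for
  the three categories `sw = 0`, `sw = NA` (site sets differ) and
  `sw > 0`, plus `total.sw`, `snv.by.sw` (SNVs per switch) and
  `sw.per.blk` (switches per block, over `sw > 0` blocks).

The matrix of all ordered pairs is asymmetric by construction: HA1
supplies the denominators.

Supporting analyses: per-result block/SNV summaries (min/Q1/median/mean/
Q3/max SNVs per block), overlap of inferred positions with a known
("gold standard") phased call set, restriction of one result to the
positions another inferred, and read-depth (DP) filtering of
extractHAIRS-style fragment files.

## Worked example

Two synthetic tool outputs over the same 120-site truth ship with the
package (generated by the package's own simulator; one in HapCUT2 block
format, one as a phased VCF):

```r
library(hapcompare)

a <- system.file("extdata", "synthetic_toolA.blocks.txt", package = "hapcompare") |>
  read_block_file(dialect = "hapcut2", tool_name = "synthetic_toolA") |>
  normalize_phasing()
b <- system.file("extdata", "synthetic_toolB.vcf", package = "hapcompare") |>
  read_phased_vcf(tool_name = "synthetic_toolB") |>
  normalize_phasing()

phasing_summary(a)
#> # A tibble: 1 × 10
#>   tool_name       chromosome total_snvs total_blocks   min    q1 median  mean    q3   max
#>   <chr>           <chr>           <int>        <int> <int> <dbl>  <dbl> <dbl> <dbl> <int>
#> 1 synthetic_toolA chr10             107           35     2     2      3  3.06     4     6

cmp <- compare_phasings(a, b)
cmp
#> <phasing_comparison: synthetic_toolA (HA1) vs synthetic_toolB (HA2)>
#>   blocks: 12/35 (34.29%)  SNVs: 39/107 (36.45%)  total switches: 4
```

`a` asserts 107 phased SNVs in 35 blocks of 2–6 sites. Of those 35
blocks, 23 agree exactly with `b`, 8 cannot be compared (the two tools
dropped or unphased different sites, so the site sets differ), and 4
disagree with one phase switch each — 12 disagreeing blocks (34.29% of
blocks, 36.45% of SNVs). The per-block table and the one-row summary are
ordinary tibbles:

```r
tidy(cmp)     # block ID, SNV counts, match flags, switch count per block
glance(cmp)   # disagreement counts/percentages + the 12 switch metrics
```

For several tools at once:

```r
ps <- compare_all(list(a = a, b = b))
disagreement_matrix(ps, "block")   # cells like "12/35 (34.29%)"
switch_metric_table(ps)            # 12 metrics per ordered pair
plot_disagreement(ps, "snv")       # ggplot bar chart
```

## Command line

Every analysis is also a shell subcommand (thin wrapper in
`inst/cli/hapcompare.R`):

```sh
Rscript inst/cli/hapcompare.R summarize --dialect hapcut2 toolA.blocks.txt
Rscript inst/cli/hapcompare.R compare --out-dir cmp/ toolA.blocks.txt toolB.vcf
Rscript inst/cli/hapcompare.R overlap --known gold.vcf toolA.blocks.txt
Rscript inst/cli/hapcompare.R simulate --config sim.yaml --out-dir sim/
```

SDhaP output is 0-based: pass `--dialect sdhap` (or
`read_block_file(..., dialect = "sdhap")`) and positions are shifted to
1-based automatically.

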