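---
title: "Detecting selective sweeps with pooled heterozygosity and windowed FST"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps with pooled heterozygosity and windowed FST}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
library(data.table)
```

## The problem

Strong artificial selection — for example, breeding a fighting chicken from
a wild junglefowl background — leaves footprints in the genome: around a
selected locus, diversity collapses in the selected population while allele
frequencies diverge from the unselected reference. `sweepscan` implements
the classic two-statistic genome scan for such sweeps from pooled
resequencing data of two populations: a **focal** (selected) pool and a
**reference** (wild) pool.

Two window statistics are computed along the genome and examined jointly:

* **Pooled heterozygosity** of the focal pool,
  $$H_p = \frac{2\,\Sigma n_{MAJ}\,\Sigma n_{MIN}}
               {(\Sigma n_{MAJ} + \Sigma n_{MIN})^2},$$
  where $n_{MAJ}$ and $n_{MIN}$ are, per SNP, the counts (reads or allele
  copies) of the most and least frequently observed allele summed over all
  individuals of the pool, and the sums run over the SNPs of a window.
  $H_p \in [0, 0.5]$; a sweep drives it toward 0.

* **Fixation index** between the pools, built from per-site nucleotide
  diversity terms. With $f_A, f_T, f_C, f_G$ a pool's nucleotide
  frequencies at a site, $\Pi = 1 - f_A^2 - f_T^2 - f_C^2 - f_G^2$;
  $\Pi_{within}$ averages the two pools' $\Pi$ and $\Pi_{total}$ is the
  $\Pi$ of their averaged frequencies. The window statistic is the ratio of
  window means
  $$F_{ST} = \frac{\overline{\Pi}_{total} - \overline{\Pi}_{within}}
                  {\overline{\Pi}_{within}}.$$

Both statistics are **Z-transformed genome-wide** ($z = (x-\mu)/\sigma$),
and windows simultaneously in the lower 5 % tail of $ZH_p$ and the upper
5 % tail of $ZF_{ST}$ are called putative sweep windows, merged into
regions, and intersected with a gene annotation.

## Formula conventions

Several conventions in the literature for these statistics are ambiguous or
vary between implementations; `sweepscan` fixes them explicitly and records
the choices in every output file header:

* **FST denominator.** The form above (division by
  $\overline{\Pi}_{within}$) is the package default; the conventional
  normalisation by $\overline{\Pi}_{total}$ — which bounds the statistic by
  1 — is available via `denominator = "total"`. Because the Z-transform and
  empirical quantiles only use ranks and spacings of the window values, the
  two conventions produce very similar outlier sets; both are kept so
  results can be compared either way.
* **Ratio of averages.** Window FST averages the per-site $\Pi$ terms first
  and divides once, rather than averaging per-site ratios. This is the
  standard windowed estimator and avoids division by zero at individual
  sites. A site whose denominator term is zero (e.g. a fixed difference,
  where $\Pi_{within}=0$) contributes to neither mean; a window with no
  contributing site is left unevaluated.
* **Population SD.** Z-transforms use the divisor-$n$ standard deviation
  over all evaluated windows. With thousands of windows the difference from
  the sample SD is negligible, but the choice makes the mean-0/SD-1
  contract exact and testable to $10^{-9}$.
* **Genome-wide standardisation.** $\mu$ and $\sigma$ are computed over the
  whole genome, not per chromosome, so tails are comparable across
  chromosomes and the two statistics share one scale.
* **Quantile thresholds.** Empirical order statistics with linear
  interpolation (type-7); windows exactly at a threshold are included.
  Thresholds are always recomputed from the data at hand — published
  values such as $ZH_p = -1.75$ are properties of a particular dataset.
* **Coordinates.** VCF and GFF3 are 1-based on disk; internally all
  window and gene arithmetic is 0-based half-open, converted only at I/O
  boundaries. Gene-region assignment requires ≥1 bp of true overlap; a
  gene starting exactly where a region ends is not assigned.

## Windows

Windows are `window_size` = 100 kb wide, stepping every `step_size` = 10 kb
(each SNP therefore contributes to up to 10 overlapping windows). Window
starts are $k \cdot \mathrm{step}$ for $k = 0, \dots,
\lceil (L - \mathrm{size})/\mathrm{step} \rceil$ on a chromosome of length
$L$; only the last window can be truncated, and a chromosome shorter than
one window yields a single window covering it.

Windows with fewer than `min_snps` = 10 SNPs are reported but excluded from
the Z-standardisation and from outlier calling: near-empty windows have
wildly variable statistics and would otherwise dominate both tails of the
empirical distribution. The threshold is deliberately low — it guards
against near-empty windows, not low-diversity ones (a swept window keeps
its SNP count; its minor-allele counts shrink).

## SNP quality filters

`apply_filters()` implements the usual post-calling filters, each with a
default reflecting common resequencing practice:

| rule | default | meaning |
|---|---|---|
| `min_rms_mq` | 20 | site RMS mapping quality (INFO/MQ) |
| `min_depth`, `max_depth` | 4, 1000 | total depth across all samples |
| `max_missing_rate` | 0.5 (strict) | per-pool fraction of uncalled samples |
| `min_adjacent_gap` | 5 bp | minimum spacing between SNPs |

The spacing rule is symmetric: **both** members of a pair closer than the
gap are removed, since nothing in a distance criterion distinguishes the
two. It is evaluated on the full input site map rather than on the
survivors of the other rules. This was a genuine design fork: filtering
first and then spacing sounds natural, but it couples the rules — relaxing
a depth threshold could reinstate a site that then eliminates a previously
retained neighbour, so a *looser* configuration would retain *fewer* SNPs.
Spacing on the input map keeps every rule independent, makes filtering
idempotent and monotone in each threshold, and matches the reading that
SNP spacing is a property of the variant map, not of the quality-filtered
subset. Whether the depth bounds apply per sample or across samples is
another open choice; total (across-sample) depth is used, matching how a
single site-level depth annotation is emitted by standard callers.

Each removed site is attributed to its first failing rule (mapping quality,
low depth, high depth, missingness, spacing) in the filter report.

## Counting modes

The pooled counts can come from two sources. `count_source = "allele-depth"`
sums per-sample allelic read depths (the `AD` field) into pool read counts —
this weighs sites by sequencing evidence, the natural analogue of counting
reads from a pooled library. `"genotype"` counts called allele copies
(0/1/2 per diploid) and is the documented fallback for VCFs without
per-sample depths. Multiallelic SNPs are kept: $n_{MAJ}/n_{MIN}$ are the
top two of the four nucleotide counts (ties broken A<C<G<T for
determinism) and the FST terms use all four nucleotide frequencies. Indels
and other non-SNP records are skipped with a logged count.

## The synthetic experiment

Since a scan of this kind is usually validated against resequencing data
that cannot ship with a package, `sweepscan` includes a first-class
simulator that generates the entire input set (VCF, population map, GFF3,
truth file) from one seed:

* **Drift:** per site, an ancestral frequency $p \sim U(0.05, 0.95)$ and
  two independent population frequencies from the **Balding–Nichols**
  model, $\mathrm{Beta}\!\big(p\tfrac{1-F}{F}, (1-p)\tfrac{1-F}{F}\big)$,
  with $F$ = `drift_f` = 0.05 — a one-parameter stand-in for divergence
  after a population split, matching a moderately diverged domestic/wild
  pair. Explicit Wright–Fisher generations would add cost without changing
  what the window statistics see.
* **Sweeps:** three 150-kb intervals (defaults) in which each site is,
  with probability `sweep_strength` = 0.9, driven to near-fixation in the
  focal population (frequency `residual_maf` = 0.02 or 0.98, toward the
  nearer boundary). This is a hard-sweep caricature: it produces exactly
  the joint low-$H_p$/high-$F_{ST}$ signal the scan targets.
* **Reads:** diploid genotypes $\sim \mathrm{Binomial}(2, p)$ for
  8 + 6 individuals, per-individual depth $\sim$ Poisson(10) (zero depth =
  missing call), per-read error 1 % flipping alleles. RMS mapping quality
  is constant 60, with an option (`low_mq_rate`) to inject low-MQ sites so
  the MQ filter is exercised.
* **Annotation:** uniformly placed toy genes, with at least one guaranteed
  inside a sweep interval.

What the simulator deliberately **omits**: linkage disequilibrium and
haplotype structure (the statistics only see marginal frequencies),
recombination, demography beyond a single split, base-composition or
mappability variation. Passing tests therefore demonstrate the *estimator
contracts* — not that the scan separates selection from demography on real
data, which is the recognised hard problem for all outlier scans.

Default problem sizes (two 1-Mb chromosomes, 5 000 SNPs each — about one
SNP per 200 bp, typical of chicken resequencing) were chosen so the full
pipeline, including the permutation baseline in the test-suite, runs in
seconds while leaving ~180 evaluated windows, enough for stable empirical
quantiles.

## Worked example

```{r pipeline, eval = FALSE}
cfg <- sim_config(seed = 1)
res <- run_pipeline("sweepscan_demo", sim = cfg)
res$outliers$zhp_threshold   # empirical top-5% thresholds, data-derived
res$regions                  # merged sweep regions with their genes
```

The run directory then contains `sites.tsv`, `filter_report.txt`,
`windows.tsv` (with the formula-variant metadata in its header),
`regions.bed`, `candidate_genes.txt`, `run_summary.txt` and two figures:
the genome-wide $ZH_p$ vs $ZF_{ST}$ scatter with joint outliers
highlighted, and a per-region track of both statistics along position.

## Degenerate inputs and numerical corner cases

* A constant window statistic (all windows identical) makes Z-scores
  undefined; `ztransform()` raises a hard error naming the statistic.
* Fewer than 20 evaluated windows triggers a warning from
  `call_outliers()` (empirical 5 % quantiles from so few values are noise).
* Pools with no called alleles at a site yield zero counts and NA
  frequencies; such sites are flagged through the missingness filter and
  excluded from FST site means.
* All counts are stored as integers in the site table, so the TSV
  round-trip is exact; frequencies are always derived on the fly.

## Limitations

* Only two pools are supported; the statistics as formulated are pairwise.
* The within-denominator FST is unbounded above as
  $\overline{\Pi}_{within} \to 0$; rankings are robust but absolute values
  should be read with the denominator convention in mind.
* Empirical-quantile outlier calling always "finds" outliers — the top 5 %
  exists in any dataset. Interpretation requires the joint criterion and,
  on real data, external evidence; the package reports thresholds and
  counts so this is auditable.
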