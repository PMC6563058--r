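---
title: "Whole-genome homozygosity analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-genome homozygosity analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgha)
```

## The problem

Runs of homozygosity (ROH) are contiguous stretches of SNPs at which an
individual carries two identical alleles. Long ROH arise mainly through
autozygosity -- both haplotypes descending from a recent common ancestor
-- and are detectable at appreciable frequency even in outbred
populations. A locus where cases are in ROH more often than controls is
a candidate for a recessively acting risk allele that single-SNP
association scans are poorly powered to find. `wgha` implements the
full case-control workflow on array genotypes: QC, calibration of the
minimum ROH length, per-sample ROH calling, construction of shared
("common") ROH regions, burden and per-region association tests, and
fixed-effects meta-analysis across a discovery and a replication
cohort.

## Calling broad-sense ROH

The caller scans each sample and chromosome with a sliding window of
`window_snps` consecutive SNPs (default 50). A window is scored
homozygous when it contains at most `window_het_max` heterozygous calls
-- by default `ceiling(0.02 * window_snps)`, i.e. a 2% heterozygote
tolerance that survives window resizing -- and at most
`window_missing_max = 5` missing calls. Each SNP then receives a hit
fraction: the proportion of windows covering it that scored homozygous;
windows are fully contained in a chromosome, so SNPs near chromosome
ends are covered by fewer windows and the denominator shrinks
accordingly. A SNP is *in ROH* when its hit fraction reaches
`snp_hit_threshold` (default 0.05).

This is the *broad-sense* definition: an ROH is a homozygosity-rich
region that may contain a small proportion of heterozygous calls
(genotyping error, somatic artefact, or recent mutation). Isolated
heterozygotes are absorbed by the window tolerance rather than splitting
the run; they are counted in the segment's `n_het`. Demanding
perfectly homozygous runs would systematically underestimate both the
number and the size of ROH at realistic error rates. Ends are a
different matter: maximal runs of in-ROH SNPs are trimmed so that both
endpoint SNPs are homozygous non-missing calls, which keeps reported
boundaries anchored to observed homozygosity.

Runs are split wherever adjacent SNPs are more than `max_gap_kb`
(default 1000) apart, and a run is reported as a segment only if it has
at least `min_segment_snps` SNPs, spans at least `min_segment_kb`
(default 1000), and is dense enough
(span/SNP count at most `min_density_kb_per_snp = 50` kb per SNP).
All thresholds other than `min_segment_snps` keep the conventional
defaults of genome-wide ROH scans.

## Calibrating the minimum length

`min_segment_snps` is the parameter that controls the false-positive
run rate, and it is cohort-specific. For mean heterozygosity $h$, the
chance that $L$ consecutive calls in one individual are all homozygous
is $(1-h)^L$, so across $S$ SNPs and $N$ individuals the expected
number of chance runs is approximately

$$E(L) = (1-h)^L \, S \, N,$$

and the calibrated minimum is the smallest integer $L$ with
$E(L) < \alpha$ (default $\alpha = 0.05$: fewer than 5% of a chance
run expected across all subjects). `expected_chance_roh()` evaluates
the product in the log domain; `min_run_length()` applies the closed
form $\lceil (\ln\alpha - \ln S - \ln N)/\ln(1-h) \rceil$ and then
verifies the strict inequality by direct evaluation, which matters when
the expectation lands exactly on $\alpha$.

Because LD makes neighbouring genotypes redundant, $L$ counted in
genotyped SNPs understates the information content. `count_tag_groups()`
estimates the number of separable tag groups $T$ by greedy pairwise
pruning (drop the lower-MAF member of the worst $r^2 > 0.5$ pair inside
a 50-SNP window advancing by 5; all three knobs configurable), and
`ld_adjusted_length()` inflates the independent-SNP length
multiplicatively: $L_{adj} = \mathrm{round}(L \cdot S/T)$. The
multiplicative rule is the only arithmetic implied by treating $T/S$ as
the fraction of information retained; it is stated explicitly here
because verbal descriptions of this adjustment admit several
arithmetics, and the package always reports $L$, $T$ and $L_{adj}$
side by side (`calibrate_min_length()`) so the choice is auditable.

For a panel with $h = 0.35$, $S = 408{,}422$, $N = 7{,}478$ the formula
gives $E(57) \approx 0.066$ and a calibrated $L = 58$; with
$T = 311{,}773$ tag groups the information reduction is $23.7\%$ and
the adjusted length $\mathrm{round}(57 \times 408422/311773) = 75$.
Published analyses of panels of this shape have used slightly different
values (57 and 73); neither is derivable from the formulas above with
these inputs, so the package computes what the model implies and leaves
externally supplied values as explicit configuration
(`min_segment_snps` is always accepted directly, e.g. 73 for a
discovery cohort and 100 for a replication cohort).

## Common ROH regions

Association testing operates on consensus regions, not on individual
segments. Per-sample segments are rasterised to a samples-by-SNPs 0/1
indicator matrix (`build_indicator()`); SNPs carried by fewer than
`min_carriers` samples (default 10) are recoded to zero; per-sample
runs that drop below `min_snps` are then removed. Removing a short run
can push further SNPs below the carrier threshold, so
`consensus_regions()` iterates mask-and-reprune to a fixpoint --
guaranteed to terminate because ones strictly decrease -- at which
every surviving SNP genuinely has `min_carriers` carriers. A
`single_pass` mode performs the pair of steps exactly once for
strict reproduction of one-pass descriptions of this construction; the
two modes give identical region coordinates in typical data and differ
only through deep pruning cascades, where single-pass mode can retain
carriers whose support the fixpoint has removed.

A region is a maximal stretch of SNPs whose final carrier count meets
the threshold, kept if it has at least `min_snps` SNPs; its carriers
are the samples with at least one surviving in-ROH call inside it --
the weakest carriership definition consistent with the construction,
since surviving runs are already at least `min_snps` long.

## Association and meta-analysis

Global burden: `per_sample_summary()` tabulates per-sample ROH count
and total length; `burden_tests()` compares cases and controls with
two-sided t-tests. Welch's form is the default because cohort case and
control arms are typically very unequal in size; the pooled-variance
form is a flag. Per region, `region_association()` forms the 2x2
carrier table and applies a 1-df Pearson chi-square without continuity
correction (Yates' correction is a flag); odds ratios use
Haldane--Anscombe +0.5 on all four cells if and only if a zero cell
occurs. Discovery regions with $p$ strictly below `candidate_p_max`
(default 0.01) are carried to the replication cohort by base-pair
interval overlap (`merge_overlap()`), since region numbering is
cohort-specific. For each overlapping pair `meta_fixed()` pools the
per-study log odds ratios by fixed-effects inverse variance:
$w_i = 1/\mathrm{SE}_i^2$, pooled effect $\sum w_i\theta_i / \sum w_i$,
pooled SE $(\sum w_i)^{-1/2}$, two-sided normal $p$.

No multiple-testing correction is applied to the per-region tests; the
report instead states how many regions were tested. This follows the
practice of treating region discovery as hypothesis generation for
replication, where a correction optimised for family-wise error would
trade a known, reported test count for type II errors.

One point worth recording about pooled evidence: fixed-effects pooling
beats the *better* of two studies only when the weaker study's effect
is comparable to the stronger's (roughly, when the weaker log OR
exceeds about half the stronger one at similar weights). Pooling a
strong discovery signal with a weak but direction-consistent
replication therefore usually yields a pooled $p$ between the two --
tighter than replication alone, wider than discovery alone. The test
suite asserts exactly this pattern rather than the naive expectation
that pooling always sharpens both.

## The synthetic cohort generator

`simulate_panel()` provides cohorts with known truth for validation and
power work. Haplotypes are drawn per LD block (default 25 SNPs) from a
finite pool of `haplotypes_per_block` (default 20) block haplotypes
generated from per-SNP allele frequencies (uniform on $[0.05, 0.5]$ by
default); each individual copies two pool haplotypes with replacement.
Finite pools produce realistic LD, tunable tag-group counts, and
occasional chance autozygosity (two identical pool draws), at a
fraction of the cost of a coalescent simulation;
`haplotypes_per_block = Inf` degenerates to independent Hardy-Weinberg
draws, which is the right null for calibration checks because the
per-SNP heterozygosity is then exactly $2p(1-p)$. A finite pool of size
$K$ shrinks expected heterozygosity by $1 - 1/K$;
`expected_mean_heterozygosity()` accounts for this, and when
`target_mean_heterozygosity` is set (default 0.35, the typical control
value on arrays of this class) drawn frequencies are rescaled by a
single factor so the analytic mean meets the target.

Planted autozygous tracts are implemented as haplotype duplication --
the carrier's second haplotype is overwritten by the first across the
tract -- rather than forcing reference homozygosity, so allele
frequencies inside the tract remain realistic, exactly as under
identity by descent. Carriers are drawn per phenotype by independent
Bernoulli draws with the configured fractions. Heterozygote-miscall
error (homozygous call rendered heterozygous) and missingness are
applied after planting, in that order. SNP spacing is a constant 15 kb
so that a 73-SNP segment spans just over the 1 Mb minimum, matching the
marker density of a genome-wide array. One global seed drives fixed
per-stage sub-seeds (frequencies, haplotype pools, carrier draws,
error, missingness), so a run is exactly reproducible and stages are
stable when unrelated knobs change.

What the generator does *not* emulate: recombination-map heterogeneity,
population structure, relatedness, and centromeric SNP deserts. Tests
passing on these panels therefore validate the algorithmic contracts
(calling, masking, testing, pooling), not robustness to stratification
or to array-specific artefacts; on real data the QC stage and an
upstream ancestry analysis must carry that weight.

## Recovery behaviour at realistic error rates

Two properties of the windowed caller are worth knowing. First, a
planted tract flanked by ordinary genotypes is usually called a few
SNPs *longer* than planted, because flanking SNPs are homozygous by
chance (probability $1-h$ each) and chance-autozygous LD blocks can
extend a call by a whole block; exact boundary recovery is only
expected where a tract abuts a chromosome end. Second, at a 1%
heterozygote-error rate, a single error heterozygote falling within
about one window of a tract edge truncates that sample's call at the
error position. Per-carrier recovery at tight (90% reciprocal) overlap
therefore plateaus around 80% regardless of tract length. The
positions of error heterozygotes are independent across carriers, so
the *consensus region* over ten or more carriers localises the tract
sharply; the test suite measures recovery at tract level through the
consensus construction, where it is essentially complete, and verifies
per-carrier containment and exact chromosome-end boundaries in the
error-free case.

## Numerical and interface choices

- Genotypes are dosage-coded 0/1/2 with `NA` for missing; only
  hom/het/missing status is ever used downstream, so allele polarity is
  preserved as read and never re-oriented.
- Binary triplets are accepted in SNP-major mode only; the legacy
  individual-major layout is rejected outright rather than silently
  transposed. Map positions must be strictly increasing per chromosome;
  ties are rejected at load.
- File coordinates are 1-based inclusive; in-memory segment and region
  spans are 1-based with half-open ends (`n_snps = end_snp -
  start_snp`), the natural R analogue of half-open indexing.
- The exact Hardy-Weinberg test enumerates the conditional heterozygote
  distribution in the log-gamma domain and is applied to controls only,
  so genuinely case-enriched homozygosity is not discarded as a typing
  artefact. Minor allele frequency is computed from non-missing calls
  of all retained samples.
- `hwe_exact_p`, the ROH caller and the consensus fixpoint are all
  pinned by independent oracles in the test suite (full enumeration,
  an exhaustive literal scanner, and hand-traced matrices,
  respectively); the meta-analysis is cross-checked against an
  independent general-purpose meta-analysis implementation.
- Test and validation problem sizes (panels of a few hundred samples by
  a few thousand SNPs, 100 oracle panels of 20 x 300, 10,000-replicate
  type-I checks) were chosen so the full suite completes in minutes on
  one core while keeping every Monte-Carlo bound at 3 sigma.

## Limitations

- Ancestry outliers, relatedness and imputation are out of scope; the
  pipeline expects genotyped calls from a QC'd, ancestrally homogeneous
  cohort.
- Autosomes only; sex chromosomes require a hemizygosity-aware caller.
- The chance-run model treats SNPs as exchangeable with a single mean
  heterozygosity; the LD adjustment is a global multiplicative factor,
  not a local map.
- Carrier status is binary per region; dosage-like refinements
  (fractional coverage of a region) are not implemented.
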