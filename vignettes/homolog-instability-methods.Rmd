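---
title: "Calling genomic alterations from homolog-specific SNP coverage: models and methods"
author: "lohscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling genomic alterations from homolog-specific SNP coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lohscan)
```

## The measurement model

`lohscan` analyzes genome instability in a hybrid diploid *Saccharomyces
cerevisiae* strain built by mating two divergent haploids (W303-1A and
YJM789). The two parental genomes differ at roughly 50,000 single-nucleotide
positions spread over the 16 chromosomes (about one marker per 240 bp), so
every heterozygous site reports which homolog a sequencing read came from.
The quantity everything downstream rests on is the **relative coverage**
(RC) of each homolog at each SNP:

$$\mathrm{RC}_{h,i} \;=\; \frac{d_{h,i}}{\bar{d}}, \qquad
\bar{d} = \operatorname{mean}_{j \in \text{nonrepeat}}\,(d_{W,j} + d_{Y,j}),$$

where $d_{h,i}$ is the read depth of homolog $h \in \{W, Y\}$ at SNP $i$ and
$\bar d$ is the average *total* per-SNP coverage over all SNPs outside
repeat (Ty) intervals. On this scale one homolog copy sits at RC 0.5, two
copies at 1, and zero copies at 0, and for a fully heterozygous diploid
$\operatorname{mean}(\mathrm{RC}_W + \mathrm{RC}_Y) = 1$ holds exactly by
construction. Repeat-overlapping SNPs stay in the profile (flagged) but are
excluded from $\bar d$, since read mapping inside dispersed repeats is
unreliable. The same caller consumes SNP-microarray data after
`array_to_copy_signal()` maps hybridization ratios (levels 0.2 / 1.0 / 1.5
for 0 / 1 / 2 copies, thresholds at the level midpoints, ties upward) onto
the RC scale.

The mean-coverage normalizer follows the RC definition. It is worth knowing
its one failure mode: an isolate carrying many whole-chromosome gains or
losses shifts the genome-wide mean itself, compressing or inflating all RC
values by a few percent. For such karyotypes `compute_rc(..., center =
"median")` substitutes the median total coverage, which is unaffected as
long as less than half the genome changed copy number. The default remains
the mean.

## Copy-state segmentation

Each homolog track is assigned a copy state in $\{0,1,2,3\}$ per SNP and
collapsed into maximal runs. Assignment is a *penalized minimal-misfit
segmentation*: after running-median smoothing (window 5 SNPs, shrunken at
chromosome ends), the state sequence $s_{1..n}$ minimizes

$$\sum_i (x_i - \ell_{s_i})^2 \;+\; \lambda \cdot \#\{i : s_i \neq s_{i+1}\},$$

with levels $\ell = (0, 0.5, 1, 1.5)$ and $\lambda = 0.2$, solved exactly by
dynamic programming in one pass per chromosome. With $\lambda = 0$ this is
plain nearest-level thresholding (cut points 0.25 / 0.75 / 1.25); the
penalty is what keeps a short cluster of high-depth outliers — which a
median filter happily converts into a 3-SNP run at an elevated state — from
spawning a spurious segment, while a genuine 3-SNP conversion tract (level
shift 0.5, misfit gain $3 \times 0.25 = 0.75 > 2\lambda$) always survives.
Runs shorter than `min_snps = 3` merge into their longer neighbor; 3 SNPs
is the smallest span at which an event is resolvable at the marker density,
matching the ~2.2-kb smallest tracts such data exhibit. Because the
smoothed fit localizes each transition only to within a couple of sites,
every boundary is then re-placed on the *raw* RC of both homolog tracks
jointly, choosing the cut (within ±4 SNPs) that minimizes the summed
squared misfit — this is what makes the reported breakpoint interval (the
pair of SNPs bracketing the transition, midpoint = their mean) contain the
true breakpoint in ≥95% of noisy simulations and always in noiseless ones.

## Event taxonomy

The W and Y segmentations combine into joint-state runs, which map onto the
event classes:

| joint state (W, Y) | extent | call |
|---|---|---|
| (0, 2) or (2, 0) | interior | interstitial LOH (gene conversion), class A1/A2 |
| (0, 2) or (2, 0) | reaches one telomere | terminal LOH (crossover/BIR), B1–B4 |
| (0, 1) or (1, 0) | reaches one telomere | terminal deletion, C1/C2 |
| (2, 1) or (1, 2) | reaches one telomere | terminal duplication, C3/C4 |
| (2, 1) or (1, 2) | whole chromosome | trisomy, D1/D2 |
| (0, 1) or (1, 0) | whole chromosome | monosomy, D3 |
| (0, 2) or (2, 0) | whole chromosome | uniparental disomy, D4 |

A whole-chromosome call requires the state over at least 95% of the
chromosome's SNPs *and* at both chromosome ends. The both-ends condition is
deliberate: a terminal LOH spanning 97% of a chromosome still leaves a
heterozygous terminal remnant and must not be promoted to UPD; the 95% band
only absorbs edge noise. A terminal LOH with an interstitial tract of the
same configuration within 5 SNPs of its breakpoint is reported once as
conversion-associated (class B5), the adjacent tract being the conversion
signature of the initiating repair event. The B1–B4 split (retained homolog
× chromosome arm relative to the centromere) is an interpretive convention
and is remappable through `class_map`. Joint states with no interpretation
(e.g. interior deletions, (0,0), states involving 3 copies) are reported as
`UNCLASSIFIED`, never dropped. Sub-`min_snps` slivers of joint state at run
boundaries — where the W and Y transitions disagree by a site — are merged
away before classification.

## Translocation pairing

Paired terminal duplications on two chromosomes (or the retained
complements of paired terminal deletions) are interpreted as a
translocation joining a centromere-containing fragment to an acentric
fragment, because only monocentric products are mitotically stable. A
hypothesis is emitted only when exactly one fragment of the pair carries
its centromere; its predicted size is the sum of the fragment lengths
(e.g. duplications of II:1–635,650 and XIII:1–182,683 predict an 818-kb
product). When several pairings are possible the matching minimizing total
unexplained fragment length is chosen, ties broken by chromosome order;
unpaired terminal CNVs are reported unresolved rather than forced.

## Rates per genome per cell division

Event rates divide counts by genome-divisions accumulated under the
subculture design: one colony grown from a single cell represents ~25 cell
divisions, so divisions = isolates × cycles × colony formations per cycle ×
25. For the furfural-exposed arm each cycle comprises **two** colony
formations — selection on the furfural plate followed by purification on
YPD — giving 50 divisions per cycle and 11,350 divisions for the 31-isolate
cohort (28 × 8 cycles + 3 × 1 cycle); the untreated control has one
formation per cycle (20 isolates × 20 cycles × 25 = 10,000). The
two-formations accounting is a reconstruction: it is the unique choice
consistent with all the per-division rates these designs are meant to
yield, but it is not stated explicitly in descriptions of such protocols,
so `culture_design()` keeps the factor explicit and configurable. Per-base
mutation rates additionally divide by the 24-Mb diploid genome, using only
the sequenced isolates' divisions (18 × 400 + 3 × 50 = 7,350). Rates are
reported at two significant figures with full precision retained; fold
changes are ratios of rates, with the zero-baseline case refused rather
than returned as infinity.

## Statistics

* **Fisher's exact test** (`fisher_exact_2x2`) uses the two-sided
  point-probability rule: with margins fixed, sum the hypergeometric point
  probabilities of all tables no more probable than the observed one
  (relative tie slack 1e-7). Two-sided conventions differ between
  implementations, so the rule is stated here; the test suite verifies it
  against full enumeration to 1e-10.
* **Region enrichment** (`region_enrichment`) compares an observed
  in-region count against the uniform expectation
  $\text{region}/\text{genome} \times \text{total}$ with a df-1 chi-square
  *without* continuity correction, and forms the statistic against the
  expectation rounded to two significant figures — the convention of
  testing against the expectation as reported (`expected_digits = NULL`
  restores full precision). For 4 observed vs 1.2 expected of 53 this gives
  $\chi^2 = 6.68$, p = 0.0097; Yates' correction would roughly halve the
  significance and is inappropriate at these expected counts for a
  goodness-of-fit comparison.
* **Mutation spectra** collapse complementary substitutions onto six
  classes (CG→TA, CG→AT, CG→GC, TA→CG, TA→AT, TA→GC); spectra are compared
  by a 2×2 Fisher test on the oxidation-associated share (CG→TA + CG→AT)
  versus the rest, the contrast of interest for oxidative mutagens.
* **Mutant frequencies** across parallel cultures are summarized by the
  median (robust to Luria–Delbrück jackpots), with the mean reported
  alongside.
* No multiple-testing correction is applied anywhere; each test answers a
  single pre-stated question, and downstream users combining many tests
  should correct themselves.

## The synthetic cohort generator

Because the raw sequencing data of such experiments live in external
archives, validation runs on a generator whose defaults *are* the study
conditions: ~50,000 SNP sites over the 16 chromosomes (S288C lengths,
approximate centromere coordinates; the Ty-like repeat intervals are
synthetic placements), total depth 50 per SNP with independent Poisson
homolog depths of mean $\text{depth} \times \text{copies}/2$, array levels
0.2 / 1.0 / 1.5 with Gaussian noise (SD 0.05), and per-division event rates
of 2.2e-3 (I-LOH), 3.4e-3 (T-LOH), 7e-4 (terminal rearrangements, split 6:2
deletion:duplication as observed) and 3.2e-3 (aneuploidy, split 15:17:4
trisomy:monosomy:UPD as observed). Interstitial tract lengths are drawn
uniformly over 2–50 kb, bracketing the observed tract scale. Six-class SNV
spectra put 22% / 26% on CG→TA / CG→AT for the untreated-like setting; the
published split of the remaining 52% across the other four classes is not
available numerically, so it is spread in plausible proportions
(8/16/16/12%) — only the oxidation-associated share is quantitatively
meaningful. Event breakpoints snap to inter-SNP midpoints so ground truth
is well-defined at SNP resolution, segmental events keep a ≥3-SNP margin to
chromosome ends (below that no caller could distinguish interstitial from
terminal), and draws conflicting with an already-placed event on the same
chromosome are re-drawn up to 20 times, then dropped. Every draw is
reproducible from `rng_seed`.

What the generator deliberately omits: read-level artifacts (GC bias,
mappability, mapping errors beyond the repeat mask), depth overdispersion
beyond Poisson, chromatid-level mechanism (the caller sees products, not
intermediates), and clustered or recurrent breakpoints. Passing the
simulation studies therefore demonstrates correctness of the statistical
machinery under the stated noise model, not robustness to every artifact of
real libraries.

## Validation studies and problem sizes

The packaged studies (`caller_oracle_study`, `rate_recovery_study`) size
their genomes so the full suite runs in minutes while keeping ≥40 SNPs per
smallest event class: noiseless exactness and noisy recall/precision run 60
isolates on a 12,000-SNP genome (≥200 scored events; observed recall and
precision ≈ 0.99 at depth 50), and rate recovery re-estimates a spiked
T-LOH rate of 3.4e-3 over 20 replicate experiments of 50 isolates × 400
divisions on a 4,000-SNP genome, landing within 3 binomial SE of truth.
The `analysis/` drivers run the full 50,000-SNP, 31-isolate cohort.

## Known limitations

Events smaller than the SNP spacing are invisible; segmental calls inside
repeat-masked regions inherit the mask's blind spots. The caller does not
reconstruct which chromatid carried which intermediate, so reciprocal-
crossover versus BIR origins of a terminal LOH are indistinguishable, as
they are in the underlying data. Heavily aneuploid isolates need the median
normalizer (above). The relative-ratio table reports whatever counts it is
given; reconciling count discrepancies between alternative tallies of the
same isolates is left to the user.
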