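---
title: "Methods: segregation distortion scans in achiasmatic F2 crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segregation distortion scans in achiasmatic F2 crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segscan)
```

## The problem

Crosses between strongly diverged populations of the splash-pool copepod
*Tigriopus californicus* show reduced fitness in second-generation (F2)
hybrids. One way to localize the responsible genetic interactions is to
genotype a panel of population-diagnostic codominant markers in F2
offspring and ask, marker by marker, whether genotype frequencies deviate
from Mendelian expectations — *segregation distortion*. Comparing newly
hatched larvae (nauplii) with adults separates distortion that arises
before hatching (meiotic drive, gametic selection, embryonic mortality)
from viability selection acting between hatching and adulthood.

Two biological peculiarities of the system shape everything in this
package:

* **Female achiasmy.** Female *T. californicus* do not recombine, so every
  maternal gamete carries intact parental chromosomes. Only the male map
  has non-zero genetic length, and a conventional mapping analysis that
  assumes both sexes recombine sees *attenuated* recombination fractions
  (see below).
* **The non-recombinant backcross (NR-BC).** Backcrossing achiasmatic F1
  females to paternal-line males yields offspring in which each
  chromosome is, as a unit, either fully heterozygous or fully homozygous
  for the paternal line — a chromosome-level segregation assay and a
  direct check that inferred linkage groups are physical chromosomes.

The package provides the full analysis pipeline (two-point linkage map,
single-locus and two-locus chi-square scans, NR-BC chromosome tests) and a
gene-drop simulator of the cross design, so every stage is exercisable
without the original genotype data, which were never deposited.

## The cross simulator

`simulate_f2_cohorts()` and `simulate_nrbc()` perform a standard gene
drop. Every F1 individual is heterozygous at every marker with known
coupling phase (one whole maternal-line homolog, one whole paternal-line
homolog). Maternal gametes transmit an intact haplotype per chromosome
with probability 1/2 (`meiosis_female()`). Paternal gametes follow a
no-interference Markov walk along each chromosome
(`meiosis_male()`): the walk starts on a random homolog and switches
between adjacent markers with probability `r_j`, the inverse-Kosambi
transform of the configured map interval. The partial interference
implied by the Kosambi function itself is deliberately ignored: two-point
statistics, which are all this package computes, are insensitive to
interference, and a Markov walk is the standard gene-drop simplification.

**Viability selection** is expressed as relative viabilities in `[0, 1]`:
per-locus triples `(w_HOM_P1, w_HET, w_HOM_P2)` and/or per-pair 3 x 3
tables, acting either before hatching or between hatching and adulthood.
An individual's survival probability is the product of its viabilities
normalized by the maximum achievable product, so the fittest multilocus
genotype survives with probability 1 and configured cohort sizes remain
interpretable (the source study gives no fitness parametrization, so this
normalization is the package's own choice). Cohorts are drawn by
rejection until the requested number of survivors — and males, for the
adult cohorts, with sex an independent Bernoulli(1/2) — is reached;
family labels cycle over the configured number of F1 pairs. Genotype-
dependent sex determination is out of scope: the study observed a
female-biased NR-BC but no mechanism is known, so the simulator does not
model it.

**Genotyping artifacts** are applied last: each true heterozygote is
rewritten to a random homozygote with probability `het_undercall_rate`
(heterozygote undercalling is a documented failure mode of both the SNP
assays and microsatellites with large allele-size differences) and each
call then goes missing with probability `missing_rate`. Defaults are 2%
for both — small but non-zero, matching a panel from which badly
undercalling assays have already been removed. Note one consequence: an
undercalled heterozygote in NR-BC data can surface as a maternal-line
homozygote, a genotype the cross design cannot produce; the reader flags
such calls as artifacts rather than refusing the file, and the
chromosome-state summarizer does not let them vote.

**Default layout.** The default genome emulates the study panel: 53
markers (45 SNPs, 8 anchoring microsatellites) on 12 chromosomes — eleven
multi-marker groups totalling 52 markers (hence 41 marker intervals) and
one chromosome represented by a single unlinked marker. Positions are
*male-map* centimorgans with uniform spacing calibrated so that the
conventional symmetric-model analysis of achiasmatic data reproduces the
published observed mean spacing of 6.5 cM:

```{r layout}
r_obs <- kosambi_r(6.5)                    # observed adjacent fraction
spacing <- kosambi_cm(1 - (1 - r_obs)^2)   # male-map spacing, ~12.8 cM
spacing
head(default_genome_layout(), 7)
```

The defaults of `cross_config()` are the study conditions themselves: 190
genotyped nauplii from 4 F1 pairs, 205 adult males from 25 pairs, 39
NR-BC males from 7 pairs. Two selection presets encode the study's
qualitative adult patterns for power work: `"chr10_sd_deficit"`
(maternal-line homozygote viability 0.05 across chromosome 10) and
`"het_excess_2_7"` (paternal-line homozygote viability 0.5 on
chromosomes 2 and 7).

## Two-point linkage estimation

`estimate_two_point()` computes the maximum-likelihood recombination
fraction from a 3 x 3 joint genotype table of a phase-known intercross by
EM. Gamete classes are parental with probability `(1 - r)/2` each and
recombinant with `r/2` each, for every recombining parent. All genotype
classes except the double heterozygote determine their recombinant gamete
count; the double heterozygote mixes both-parental and both-recombinant
origins, split in the E-step with weights
`(1 - r)^2 / ((1 - r)^2 + r^2)` and `r^2 / ((1 - r)^2 + r^2)`. The M-step
divides expected recombinant gametes by `2n` (`sex_model = "symmetric"`)
or by `n` (`"female_achiasmatic"`, where only male gametes can recombine
and the double heterozygote carries no recombinants). Iteration starts at
`r = 0.25` and stops at `|Δr| < 1e-8` or 100 iterations; the estimate is
clamped to `[0, 0.5]`. The LOD score is the log10 likelihood ratio
against `r = 0.5`, and `p_linkage` is the chi-square(1) upper tail of the
likelihood-ratio statistic. The tests cross-check the EM against an
independent grid-search likelihood oracle (step `1e-4`) on hundreds of
random tables.

Two numerical conventions are worth stating. First, since the null
`r = 0.5` sits on the boundary of the parameter space, the exact null
distribution of the statistic is the mixture `½χ²₀ + ½χ²₁`; the package
uses the plain χ²(1) tail, which is conservative (about half the nominal
type-I error) and matches how mapping packages of the study's era
behaved. Second, under `"female_achiasmatic"` the double-homozygote
repulsion classes have probability zero; observations there (possible
only through genotyping error) are dropped with a warning rather than
crashing the likelihood.

**Achiasmy attenuation.** When achiasmatic data are analysed under the
symmetric model — as the original study's tooling did — the estimate
converges not to the male-map fraction `r_m` but to
`1 - sqrt(1 - r_m)` (≈ `r_m / 2` for small `r_m`), because the model
spreads the male-only recombination over two parents. The
`"female_achiasmatic"` model recovers `r_m` itself. Both facts are
property-tested at n = 10,000. The default is `sex_model = "symmetric"`
to mirror the published maps, whose lengths are therefore attenuated
male-map lengths; the achiasmatic model is one flag away.

## Grouping, ordering and map summaries

`group_markers()` forms linkage groups as the single-linkage transitive
closure of the relation `p_linkage < alpha` (study criterion:
`alpha = 0.001`); markers with no significant partner stay singletons.
`build_map()` additionally requires `r_hat <= group_max_r` (default
0.35) for a pair to join groups. The rationale: a genome-wide panel of 53
markers yields ~1,300 between-chromosome pairs, so even at a conservative
effective type-I error of ~5e-4 the expected number of spurious
significant pairs is ~0.6 per map, and a single one chains two
chromosomes together under pure single-linkage. Requiring the point
estimate to also look linked is the standard two-point safeguard (compare
`max.rf` plus `min.lod` in classical mapping software) and reduces the
false-join probability to ~1%.

Within each group `order_group()` minimizes the sum of adjacent
recombination fractions (SARF): exhaustively for up to 8 markers (the
default layout's groups have at most 6), greedy end-insertion with 2-opt
refinement beyond that, with orientation canonicalized by marker name.
Multipoint likelihood ordering is out of scope; at these group sizes SARF
and maximum likelihood agree in practice.

`map_summary()` implements the published corrected-length and coverage
estimators: each multi-marker group contributes
`(length + 2) * (m + 1) / (m - 1)` to the corrected length `L`; the mean
spacing is `d = total / Σ(m - 1)` over multi-marker groups; coverage is
`c = 1 - exp(-2 d n / L)`. Singleton groups are excluded from `d`, `n`
and `L` — the correction factor is undefined at `m = 1`, and the
published numbers themselves imply the unlinked locus was excluded
(`n = 52` of 53 markers; `d = 266.7 / 41 = 6.5` cM only if the singleton
contributes neither length nor intervals, and with `L = 484.8` cM those
inputs reproduce the printed 75.2% coverage exactly).

```{r coverage}
100 * genome_coverage(6.5, 52, 484.8)
```

## Distortion scans

`f2_distortion_test()` compares genotype counts at one marker against the
Mendelian F2 expectation 2:1:1 (heterozygote : each homozygote; the
Hardy-Weinberg proportions at allele frequency 1/2) with a plain Pearson
chi-square, 2 df, no continuity correction. Each marker uses its own
non-missing sample size, since genotyping success differs between marker
classes. `scan_f2()` applies the scan-wide Bonferroni threshold
`0.05 / m` (0.00094 for 53 markers) and reports the three-tier star
convention (p < 0.05, p < 0.01, p < Bonferroni) plus direction flags
(heterozygote excess/deficit, homozygote deficit/excess per parental
line). `allele_ratio_test()` pools two alleles per call over all markers
and tests the parental allele totals against 1:1; like the original
pooled test it ignores the non-independence of alleles within individuals
and across linked markers, and is documented as a directional summary
rather than "fixed". `nrbc_chromosome_test()` and `scan_nrbc()` test each
NR-BC chromosome's heterozygote/homozygote split against 1:1 (Bonferroni
0.05/12 ≈ 0.004), after collapsing each individual's chromosome to a
majority state (ties and all-missing chromosomes are excluded).

## Two-locus epistasis tests

`pair_epistasis_test()` compares observed joint genotype counts at a pair
of physically unlinked markers against the multiplicative expectation
formed from the pair's own observed marginals. Two class conventions are
implemented. The methods wording of the source study lists six unordered
genotype combinations (`pooled6`, df = 5), but every chi-square/p pair it
prints (17.1 → 0.03, 14.5 → 0.07, 16.2 → 0.04, 18.3 → 0.02, 11.9 → 0.16,
17.7 → 0.02) is consistent only with nine ordered classes at df = 8 —
so `ordered9` is the default and `pooled6` is retained as an option. The
df is *not* reduced for the estimated marginals (the printed p-values
show the study did not reduce it either). A consequence documented here
rather than silently "corrected": because the expectation absorbs the
marginals, the true null statistic is approximately χ²(4), and the scan
is conservative at any nominal level — its null rejection rate at 0.05 is
well below 0.05. Signed per-class contributions
`sign(obs − exp) · (obs − exp)² / exp` decompose the statistic exactly
(they sum in absolute value to chi-square) and reproduce the published
figure convention of negative bars for under-represented combinations.
Expected counts below 5 are flagged, never pooled.

`scan_pairs()` tests all between-group pairs and reports the Bonferroni
denominator as ordered pairs of distinct groups (`g(g-1)`; 132 for 12
groups). The unordered count would be 66; only the ordered convention
reproduces the published 132, so it is adopted. `nrbc_ld_test()` and
`scan_nrbc_ld()` test pairwise independence of NR-BC chromosome states
with a 2 x 2 Pearson chi-square (no continuity correction); tables with
an empty margin are flagged untestable.

## Problem sizes, determinism and limitations

Every simulation consumed by the test-suite and the acceptance script
runs at the study's own sample sizes (190/205/39) except where a
convergence property explicitly needs large n (10,000 individuals for the
attenuation identity and Mendelian-ratio checks; 2,000 for epistasis
power; 2,000 replicate markers for the type-I calibration). Fixing
`seed` in `cross_config()` fixes every output byte; the NR-BC draw uses
`seed + 1` so one configuration drives both designs without replaying an
identical stream.

What passing tests do *not* show: the simulator draws marker genotypes
from an idealized pedigree — no genotype-dependent sex, no family
structure in survival (families label offspring but share one fitness
surface), no linkage between sex and viability, no mutation or de novo
marker failure, and uniform per-call error rates. Data-dependent
published quantities (the 266.7/263.4 cM map totals, the specific
Bonferroni-significant adult markers, the observed 45% adult distortion
fraction, the figure-level chi-squares) depend on the undeposited
genotype matrix and are not reproduction targets; the package reproduces
the printed formula arithmetic, the multiple-testing conventions, and the
qualitative larva/adult contrast under the shipped selection presets. At
n = 205 the estimated map totals run ~10% above the configured truth
because the convex Kosambi transform of a noisy `r_hat` is upward-biased
at finite sample size — visible in simulation, and worth remembering when
comparing two maps of different sample sizes.
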