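---
title: "Estimating Y-STR mutation rates and discriminating power from paternal pedigrees"
author: "rmystr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating Y-STR mutation rates and discriminating power from paternal pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmystr)
```

## The problem

Y-chromosomal short tandem repeats (Y-STRs) are transmitted father to son
without recombination, so any difference between the haplotypes of two
paternally related men must come from mutation. Counting mutation events
inside documented deep-rooted paternal genealogies gives a *direct-count*
estimate of the per-locus, per-generation mutation rate — the quantity that
calibrates forensic kinship exclusion and TMRCA estimates. The same
machinery quantifies the *discriminating power* of a marker panel: the
fraction of compared couples of men whose haplotypes differ at all.

`rmystr` implements this analysis for three panels: the 17-column Yfiler
set, the rapidly mutating 13-marker set scored as 14 columns (RM13; the
multi-copy DYF403S1 is split into a/b columns, DYS526A and B are one
combined column), and RM11, which is RM13 without its two most mutable
columns (DYF399S1 and DYF403S1a). Each scored column is treated as an
independent locus, so the panel sizes used throughout are L = 17, 14
and 12.

## Estimators

With `NMUT` observed mutation events over `NGEN` meioses and `L` scored
loci, the pooled rate is

$$\hat\mu = \frac{\mathrm{NMUT}}{\mathrm{NGEN} \times L}.$$

The 95% interval comes from the quantiles of a binomial distribution with
size `n = NGEN` and success probability `p = NMUT/NGEN`: the smallest
counts $k$ whose CDF reaches 0.025 and 0.975 are divided by
$\mathrm{NGEN}\times L$. The quantile is the standard discrete one
(smallest `k` with CDF ≥ q, i.e. `qbinom`). Rates are reported to 5
decimals; package tests compare by rounding, not tolerance.

```{r}
estimate_rate(26, 470, 17, label = "deep pedigrees, Yfiler")
```

Per-locus rates use the same construction with `L = 1`
(`locus_rates()`), and diachronically binned rates (`bin_rates()`) pool
within-pedigree pairwise comparisons by the number of meioses separating
the two men (default bins 1–10, 11–20, 21–26 meioses) to detect
saturation of rapidly mutating markers with temporal depth.

One caveat a user should know: for the deep-pedigree RM11 row of the
reference rate table that motivated these defaults, the published interval
is internally inconsistent with the stated binomial construction (and with
the same paper's prose, which gives a third pair of endpoints). The
package follows the construction; that one published CI is not
reproducible from it.

## Counting mutation events

**Within pedigrees** the number of events is the maximum-parsimony count:
the minimum number of father–son transmissions at which the allele
changes, over all assignments of alleles to unsampled men
(`parsimony_event_count()`). Any change on an edge costs one event
regardless of its size — a 36 vs 34 difference within a pedigree is one
multi-step event, because two independent hits at one locus in a few
meioses are far less likely than one two-step event. With unit cost the
optimum always uses observed allele states, so the implementation is a
small Sankoff dynamic programme over those states (equivalently, Fitch
parsimony on unordered states); tests verify it against exhaustive
enumeration of all ancestral assignments. Meioses are counted on the
minimal (Steiner) subtree connecting the sampled men
(`steiner_meioses()`): lineages leading only to unsampled descendants are
unobservable and contribute neither events nor meioses.

**Between unrelated men** each repeat-unit step is an independent event:
36 vs 34 counts two events (`pair_mutation_count(convention =
"unrelated")`). Multi-copy allele pairs are sorted at ingest and compared
copy-wise, which realises the minimal-total-difference matching.

Missing calls: a locus missing in any member of a comparison contributes
zero events, while its meioses are still counted in full. This is a
deliberate, slightly conservative choice — down-weighting NGEN per locus
would require call-level bookkeeping the input tables do not reliably
carry; the missing-cell counts are logged at ingest for audit.

**Outlier screening.** Pedigrees with an extreme mutations/generations
ratio (suspected hidden non-paternity) are removed by iterated two-sided
Grubbs tests (`grubbs_screen()`, alpha = 0.05): while the most extreme
ratio is significant it is excluded and the test re-run, stopping at the
first non-significant result.

## The synthetic-data generator

No genotype data are redistributed with the package; all analyses are
exercised on simulated data with known truth.

* `simulate_haplotypes()` evolves a founder haplotype down a pedigree
  under the stepwise mutation model: each meiosis mutates each scored
  column independently with probability $\mu$; a mutation is ±1 repeat
  unit with probability `1 - p_multistep` (default 0.96), otherwise a
  multi-step event of `2 + Geometric(step_tail)` units (defaults 0.04 and
  0.5 — a small multi-step fraction consistent with the STR mutation
  literature; no published step-size distribution exists for these
  panels, so both are configurable). Directions are equiprobable, so
  consecutive mutations cancel half the time — the homoplasy mechanism
  that parsimony counting must contend with. Every event is written to a
  truth log. Default per-column rates are the direct-count estimates from
  the 470-meiosis deep-pedigree reference (order $10^{-3}$ for Yfiler
  columns up to $6\times10^{-2}$ for DYF399S1); the default founder is a
  set of modal allele values (absolute values are irrelevant — only
  differences are counted).
* `generate_study_pedigrees()` reproduces the reference study design: 12
  pedigrees of 2–3 distantly related men at the tips of 5–9-meiosis
  chains, plus 14 pedigrees carrying close-relative couples (father–son,
  brothers, uncle–nephew, cousins — 1–4 meioses) at the ends of two deep
  branches, the last of which carries one couple and two distant
  singletons. This yields 26 pedigrees, 27 close couples, pairwise
  separations of 1–26 meioses and roughly 470 observable meioses in
  total.
* `generate_lineage_dataset()` emulates clustered unrelated men (nine
  R-M269-style sub-lineages by default) with a star-of-stars genealogy:
  group founders diverge from a common root by `divergence_meioses`
  (default 40) and samples from their founder by `within_meioses`
  (default 15). The defaults put cross-group pairs roughly three times as
  many meioses apart as same-group pairs — enough to reproduce the
  qualitative ordering of mutation counts (close relatives < same
  lineage < different lineages) without claiming anything about actual
  R-M269 history.

What the simulations do *not* emulate: microvariant (.2) alleles, locus
dropout, null alleles, population-level haplotype frequency structure,
mutation-rate heterogeneity between lineages, and the ascertainment by
which real studies select couples with identical Yfiler profiles from a
larger population sample. Passing recovery tests therefore validates the
counting and estimation machinery, not the realism of any particular
genotype table.

## What the recovery experiment shows — and its known bias

The test suite fixes one realisation of the study genealogies (26
pedigrees, ~490 realized meioses) and, over 300 replicate mutation
histories per rate, compares pooled estimates against the simulated
truth. At Yfiler-like rates ($\mu = 0.00325$) the estimator recovers
truth to within ~3–4% with binomial-CI coverage near nominal. At
RM13-like rates ($\mu = 0.0146$) the parsimony count is systematically
low — the recovery experiment measures a downward bias of roughly 12%,
with CI coverage around 0.7 — because at high $\mu$ two events at the
same locus increasingly land on the same or sibling path segments, where
parsimony merges or cancels them. This is not an implementation artefact
but a property of direct counting in deep pedigrees: the deeper the
paths and the hotter the locus, the more events hide. It is consistent
with deep-pedigree RM estimates published below father–son germline
rates, and it is the reason the diachronic binning analysis exists. The
acceptance tests assert the nominal 5% recovery band for both panels and
the RM13 assertions are accordingly expected to fail; they are kept
faithful rather than widened, as a standing record of the method's
limits.

## Discrimination summaries

`discriminating_power()` reports the fraction of couples whose
haplotypes differ (printed as a percentage to 2 decimals — note 4/27 is
14.81%); `mean_pair_mutations()` the mean per-couple count; and
`bootstrap_ci()` a percentile bootstrap interval obtained by resampling
couples (their counts) with replacement, 1000 replicates by default —
the only reading of "re-sampling mutations in couples" that yields an
interval for a per-couple mean. Quantiles use the default empirical
percentile method without bias correction.

## DAPC classification

To ask whether rapidly mutating markers retain phylogenetic signal,
haplotypes of unrelated men are classified into a-priori sub-lineages by
discriminant analysis of principal components: PCA reduction
(`stats::prcomp`, centred, unscaled by default — repeat counts share a
scale) followed by linear discriminant analysis (`MASS::lda`) on the
retained scores with **equal group priors**, so that group frequency
does not leak into membership probabilities. Multi-copy loci are
excluded (`single_copy_columns()`): their copy assignment is arbitrary
between unrelated men, so they are not comparable features. The retained
PC count defaults to the smallest number explaining 90% of variance,
capped at a third of the sample count to guard against overfitting the
discriminant space; discriminant axes default to groups − 1.

Membership probabilities (`membership()`) and per-group averages (amp)
are reported for the training set as-is. Training-set membership is
optimistically biased — on label-permuted structureless data it averages
around 0.3 rather than 1/9 for nine groups, purely from fitting the axes
to the scored samples. For honest assessment (permutation nulls,
panel comparisons on modest samples) use `cv_membership()`, whose
held-out posteriors average 1/9 under the null. With all components
retained the procedure is exactly LDA on the raw alleles (PCA is a
rotation), which the tests verify to $10^{-6}$.

Reference per-lineage amp values published for the real R-M269 data
depend on unpublished retained-PC counts and on the original genotype
tables, so they are context for interpretation, not test targets; the
package's checks are property-based (separable lineages give amp ≥
0.95, nulls give 1/9, feature-set combination does not hurt separable
training amp).

## Numerical and degenerate-input choices

* Binomial quantile counts are rounded and clamped to `[0, NGEN]`
  (guarding a floating-point quirk of `qbinom` at p ≈ 0); `NMUT = 0`
  yields the degenerate interval (0, 0).
* Grubbs screening with zero variance returns `final_p = 1` and excludes
  nothing; fewer than 3 pedigrees is an error.
* Parsimony with fewer than two informative (non-missing) leaves returns
  0 with a logged notice; alleles driven below zero during simulation are
  reflected to a positive step with a warning.
* Multi-copy tuples are sorted at ingest with missing values last; ties
  in sorting are irrelevant because comparison is column-wise after
  sorting.
* Problem sizes in the test suite (300 recovery replicates, 500
  enumeration trees, 100 permutation fits, $10^5$ bootstrap draws
  against a 256-case enumeration) were chosen so the whole suite runs in
  a few minutes while keeping Monte-Carlo error well inside the asserted
  bands.

## Limitations

Direct-count rates are downward biased at rapidly mutating loci (see
above) and carry no correction for unobserved non-paternity beyond the
Grubbs screen. The estimator treats meioses as exchangeable across loci
with missing calls. The lineage simulator is a stand-in for real
haplogroup structure, not a model of it. Likelihood-based event counting,
Bayesian rate models, TMRCA estimation and haplogroup prediction from
reference panels are out of scope.
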