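---
title: "Transmission tests under asymmetric genotype-calling error: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transmission tests under asymmetric genotype-calling error: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triotdt)
```

## The problem

At rare-variant sites, short-read genotype callers err asymmetrically: a true
heterozygote is far more likely to be reported as reference homozygote (rate
`r1`) than a true reference homozygote is to be reported as heterozygote
(rate `r2`). In parent-offspring trio designs this asymmetry is not just
noise. The transmission disequilibrium test (TDT) compares the counts `p` of
transmitted and `q` of non-transmitted rare alleles from heterozygous
parents via

\[
\mathrm{TDT} = \frac{(p - q)^2}{p + q} \sim \chi^2_1
\quad\text{under fair transmission,}
\]

and each miscall mode perturbs `p` and `q` in a *directional* way. The
package simulates the full chain — rare-variant panel, Hardy-Weinberg trios,
error injection, Mendelian screening, single-marker TDT and gene-collapsed
TDT — and provides closed-form expectations for the tally shifts, so that
type-I inflation and power loss can be studied quantitatively.

## The four error scenarios and their mechanisms

With dosages coded 0/1/2 for the panel-defined rare allele:

1. **`r1` in parents.** A het parent miscalled 0/0 withdraws its event: if
   it had transmitted the rare allele the trio becomes Mendelian-
   inconsistent at that site and is excluded; if not, the site becomes
   uninformative. Both tallies thin proportionally:
   \(T' = (1-r_1)T,\; U' = (1-r_1)U\). The transmitted *percentage* is
   invariant — which is exactly how tally tables diagnose this scenario.
2. **`r1` in offspring.** A het child miscalled 0/0 with a het parent turns
   a transmission into an apparent non-transmission:
   \(T' = (1-r_1)T,\; U' = U + r_1 T\). Totals are conserved, the apparent
   transmission fraction falls below one half, and the TDT inflates in the
   under-transmitted direction.
3. **`r2` in parents.** Enumerating all consistent triples shows that
   *every* 0/0→0/1 parent flip adds exactly one apparent non-transmission,
   never changes the transmitted count, and never creates an inconsistency:
   \(T' = T,\; U' = U + r_2 E\), where `E` counts hom-ref targeted-parent
   cells (`count_homref_exposures()`). We deliberately define `E` over all
   hom-ref parent cells rather than only those with a hom-ref child: the
   flip adds a non-transmission in either case ((0,1,1)→(1,1,1) contributes
   an extra `u` just as (0,1,0)→(1,1,0) does), and with this definition the
   scenario-3 expectation is exact rather than first-order.
4. **`r2` in offspring.** A hom-ref child with a het parent miscalled 0/1
   converts a non-transmission into an apparent transmission:
   \(T' = T + r_2 U,\; U' = (1-r_2)U\); double-hom-ref trios turned
   inconsistent are excluded and contribute nothing.

### First-order vs exact propagation

`propagate()` implements the four formulas above from aggregate totals
alone — the right tool when only published tallies are available. The
neglected terms all require two rare alleles in one trio at one site, and
their size is governed by the *event-weighted* allele frequency
\(\mathbb{E}[f^2]/\mathbb{E}[f]\), not the panel mean. Under a `1/f`
spectrum truncated at cap `c` this weight is roughly `c/2` (2.5% for a 5%
cap), so at `r1 = 10%` the scenario-1/2 formulas carry a relative bias of a
fraction of a percent of `T` — visible once Monte-Carlo error is pushed
below it. `expected_tally()` therefore complements the closed forms: given
the cohort itself it enumerates, for every eligible cell, the tally change
that a flip of that cell would cause, and sums `rate × change`. That
expectation is exact up to within-trio double-flip interactions, which are
O(rate²). The test suite validates `expected_tally()` against injection
simulations across the whole scenario-rate grid, and the first-order
operator against `expected_tally()` at the low-rate end and against
published tally percentages at all rates.

## The simulator and what it emulates

`sample_panel()` builds a gene panel with per-variant rare-allele
frequencies drawn from a configurable spectrum. The default,
`maf_spectrum_neutral(n_eff = 5000)`, has density ∝ `1/f` truncated to
`[1/(2 n_eff), maf_cap]` — the neutral site-frequency shape, dominated by
very rare variants as sequencing panels are. An explicit frequency table
(e.g. from a reference cohort) can be supplied instead. The rare allele is
fixed at panel creation and never re-polarized from sample frequencies.

`simulate_trios()` draws parental genotypes under Hardy-Weinberg equilibrium
per variant and transmits one uniformly chosen allele from each parent; the
chosen alleles are recorded so tests can audit the counting logic against
the construction. Variants are independent: no linkage disequilibrium, no
haplotypes, no de-novo mutation. None of the tally or test quantities
studied here depend on LD, but the simulator should not be used to study
haplotype-level methods. Missing genotypes never arise in simulation (they
are supported on the IO path for real data).

`simulate_affected_trios()` ascertains on an affected child under a logistic
penetrance: log-odds = `qlogis(baseline_prevalence) + beta × (causal
rare-allele count)`. The intercept is solved so a causal-allele-free child
is affected with exactly `baseline_prevalence`; with `beta = log(4)`, one
causal allele multiplies the odds by exactly 4. Because variants are
independent and affection depends only on causal dosages, candidates are
screened on the causal subpanel and non-causal genotypes are filled in
afterwards — identical in distribution, and much cheaper at low prevalence.
A configurable candidate budget turns pathologically low acceptance into a
clear error rather than a hang.

### Parameter defaults

| parameter | default | rationale |
|---|---|---|
| `maf_cap` | 0.05 | conventional rare-variant cutoff for type-I panels; power panels use 0.01 |
| spectrum | `1/f`, `n_eff = 5000` | neutral-like, rare-dominated; configurable |
| `causal_fraction` | 0.30 | standard fraction of causal variants in burden-test simulations |
| `beta` | `log(4)` | a strong per-allele rare-variant effect |
| `baseline_prevalence` | 0.01 | see below |
| trios per cohort | 100 | the canonical trio-study scale used throughout |

The prevalence default deserves a note. A high baseline attenuates the
effective odds ratio (at 0.05 baseline, one `log(4)` allele multiplies the
*probability* by only 3.5) and, combined with realistic causal-allele
carriage, saturates the ascertainment signal: the aggregate transmitted
fraction barely leaves 0.5 and gene-level power is nil, leaving nothing for
an error model to erode. At 0.01 — the right order of magnitude for the
neuropsychiatric traits trio studies target — ascertained cohorts show the
strong aggregate over-transmission (≈58% at the scales we simulate)
characteristic of published trio power studies, and power loss under
offspring het-loss errors becomes measurable.

## Counting conventions

* **Mendelian exclusion is per trio-variant cell**: an inconsistent triple
  removes that trio at that variant only, matching standard per-SNP TDT
  implementations. Exclusions are tallied in `n_excluded`.
* **Double-het triples** (1,1,1) contribute `(t, u) = (1, 1)` — the
  classical convention; in general `t = child − (hom-alt parents)` and
  `u = (het parents) − t`, which a brute-force enumeration over all 27
  dosage triples confirms is invariant across the compatible parental
  transmissions.
* **Missing genotypes** drop the trio-variant cell; nothing is imputed.
* **Uninformative tests** (`p + q = 0`) report statistic `NA` and p-value 1.
* **Percentages** in tally tables round to the nearest integer, ties away
  from zero.
* **p-values of exactly 0** are floored at the smallest positive double
  before `−log10` in QQ summaries.

The gene-level test collapses counts within a gene
(\(P_g = \sum p,\; Q_g = \sum q\)) and applies the same 1-df chi-square.
This is the natural gene-based extension of the TDT, and it reproduces the
behaviours that matter here: single-variant genes recover the single-marker
statistic exactly, bias accumulates with gene length, and no MAF weighting
or covariates are involved. Published gene-based trio software differs in
internals (likelihood-based variants exist); absolute gene-level p-values
should therefore be compared across implementations only qualitatively.

## Evaluation machinery

`qq_summary()` uses the exact finite-sample law of uniform order statistics:
the i-th smallest of n uniform p-values is Beta(i, n−i+1), giving the
expected quantile (its median) and a pointwise band (its tail quantiles) per
rank. `estimate_rate()` reports rejection fractions with Clopper-Pearson
intervals. `run_experiment()` wires the stages together for a condition
grid, pooling gene p-values across replicates; all sub-seeds derive from one
master seed and reruns are bit-identical.

Two design choices in the monotonicity evaluations are worth stating. We
reuse the same cohort realisation across the error-rate arms of a replicate
and drive injections from a common random stream, so the flip set at a lower
rate is nested inside that at a higher rate. This is a paired (common
random numbers) design: rate contrasts are then nearly deterministic in the
direction of the effect, and monotone trends are testable at a fraction of
the sample size an independent design would need. Second, the chi-square
rejection rate at the null is itself slightly discrete (counts are
integers), so calibration checks use exact binomial intervals around the
nominal level rather than normal approximations.

## Problem sizes used by the test suite

The shipped tests run scaled versions of the study design, chosen so each
property is decided by its statistics, not by runtime: type-I calibration
and inflation use 500 genes × 20 variants × 100 trios × 20 replicates
(10,000 gene tests per error rate); power uses 50 genes × 28 variants
(MAF < 0.01, 30% causal, `beta = log(4)`) × 100 affected trios × 40
replicates; propagation-vs-simulation uses a fixed 10,000-variant cohort
with 20 injection replicates per scenario-rate pair; gene-length contrasts
use a mixed panel of 20-variant and 120-variant genes. At these sizes the
entire suite completes in about a minute on a single core.

## Known limitations

* No linkage, haplotypes, or de-novo mutations; trios only, no extended
  pedigrees or siblings.
* The error model is a flat per-cell rate: no depth, genotype-quality, or
  per-site clustering structure, and hom-alt calls are assumed error-free
  (both flip types involving 1/1 are negligible at rare sites). Users with
  depth-stratified error estimates can map depth to `(r1, r2)` themselves.
* The gene test is the collapsed-count TDT; kernel/variance-component
  rare-variant tests are out of scope.
* `read_trio_vcf()` handles biallelic GT-only records; genotype likelihoods
  (PL/GL) are not modelled.
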