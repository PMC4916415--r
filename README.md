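# triotdt

Transmission disequilibrium tests under asymmetric genotype-calling error in
parent-offspring trios.

## The problem

Rare-variant genotype calls from short-read sequencing err asymmetrically: a
true heterozygote (0/1) is much more likely to be reported as reference
homozygote (0/0) — rate `r1` — than the reverse (rate `r2`). Trio designs
test association through transmission: with `p` transmitted and `q`
non-transmitted rare alleles from heterozygous parents,

    TDT = (p − q)² / (p + q)  ~  χ²(1 df)  under fair transmission,

and rare variants are collapsed within genes (`P_g = Σp`, `Q_g = Σq`, same
statistic) for gene-level testing. Because the errors are directional, they
do not merely add noise: het→hom-ref miscalls in *offspring* convert
transmissions into apparent non-transmissions, hom-ref→het miscalls in
*parents* add spurious non-transmissions, and both inflate the gene-level
type-I error while eroding power — more strongly in longer genes, where
per-variant bias accumulates.

`triotdt` is for statistical geneticists who want to quantify, predict, or
diagnose this bias. It provides:

- a rare-variant panel and Hardy-Weinberg trio simulator, with a logistic
  disease model for affected-offspring ascertainment
  (`sample_panel()`, `simulate_trios()`, `simulate_affected_trios()`);
- an error injector for the four canonical scenarios — `r1` or `r2`, in
  parents or offspring (`error_spec()`, `inject_errors()`);
- Mendelian-consistency screening, transmission tallies, single-marker and
  gene-collapsed TDT (`tally()`, `tdt_test()`, `gene_tdt()`);
- closed-form expected post-error tallies per scenario (`propagate()`,
  `expected_tally()`);
- type-I/power/QQ-band evaluation over replicated simulations
  (`estimate_rate()`, `qq_summary()`, `run_experiment()`);
- VCF/PED/gene-map IO and a thin command-line surface
  (`read_trio_vcf()`, `write_trio_cohort()`, `inst/cli/triotdt.R`).

## Worked example

Simulate a null cohort (no associated genes), miscall 10% of offspring
heterozygotes, and watch the tally and the gene-level test react:

```r
library(triotdt)

panel  <- sample_panel(200, variants_per_gene = 20, maf_cap = 0.05, seed = 1)
cohort <- simulate_trios(panel, n_trios = 100, seed = 2)
noisy  <- inject_errors(cohort, error_spec(2, 0.10), seed = 3)  # r1 = 10% in offspring

write_tally_table(list(
  `error-free` = tally(cohort, layer = "true"),
  `r1 = 10% in offspring` = tally(noisy)
))
#>                 error-free    r1 = 10% in offspring
#> Transmitted     "6,344 (50%)" "5,731 (45%)"
#> Non-transmitted "6,294 (50%)" "6,904 (55%)"
```

The error-free tally splits 50/50 — transmission is fair under the null.
The offspring errors push the apparent transmitted fraction to 45%: roughly
one in ten true transmissions now looks like a non-transmission, while the
total stays put. That directional shift is what inflates the test:

```r
genes <- gene_tdt(tally(noisy), panel)
estimate_rate(genes$p_value, alpha = 0.05)
#> rejection rate at alpha = 0.05: 27 / 200 = 0.1350 (95% CI 0.0909-0.1903)

head(genes[order(genes$p_value), c("gene_id", "P_g", "Q_g", "statistic", "p_value")], 3)
#>      gene_id P_g Q_g statistic      p_value
#> 154 gene0154  31  71  15.68627 7.476475e-05
#> 128 gene0128  23  55  13.12821 2.908833e-04
#> 153 gene0153  13  36  10.79592 1.017241e-03
```

With no true signal, 13.5% of genes reject at the 5% level, and every top
gene is *under*-transmitted (`Q_g > P_g`) — the tell-tale direction of
calling bias rather than association, and the diagnostic worth checking in
any real trio study whose top genes skew that way.

The closed-form propagation operator predicts tally shifts directly from
aggregate totals, e.g. starting from a published error-free tally:

```r
propagate(374502, 427972, error_spec(2, 0.10))
#> scenario 2: T 374,502 -> 337,051.8, U 427,972 -> 465,422.2 (42% transmitted)
```

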