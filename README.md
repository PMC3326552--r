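# retrocarrier

Tumour-subtype-specific risk-modifier estimation for BRCA1/BRCA2 mutation
carriers, for statistical geneticists and epidemiologists analysing
clinic-ascertained carrier cohorts.

Carrier cohorts over-sample affected individuals: the first person genotyped
in a family is usually someone who already had cancer. A standard Cox or
case-control analysis then biases a true risk modifier's hazard ratio toward
1, because the "unaffected" comparison group was selected partly on future
disease status. `retrocarrier` implements the retrospective likelihood that
conditions genotype and tumour subtype on the disease phenotype,

```
L = prod_i  P(y_i(t_i), d_i | g_i) P(g_i) / P(y_i(t_i)) ,
```

extended to two competing subtypes (ER- or PR-positive vs negative breast
cancer) with Cox-type genotype effects on each:

```
lambda(t) = nu(t) + mu(t),   nu(t) = nu0(t) exp(beta' z_g),   mu(t) = mu0(t) exp(gamma' z_g).
```

The baseline subtype hazards `nu0, mu0` are solved recursively under two
per-age constraints: the genotype-averaged total incidence among carriers
still at risk equals an external carrier incidence curve, and the expected
positive:negative case ratio equals age-group fractions `pi+/pi-` estimated
jointly with `beta`, `gamma` and the allele frequency. Affected carriers
with unknown subtype stay in the likelihood (missing-at-random
marginalization), variances are family-clustered sandwiches, and subtype
heterogeneity is a robust Wald test of `b2 = gamma - beta = 0`, with a
case-only logistic regression as cross-check. A synthetic-cohort generator
reproduces the ascertained, family-clustered, label-masked data structure
so every stage is testable without access to consortium data, and a
multilocus score module converts per-allele log-HRs into percentile-specific
absolute-risk curves.

## Worked example

The numbered scripts under `analysis/` form the full workflow; each writes
its tables under `results/`. Step 1 simulates an ascertained BRCA1-like
singleton cohort of ~20,000 carriers under FGFR2-like truths (per-allele HR
0.91 for ER-negative, 1.35 for ER-positive disease, MAF 0.40, 55% of
subtype labels masked). Step 2 refits it:

```
$ Rscript analysis/01_simulate_cohort.R
$ Rscript analysis/02_fit_retrospective.R
Per-allele model:
Retrospective-likelihood fit (per_allele model), logLik = -22907.672
q-hat = 0.3970; n = 20118 carriers
 subtype       term    hr    lo    hi       p
     neg per_allele 0.912 0.871 0.954 7.3e-05
     pos per_allele 1.365 1.259 1.480 4.7e-14
```

Both generating hazard ratios are recovered with honest cluster-robust
intervals, despite the over-sampling of affected carriers and the masked
labels. Step 3 shows the heterogeneity machinery on the same data — the
subtype difference `b2 = 0.404 (SE 0.050)`, its case-only logistic
cross-check `log-OR = 0.392`, and the naive Cox comparator collapsing to
`log-HR = 0.010`: the ascertainment bias the method exists to avoid. Step 4
compares published per-allele HR profiles across the 12 modifier loci
(one-way random-effects ICC: ER-positive profiles agree across genes at
0.65; ER-negative profiles do not, 0.05), and step 5 turns the published
panels into subtype-specific absolute-risk curves at the 5th/50th/95th score
percentiles (with the packaged synthetic incidence, BRCA2 carriers span
28–61% ER-positive risk by age 80 across percentiles, ER-negative only
10–19%; the spread is wider for the subtype with the more dispersed
log-HRs).

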