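---
title: "Subtype-specific risk-modifier estimation in ascertained carrier cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtype-specific risk-modifier estimation in ascertained carrier cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Carriers of pathogenic BRCA1 or BRCA2 mutations are mostly recruited through
cancer-genetics clinics, where the first person tested in a family is
typically someone already diagnosed with breast cancer at a young age. The
resulting cohorts heavily over-sample affected carriers. A standard Cox or
case-control analysis of a genetic risk modifier in such a cohort compares
cases against "unaffected" carriers who were selected partly on their future
disease status; when the variant is truly associated with risk, the
comparison group is enriched for the risk allele and the estimate is biased
toward the null. `retrocarrier` implements the retrospective-likelihood
remedy, extended to competing tumour subtypes (ER- or PR-positive versus
negative disease), so that a variant's effect can differ between subtypes
and carriers with unknown subtype still contribute.

## Model

Each carrier contributes a phenotype $y(t)$ — affected with breast cancer at
censoring age $t$, or unaffected at $t$ — a subtype label
$d \in \{\text{neg}, \text{pos}, \text{unknown}\}$, and a genotype
$g \in \{0,1,2\}$ (possibly missing). Carriers are censored at the first of:
breast cancer diagnosis, ovarian cancer diagnosis, bilateral prophylactic
mastectomy, or last follow-up; those censored at ovarian cancer are coded
unaffected.

Total incidence decomposes over competing subtypes,
$\lambda(t) = \nu(t) + \mu(t)$, with Cox-type genotype dependence

$$\nu(t) = \nu_0(t)\, e^{\beta' z_g}, \qquad \mu(t) = \mu_0(t)\, e^{\gamma' z_g},$$

where $z_g$ is the allele count (per-allele model) or a heterozygote /
homozygote indicator pair (2-df model). Working in discrete one-year ages,
the probability of the observed phenotype given genotype is the survival
factor $\exp\{-\sum_{u<t} [\nu_g(u) + \mu_g(u)]\}$ times, for affected
carriers, the subtype hazard at $t$ (their sum $\nu_g(t)+\mu_g(t)$ when the
label is unknown, which is valid when labels are missing at random with
respect to genotype).

The likelihood conditions the genotype and subtype on the phenotype:

$$\prod_i \frac{P(y_i(t_i), d_i \mid g_i)\, P(g_i)}{P(y_i(t_i))},$$

with Hardy–Weinberg genotype probabilities $P(g)$. Crucially, the
denominator marginalizes the subtype as well as the genotype: ascertainment
is assumed to depend on whether a carrier developed breast cancer, not on
which subtype — pathology rarely guided mutation screening historically.
This is what allows the age-group subtype fractions $\pi_+(t), \pi_-(t)$ to
be estimated within the data rather than supplied externally; a switch for
subtype-dependent ascertainment is deliberately not provided, since it would
require exactly such external estimates. Records with missing genotype keep
their subtype information (the genotype factor marginalizes out of the
ratio).

### Constrained baselines

$\nu_0(t)$ and $\mu_0(t)$ are not free: at every age the genotype-averaged
total incidence among carriers still at risk must reproduce an external
carrier incidence curve $\lambda(t)$, and the expected ratio of positive to
negative incident cases must equal $\pi_+(t)/\pi_-(t)$. Proceeding age by
age, the at-risk genotype distribution is the Hardy–Weinberg prior updated
by genotype-specific survival, and the two constraints are then linear in
$(\nu_0, \mu_0)$, giving the closed-form per-age solution

$$\nu_0(t) = \frac{\lambda(t)\,\pi_-(t)}{A(t)}, \qquad
  \mu_0(t) = \frac{\lambda(t)\,\pi_+(t)}{B(t)},$$

with $A, B$ the at-risk-averaged hazard multipliers of the two subtypes. No
global iteration is needed; the solver asserts the conservation identities
to $10^{-10}$ and they hold to machine precision in the test suite.

## Estimation

The likelihood is maximized jointly over $(\beta, \gamma)$, the allele
frequency $q$ and the $\pi$ fractions, with $q$ and $\pi$ on the logit
scale. The optimizer is BFGS with numerically differenced gradients,
restarted from its own solution until the objective stops improving (a
fresh Hessian approximation escapes premature stops on nearly flat
likelihoods); baselines are re-solved at every evaluation. Starting values
— null log-HRs, the observed allele frequency, and observed subtype
fractions per age group — make the null fit a one-step check. Identical
phenotype/genotype records are aggregated into cells first, so a fit on
20,000 carriers takes well under a second.

Variances are Huber–White sandwiches $A^{-1} B A^{-1}$ with score
contributions summed within family clusters, accommodating relatedness;
confidence intervals are $\exp(\hat\theta \pm 1.96\,\mathrm{SE})$.
Heterogeneity between subtypes is assessed by refitting in the
$(b_1, b_2)$ parameterization ($\beta = b_1$, $\gamma = b_1 + b_2$) and
Wald-testing $b_2 = 0$ on the robust variance; a likelihood-ratio version
(no robust correction) is reported as a secondary diagnostic, and a
case-only logistic regression of subtype on allele count gives an
asymptotically equivalent external check. A naive Cox comparator
(`naive_cox()`) is included only to demonstrate the ascertainment bias it
suffers.

### ICC between hazard-ratio profiles

`icc_oneway()` computes the one-way random-effects intraclass correlation
from the ANOVA decomposition, treating each locus as a group with two
ratings. The published cross-gene and cross-subtype comparisons of
per-allele HR profiles are reproduced when the ICC is taken on the
hazard-ratio scale directly; a log-scale ICC of the same vectors is
slightly lower (0.59 rather than 0.65 for the ER-positive cross-gene
comparison). The function is scale-agnostic; the analysis scripts apply it
on the HR scale, which is the convention that matches the reported values.

## Tunable parameters and defaults

* **Age grid** — annual integers 0–80; hazards are per-year rates, survival
  uses $\exp(-\sum)$ of them. Ages beyond the grid are invalid input.
* **$\pi$ age groups** — `<40, 40–49, 50–59, ≥60` by default
  (`pi_edges = c(40, 50, 60)`), configurable; published analyses do not
  state their grouping, so it is exposed rather than fixed.
* **Allele frequency and $\pi$** — shared across country strata (baselines
  are still solved per stratum against each stratum's incidence curve).
  Whether consortium analyses estimated them per country is unstated;
  global estimation is the default and the only implemented option.
* **Incidence curves** — user-supplied TSV per gene (and optionally per
  stratum). The packaged `synthetic_incidence()` curves are smooth logistic
  ramps from age 20 reaching cumulative risks of roughly 70% (BRCA1-like)
  and 50% (BRCA2-like) by age 80 — realistic magnitudes for carriers, used
  for simulation and testing only.
* **Generator defaults** — singleton carriers; clinic ascertainment keeping
  affected families with probability 1 and unaffected ones with 0.4 (about
  half of retained carriers affected, as in large carrier cohorts); subtype
  labels masked at 0.56 (matching the roughly 4,310 of 9,815 affected
  carriers with receptor data in the motivating consortium); interview ages
  uniform on 25–79; a 0.005/year competing censoring hazard from age 18 for
  the prophylactic-surgery/ovarian-cancer analogue; subtype splits
  $\pi_+ \approx 0.22$–$0.28$ (BRCA1-like) or $0.72$–$0.80$ (BRCA2-like)
  rising with age, mirroring reported receptor distributions.

## What the simulator does and does not emulate

Sibships with two unobserved founders and Mendelian transmission give
positive within-family genotype correlation — the minimal structure that
makes the cluster-robust sandwich testable. The generator draws latent
competing subtype event ages from the genotype-specific hazards implied by
the same constrained-baseline machinery used in fitting, so generating and
fitting models agree by construction. It does not emulate: heterogeneous
ascertainment across 36 real study designs, mutation-testing cascades
within families, calendar-time incidence trends, competing mortality, more
than two subtypes, or subtype misclassification. Passing recovery tests
therefore show the estimator is consistent and unbiased under its own
assumptions, not that those assumptions hold in any particular registry.

## Numerical choices

Probabilities are computed in log space from per-age matrices; an observed
event at an age with zero hazard is surfaced as an error rather than
silently returning $-\infty$. $\pi$ components are constrained to the open
interval (0,1) by construction; a subtype split of exactly 0 or 1 at an age
with positive incidence would make one subtype impossible and is rejected
at construction. Score-distribution percentiles use the weighted inverse
CDF with ties broken toward the lower score. In the multilocus risk curves
the survivor score distribution is updated for attrition age by age (the
static-distribution alternative would overstate high-score incidence at
late ages); with all log-HRs zero the curves collapse exactly to
$1 - \exp(-\sum \lambda_{\text{subtype}})$.

## Problem sizes

The test suite runs its enumeration oracle on 100 random toy cohorts, null
calibration on 200 ascertained replicates of ~2,000 carriers, attenuation
on 50 replicates, recovery on 12 replicates of ~6,000 carriers, and
coverage on 40 replicates — sizes chosen so the whole suite completes in a
few minutes. The acceptance script runs the recovery studies at 25
replicates of ~20,000 (BRCA1-like) and ~15,000 (BRCA2-like) retained
singleton carriers per scenario.

## Known limitations

No pedigree likelihood: unobserved relatives do not contribute, so the
method is a working-model sandwich approach rather than full kin-cohort
inference. Strata with very few carriers should be grouped by the user
before fitting. The 2-df model can be weakly identified for rare
homozygotes in small cohorts; the per-allele model is the default
throughout. Multilocus risk curves assume linkage equilibrium and a
multiplicative combined model, and population percentiles — not individual
imputation-aware scores — drive the reported curves.
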