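#!/usr/bin/env Rscript

# Step 2: fit the retrospective likelihood to the example cohort.
#
# Estimates per-allele and 2-df genotype-specific hazard ratios for
# ER-negative and ER-positive disease jointly with the allele frequency and
# the age-group subtype fractions, with cluster-robust confidence intervals.
# The generating truths were HR 0.91 (ER-negative) and 1.35 (ER-positive).

suppressPackageStartupMessages(library(retrocarrier))

cohort <- read_carrier_tsv("results/example_cohort.tsv")
inc <- synthetic_incidence("BRCA1")

fit_pa <- fit_single_snp(cohort, inc, model = "per_allele")
fit_2df <- fit_single_snp(cohort, inc, model = "genotype")

cat("Per-allele model:\n"); print(fit_pa)
cat("\n2-df genotype model:\n"); print(fit_2df)

write_fit_results(list(example_per_allele = fit_pa,
                       example_genotype = fit_2df),
                  "results/fit_example")
cat("\nwrote results/fit_example.{tsv,json}\n")
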