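#!/usr/bin/env Rscript

# Step 3: subtype heterogeneity and sensitivity comparators.
#
# Tests whether the variant's per-allele effect differs between ER-positive
# and ER-negative disease (Wald on b2 = gamma - beta with cluster-robust
# variance), cross-checks it with the case-only logistic regression, and
# shows the attenuation of the naive Cox estimate on ascertained data.

suppressPackageStartupMessages(library(retrocarrier))

cohort <- read_carrier_tsv("results/example_cohort.tsv")
inc <- synthetic_incidence("BRCA1")
truth <- jsonlite::read_json("results/example_cohort_truth.json")

het <- heterogeneity_test(cohort, inc)
print(het)

co <- case_only_logistic(cohort)
cat(sprintf("Case-only logistic log-OR = %.4f (SE %.4f, p = %.3g)\n",
            co$log_or, co$se, co$p))
cat(sprintf("  (cross-check of b2; generating value %.4f)\n",
            truth$gamma - truth$beta))

nv <- naive_cox(cohort, "any")
cat(sprintf("Naive Cox per-allele log-HR (any breast cancer) = %.4f (SE %.4f)\n",
            nv$log_hr, nv$se))
cat("  attenuated toward 0 by the over-sampling of affected carriers;\n")
cat("  compare the retrospective per-subtype estimates of step 2.\n")

jsonlite::write_json(
  list(b2 = het$b2, se = het$se, p_wald = het$p, p_lrt = het$p_lrt,
       case_only_log_or = co$log_or, case_only_se = co$se,
       naive_cox_log_hr = nv$log_hr),
  "results/heterogeneity.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/heterogeneity.json\n")
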