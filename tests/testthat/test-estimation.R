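sim_small <- function(seed, n_fam = 1500, beta = log(0.9), gamma = log(1.4),
                      q = 0.35, ...) {
  simulate_cohort(sim_config(n_families = n_fam, q = q, beta = beta,
                             gamma = gamma, subtype_missing = 0.4,
                             seed = seed, ...))
}

test_that("the fitted effect pair is a lattice argmax of the profiled likelihood", {
  # small-cohort fit cross-checked against a grid search over (beta, gamma)
  # holding the nuisance parameters at their fitted values
  toy <- data.frame(
    carrier_id = paste0("c", 1:8), family_id = paste0("f", 1:8),
    stratum = "S1", gene = "BRCA1",
    censor_age = c(45, 55, 42, 58, 47, 60, 52, 65),
    affected = c(1, 1, 1, 1, 1, 0, 0, 0),
    subtype = c("pos", "pos", "neg", "neg", "neg", "unknown", "unknown", "unknown"),
    genotype = c(1, 0, 0, 2, 1, 0, 1, 2), stringsAsFactors = FALSE)
  inc <- synthetic_incidence("BRCA1")
  fit <- fit_single_snp(toy, inc, pi_edges = c(50), compute_se = FALSE,
                        control = list(reltol = 1e-14))
  bhat <- fit$coef[["beta"]]; ghat <- fit$coef[["gamma"]]
  prof <- function(b, g) {
    p <- model_params(b, g, fit$q, fit$pi)
    cohort_loglik(toy, p, solve_baselines(p, inc))
  }
  # fine lattice around the optimum at the spec'd 0.001 step
  grid <- expand.grid(b = bhat + seq(-0.02, 0.02, by = 0.001),
                      g = ghat + seq(-0.02, 0.02, by = 0.001))
  ll <- mapply(prof, grid$b, grid$g)
  best <- grid[which.max(ll), ]
  expect_lt(abs(best$b - bhat), 1e-3 + 1e-9)
  expect_lt(abs(best$g - ghat), 1e-3 + 1e-9)
  # and no better point on a coarse wide lattice
  wide <- expand.grid(b = seq(-1, 1, by = 0.05), g = seq(-1, 1, by = 0.05))
  expect_lte(max(mapply(prof, wide$b, wide$g)), prof(bhat, ghat) + 1e-6)
})

test_that("heterogeneity refit reproduces the unconstrained fit", {
  d <- sim_small(101, n_fam = 1200)
  inc <- synthetic_incidence("BRCA1")
  fit <- fit_single_snp(d, inc, compute_se = FALSE,
                        control = list(reltol = 1e-14))
  het <- heterogeneity_test(d, inc, control = list(reltol = 1e-14))
  # reparameterization identity: b2 = gamma - beta, b1 = beta
  expect_equal(het$b2, fit$coef[["gamma"]] - fit$coef[["beta"]],
               tolerance = 1e-5)
  expect_equal(het$fit_het$loglik, fit$loglik, tolerance = 1e-8)
  expect_true(het$p >= 0 && het$p <= 1)
  expect_gte(het$lrt_stat, -1e-8)
  # constrained fit can never beat the unconstrained one
  expect_lte(het$fit_common$loglik, fit$loglik + 1e-8)
})

test_that("the likelihood is invariant to minor-allele relabelling", {
  d <- sim_small(202, n_fam = 800)
  inc <- synthetic_incidence("BRCA1")
  fit1 <- fit_single_snp(d, inc, compute_se = FALSE,
                         control = list(reltol = 1e-14))
  d2 <- d
  d2$genotype <- 2L - d2$genotype
  fit2 <- fit_single_snp(d2, inc, compute_se = FALSE,
                         control = list(reltol = 1e-14))
  expect_equal(fit2$loglik, fit1$loglik, tolerance = 1e-8)
  expect_equal(fit2$coef[["beta"]], -fit1$coef[["beta"]], tolerance = 1e-4)
  expect_equal(fit2$coef[["gamma"]], -fit1$coef[["gamma"]], tolerance = 1e-4)
  expect_equal(fit2$q, 1 - fit1$q, tolerance = 1e-4)
})

test_that("fit diagnostics: likelihood at the optimum has a small gradient", {
  d <- sim_small(303, n_fam = 600)
  fit <- fit_single_snp(d, synthetic_incidence("BRCA1"), compute_se = FALSE)
  expect_identical(fit$convergence, 0L)
  expect_lt(fit$gradient_norm, 0.5)
  # the maximized likelihood beats the starting values
  env <- fit$core$env
  start_ll <- -env$nll(retrocarrier:::start_values(env))
  expect_gte(fit$loglik, start_ll)
})

test_that("robust variance is symmetric PSD and consistent for singletons", {
  d <- sim_small(404, n_fam = 4000)
  inc <- synthetic_incidence("BRCA1")
  fit <- fit_single_snp(d, inc)
  V <- fit$vcov
  expect_equal(V, t(V))
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
  # singleton families, well-specified model: robust ~ model-based
  A <- stats::optimHess(fit$coef, fit$core$env$nll)
  se_model <- sqrt(diag(solve(A)))
  ratio <- sqrt(diag(V)) / se_model
  expect_true(all(ratio[1:2] > 0.8 & ratio[1:2] < 1.2))
})

test_that("duplicating carriers as twin families inflates robust SEs by sqrt(2)", {
  d <- sim_small(505, n_fam = 1200)
  inc <- synthetic_incidence("BRCA1")
  dup <- rbind(d, d)
  dup$carrier_id <- paste0(dup$carrier_id, rep(c("a", "b"), each = nrow(d)))
  # (i) duplicates share a family: clustered
  fit_tw <- fit_single_snp(dup, inc)
  # (ii) duplicates treated as independent singletons
  dup2 <- dup
  dup2$family_id <- dup2$carrier_id
  fit_sg <- fit_single_snp(dup2, inc)
  ratio <- sqrt(diag(fit_tw$vcov)[1:2] / diag(fit_sg$vcov)[1:2])
  expect_equal(unname(ratio), c(sqrt(2), sqrt(2)), tolerance = 0.05)
})

test_that("robust CIs for the positive-subtype effect achieve near-nominal coverage", {
  set.seed(77)
  truth <- log(1.3)
  hits <- 0
  nrep <- 40
  for (r in 1:40) {
    d <- simulate_cohort(sim_config(n_families = 2500, q = 0.3,
                                    beta = log(0.95), gamma = truth,
                                    subtype_missing = 0.4, seed = 7000 + r))
    fit <- fit_single_snp(d, synthetic_incidence("BRCA1"))
    se <- sqrt(fit$vcov["gamma", "gamma"])
    est <- fit$coef[["gamma"]]
    hits <- hits + (truth >= est - 1.96 * se && truth <= est + 1.96 * se)
  }
  # binomial band around 0.95 at 40 replicates
  expect_gte(hits / nrep, 0.85)
})

test_that("case-only logistic regression cross-checks the heterogeneity parameter", {
  d <- sim_small(606, n_fam = 8000, beta = log(0.9), gamma = log(1.5))
  co <- case_only_logistic(d)
  het <- heterogeneity_test(d, synthetic_incidence("BRCA1"))
  joint_se <- sqrt(co$se^2 + het$se^2)
  expect_lt(abs(co$log_or - het$b2), 2 * joint_se)
  # equal genotype distributions in the two subtypes: log-OR near 0
  bal <- data.frame(
    carrier_id = paste0("c", 1:240), family_id = paste0("f", 1:240),
    stratum = "S1", gene = "BRCA1", censor_age = rep(c(40, 50), 120),
    affected = 1,
    subtype = rep(c("neg", "pos"), each = 120),
    genotype = rep(rep(0:2, times = c(50, 50, 20)), 2),
    stringsAsFactors = FALSE)
  expect_lt(abs(case_only_logistic(bal)$log_or), 1e-8)
  # all cases of one subtype: degenerate
  one <- bal[bal$subtype == "neg", ]
  expect_error(case_only_logistic(one), "both subtypes")
})
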