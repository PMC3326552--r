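flat_inc <- function(rate = 0.02, amax = 80) incidence_curve(0:amax, rep(rate, amax + 1))

test_that("phenotype probability branches behave as probabilities", {
  pi <- subtype_pi(rep(0.4, 4))
  p <- model_params(log(0.9), log(1.35), 0.38, pi)
  bl <- solve_baselines(p, flat_inc())
  # zero hazards: unaffected probability 1
  bl0 <- solve_baselines(p, incidence_curve(0:80, rep(0, 81)))
  rec <- list(censor_age = 50, affected = 0, subtype = "unknown", genotype = 1)
  expect_equal(phenotype_given_genotype(rec, p, bl0), 1)
  # affected where the subtype hazard is zero: impossible event
  inc_gap <- incidence_curve(0:80, c(rep(0, 30), rep(0.02, 51)))
  blg <- solve_baselines(p, inc_gap)
  rec2 <- list(censor_age = 20, affected = 1, subtype = "neg", genotype = 0)
  expect_equal(phenotype_given_genotype(rec2, p, blg), 0)
  # unknown subtype = sum of the two known-subtype branches
  for (g in 0:2) {
    r <- function(s) list(censor_age = 45, affected = 1, subtype = s, genotype = g)
    expect_equal(phenotype_given_genotype(r("unknown"), p, bl),
                 phenotype_given_genotype(r("neg"), p, bl) +
                 phenotype_given_genotype(r("pos"), p, bl))
  }
})

test_that("under the null the retrospective likelihood factorizes", {
  pi <- subtype_pi(c(0.3, 0.4, 0.5, 0.6))
  p <- model_params(0, 0, 0.38, pi)
  bl <- solve_baselines(p, flat_inc())
  pg <- genotype_prior(0.38)
  # affected, known subtype: log P(g) + log pi_d(t)
  rec <- list(censor_age = 45, affected = 1, subtype = "pos", genotype = 2)
  expect_equal(retro_loglik_one(rec, p, bl), log(pg[3]) + log(0.4),
               tolerance = 1e-12)
  rec$subtype <- "neg"
  expect_equal(retro_loglik_one(rec, p, bl), log(pg[3]) + log(0.6),
               tolerance = 1e-12)
  # unaffected and unknown-subtype records: log P(g) only
  for (r in list(list(censor_age = 45, affected = 0, subtype = "unknown", genotype = 1),
                 list(censor_age = 45, affected = 1, subtype = "unknown", genotype = 1))) {
    expect_equal(retro_loglik_one(r, p, bl), log(pg[2]), tolerance = 1e-12)
  }
})

test_that("conditional probabilities normalize over genotypes and subtypes", {
  pi <- subtype_pi(c(0.25, 0.35, 0.45, 0.55))
  p <- model_params(0.3, -0.4, 0.2, pi)
  bl <- solve_baselines(p, synthetic_incidence("BRCA1"))
  # affected carrier: sum over (g, d) of P(g, d | y) is 1
  tot <- 0
  for (g in 0:2) for (d in c("neg", "pos")) {
    tot <- tot + exp(retro_loglik_one(
      list(censor_age = 52, affected = 1, subtype = d, genotype = g), p, bl))
  }
  expect_equal(tot, 1, tolerance = 1e-10)
  # unaffected: sum over g is 1
  tot0 <- sum(vapply(0:2, function(g) exp(retro_loglik_one(
    list(censor_age = 52, affected = 0, subtype = "unknown", genotype = g),
    p, bl)), numeric(1)))
  expect_equal(tot0, 1, tolerance = 1e-10)
})

test_that("the spec toy cohort matches brute-force enumeration", {
  pi <- subtype_pi(rep(0.4, 4))
  p <- model_params(log(0.9), log(1.35), 0.38, pi)
  bl <- solve_baselines(p, flat_inc(0.02))
  toy <- data.frame(
    carrier_id = c("a", "b", "c"), family_id = c("a", "b", "c"),
    stratum = "S1", gene = "BRCA1",
    censor_age = c(40, 55, 62), affected = c(1, 0, 1),
    subtype = c("pos", "unknown", "neg"), genotype = c(1, 0, 2),
    stringsAsFactors = FALSE)
  expect_equal(cohort_loglik(toy, p, bl),
               oracle_cohort_loglik(toy, p, bl), tolerance = 1e-8)
})

test_that("modular likelihood equals enumeration on randomized toy cohorts", {
  set.seed(21)
  inc <- synthetic_incidence("BRCA1")
  for (rep in 1:30) {
    p <- random_params()
    bl <- solve_baselines(p, inc)
    toy <- random_toy_cohort(sample(2:10, 1))
    expect_equal(cohort_loglik(toy, p, bl),
                 oracle_cohort_loglik(toy, p, bl), tolerance = 1e-8)
  }
})

test_that("cohort likelihood is order-invariant and stratification-consistent", {
  set.seed(31)
  p <- random_params()
  inc <- synthetic_incidence("BRCA1")
  bl <- solve_baselines(p, inc)
  toy <- random_toy_cohort(40)
  ll <- cohort_loglik(toy, p, bl)
  expect_equal(cohort_loglik(toy[sample(40), ], p, bl), ll)
  # two strata with identical incidence and parameters equal the pooled value
  toy2 <- toy
  toy2$stratum <- rep(c("A", "B"), 20)
  expect_equal(cohort_loglik(toy2, p, list(A = bl, B = bl)), ll)
  expect_error(cohort_loglik(toy2, p, list(A = bl)), "no baselines")
})

test_that("an observed event with zero hazard is surfaced as an error", {
  pi <- subtype_pi(rep(0.4, 4))
  p <- model_params(0, 0, 0.3, pi)
  inc_gap <- incidence_curve(0:80, c(rep(0, 30), rep(0.02, 51)))
  bl <- solve_baselines(p, inc_gap)
  toy <- data.frame(carrier_id = "a", family_id = "a", stratum = "S1",
                    gene = "BRCA1", censor_age = 20, affected = 1,
                    subtype = "neg", genotype = 0, stringsAsFactors = FALSE)
  expect_error(cohort_loglik(toy, p, bl), "zero hazard")
})
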