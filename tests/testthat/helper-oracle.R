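# Brute-force oracles, independent of the package's vectorized likelihood
# path: explicit loops over genotypes and subtypes, survival recomputed from
# the baseline vectors by direct summation.

# survival of genotype g to the start of age t (explicit sum, no matrices)
oracle_survival <- function(g, t, params, baselines) {
  a <- if (params$model == "per_allele") exp(params$beta * g) else
    c(1, exp(params$beta))[g + 1]
  b <- if (params$model == "per_allele") exp(params$gamma * g) else
    c(1, exp(params$gamma))[g + 1]
  tot <- 0
  for (u in baselines$age[baselines$age < t]) {
    i <- which(baselines$age == u)
    tot <- tot + baselines$nu0[i] * a + baselines$mu0[i] * b
  }
  exp(-tot)
}

# P(y(t), d | g) by direct evaluation
oracle_pheno_prob <- function(censor_age, affected, subtype, g, params, baselines) {
  a <- if (params$model == "per_allele") exp(params$beta * g) else
    c(1, exp(params$beta))[g + 1]
  b <- if (params$model == "per_allele") exp(params$gamma * g) else
    c(1, exp(params$gamma))[g + 1]
  S <- oracle_survival(g, censor_age, params, baselines)
  if (affected == 0) return(S)
  i <- which(baselines$age == censor_age)
  nu <- baselines$nu0[i] * a
  mu <- baselines$mu0[i] * b
  h <- switch(subtype, neg = nu, pos = mu, unknown = nu + mu)
  h * S
}

# per-record retrospective log-likelihood by full enumeration over (g, d)
oracle_retro_loglik <- function(rec, params, baselines) {
  pg <- genotype_prior(params$q)
  # denominator: phenotype only (subtype marginalized)
  den <- 0
  for (gp in 0:2) {
    den <- den + pg[gp + 1] *
      oracle_pheno_prob(rec$censor_age, rec$affected, "unknown", gp,
                        params, baselines)
  }
  if (is.na(rec$genotype)) {
    num <- 0
    for (gp in 0:2) {
      num <- num + pg[gp + 1] *
        oracle_pheno_prob(rec$censor_age, rec$affected, rec$subtype, gp,
                          params, baselines)
    }
  } else {
    num <- pg[rec$genotype + 1] *
      oracle_pheno_prob(rec$censor_age, rec$affected, rec$subtype,
                        rec$genotype, params, baselines)
  }
  log(num) - log(den)
}

oracle_cohort_loglik <- function(records, params, baselines) {
  tot <- 0
  for (i in seq_len(nrow(records))) {
    tot <- tot + oracle_retro_loglik(records[i, ], params, baselines)
  }
  tot
}

# random toy cohort on a short age grid
random_toy_cohort <- function(n, amax = 60) {
  aff <- stats::rbinom(n, 1, 0.5)
  sub <- ifelse(aff == 1,
                sample(c("neg", "pos", "unknown"), n, replace = TRUE),
                "unknown")
  g <- sample(c(0:2, NA), n, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  data.frame(
    carrier_id = paste0("c", seq_len(n)),
    family_id = paste0("f", seq_len(n)),
    stratum = "S1", gene = "BRCA1",
    censor_age = sample(25:amax, n, replace = TRUE),
    affected = aff, subtype = sub, genotype = g,
    stringsAsFactors = FALSE)
}

random_params <- function() {
  model_params(beta = stats::runif(1, -0.5, 0.5),
               gamma = stats::runif(1, -0.5, 0.5),
               q = stats::runif(1, 0.1, 0.6),
               pi = subtype_pi(stats::runif(4, 0.15, 0.85)))
}
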