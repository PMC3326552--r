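#' Age-group subtype case fractions
#'
#' Holds the fraction of incident breast cancers that are subtype-positive
#' (e.g. ER-positive) within each age group. The groups partition the age
#' grid; each fraction must lie strictly inside (0, 1) so that the subtype
#' split of the total incidence is well posed at every age with positive
#' hazard.
#'
#' @param pi_pos Numeric vector of subtype-positive fractions, one per group,
#'   each in the open interval (0, 1).
#' @param edges Increasing interior age boundaries; `length(edges) + 1` groups.
#'   The default groups are `<40`, `40-49`, `50-59`, `>=60`.
#' @return Object of class `subtype_pi`.
#' @export
subtype_pi <- function(pi_pos, edges = c(40, 50, 60)) {
  pi_pos <- as.numeric(pi_pos)
  edges <- as.numeric(edges)
  if (length(pi_pos) != length(edges) + 1L) {
    stop("need length(edges) + 1 subtype-positive fractions")
  }
  if (any(!is.finite(pi_pos)) || any(pi_pos <= 0) || any(pi_pos >= 1)) {
    stop("pi_pos must lie strictly in (0, 1)")
  }
  if (is.unsorted(edges, strictly = TRUE)) stop("edges must be strictly increasing")
  structure(list(pi_pos = pi_pos, edges = edges), class = "subtype_pi")
}

# age-group index for each age (1-based)
pi_group <- function(pi, ages) findInterval(ages, pi$edges) + 1L

# per-age subtype-positive fraction
pi_at_ages <- function(pi, ages) pi$pi_pos[pi_group(pi, ages)]

#' Model parameters for the two-subtype hazard model
#'
#' Bundles the genotype log-hazard-ratios for the two competing tumour
#' subtypes, the minor-allele frequency and the age-group subtype fractions.
#' Under the per-allele (multiplicative) model `beta` and `gamma` are scalars:
#' the log-HR per copy of the minor allele for subtype-negative and
#' subtype-positive disease respectively. Under the 2-df `"genotype"` model
#' each is a pair `(heterozygote, homozygote)` of log-HRs with the common
#' homozygote as reference.
#'
#' @param beta Log-HR(s) for subtype-negative disease.
#' @param gamma Log-HR(s) for subtype-positive disease.
#' @param q Minor-allele frequency, in (0, 1).
#' @param pi A [subtype_pi()] object.
#' @param model `"per_allele"` or `"genotype"`.
#' @return Object of class `model_params`.
#' @export
model_params <- function(beta, gamma, q, pi,
                         model = c("per_allele", "genotype")) {
  model <- match.arg(model)
  k <- if (model == "per_allele") 1L else 2L
  if (length(beta) != k || length(gamma) != k) {
    stop("beta and gamma must have length ", k, " under the ", model, " model")
  }
  if (any(!is.finite(c(beta, gamma)))) stop("log-HRs must be finite")
  if (!is.finite(q) || q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  if (!inherits(pi, "subtype_pi")) stop("pi must be a subtype_pi object")
  structure(list(beta = as.numeric(beta), gamma = as.numeric(gamma),
                 q = q, pi = pi, model = model),
            class = "model_params")
}

#' Hardy-Weinberg genotype prior
#'
#' Probabilities of carrying 0, 1 or 2 copies of the minor allele under
#' Hardy-Weinberg equilibrium.
#'
#' @param q Minor-allele frequency in (0, 1).
#' @return Numeric triple `( (1-q)^2, 2q(1-q), q^2 )`.
#' @export
genotype_prior <- function(q) {
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0 || q >= 1) {
    stop("q must be a single number in (0, 1)")
  }
  c((1 - q)^2, 2 * q * (1 - q), q^2)
}

# hazard-ratio multipliers over g = 0, 1, 2 for one subtype
geno_relrisk <- function(coef, model) {
  if (model == "per_allele") exp(coef * (0:2)) else c(1, exp(coef[1]), exp(coef[2]))
}

#' Solve the constrained subtype baseline hazards
#'
#' Proceeding age by age from the start of the grid, solves for the baseline
#' subtype-negative hazard `nu0(t)` and subtype-positive hazard `mu0(t)` such
#' that, among carriers still at risk at age t (whose genotype distribution is
#' the Hardy-Weinberg prior updated by genotype-specific survival),
#' the genotype-averaged total hazard equals the external incidence
#' `lambda(t)` and the expected positive:negative incident-case ratio equals
#' `pi_pos(t) : pi_neg(t)`. Writing `A(t)` and `B(t)` for the at-risk-averaged
#' hazard-ratio multipliers of the two subtypes, the per-age solution is
#' closed form: `nu0(t) = lambda(t) pi_neg(t) / A(t)` and
#' `mu0(t) = lambda(t) pi_pos(t) / B(t)`.
#'
#' @param params A [model_params()] object.
#' @param incidence An [incidence_curve()] on the analysis age grid.
#' @return Object of class `subtype_baselines` with fields `age`, `nu0`,
#'   `mu0`, and `surv_geno_dist` (genotype distribution among carriers at
#'   risk at each age; rows sum to 1).
#' @export
solve_baselines <- function(params, incidence) {
  stopifnot(inherits(params, "model_params"), inherits(incidence, "incidence_curve"))
  ages <- incidence$age
  lam <- incidence$rate
  n <- length(ages)
  a <- geno_relrisk(params$beta, params$model)   # subtype-negative multipliers
  b <- geno_relrisk(params$gamma, params$model)  # subtype-positive multipliers
  prior <- genotype_prior(params$q)
  ppos <- pi_at_ages(params$pi, ages)

  nu0 <- numeric(n)
  mu0 <- numeric(n)
  dist <- matrix(NA_real_, n, 3L)
  S <- c(1, 1, 1)  # genotype-specific survival to the start of each age
  for (i in seq_len(n)) {
    pg <- prior * S
    pg <- pg / sum(pg)
    dist[i, ] <- pg
    if (lam[i] > 0) {
      A <- sum(pg * a)
      B <- sum(pg * b)
      nu0[i] <- lam[i] * (1 - ppos[i]) / A
      mu0[i] <- lam[i] * ppos[i] / B
    }
    S <- S * exp(-(nu0[i] * a + mu0[i] * b))
  }
  stopifnot(all(nu0 >= 0), all(mu0 >= 0))
  structure(list(age = ages, nu0 = nu0, mu0 = mu0, surv_geno_dist = dist),
            class = "subtype_baselines")
}

#' @export
print.subtype_baselines <- function(x, ...) {
  cat(sprintf("<subtype_baselines> ages %d-%d, cum nu0 %.3f, cum mu0 %.3f\n",
              min(x$age), max(x$age), sum(x$nu0), sum(x$mu0)))
  invisible(x)
}

#' Genotype-specific subtype hazards
#'
#' Applies the Cox-type genotype dependence to the solved baselines:
#' `nu(t) = nu0(t) exp(beta' z_g)` for subtype-negative disease and
#' `mu(t) = mu0(t) exp(gamma' z_g)` for subtype-positive disease.
#'
#' @param g Genotype, 0, 1 or 2 minor alleles.
#' @param params A [model_params()].
#' @param baselines A [solve_baselines()] result.
#' @return List with per-age vectors `nu` and `mu`.
#' @export
subtype_hazards <- function(g, params, baselines) {
  if (!g %in% 0:2) stop("g must be 0, 1 or 2")
  a <- geno_relrisk(params$beta, params$model)[g + 1L]
  b <- geno_relrisk(params$gamma, params$model)[g + 1L]
  list(age = baselines$age, nu = baselines$nu0 * a, mu = baselines$mu0 * b)
}

# per-age, per-genotype hazard and survival matrices used throughout:
# hneg/hpos/htot are (n_ages x 3); S[t, g] is survival to the *start* of age t.
hazard_matrices <- function(params, baselines) {
  a <- geno_relrisk(params$beta, params$model)
  b <- geno_relrisk(params$gamma, params$model)
  hneg <- outer(baselines$nu0, a)
  hpos <- outer(baselines$mu0, b)
  htot <- hneg + hpos
  n <- nrow(htot)
  cum <- apply(htot, 2, cumsum)
  S <- exp(-rbind(0, cum[-n, , drop = FALSE]))
  list(age = baselines$age, hneg = hneg, hpos = hpos, htot = htot, S = S)
}
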