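#' Multilocus SNP panel
#'
#' A small table of independent loci (linkage equilibrium assumed), each with
#' a minor-allele frequency and a per-allele log-HR for the tumour subtype
#' under consideration. The multilocus score of a genotype profile is
#' `sum_j beta_j g_j`, assuming a multiplicative model for the combined
#' associations.
#'
#' @param locus Character identifiers.
#' @param maf Minor-allele frequencies in (0, 1).
#' @param loghr Per-allele log-hazard-ratios (finite).
#' @return Object of class `snp_panel` (a data.frame).
#' @export
snp_panel <- function(locus, maf, loghr) {
  if (length(maf) != length(locus) || length(loghr) != length(locus)) {
    stop("locus, maf and loghr must have equal length")
  }
  if (any(maf <= 0) || any(maf >= 1)) stop("maf must lie in (0, 1)")
  if (any(!is.finite(loghr))) stop("loghr must be finite")
  structure(data.frame(locus = as.character(locus), maf = maf, loghr = loghr),
            class = c("snp_panel", "data.frame"))
}

#' Population distribution of the multilocus score
#'
#' Exact enumeration of all multilocus genotypes: the score support is built
#' by convolving the three-point per-locus distributions `(0, beta, 2 beta)`
#' with Hardy-Weinberg probabilities, giving `3^K` outcomes for `K` loci.
#' Beyond 16 loci exact enumeration is replaced by Monte-Carlo sampling.
#'
#' @param panel A [snp_panel()].
#' @param mc_draws Number of draws for the Monte-Carlo fallback.
#' @return List with `score` and `prob` (probabilities summing to 1),
#'   sorted by score.
#' @export
score_distribution <- function(panel, mc_draws = 1e6) {
  K <- nrow(panel)
  if (K <= 16) {
    score <- 0
    prob <- 1
    for (j in seq_len(K)) {
      hw <- genotype_prior(panel$maf[j])
      score <- as.vector(outer(score, panel$loghr[j] * (0:2), "+"))
      prob <- as.vector(outer(prob, hw))
    }
  } else {
    g <- vapply(seq_len(K),
                function(j) stats::rbinom(mc_draws, 2, panel$maf[j]),
                numeric(mc_draws))
    score <- as.vector(g %*% panel$loghr)
    prob <- rep(1 / mc_draws, mc_draws)
  }
  o <- order(score)
  list(score = score[o], prob = prob[o])
}

#' Score values at population percentiles
#'
#' Weighted inverse-CDF quantiles of a [score_distribution()]; ties are
#' broken toward the lower score (the smallest score whose cumulative
#' probability reaches the requested percentile).
#'
#' @param distribution List with sorted `score` and `prob`.
#' @param percentiles Percentiles in (0, 100); default the 5th, 50th and
#'   95th.
#' @return Named numeric vector of scores.
#' @export
percentile_scores <- function(distribution, percentiles = c(5, 50, 95)) {
  if (any(percentiles <= 0) || any(percentiles >= 100)) {
    stop("percentiles must lie strictly between 0 and 100")
  }
  cp <- cumsum(distribution$prob)
  idx <- vapply(percentiles / 100,
                function(p) which(cp >= p - 1e-12)[1], integer(1))
  stats::setNames(distribution$score[idx], paste0("p", percentiles))
}

#' Subtype-specific absolute-risk curves by score percentile
#'
#' Converts a subtype-specific external incidence curve into cumulative-risk
#' curves for carriers at chosen percentiles of the multilocus score
#' distribution. The baseline subtype hazard `m0(t)` is solved recursively so
#' that the score-distribution-weighted average incidence among survivors
#' equals the external subtype incidence at every age (the same calibration
#' used for the single-SNP baselines, applied to the score); the survivor
#' score distribution is updated for attrition age by age. A profile with
#' score `s` then has incidence `m0(t) exp(s)` and cumulative risk
#' `F(t) = 1 - exp(-sum_{u<=t} m0(u) exp(s))`.
#'
#' @param panel A [snp_panel()] for the subtype under consideration.
#' @param subtype_incidence An [incidence_curve()] for the subtype-specific
#'   incidence (e.g. the age-group split of the overall carrier incidence).
#' @param percentiles Percentiles of the score distribution.
#' @return `data.frame(age, percentile, score, risk)`, risks nondecreasing in
#'   age and ordered across percentiles at every age.
#' @export
absolute_risk_curves <- function(panel, subtype_incidence,
                                 percentiles = c(5, 50, 95)) {
  stopifnot(inherits(subtype_incidence, "incidence_curve"))
  dist <- score_distribution(panel)
  sc <- percentile_scores(dist, percentiles)
  ages <- subtype_incidence$age
  lam <- subtype_incidence$rate
  es <- exp(dist$score)
  w <- dist$prob
  m0 <- numeric(length(ages))
  for (i in seq_along(ages)) {
    if (lam[i] > 0) m0[i] <- lam[i] * sum(w) / sum(w * es)
    w <- w * exp(-m0[i] * es)
  }
  out <- do.call(rbind, lapply(seq_along(sc), function(k) {
    data.frame(age = ages, percentile = percentiles[k], score = sc[[k]],
               risk = 1 - exp(-cumsum(m0 * exp(sc[[k]]))))
  }))
  rownames(out) <- NULL
  attr(out, "m0") <- m0
  out
}

#' Expected-dosage score for individual genotype profiles
#'
#' Convenience scoring of observed profiles: loci with missing genotype are
#' imputed at their Hardy-Weinberg expected dosage `2 * maf`. The population
#' score distribution itself ([score_distribution()]) always uses exact
#' enumeration; imputation affects only this per-individual helper.
#'
#' @param panel A [snp_panel()].
#' @param genotypes Matrix (individuals x loci) of 0/1/2 dosages, NA allowed.
#' @return Numeric vector of scores.
#' @export
profile_scores <- function(panel, genotypes) {
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) != nrow(panel)) stop("genotype columns must match panel loci")
  for (j in seq_len(ncol(genotypes))) {
    genotypes[is.na(genotypes[, j]), j] <- 2 * panel$maf[j]
  }
  as.vector(genotypes %*% panel$loghr)
}

#' Split an overall incidence curve by subtype fractions
#'
#' Returns the subtype-specific incidence `pi(t) * lambda(t)` used as the
#' calibration target of [absolute_risk_curves()].
#'
#' @param incidence An [incidence_curve()] of total incidence.
#' @param pi A [subtype_pi()].
#' @param subtype `"pos"` or `"neg"`.
#' @return An [incidence_curve()].
#' @export
split_incidence <- function(incidence, pi, subtype = c("pos", "neg")) {
  subtype <- match.arg(subtype)
  p <- pi_at_ages(pi, incidence$age)
  if (subtype == "neg") p <- 1 - p
  incidence_curve(incidence$age, incidence$rate * p)
}
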