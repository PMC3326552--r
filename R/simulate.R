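#' Configuration for the synthetic-cohort generator
#'
#' Describes the generating model and the sampling design of a simulated
#' carrier cohort: competing subtype hazards under per-allele (or 2-df)
#' genotype effects calibrated to an external incidence curve, sibship
#' families with Mendelian genotype transmission from two founders,
#' clinic-style ascertainment that retains families containing an affected
#' member with higher probability than unaffected families, interview-age
#' censoring with a competing censoring hazard (the prophylactic-surgery /
#' ovarian-cancer analogue), and missing-at-random masking of subtype labels
#' and genotypes.
#'
#' @param n_families Number of families drawn before ascertainment.
#' @param family_size Sibship size; 1 gives the fast singleton mode.
#' @param q Minor-allele frequency of the simulated variant.
#' @param beta,gamma Generating log-HRs (subtype-negative, subtype-positive).
#' @param incidence [incidence_curve()] (or named list by stratum) to which
#'   the generating hazards are calibrated.
#' @param pi [subtype_pi()] of the generating subtype split.
#' @param model `"per_allele"` or `"genotype"`.
#' @param p_aff,p_unaff Retention probabilities for families with/without an
#'   affected member at interview (`p_aff >> p_unaff` emulates clinic-based
#'   ascertainment; `p_aff = p_unaff = 1` gives population sampling).
#' @param subtype_missing Probability that an affected carrier's subtype
#'   label is masked (missing at random).
#' @param genotype_missing Probability that a carrier's genotype is masked.
#' @param censor_window Interview/last-follow-up ages, drawn uniformly on
#'   this integer window.
#' @param competing_censor_rate Per-year rate of the competing censoring
#'   event from age 18.
#' @param strata Named probability vector of stratum labels (or one label).
#' @param gene Gene label written to the table.
#' @param seed Mandatory integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_families = 1000, family_size = 1, q = 0.3,
                       beta = 0, gamma = 0,
                       incidence = synthetic_incidence("BRCA1"),
                       pi = subtype_pi(c(0.22, 0.24, 0.26, 0.28)),
                       model = c("per_allele", "genotype"),
                       p_aff = 1, p_unaff = 0.4,
                       subtype_missing = 0.56, genotype_missing = 0,
                       censor_window = c(25, 79),
                       competing_censor_rate = 0.005,
                       strata = c(S1 = 1), gene = "BRCA1", seed) {
  model <- match.arg(model)
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  probs <- c(p_aff, p_unaff, subtype_missing, genotype_missing)
  if (any(probs < 0) || any(probs > 1)) stop("probabilities must lie in [0, 1]")
  if (is.null(names(strata))) names(strata) <- paste0("S", seq_along(strata))
  structure(list(n_families = n_families, family_size = family_size, q = q,
                 beta = beta, gamma = gamma, incidence = incidence, pi = pi,
                 model = model, p_aff = p_aff, p_unaff = p_unaff,
                 subtype_missing = subtype_missing,
                 genotype_missing = genotype_missing,
                 censor_window = censor_window,
                 competing_censor_rate = competing_censor_rate,
                 strata = strata / sum(strata), gene = gene,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an ascertained carrier cohort
#'
#' Draws genotypes (Hardy-Weinberg founders, Mendelian transmission within
#' sibships), latent subtype-specific event ages from the genotype-specific
#' discrete hazards implied by the generating parameters (first event wins),
#' applies interview and competing censoring, retains families under the
#' ascertainment rule, and masks subtype labels and genotypes at the
#' configured rates. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return Carrier table (`data.frame`) with columns `carrier_id`,
#'   `family_id`, `stratum`, `gene`, `censor_age`, `affected`, `subtype`,
#'   `genotype`, with the generating truths in `attr(, "truth")`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nf <- config$n_families
  fs <- config$family_size
  sizes <- if (length(fs) == 1L) rep(as.integer(fs), nf)
           else sample(as.integer(fs), nf, replace = TRUE)
  n <- sum(sizes)
  fam <- rep(seq_len(nf), sizes)

  # stratum per family
  labs <- names(config$strata)
  fam_str <- if (length(labs) == 1L) rep(labs, nf)
             else sample(labs, nf, replace = TRUE, prob = config$strata)
  stratum <- fam_str[fam]

  # founder alleles, Mendelian transmission to sibs
  mom <- matrix(stats::rbinom(2 * nf, 1, config$q), nf, 2)
  dad <- matrix(stats::rbinom(2 * nf, 1, config$q), nf, 2)
  pickm <- stats::rbinom(n, 1, 0.5) + 1L
  pickd <- stats::rbinom(n, 1, 0.5) + 1L
  g <- mom[cbind(fam, pickm)] + dad[cbind(fam, pickd)]

  # generating hazards calibrated to the external curve
  params <- model_params(config$beta, config$gamma, config$q, config$pi,
                         config$model)
  inc <- config$incidence
  if (inherits(inc, "incidence_curve")) {
    inc <- stats::setNames(rep(list(inc), length(labs)), labs)
  }
  ages <- inc[[1]]$age
  na <- length(ages)

  ev_age <- rep(NA_integer_, n)
  ev_pos <- rep(NA, n)
  u <- stats::runif(n)
  upos <- stats::runif(n)
  for (s in labs) {
    bl <- solve_baselines(params, inc[[s]])
    H <- hazard_matrices(params, bl)
    Sx <- rbind(H$S, H$S[na, ] * exp(-H$htot[na, ]))  # survival incl. end
    for (gg in 0:2) {
      sel <- which(stratum == s & g == gg)
      if (!length(sel)) next
      Fc <- 1 - Sx[, gg + 1L]                         # P(event before age k)
      idx <- findInterval(u[sel], Fc)
      has <- u[sel] < Fc[na + 1L]
      idx[!has] <- NA_integer_
      ev_age[sel] <- ages[idx]
      pr <- H$hpos[idx, gg + 1L] / H$htot[idx, gg + 1L]
      ev_pos[sel] <- upos[sel] < pr
    }
  }

  # censoring: interview age, competing censoring event, grid end
  interview <- sample(seq(config$censor_window[1], config$censor_window[2]),
                      n, replace = TRUE)
  comp <- if (config$competing_censor_rate > 0) {
    18L + floor(stats::rexp(n, config$competing_censor_rate))
  } else rep(Inf, n)
  cand <- pmin(interview, comp, max(ages))
  affected <- !is.na(ev_age) & ev_age <= cand
  censor_age <- as.integer(ifelse(affected, ev_age, cand))
  subtype <- ifelse(affected, ifelse(ev_pos, "pos", "neg"), "unknown")

  # clinic-style ascertainment on family affection status
  fam_aff <- as.logical(rowsum(as.integer(affected), fam)[, 1] > 0)
  keep_fam <- stats::runif(nf) < ifelse(fam_aff, config$p_aff, config$p_unaff)
  keep <- keep_fam[fam]
  if (!any(keep)) stop("no families retained under the ascertainment rule")

  genotype <- g
  if (config$genotype_missing > 0) {
    genotype[stats::runif(n) < config$genotype_missing] <- NA_integer_
  }

  out <- data.frame(
    carrier_id = sprintf("C%06d", seq_len(n)),
    family_id = sprintf("F%05d", fam),
    stratum = stratum, gene = config$gene,
    censor_age = censor_age,
    affected = as.integer(affected),
    subtype = subtype, genotype = as.integer(genotype),
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out <- mask_subtype(out, config$subtype_missing)
  attr(out, "truth") <- list(beta = config$beta, gamma = config$gamma,
                             q = config$q, model = config$model)
  out
}

#' Mask subtype labels at random
#'
#' Sets each affected carrier's subtype label to `"unknown"` independently
#' with the given probability, independent of genotype (missing at random).
#'
#' @param table Carrier table.
#' @param rate Masking probability in \[0, 1\].
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @return The masked table.
#' @export
mask_subtype <- function(table, rate, seed = NULL) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (rate > 0) {
    aff <- which(table$affected == 1)
    hit <- aff[stats::runif(length(aff)) < rate]
    table$subtype[hit] <- "unknown"
  }
  table
}
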