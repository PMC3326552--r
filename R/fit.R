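# Parameter packing ---------------------------------------------------------
# Internal parameterization: log-HRs free, allele frequency and age-group
# subtype fractions on the logit scale so the optimizer is unconstrained.

logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

# mode: "per_allele", "genotype", "het" (b1, b2 with beta = b1,
# gamma = b1 + b2), "common" (beta = gamma, for the heterogeneity LRT)
n_effect_par <- function(mode) {
  switch(mode, per_allele = 2L, genotype = 4L, het = 2L, common = 1L)
}

decode_theta <- function(theta, mode, pi_edges) {
  ne <- n_effect_par(mode)
  K <- length(pi_edges) + 1L
  eff <- theta[seq_len(ne)]
  q <- expit(theta[ne + 1L])
  pp <- expit(theta[ne + 1L + seq_len(K)])
  pi <- subtype_pi(pp, pi_edges)
  switch(mode,
    per_allele = model_params(eff[1], eff[2], q, pi, "per_allele"),
    genotype   = model_params(eff[1:2], eff[3:4], q, pi, "genotype"),
    het        = model_params(eff[1], eff[1] + eff[2], q, pi, "per_allele"),
    common     = model_params(eff[1], eff[1], q, pi, "per_allele"))
}

theta_names <- function(mode, pi_edges) {
  K <- length(pi_edges) + 1L
  eff <- switch(mode,
    per_allele = c("beta", "gamma"),
    genotype   = c("beta_het", "beta_hom", "gamma_het", "gamma_hom"),
    het        = c("b1", "b2"),
    common     = "b")
  c(eff, "logit_q", paste0("logit_pi", seq_len(K)))
}

# Shared fitting state: aggregated cells, per-stratum baselines closure,
# record-to-cell map and family ids for the cluster sandwich.
build_fit_env <- function(records, incidence, mode, pi_edges) {
  records <- validate_carrier_table(records)$records
  strata <- unique(records$stratum)
  if (inherits(incidence, "incidence_curve")) {
    incidence <- stats::setNames(rep(list(incidence), length(strata)), strata)
  }
  if (!all(strata %in% names(incidence))) {
    stop("incidence must be a curve or a named list covering every stratum")
  }
  cells <- aggregate_cells(records)
  obj <- list(records = records, cells = cells,
              row_cell = attr(cells, "row_cell"),
              family = records$family_id,
              incidence = incidence[strata], strata = strata,
              mode = mode, pi_edges = pi_edges)
  obj$cell_ll <- function(theta, per_cell = FALSE) {
    params <- decode_theta(theta, mode, pi_edges)
    bl <- lapply(obj$incidence, function(inc) solve_baselines(params, inc))
    cell_loglik(cells, params, bl, per_cell = per_cell)
  }
  obj$nll <- function(theta) {
    v <- tryCatch(-obj$cell_ll(theta), error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else v
  }
  obj
}

start_values <- function(env) {
  r <- env$records
  g <- r$genotype[!is.na(r$genotype)]
  if (!length(g)) stop("no observed genotypes")
  qhat <- min(max(mean(g) / 2, 0.01), 0.99)
  K <- length(env$pi_edges) + 1L
  lab <- r$affected == 1 & r$subtype %in% c("neg", "pos")
  overall <- if (any(lab)) mean(r$subtype[lab] == "pos") else 0.5
  grp <- findInterval(r$censor_age, env$pi_edges) + 1L
  pstart <- vapply(seq_len(K), function(k) {
    sel <- lab & grp == k
    if (sum(sel) >= 5) mean(r$subtype[sel] == "pos") else overall
  }, numeric(1))
  pstart <- pmin(pmax(pstart, 0.02), 0.98)
  stats::setNames(c(numeric(n_effect_par(env$mode)), logit(qhat), logit(pstart)),
                  theta_names(env$mode, env$pi_edges))
}

# Maximize the retrospective likelihood for one internal parameter mode.
fit_mode <- function(records, incidence, mode, pi_edges, compute_se,
                     control = list()) {
  env <- build_fit_env(records, incidence, mode, pi_edges)
  start <- start_values(env)
  ctrl <- utils::modifyList(list(maxit = 500L, reltol = 1e-12), control)
  opt <- stats::optim(start, env$nll, method = "BFGS", control = ctrl)
  # restart until no further improvement: a fresh Hessian approximation lets
  # quasi-Newton escape premature stops on nearly flat likelihoods
  for (k in 1:5) {
    opt2 <- stats::optim(opt$par, env$nll, method = "BFGS", control = ctrl)
    improved <- opt$value - opt2$value
    if (opt2$value <= opt$value) opt <- opt2
    if (improved < 1e-10) break
  }
  grad <- num_gradient(env$nll, opt$par)
  fit <- structure(list(
    mode = mode, coef = opt$par, loglik = -opt$value,
    params = decode_theta(opt$par, mode, pi_edges),
    convergence = opt$convergence, iterations = opt$counts,
    gradient_norm = sqrt(sum(grad^2)),
    pi_edges = pi_edges, env = env), class = "carrier_fit_core")
  if (fit$convergence != 0) {
    warning("optimizer did not report convergence (code ", fit$convergence,
            "); gradient norm ", format(fit$gradient_norm))
  }
  if (compute_se) fit$vcov <- robust_variance(fit)
  fit
}

num_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h * (1 + abs(x[j]))
    (f(x + e) - f(x - e)) / (2 * e[j])
  }, numeric(1))
}

#' Cluster-robust (sandwich) variance of a retrospective-likelihood fit
#'
#' Huber-White sandwich `A^-1 B A^-1`, where `A` is the observed information
#' (numerical Hessian of the negative log-likelihood at the maximum) and `B`
#' sums outer products of score contributions aggregated within family
#' clusters, allowing for the non-independence of related carriers. With
#' singleton families and a well-specified model it is consistent for the
#' usual inverse information.
#'
#' @param fit A fit object from [fit_single_snp()] (or an internal fit core).
#' @return Symmetric positive semi-definite covariance matrix of the internal
#'   parameter vector.
#' @export
robust_variance <- function(fit) {
  if (inherits(fit, "carrier_fit")) fit <- fit$core
  env <- fit$env
  theta <- fit$coef
  A <- stats::optimHess(theta, env$nll)
  # per-cell score vectors by central differences
  G <- vapply(seq_along(theta), function(j) {
    e <- numeric(length(theta)); e[j] <- 1e-5 * (1 + abs(theta[j]))
    (env$cell_ll(theta + e, per_cell = TRUE) -
     env$cell_ll(theta - e, per_cell = TRUE)) / (2 * e[j])
  }, numeric(nrow(env$cells)))
  scores <- G[env$row_cell, , drop = FALSE]
  fam <- rowsum(scores, env$family)
  B <- crossprod(fam)
  Ai <- solve(A)
  V <- Ai %*% B %*% Ai
  V <- (V + t(V)) / 2
  dimnames(V) <- list(names(theta), names(theta))
  V
}

#' Fit the retrospective likelihood for a single variant
#'
#' Maximizes the stratified retrospective likelihood jointly over the
#' subtype-specific genotype log-HRs, the minor-allele frequency and the
#' age-group subtype fractions, re-solving the constrained baselines at every
#' parameter evaluation (quasi-Newton with numerically differenced
#' gradients). Per-subtype hazard ratios with cluster-robust 95% confidence
#' intervals and trend-test p-values are derived from the internal estimates.
#'
#' @param records Carrier table; see [validate_carrier_table()].
#' @param incidence An [incidence_curve()] (applied to all strata) or a named
#'   list of curves by stratum.
#' @param model `"per_allele"` (multiplicative, 1 log-HR per subtype) or
#'   `"genotype"` (2-df: heterozygote and homozygote log-HRs per subtype).
#' @param pi_edges Interior age-group boundaries for the subtype fractions.
#' @param compute_se Compute the cluster-robust covariance (default TRUE;
#'   skipping it speeds up large simulation studies where only point
#'   estimates are needed).
#' @param control Passed to [stats::optim()] control.
#' @return Object of class `carrier_fit` with elements `hr` (per-subtype HR
#'   table with CIs and trend p-values), `coef`, `vcov` (robust, internal
#'   scale), `loglik`, `params`, `counts`, and convergence diagnostics.
#' @export
fit_single_snp <- function(records, incidence,
                           model = c("per_allele", "genotype"),
                           pi_edges = c(40, 50, 60),
                           compute_se = TRUE, control = list()) {
  model <- match.arg(model)
  core <- fit_mode(records, incidence, model, pi_edges, compute_se, control)
  th <- core$coef
  V <- core$vcov
  se <- if (!is.null(V)) sqrt(diag(V)) else
    stats::setNames(rep(NA_real_, length(th)), names(th))
  mk_row <- function(subtype, term, est, s) {
    data.frame(subtype = subtype, term = term, hr = exp(est),
               lo = exp(est - 1.96 * s), hi = exp(est + 1.96 * s),
               p = 2 * stats::pnorm(-abs(est / s)))
  }
  hr <- if (model == "per_allele") {
    rbind(mk_row("neg", "per_allele", th[["beta"]], se[["beta"]]),
          mk_row("pos", "per_allele", th[["gamma"]], se[["gamma"]]))
  } else {
    rbind(mk_row("neg", "het", th[["beta_het"]], se[["beta_het"]]),
          mk_row("neg", "hom", th[["beta_hom"]], se[["beta_hom"]]),
          mk_row("pos", "het", th[["gamma_het"]], se[["gamma_het"]]),
          mk_row("pos", "hom", th[["gamma_hom"]], se[["gamma_hom"]]))
  }
  rec <- core$env$records
  counts <- table(affected = rec$affected, subtype = rec$subtype)
  structure(list(model = model, coef = th, vcov = V, hr = hr,
                 loglik = core$loglik, params = core$params,
                 q = core$params$q, pi = core$params$pi,
                 counts = counts, convergence = core$convergence,
                 iterations = core$iterations,
                 gradient_norm = core$gradient_norm,
                 core = core), class = "carrier_fit")
}

#' @export
print.carrier_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Retrospective-likelihood fit (%s model), logLik = %.3f\n",
              x$model, x$loglik))
  cat(sprintf("q-hat = %.4f; n = %d carriers\n", x$q, sum(x$counts)))
  hr <- x$hr
  hr[c("hr", "lo", "hi")] <- lapply(hr[c("hr", "lo", "hi")], round, digits)
  hr$p <- signif(hr$p, 2)
  print(hr, row.names = FALSE)
  invisible(x)
}

#' Test for heterogeneity of a variant's effect between tumour subtypes
#'
#' Refits the model in the parameterization where the subtype-negative
#' log-HR is `b1` and the subtype-positive log-HR is `b1 + b2`, and performs
#' a Wald test of `b2 = 0` against the normal reference using the
#' cluster-robust variance. A likelihood-ratio test (refitting with the
#' common-effect constraint `b2 = 0`, no robust correction) is reported as a
#' secondary diagnostic.
#'
#' @inheritParams fit_single_snp
#' @return Object of class `het_test`: `b2` (log-HR difference), `se`, `z`,
#'   `p` (robust Wald, two-sided), `lrt_stat`, `p_lrt`, and the two fits.
#' @export
heterogeneity_test <- function(records, incidence, pi_edges = c(40, 50, 60),
                               control = list()) {
  fit_het <- fit_mode(records, incidence, "het", pi_edges,
                      compute_se = TRUE, control = control)
  fit_com <- fit_mode(records, incidence, "common", pi_edges,
                      compute_se = FALSE, control = control)
  b2 <- fit_het$coef[["b2"]]
  se <- sqrt(fit_het$vcov["b2", "b2"])
  z <- b2 / se
  lrt <- 2 * (fit_het$loglik - fit_com$loglik)
  structure(list(b2 = b2, se = se, z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 lrt_stat = lrt,
                 p_lrt = stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE),
                 fit_het = fit_het, fit_common = fit_com),
            class = "het_test")
}

#' @export
print.het_test <- function(x, ...) {
  cat(sprintf("Subtype heterogeneity: b2 = %.4f (SE %.4f), Wald p = %.3g (LRT p = %.3g)\n",
              x$b2, x$se, x$p, x$p_lrt))
  invisible(x)
}

#' Case-only logistic sensitivity analysis
#'
#' Logistic regression of tumour subtype (positive vs negative) on minor
#' allele count among affected carriers with observed subtype and genotype,
#' adjusted for country stratum. The genotype log-odds-ratio is an
#' asymptotic cross-check of the heterogeneity parameter `b2` of
#' [heterogeneity_test()].
#'
#' @param records Carrier table.
#' @return List with `log_or`, `se`, `p`, and the underlying `glm` fit.
#' @export
case_only_logistic <- function(records) {
  d <- records[records$affected == 1 &
               records$subtype %in% c("neg", "pos") &
               !is.na(records$genotype), , drop = FALSE]
  if (!nrow(d) || length(unique(d$subtype)) < 2) {
    stop("case-only analysis needs affected carriers of both subtypes")
  }
  d$y <- as.integer(d$subtype == "pos")
  form <- if (length(unique(d$stratum)) > 1) y ~ genotype + factor(stratum)
          else y ~ genotype
  fit <- stats::glm(form, family = stats::binomial(), data = d)
  co <- summary(fit)$coefficients
  if (abs(co["genotype", "Estimate"]) > 10) {
    warning("possible separation: genotype log-OR is extreme")
  }
  list(log_or = co["genotype", "Estimate"], se = co["genotype", "Std. Error"],
       p = co["genotype", "Pr(>|z|)"], fit = fit)
}

#' Naive Cox comparator
#'
#' Standard Cox partial-likelihood estimate of the per-allele log-HR,
#' ignoring the ascertainment scheme. On cohorts in which affected carriers
#' are over-sampled this estimate is attenuated toward zero, because carriers
#' selected for their future disease status (enriched for risk alleles)
#' enter the comparison risk sets; it is provided as the internal comparator
#' demonstrating why the retrospective likelihood is needed.
#'
#' @param records Carrier table.
#' @param outcome `"any"` (any breast cancer), `"neg"` or `"pos"` (events of
#'   one subtype only; affected carriers of the other or unknown subtype are
#'   censored at diagnosis).
#' @return List with `log_hr`, `se` and the `coxph` fit.
#' @export
naive_cox <- function(records, outcome = c("any", "neg", "pos")) {
  outcome <- match.arg(outcome)
  d <- records[!is.na(records$genotype), , drop = FALSE]
  event <- if (outcome == "any") d$affected == 1
           else d$affected == 1 & d$subtype == outcome
  fit <- survival::coxph(survival::Surv(d$censor_age, event) ~ d$genotype)
  list(log_hr = unname(stats::coef(fit)),
       se = sqrt(unname(stats::vcov(fit)[1, 1])), fit = fit)
}
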