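#' Phenotype probability given genotype
#'
#' Probability of a carrier's observed phenotype (affected/unaffected at the
#' censoring age, with known or unknown tumour subtype) conditional on
#' genotype. An unaffected carrier contributes the survival through all ages
#' before the censoring age; an affected carrier contributes the relevant
#' subtype hazard at the censoring age times that survival; an affected
#' carrier with unknown subtype contributes the total hazard times the
#' survival (missing-at-random marginalization over the subtype label).
#'
#' @param record One-row data.frame (or list) with fields `censor_age`,
#'   `affected` (0/1), `subtype` (`"neg"`, `"pos"`, `"unknown"`) and
#'   `genotype` (0, 1, 2).
#' @param params A [model_params()].
#' @param baselines Matching [solve_baselines()] output.
#' @return A probability.
#' @export
phenotype_given_genotype <- function(record, params, baselines) {
  g <- record$genotype
  if (is.na(g) || !g %in% 0:2) stop("genotype must be observed (0, 1 or 2) here")
  H <- hazard_matrices(params, baselines)
  i <- match(record$censor_age, H$age)
  if (is.na(i)) stop("censor_age outside the baseline age grid")
  j <- g + 1L
  if (record$affected == 0) return(H$S[i, j])
  haz <- switch(as.character(record$subtype),
                neg = H$hneg[i, j],
                pos = H$hpos[i, j],
                unknown = H$htot[i, j],
                stop("subtype must be 'neg', 'pos' or 'unknown'"))
  haz * H$S[i, j]
}

#' Per-carrier retrospective log-likelihood
#'
#' Log of `P(g, d | y(t))`: the probability of the observed genotype and
#' tumour subtype conditional on the overall disease phenotype. The
#' denominator marginalizes both genotype (over the Hardy-Weinberg prior) and
#' subtype, implementing the assumption that ascertainment depends on the
#' overall breast-cancer phenotype but not on the tumour subtype. A record
#' with missing genotype additionally marginalizes the genotype in the
#' numerator and contributes only through the subtype label.
#'
#' @inheritParams phenotype_given_genotype
#' @return Log-probability (a single number).
#' @export
retro_loglik_one <- function(record, params, baselines) {
  cells <- data.frame(stratum = "s", censor_age = record$censor_age,
                      affected = record$affected,
                      subtype = as.character(record$subtype),
                      genotype = record$genotype, n = 1)
  cell_loglik(cells, params, list(s = baselines))
}

# Aggregate a carrier table into unique likelihood cells.
# Returns data.frame(stratum, censor_age, affected, subtype, genotype, n)
# plus a `cell` index per input row (attribute "row_cell").
aggregate_cells <- function(records) {
  key <- paste(records$stratum, records$censor_age, records$affected,
               records$subtype, ifelse(is.na(records$genotype), "NA",
                                       records$genotype),
               sep = "\r")
  u <- !duplicated(key)
  cells <- records[u, c("stratum", "censor_age", "affected", "subtype",
                        "genotype")]
  cells$n <- as.vector(table(key)[key[u]])
  rownames(cells) <- NULL
  attr(cells, "row_cell") <- match(key, key[u])
  cells
}

# Vectorized per-cell retrospective log-likelihood. `baselines` is a named
# list of subtype_baselines keyed by stratum. Returns total over cells
# (weighted by n) unless per_cell = TRUE.
cell_loglik <- function(cells, params, baselines, per_cell = FALSE) {
  prior <- genotype_prior(params$q)
  ll <- numeric(nrow(cells))
  for (s in unique(cells$stratum)) {
    bl <- baselines[[s]]
    if (is.null(bl)) stop("no baselines for stratum '", s, "'")
    H <- hazard_matrices(params, bl)
    # phenotype-only denominators by age
    D0 <- as.vector(H$S %*% prior)                 # unaffected at t
    D1 <- as.vector((H$htot * H$S) %*% prior)      # affected at t, any subtype
    idx <- which(cells$stratum == s)
    i <- match(cells$censor_age[idx], H$age)
    if (anyNA(i)) stop("censor_age outside the incidence age grid")
    g <- cells$genotype[idx]
    aff <- cells$affected[idx] == 1
    sub <- cells$subtype[idx]
    obs <- !is.na(g)
    v <- numeric(length(idx))

    # observed genotype
    if (any(obs)) {
      jj <- g[obs] + 1L
      ii <- i[obs]
      lin <- cbind(ii, jj)
      num <- log(prior[jj]) + log(H$S[lin])
      a <- aff[obs]
      if (any(a)) {
        haz <- numeric(sum(obs))
        sb <- sub[obs]
        haz[a & sb == "neg"] <- H$hneg[lin[a & sb == "neg", , drop = FALSE]]
        haz[a & sb == "pos"] <- H$hpos[lin[a & sb == "pos", , drop = FALSE]]
        haz[a & sb == "unknown"] <- H$htot[lin[a & sb == "unknown", , drop = FALSE]]
        num[a] <- num[a] + log(haz[a])
      }
      den <- ifelse(a, log(D1[ii]), log(D0[ii]))
      v[obs] <- num - den
    }

    # missing genotype: marginalize g in the numerator; only affected records
    # with a known subtype carry information (others contribute log 1 = 0)
    mk <- !obs & aff & sub %in% c("neg", "pos")
    if (any(mk)) {
      ii <- i[mk]
      numm <- numeric(sum(mk))
      isneg <- sub[mk] == "neg"
      if (any(isneg)) {
        numm[isneg] <- log((H$hneg[ii[isneg], , drop = FALSE] *
                            H$S[ii[isneg], , drop = FALSE]) %*% prior)
      }
      if (any(!isneg)) {
        numm[!isneg] <- log((H$hpos[ii[!isneg], , drop = FALSE] *
                             H$S[ii[!isneg], , drop = FALSE]) %*% prior)
      }
      v[mk] <- numm - log(D1[ii])
    }
    ll[idx] <- v
  }
  if (any(!is.finite(ll))) {
    stop("non-finite log-likelihood: an observed event has zero hazard ",
         "(or zero phenotype probability) under the model")
  }
  if (per_cell) ll else sum(cells$n * ll)
}

#' Cohort retrospective log-likelihood
#'
#' Sum of per-carrier retrospective log-likelihoods, each record evaluated
#' against its own stratum's incidence-constrained baselines. The log-HRs,
#' allele frequency and subtype fractions are shared across strata.
#'
#' @param records Carrier table (see [validate_carrier_table()]), with
#'   columns `stratum`, `censor_age`, `affected`, `subtype`, `genotype`.
#' @param params A [model_params()].
#' @param baselines A single [solve_baselines()] result (applied to every
#'   stratum) or a named list keyed by stratum label.
#' @return The cohort log-likelihood (a single number).
#' @export
cohort_loglik <- function(records, params, baselines) {
  if (inherits(baselines, "subtype_baselines")) {
    baselines <- stats::setNames(
      rep(list(baselines), length(unique(records$stratum))),
      unique(records$stratum))
  }
  missing_strata <- setdiff(unique(records$stratum), names(baselines))
  if (length(missing_strata)) {
    stop("no baselines for strata: ", paste(missing_strata, collapse = ", "))
  }
  cells <- aggregate_cells(records)
  cell_loglik(cells, params, baselines)
}
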