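#' External carrier incidence curve
#'
#' An `incidence_curve` holds the age-specific per-year hazard of a first
#' breast cancer (of any subtype) for mutation carriers, on a contiguous
#' annual age grid. It is the external constraint to which the subtype
#' baseline solver calibrates the genotype-averaged total incidence.
#'
#' @param ages Integer vector of ages, a contiguous annual grid.
#' @param rate Non-negative per person-year hazard at each age.
#' @return An object of class `incidence_curve` with fields `age` and `rate`.
#' @seealso [synthetic_incidence()], [read_incidence_tsv()], [solve_baselines()]
#' @export
incidence_curve <- function(ages, rate) {
  ages <- as.integer(ages)
  rate <- as.numeric(rate)
  if (length(ages) != length(rate)) stop("ages and rate must have equal length")
  if (length(ages) < 1L) stop("empty incidence curve")
  if (any(diff(ages) != 1L)) stop("age grid must be contiguous annual integers")
  if (any(!is.finite(rate)) || any(rate < 0)) stop("rates must be finite and >= 0")
  structure(list(age = ages, rate = rate), class = "incidence_curve")
}

#' @export
print.incidence_curve <- function(x, ...) {
  cat(sprintf("<incidence_curve> ages %d-%d, cumulative hazard %.3f\n",
              min(x$age), max(x$age), sum(x$rate)))
  invisible(x)
}

#' Smooth synthetic carrier incidence curves
#'
#' Packaged default incidence curves for testing and simulation, shaped like
#' carrier breast-cancer incidence: zero before age 20, then a smooth logistic
#' ramp in age. The BRCA1-like curve reaches a cumulative risk of roughly 70%
#' by age 80 and the BRCA2-like curve roughly 50%. Real analyses should supply
#' cohort-specific external estimates via [read_incidence_tsv()].
#'
#' @param gene `"BRCA1"` or `"BRCA2"` (selects the plateau height).
#' @param ages Age grid (annual integers), default 0 to 80.
#' @return An [incidence_curve()].
#' @export
synthetic_incidence <- function(gene = c("BRCA1", "BRCA2"), ages = 0:80) {
  gene <- match.arg(gene)
  peak <- if (gene == "BRCA1") 0.035 else 0.020
  rate <- peak * stats::plogis((ages - 45) / 6) * (ages >= 20)
  incidence_curve(ages, rate)
}

#' Read an incidence table from TSV
#'
#' Strictly parses a tab-delimited table with columns `age`, `rate` and an
#' optional `stratum` column. With a `stratum` column a named list of curves
#' (one per stratum) is returned; otherwise a single [incidence_curve()].
#'
#' @param path Path to the TSV file.
#' @return An `incidence_curve` or a named list of them.
#' @export
read_incidence_tsv <- function(path) {
  if (!file.exists(path)) stop("incidence file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("age", "rate")
  if (!all(need %in% names(tab))) {
    stop("incidence table must have columns 'age' and 'rate'")
  }
  if ("stratum" %in% names(tab)) {
    out <- lapply(split(tab, tab$stratum),
                  function(d) incidence_curve(d$age[order(d$age)],
                                              d$rate[order(d$age)]))
    return(out)
  }
  incidence_curve(tab$age[order(tab$age)], tab$rate[order(tab$age)])
}
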