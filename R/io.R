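#' Validate a carrier table
#'
#' Enforces the carrier-record invariants: required columns present;
#' `censor_age` a non-negative integer; `affected` 0/1; `subtype` one of
#' `"neg"`, `"pos"`, `"unknown"` with `"unknown"` forced for unaffected
#' carriers (a subtype label on an unaffected row is an error); `genotype`
#' 0, 1, 2 or NA; `carrier_id` unique. Errors cite row numbers.
#'
#' @param records Data.frame of carrier records.
#' @return List with `records` (validated, subtype as character) and
#'   `report`: counts of carriers by affection/subtype/genotype cell.
#' @export
validate_carrier_table <- function(records) {
  need <- c("carrier_id", "family_id", "stratum", "gene", "censor_age",
            "affected", "subtype", "genotype")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records$subtype <- as.character(records$subtype)

  bad <- function(rows, what) {
    if (length(rows)) {
      stop(what, " at row(s): ",
           paste(utils::head(rows, 10), collapse = ", "),
           if (length(rows) > 10) " ..." else "")
    }
  }
  dup <- which(duplicated(records$carrier_id))
  bad(dup, "duplicate carrier_id")
  bad(which(is.na(records$censor_age) | records$censor_age < 0 |
            records$censor_age != round(records$censor_age)),
      "censor_age must be a non-negative integer")
  bad(which(!records$affected %in% c(0L, 1L)), "affected must be 0 or 1")
  bad(which(!records$subtype %in% c("neg", "pos", "unknown")),
      "subtype must be 'neg', 'pos' or 'unknown'")
  bad(which(records$affected == 0 & records$subtype != "unknown"),
      "unaffected carriers cannot carry a subtype label")
  gok <- is.na(records$genotype) | records$genotype %in% c(0L, 1L, 2L)
  bad(which(!gok), "genotype must be 0, 1, 2 or NA")
  records$genotype <- as.integer(records$genotype)
  records$censor_age <- as.integer(records$censor_age)

  report <- table(affected = records$affected, subtype = records$subtype,
                  genotype = ifelse(is.na(records$genotype), "NA",
                                    records$genotype))
  list(records = records, report = report)
}

#' Read a carrier table from TSV
#'
#' Tab-delimited, one row per carrier, columns `carrier_id`, `family_id`,
#' `stratum`, `gene`, `censor_age`, `affected`, `subtype`, `genotype`;
#' missing values encoded as `NA`. The table is validated strictly (see
#' [validate_carrier_table()]).
#'
#' @param path Path to the TSV file.
#' @return Validated carrier `data.frame`.
#' @export
read_carrier_tsv <- function(path) {
  if (!file.exists(path)) stop("carrier file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", na.strings = "NA",
                           stringsAsFactors = FALSE)
  validate_carrier_table(tab)$records
}

#' Write a carrier table to TSV
#'
#' @param records Carrier table.
#' @param path Output path.
#' @export
write_carrier_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

#' Write fit results to TSV and JSON
#'
#' Serializes one or more [fit_single_snp()] results as a per-SNP,
#' per-subtype table of hazard ratios with 95% CIs and trend p-values
#' (hazard ratios formatted to 2 decimals in a display column alongside the
#' full-precision values), plus a machine-readable JSON that round-trips the
#' numeric content.
#'
#' @param fits Named list of `carrier_fit` objects (names are SNP labels);
#'   may be empty (header-only TSV).
#' @param path Output path stem; writes `<path>.tsv` and `<path>.json`.
#' @return Invisibly, the table written.
#' @export
write_fit_results <- function(fits, path) {
  rows <- lapply(names(fits), function(nm) {
    hr <- fits[[nm]]$hr
    hr$snp <- nm
    hr$display <- sprintf("%.2f (%.2f to %.2f)", hr$hr, hr$lo, hr$hi)
    hr[, c("snp", "subtype", "term", "hr", "lo", "hi", "p", "display")]
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp = character(), subtype = character(), term = character(),
               hr = numeric(), lo = numeric(), hi = numeric(), p = numeric(),
               display = character())
  utils::write.table(tab, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  js <- lapply(fits, function(f) {
    list(model = f$model, loglik = f$loglik, q = f$q,
         coef = as.list(f$coef),
         hr = f$hr[, c("subtype", "term", "hr", "lo", "hi", "p")],
         convergence = f$convergence)
  })
  jsonlite::write_json(js, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(tab)
}

#' Read fit results back from JSON
#'
#' @param path The same stem given to [write_fit_results()].
#' @return Named list of result summaries.
#' @export
read_fit_results <- function(path) {
  jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE,
                      simplifyDataFrame = TRUE)
}

#' Read a run configuration (YAML or JSON)
#'
#' A run configuration names the input tables and analysis settings
#' (carrier/incidence/panel paths, subtype field, model, age-group edges,
#' seed, output directory). Referenced files must exist.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in intersect(c("carriers", "incidence", "panel"), names(cfg))) {
    if (!file.exists(cfg[[f]])) {
      stop("config references missing file for '", f, "': ", cfg[[f]])
    }
  }
  cfg
}
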