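# File dialects and screen configuration.
#
# Everything the pipeline reads or writes is plain delimited text with
# documented headers: coded designs and dose maps as TSV, viability records
# and dose-response series as CSV, model reports as JSON, configuration as
# a YAML mapping.

#' Choose screening dose levels for a drug
#'
#' The screen's low/high (coded 0/+1) doses for a small molecule are its
#' IC15 and IC30 when the IC50 lies below the clinically achievable plasma
#' concentration Cmax; otherwise 5% and 10% of Cmax are used so doses stay
#' clinically relevant. The boundary `ic50 == cmax` takes the Cmax branch
#' (the IC rule requires the IC50 to be strictly lower).
#'
#' @param ic50,ic15,ic30 Single-agent inhibitory concentrations (> 0,
#'   `ic15 < ic30`).
#' @param cmax Maximum plasma concentration (> 0, same unit).
#' @return List: `low`, `high`, `rule` (`"IC"` or `"CMAX"`).
#' @export
select_drug_levels <- function(ic50, ic15, ic30, cmax) {
  for (nm in c("ic50", "ic15", "ic30", "cmax"))
    .check_number(get(nm), nm, positive = TRUE)
  if (!(ic15 < ic30)) stop("`ic15` must be smaller than `ic30`")
  if (ic50 < cmax) list(low = ic15, high = ic30, rule = "IC")
  else list(low = 0.05 * cmax, high = 0.10 * cmax, rule = "CMAX")
}

# ---- viability and dose-response files -------------------------------------

#' Write / read viability records as CSV
#'
#' Columns `run_id`, `replicate`, `viability`; joined to the coded design
#' by `run_id` when fitting.
#'
#' @param records Data frame of viability records.
#' @param path File path.
#' @return The records (read) or `path` invisibly (write).
#' @export
write_viability_csv <- function(records, path) {
  stopifnot(all(c("run_id", "replicate", "viability") %in% names(records)))
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_viability_csv
#' @export
read_viability_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("run_id", "replicate", "viability")
  if (!all(need %in% names(df)))
    stop("viability file must have columns run_id, replicate, viability: ", path)
  if (any(!is.finite(df$viability)) || any(df$viability < 0))
    stop("viability must be finite and >= 0: ", path)
  df[, need]
}

#' Read a dose-response series
#'
#' Accepts `dose, fa` or `dose, viability` (then `fa = 1 - viability`).
#'
#' @param path CSV path.
#' @return Data frame `dose`, `fa`.
#' @export
read_dose_response_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"dose" %in% names(df)) stop("dose-response file needs a `dose` column: ", path)
  if ("fa" %in% names(df)) {
    out <- df[, c("dose", "fa")]
  } else if ("viability" %in% names(df)) {
    out <- data.frame(dose = df$dose, fa = 1 - df$viability)
  } else stop("dose-response file needs `fa` or `viability`: ", path)
  out
}

#' @rdname read_dose_response_csv
#' @param points Data frame with `dose` and `fa`.
#' @export
write_dose_response_csv <- function(points, path) {
  stopifnot(all(c("dose", "fa") %in% names(points)))
  utils::write.csv(points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- model report ----------------------------------------------------------

#' Export / import a fitted model report as JSON
#'
#' The report carries the canonical term names, estimates, inclusion mask,
#' per-term F-test p-values (where residual df allow) and fit diagnostics,
#' and round-trips through [read_model_report_json()] into a coefficient
#' vector usable by [enumerate_combinations()].
#'
#' @param fit A `qpop_fit`.
#' @param path File path.
#' @return The report list (read) or `path` invisibly (write).
#' @export
write_model_report_json <- function(fit, path) {
  stopifnot(inherits(fit, "qpop_fit"))
  pv <- if (fit$df_residual >= 1) as.list(term_significance(fit)) else NULL
  report <- list(
    k = fit$k,
    method = fit$method,
    n_observations = fit$n,
    r_squared = fit$r_squared,
    df_residual = fit$df_residual,
    coefficients = as.list(fit$coefficients),
    included = as.list(fit$included),
    term_pvalues = pv)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_report_json
#' @export
read_model_report_json <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep$coefficients <- unlist(rep$coefficients)
  rep$included <- unlist(rep$included)
  if (!identical(names(rep$coefficients), quadratic_terms(rep$k)))
    stop("model report term names are not canonical: ", path)
  rep
}

# ---- run configuration -----------------------------------------------------

#' Write / read a screen configuration (YAML)
#'
#' One structured mapping holding the modulator table (name, kind, three
#' dose levels, unit), the SSO `constant_total`, stepwise thresholds, the
#' fa grid for synergy profiles, and seeds. [read_run_config()] validates
#' and rebuilds the [modulator()] list.
#'
#' @param config List as returned by `read_run_config()`: fields
#'   `modulators`, `constant_total`, `enter_p`, `remove_p`, `fa_grid`,
#'   `seed`.
#' @param path File path.
#' @return The validated config list (read) or `path` invisibly (write).
#' @export
write_run_config <- function(config, path) {
  mods <- lapply(config$modulators, function(m)
    list(name = m$name, kind = m$kind, dose_levels = m$dose_levels,
         unit = m$unit))
  yaml::write_yaml(list(
    modulators = mods,
    constant_total = config$constant_total,
    enter_p = config$enter_p,
    remove_p = config$remove_p,
    fa_grid = config$fa_grid,
    seed = config$seed), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$modulators)) stop("config has no `modulators` table: ", path)
  mods <- lapply(raw$modulators, function(m)
    modulator(m$name, m$kind, as.numeric(m$dose_levels),
              if (is.null(m$unit)) "" else m$unit))
  nm <- .modulator_names(mods)
  if (anyDuplicated(nm))
    stop("modulator defined more than once: ",
         paste(nm[duplicated(nm)], collapse = ", "))
  if (!is.null(raw$constant_total))
    attr(mods, "constant_total") <- .check_number(raw$constant_total,
                                                 "constant_total",
                                                 positive = TRUE)
  cfg <- list(
    modulators = mods,
    constant_total = raw$constant_total,
    enter_p = if (is.null(raw$enter_p)) 0.05 else raw$enter_p,
    remove_p = if (is.null(raw$remove_p)) 0.10 else raw$remove_p,
    fa_grid = if (is.null(raw$fa_grid)) seq(0.05, 0.95, by = 0.05)
              else as.numeric(raw$fa_grid),
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed))
  if (!(cfg$enter_p < cfg$remove_p))
    stop("config must satisfy enter_p < remove_p")
  cfg
}
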