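# Drug-pair synergy by the Chou-Talalay median-effect method and by Bliss
# independence.
#
# Single agents and the fixed-ratio combination each follow the
# median-effect equation fa/fu = (D/Dm)^m, fitted by least squares on the
# linearization log10(fa/fu) = m*log10(D) - m*log10(Dm). At each fraction
# affected fa the combination index is
#   CI = D1/Dx1(fa) + D2/Dx2(fa)
# (mutually exclusive two-term form), where D1, D2 split the combination's
# own dose at fa by the fixed ratio and Dx is each single agent's dose for
# that fa. CI < 1 synergy, = 1 additivity, > 1 antagonism; DRI_j =
# Dx_j(fa)/D_j is each drug's fold dose reduction, favorable when > 1.

.FA_CLAMP <- 1e-3

#' Fit the median-effect equation to a dose-response series
#'
#' Points with `fa` exactly 0 or 1 carry no information on the log-odds
#' scale and are dropped with a warning; remaining `fa` are clamped to
#' `[1e-3, 1 - 1e-3]` before linearization.
#'
#' @param dose Doses (> 0, any consistent concentration unit).
#' @param fa Fractions affected (1 - viability), in `[0, 1]`.
#' @return A `median_effect_fit`: `dm` (median-effect dose, `fa = 0.5`),
#'   `m` (sigmoidicity), `r` (correlation of the linearization), `n`.
#' @export
fit_median_effect <- function(dose, fa) {
  if (length(dose) != length(fa)) stop("`dose` and `fa` lengths differ")
  if (any(!is.finite(dose)) || any(dose <= 0)) stop("doses must be finite and > 0")
  if (any(!is.finite(fa)) || any(fa < 0 | fa > 1)) stop("`fa` must lie in [0, 1]")
  keep <- fa > 0 & fa < 1
  if (!all(keep)) {
    warning(sum(!keep), " point(s) with fa exactly 0 or 1 excluded from the fit")
    dose <- dose[keep]; fa <- fa[keep]
  }
  if (length(unique(dose)) < 2L)
    stop("need at least two distinct doses with fa in (0, 1)")
  fa <- pmin(pmax(fa, .FA_CLAMP), 1 - .FA_CLAMP)
  x <- log10(dose)
  y <- log10(fa / (1 - fa))
  cf <- stats::coef(stats::lm(y ~ x))
  m <- unname(cf[2])
  if (!is.finite(m) || m <= 0)
    warning("non-positive shape exponent m = ", signif(m, 3),
            ": dose-response is not increasing")
  dm <- 10^(-unname(cf[1]) / m)
  r <- if (stats::sd(y) > 0) stats::cor(x, y) else NA_real_
  structure(list(dm = dm, m = m, r = r, n = length(dose),
                 data = data.frame(dose = dose, fa = fa)),
            class = "median_effect_fit")
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("<median_effect_fit> Dm = %.4g, m = %.3f, r = %.4f (n = %d)\n",
              x$dm, x$m, x$r, x$n))
  invisible(x)
}

#' Dose producing a given fraction affected
#'
#' Inverts the median-effect equation: `Dx = Dm * (fa/(1-fa))^(1/m)`.
#'
#' @param fit A `median_effect_fit`.
#' @param fa Fractions affected, strictly inside (0, 1).
#' @return Doses.
#' @export
dose_for_fa <- function(fit, fa) {
  stopifnot(inherits(fit, "median_effect_fit"))
  if (any(fa <= 0 | fa >= 1)) stop("`fa` must be strictly inside (0, 1)")
  fit$dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Fraction affected at a given dose
#' @param fit A `median_effect_fit`.
#' @param dose Doses > 0.
#' @return Fractions affected.
#' @export
fa_at_dose <- function(fit, dose) {
  stopifnot(inherits(fit, "median_effect_fit"))
  if (any(dose <= 0)) stop("`dose` must be > 0")
  1 / (1 + (fit$dm / dose)^fit$m)
}

#' Combination index profile over the fraction-affected spectrum
#'
#' For a fixed-ratio combination (`ratio` = dose of drug 1 : dose of drug
#' 2, conventionally the ratio of single-agent IC50s): at each `fa` the
#' combination's own fit gives the total dose, which is split by the ratio
#' into component doses and compared with the single-agent doses achieving
#' the same effect.
#'
#' @param fit1,fit2 Single-agent `median_effect_fit`s.
#' @param fit_combo `median_effect_fit` of the fixed-ratio combination,
#'   expressed on total combination dose.
#' @param ratio Dose ratio drug1:drug2 (> 0).
#' @param fa_grid Fractions affected; default 0.05..0.95 step 0.05.
#' @param exclusive Use the mutually exclusive two-term form (default). If
#'   `FALSE`, adds the mutually nonexclusive third term
#'   `D1*D2/(Dx1*Dx2)`.
#' @return Data frame: `fa`, `total_dose`, `dose1`, `dose2`, `ci`,
#'   `log_ci`.
#' @export
combination_index <- function(fit1, fit2, fit_combo, ratio,
                              fa_grid = seq(0.05, 0.95, by = 0.05),
                              exclusive = TRUE) {
  .check_number(ratio, "ratio", positive = TRUE)
  if (any(fa_grid <= 0 | fa_grid >= 1)) stop("`fa_grid` must lie inside (0, 1)")
  dc <- dose_for_fa(fit_combo, fa_grid)
  d1 <- dc * ratio / (1 + ratio)
  d2 <- dc / (1 + ratio)
  dx1 <- dose_for_fa(fit1, fa_grid)
  dx2 <- dose_for_fa(fit2, fa_grid)
  ci <- d1 / dx1 + d2 / dx2
  if (!exclusive) ci <- ci + (d1 * d2) / (dx1 * dx2)
  data.frame(fa = fa_grid, total_dose = dc, dose1 = d1, dose2 = d2,
             ci = ci, log_ci = log10(ci))
}

#' Dose reduction index
#'
#' `DRI = Dx_single(fa) / dose_in_combination`: the fold by which the
#' single-agent dose shrinks in combination at equal effect.
#'
#' @param fit_single A single-agent `median_effect_fit`.
#' @param dose_in_combination The drug's dose within the combination (> 0).
#' @param fa Fractions affected.
#' @return DRI values (vectorized over `fa` / doses).
#' @export
dose_reduction_index <- function(fit_single, dose_in_combination, fa) {
  if (any(dose_in_combination <= 0)) stop("`dose_in_combination` must be > 0")
  dose_for_fa(fit_single, fa) / dose_in_combination
}

#' Paired DRI profile for a fixed-ratio combination
#'
#' @inheritParams combination_index
#' @return Data frame: `fa`, `dri1`, `dri2`, `log_dri1`, `log_dri2`.
#' @export
dri_profile <- function(fit1, fit2, fit_combo, ratio,
                        fa_grid = seq(0.05, 0.95, by = 0.05)) {
  .check_number(ratio, "ratio", positive = TRUE)
  dc <- dose_for_fa(fit_combo, fa_grid)
  d1 <- dc * ratio / (1 + ratio)
  d2 <- dc / (1 + ratio)
  dri1 <- dose_reduction_index(fit1, d1, fa_grid)
  dri2 <- dose_reduction_index(fit2, d2, fa_grid)
  data.frame(fa = fa_grid, dri1 = dri1, dri2 = dri2,
             log_dri1 = log10(dri1), log_dri2 = log10(dri2))
}

#' Bliss independence expected viability and excess
#'
#' Under Bliss independence the combination's expected surviving fraction
#' is the product of the single-agent surviving fractions. The excess
#' `expected - observed` is positive when the observed viability falls
#' below expectation, i.e. synergy.
#'
#' @param viability_a,viability_b Singlet viabilities in `[0, 1]`.
#' @return `bliss_expected()`: expected combination viability.
#' @export
bliss_expected <- function(viability_a, viability_b) {
  v <- c(viability_a, viability_b)
  if (any(!is.finite(v)) || any(v < 0 | v > 1))
    stop("viabilities must lie in [0, 1]")
  viability_a * viability_b
}

#' @rdname bliss_expected
#' @param observed,expected Observed and Bliss-expected combination
#'   viabilities in `[0, 1]`.
#' @return `bliss_excess()`: signed synergy score `expected - observed`.
#' @export
bliss_excess <- function(observed, expected) {
  v <- c(observed, expected)
  if (any(!is.finite(v)) || any(v < 0 | v > 1))
    stop("viabilities must lie in [0, 1]")
  expected - observed
}
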