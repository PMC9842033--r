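# Seeded synthetic-data generators.
#
# Screen measurements from the published platform are proprietary, so the
# pipeline is exercised on synthetic viability surfaces drawn from the same
# model family it fits: a sparse second-order polynomial in coded dose
# levels plus additive Gaussian measurement noise, and median-effect
# (Hill-type) dose-response curves for the synergy analysis. All
# generators are pure functions of their parameters and a seed.
#
# Truths are parameterized on the "activity" scale a_j = (x_j + 1)/2 in
# {0, 1/2, 1} (0 = modulator absent), where effects read naturally --
# v = 1 + sum_j (c_j a_j + q_j a_j^2) + sum_{i<j} C_ij a_i a_j -- and
# expanded exactly into the coded quadratic basis, so every truth lies in
# the fitted model family and untreated viability is exactly 1.

#' Expand activity-scale effects into canonical coded coefficients
#'
#' Substitutes `a = (x + 1)/2` into
#' `v = baseline + sum(c*a + q*a^2) + sum C_ij a_i a_j` and collects terms
#' of the coded quadratic basis.
#'
#' @param baseline Viability with every modulator absent (usually 1).
#' @param linear Length-k vector `c` of full-dose linear effects.
#' @param quadratic Length-k vector `q` of activity-scale curvatures.
#' @param pairwise k x k matrix `C`, upper triangle used.
#' @return Named coefficient vector in [quadratic_terms()] order.
#' @export
activity_to_coded <- function(baseline = 1, linear,
                              quadratic = rep(0, length(linear)),
                              pairwise = matrix(0, length(linear), length(linear))) {
  k <- length(linear)
  stopifnot(length(quadratic) == k, identical(dim(pairwise), c(k, k)))
  C <- pairwise
  C[lower.tri(C, diag = TRUE)] <- 0
  S <- C + t(C)
  alpha <- baseline + sum(linear / 2 + quadratic / 4) + sum(C) / 4
  beta <- linear / 2 + quadratic / 2 + rowSums(S) / 4
  pairs <- if (k >= 2) utils::combn(k, 2) else matrix(integer(0), 2, 0)
  beta_ij <- vapply(seq_len(ncol(pairs)),
                    function(p) C[pairs[1, p], pairs[2, p]] / 4, numeric(1))
  stats::setNames(c(alpha, beta, beta_ij, quadratic / 4), quadratic_terms(k))
}

# calibrated activity-scale effects for the default six-modulator panel:
# order sorafenib, cabozantinib, ssCHK1, ssMAX, ssMCL1, ssBRD4. Magnitudes
# chosen so top-ranked two-modulator projections land around 0.25-0.45.
.MYC_LINEAR6 <- c(-0.30, -0.10, -0.15, -0.12, -0.35, -0.13)
.MYC_QUAD <- 0.05
.MYC_PAIR <- -0.40

#' Manufacture a ground-truth viability surface
#'
#' Profiles: `"myc_high"` carries a strong negative bilinear (synthetic
#' lethal) interaction between the two designated SSO indices on top of
#' modest negative single-agent effects; `"myc_low"` is identical except
#' that the designated interaction is exactly 0, so the two truths differ
#' in one coefficient only; `"random_sparse"` draws a seeded sparse effect
#' set (each linear effect present w.p. 0.7 in -0.25..-0.05; each pair
#' w.p. 0.15 with magnitude 0.05..0.2, negative three times out of four;
#' each curvature w.p. 0.3 in 0.04..0.1) and is then rescaled about the
#' untreated baseline so the minimum viability over the coded cube is at
#' least 0.15, keeping the measurement floor at 0 from binding.
#'
#' @param profile `"myc_high"`, `"myc_low"` or `"random_sparse"`.
#' @param k Number of modulators (>= 2).
#' @param seed Seed (used by `random_sparse`; recorded for the screen
#'   simulation in all profiles).
#' @param pair Two designated SSO indices carrying the interaction; default
#'   `c(3, 6)` (ssCHK1 and ssBRD4 in the default panel order).
#' @param noise_sd Additive Gaussian viability noise for simulated screens.
#' @param replicates Replicates per run for simulated screens.
#' @return A `qpop_truth`: canonical coefficient vector, profile, pair,
#'   noise model and seed.
#' @export
make_truth <- function(profile = c("myc_high", "myc_low", "random_sparse"),
                       k = 6, seed = 1L, pair = c(3, 6),
                       noise_sd = 0.05, replicates = 3L) {
  profile <- match.arg(profile)
  if (k < 2) stop("k must be >= 2")
  pair <- as.integer(pair)
  if (length(pair) != 2L || anyDuplicated(pair) || any(pair < 1L | pair > k))
    stop("`pair` must be two distinct indices in 1..", k)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (profile %in% c("myc_high", "myc_low")) {
    lin <- if (k == 6) .MYC_LINEAR6 else {
      l <- rep(-0.12, k); l[pair] <- c(-0.15, -0.13); l
    }
    quad <- rep(.MYC_QUAD, k)
    C <- matrix(0, k, k)
    if (profile == "myc_high")
      C[min(pair), max(pair)] <- .MYC_PAIR
    coefficients <- activity_to_coded(1, lin, quad, C)
  } else {
    coefficients <- with_seed(seed, {
      lin <- ifelse(stats::runif(k) < 0.7,
                    -stats::runif(k, 0.05, 0.25), 0)
      if (all(lin == 0)) lin[1] <- -0.2
      quad <- ifelse(stats::runif(k) < 0.3, stats::runif(k, 0.04, 0.1), 0)
      C <- matrix(0, k, k)
      for (i in seq_len(k - 1)) for (j in (i + 1):k)
        if (stats::runif(1) < 0.15)
          C[i, j] <- stats::runif(1, 0.05, 0.2) *
            sample(c(-1, 1), 1, prob = c(0.75, 0.25))
      activity_to_coded(1, lin, quad, C)
    })
    # rescale about the baseline so the surface clears the measurement floor
    if (k <= 10) {
      vmin <- min(eval_quadratic(coefficients, .coded_grid(k)))
      if (vmin < 0.15) {
        # shrink all effects about the untreated baseline (exactly 1 by
        # construction) until the cube minimum reaches 0.15
        s <- 0.85 / (1 - vmin)
        coefficients <- coefficients * s
        coefficients[1] <- coefficients[1] + (1 - s)
      }
    }
  }
  structure(list(k = as.integer(k), coefficients = coefficients,
                 profile = profile, pair = pair,
                 noise_sd = noise_sd, replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "qpop_truth")
}

#' @export
print.qpop_truth <- function(x, ...) {
  nz <- sum(x$coefficients[-1] != 0)
  cat(sprintf("<qpop_truth> %s, k = %d, %d nonzero effect terms, noise_sd = %g, seed = %d\n",
              x$profile, x$k, nz, x$noise_sd, x$seed))
  invisible(x)
}

#' Simulate a viability screen on a design
#'
#' For every run x replicate, viability = truth polynomial at the run's
#' coded levels + Normal(0, noise_sd), floored at 0 (an MTS-type readout
#' cannot go negative).
#'
#' @param truth A `qpop_truth`.
#' @param design An `oacd_design`, or a plain coded matrix (runs x k).
#' @param noise_sd,replicates,seed Override the truth's recorded values.
#' @return Data frame `run_id`, `replicate`, `viability` (replicate blocks:
#'   all runs for replicate 1, then replicate 2, ...).
#' @export
simulate_screen <- function(truth, design, noise_sd = truth$noise_sd,
                            replicates = truth$replicates,
                            seed = truth$seed) {
  stopifnot(inherits(truth, "qpop_truth"))
  if (inherits(design, "oacd_design")) {
    runs <- design$runs
    run_id <- design$run_id
  } else {
    runs <- as.matrix(design)
    run_id <- seq_len(nrow(runs))
  }
  if (ncol(runs) != truth$k)
    stop("design has ", ncol(runs), " modulators but truth has k = ", truth$k)
  mu <- eval_quadratic(truth$coefficients, runs)
  n <- length(mu) * replicates
  noise <- if (noise_sd > 0) with_seed(seed, stats::rnorm(n, 0, noise_sd))
           else numeric(n)
  data.frame(run_id = rep(run_id, times = replicates),
             replicate = rep(seq_len(replicates), each = length(mu)),
             viability = pmax(rep(mu, times = replicates) + noise, 0))
}

#' Simulate a median-effect dose-response series
#'
#' Fraction affected follows the median-effect equation with lognormal
#' noise on the dose axis (each nominal dose is perturbed by
#' `10^Normal(0, noise_sd_log)` before evaluating the curve), emulating
#' serial-dilution error.
#'
#' @param dm Median-effect dose (> 0).
#' @param m Shape exponent.
#' @param doses Nominal doses (> 0).
#' @param noise_sd_log SD of the dose perturbation in log10 units.
#' @param seed Seed.
#' @return Data frame `dose` (nominal), `fa`.
#' @export
simulate_dose_response <- function(dm, m, doses, noise_sd_log = 0.05,
                                   seed = 1L) {
  .check_number(dm, "dm", positive = TRUE)
  .check_number(m, "m")
  if (any(doses <= 0)) stop("doses must be > 0")
  eff <- if (noise_sd_log > 0)
    doses * 10^with_seed(seed, stats::rnorm(length(doses), 0, noise_sd_log))
  else doses
  data.frame(dose = doses, fa = 1 / (1 + (dm / eff)^m))
}

#' Simulate a fixed-ratio combination curve with known combination index
#'
#' Constructs the combination's median-effect curve on total dose so that
#' its true CI equals `ci_target` at every fraction affected under the
#' equal-shape closed form: with component fractions f1 = ratio/(1+ratio),
#' f2 = 1/(1+ratio), the additive median-effect dose is
#' `D_add = 1 / (f1/Dm1 + f2/Dm2)` and the combination curve gets
#' `Dm = ci_target * D_add` with the common shape exponent.
#'
#' @param fit1,fit2 Single-agent `median_effect_fit`s (or lists with `dm`
#'   and `m`); shape exponents should agree for the closed form to hold.
#' @param ratio Fixed dose ratio drug1:drug2.
#' @param ci_target True combination index (> 0); 1 = additivity.
#' @param doses Nominal total doses.
#' @param noise_sd_log,seed As in [simulate_dose_response()].
#' @return Data frame `dose` (total), `fa`.
#' @export
simulate_fixed_ratio_combo <- function(fit1, fit2, ratio, ci_target, doses,
                                       noise_sd_log = 0, seed = 1L) {
  .check_number(ratio, "ratio", positive = TRUE)
  .check_number(ci_target, "ci_target", positive = TRUE)
  if (abs(fit1$m - fit2$m) > 0.025 * (abs(fit1$m) + abs(fit2$m)))
    warning("shape exponents differ (m1 = ", signif(fit1$m, 3), ", m2 = ",
            signif(fit2$m, 3), "); target CI holds only approximately")
  f1 <- ratio / (1 + ratio)
  f2 <- 1 / (1 + ratio)
  d_add <- 1 / (f1 / fit1$dm + f2 / fit2$dm)
  simulate_dose_response(ci_target * d_add, (fit1$m + fit2$m) / 2, doses,
                         noise_sd_log, seed)
}
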