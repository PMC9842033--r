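# Second-order response-surface model of combination viability.
#
# Viability y on the coded design is modeled as
#   y = b0 + sum_j b_j x_j + sum_{i<j} b_ij x_i x_j + sum_j b_jj x_j^2
# fitted by ordinary least squares, either with all 1 + 2k + k(k-1)/2 terms
# or with bidirectional stepwise selection on partial-F p-values (MATLAB
# stepwisefit-style defaults: enter 0.05, remove 0.10). Fitting is on coded
# levels, not raw concentrations, so coefficients are comparable across
# modulators whose doses differ by orders of magnitude.

#' Canonical term names of the quadratic model
#'
#' Order: intercept `b0`; linear `b_1..b_k`; bilinear `b_i_j` for i < j in
#' lexicographic order; quadratic `b_j_j`.
#'
#' @param k Number of modulators.
#' @return Character vector of length `1 + 2k + k(k-1)/2`.
#' @export
quadratic_terms <- function(k) {
  pairs <- if (k >= 2) utils::combn(k, 2) else matrix(integer(0), 2, 0)
  c("b0", paste0("b_", seq_len(k)),
    if (ncol(pairs)) paste0("b_", pairs[1, ], "_", pairs[2, ]),
    paste0("b_", seq_len(k), "_", seq_len(k)))
}

#' Build the quadratic model matrix from coded runs
#'
#' Columns follow [quadratic_terms()]: intercept, linear, bilinear products
#' `x_i * x_j`, squares `x_j^2`. Accepts any finite real levels (projection
#' on a continuous coded grid uses the same matrix).
#'
#' @param coded Numeric matrix (runs x k) or a single length-k vector.
#' @param k Number of modulators; defaults to `ncol(coded)`.
#' @return Numeric matrix (runs x terms) with canonical column names.
#' @export
build_design_matrix <- function(coded, k = NULL) {
  if (is.null(dim(coded))) coded <- matrix(coded, nrow = 1)
  coded <- as.matrix(coded)
  if (is.null(k)) k <- ncol(coded)
  if (ncol(coded) != k) stop("coded rows have length ", ncol(coded), ", expected k = ", k)
  if (!is.numeric(coded) || any(!is.finite(coded))) stop("coded levels must be finite numbers")
  n <- nrow(coded)
  pairs <- if (k >= 2) utils::combn(k, 2) else matrix(integer(0), 2, 0)
  M <- matrix(NA_real_, n, 1L + 2L * k + ncol(pairs))
  M[, 1L] <- 1
  M[, 1L + seq_len(k)] <- coded
  for (p in seq_len(ncol(pairs)))
    M[, 1L + k + p] <- coded[, pairs[1, p]] * coded[, pairs[2, p]]
  M[, 1L + k + ncol(pairs) + seq_len(k)] <- coded^2
  colnames(M) <- quadratic_terms(k)
  M
}

#' Evaluate a quadratic coefficient vector on coded levels
#'
#' @param coefficients Full coefficient vector in canonical term order.
#' @param coded Coded matrix or single vector.
#' @return Numeric vector of polynomial values.
#' @export
eval_quadratic <- function(coefficients, coded) {
  if (is.null(dim(coded))) coded <- matrix(coded, nrow = 1)
  k <- ncol(coded)
  if (length(coefficients) != length(quadratic_terms(k)))
    stop("coefficient vector length does not match k = ", k)
  drop(build_design_matrix(coded, k) %*% coefficients)
}

# least-squares on a column subset; returns sse/df/rank/coef
.ls_sse <- function(M, y, cols) {
  f <- stats::lm.fit(M[, cols, drop = FALSE], y)
  list(sse = sum(f$residuals^2), df = length(y) - f$rank, rank = f$rank,
       coef = f$coefficients)
}

# partial-F p-value for one term: reduced vs full model.
# Near-zero SSEs (relative to `tol`) are resolved before forming the ratio:
# nothing left to explain -> p = 1; exact fit gained -> p = 0.
.partial_f_p <- function(sse_reduced, sse_full, df_full, tol) {
  if (sse_reduced <= tol) return(1)
  if (sse_full <= tol) return(0)
  if (df_full < 1) return(1)
  f <- max(0, (sse_reduced - sse_full) / (sse_full / df_full))
  stats::pf(f, 1, df_full, lower.tail = FALSE)
}

.sse_tol <- function(y) {
  n <- length(y)
  1e-10 * (sum((y - mean(y))^2) / max(1, n) + mean(y)^2 + .Machine$double.eps)
}

.new_qpop_fit <- function(M, y, included, k, method) {
  sol <- .ls_sse(M, y, which(included))
  coefficients <- stats::setNames(numeric(ncol(M)), colnames(M))
  coefficients[which(included)] <- sol$coef
  fitted <- drop(M[, included, drop = FALSE] %*% sol$coef)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst <= .Machine$double.eps * length(y)) {
    warning("degenerate response (SST = 0); r_squared reported as 0")
    0
  } else max(0, min(1, 1 - sol$sse / sst))
  df <- length(y) - sum(included)
  structure(list(k = k, coefficients = coefficients,
                 included = stats::setNames(included, colnames(M)),
                 r_squared = r2, sse = sol$sse, sst = sst,
                 df_residual = df,
                 sigma2 = if (df > 0) sol$sse / df else NA_real_,
                 n = length(y), fitted = fitted, residuals = y - fitted,
                 method = method, model_matrix = M, y = y),
            class = "qpop_fit")
}

#' Fit the full second-order viability model by least squares
#'
#' All `1 + 2k + k(k-1)/2` terms are estimated. Replicates enter as
#' individual observations (no pre-averaging), preserving residual degrees
#' of freedom for the F tests.
#'
#' @param coded Coded level matrix, one row per observation (replicate rows
#'   repeat their run's coded levels).
#' @param viability Viability fractions (untreated = 1); values above 1 are
#'   retained (stimulation/noise).
#' @param k Number of modulators.
#' @return A `qpop_fit`: full-length coefficient vector, inclusion mask,
#'   `r_squared`, residual variance, the model matrix and response.
#' @export
fit_full_quadratic <- function(coded, viability, k = NULL) {
  if (is.null(dim(coded))) coded <- matrix(coded, nrow = 1)
  if (is.null(k)) k <- ncol(coded)
  y <- as.numeric(viability)
  if (nrow(coded) != length(y)) stop("coded rows and viability length differ")
  if (any(!is.finite(y))) stop("viability must be finite")
  M <- build_design_matrix(coded, k)
  if (length(y) < ncol(M))
    stop("need at least ", ncol(M), " observations for the full quadratic, got ", length(y))
  q <- qr(M)
  if (q$rank < ncol(M)) {
    bad <- colnames(M)[q$pivot[(q$rank + 1L):ncol(M)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  .new_qpop_fit(M, y, rep(TRUE, ncol(M)), k, "full")
}

#' Bidirectional stepwise fit of the second-order viability model
#'
#' Starting from the intercept-only model, repeatedly (i) adds the excluded
#' term with the smallest partial-F p-value if it is below `enter_p`, then
#' (ii) removes the included term with the largest p-value if it is above
#' `remove_p`, until a fixed point. The intercept is always retained and
#' excluded coefficients are exactly 0. The selected support is refit by
#' ordinary least squares, so reported coefficients equal the OLS fit on
#' the included terms.
#'
#' @inheritParams fit_full_quadratic
#' @param enter_p,remove_p Entry/removal p-value thresholds; must satisfy
#'   `enter_p < remove_p`. Defaults 0.05 / 0.10.
#' @param max_iter Iteration guard; non-convergence raises a warning.
#' @return A `qpop_fit` with `included` recording the selected support.
#' @export
stepwise_fit <- function(coded, viability, k = NULL,
                         enter_p = 0.05, remove_p = 0.10, max_iter = 200L) {
  if (!(enter_p < remove_p)) stop("`enter_p` must be smaller than `remove_p`")
  if (is.null(dim(coded))) coded <- matrix(coded, nrow = 1)
  if (is.null(k)) k <- ncol(coded)
  y <- as.numeric(viability)
  if (nrow(coded) != length(y)) stop("coded rows and viability length differ")
  M <- build_design_matrix(coded, k)
  tol <- .sse_tol(y)
  inc <- c(TRUE, rep(FALSE, ncol(M) - 1L))
  cur <- .ls_sse(M, y, which(inc))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    # forward step
    cand <- which(!inc)
    if (length(cand) && cur$df > 1 && cur$sse > tol) {
      pv <- vapply(cand, function(j) {
        f <- .ls_sse(M, y, c(which(inc), j))
        if (f$rank < sum(inc) + 1L) return(1)  # collinear with current terms
        .partial_f_p(cur$sse, f$sse, f$df, tol)
      }, numeric(1))
      if (min(pv) < enter_p) {
        inc[cand[which.min(pv)]] <- TRUE
        cur <- .ls_sse(M, y, which(inc))
        changed <- TRUE
      }
    }
    # backward step
    ins <- setdiff(which(inc), 1L)
    if (length(ins)) {
      pv <- vapply(ins, function(j) {
        f <- .ls_sse(M, y, setdiff(which(inc), j))
        .partial_f_p(f$sse, cur$sse, cur$df, tol)
      }, numeric(1))
      if (max(pv) > remove_p) {
        inc[ins[which.max(pv)]] <- FALSE
        cur <- .ls_sse(M, y, which(inc))
        changed <- TRUE
      }
    }
    if (!changed) { converged <- TRUE; break }
  }
  if (!converged)
    warning("stepwise selection did not reach a fixed point in ", max_iter,
            " iterations")
  .new_qpop_fit(M, y, inc, k, "stepwise")
}

#' Extra-sum-of-squares F tests for the included terms
#'
#' For each included non-intercept term, compares the fitted model with the
#' model lacking that term (1-df partial F against the residual variance of
#' the full fit).
#'
#' @param fit A `qpop_fit`.
#' @param terms Optional character vector of canonical term names to test;
#'   default all included non-intercept terms.
#' @return Named vector of p-values.
#' @export
term_significance <- function(fit, terms = NULL) {
  stopifnot(inherits(fit, "qpop_fit"))
  if (fit$df_residual < 1)
    stop("saturated model: no residual degrees of freedom for F tests")
  inc <- which(fit$included)
  test <- setdiff(inc, 1L)
  if (!is.null(terms)) {
    idx <- match(terms, names(fit$included))
    if (any(is.na(idx))) stop("unknown term(s): ", paste(terms[is.na(idx)], collapse = ", "))
    if (any(!fit$included[idx])) stop("cannot test excluded term(s)")
    test <- setdiff(idx, 1L)
  }
  tol <- .sse_tol(fit$y)
  pv <- vapply(test, function(j) {
    red <- .ls_sse(fit$model_matrix, fit$y, setdiff(inc, j))
    .partial_f_p(red$sse, fit$sse, fit$df_residual, tol)
  }, numeric(1))
  stats::setNames(pv, names(fit$included)[test])
}

#' Project viability for coded combinations
#'
#' Evaluates the fitted polynomial. Projections are not clipped by default
#' (they may leave `[0, 1]`); `clip = TRUE` truncates for reporting.
#'
#' @param object A `qpop_fit`.
#' @param coded Coded matrix or single length-k vector.
#' @param clip Truncate projections to `[0, 1]`?
#' @param ... Unused.
#' @return Numeric vector of projected viabilities.
#' @export
predict.qpop_fit <- function(object, coded, clip = FALSE, ...) {
  if (is.null(dim(coded))) coded <- matrix(coded, nrow = 1)
  if (ncol(coded) != object$k)
    stop("coded vectors must have length k = ", object$k)
  out <- eval_quadratic(object$coefficients, coded)
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}

#' @export
print.qpop_fit <- function(x, ...) {
  cat(sprintf("<qpop_fit> %s quadratic model, k = %d: %d/%d terms, R^2 = %.3f (n = %d)\n",
              x$method, x$k, sum(x$included), length(x$included),
              x$r_squared, x$n))
  invisible(x)
}

#' Fit a screen: join viability records to a design and fit
#'
#' Convenience wrapper matching measurement rows to design runs by
#' `run_id`, then delegating to [fit_full_quadratic()] or [stepwise_fit()].
#'
#' @param design An `oacd_design`.
#' @param records Data frame with columns `run_id`, `replicate`,
#'   `viability` (the dialect written by [write_viability_csv()]).
#' @param method `"stepwise"` (default, the screen's standard analysis) or
#'   `"full"`.
#' @param ... Passed to the fitter.
#' @return A `qpop_fit`.
#' @export
fit_screen <- function(design, records, method = c("stepwise", "full"), ...) {
  method <- match.arg(method)
  need <- c("run_id", "viability")
  if (!all(need %in% names(records))) stop("records need columns run_id and viability")
  idx <- match(records$run_id, design$run_id)
  if (any(is.na(idx)))
    stop("records reference run_id(s) absent from the design: ",
         paste(unique(records$run_id[is.na(idx)]), collapse = ", "))
  coded <- design$runs[idx, , drop = FALSE]
  switch(method,
         stepwise = stepwise_fit(coded, records$viability, ...),
         full = fit_full_quadratic(coded, records$viability, ...))
}
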