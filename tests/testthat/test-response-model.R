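test_that("quadratic model matrix has canonical structure", {
  expect_length(quadratic_terms(6), 28L)  # 1 + 6 + 15 + 6
  M0 <- build_design_matrix(rep(0, 6))
  expect_equal(unname(M0[1, ]), c(1, rep(0, 27)))
  M1 <- build_design_matrix(c(1, 1, 0, 0, 0, 0))
  expect_equal(unname(M1[1, "b_1_2"]), 1)
  expect_equal(unname(M1[1, c("b_1_1", "b_2_2")]), c(1, 1))
  expect_equal(unname(M1[1, c("b_1_3", "b_3_3")]), c(0, 0))
  # hand-computed k = 2 row: order b0, b_1, b_2, b_1_2, b_1_1, b_2_2
  expect_equal(unname(build_design_matrix(c(-1, 1))[1, ]),
               c(1, -1, 1, -1, 1, 1))
  expect_error(build_design_matrix(matrix(1, 2, 3), k = 4), "expected k")
})

test_that("full least-squares fit recovers known coefficients exactly without noise", {
  d <- compose_oacd(6)
  X <- d$runs[rep(1:50, 3), ]
  for (seed in 1:5) {
    parts <- oracle_random_parts(6, seed)
    y <- apply(X, 1, function(x)
      oracle_eval(parts$alpha, parts$beta, parts$B, parts$gamma, x))
    fit <- fit_full_quadratic(X, y)
    expect_equal(fit$coefficients,
                 oracle_coef_vector(parts$alpha, parts$beta, parts$B, parts$gamma),
                 tolerance = 1e-8)
    expect_equal(fit$r_squared, 1, tolerance = 1e-8)
    expect_equal(predict(fit, X), fit$fitted)
  }
})

test_that("constant response yields the degenerate fit convention", {
  d <- compose_oacd(6)
  X <- d$runs[rep(1:50, 3), ]
  expect_warning(fit <- fit_full_quadratic(X, rep(0.5, nrow(X))),
                 "degenerate")
  expect_equal(unname(fit$coefficients["b0"]), 0.5, tolerance = 1e-10)
  expect_equal(max(abs(fit$coefficients[-1])), 0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 0)
})

test_that("noisy fits recover coefficients within their standard errors", {
  d <- compose_oacd(6)
  X <- d$runs[rep(1:50, 3), ]
  truth <- make_truth("random_sparse", seed = 1, noise_sd = 0.05)
  rec <- simulate_screen(truth, d, seed = 2)
  fit <- fit_full_quadratic(X, rec$viability)
  se <- sqrt(diag(solve(crossprod(build_design_matrix(X)))) * fit$sigma2)
  z <- abs(fit$coefficients - truth$coefficients) / se
  # 28 simultaneous z scores: essentially all within 3 SE, none extreme
  expect_gte(mean(z <= 3), 0.95)
  expect_lt(max(z), 4.5)
  expect_lt(median(z), 2)
})

test_that("adding a constant shifts the intercept only", {
  d <- compose_oacd(6)
  X <- d$runs[rep(1:50, 3), ]
  y <- with_seed(3, 0.8 + 0.1 * X[, 1] + rnorm(nrow(X), 0, 0.05))
  f1 <- fit_full_quadratic(X, y)
  f2 <- fit_full_quadratic(X, y + 0.3)
  expect_equal(unname(f2$coefficients["b0"] - f1$coefficients["b0"]), 0.3,
               tolerance = 1e-10)
  expect_equal(f2$coefficients[-1], f1$coefficients[-1], tolerance = 1e-10)
})

test_that("stepwise selection finds exact sparse support and is an OLS refit", {
  d <- compose_oacd(6)
  X <- d$runs[rep(1:50, 3), ]
  # truth: viability 1 - 0.2 x1 - 0.15 x1 x2 (noiseless)
  y <- 1 - 0.2 * X[, 1] - 0.15 * X[, 1] * X[, 2]
  fit <- stepwise_fit(X, y)
  expect_setequal(names(which(fit$included)), c("b0", "b_1", "b_1_2"))
  expect_equal(unname(fit$coefficients[c("b0", "b_1", "b_1_2")]),
               c(1, -0.2, -0.15), tolerance = 1e-10)
  # reported coefficients equal the OLS refit on the selected support
  ols <- lm.fit(build_design_matrix(X)[, fit$included], y)$coefficients
  expect_equal(unname(fit$coefficients[fit$included]), unname(ols),
               tolerance = 1e-12)
  # re-running stepwise on its own fitted values returns the same support
  fit2 <- stepwise_fit(X, fit$fitted)
  expect_identical(fit2$included, fit$included)

  yn <- with_seed(4, y + rnorm(length(y), 0, 0.05))
  expect_gte(fit_full_quadratic(X, yn)$r_squared,
             stepwise_fit(X, yn)$r_squared)
  expect_error(stepwise_fit(X, y, enter_p = 0.2, remove_p = 0.1), "smaller")
})

test_that("stepwise stays near-empty under a pure-noise null", {
  # With per-step thresholds, screening the best of 27 candidate terms at
  # p < 0.05 admits a spurious term on most null data sets (the minimum of
  # 27 null p-values falls below 0.05 with probability ~ 1 - 0.95^27); the
  # selected null support is nonetheless small. Family-corrected
  # thresholds make the null support empty almost always.
  d <- compose_oacd(6)
  X <- d$runs[rep(1:50, 3), ]
  sizes <- vapply(1:100, function(s) {
    y <- with_seed(s, rnorm(nrow(X), 0.8, 0.05))
    sum(stepwise_fit(X, y)$included) - 1L
  }, integer(1))
  expect_lte(median(sizes), 2)
  expect_lt(mean(sizes), 3)

  empty <- vapply(1:100, function(s) {
    y <- with_seed(s, rnorm(nrow(X), 0.8, 0.05))
    sum(stepwise_fit(X, y, enter_p = 0.05 / 27, remove_p = 0.10 / 27)$included) == 1L
  }, logical(1))
  expect_gte(mean(empty), 0.90)
})

test_that("per-term F tests detect strong effects and refuse degenerate fits", {
  d <- compose_oacd(6)
  X <- d$runs[rep(1:50, 3), ]
  y <- with_seed(5, 1 - 0.3 * X[, 1] + rnorm(nrow(X), 0, 0.02))
  fit <- fit_full_quadratic(X, y)
  pv <- term_significance(fit)
  expect_lt(pv[["b_1"]], 1e-6)
  expect_identical(term_significance(fit, "b_1"), pv["b_1"])
  expect_error(term_significance(fit, "b_99"), "unknown term")

  # saturated model: six observations, six terms, no residual df
  g <- as.matrix(expand.grid(x1 = c(-1, 0, 1), x2 = c(-1, 0, 1)))
  sub <- g[c(1, 2, 3, 4, 7, 9), ]
  sat <- fit_full_quadratic(sub, c(1, .9, .8, .7, .6, .5))
  expect_error(term_significance(sat), "saturated")

  # a duplicated modulator column is reported as a rank problem at fit time
  Xdup <- X
  Xdup[, 2] <- Xdup[, 1]
  expect_error(fit_full_quadratic(Xdup, y), "rank deficient")
})

test_that("projection evaluates the polynomial without clipping by default", {
  d <- compose_oacd(2)
  y <- apply(d$runs, 1, function(x) oracle_eval(1, c(0, 0),
    matrix(c(0, -0.1, 0, 0), 2, 2, byrow = TRUE), c(0, 0), x))
  fit <- fit_full_quadratic(d$runs, y)
  expect_equal(predict(fit, c(0, 0)), 1, tolerance = 1e-10)
  expect_equal(predict(fit, c(1, 1)), 0.9, tolerance = 1e-10)
  big <- fit
  big$coefficients["b0"] <- 1.4
  expect_equal(predict(big, c(0, 0)), 1.4, tolerance = 1e-10)
  expect_equal(predict(big, c(0, 0), clip = TRUE), 1)
  expect_error(predict(fit, c(0, 0, 0)), "length")
})

test_that("fit_screen joins records to design runs by run id", {
  panel <- default_modulator_panel()
  d <- compose_oacd(6, modulators = panel)
  truth <- make_truth("myc_low", noise_sd = 0)  # surface >= 0: floor inert
  rec <- simulate_screen(truth, d, noise_sd = 0)
  fit <- fit_screen(d, rec, method = "full")
  expect_equal(fit$coefficients, truth$coefficients, tolerance = 1e-8)
  bad <- rec
  bad$run_id[1] <- 99L
  expect_error(fit_screen(d, bad), "absent from the design")
})
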