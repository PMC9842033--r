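test_that("exhaustive enumeration covers the coded cube in canonical order", {
  parts <- oracle_random_parts(3, 11)
  cf <- oracle_coef_vector(parts$alpha, parts$beta, parts$B, parts$gamma)
  pred <- enumerate_combinations(cf, k = 3)
  expect_equal(nrow(pred), 27L)
  g <- oracle_grid(3)
  expect_equal(unname(as.matrix(pred[, c("x1", "x2", "x3")])), unname(g))
  vals <- apply(g, 1, function(x)
    oracle_eval(parts$alpha, parts$beta, parts$B, parts$gamma, x))
  expect_equal(pred$viability, unname(vals), tolerance = 1e-12)
  expect_equal(pred$n_active, unname(oracle_n_active(g)))

  # constant surface
  cf0 <- oracle_coef_vector(0.7, rep(0, 6), matrix(0, 6, 6), rep(0, 6))
  expect_equal(unique(enumerate_combinations(cf0, k = 6)$viability), 0.7)
  expect_equal(nrow(enumerate_combinations(cf0, k = 6)), 729L)
  expect_error(enumerate_combinations(cf0, k = 13), "guarded")
})

test_that("ranking matches an independent brute-force oracle, filter included", {
  g <- oracle_grid(6)
  for (seed in 1:5) {
    parts <- oracle_random_parts(6, seed)
    cf <- oracle_coef_vector(parts$alpha, parts$beta, parts$B, parts$gamma)
    vals <- apply(g, 1, function(x)
      oracle_eval(parts$alpha, parts$beta, parts$B, parts$gamma, x))
    want <- oracle_overall_ranks(vals, g)

    rk <- rank_combinations(enumerate_combinations(cf, k = 6))
    # realign: returned table is sorted by rank; map back to grid order
    ord <- do.call(order, lapply(1:6, function(j) rk[[paste0("x", j)]]))
    expect_equal(rk$overall_rank[ord], unname(want))
    expect_equal(rk$rank, 1:729)
    expect_equal(sort(rk$overall_rank), 1:729)

    # filtering keeps overall ranks and drops nothing else
    two <- rank_combinations(enumerate_combinations(cf, k = 6), max_active = 2)
    expect_true(all(two$n_active <= 2))
    expect_equal(nrow(two), 73L)  # 1 + 6*2 + 15*4
    keep <- oracle_n_active(g) <= 2
    expect_setequal(two$overall_rank, want[keep])
    expect_equal(two$rank, seq_len(nrow(two)))
    expect_false(is.unsorted(two$overall_rank))
  }
})

test_that("monotone effects rank the all-high combination first", {
  cf <- oracle_coef_vector(1, c(-0.1, -0.2), matrix(0, 2, 2), c(0, 0))
  rk <- rank_combinations(enumerate_combinations(cf, k = 2))
  expect_equal(unname(unlist(rk[1, c("x1", "x2")])), c(1, 1))
  expect_error(rank_combinations(data.frame()), "empty")
})

test_that("between-line normalization is an antisymmetric difference with Table-S4 ranking", {
  parts <- oracle_random_parts(6, 21)
  cfA <- oracle_coef_vector(parts$alpha, parts$beta, parts$B, parts$gamma)
  pA <- enumerate_combinations(cfA, k = 6)

  nAA <- normalize_between_lines(pA, pA)
  expect_equal(unique(nAA$normalized), 0)

  # add a synergistic (negative bilinear) term between modulators 3 and 6
  B2 <- parts$B
  B2[3, 6] <- B2[3, 6] - 0.15
  cfB <- oracle_coef_vector(parts$alpha, parts$beta, B2, parts$gamma)
  pB <- enumerate_combinations(cfB, k = 6)

  nAB <- normalize_between_lines(pA, pB)
  nBA <- normalize_between_lines(pB, pA)
  ordAB <- do.call(order, lapply(1:6, function(j) nAB[[paste0("x", j)]]))
  ordBA <- do.call(order, lapply(1:6, function(j) nBA[[paste0("x", j)]]))
  expect_equal(nAB$normalized[ordAB], -nBA$normalized[ordBA])

  # combinations with the pair fully on rise above those with it mixed
  on <- nAB$x3 == 1 & nAB$x6 == 1
  mixed <- nAB$x3 * nAB$x6 == -1
  expect_lt(max(nAB$overall_rank[on]), min(nAB$overall_rank[mixed]))

  expect_error(normalize_between_lines(pA, pA[1:10, ]), "differ|same k")
})

test_that("surface grids are separable exactly when the bilinear term vanishes", {
  panel <- default_modulator_panel()
  d <- compose_oacd(6, modulators = panel)
  truth <- make_truth("myc_high", noise_sd = 0)
  # fit on exact polynomial values so the fitted model equals the truth
  fit <- fit_full_quadratic(d$runs, eval_quadratic(truth$coefficients, d$runs))

  # pair (1, 2): no bilinear term in the truth -> additively separable
  s12 <- surface_grid(fit, c(1, 2), panel, n_grid = 15)
  v <- s12$viability
  resid <- v - outer(v[, 1], rep(1, 15)) - outer(rep(1, 15), v[1, ]) + v[1, 1]
  expect_equal(max(abs(resid)), 0, tolerance = 1e-9)

  # pair (3, 6) carries the negative interaction -> negative residual at (max, max)
  s36 <- surface_grid(fit, c(3, 6), panel, n_grid = 15)
  v <- s36$viability
  resid <- v - outer(v[, 1], rep(1, 15)) - outer(rep(1, 15), v[1, ]) + v[1, 1]
  expect_lt(resid[15, 15], -1e-3)

  # dose-0 corner equals the projection at the zero-dose coded point
  base <- rep(-1, 6)
  expect_equal(s36$viability[1, 1], predict(fit, base))
  expect_equal(s36$axis_doses_i[1], 0)
  expect_equal(s36$axis_doses_i[15], 50)  # spans up to the +1 dose

  expect_error(surface_grid(fit, c(2, 2), panel), "distinct")
  expect_error(surface_grid(fit, c(0, 7), panel), "distinct|1\\.\\.")
})

test_that("polygonogram assigns sextile bins from geometric-mean pair efficacy", {
  # exchangeable model: every pair identical
  cf <- oracle_coef_vector(0.9, rep(-0.05, 4), matrix(0, 4, 4), rep(0, 4))
  d <- compose_oacd(4)
  y <- apply(d$runs, 1, function(x)
    oracle_eval(0.9, rep(-0.05, 4), matrix(0, 4, 4), rep(0, 4), x))
  fit <- fit_full_quadratic(d$runs, y)
  pg <- polygonogram_summary(fit)
  expect_equal(nrow(pg), 6L)  # 4 choose 2
  expect_equal(diff(range(pg$gm_efficacy)), 0, tolerance = 1e-10)
  expect_true(all(pg$bin %in% 1:6))
  expect_identical(pg, polygonogram_summary(fit))  # deterministic ties

  # a strongly synergistic pair lands in the top percentile bin
  panel <- default_modulator_panel()
  d6 <- compose_oacd(6, modulators = panel)
  truth <- make_truth("myc_high", noise_sd = 0)
  fit6 <- fit_full_quadratic(d6$runs, eval_quadratic(truth$coefficients, d6$runs))
  pg6 <- polygonogram_summary(fit6, panel)
  row36 <- pg6[pg6$i == 3 & pg6$j == 6, ]
  expect_equal(row36$pair, "ssCHK1+ssBRD4")
  expect_equal(row36$bin, 6L)
  expect_equal(row36$bin_label, "most effective")

  # with no other effects, a lone synergistic interaction (negative
  # activity-scale pair term, zero when either modulator is absent) tops
  # the ranking outright
  Conly <- matrix(0, 6, 6); Conly[2, 5] <- -0.2
  cf25 <- activity_to_coded(1, rep(0, 6), rep(0, 6), Conly)
  y25 <- eval_quadratic(cf25, d6$runs)
  pg25 <- polygonogram_summary(fit_full_quadratic(d6$runs, y25))
  expect_equal(pg25$percentile[pg25$i == 2 & pg25$j == 5], 100)
  expect_equal(pg25$bin[pg25$i == 2 & pg25$j == 5], 6L)
  # sextile widths: percentile 100 -> bin 6, percentile just above 0 -> bin 1
  expect_equal(sort(unique(pg6$bin[pg6$percentile <= 100 / 6])), 1L)

  # viability projections at or above 1 floor the efficacy, gm stays finite
  hi <- fit
  hi$coefficients["b0"] <- 1.2
  pghi <- polygonogram_summary(hi)
  expect_true(all(is.finite(pghi$gm_efficacy)))
  expect_equal(unique(pghi$gm_efficacy), 1e-6)
})
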