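# Exhaustive projection and ranking of the combination space.
#
# The fitted quadratic is evaluated at every coded combination (3^k of
# them), combinations are ranked by ascending projected viability (rank 1 =
# most effective), and pairwise interaction structure is summarized as
# response-surface grids and polygonogram percentile bins.

.coded_grid <- function(k) {
  g <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), k)))[, rev(seq_len(k)),
                                                            drop = FALSE]
  dimnames(g) <- list(NULL, paste0("x", seq_len(k)))
  g
}

# coded level whose mapped dose is 0 (the "modulator absent" axis position);
# -1 when no dose table is available (low dose 0 by convention)
.zero_coded <- function(modulators, k) {
  if (is.null(modulators)) return(rep(-1, k))
  vapply(modulators, function(m) dose_to_coded(0, m), numeric(1))
}

#' Project viability for every coded combination
#'
#' Enumerates the full `3^k` coded grid in canonical lexicographic order
#' (levels ordered -1 < 0 < +1, first modulator most significant) and
#' evaluates the fitted polynomial at each point.
#'
#' @param fit A `qpop_fit` (or full canonical coefficient vector with `k`
#'   supplied).
#' @param modulators Optional modulator list; adds dose columns and bases
#'   `n_active` on mapped doses.
#' @param k Required when `fit` is a plain coefficient vector.
#' @return Data frame with coded columns `x1..xk`, optional `<name>_dose`
#'   columns, `viability` (unclipped projection) and `n_active` (modulators
#'   at nonzero dose). Attribute `k` records the dimension.
#' @export
enumerate_combinations <- function(fit, modulators = NULL, k = NULL) {
  if (inherits(fit, "qpop_fit")) {
    k <- fit$k
    coefficients <- fit$coefficients
  } else {
    if (is.null(k)) stop("supply `k` when `fit` is a coefficient vector")
    coefficients <- fit
  }
  if (k > 12) stop("k = ", k, ": exhaustive enumeration is guarded at k <= 12")
  if (!is.null(modulators) && length(modulators) != k)
    stop("`modulators` must have length k = ", k)
  grid <- .coded_grid(k)
  viability <- eval_quadratic(coefficients, grid)
  out <- data.frame(grid, check.names = FALSE)
  if (!is.null(modulators)) {
    for (j in seq_len(k))
      out[[paste0(modulators[[j]]$name, "_dose")]] <-
        coded_to_dose(grid[, j], modulators[[j]])
    dose_cols <- paste0(.modulator_names(modulators), "_dose")
    out$n_active <- rowSums(out[, dose_cols, drop = FALSE] > 0)
  } else {
    out$n_active <- rowSums(grid > -1L)
  }
  out$viability <- viability
  attr(out, "k") <- k
  out
}

#' Rank combinations by projected viability
#'
#' Overall ranks are assigned on the full enumeration by ascending
#' projected viability (rank 1 = lowest viability = most effective), with
#' deterministic tie-breaking by lower total coded dose then lexicographic
#' coded vector. When `max_active` is given the returned table is filtered
#' to combinations with at most that many active modulators but keeps the
#' overall ranks, mirroring published "two-modulator" tables where the
#' filtered rank 3 can carry overall rank 187.
#'
#' @param predictions Output of [enumerate_combinations()].
#' @param max_active Optional cap on `n_active` for the returned rows.
#' @return The predictions sorted by rank, with columns `rank` (position in
#'   the returned, possibly filtered, list) and `overall_rank`.
#' @export
rank_combinations <- function(predictions, max_active = NULL) {
  if (!nrow(predictions)) stop("empty prediction set")
  k <- attr(predictions, "k")
  if (is.null(k)) stop("`predictions` must come from enumerate_combinations()")
  coded <- as.matrix(predictions[, paste0("x", seq_len(k)), drop = FALSE])
  ord <- do.call(order, c(list(predictions$viability, rowSums(coded)),
                          lapply(seq_len(k), function(j) coded[, j])))
  overall <- integer(nrow(predictions))
  overall[ord] <- seq_len(nrow(predictions))
  predictions$overall_rank <- overall
  if (!is.null(max_active))
    predictions <- predictions[predictions$n_active <= max_active, , drop = FALSE]
  predictions <- predictions[order(predictions$overall_rank), , drop = FALSE]
  predictions <- cbind(rank = seq_len(nrow(predictions)), predictions)
  rownames(predictions) <- NULL
  attr(predictions, "k") <- k
  predictions
}

#' Cross-line normalized viability ranking
#'
#' Computes, per combination, `reference viability - target viability`
#' (e.g. MYC-low reference minus MYC-high target): large positive values
#' mark combinations selectively effective in the target line. Ranking is
#' descending on the full enumeration; `max_active` filters afterwards,
#' retaining overall ranks.
#'
#' @param pred_reference,pred_target Enumerations from
#'   [enumerate_combinations()] over the identical coded grid.
#' @param max_active Optional cap on target-line `n_active`.
#' @return Data frame with the coded columns, `viability_reference`,
#'   `viability_target`, `normalized`, `n_active`, `overall_rank` and
#'   `rank`.
#' @export
normalize_between_lines <- function(pred_reference, pred_target,
                                    max_active = NULL) {
  k <- attr(pred_reference, "k")
  if (is.null(k) || !identical(k, attr(pred_target, "k")))
    stop("both predictions must come from enumerate_combinations() with the same k")
  xc <- paste0("x", seq_len(k))
  if (!identical(pred_reference[, xc], pred_target[, xc]))
    stop("enumeration orders differ between the two lines")
  out <- pred_reference[, xc, drop = FALSE]
  out$viability_reference <- pred_reference$viability
  out$viability_target <- pred_target$viability
  out$normalized <- pred_reference$viability - pred_target$viability
  out$n_active <- pred_target$n_active
  coded <- as.matrix(out[, xc, drop = FALSE])
  ord <- do.call(order, c(list(-out$normalized, rowSums(coded)),
                          lapply(seq_len(k), function(j) coded[, j])))
  overall <- integer(nrow(out))
  overall[ord] <- seq_len(nrow(out))
  out$overall_rank <- overall
  if (!is.null(max_active))
    out <- out[out$n_active <= max_active, , drop = FALSE]
  out <- out[order(out$overall_rank), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "k") <- k
  out
}

#' Response-surface grid for one modulator pair
#'
#' Projected viability over a dose grid for modulators `pair`, all other
#' modulators held at the coded level corresponding to dose 0. Dose axes
#' are converted to the coded scale by piecewise-linear interpolation
#' through the three anchor doses ([dose_to_coded()]), so the surface is
#' drawn over concentration axes without asserting any dose-response form
#' the model never saw. Without a modulator table the grid is drawn
#' directly on the coded scale in `[-1, 1]`.
#'
#' @param fit A `qpop_fit`.
#' @param pair Integer vector of two distinct modulator indices.
#' @param modulators Optional modulator list (dose-axis mode).
#' @param n_grid Grid points per axis.
#' @return A `qpop_surface`: axis doses (or coded values), the viability
#'   matrix (rows = first pair member), and the pair labels.
#' @export
surface_grid <- function(fit, pair, modulators = NULL, n_grid = 41L) {
  k <- fit$k
  pair <- as.integer(pair)
  if (length(pair) != 2L || anyDuplicated(pair) || any(pair < 1L | pair > k))
    stop("`pair` must be two distinct indices in 1..", k)
  if (!is.null(modulators)) {
    if (length(modulators) != k) stop("`modulators` must have length k = ", k)
    di <- seq(0, max(modulators[[pair[1]]]$dose_levels), length.out = n_grid)
    dj <- seq(0, max(modulators[[pair[2]]]$dose_levels), length.out = n_grid)
    ci <- dose_to_coded(di, modulators[[pair[1]]])
    cj <- dose_to_coded(dj, modulators[[pair[2]]])
    labs <- .modulator_names(modulators)[pair]
  } else {
    di <- ci <- seq(-1, 1, length.out = n_grid)
    dj <- cj <- seq(-1, 1, length.out = n_grid)
    labs <- paste0("x", pair)
  }
  base <- .zero_coded(modulators, k)
  coded <- matrix(rep(base, each = n_grid^2), n_grid^2, k)
  coded[, pair[1]] <- rep(ci, times = n_grid)
  coded[, pair[2]] <- rep(cj, each = n_grid)
  v <- matrix(predict(fit, coded), n_grid, n_grid)
  structure(list(pair = pair, labels = labs,
                 axis_doses_i = di, axis_doses_j = dj,
                 axis_coded_i = ci, axis_coded_j = cj,
                 viability = v),
            class = "qpop_surface")
}

#' @export
print.qpop_surface <- function(x, ...) {
  cat(sprintf("<qpop_surface> %s x %s: %d x %d grid, viability %.3f .. %.3f\n",
              x$labels[1], x$labels[2], nrow(x$viability), ncol(x$viability),
              min(x$viability), max(x$viability)))
  invisible(x)
}

#' Write a surface grid as long-format TSV
#' @param surface A `qpop_surface`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_surface_tsv <- function(surface, path) {
  df <- expand.grid(dose_i = surface$axis_doses_i,
                    dose_j = surface$axis_doses_j)
  names(df) <- paste0(surface$labels, "_dose")
  df$viability <- as.vector(surface$viability)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Polygonogram pairwise efficacy summary
#'
#' For each modulator pair, predicted inhibition `E = 1 - viability`
#' (floored at `eps` so geometric means stay finite even where projections
#' reach 1) is evaluated at the three combinations with the pair at coded
#' levels \{0, +1\} x \{0, +1\} excluding (0, 0), all other modulators at
#' zero dose, and summarized as a geometric mean. Pairs are then ranked,
#' converted to percentiles among all k(k-1)/2 pairs, and assigned to six
#' equal-width percentile bins (bin 6 = 83.3-100th percentile = most
#' effective). Ties are broken by lexicographic pair index.
#'
#' @param fit A `qpop_fit`.
#' @param modulators Optional modulator list (names the pairs and sets the
#'   zero-dose coded level).
#' @param pair_levels Coded levels forming the 2x2 pair grid; default
#'   `c(0, 1)` (the realized mid/high screen levels).
#' @param eps Efficacy floor.
#' @return Data frame: `i`, `j`, `pair`, `gm_efficacy`, `percentile`,
#'   `bin` (1..6), `bin_label`.
#' @export
polygonogram_summary <- function(fit, modulators = NULL,
                                 pair_levels = c(0, 1), eps = 1e-6) {
  k <- fit$k
  if (k < 2) stop("polygonogram needs at least two modulators")
  base <- .zero_coded(modulators, k)
  nm <- if (is.null(modulators)) paste0("x", seq_len(k))
        else .modulator_names(modulators)
  pairs <- utils::combn(k, 2)
  lev <- expand.grid(a = pair_levels, b = pair_levels)
  lev <- lev[!(lev$a == min(pair_levels) & lev$b == min(pair_levels)), ]
  gm <- vapply(seq_len(ncol(pairs)), function(p) {
    coded <- matrix(rep(base, each = nrow(lev)), nrow(lev), k)
    coded[, pairs[1, p]] <- lev$a
    coded[, pairs[2, p]] <- lev$b
    eff <- pmax(1 - predict(fit, coded), eps)
    exp(mean(log(eff)))
  }, numeric(1))
  np <- ncol(pairs)
  ord <- order(gm, pairs[1, ], pairs[2, ])
  rnk <- integer(np)
  rnk[ord] <- seq_len(np)
  percentile <- 100 * rnk / np
  bin <- pmin(6L, pmax(1L, as.integer(ceiling(percentile / (100 / 6)))))
  labels <- c("least effective", "second least effective",
              "third least effective", "third most effective",
              "second most effective", "most effective")
  data.frame(i = pairs[1, ], j = pairs[2, ],
             pair = paste(nm[pairs[1, ]], nm[pairs[2, ]], sep = "+"),
             gm_efficacy = gm, percentile = percentile,
             bin = bin, bin_label = labels[bin])
}

#' Write a ranking table as TSV
#' @param ranking Output of [rank_combinations()] or
#'   [normalize_between_lines()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_ranking_tsv <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
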