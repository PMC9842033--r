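# Independent oracles used across the suite: explicit-loop evaluation of
# the second-order polynomial and brute-force enumeration/sorting, kept
# free of the package's matrix-based code paths.

# polynomial value at one coded point, term by term
oracle_eval <- function(alpha, beta, B, gamma, x) {
  k <- length(beta)
  v <- alpha
  for (j in seq_len(k)) v <- v + beta[j] * x[j] + gamma[j] * x[j]^2
  if (k >= 2)
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      v <- v + B[i, j] * x[i] * x[j]
  v
}

# assemble the canonical named coefficient vector from parts by explicit
# per-term naming (the names, not the package's column builder, define it)
oracle_coef_vector <- function(alpha, beta, B, gamma) {
  k <- length(beta)
  v <- c(b0 = alpha)
  for (j in seq_len(k)) v[paste0("b_", j)] <- beta[j]
  if (k >= 2)
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      v[paste0("b_", i, "_", j)] <- B[i, j]
  for (j in seq_len(k)) v[paste0("b_", j, "_", j)] <- gamma[j]
  v[quadratic_terms(k)]
}

# seeded random model parts
oracle_random_parts <- function(k, seed) {
  with_seed(seed, {
    B <- matrix(0, k, k)
    B[upper.tri(B)] <- stats::runif(k * (k - 1) / 2, -0.15, 0.1)
    list(alpha = stats::runif(1, 0.6, 1.1),
         beta = stats::runif(k, -0.2, 0.05),
         B = B,
         gamma = stats::runif(k, -0.05, 0.08))
  })
}

# full 3^k enumeration in lexicographic order (x1 most significant),
# built by natural expand.grid followed by an explicit lexicographic sort
oracle_grid <- function(k) {
  g <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), k)))
  colnames(g) <- paste0("x", seq_len(k))
  g[do.call(order, lapply(seq_len(k), function(j) g[, j])), , drop = FALSE]
}

# brute-force overall ranks: ascending value, ties by lower coded total
# then lexicographic coded vector
oracle_overall_ranks <- function(values, grid) {
  k <- ncol(grid)
  ord <- do.call(order, c(list(values, rowSums(grid)),
                          lapply(seq_len(k), function(j) grid[, j])))
  rnk <- integer(length(values))
  rnk[ord] <- seq_along(values)
  rnk
}

# n_active for the default dose convention (level -1 = dose 0)
oracle_n_active <- function(grid) rowSums(grid > -1)

.mod_names <- function(panel) vapply(panel, `[[`, character(1), "name")
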