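# Orthogonal array composite designs (OACD) for combination screens.
#
# The screen design merges a two-level fractional factorial (coded -1/+1,
# good for factor screening) with a three-level orthogonal array (coded
# -1/0/+1, supplies the curvature information a quadratic response-surface
# model needs). For six modulators this gives 2^(6-1) + L18 = 32 + 18 = 50
# runs instead of the 3^6 = 729 exhaustive grid.

#' Define a modulator (drug or splice-switching oligonucleotide)
#'
#' A modulator is anything dosed in the screen: a small-molecule drug or an
#' SSO. Each modulator is screened at three concentrations mapped to coded
#' levels -1/0/+1; a zero dose at level -1 (modulator absent) is the usual
#' convention.
#'
#' @param name Modulator label.
#' @param kind `"small_molecule"` or `"sso"`. SSO doses participate in the
#'   constant-total filler rule of [map_runs_to_doses()].
#' @param dose_levels Numeric length 3, non-decreasing; concentrations for
#'   coded levels -1, 0, +1 (same unit within a modulator).
#' @param unit Concentration unit label, e.g. `"uM"` or `"nM"`.
#' @return An object of class `qpop_modulator`.
#' @export
modulator <- function(name, kind = c("small_molecule", "sso"), dose_levels,
                      unit = "") {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a non-empty string")
  if (length(dose_levels) != 3L || !is.numeric(dose_levels) ||
      any(!is.finite(dose_levels)))
    stop("`dose_levels` must be three finite concentrations")
  if (is.unsorted(dose_levels))
    stop("`dose_levels` must be non-decreasing (levels -1, 0, +1)")
  if (any(dose_levels < 0))
    stop("`dose_levels` must be non-negative")
  structure(list(name = name, kind = kind,
                 dose_levels = as.numeric(dose_levels), unit = unit),
            class = "qpop_modulator")
}

#' @export
print.qpop_modulator <- function(x, ...) {
  cat(sprintf("<modulator> %s (%s): %s %s\n", x$name, x$kind,
              paste(x$dose_levels, collapse = " / "), x$unit))
  invisible(x)
}

#' Default six-modulator screen panel
#'
#' Two standard-of-care small molecules plus four SSOs against MYC synthetic
#' lethal targets, with a 200 nM constant SSO total (negative-control SSO
#' filler). Sorafenib levels are its IC15/IC30; the cabozantinib high dose
#' and the 25 nM SSO mid dose are synthetic placeholders (mid-level doses
#' only matter for bench export, not for fitting on coded levels).
#'
#' @return List of six [modulator()] objects with attribute `constant_total`
#'   (nM) for the SSO filler rule.
#' @export
default_modulator_panel <- function() {
  panel <- list(
    modulator("sorafenib",    "small_molecule", c(0, 4.417, 6.461),  "uM"),
    modulator("cabozantinib", "small_molecule", c(0, 0.2305, 0.461), "uM"),
    modulator("ssCHK1", "sso", c(0, 25, 50), "nM"),
    modulator("ssMAX",  "sso", c(0, 25, 50), "nM"),
    modulator("ssMCL1", "sso", c(0, 25, 50), "nM"),
    modulator("ssBRD4", "sso", c(0, 25, 50), "nM"))
  attr(panel, "constant_total") <- 200
  panel
}

.modulator_names <- function(modulators) {
  vapply(modulators, function(m) m$name, character(1))
}

# ---- two-level fractional factorial part -----------------------------------

.parse_generators <- function(k, generators) {
  letters_k <- LETTERS[seq_len(k)]
  added <- integer(0)
  words <- list()
  for (g in generators) {
    g2 <- gsub("[[:space:]]", "", g)
    parts <- strsplit(g2, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L || nchar(parts[1]) != 1L || !nzchar(parts[2]))
      stop("generator must look like \"F=ABCDE\": ", g)
    lhs <- match(parts[1], letters_k)
    rhs <- match(strsplit(parts[2], "")[[1]], letters_k)
    if (is.na(lhs) || any(is.na(rhs)))
      stop("generator references a factor beyond k = ", k, ": ", g)
    if (lhs %in% rhs || anyDuplicated(rhs))
      stop("inconsistent generator: ", g)
    if (lhs %in% added)
      stop("factor ", parts[1], " defined by more than one generator")
    added <- c(added, lhs)
    words[[length(words) + 1L]] <- rhs
  }
  base <- setdiff(seq_len(k), added)
  for (w in words)
    if (!all(w %in% base))
      stop("generators must be written in terms of base factors only")
  list(base = base, added = added, words = words)
}

#' Build the two-level fractional factorial part of an OACD
#'
#' Returns a regular 2^(k-p) fraction over coded levels -1/+1. The default
#' is the full factorial for k <= 4 and, for k >= 5, the half fraction in
#' which the last factor is the product of all the others (defining relation
#' I = AB...K, the maximum-resolution half fraction; for k = 6 this is the
#' resolution VI fraction I = ABCDEF with 32 runs).
#'
#' @param k Number of factors, 2..8.
#' @param generators Character vector of generators such as `"F=ABCDE"`,
#'   each defining one added factor as a product of base factors. Empty
#'   vector requests the full 2^k factorial.
#' @return Integer matrix (runs x k) with entries -1/+1, columns named
#'   `M1..Mk`, attribute `origin = "fractional_factorial"`.
#' @export
build_fractional_factorial <- function(k, generators = NULL) {
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 2 || k > 8)
    stop("k must be an integer in 2..8")
  k <- as.integer(k)
  if (is.null(generators))
    generators <- if (k <= 4) character(0) else
      sprintf("%s=%s", LETTERS[k], paste(LETTERS[seq_len(k - 1L)], collapse = ""))
  gen <- .parse_generators(k, generators)
  nb <- length(gen$base)
  m <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), nb)))[, rev(seq_len(nb)),
                                                         drop = FALSE]
  runs <- matrix(0L, nrow(m), k)
  runs[, gen$base] <- m
  for (i in seq_along(gen$added)) {
    cols <- match(gen$words[[i]], gen$base)
    runs[, gen$added[i]] <- as.integer(apply(m[, cols, drop = FALSE], 1, prod))
  }
  if (anyDuplicated(runs) > 0)
    stop("inconsistent generator spec: duplicate runs in the fraction")
  dimnames(runs) <- list(NULL, paste0("M", seq_len(k)))
  attr(runs, "origin") <- "fractional_factorial"
  runs
}

# ---- three-level orthogonal array part -------------------------------------

# Textbook L9(3^4), rows in canonical order, levels 1..3.
.L9 <- matrix(c(
  1, 1, 1, 1,
  1, 2, 2, 2,
  1, 3, 3, 3,
  2, 1, 2, 3,
  2, 2, 3, 1,
  2, 3, 1, 2,
  3, 1, 3, 2,
  3, 2, 1, 3,
  3, 3, 2, 1), ncol = 4, byrow = TRUE)

# Textbook L18(2^1 x 3^7): the seven three-level columns, canonical row order.
.L18 <- matrix(c(
  1, 1, 1, 1, 1, 1, 1,
  1, 2, 2, 2, 2, 2, 2,
  1, 3, 3, 3, 3, 3, 3,
  2, 1, 1, 2, 2, 3, 3,
  2, 2, 2, 3, 3, 1, 1,
  2, 3, 3, 1, 1, 2, 2,
  3, 1, 2, 1, 3, 2, 3,
  3, 2, 3, 2, 1, 3, 1,
  3, 3, 1, 3, 2, 1, 2,
  1, 1, 3, 3, 2, 2, 1,
  1, 2, 1, 1, 3, 3, 2,
  1, 3, 2, 2, 1, 1, 3,
  2, 1, 2, 3, 1, 3, 2,
  2, 2, 3, 1, 2, 1, 3,
  2, 3, 1, 2, 3, 2, 1,
  3, 1, 3, 2, 3, 1, 2,
  3, 2, 1, 3, 1, 2, 3,
  3, 3, 2, 1, 2, 3, 1), ncol = 7, byrow = TRUE)

# L27(3^13) from the canonical GF(3) parametrization: runs indexed by
# (a, b, c) in {0,1,2}^3 (a slowest), columns the 13 distinct linear forms
# with leading coefficient 1. Any two columns are independent forms, so the
# array has strength 2.
.L27 <- local({
  base <- as.matrix(expand.grid(c = 0:2, b = 0:2, a = 0:2))[, 3:1]
  coef <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, 2, 0),
    c(0, 0, 1), c(1, 0, 1), c(1, 0, 2), c(0, 1, 1), c(0, 1, 2),
    c(1, 1, 1), c(1, 1, 2), c(1, 2, 1), c(1, 2, 2))
  (base %*% t(coef)) %% 3 + 1
})

#' Build the three-level orthogonal array part of an OACD
#'
#' Selects the smallest standard array accommodating `k` three-level
#' columns -- L9(3^4) for k <= 4, L18 for k <= 7, L27(3^13) for k <= 13 --
#' restricts it to the first `k` columns, and recodes levels 1/2/3 to
#' -1/0/+1. Every column is balanced and every column pair is orthogonal
#' (each ordered level pair occurs equally often).
#'
#' @param k Number of factors (k <= 13).
#' @return Integer matrix (runs x k) with entries -1/0/+1, attribute
#'   `origin = "orthogonal_array"` and attribute `array` naming the table.
#' @export
build_orthogonal_array <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 1)
    stop("k must be a positive integer")
  k <- as.integer(k)
  tab <- if (k <= 4) list("L9", .L9) else if (k <= 7) list("L18", .L18)
         else if (k <= 13) list("L27", .L27)
         else stop("k = ", k, " exceeds the columns of the embedded arrays (max 13)")
  runs <- tab[[2]][, seq_len(k), drop = FALSE] - 2L
  storage.mode(runs) <- "integer"
  dimnames(runs) <- list(NULL, paste0("M", seq_len(k)))
  attr(runs, "origin") <- "orthogonal_array"
  attr(runs, "array") <- tab[[1]]
  runs
}

# ---- composition -----------------------------------------------------------

.new_oacd <- function(runs, origin, ff, oa, modulators = NULL) {
  rownames(runs) <- NULL
  if (!is.null(modulators)) colnames(runs) <- .modulator_names(modulators)
  structure(list(runs = runs, origin = origin,
                 run_id = seq_len(nrow(runs)),
                 ff_part_size = ff, oa_part_size = oa,
                 modulators = modulators),
            class = "oacd_design")
}

#' Compose an orthogonal array composite design
#'
#' Concatenates the two-level fractional factorial part and the three-level
#' orthogonal array part into one screen design with sequential run ids.
#' For k = 6 this yields the 50-run design (32 + 18) used to screen six
#' modulators in place of all 729 level combinations.
#'
#' @param k Number of modulators.
#' @param modulators Optional list of [modulator()] objects of length `k`;
#'   attaches names and dose levels to the design.
#' @param ff_generators Passed to [build_fractional_factorial()].
#' @param center_point Append one all-zero (mid-level) run? Default `FALSE`
#'   (the composite already estimates curvature without it).
#' @param randomize Shuffle run order (seeded)? Default `FALSE` so fixtures
#'   are deterministic; run ids follow the shuffled order.
#' @param seed Seed for `randomize = TRUE`.
#' @return An `oacd_design`: coded run matrix, per-run origin, part sizes.
#' @export
compose_oacd <- function(k, modulators = NULL, ff_generators = NULL,
                         center_point = FALSE, randomize = FALSE, seed = 1L) {
  if (!is.null(modulators)) {
    if (length(modulators) != k)
      stop("`modulators` must have length k = ", k)
    lapply(modulators, function(m)
      if (!inherits(m, "qpop_modulator")) stop("`modulators` must be a list of modulator() objects"))
  }
  ff <- build_fractional_factorial(k, ff_generators)
  oa <- build_orthogonal_array(k)
  runs <- rbind(ff, oa)
  origin <- c(rep("fractional_factorial", nrow(ff)),
              rep("orthogonal_array", nrow(oa)))
  if (center_point) {
    runs <- rbind(runs, rep(0L, k))
    origin <- c(origin, "center")
  }
  if (randomize) {
    ord <- with_seed(seed, sample.int(nrow(runs)))
    runs <- runs[ord, , drop = FALSE]
    origin <- origin[ord]
  }
  attr(runs, "origin") <- NULL
  attr(runs, "array") <- NULL
  .new_oacd(runs, origin, nrow(ff), nrow(oa), modulators)
}

#' @export
print.oacd_design <- function(x, ...) {
  cat(sprintf(
    "<oacd_design> %d runs x %d modulators (%d fractional-factorial + %d orthogonal-array%s)\n",
    nrow(x$runs), ncol(x$runs), x$ff_part_size, x$oa_part_size,
    if (any(x$origin == "center")) " + center" else ""))
  if (!is.null(x$modulators))
    cat("  modulators:", paste(colnames(x$runs), collapse = ", "), "\n")
  invisible(x)
}

# ---- dose mapping ----------------------------------------------------------

#' Map a coded level to its concentration
#' @param coded Coded levels in \{-1, 0, +1\}.
#' @param modulator A [modulator()] object.
#' @return Doses in the modulator's unit.
#' @export
coded_to_dose <- function(coded, modulator) {
  if (any(!coded %in% .coded_levels)) stop("coded levels must be -1, 0 or +1")
  modulator$dose_levels[coded + 2L]
}

#' Map a dose back to the (continuous) coded scale
#'
#' Piecewise-linear interpolation through the three anchor doses
#' (dose_levels -> -1/0/+1), clamped at the ends. Inverts [coded_to_dose()]
#' at the anchors whenever the dose levels are strictly increasing.
#'
#' @param dose Doses in the modulator's unit.
#' @param modulator A [modulator()] object.
#' @return Continuous coded values in `[-1, 1]`.
#' @export
dose_to_coded <- function(dose, modulator) {
  dl <- modulator$dose_levels
  if (any(duplicated(dl)))
    stop("dose levels of ", modulator$name, " are not strictly increasing; coded scale not invertible")
  stats::approx(dl, c(-1, 0, 1), xout = dose, rule = 2)$y
}

#' Replace coded levels by concentrations and apply the SSO filler rule
#'
#' Every run's SSO doses are topped up with a negative-control SSO so the
#' total oligonucleotide load is identical across runs (`constant_total`,
#' default 200 nM for the default panel): filler = constant_total - sum of
#' SSO doses in the run. A run whose SSO doses exceed the constant total is
#' an error.
#'
#' @param design An `oacd_design` whose `modulators` are set, or set via
#'   `modulators`.
#' @param modulators Optional modulator list overriding `design$modulators`.
#' @param constant_total Constant total SSO concentration; defaults to the
#'   panel's `constant_total` attribute. Ignored when the panel has no SSOs.
#' @return Data frame: `run_id`, `origin`, one `<name>_dose` column per
#'   modulator, and `filler_dose` when the panel contains SSOs.
#' @export
map_runs_to_doses <- function(design, modulators = design$modulators,
                              constant_total = attr(modulators, "constant_total")) {
  if (is.null(modulators))
    stop("`design` carries no modulators; supply `modulators`")
  if (length(modulators) != ncol(design$runs))
    stop("modulator count does not match the design")
  doses <- matrix(NA_real_, nrow(design$runs), length(modulators))
  for (j in seq_along(modulators))
    doses[, j] <- coded_to_dose(design$runs[, j], modulators[[j]])
  nm <- .modulator_names(modulators)
  colnames(doses) <- paste0(nm, "_dose")
  out <- data.frame(run_id = design$run_id, origin = design$origin, doses,
                    check.names = FALSE)
  sso <- vapply(modulators, function(m) m$kind == "sso", logical(1))
  if (any(sso)) {
    if (is.null(constant_total))
      stop("panel contains SSOs: `constant_total` is required for the filler rule")
    .check_number(constant_total, "constant_total", positive = TRUE)
    filler <- constant_total - rowSums(doses[, sso, drop = FALSE])
    if (any(filler < -sqrt(.Machine$double.eps)))
      stop("negative filler: SSO doses exceed constant_total = ", constant_total,
           " in run(s) ", paste(design$run_id[filler < 0], collapse = ", "))
    out$filler_dose <- pmax(filler, 0)
  }
  out
}

# ---- design I/O ------------------------------------------------------------

#' Write / read a coded design as TSV
#'
#' Header `run_id, <modulator names...>, origin`; coded levels as integers
#' -1/0/1. `read_design_tsv()` reconstructs the `oacd_design` (part sizes
#' are recovered from the `origin` column), so a design table produced
#' elsewhere, e.g. a published supplementary table, can be dropped in.
#'
#' @param design An `oacd_design`.
#' @param path File path.
#' @param modulators Optional modulator list to attach on read (names must
#'   match the file's columns).
#' @return `write_design_tsv()` returns `path` invisibly; `read_design_tsv()`
#'   an `oacd_design`.
#' @export
write_design_tsv <- function(design, path) {
  df <- data.frame(run_id = design$run_id, design$runs,
                   origin = design$origin, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path, modulators = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("run_id", "origin")
  if (!all(need %in% names(df)))
    stop("design file must have `run_id` and `origin` columns: ", path)
  mod_cols <- setdiff(names(df), need)
  runs <- as.matrix(df[, mod_cols, drop = FALSE])
  storage.mode(runs) <- "integer"
  if (any(!runs %in% .coded_levels))
    stop("coded levels outside {-1,0,1} in ", path)
  if (!all(df$origin %in% c("fractional_factorial", "orthogonal_array", "center")))
    stop("unknown origin values in ", path)
  if (!is.null(modulators) && !identical(.modulator_names(modulators), mod_cols))
    stop("modulator names do not match the design file columns")
  out <- .new_oacd(runs, df$origin,
                   sum(df$origin == "fractional_factorial"),
                   sum(df$origin == "orthogonal_array"),
                   modulators)
  out$run_id <- df$run_id
  out
}
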