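---
title: "Methods: quadratic response-surface prioritization of modulator combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quadratic response-surface prioritization of modulator combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpopr)
```

# The problem and the model

Given a panel of k dose-titratable modulators — small-molecule drugs and
splice-switching oligonucleotides (SSOs) that knock down candidate
synthetic-lethal targets — we want the combination (typically a pair) that
most reduces tumor-cell viability, and we want it specifically in the
disease context (e.g. MYC-deregulated lines) rather than everywhere.
Exhaustive screening of all 3^k dose combinations is impractical; the
working premise of the quadratic phenotypic optimization approach is that
cellular response surfaces are well approximated by a second-order
polynomial in the (coded) doses, so a small designed screen suffices to
estimate the full surface:

$$y = \beta_0 + \sum_j \beta_j x_j + \sum_{i<j} \beta_{ij} x_i x_j +
\sum_j \beta_{jj} x_j^2 .$$

Here $y$ is viability as a fraction of untreated control and $x_j \in
\{-1, 0, +1\}$ codes each modulator's three screening concentrations,
with dose 0 at level $-1$ by convention. Negative $\beta_{ij}$ is the
signature of a synergistic pair. We fit on coded levels rather than raw
concentrations so that coefficients are comparable across modulators whose
doses differ by orders of magnitude (micromolar drugs vs nanomolar SSOs);
this matches how such screens are tabulated and analyzed.

# The design

`compose_oacd()` merges two standard designs:

* a **two-level fractional factorial** over $\{-1,+1\}^k$ for efficient
  factor screening. For $k \le 4$ the full factorial is used; for
  $k \ge 5$ the maximum-resolution half fraction whose last factor is the
  product of all others. For $k = 6$ this is the resolution-VI fraction
  with defining relation $I = ABCDEF$ (32 runs): main effects are aliased
  only with five-factor interactions, which the model family assumes away.
* a **three-level orthogonal array** for curvature: L9 for $k \le 4$,
  L18 for $k \le 7$, L27 for $k \le 13$, restricted to the first $k$
  columns and recoded to $-1/0/+1$. Every column is balanced and every
  column pair orthogonal (verified by brute force in the tests).

For $k=6$ the composition is forced to $32 + 18 = 50$ runs. The L9 and
L18 tables are embedded literally in canonical row order; L27 is generated
from the canonical GF(3) linear-form parametrization (runs indexed by
three base digits, columns the 13 distinct forms with leading coefficient
1), which is the same array without a 27×13 literal. No center point is
added by default (the OA part already carries all three levels); a flag
appends one. Run order is not randomized by default so fixtures are
deterministic; a seeded shuffle is available. The all-low and all-high
rows occur in both parts for $k=6$; duplicates across parts are inherent
to the composition and are kept, as only within-part uniqueness is
guaranteed.

Dose mapping replaces coded levels by concentrations and applies the
**constant-total SSO filler**: each run's SSO doses are topped up with a
negative-control SSO to a constant total (200 nM for the default panel,
which doses four SSOs at 0/25/50 nM — four SSOs at the 50 nM high level
exactly exhaust the total). A run whose SSO load exceeds the total is an
error, not a clamp. In the default panel, sorafenib's levels (0, 4.417,
6.461 µM) are its IC15/IC30; the cabozantinib high dose and the 25 nM SSO
mid dose are synthetic placeholders — the model fits on coded levels, so
mid-level doses matter only for bench export. For small molecules,
`select_drug_levels()` implements the dose-selection rule: screen at
IC15/IC30 when the IC50 is below the clinically achievable plasma
concentration (Cmax), otherwise at 5%/10% of Cmax; the boundary
IC50 = Cmax takes the Cmax branch because the IC rule requires a strictly
lower IC50.

# Fitting and term selection

Replicates enter the least-squares fit as individual observations —
averaging first would discard the error degrees of freedom the F tests
need. `stepwise_fit()` is bidirectional: starting from the intercept, it
adds the excluded term with the smallest partial-F p-value while below
`enter_p`, then removes the worst included term while above `remove_p`,
to a fixed point (guarded by `max_iter`). Defaults `enter_p = 0.05`,
`remove_p = 0.10` are the conventional stepwise-regression defaults of the
tooling such screens are usually analyzed with; both are configurable.
Excluded coefficients are exactly zero, and the reported coefficients are
the OLS refit on the selected support, so re-running selection on its own
fitted values is a fixed point.

Two selection behaviours are worth knowing. First, because each forward
step screens the *minimum* of ~27 candidate p-values against `enter_p`,
pure-noise data admits at least one spurious term on most datasets
(probability about $1 - 0.95^{27}$); the selected null support stays
small, and family-corrected thresholds (e.g. `enter_p = 0.05/27`) keep it
empty almost always. This is a property of the classical stepwise rule
itself, not of this implementation. Second, on noiseless data the residual
sum of squares can reach exactly zero, where partial-F ratios are 0/0;
the implementation resolves these against a relative tolerance
(`1e-10` of the response scale): nothing left to explain means p = 1,
an exact fit gained means p = 0. This makes noiseless support recovery
exact rather than numerically unstable.

Other numerical conventions: a constant response (zero total sum of
squares) reports $R^2 = 0$ with a warning rather than 0/0; viability
values above 1 (stimulation or noise) are retained for fitting; rank
deficiency is reported with the offending columns at fit time, which is
also where duplicated modulator columns surface. Projections are **not**
clipped to $[0,1]$ — a projection may leave the physical range, and
clipping is a reporting option only.

# Projection, ranking and pair summaries

`enumerate_combinations()` evaluates the fitted polynomial at all $3^k$
coded vectors in a canonical lexicographic order; `rank_combinations()`
sorts ascending (rank 1 = most effective) with deterministic tie-breaking
by lower total coded dose, then lexicographic coded vector. Two-modulator
tables filter to combinations with at most two modulators at nonzero dose
*after* overall ranks are assigned, so a filtered rank 3 can carry overall
rank 187. Cross-line selectivity subtracts the target line's projection
from the reference line's per combination and ranks descending; the
filtered (two-modulator) normalized table is the meaningful one here —
on the full enumeration, every combination containing the synergistic
pair at full dose shifts by the same amount, so their relative order
within that block is noise.

Response surfaces for a pair are drawn over concentration axes by mapping
dose to the coded scale piecewise-linearly through the three anchor doses,
with all other modulators at their dose-0 coded level; this reproduces
dose-labeled surface maps without asserting any dose–response shape the
model never saw.

The polygonogram summarizes each pair by the geometric mean of predicted
inhibition $(1 - y)$, floored at $10^{-6}$ so means stay finite when
projections reach 1, over the three combinations with the pair at coded
$\{0,+1\}^2$ excluding $(0,0)$ and everything else at zero dose — the
realized screen levels of that pair alone. The averaging set is a design
choice (the convention in published polygonograms is not fully specified);
it is configurable via `pair_levels`. Pairs are converted to percentiles
among all $\binom{k}{2}$ pairs and binned into six equal sextiles
(bin 6 = 83.3–100th percentile = most effective); published bin legends
of this kind contain an overlapping range that we read as a typo for
equal sextiles. Note that a pair of two strong single agents can out-score
a moderately synergistic pair on this statistic — the geometric mean
rewards total efficacy, not interaction per se.

# Synergy module

`fit_median_effect()` fits $f_a/f_u = (D/D_m)^m$ by least squares on the
linearization $\log_{10}(f_a/f_u) = m \log_{10} D - m \log_{10} D_m$.
Points with $f_a$ exactly 0 or 1 carry no information on the log-odds
scale and are dropped with a warning; the rest are clamped to
$[10^{-3}, 1-10^{-3}]$. The combination index uses the mutually exclusive
two-term form $CI = D_1/D_{x1} + D_2/D_{x2}$ — the standard presentation —
with the mutually nonexclusive third term available behind
`exclusive = FALSE`; the fraction-affected grid defaults to 0.05–0.95 in
steps of 0.05. Combinations are dosed at a fixed ratio, conventionally
the ratio of single-agent IC50s, supplied as input. For Hill-consistent
inputs (equal shape exponents), CI is constant in $f_a$ and equals the
ratio of the combination's $D_m$ to the additive prediction, which is the
closed form the synthetic fixtures are built from and the tests check
against. CI is invariant to consistent rescaling of dose units, and
$CI = \sum_j 1/DRI_j$ holds identically on fixed-ratio designs.

# The synthetic-data generator

Real screens of this kind are proprietary, so validation runs on
manufactured data. Truths are parameterized on the **activity scale**
$a_j = (x_j+1)/2 \in \{0, \tfrac12, 1\}$, where "modulator absent" means
$a_j = 0$ and effects read naturally:
$v = 1 + \sum_j (c_j a_j + q_j a_j^2) + \sum_{i<j} C_{ij} a_i a_j$,
expanded exactly into the coded basis. This avoids the coded-basis quirk
that a bilinear term $x_i x_j$ is active when both modulators are absent
(both at $-1$), and makes untreated viability exactly 1.

* `myc_high` plants one negative interaction $C = -0.40$ between the two
  designated SSO indices (defaults 3 and 6, ssCHK1 and ssBRD4 in the
  default panel order) on top of modest negative single-agent effects
  $c = (-0.30, -0.10, -0.15, -0.12, -0.35, -0.13)$ with mild curvature
  $q = 0.05$; `myc_low` zeroes exactly that interaction. Magnitudes were
  chosen once so that top-ranked two-modulator projections fall in the
  0.25–0.45 band such screens report, and are configuration, not claims
  about any particular cell line. A consequence of fitting a quadratic to
  saturating biology: the `myc_high` truth dips below zero at the all-high
  corner, where the simulator's floor at 0 binds — as a real assay's floor
  would. The ranking properties were verified robust to this.
* `random_sparse` draws seeded sparse effect sets (documented inclusion
  probabilities and ranges in `?make_truth`) and rescales about the
  untreated baseline so the cube-minimum viability is at least 0.15;
  that keeps the floor inert, so noiseless fits recover the generating
  coefficients exactly — the round trip several tests rely on.

Measurement noise is additive Gaussian on viability (default sd 0.05,
MTS-like; 3 replicates), floored at 0. Dose–response fixtures perturb the
dose axis lognormally (default 0.05 log10 units), emulating
serial-dilution error, and fixed-ratio combination curves are constructed
so their true CI equals a requested target under the equal-shape closed
form. All generators are pure functions of parameters and seed.

What the generator does *not* emulate: transfection-efficiency limits,
splicing kinetics, plate/edge effects, heteroscedastic or correlated
replicate noise, and any saturating dose–response shape beyond the
quadratic itself. Passing tests therefore demonstrate that the pipeline's
inference and combinatorics are correct under its own model family — not
that a quadratic is an adequate model for any particular assay.

# Problem sizes and statistical checks

The validation suites use sizes chosen to make the statistical properties
sharp at desk scale: coefficient recovery over 100 seeds at noise sd 0,
0.02 and 0.05 (median absolute coefficient error stays well under the
noise sd; machine precision at zero noise), exact stepwise support
recovery on 20 noiseless sparse truths, ranking equality with a
brute-force oracle over 20 random models, MYC-high/MYC-low discrimination
over 100 seeded screen pairs (the designated pair reaches the top-10
two-modulator list in ≥ 90% of MYC-high screens and ≤ 20% of MYC-low
screens; the normalized ranking places it top-10 in ≥ 90%), synergy
closed forms to machine precision plus a seed-median noisy-recovery check
(the error of a single noisy CI determination is dominated by three
median-effect dose estimates, so the median over 20 seeded fixtures of
3 replicate curves × 9 doses is the stable statistic), and a
1000-simulation null calibration of the per-term F test
(Kolmogorov–Smirnov distance from uniform < 0.05).

# Limitations

* The quadratic surface cannot represent saturation or thresholds;
  extreme-corner projections can leave $[0,1]$ and should be read as
  ordering information, not calibrated viabilities.
* Rankings inherit the model's variance: combinations separated by less
  than the projection noise are effectively tied.
* The polygonogram statistic conflates potency and interaction by design.
* CI/DRI inference assumes the median-effect form fits each curve well
  (check `r` from the linearization) and provides no significance test
  against CI = 1.
* Stepwise selection at per-step thresholds over-selects under the null;
  use family-corrected thresholds when the support itself is the claim.
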