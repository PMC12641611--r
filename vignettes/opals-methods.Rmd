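---
title: "Pairwise logratio analysis with OPALS coordinate systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise logratio analysis with OPALS coordinate systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opals)
```

## The problem

Compositional data — microbiome abundances, metabolite signal integrals,
any table of parts of a whole — carry only relative information. The
elemental unit of that information is the pairwise logratio (PLR)
$\ln(x_i/x_j)$: scale-invariant, tied to exactly two parts, and directly
interpretable. A $D$-part composition has $D(D-1)/2$ of them (up to
reciprocals).

Working with PLRs inside the Aitchison geometry requires embedding each one
in an *orthonormal* logratio coordinate system, because orthonormality is
what guarantees that a regression coefficient attached to a PLR does not
depend on which coordinate system it was extracted from. The classical
embedding — backwards pivot coordinates (bpc), one system per PLR — needs
$D(D-1)/2$ systems, which grows quadratically and becomes unworkable for
omics-scale $D$ (450 parts would already need 101&nbsp;025 systems).

The OPALS construction implemented here packs $D/2$ *non-overlapping* PLRs
into each system, so that $D-1$ systems jointly cover all $D(D-1)/2$ PLRs.
The combinatorial core is a 1-factorization of the complete graph $K_D$,
equivalently a symmetric Latin square with constant diagonal $D$: pair
$\{i,j\}$ belongs to set $k$ exactly when the square has symbol $k$ in cells
$(i,j)$ and $(j,i)$.

## The construction

For even $D$ and $k = 2, \dots, D$ the $k$-th index set collects

* pairs $\{i,j\}$ with $i + j = k + 1$;
* pairs $\{i,j\}$ with $i, j \neq D$ and $i + j = D + k$;
* the pair $\{D, (D+k)/2\}$ ($k$ even) or $\{D, (k+1)/2\}$ ($k$ odd), when
  $k \neq D$;

with degenerate pairs $i = j$ discarded. Each set is a perfect matching of
$\{1,\dots,D\}$, and the $D-1$ sets partition all unordered pairs.
`verify_schedule()` checks the three defining properties explicitly and
`latin_square_from_schedule()` exercises the Latin-square equivalence in
both directions; the test suite runs both for every even $D \le 60$.

```{r}
sched <- opals_schedule(6)
sched$systems[[1]]
latin_square_from_schedule(sched)
```

Each pair set is completed into a full orthonormal system by a sequential
binary partition (SBP): with pairs ordered ascending by their smaller
element, filler balance $m$ contrasts the two parts of pair $m$ against the
pooled parts of all later pairs; the remaining $D/2$ rows are the PLRs
themselves, $\tfrac{1}{\sqrt 2}\ln(x_i/x_j)$. Any completing SBP spans the
same space and yields the same PLR coefficients — the choice here (the
nested pair-versus-rest scheme) is fixed for reproducibility, and the test
suite verifies rotation-equivalence against an alternative published
nesting of the same pair set. Pair orientation is stored with the smaller
part index in the numerator; focal-part re-orientation is a sign flip done
only at aggregation time.

Odd $D$ is a hard error rather than a silent fix: the caller (or the CLI
with `--drop-odd-part`) must name the part to drop, and the dropped part is
recorded in the output. In high-dimensional screening the omission of one
part is immaterial, but it should never be implicit.

## Normalization: orthonormal vs orthogonal

Every constructor takes a `normalization` flag. `"orthonormal"` keeps the
$\sqrt{rs/(r+s)}$ balance constants (contrast rows form an orthonormal
basis; the default for transforms). `"orthogonal"` removes them, so a PLR
coordinate is plainly $\ln(x_i/x_j)$ and its regression coefficient reads
as "effect per unit log fold-change" — the default in the modelling layer,
where interpretability matters more than unit row norms. Coefficients in
the two modes differ only by the dropped constants ($\sqrt 2$ per PLR row).

## Regression and classification over all PLRs

`fit_all_plrs()` fits one model per system — $D-1$ fits instead of
$D(D-1)/2$ — and extracts only the tagged PLR coefficients. For OLS (and
for PLS with a full set of components) these coefficients are *identical*
to those from the corresponding single-PLR bpc systems; the suite asserts
this to $10^{-8}$ for $D \in \{4, 6, 8\}$ at $n = 5D$.

The aggregation identity linking the fine-grained and aggregated views: the
first pivot coordinate of part $l$ collects all PLRs with $x_l$ in the
numerator, and under OLS on orthogonal coordinates

$$\beta_1^{[l]} = \frac{2}{D}\sum_{r \neq l} \beta_1^{(lr)},$$

so the ratio of the summed bpc coefficients to the pivot coefficient is
exactly $D/2$ (on orthonormal coordinates the same argument gives
$\sqrt{D(D-1)/2}$; both forms were derived from the clr-gradient
basis-change argument and are asserted against an independent OLS oracle).
`pivot_bpc_ratio()` computes the ratio for one fit; `ratio_experiment()`
profiles it across PLS component counts on simulated data, where it
stabilises at $D/2$ in the regular $n > D$ case and plateaus below that in
wide ($n < D$) problems.

The PLS kernel is a univariate SIMPLS, which coincides with NIPALS PLS1 for
a single response and with OLS at full rank; the test suite cross-checks
its coefficients against mixOmics to $10^{-8}$. Predictors are centred but
not scaled by default — logratio coordinates already share a scale by
construction — with scaling available as a flag.

### Component selection

`select_components()` performs K-fold cross-validation (default 10),
minimising RMSEP in regression mode or maximising classification accuracy
(0.5 score threshold on the 0/1-coded response) in discriminant mode, then
applies the one-standard-error rule: the simplest count whose criterion is
within one SE (over folds, at the optimum) of the optimum. Fold assignment
is drawn deterministically from the configured seed. Because PLS on
unscaled orthonormal coordinates depends on the data only through inner
products, the CV curve is the same for every system of a basis; the
selection is therefore run once (on the first-part pivot system) and the
chosen count is frozen for all systems and all bootstrap refits.

### Bootstrap standardization and significance

`bootstrap_standardize()` refits all systems on B resamples of the
observations (default B = 1000), with the component count frozen and
predictors/response re-centred per resample (the natural reading of
resampling the whole estimation; re-using the original centring statistics
would treat them as known). Each coefficient is divided by its bootstrap
standard deviation and compared with the $1-\alpha/2$ standard normal
quantile ($\pm 1.959964$ at $\alpha = 0.05$). No multiplicity adjustment is
applied by default — the screening is intentionally per-coefficient — but
`adjust = "BH"` is available. A coefficient with zero bootstrap variance
(e.g. a degenerate, constant coordinate) is flagged non-significant with a
warning rather than producing an undefined ratio.

`aggregate_by_part()` then re-orients every significant record so the focal
part is in the numerator and tallies positive/negative counts; each
significant pair contributes once to each of its two parts with opposite
signs, so totals sum to twice the significant-record count. Ranking is by
descending total, then descending sign imbalance, then label.
`coefficient_distributions()` provides the per-part quantiles and kernel
densities behind the usual coefficient heatmap; degenerate (zero-spread)
value sets fall back to a small fixed bandwidth instead of failing.

## The synthetic-data generator

`simulate_composition()` draws pivot coordinates from a multivariate normal
— zero means, unit variances, uniform covariance 0.7 by default, the
strongly collinear regime in which PLS is the natural estimator — and maps
them to the simplex by the inverse pivot transform (any orthonormal basis
induces the same distribution on the simplex; the pivot basis makes the
round trip `pivot_coordinates(simulate_composition(...))` exact, which the
tests verify to $10^{-10}$). `simulate_response()` adds the linear model
$y = \beta_0 + Z\beta + \varepsilon$ with defaults $\beta_0 = 0$,
$\beta = 1$, $\varepsilon \sim N(0,1)$.

What the generator does *not* emulate: zeros and detection limits,
count-based sampling noise, heavy-tailed or clustered abundance patterns,
and dependence structures beyond an exchangeable covariance. Passing tests
on this generator therefore establish the algebraic and statistical
correctness of the machinery, not robustness to the pathologies of real
sequencing data (zeros must be handled by filtering before analysis —
`filter_min_nonzero()` implements the usual minimum-prevalence rule, and
transforms refuse non-positive entries outright; no imputation is built
in).

## Numerical and design choices

* SBP validation is structural and order-agnostic: row supports must form a
  laminar family whose splits separate all parts, so pivot-style (top-down)
  and backwards-style (bottom-up) tables are both accepted, and malformed
  tables are rejected with the offending row named.
* Orthonormality is enforced to $10^{-10}$ in tests; coordinate evaluation
  is a single matrix product `log(X) %*% t(V)`, valid because contrast rows
  sum to zero.
* Bootstrap resamples with a degenerate response (constant `y`, or a single
  class in discriminant mode) are redrawn, with a cap of 100 attempts.
* The null-calibration check (response independent of the composition)
  pools significance indicators over several independently simulated
  datasets before applying a binomial tolerance around $\alpha$: the
  $D(D-1)/2$ statistics of one dataset share a fit and are strongly
  correlated, so a single dataset's significant fraction is over-dispersed
  relative to a binomial. It uses OLS in the regular $n > D$ regime, where
  the normal reference for bootstrap-standardized coefficients is exact
  enough to make the nominal level meaningful.
* Problem sizes in the test and acceptance suites are desk-scale by design:
  schedules and Latin squares up to $D = 60$, model-fitting identities at
  $D \in \{4,6,8\}$ with $n = 5D$, bootstrap behaviour at $D = 10$,
  $n = 100$, $B = 200$, and the ratio experiment at 5 runs. The identities
  being checked are exact or have known sampling tolerances, so larger
  sizes would add cost without information.

## Limitations

* The construction requires even $D$; odd $D$ costs one part (explicitly).
* The number of PLR *features* remains quadratic in $D$ — OPALS removes the
  quadratic number of coordinate *systems*, not the features; downstream
  selection or regularisation is still the user's concern.
* Significance screening uses fixed normal quantiles on
  bootstrap-standardized coefficients, per coefficient; it is a ranking and
  screening device, not a family-wise error control procedure.
* Robust fits, zero-imputation methods and weighted pivot coordinates are
  out of scope.
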