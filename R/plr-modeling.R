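# Regression / discriminant modelling over OPALS coordinate systems:
# one model per system, pairwise-logratio coefficients pooled across systems,
# bootstrap-standardized and screened for significance, then aggregated per
# compositional part.

#' Modelling configuration
#'
#' Collects the knobs shared by the modelling layer. Defaults follow the
#' screening workflow this package implements: PLS with the component count
#' chosen by 10-fold cross-validation and the one-standard-error rule,
#' B = 1000 bootstrap resamples, significance from the +/- 2.5% standard
#' normal quantiles, and *orthogonal* coordinates (plain `ln(x_i/x_j)`
#' predictors, easier to read than the `1/sqrt(2)`-scaled orthonormal ones).
#'
#' @param model `"pls"` (default; works for wide data, `n < D`) or `"ols"`
#'   (requires `n >` number of coordinates).
#' @param mode `"regression"` for a real response, `"discriminant"` for a
#'   binary response (internally coded 0/1, predicted scores cut at 0.5).
#' @param n_components `"auto"` (cross-validated) or a fixed positive integer.
#' @param cv_folds folds for component selection (default 10).
#' @param component_rule `"one_se"` (default) picks the simplest model within
#'   one standard error of the best cross-validated score; `"min"` picks the
#'   best.
#' @param bootstrap_B number of bootstrap resamples used to standardize
#'   coefficients (default 1000).
#' @param alpha significance level for the normal-quantile cut-offs
#'   (default 0.05).
#' @param seed integer seed driving fold assignment and bootstrap resampling;
#'   `NULL` leaves the RNG state alone.
#' @param normalization `"orthogonal"` (default for modelling) or
#'   `"orthonormal"`; coefficients in the two modes differ by the dropped
#'   normalising constants only.
#' @param center centre predictors and (real) response before fitting
#'   (default `TRUE`; the intercept is then dropped from the model).
#' @param scale scale predictor columns to unit variance (default `FALSE`:
#'   logratio coordinates already share a common scale by construction).
#' @param adjust `"none"` (default) or `"BH"` to additionally apply a
#'   Benjamini-Hochberg correction across all pairwise logratios.
#' @return list of class `fit_config`.
#' @export
fit_config <- function(model = c("pls", "ols"),
                       mode = c("regression", "discriminant"),
                       n_components = "auto", cv_folds = 10L,
                       component_rule = c("one_se", "min"),
                       bootstrap_B = 1000L, alpha = 0.05, seed = NULL,
                       normalization = c("orthogonal", "orthonormal"),
                       center = TRUE, scale = FALSE,
                       adjust = c("none", "BH")) {
  cfg <- list(model = match.arg(model), mode = match.arg(mode),
              n_components = n_components, cv_folds = as.integer(cv_folds),
              component_rule = match.arg(component_rule),
              bootstrap_B = as.integer(bootstrap_B), alpha = alpha,
              seed = seed, normalization = match.arg(normalization),
              center = isTRUE(center), scale = isTRUE(scale),
              adjust = match.arg(adjust))
  if (!identical(cfg$n_components, "auto")) {
    cfg$n_components <- as.integer(cfg$n_components)
    if (cfg$n_components < 1L) stop("n_components must be positive", call. = FALSE)
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (cfg$cv_folds < 2L) stop("cv_folds must be at least 2", call. = FALSE)
  class(cfg) <- "fit_config"
  cfg
}

.prep_response <- function(y, cfg) {
  if (cfg$mode == "discriminant") {
    u <- unique(y)
    if (length(u) != 2L)
      stop("discriminant mode needs a binary response (exactly two distinct values)",
           call. = FALSE)
    lev <- if (is.factor(y)) levels(y) else sort(u)
    y <- as.numeric(y == lev[2L])
    attr(y, "levels") <- as.character(lev)
  } else {
    y <- as.numeric(y)
  }
  y
}

.fit_coords <- function(Z, y, cfg, ncomp = NULL) {
  if (cfg$center) {
    zbar <- colMeans(Z); Z <- sweep(Z, 2L, zbar)
    ybar <- mean(y); y <- y - ybar
  } else { zbar <- rep(0, ncol(Z)); ybar <- 0 }
  if (cfg$scale) {
    zsd <- apply(Z, 2L, stats::sd)
    zsd[zsd == 0] <- 1
    Z <- sweep(Z, 2L, zsd, "/")
  }
  coef <- if (cfg$model == "ols") ols_coef(Z, y) else {
    if (is.null(ncomp)) stop("internal: ncomp unresolved for PLS fit")
    simpls_coef(Z, y, ncomp)
  }
  if (cfg$scale) coef <- coef / zsd
  list(coefficients = as.numeric(coef), center = zbar, y_center = ybar)
}

#' Fit one coordinate system against a response
#'
#' Fits the configured model (OLS or PLS) to all `D - 1` coordinates of a
#' single system. With centring on (the default), predictors and a real
#' response are mean-centred and the intercept is dropped; a binary response
#' in discriminant mode is coded 0/1 first.
#'
#' @param X composition matrix.
#' @param y response vector, length `n`.
#' @param system a [coordinate_system()].
#' @param cfg a [fit_config()].
#' @return list of class `system_fit` with elements `coefficients` (named,
#'   one per coordinate), `system`, `n_components`, `intercept` (response
#'   mean when centred) and `cfg`.
#' @export
fit_system <- function(X, y, system, cfg = fit_config()) {
  X <- .comp_values(X)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  y <- .prep_response(y, cfg)
  Z <- coordinates(X, system)
  ncomp <- NULL
  if (cfg$model == "pls") {
    ncomp <- if (identical(cfg$n_components, "auto"))
      select_components(X, y0 = y, cfg = cfg, system = system)$n_components
    else min(cfg$n_components, ncol(Z), nrow(Z) - 1L)
  }
  fit <- .fit_coords(Z, y, cfg, ncomp)
  structure(list(coefficients = stats::setNames(fit$coefficients, colnames(Z)),
                 system = system, n_components = ncomp,
                 intercept = fit$y_center, cfg = cfg),
            class = "system_fit")
}

#' @export
print.system_fit <- function(x, ...) {
  cat(sprintf("<system_fit: %s%s on %d coordinates>\n", x$cfg$model,
              if (!is.null(x$n_components)) sprintf(" (%d components)", x$n_components) else "",
              length(x$coefficients)))
  print(round(x$coefficients, 4))
  invisible(x)
}

# choose the smallest model whose error is within one SE of the minimum
one_se_choice <- function(err, se_at_min) {
  best <- which.min(err)
  min(which(err <= err[best] + se_at_min))
}

#' Cross-validated choice of the number of PLS components
#'
#' K-fold cross-validation over component counts. In regression mode the
#' criterion is the root-mean-square error of prediction (RMSEP); in
#' discriminant mode it is classification accuracy at the 0.5 score
#' threshold. Under the one-standard-error rule (the default) the chosen
#' count is the smallest whose criterion is within one standard error (over
#' folds, at the optimum) of the optimum. Fold assignment is drawn
#' deterministically from `cfg$seed`.
#'
#' @inheritParams fit_system
#' @param system coordinate system whose coordinates are cross-validated;
#'   defaults to the first-part pivot system. PLS on unscaled orthonormal
#'   coordinates is rotation-invariant, so any system of the same
#'   normalization gives the same curve.
#' @param max_components upper bound on the component grid (default
#'   `min(D - 1, 15)` capped by the training-fold size).
#' @param y0 internal: response already passed through the binary coding.
#' @return list with `n_components`, and `cv` — a data frame with one row per
#'   component count: the criterion (`rmsep` or `accuracy`) and its
#'   standard error over folds.
#' @export
select_components <- function(X, y, cfg = fit_config(), system = NULL,
                              max_components = NULL, y0 = NULL) {
  X <- .comp_values(X)
  y <- if (is.null(y0)) .prep_response(y, cfg) else y0
  n <- nrow(X)
  if (is.null(system))
    system <- pivot_system(ncol(X), 1L, cfg$normalization, parts = colnames(X))
  Z <- coordinates(X, system)
  K <- min(cfg$cv_folds, n)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  fold <- sample(rep_len(seq_len(K), n))
  amax <- min(ncol(Z), n - max(table(fold)) - 1L, 15L)
  if (!is.null(max_components)) amax <- min(amax, max_components)
  if (amax < 1L) stop("too few observations per fold for any PLS component",
                      call. = FALSE)
  err <- matrix(NA_real_, K, amax)  # per-fold criterion per component count
  for (f in seq_len(K)) {
    tr <- fold != f
    ztr <- Z[tr, , drop = FALSE]; ytr <- y[tr]
    zbar <- colMeans(ztr); ybar <- mean(ytr)
    if (stats::var(ytr) == 0)
      stop("a cross-validation fold has a constant training response", call. = FALSE)
    B <- simpls_paths(sweep(ztr, 2L, zbar), ytr - ybar, amax)
    pred <- ybar + sweep(Z[!tr, , drop = FALSE], 2L, zbar) %*% B
    obs <- y[!tr]
    for (a in seq_len(ncol(B))) {
      err[f, a] <- if (cfg$mode == "regression")
        sqrt(mean((obs - pred[, a])^2))
      else mean((pred[, a] >= 0.5) == (obs == 1))
    }
  }
  # components dropped by rank exhaustion in some fold are not comparable
  keep <- colSums(is.na(err)) == 0L
  err <- err[, keep, drop = FALSE]
  crit <- colMeans(err)
  if (cfg$mode == "discriminant") crit <- -crit  # maximise accuracy
  best <- which.min(crit)
  se <- stats::sd(err[, best]) / sqrt(K)
  chosen <- if (cfg$component_rule == "one_se") one_se_choice(crit, se) else best
  cv <- data.frame(n_components = seq_len(length(crit)),
                   criterion = if (cfg$mode == "regression") colMeans(err) else colMeans(err),
                   se = apply(err, 2L, stats::sd) / sqrt(K))
  names(cv)[2L] <- if (cfg$mode == "regression") "rmsep" else "accuracy"
  list(n_components = as.integer(chosen), cv = cv)
}

#' Pairwise-logratio coefficients from all OPALS systems
#'
#' Fits one model per OPALS coordinate system (`D - 1` fits) and collects the
#' coefficient of every tagged pairwise-logratio coordinate — exactly
#' `D(D-1)/2` records, one per unordered part pair, stored with the smaller
#' part index in the numerator. For OLS (and full-rank PLS) these
#' coefficients are identical to the ones obtained from the `D(D-1)/2`
#' single-pair backwards-pivot systems, at a fraction of the cost.
#'
#' @inheritParams fit_system
#' @param basis optionally a precomputed [opals_basis()] (its normalization
#'   must match `cfg`).
#' @param drop_part for an odd number of parts: index or label of the part to
#'   remove before construction (recorded in the result); without it an odd
#'   `D` is an error.
#' @return data frame of class `plr_records` with columns `part_i`, `part_j`
#'   (labels, numerator first), `i`, `j` (indices), `system_k`,
#'   `coefficient`; attributes `n_components`, `cfg`, `dropped_part`.
#' @export
fit_all_plrs <- function(X, y, cfg = fit_config(), basis = NULL,
                         drop_part = NULL) {
  X <- .comp_values(X)
  if (!is.null(drop_part)) {
    d <- .part_index(X, drop_part)
    dropped <- colnames(X)[d]
    X <- X[, -d, drop = FALSE]
  } else dropped <- NULL
  .check_even_D(ncol(X))
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  y <- .prep_response(y, cfg)
  if (is.null(basis))
    basis <- opals_basis(ncol(X), cfg$normalization, parts = colnames(X))
  else if (!identical(attr(basis, "normalization"), cfg$normalization))
    stop("basis normalization does not match the configuration", call. = FALSE)
  ncomp <- NULL
  if (cfg$model == "pls") {
    ncomp <- if (identical(cfg$n_components, "auto"))
      select_components(X, y0 = y, cfg = cfg)$n_components
    else min(cfg$n_components, ncol(X) - 1L, nrow(X) - 1L)
  }
  recs <- lapply(basis, function(sys) {
    Z <- coordinates(X, sys)
    fit <- .fit_coords(Z, y, cfg, ncomp)
    rr <- sys$row_roles
    tag <- which(rr$role == "pairwise_logratio")
    co <- fit$coefficients[tag]
    num <- rr$num[tag]; den <- rr$den[tag]
    flip <- num > den  # store numerator = smaller index
    co[flip] <- -co[flip]
    i <- pmin(num, den); j <- pmax(num, den)
    data.frame(part_i = colnames(X)[i], part_j = colnames(X)[j],
               i = i, j = j, system_k = sys$k, coefficient = co)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "n_components") <- ncomp
  attr(out, "cfg") <- cfg
  attr(out, "dropped_part") <- dropped
  class(out) <- c("plr_records", class(out))
  out
}

#' Bootstrap-standardized pairwise-logratio screening
#'
#' The complete screening workflow: fit all pairwise-logratio coefficients
#' with [fit_all_plrs()], then refit on `B` bootstrap resamples of the
#' observations (component count frozen at the full-data choice, predictors
#' and response re-centred per resample), standardize each coefficient by its
#' bootstrap standard deviation, and flag significance where the standardized
#' value exceeds the `1 - alpha/2` standard normal quantile in absolute value
#' (1.959964 at the default `alpha = 0.05`). Resamples with a constant
#' response are redrawn (up to 100 attempts each).
#'
#' @inheritParams fit_all_plrs
#' @return `plr_records` data frame with additional columns `bootstrap_sd`,
#'   `standardized`, `significant`, `sign`; attribute `cutoff` holds the
#'   normal quantile used. A coefficient whose bootstrap distribution is
#'   degenerate (`bootstrap_sd = 0`) gets `standardized = NA` and is flagged
#'   non-significant, with a warning.
#' @export
bootstrap_standardize <- function(X, y, cfg = fit_config(), basis = NULL,
                                  drop_part = NULL) {
  if (cfg$bootstrap_B < 2L) stop("bootstrap_B must be at least 2", call. = FALSE)
  X <- .comp_values(X)
  if (!is.null(drop_part)) {
    d <- .part_index(X, drop_part)
    dropped <- colnames(X)[d]
    X <- X[, -d, drop = FALSE]
  } else dropped <- NULL
  .check_even_D(ncol(X))
  y <- .prep_response(y, cfg)
  if (is.null(basis))
    basis <- opals_basis(ncol(X), cfg$normalization, parts = colnames(X))
  records <- fit_all_plrs(X, y, cfg, basis = basis)
  ncomp <- attr(records, "n_components")
  cfg_fixed <- cfg
  if (!is.null(ncomp)) cfg_fixed$n_components <- ncomp
  n <- nrow(X)
  # coordinates are per-sample, so resampling rows of Z == resampling rows of X
  Zs <- lapply(basis, function(sys) coordinates(X, sys))
  tags <- lapply(basis, function(sys) {
    rr <- sys$row_roles
    tag <- which(rr$role == "pairwise_logratio")
    list(tag = tag, flip = rr$num[tag] > rr$den[tag])
  })
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  B <- cfg$bootstrap_B
  boot <- matrix(NA_real_, B, nrow(records))
  redraws <- 0L
  for (b in seq_len(B)) {
    for (try in seq_len(101L)) {
      idx <- sample.int(n, n, replace = TRUE)
      ok <- if (cfg$mode == "discriminant") length(unique(y[idx])) == 2L
            else stats::var(y[idx]) > 0
      if (ok) break
      redraws <- redraws + 1L
      if (try == 101L) stop("bootstrap resampling failed: response degenerate in 100 consecutive redraws",
                            call. = FALSE)
    }
    yb <- y[idx]
    col0 <- 0L
    for (s in seq_along(Zs)) {
      fit <- .fit_coords(Zs[[s]][idx, , drop = FALSE], yb, cfg_fixed, ncomp)
      co <- fit$coefficients[tags[[s]]$tag]
      co[tags[[s]]$flip] <- -co[tags[[s]]$flip]
      boot[b, col0 + seq_along(co)] <- co
      col0 <- col0 + length(co)
    }
  }
  if (redraws > 0L)
    message(sprintf("%d degenerate bootstrap resample(s) redrawn", redraws))
  sdv <- apply(boot, 2L, stats::sd)
  cutoff <- stats::qnorm(1 - cfg$alpha / 2)
  records$bootstrap_sd <- sdv
  records$standardized <- ifelse(sdv > 0, records$coefficient / sdv, NA_real_)
  if (any(sdv == 0))
    warning(sprintf("%d coefficient(s) had zero bootstrap variance; flagged non-significant",
                    sum(sdv == 0)))
  records$significant <- !is.na(records$standardized) &
    abs(records$standardized) > cutoff
  if (cfg$adjust == "BH") {
    p <- 2 * stats::pnorm(-abs(records$standardized))
    records$p_adjusted <- stats::p.adjust(p, method = "BH")
    records$significant <- !is.na(records$p_adjusted) & records$p_adjusted < cfg$alpha
  }
  records$sign <- ifelse(records$coefficient >= 0, "+", "-")
  attr(records, "cutoff") <- cutoff
  attr(records, "cfg") <- cfg
  attr(records, "n_components") <- ncomp
  attr(records, "dropped_part") <- dropped
  records
}

.records_for_part <- function(records, part_label) {
  as_num <- records$part_i == part_label
  as_den <- records$part_j == part_label
  r <- records[as_num | as_den, , drop = FALSE]
  flip <- r$part_j == part_label   # put the focal part in the numerator
  r$coefficient[flip] <- -r$coefficient[flip]
  if (!is.null(r$standardized)) r$standardized[flip] <- -r$standardized[flip]
  if (!is.null(r$sign)) r$sign[flip] <- ifelse(r$sign[flip] == "+", "-", "+")
  other <- ifelse(flip, r$part_i, r$part_j)
  r$part_i <- part_label; r$part_j <- other
  r
}

#' Per-part summary of significant pairwise logratios
#'
#' For each part, every significant record containing it is re-oriented so
#' the part sits in the numerator, and the counts of positive and negative
#' coefficients are tallied. Because each significant pair contributes once
#' to each of its two parts (with opposite signs), the totals sum to twice
#' the number of significant records. Rows are sorted by descending total,
#' ties broken by descending sign imbalance `|positive - negative|`, then by
#' label.
#'
#' @param records output of [bootstrap_standardize()] (or any `plr_records`
#'   with `significant` and numeric `coefficient`).
#' @param parts optional character vector fixing the set/order of parts to
#'   report (defaults to all parts present in `records`).
#' @return data frame of class `part_summary`: `part`, `total`, `positive`,
#'   `negative`, `rank`.
#' @export
aggregate_by_part <- function(records, parts = NULL) {
  if (is.null(records$significant))
    stop("records carry no significance flags; run bootstrap_standardize() first",
         call. = FALSE)
  if (is.null(parts)) parts <- sort(unique(c(records$part_i, records$part_j)))
  sig <- records[records$significant, , drop = FALSE]
  tab <- do.call(rbind, lapply(parts, function(p) {
    r <- .records_for_part(sig, p)
    pos <- sum(r$coefficient > 0); neg <- sum(r$coefficient < 0)
    data.frame(part = p, total = pos + neg, positive = pos, negative = neg)
  }))
  ord <- order(-tab$total, -abs(tab$positive - tab$negative), tab$part)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  class(tab) <- c("part_summary", class(tab))
  tab
}

#' Per-part distributions of standardized coefficients
#'
#' For each part, the `D - 1` standardized coefficients of the pairwise
#' logratios containing it (re-oriented so the part is in the numerator),
#' summarised by quantiles and a kernel density estimate on a grid shared
#' across parts — the ingredients of the usual coefficient-distribution
#' heatmap. Parts are ordered as in [aggregate_by_part()].
#'
#' @inheritParams aggregate_by_part
#' @param grid_n number of grid points for the kernel density (default 256).
#' @param probs quantiles to report.
#' @return list with `parts` (ordered), `values` (named list of standardized
#'   coefficient vectors), `quantiles` (data frame), `grid` and `density`
#'   (matrix, parts x grid; each row integrates to 1).
#' @export
coefficient_distributions <- function(records, grid_n = 256L,
                                      probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  if (is.null(records$standardized))
    stop("records carry no standardized coefficients; run bootstrap_standardize() first",
         call. = FALSE)
  ord <- aggregate_by_part(records)
  parts <- ord$part
  vals <- lapply(parts, function(p) {
    v <- .records_for_part(records, p)$standardized
    v <- v[!is.na(v)]
    if (length(v) < 2L)
      stop(sprintf("part '%s' has fewer than two usable records", p), call. = FALSE)
    v
  })
  names(vals) <- parts
  allv <- unlist(vals)
  bw_of <- function(v) {
    bw <- tryCatch(stats::bw.nrd0(v), error = function(e) 0)
    if (!is.finite(bw) || bw <= 0) bw <- max(abs(mean(v)) * 0.01, 0.01)
    bw
  }
  pad <- 3 * max(vapply(vals, bw_of, 1))
  grid <- seq(min(allv) - pad, max(allv) + pad, length.out = grid_n)
  dens <- t(vapply(vals, function(v) {
    d <- stats::density(v, bw = bw_of(v), from = grid[1L],
                        to = grid[grid_n], n = grid_n)
    d$y
  }, numeric(grid_n)))
  rownames(dens) <- parts
  q <- t(vapply(vals, stats::quantile, numeric(length(probs)), probs = probs))
  list(parts = parts, values = vals,
       quantiles = data.frame(part = parts, q, check.names = FALSE,
                              row.names = NULL),
       grid = grid, density = dens)
}

#' Ratio linking pivot and backwards-pivot regression coefficients
#'
#' Fits (a) the pivot-coordinate model with the given part in the lead and
#' (b) the `D - 1` backwards-pivot models pairing that part with every other
#' part as divisor, then returns the ratio of the summed first
#' backwards-pivot coefficients to the first pivot coefficient. For OLS (or
#' full-rank PLS) on *orthogonal* coordinates the ratio is exactly `D/2` —
#' the first pivot coefficient aggregates the pairwise-logratio coefficients
#' up to that factor; on orthonormal coordinates it is
#' `sqrt(D (D - 1) / 2)`.
#'
#' @inheritParams fit_system
#' @param lead focal part, index or label.
#' @return list with `ratio`, `pivot_coefficient`, `bpc_sum`,
#'   `bpc_coefficients` (named by divisor part). A near-zero pivot
#'   coefficient yields `ratio = NA` with a warning.
#' @export
pivot_bpc_ratio <- function(X, y, lead = 1L, cfg = fit_config()) {
  X <- .comp_values(X)
  l <- .part_index(X, lead)
  D <- ncol(X)
  psys <- pivot_system(D, l, cfg$normalization, parts = colnames(X))
  b_pivot <- fit_system(X, y, psys, cfg)$coefficients[1L]
  others <- setdiff(seq_len(D), l)
  b_bpc <- vapply(others, function(r) {
    sys <- bpc_system(D, l = l, r = r, normalization = cfg$normalization,
                      parts = colnames(X))
    fit_system(X, y, sys, cfg)$coefficients[1L]
  }, 1)
  names(b_bpc) <- colnames(X)[others]
  s <- sum(b_bpc)
  if (abs(b_pivot) < 1e-12 * max(1, abs(s))) {
    warning("pivot coefficient is numerically zero; ratio undefined")
    ratio <- NA_real_
  } else ratio <- s / b_pivot
  list(ratio = unname(ratio), pivot_coefficient = unname(b_pivot),
       bpc_sum = s, bpc_coefficients = b_bpc)
}
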