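# Synthetic compositional data: a normal distribution on the simplex,
# expressed in pivot coordinates, plus the linear-response generator and the
# pivot/backwards-pivot ratio experiment used to study the aggregation
# identity under PLS.

#' Simulate compositions from a normal distribution on the simplex
#'
#' Draws `n` samples of `D - 1` pivot coordinates from a multivariate normal
#' distribution and maps them back to the simplex through the inverse pivot
#' transform, closing each row to sum 1. The defaults — zero means, unit
#' variances, uniform covariance 0.7 between coordinates — give strongly
#' correlated coordinates, the regime in which partial least squares is the
#' natural estimator.
#'
#' @param n number of samples.
#' @param D number of parts (`D >= 2`).
#' @param mean coordinate mean vector, length `D - 1` or scalar (default 0).
#' @param cov coordinate covariance: a `(D-1) x (D-1)` symmetric positive
#'   definite matrix, or `NULL` for the default compound-symmetric matrix
#'   with unit variances and off-diagonal `cov_offdiag`.
#' @param cov_offdiag off-diagonal value of the default covariance
#'   (default 0.7).
#' @param seed optional integer seed.
#' @return composition matrix (`n x D`, rows summing to 1) with attribute
#'   `coordinates`, the drawn `n x (D-1)` pivot-coordinate matrix.
#' @export
simulate_composition <- function(n, D, mean = 0, cov = NULL, cov_offdiag = 0.7,
                                 seed = NULL) {
  if (D < 2L) stop("D must be at least 2", call. = FALSE)
  p <- D - 1L
  if (length(mean) == 1L) mean <- rep(mean, p)
  if (length(mean) != p) stop("mean must have length D - 1", call. = FALSE)
  if (is.null(cov)) cov <- matrix(cov_offdiag, p, p) + diag(1 - cov_offdiag, p)
  if (!isSymmetric(unname(cov), tol = 1e-10))
    stop("covariance must be symmetric", call. = FALSE)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(abs(ev)))
    stop("covariance must be positive definite", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  Z <- MASS::mvrnorm(n, mu = mean, Sigma = cov)
  Z <- matrix(Z, nrow = n)  # mvrnorm drops dims when n == 1
  X <- inverse_pivot(Z)
  attr(X, "coordinates") <- Z
  X
}

#' Inverse pivot transform
#'
#' Maps an `n x (D-1)` matrix of pivot coordinates back to compositions on
#' the unit simplex: `X = closure(exp(Z V))` where `V` is the orthonormal
#' pivot contrast matrix. Exactly inverts [pivot_coordinates()] with the
#' first part in the lead.
#'
#' @param Z numeric matrix of pivot coordinates.
#' @param parts optional part labels for the result.
#' @return composition matrix with rows summing to 1.
#' @export
inverse_pivot <- function(Z, parts = NULL) {
  Z <- as.matrix(Z)
  D <- ncol(Z) + 1L
  V <- pivot_system(D, 1L, "orthonormal")$contrast
  X <- exp(Z %*% V)
  X <- X / rowSums(X)
  as_composition(X, parts = parts)
}

#' Simulate a linear response on coordinates
#'
#' `y = beta0 + Z beta + eps`, with `eps ~ N(0, noise_sd^2)` i.i.d. The
#' defaults (`beta0 = 0`, all slopes 1, unit noise) make every coordinate an
#' equally weighted predictor.
#'
#' @param Z numeric `n x p` coordinate matrix (e.g. the `coordinates`
#'   attribute of [simulate_composition()]).
#' @param beta0 intercept.
#' @param beta slope vector, length `p` or scalar (recycled).
#' @param noise_sd standard deviation of the noise (`>= 0`).
#' @param seed optional integer seed.
#' @return numeric response vector of length `n`.
#' @export
simulate_response <- function(Z, beta0 = 0, beta = 1, noise_sd = 1,
                              seed = NULL) {
  Z <- as.matrix(Z)
  if (length(beta) == 1L) beta <- rep(beta, ncol(Z))
  if (length(beta) != ncol(Z)) stop("beta must have length ncol(Z)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  eps <- if (noise_sd > 0) stats::rnorm(nrow(Z), 0, noise_sd) else 0
  as.numeric(beta0 + Z %*% beta + eps)
}

#' Pivot/backwards-pivot coefficient ratio across PLS components
#'
#' Monte Carlo experiment: simulate simplex-normal compositions and a linear
#' pivot-coordinate response, fit PLS models in pivot coordinates and in all
#' backwards-pivot systems for each lead part, and record — per number of
#' PLS components — the ratio of the summed first backwards-pivot
#' coefficients to the first pivot coefficient. In the regular case
#' (`n > D`, components ~ `D - 1`, orthogonal coordinates) the curve
#' stabilises at `D/2`; in wide problems (`n < D`) it plateaus below that.
#'
#' @param n samples per run.
#' @param D parts.
#' @param components integer vector of PLS component counts to profile
#'   (default `1:min(D - 1, 15)`).
#' @param runs number of simulation runs (default 20).
#' @param leads part indices to use as leads (default: all, capped at `D`).
#' @param noise_sd,cov_offdiag passed to the generators.
#' @param normalization coordinate normalization for the fitted models
#'   (default `"orthogonal"`, under which the reference level is `D/2`).
#' @param seed integer seed (one stream across runs).
#' @return data frame with one row per component count: `n_components`,
#'   `mean_ratio`, `sd_ratio` (across runs and leads), and attribute
#'   `per_lead`, the full runs x leads x components array.
#' @export
ratio_experiment <- function(n, D, components = NULL, runs = 20L,
                             leads = seq_len(D), noise_sd = 1,
                             cov_offdiag = 0.7,
                             normalization = c("orthogonal", "orthonormal"),
                             seed = NULL) {
  normalization <- match.arg(normalization)
  if (runs < 1L) stop("runs must be at least 1", call. = FALSE)
  amax <- min(D - 1L, n - 1L, 15L)
  if (is.null(components)) components <- seq_len(amax)
  components <- sort(unique(as.integer(components)))
  if (any(components < 1L) || any(components > min(D - 1L, n - 1L)))
    stop("component counts must lie in 1..min(D-1, n-1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  piv_sys <- lapply(leads, function(l) pivot_system(D, l, normalization))
  bpc_sys <- lapply(leads, function(l)
    lapply(setdiff(seq_len(D), l), function(r) bpc_system(D, l, r, normalization)))
  res <- array(NA_real_, c(runs, length(leads), length(components)),
               dimnames = list(NULL, paste0("lead", leads),
                               paste0("A", components)))
  ratio_path <- function(Z, y, amax) {
    Zc <- sweep(Z, 2L, colMeans(Z)); yc <- y - mean(y)
    B <- simpls_paths(Zc, yc, amax)   # first-coordinate coefficient per count
    path <- rep(NA_real_, amax)
    path[seq_len(ncol(B))] <- B[1L, ]
    path[is.na(path)] <- path[ncol(B)]  # rank exhausted: fit no longer changes
    path
  }
  amax_fit <- max(components)
  for (run in seq_len(runs)) {
    X <- simulate_composition(n, D, cov_offdiag = cov_offdiag)
    Zp <- attr(X, "coordinates")
    y <- simulate_response(Zp, noise_sd = noise_sd)
    logX <- log(unclass(X))
    for (li in seq_along(leads)) {
      piv <- ratio_path(logX %*% t(piv_sys[[li]]$contrast), y, amax_fit)
      ssum <- rep(0, amax_fit)
      for (bs in bpc_sys[[li]])
        ssum <- ssum + ratio_path(logX %*% t(bs$contrast), y, amax_fit)
      res[run, li, ] <- ifelse(abs(piv[components]) < 1e-12, NA_real_,
                               ssum[components] / piv[components])
    }
  }
  flat <- matrix(res, nrow = runs * length(leads))
  out <- data.frame(n_components = components,
                    mean_ratio = colMeans(flat, na.rm = TRUE),
                    sd_ratio = apply(flat, 2L, stats::sd, na.rm = TRUE))
  attr(out, "per_lead") <- res
  out
}
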