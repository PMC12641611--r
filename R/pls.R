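# Univariate SIMPLS (de Jong 1993). For a single response, SIMPLS and
# NIPALS PLS1 coincide, and at full rank the fit equals ordinary least
# squares. A minimal dense implementation keeps the bootstrap loops
# (B resamples x D-1 systems) cheap.

# X: n x p matrix, y: length-n vector, both already centred (and optionally
# scaled) by the caller. Returns the p x A matrix of coefficient paths:
# column a = coefficients using a components.
simpls_paths <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, p, n - 1L)
  if (ncomp < 1L) stop("need at least one PLS component", call. = FALSE)
  S <- crossprod(X, y)                      # p x 1
  R <- matrix(0, p, ncomp)                  # weights (X-side)
  TT <- matrix(0, n, ncomp)                 # scores
  Q <- numeric(ncomp)                       # y loadings
  V <- matrix(0, p, ncomp)                  # orthonormalised X loadings
  B <- matrix(0, p, ncomp)
  for (a in seq_len(ncomp)) {
    r <- S
    t <- X %*% r
    nt <- sqrt(sum(t^2))
    if (nt < .Machine$double.eps^0.75) {    # residual covariance exhausted
      ncomp <- a - 1L
      break
    }
    t <- t / nt; r <- r / nt
    pl <- crossprod(X, t)                   # X loading
    q <- sum(y * t)
    v <- pl
    if (a > 1L) v <- v - V[, seq_len(a - 1L), drop = FALSE] %*%
        crossprod(V[, seq_len(a - 1L), drop = FALSE], pl)
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; TT[, a] <- t; Q[a] <- q; V[, a] <- v
    B[, a] <- if (a == 1L) R[, 1L] * Q[1L] else
      R[, seq_len(a), drop = FALSE] %*% Q[seq_len(a)]
  }
  if (ncomp < 1L) stop("degenerate fit: predictors carry no covariance with the response",
                       call. = FALSE)
  B[, seq_len(ncomp), drop = FALSE]
}

# Coefficients with exactly ncomp components (or fewer if rank runs out).
simpls_coef <- function(X, y, ncomp) {
  B <- simpls_paths(X, y, ncomp)
  B[, ncol(B)]
}

# OLS coefficients on centred data without intercept; errors when the
# problem is rank deficient.
ols_coef <- function(X, y) {
  if (nrow(X) <= ncol(X))
    stop("OLS needs n > number of coordinates; use model = \"pls\" for wide data",
         call. = FALSE)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X))
    stop("rank-deficient OLS fit; use model = \"pls\"", call. = FALSE)
  fit$coefficients
}
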