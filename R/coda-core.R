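#' @keywords internal
"_PACKAGE"

# ---- composition container ---------------------------------------------

#' Validate a composition matrix
#'
#' Coerces a matrix or data frame of strictly positive relative abundances
#' into the validated numeric matrix used throughout the package: `n` samples
#' in rows, `D` parts in columns, unique part labels. Compositions carry only
#' relative information, so no closure (row-sum normalisation) is imposed;
#' every logratio computed downstream is invariant to the scale of each row.
#'
#' @param x numeric matrix or data frame, samples in rows, parts in columns.
#' @param parts optional character vector of `D` unique part labels
#'   (defaults to column names, or `x1..xD`).
#' @param samples optional character vector of `n` sample labels.
#' @param require_positive if `TRUE` (default) any entry `<= 0` is an error.
#'   Set `FALSE` only for raw tables that still await zero filtering
#'   (see [filter_min_nonzero()]); all transforms re-check positivity.
#' @return numeric matrix of class `composition_matrix` with part labels as
#'   column names.
#' @examples
#' X <- as_composition(matrix(c(1, 2, 3, 4, 5, 6), nrow = 2))
#' @export
as_composition <- function(x, parts = NULL, samples = NULL,
                           require_positive = TRUE) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("'x' must be a numeric matrix or data frame", call. = FALSE)
  if (ncol(x) < 2L) stop("a composition needs at least D = 2 parts", call. = FALSE)
  if (nrow(x) < 1L) stop("need at least one sample", call. = FALSE)
  if (anyNA(x)) stop("composition contains missing values", call. = FALSE)
  if (require_positive && any(x <= 0)) {
    bad <- which(x <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("compositional parts must be strictly positive; first offender at row %d, column %d (value %g)",
                 bad[1L], bad[2L], x[bad[1L], bad[2L]]), call. = FALSE)
  }
  if (is.null(parts)) parts <- colnames(x)
  if (is.null(parts)) parts <- paste0("x", seq_len(ncol(x)))
  if (anyDuplicated(parts)) stop("part labels must be unique", call. = FALSE)
  if (length(parts) != ncol(x)) stop("length(parts) != ncol(x)", call. = FALSE)
  colnames(x) <- parts
  if (!is.null(samples)) rownames(x) <- samples
  class(x) <- c("composition_matrix", class(unclass(x)))
  x
}

.comp_values <- function(X) {
  if (inherits(X, "composition_matrix")) return(unclass(X))
  unclass(as_composition(X))
}

.check_positive <- function(X) {
  if (any(X <= 0))
    stop("logratio transforms require strictly positive entries; filter or drop zero-laden parts first",
         call. = FALSE)
  invisible(X)
}

.part_index <- function(X, part) {
  D <- ncol(X)
  if (is.character(part)) {
    i <- match(part, colnames(X))
    if (is.na(i)) stop(sprintf("unknown part label '%s'", part), call. = FALSE)
    return(i)
  }
  i <- as.integer(part)
  if (length(i) != 1L || is.na(i) || i < 1L || i > D)
    stop(sprintf("part index must be in 1..%d", D), call. = FALSE)
  i
}

# ---- elementary logratio transforms ------------------------------------

#' Additive logratio coordinates
#'
#' `alr(x)_j = ln(x_j / x_divisor)` for every part except the divisor,
#' keeping the original part order. The alr basis is oblique, so these
#' coordinates are kept for quick pairwise comparisons, not for any
#' distance-based method.
#'
#' @param X composition matrix (see [as_composition()]).
#' @param divisor index or label of the divisor part (default: last part).
#' @return numeric `n x (D-1)` matrix, columns named `"<part>/<divisor>"`.
#' @export
alr_transform <- function(X, divisor = ncol(X)) {
  X <- .comp_values(X); .check_positive(X)
  d <- .part_index(X, divisor)
  L <- log(X)
  out <- L[, -d, drop = FALSE] - L[, d]
  colnames(out) <- paste0(colnames(X)[-d], "/", colnames(X)[d])
  out
}

#' Centred logratio coefficients
#'
#' `clr(x)_j = ln x_j - mean(ln x)`: the log abundances centred by the row
#' mean, i.e. each part against the geometric mean of all parts. Rows sum to
#' zero. The clr representation is the common ground on which all orthonormal
#' coordinates in this package are linear: any contrast matrix `V` gives
#' coordinates `clr(X) %*% t(V)`.
#'
#' @inheritParams alr_transform
#' @return numeric `n x D` matrix with zero row sums.
#' @export
clr_transform <- function(X) {
  X <- .comp_values(X); .check_positive(X)
  L <- log(X)
  out <- L - rowMeans(L)
  colnames(out) <- colnames(X)
  out
}

#' Pivot logratio coordinates
#'
#' Orthonormal coordinates in which the first coordinate isolates one focal
#' part against the geometric mean of all others,
#' `z_1 = sqrt((D-1)/D) ln(x_lead / gmean(rest))`, and coordinate `i` contrasts
#' the `i`-th part (in the reordered vector, focal part first, remaining parts
#' in original order) with the geometric mean of all later parts:
#' `z_i = sqrt((D-i)/(D-i+1)) ln(x_i / gmean(x_{i+1}, ..., x_D))`.
#'
#' The first pivot coordinate aggregates all pairwise logratios with the
#' focal part in the numerator, and relates to the clr coefficient of the
#' focal part by `clr_lead = sqrt((D-1)/D) * z_1`.
#'
#' @inheritParams alr_transform
#' @param lead index or label of the focal part placed first.
#' @param normalization `"orthonormal"` (default) keeps the
#'   `sqrt((D-i)/(D-i+1))` constants; `"orthogonal"` drops them, leaving plain
#'   logs of ratios of geometric means.
#' @return numeric `n x (D-1)` matrix.
#' @export
pivot_coordinates <- function(X, lead = 1L,
                              normalization = c("orthonormal", "orthogonal")) {
  X <- .comp_values(X); .check_positive(X)
  normalization <- match.arg(normalization)
  l <- .part_index(X, lead)
  sys <- pivot_system(ncol(X), lead = l, normalization = normalization,
                      parts = colnames(X))
  coordinates(X, sys)
}

# ---- sequential binary partitions --------------------------------------

#' Validate a sequential binary partition table
#'
#' An SBP is a `(D-1) x D` table with entries in `{-1, 0, +1}` whose rows
#' recursively split the parts: the rows' nonzero supports form a laminar
#' family (any two are nested or disjoint), a nested support lies entirely
#' within one sign block of the enclosing row, and the `D-1` splits separate
#' all `D` parts. Row order is free: tables written top-down (pivot style) and
#' bottom-up (backwards pivot style) are both accepted.
#'
#' @param codes integer matrix with entries in `{-1, 0, 1}`.
#' @return `codes` invisibly, as an integer matrix, if valid; otherwise an
#'   error naming the first offending row.
#' @export
validate_sbp <- function(codes) {
  codes <- as.matrix(codes)
  if (!all(codes %in% c(-1L, 0L, 1L)))
    stop("SBP entries must be -1, 0 or +1", call. = FALSE)
  storage.mode(codes) <- "integer"
  D <- ncol(codes)
  if (nrow(codes) != D - 1L)
    stop(sprintf("SBP must have D-1 = %d rows, found %d", D - 1L, nrow(codes)),
         call. = FALSE)
  for (k in seq_len(nrow(codes))) {
    if (!any(codes[k, ] == 1L) || !any(codes[k, ] == -1L))
      stop(sprintf("SBP row %d must contain at least one +1 and one -1", k),
           call. = FALSE)
  }
  # top-down reconstruction: largest supports must match available blocks
  supports <- lapply(seq_len(nrow(codes)), function(k) unname(which(codes[k, ] != 0L)))
  ord <- order(vapply(supports, length, 1L), decreasing = TRUE)
  blocks <- list(seq_len(D))
  for (k in ord) {
    s <- supports[[k]]
    hit <- which(vapply(blocks, function(b) identical(b, s), TRUE))
    if (length(hit) != 1L)
      stop(sprintf("SBP row %d is not a split of one block of the partition hierarchy", k),
           call. = FALSE)
    plus <- unname(which(codes[k, ] == 1L))
    minus <- unname(which(codes[k, ] == -1L))
    blocks <- c(blocks[-hit], list(plus), list(minus))
  }
  if (!all(lengths(blocks) == 1L))
    stop("SBP does not separate all parts", call. = FALSE)
  invisible(codes)
}

#' Contrast matrix of a sequential binary partition
#'
#' Turns an SBP sign table into the `(D-1) x D` matrix of logratio contrast
#' rows. With `r` parts coded `+1` and `s` parts coded `-1` in a row, the
#' orthonormal weights are `+sqrt(s / (r (r + s)))` and
#' `-sqrt(r / (s (r + s)))`, so that the coordinate is the balance
#' `sqrt(r s / (r + s)) * ln(gmean(plus) / gmean(minus))`. The orthogonal
#' variant drops the normalising constant and uses weights `+1/r` and `-1/s`,
#' giving the plain log of the ratio of geometric means — often preferred in
#' regression for interpretability.
#'
#' @param sbp SBP sign table, validated with [validate_sbp()].
#' @param normalization `"orthonormal"` or `"orthogonal"`.
#' @return numeric `(D-1) x D` matrix with attribute `normalization`; rows sum
#'   to zero, and in orthonormal mode are mutually orthonormal.
#' @export
contrast_from_sbp <- function(sbp, normalization = c("orthonormal", "orthogonal")) {
  normalization <- match.arg(normalization)
  codes <- validate_sbp(sbp)
  D <- ncol(codes)
  V <- matrix(0, nrow(codes), D, dimnames = dimnames(codes))
  for (k in seq_len(nrow(codes))) {
    plus <- codes[k, ] == 1L
    minus <- codes[k, ] == -1L
    r <- sum(plus); s <- sum(minus)
    if (normalization == "orthonormal") {
      V[k, plus] <- sqrt(s / (r * (r + s)))
      V[k, minus] <- -sqrt(r / (s * (r + s)))
    } else {
      V[k, plus] <- 1 / r
      V[k, minus] <- -1 / s
    }
  }
  attr(V, "normalization") <- normalization
  V
}

#' Balance coordinates from a sequential binary partition
#'
#' Evaluates the `D-1` balances of an SBP on each sample. In orthonormal mode
#' this equals `clr_transform(X) %*% t(contrast_from_sbp(sbp))`.
#'
#' @inheritParams alr_transform
#' @inheritParams contrast_from_sbp
#' @return numeric `n x (D-1)` matrix of balances.
#' @export
balances_from_sbp <- function(X, sbp, normalization = c("orthonormal", "orthogonal")) {
  X <- .comp_values(X); .check_positive(X)
  V <- contrast_from_sbp(sbp, normalization)
  if (ncol(V) != ncol(X))
    stop("SBP width does not match the number of parts", call. = FALSE)
  log(X) %*% t(V)   # rows of V sum to 0, so log and clr agree
}

#' Backwards pivot coordinates
#'
#' Orthonormal coordinates whose *first* coordinate is a single pairwise
#' logratio, `(1/sqrt(2)) ln(x_l / x_r)` — the focal part `l` against the
#' divisor part `r`. The parts are permuted to `(x_r, x_l, rest in original
#' order)` and coordinate `i` is
#' `sqrt(i/(i+1)) ln(x_{i+1} / gmean(x_1, ..., x_i))` on the permuted vector,
#' i.e. the partition is built backwards relative to pivot coordinates.
#' Because the system is orthonormal, a regression coefficient attached to the
#' first coordinate is identical in any other orthonormal system containing
#' that same pairwise logratio.
#'
#' @inheritParams pivot_coordinates
#' @param l focal part (numerator), index or label.
#' @param r divisor part (denominator), index or label; must differ from `l`.
#' @return numeric `n x (D-1)` matrix; first column is the pairwise logratio.
#' @export
bpc_coordinates <- function(X, l, r,
                            normalization = c("orthonormal", "orthogonal")) {
  X <- .comp_values(X); .check_positive(X)
  normalization <- match.arg(normalization)
  li <- .part_index(X, l); ri <- .part_index(X, r)
  if (li == ri) stop("focal part and divisor part must differ", call. = FALSE)
  sys <- bpc_system(ncol(X), l = li, r = ri, normalization = normalization,
                    parts = colnames(X))
  coordinates(X, sys)
}

# ---- coordinate systems as objects -------------------------------------

#' Construct a coordinate system from an SBP
#'
#' Bundles an SBP, its contrast matrix and per-row role metadata into a
#' `coordinate_system` object. Rows whose SBP row is a single `+1` against a
#' single `-1` are tagged as pairwise logratios with their oriented part pair;
#' all other rows are filler balances.
#'
#' @param sbp validated SBP sign table.
#' @inheritParams contrast_from_sbp
#' @param k optional integer identifier of the system.
#' @param parts optional part labels (columns).
#' @return object of class `coordinate_system`: list with elements `k`,
#'   `sbp`, `contrast`, `normalization`, `parts` and `row_roles` (data frame
#'   with columns `role`, `num`, `den`).
#' @export
coordinate_system <- function(sbp, normalization = c("orthonormal", "orthogonal"),
                              k = NA_integer_, parts = NULL) {
  normalization <- match.arg(normalization)
  codes <- validate_sbp(sbp)
  D <- ncol(codes)
  if (is.null(parts)) parts <- colnames(codes)
  if (is.null(parts)) parts <- paste0("x", seq_len(D))
  colnames(codes) <- parts
  V <- contrast_from_sbp(codes, normalization)
  role <- character(nrow(codes)); num <- den <- rep(NA_integer_, nrow(codes))
  for (i in seq_len(nrow(codes))) {
    plus <- which(codes[i, ] == 1L); minus <- which(codes[i, ] == -1L)
    if (length(plus) == 1L && length(minus) == 1L) {
      role[i] <- "pairwise_logratio"; num[i] <- plus; den[i] <- minus
    } else role[i] <- "filler_balance"
  }
  structure(list(k = as.integer(k), sbp = codes, contrast = V,
                 normalization = normalization, parts = parts,
                 row_roles = data.frame(role = role, num = num, den = den)),
            class = "coordinate_system")
}

#' @export
print.coordinate_system <- function(x, ...) {
  np <- sum(x$row_roles$role == "pairwise_logratio")
  cat(sprintf("<coordinate_system k=%s: %d parts, %d coordinates (%d pairwise logratios), %s>\n",
              ifelse(is.na(x$k), "?", x$k), length(x$parts),
              nrow(x$contrast), np, x$normalization))
  pr <- x$row_roles[x$row_roles$role == "pairwise_logratio", ]
  if (nrow(pr))
    cat("  PLRs:", paste0("ln(", x$parts[pr$num], "/", x$parts[pr$den], ")",
                          collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a coordinate system on a composition
#'
#' @param X composition matrix.
#' @param system a `coordinate_system`.
#' @return numeric `n x (D-1)` matrix of coordinate values.
#' @export
coordinates <- function(X, system) {
  stopifnot(inherits(system, "coordinate_system"))
  X <- .comp_values(X); .check_positive(X)
  if (ncol(X) != ncol(system$contrast))
    stop("composition and coordinate system disagree on the number of parts",
         call. = FALSE)
  Z <- log(X) %*% t(system$contrast)
  colnames(Z) <- coordinate_names(system)
  Z
}

coordinate_names <- function(system) {
  rr <- system$row_roles
  ifelse(rr$role == "pairwise_logratio",
         paste0("ln(", system$parts[rr$num], "/", system$parts[rr$den], ")"),
         paste0("b", seq_len(nrow(rr))))
}

#' Pivot coordinate system
#'
#' The SBP and contrast matrix behind [pivot_coordinates()]: the focal part
#' first, then each remaining part split off in turn against all later ones.
#'
#' @param D number of parts.
#' @param lead focal part index.
#' @inheritParams contrast_from_sbp
#' @param parts optional part labels.
#' @return a `coordinate_system`.
#' @export
pivot_system <- function(D, lead = 1L,
                         normalization = c("orthonormal", "orthogonal"),
                         parts = NULL) {
  normalization <- match.arg(normalization)
  if (D < 2L) stop("D must be at least 2", call. = FALSE)
  perm <- c(lead, setdiff(seq_len(D), lead))
  codes <- matrix(0L, D - 1L, D)
  for (i in seq_len(D - 1L)) {
    codes[i, perm[i]] <- 1L
    codes[i, perm[(i + 1L):D]] <- -1L
  }
  coordinate_system(codes, normalization, parts = parts)
}

#' Backwards pivot coordinate system
#'
#' The SBP and contrast matrix behind [bpc_coordinates()]: parts permuted to
#' `(divisor, focal, rest)`, first row `focal (+1)` vs `divisor (-1)`, and row
#' `i` splitting part `i+1` off against all earlier parts.
#'
#' @inheritParams pivot_system
#' @param l focal part index (numerator of the pairwise logratio).
#' @param r divisor part index (denominator).
#' @return a `coordinate_system` whose first row is tagged
#'   `pairwise_logratio` with orientation `l` over `r`.
#' @export
bpc_system <- function(D, l, r, normalization = c("orthonormal", "orthogonal"),
                       parts = NULL) {
  normalization <- match.arg(normalization)
  if (l == r) stop("focal part and divisor part must differ", call. = FALSE)
  perm <- c(r, l, setdiff(seq_len(D), c(l, r)))
  codes <- matrix(0L, D - 1L, D)
  for (i in seq_len(D - 1L)) {
    codes[i, perm[i + 1L]] <- 1L
    codes[i, perm[seq_len(i)]] <- -1L
  }
  coordinate_system(codes, normalization, parts = parts)
}
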