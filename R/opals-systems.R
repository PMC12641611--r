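# OPALS: D-1 orthonormal systems jointly holding all D(D-1)/2 pairwise
# logratios. The index sets are a 1-factorization of the complete graph K_D
# (equivalently a symmetric diagonal Latin square), built by the round-robin
# style rule below.

#' OPALS index set
#'
#' The `k`-th set of `D/2` disjoint part pairs, `k = 2..D`. For even `k` the
#' set collects pairs `{i, j}` with `i + j = k + 1`, pairs with
#' `i, j != D` and `i + j = D + k`, plus `{D, (D + k)/2}` when `k != D`; for
#' odd `k` the third pair is `{D, (k + 1)/2}`. Degenerate pairs `i = j` are
#' discarded. The result is a perfect matching of `{1..D}`, and the `D - 1`
#' sets together partition all unordered pairs.
#'
#' @param D even number of parts, `D >= 2`.
#' @param k system index, `2 <= k <= D`.
#' @return object of class `pair_set`: list with `k` and `pairs`, a
#'   `D/2 x 2` integer matrix with `pairs[, 1] < pairs[, 2]`, rows ordered by
#'   first element.
#' @export
opals_index_set <- function(D, k) {
  .check_even_D(D)
  if (k < 2L || k > D) stop(sprintf("k must be in 2..%d", D), call. = FALSE)
  pairs <- matrix(integer(), 0L, 2L)
  add <- function(i, j) {
    if (i == j) return(invisible())
    pairs <<- rbind(pairs, c(min(i, j), max(i, j)))
  }
  for (i in seq_len(D)) {            # i + j = k + 1
    j <- k + 1L - i
    if (j > i && j <= D) add(i, j)
  }
  for (i in seq_len(D - 1L)) {       # i + j = D + k, i, j != D
    j <- D + k - i
    if (j > i && j <= D - 1L) add(i, j)
  }
  if (D != k) {                      # the pair involving part D
    add(D, if (k %% 2L == 0L) (D + k) %/% 2L else (k + 1L) %/% 2L)
  }
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  ps <- structure(list(k = as.integer(k), pairs = pairs), class = "pair_set")
  if (nrow(pairs) != D %/% 2L || length(unique(as.vector(pairs))) != D)
    stop(sprintf("internal error: index set k=%d for D=%d is not a perfect matching", k, D),
         call. = FALSE)
  ps
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set k=%d: %s>\n", x$k,
              paste0("{", x$pairs[, 1], ",", x$pairs[, 2], "}", collapse = " ")))
  invisible(x)
}

.check_even_D <- function(D) {
  if (D < 2L) stop("D must be at least 2", call. = FALSE)
  if (D %% 2L != 0L)
    stop("D must be even; for an odd number of parts drop one part first (see the 'drop_part' argument of fit_all_plrs / the CLI '--drop-odd-part' flag)",
         call. = FALSE)
  invisible(as.integer(D))
}

#' Full OPALS pair schedule
#'
#' All `D - 1` index sets `k = 2..D` (a 1-factorization of the complete
#' graph on `D` vertices).
#'
#' @inheritParams opals_index_set
#' @return object of class `pair_schedule`: list with `D` and `systems`, a
#'   list of `D - 1` [opals_index_set()] results.
#' @export
opals_schedule <- function(D) {
  D <- .check_even_D(D)
  structure(list(D = D, systems = lapply(2:D, function(k) opals_index_set(D, k))),
            class = "pair_schedule")
}

#' @export
print.pair_schedule <- function(x, ...) {
  cat(sprintf("<pair_schedule D=%d: %d systems of %d pairs>\n",
              x$D, length(x$systems), x$D %/% 2L))
  invisible(x)
}

#' Verify a pair schedule
#'
#' Diagnostic check of the three defining properties of an OPALS schedule:
#' (i) the union of the sets is all `D(D-1)/2` unordered pairs, (ii) the sets
#' are pairwise disjoint, (iii) within each set the pairs are disjoint (a
#' perfect matching). Returns diagnostics rather than erroring, so broken
#' schedules can be inspected.
#'
#' @param s a `pair_schedule` (or a list with elements `D` and `systems`).
#' @return list with `pass` (logical) and `violations`, a character vector
#'   naming each violated property with a counterexample.
#' @export
verify_schedule <- function(s) {
  D <- s$D
  violations <- character()
  key <- function(p) paste(p[, 1L], p[, 2L], sep = "-")
  all_keys <- unlist(lapply(s$systems, function(ps) key(ps$pairs)))
  for (ps in s$systems) {
    idx <- as.vector(ps$pairs)
    if (anyDuplicated(idx)) {
      i <- idx[duplicated(idx)][1L]
      violations <- c(violations, sprintf(
        "property iii: set k=%d has overlapping pairs sharing part %d", ps$k, i))
    } else if (length(idx) != D) {
      violations <- c(violations, sprintf(
        "property iii: set k=%d is not a perfect matching of 1..%d", ps$k, D))
    }
  }
  if (anyDuplicated(all_keys)) {
    dup <- all_keys[duplicated(all_keys)][1L]
    violations <- c(violations, sprintf(
      "property ii: pair {%s} appears in more than one set", sub("-", ",", dup)))
  }
  want <- utils::combn(D, 2L)
  want_keys <- paste(want[1L, ], want[2L, ], sep = "-")
  missing <- setdiff(want_keys, all_keys)
  if (length(missing)) {
    violations <- c(violations, sprintf(
      "property i: pair {%s} is covered by no set", sub("-", ",", missing[1L])))
  }
  list(pass = length(violations) == 0L, violations = violations)
}

#' Symmetric diagonal Latin square of a pair schedule
#'
#' Encodes a valid schedule as the `D x D` Latin square with `L[i, j] = k`
#' iff pair `{i, j}` lies in set `k`, and constant diagonal `D`. A schedule
#' satisfies properties (i)-(iii) exactly when this array is a symmetric
#' Latin square with constant diagonal, so the construction and the square
#' validate each other.
#'
#' @inheritParams verify_schedule
#' @return integer `D x D` matrix.
#' @export
latin_square_from_schedule <- function(s) {
  chk <- verify_schedule(s)
  if (!chk$pass)
    stop(paste(c("invalid schedule:", chk$violations), collapse = "\n  "),
         call. = FALSE)
  D <- s$D
  L <- diag(D, D, D)  # diagonal constantly D
  for (ps in s$systems) {
    # systems are labelled k = 2..D; cell entries use k-1 in 1..D-1 so that
    # the off-diagonal symbols are exactly {1..D-1}
    for (m in seq_len(nrow(ps$pairs))) {
      i <- ps$pairs[m, 1L]; j <- ps$pairs[m, 2L]
      L[i, j] <- L[j, i] <- ps$k - 1L
    }
  }
  storage.mode(L) <- "integer"
  L
}

#' Check a Latin square
#'
#' @param L integer matrix.
#' @param symmetric require `L == t(L)`.
#' @param diagonal require a constant diagonal (equal to `ncol(L)`).
#' @return `TRUE` or `FALSE`.
#' @export
is_latin_square <- function(L, symmetric = TRUE, diagonal = TRUE) {
  D <- ncol(L)
  if (nrow(L) != D) return(FALSE)
  ok <- all(apply(L, 1L, function(r) setequal(r, seq_len(D)))) &&
        all(apply(L, 2L, function(r) setequal(r, seq_len(D))))
  if (symmetric) ok <- ok && identical(unname(L), unname(t(L)))
  if (diagonal) ok <- ok && all(diag(L) == D)
  ok
}

#' Complete a pair set into a full coordinate system
#'
#' Given `D/2` disjoint pairs, builds the `(D-1) x D` SBP that contains each
#' pairwise logratio as its own coordinate. Pairs are ordered ascending by
#' their smaller element (any order gives an equivalent system; a fixed one
#' makes output reproducible). The first `D/2 - 1` rows are nested filler
#' balances: row `m` contrasts the two parts of pair `m` (geometric mean)
#' against all parts of the remaining pairs, which in orthonormal mode gives
#' the coefficient `sqrt((2 D - 4 m) / (D - 2 m + 2))`. The last `D/2` rows
#' are the pairwise logratios `(1/sqrt(2)) ln(x_i / x_j)` (orthonormal) or
#' `ln(x_i / x_j)` (orthogonal), numerator the smaller part index.
#'
#' @param p a `pair_set`, or a 2-column matrix of part index pairs.
#' @param D number of parts.
#' @inheritParams contrast_from_sbp
#' @param parts optional part labels.
#' @return a [coordinate_system()] with `D/2` rows tagged
#'   `pairwise_logratio` matching the pair set.
#' @export
complete_system <- function(p, D, normalization = c("orthonormal", "orthogonal"),
                            parts = NULL) {
  normalization <- match.arg(normalization)
  if (inherits(p, "pair_set")) { k <- p$k; pairs <- p$pairs }
  else { k <- NA_integer_; pairs <- as.matrix(p) }
  if (ncol(pairs) != 2L) stop("pairs must have two columns", call. = FALSE)
  pairs <- cbind(pmin(pairs[, 1L], pairs[, 2L]), pmax(pairs[, 1L], pairs[, 2L]))
  if (anyDuplicated(as.vector(pairs)) || length(unique(as.vector(pairs))) != D ||
      any(pairs < 1L) || any(pairs > D))
    stop("pair set must be a perfect matching of 1..D", call. = FALSE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  half <- D %/% 2L
  codes <- matrix(0L, D - 1L, D)
  for (m in seq_len(half - 1L)) {          # pair m vs the pooled later pairs
    codes[m, pairs[m, ]] <- 1L
    later <- as.vector(pairs[(m + 1L):half, ])
    codes[m, later] <- -1L
  }
  for (m in seq_len(half)) {               # the pairwise logratios
    codes[half - 1L + m, pairs[m, 1L]] <- 1L
    codes[half - 1L + m, pairs[m, 2L]] <- -1L
  }
  coordinate_system(codes, normalization, k = k, parts = parts)
}

#' All OPALS coordinate systems for D parts
#'
#' The full basis: `D - 1` coordinate systems, each holding `D/2` disjoint
#' pairwise logratios, together covering all `D(D-1)/2`.
#'
#' @inheritParams opals_index_set
#' @inheritParams contrast_from_sbp
#' @param parts optional part labels.
#' @return object of class `opals_basis`: list of `D - 1`
#'   [coordinate_system()]s, with attributes `D` and `normalization`.
#' @export
opals_basis <- function(D, normalization = c("orthonormal", "orthogonal"),
                        parts = NULL) {
  normalization <- match.arg(normalization)
  sched <- opals_schedule(D)
  systems <- lapply(sched$systems, complete_system, D = D,
                    normalization = normalization, parts = parts)
  structure(systems, class = "opals_basis", D = as.integer(D),
            normalization = normalization)
}

#' @export
print.opals_basis <- function(x, ...) {
  D <- attr(x, "D")
  cat(sprintf("<opals_basis D=%d: %d systems x %d pairwise logratios = %d PLRs, %s>\n",
              D, length(x), D %/% 2L, (D * (D - 1L)) %/% 2L,
              attr(x, "normalization")))
  invisible(x)
}

#' Pairwise-logratio bookkeeping counts
#'
#' For `D` parts: the number of distinct pairwise logratios `D(D-1)/2`, the
#' number of OPALS coordinate systems `D - 1` needed to cover them, and the
#' number of pairwise logratios `D/2` held per system. For odd `D` the pair
#' count is still returned; the system counts are `NA` until a part is
#' dropped.
#'
#' @param D number of parts, `D >= 2`.
#' @return list with `n_pairs`, `n_systems`, `pairs_per_system`.
#' @export
expected_counts <- function(D) {
  if (D < 2L) stop("D must be at least 2", call. = FALSE)
  D <- as.integer(D)
  even <- D %% 2L == 0L
  list(n_pairs = (D * (D - 1L)) %/% 2L,
       n_systems = if (even) D - 1L else NA_integer_,
       pairs_per_system = if (even) D %/% 2L else NA_integer_)
}

#' Tagged pairs of a basis
#'
#' @param basis an `opals_basis`.
#' @return data frame with columns `system_k`, `i`, `j` (part indices,
#'   `i < j`), one row per pairwise logratio.
#' @export
basis_pairs <- function(basis) {
  do.call(rbind, lapply(basis, function(sys) {
    rr <- sys$row_roles
    plr <- rr[rr$role == "pairwise_logratio", ]
    data.frame(system_k = sys$k, i = pmin(plr$num, plr$den),
               j = pmax(plr$num, plr$den))
  }))
}
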