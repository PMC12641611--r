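# shared fixtures: small random compositions and brute-force oracles

random_composition <- function(n, D, seed) {
  set.seed(seed)
  as_composition(matrix(stats::rexp(n * D) + 0.05, n, D))
}

# direct evaluation of a balance: sqrt(r s / (r + s)) ln(gmean+ / gmean-)
balance_direct <- function(X, code, orthonormal = TRUE) {
  X <- unclass(X)
  plus <- which(code == 1L); minus <- which(code == -1L)
  r <- length(plus); s <- length(minus)
  gm <- function(M) exp(rowMeans(log(M)))
  lr <- log(gm(X[, plus, drop = FALSE]) / gm(X[, minus, drop = FALSE]))
  if (orthonormal) sqrt(r * s / (r + s)) * lr else lr
}

# all unordered pairs of 1..D as a sorted key vector
all_pair_keys <- function(D) {
  cb <- utils::combn(D, 2L)
  sort(paste(cb[1L, ], cb[2L, ], sep = "-"))
}

schedule_pair_keys <- function(s) {
  sort(unlist(lapply(s$systems, function(ps)
    paste(ps$pairs[, 1L], ps$pairs[, 2L], sep = "-"))))
}
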