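test_that("index sets for 6 parts match the worked construction", {
  expect_equal(opals_index_set(6, 2)$pairs,
               rbind(c(1, 2), c(3, 5), c(4, 6)), ignore_attr = TRUE)
  expect_equal(opals_index_set(6, 3)$pairs,
               rbind(c(1, 3), c(2, 6), c(4, 5)), ignore_attr = TRUE)
  expect_equal(opals_index_set(6, 4)$pairs,
               rbind(c(1, 4), c(2, 3), c(5, 6)), ignore_attr = TRUE)
  expect_equal(opals_index_set(6, 5)$pairs,
               rbind(c(1, 5), c(2, 4), c(3, 6)), ignore_attr = TRUE)
  expect_equal(opals_index_set(6, 6)$pairs,
               rbind(c(1, 6), c(2, 5), c(3, 4)), ignore_attr = TRUE)
})

test_that("small and degenerate index sets follow the defining conditions", {
  expect_equal(opals_index_set(2, 2)$pairs, rbind(c(1, 2)), ignore_attr = TRUE)
  # brute-force enumeration of the three defining conditions for D = 4
  brute <- function(D, k) {
    cb <- t(utils::combn(D, 2L))
    keep <- (rowSums(cb) == k + 1) |
      (cb[, 1] != D & cb[, 2] != D & rowSums(cb) == D + k)
    extra <- if (D != k) {
      third <- if (k %% 2 == 0) (D + k) / 2 else (k + 1) / 2
      cb[, 1] == min(D, third) & cb[, 2] == max(D, third)
    } else rep(FALSE, nrow(cb))
    m <- cb[keep | extra, , drop = FALSE]
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  }
  for (k in 2:4)
    expect_equal(opals_index_set(4, k)$pairs, brute(4, k), ignore_attr = TRUE)
  expect_error(opals_index_set(5, 2), "even")
  expect_error(opals_index_set(6, 8), "k must be")
})

test_that("schedules cover each unordered pair exactly once", {
  for (D in c(2, 6, 10, 20)) {
    s <- opals_schedule(D)
    expect_length(s$systems, D - 1)
    expect_identical(schedule_pair_keys(s), all_pair_keys(D))
    expect_true(verify_schedule(s)$pass)
  }
})

test_that("verify_schedule pinpoints injected violations", {
  s <- opals_schedule(6)
  dup <- s
  dup$systems[[2]]$pairs[1, ] <- s$systems[[1]]$pairs[1, ]  # duplicated across sets
  chk <- verify_schedule(dup)
  expect_false(chk$pass)
  expect_true(any(grepl("property ii", chk$violations)))
  expect_true(any(grepl("property i:", chk$violations)))   # coverage breaks too
  lap <- s
  lap$systems[[1]]$pairs[2, ] <- c(1, 5)   # overlaps {1,2} within the set
  chk2 <- verify_schedule(lap)
  expect_false(chk2$pass)
  expect_true(any(grepl("property iii", chk2$violations)))
  expect_error(latin_square_from_schedule(dup), "property")
})

test_that("schedules and symmetric diagonal Latin squares are equivalent", {
  expect_identical(latin_square_from_schedule(opals_schedule(2)),
                   rbind(c(2L, 1L), c(1L, 2L)))
  for (D in c(4, 6, 12, 26)) {
    s <- opals_schedule(D)
    L <- latin_square_from_schedule(s)
    expect_true(is_latin_square(L))
    expect_true(all(diag(L) == D))
    # converse direction: decode the square back into sets and re-verify
    dec <- lapply(seq_len(D - 1), function(sym) {
      idx <- which(L == sym & upper.tri(L), arr.ind = TRUE)
      m <- cbind(pmin(idx[, 1], idx[, 2]), pmax(idx[, 1], idx[, 2]))
      structure(list(k = sym + 1L, pairs = m[order(m[, 1]), , drop = FALSE]),
                class = "pair_set")
    })
    expect_true(verify_schedule(list(D = D, systems = dec))$pass)
  }
})

test_that("complete_system builds the expected nested partition", {
  # D = 4, pairs {1,2},{3,4}: one filler balance then the two logratios
  sys <- complete_system(rbind(c(1, 2), c(3, 4)), 4)
  X <- random_composition(5, 4, seed = 9)
  Z <- coordinates(X, sys)
  M <- unclass(X)
  expect_equal(Z[, 1], balance_direct(X, c(1, 1, -1, -1)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(Z[, 2], (1 / sqrt(2)) * log(M[, 1] / M[, 2]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(Z[, 3], (1 / sqrt(2)) * log(M[, 3] / M[, 4]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(sys$row_roles$role,
                   c("filler_balance", "pairwise_logratio", "pairwise_logratio"))
  # filler weights: +/- sqrt(s/(r(r+s))) with r = s = 2, i.e. 1/2
  expect_equal(unname(sys$contrast[1, ]), c(1, 1, -1, -1) / 2, tolerance = 1e-12)
  expect_error(complete_system(rbind(c(1, 2), c(2, 3)), 4), "perfect matching")
})

test_that("every system of a basis is orthonormal and tags its pair set", {
  for (D in c(4, 10)) {
    basis <- opals_basis(D)
    sched <- opals_schedule(D)
    for (idx in seq_along(basis)) {
      V <- basis[[idx]]$contrast
      expect_lt(max(abs(V %*% t(V) - diag(D - 1))), 1e-10)
      expect_lt(max(abs(rowSums(V))), 1e-10)
      rr <- basis[[idx]]$row_roles
      plr <- rr[rr$role == "pairwise_logratio", ]
      expect_equal(nrow(plr), D / 2)
      expect_equal(cbind(pmin(plr$num, plr$den), pmax(plr$num, plr$den)),
                   sched$systems[[idx]]$pairs, ignore_attr = TRUE)
    }
  }
})

test_that("tagged coordinates equal the plain pairwise logratios", {
  D <- 8
  X <- random_composition(6, D, seed = 15)
  M <- unclass(X)
  for (sys in opals_basis(D)) {
    Z <- coordinates(X, sys)
    rr <- sys$row_roles
    for (row in which(rr$role == "pairwise_logratio")) {
      expect_equal(Z[, row],
                   (1 / sqrt(2)) * log(M[, rr$num[row]] / M[, rr$den[row]]),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
  for (sys in opals_basis(D, "orthogonal")) {
    Z <- coordinates(X, sys)
    rr <- sys$row_roles
    row <- which(rr$role == "pairwise_logratio")[1]
    expect_equal(Z[, row], log(M[, rr$num[row]] / M[, rr$den[row]]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("any two systems of one basis are related by an orthogonal rotation", {
  basis <- opals_basis(10)
  M1 <- basis[[1]]$contrast; M2 <- basis[[5]]$contrast
  R <- M1 %*% t(M2)
  expect_lt(max(abs(R %*% t(R) - diag(9))), 1e-10)
})

test_that("basis coverage matches exhaustive pair enumeration", {
  for (D in c(4, 6, 8)) {
    bp <- basis_pairs(opals_basis(D))
    expect_identical(sort(paste(bp$i, bp$j, sep = "-")), all_pair_keys(D))
  }
})

test_that("bookkeeping counts are exact", {
  expect_equal(expected_counts(10)$n_pairs, 45L)
  expect_equal(expected_counts(126),
               list(n_pairs = 7875L, n_systems = 125L, pairs_per_system = 63L))
  expect_equal(expected_counts(450)$n_pairs, 101025L)
  odd <- expected_counts(7)
  expect_equal(odd$n_pairs, 21L)
  expect_true(is.na(odd$n_systems) && is.na(odd$pairs_per_system))
})
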