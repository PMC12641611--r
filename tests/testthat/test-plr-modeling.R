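test_that("a noise-free single-logratio response is recovered exactly", {
  X <- random_composition(60, 6, seed = 21)
  M <- unclass(X)
  y <- 3 * log(M[, 1] / M[, 2])
  sys2 <- complete_system(opals_index_set(6, 2), 6, "orthogonal",
                          parts = colnames(X))
  fit <- fit_system(X, y, sys2, fit_config(model = "ols", normalization = "orthogonal"))
  co <- unname(fit$coefficients)
  plr12 <- which(sys2$row_roles$num == 1 & sys2$row_roles$den == 2)
  expect_equal(co[plr12], 3, tolerance = 1e-10)
  expect_equal(co[-plr12], rep(0, 4), tolerance = 1e-10)
  # orthonormal coordinates absorb the 1/sqrt(2): coefficient scales up
  sys2n <- complete_system(opals_index_set(6, 2), 6, "orthonormal",
                           parts = colnames(X))
  fitn <- fit_system(X, y, sys2n, fit_config(model = "ols", normalization = "orthonormal"))
  expect_equal(unname(fitn$coefficients[plr12]), 3 * sqrt(2), tolerance = 1e-10)
})

test_that("full-rank PLS reproduces OLS coefficients", {
  X <- random_composition(50, 6, seed = 22)
  y <- simulate_response(pivot_coordinates(X), seed = 23)
  ols <- fit_all_plrs(X, y, fit_config(model = "ols", normalization = "orthogonal"))
  pls <- fit_all_plrs(X, y, fit_config(model = "pls", n_components = 5,
                                       normalization = "orthogonal"))
  expect_equal(pls$coefficient, ols$coefficient, tolerance = 1e-8)
})

test_that("SIMPLS agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  X <- random_composition(40, 8, seed = 24)
  Z <- coordinates(X, pivot_system(8, 1, "orthonormal"))
  Zc <- sweep(Z, 2, colMeans(Z))
  y <- simulate_response(Z, seed = 25)
  yc <- y - mean(y)
  for (a in c(1, 3, 5)) {
    m <- mixOmics::pls(Zc, yc, ncomp = a, scale = FALSE, mode = "regression")
    b_ref <- predict(m, Zc)$B.hat[, 1, a]
    expect_equal(unname(opals:::simpls_coef(Zc, yc, a)), unname(b_ref),
                 tolerance = 1e-8)
  }
})

test_that("fit_all_plrs yields one record per unordered pair", {
  X <- random_composition(30, 6, seed = 26)
  y <- stats::rnorm(30)
  rec <- fit_all_plrs(X, y, fit_config(model = "ols"))
  expect_equal(nrow(rec), 15)
  expect_true(all(rec$i < rec$j))
  expect_identical(sort(paste(rec$i, rec$j, sep = "-")), all_pair_keys(6))
  for (D in c(4, 12, 20))
    expect_equal(nrow(basis_pairs(opals_basis(D))), expected_counts(D)$n_pairs)
  expect_error(fit_all_plrs(random_composition(30, 5, seed = 1), y,
                            fit_config(model = "ols")), "even")
  # odd D with an explicit dropped part
  rec5 <- fit_all_plrs(random_composition(30, 5, seed = 1), y,
                       fit_config(model = "ols"), drop_part = "x3")
  expect_identical(attr(rec5, "dropped_part"), "x3")
  expect_false(any(c(rec5$part_i, rec5$part_j) == "x3"))
})

test_that("OLS pairwise-logratio coefficients are invariant to the hosting system", {
  D <- 6; n <- 50
  X <- random_composition(n, D, seed = 27)
  y <- simulate_response(pivot_coordinates(X), seed = 28)
  for (norm in c("orthonormal", "orthogonal")) {
    cfg <- fit_config(model = "ols", normalization = norm)
    rec <- fit_all_plrs(X, y, cfg)
    for (r in seq_len(nrow(rec))) {
      sysb <- bpc_system(D, l = rec$i[r], r = rec$j[r], normalization = norm,
                         parts = colnames(X))
      b1 <- fit_system(X, y, sysb, cfg)$coefficients[1]
      expect_equal(unname(b1), rec$coefficient[r], tolerance = 1e-8)
    }
  }
})

test_that("the one-standard-error rule picks the simplest near-optimal model", {
  expect_equal(opals:::one_se_choice(c(2.0, 1.0, 0.99), 0.05), 2L)
  expect_equal(opals:::one_se_choice(c(2.0, 1.0, 0.99), 0.001), 3L)
  expect_equal(opals:::one_se_choice(c(1.0, 1.0, 1.0), 0), 1L)
})

test_that("component selection is deterministic given the seed", {
  X <- simulate_composition(40, 8, seed = 31)
  y <- simulate_response(attr(X, "coordinates"), seed = 32)
  cfg <- fit_config(model = "pls", seed = 5)
  s1 <- select_components(X, y, cfg)
  s2 <- select_components(X, y, cfg)
  expect_identical(s1$n_components, s2$n_components)
  expect_identical(s1$cv, s2$cv)
  expect_true(s1$n_components >= 1 && s1$n_components <= 7)
  expect_true(all(diff(s1$cv$n_components) == 1))
  # discriminant criterion is an accuracy column
  yb <- as.integer(y > stats::median(y))
  sd1 <- select_components(X, yb, fit_config(model = "pls", mode = "discriminant",
                                             seed = 5))
  expect_true("accuracy" %in% names(sd1$cv))
  expect_true(all(sd1$cv$accuracy >= 0 & sd1$cv$accuracy <= 1))
})

test_that("bootstrap standardization flags a planted signal and not the rest", {
  set.seed(33)
  X <- simulate_composition(80, 6, seed = 33)
  M <- unclass(X)
  y <- 2 * log(M[, 1] / M[, 2]) + stats::rnorm(80, 0, 0.3)
  cfg <- fit_config(model = "ols", normalization = "orthogonal",
                    bootstrap_B = 200, seed = 34)
  rec <- bootstrap_standardize(X, y, cfg)
  expect_true(all(c("bootstrap_sd", "standardized", "significant", "sign")
                  %in% names(rec)))
  expect_true(all(rec$bootstrap_sd >= 0))
  ok <- !is.na(rec$standardized)
  expect_equal(rec$standardized[ok], (rec$coefficient / rec$bootstrap_sd)[ok])
  expect_identical(rec$significant,
                   !is.na(rec$standardized) &
                     abs(rec$standardized) > stats::qnorm(0.975))
  expect_true(rec$significant[rec$i == 1 & rec$j == 2])
  expect_gt(rec$standardized[rec$i == 1 & rec$j == 2], 0)
})

test_that("a constant coordinate yields zero bootstrap sd and a warning, not significance", {
  set.seed(35)
  base <- matrix(stats::rexp(40 * 5) + 0.05, 40, 5)
  X <- as_composition(cbind(base[, 1], base[, 1], base[, 2:5]))
  # x1 and x2 coincide, so ln(x1/x2) is identically zero: the centred
  # coordinate, its coefficient and its bootstrap sd are all exactly 0
  y <- stats::rnorm(40)
  cfg <- fit_config(model = "pls", n_components = 2, bootstrap_B = 50, seed = 36)
  expect_warning(rec <- bootstrap_standardize(X, y, cfg), "zero bootstrap variance")
  r12 <- rec[rec$i == 1 & rec$j == 2, ]
  expect_equal(r12$bootstrap_sd, 0)
  expect_true(is.na(r12$standardized))
  expect_false(r12$significant)
})

test_that("bootstrap sd tracks the classical OLS standard error", {
  X <- simulate_composition(100, 10, seed = 37)
  set.seed(38)
  y <- stats::rnorm(100)          # independent of the composition
  cfg <- fit_config(model = "ols", normalization = "orthogonal",
                    bootstrap_B = 400, seed = 38)
  rec <- bootstrap_standardize(X, y, cfg)
  sys <- opals_basis(10, "orthogonal")[[1]]
  Z <- scale(coordinates(X, sys), scale = FALSE)
  fit <- stats::lm(I(y - mean(y)) ~ Z - 1)
  tag <- which(sys$row_roles$role == "pairwise_logratio")
  expect_equal(rec$coefficient[1:5], unname(stats::coef(fit)[tag]),
               tolerance = 1e-8)
  se <- sqrt(diag(stats::vcov(fit)))[tag]
  expect_lt(max(abs(rec$bootstrap_sd[1:5] / se - 1)), 0.4)
})

test_that("per-part aggregation double-counts each significant pair with flipped signs", {
  rec <- data.frame(part_i = c("a", "a", "b"), part_j = c("b", "c", "c"),
                    i = c(1, 1, 2), j = c(2, 3, 3), system_k = c(2, 3, 4),
                    coefficient = c(1.5, -0.4, 2.0),
                    significant = c(TRUE, TRUE, FALSE))
  agg <- aggregate_by_part(rec)
  expect_equal(sum(agg$total), 2 * sum(rec$significant))
  a <- agg[agg$part == "a", ]; b <- agg[agg$part == "b", ]; c_ <- agg[agg$part == "c", ]
  expect_equal(a$total, 2); expect_equal(a$positive, 1); expect_equal(a$negative, 1)
  expect_equal(b$total, 1); expect_equal(b$negative, 1)  # flipped from a/b record
  expect_equal(c_$total, 1); expect_equal(c_$positive, 1)
  expect_equal(agg$rank, seq_len(3))
  expect_equal(agg$part[1], "a")
  expect_error(aggregate_by_part(rec[, !names(rec) %in% "significant"]),
               "significance")
})

test_that("per-part coefficient distributions are proper densities", {
  set.seed(39)
  X <- simulate_composition(60, 6, seed = 39)
  y <- simulate_response(attr(X, "coordinates"), seed = 40)
  cfg <- fit_config(model = "ols", normalization = "orthogonal",
                    bootstrap_B = 100, seed = 41)
  rec <- bootstrap_standardize(X, y, cfg)
  cd <- coefficient_distributions(rec)
  expect_setequal(cd$parts, colnames(X))
  expect_true(all(lengths(cd$values) == 5))
  for (p in cd$parts) {
    integ <- sum(diff(cd$grid) * (cd$density[p, -1] + cd$density[p, -length(cd$grid)]) / 2)
    expect_equal(integ, 1, tolerance = 1e-3)
  }
})

test_that("the pivot coefficient aggregates backwards-pivot coefficients", {
  for (D in c(4, 6, 8)) {
    n <- 5 * D
    X <- simulate_composition(n, D, seed = 50 + D)
    y <- simulate_response(attr(X, "coordinates"), seed = 60 + D)
    cfg <- fit_config(model = "ols", normalization = "orthogonal")
    for (l in seq_len(D)) {
      r <- pivot_bpc_ratio(X, y, lead = l, cfg)
      expect_equal(r$ratio, D / 2, tolerance = 1e-6)
    }
    cfgn <- fit_config(model = "ols", normalization = "orthonormal")
    r <- pivot_bpc_ratio(X, y, lead = 1, cfgn)
    expect_equal(r$ratio, sqrt(D * (D - 1) / 2), tolerance = 1e-6)
  }
})

test_that("discriminant mode ranks a perfectly separated logratio first", {
  set.seed(70)
  X <- simulate_composition(80, 6, seed = 70)
  M <- unclass(X)
  lr <- log(M[, 3] / M[, 5])
  y <- as.integer(lr > stats::median(lr))   # classes split by one PLR
  cfg <- fit_config(model = "pls", mode = "discriminant", n_components = 3,
                    normalization = "orthogonal", bootstrap_B = 150, seed = 71)
  rec <- bootstrap_standardize(X, y, cfg)
  top <- rec[order(-abs(rec$standardized)), ][1, ]
  expect_equal(c(top$i, top$j), c(3, 5))
  agg <- aggregate_by_part(rec)
  expect_setequal(agg$part[1:2], c("x3", "x5"))
  expect_error(fit_all_plrs(X, stats::rnorm(80),
                            fit_config(mode = "discriminant")), "binary")
})
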