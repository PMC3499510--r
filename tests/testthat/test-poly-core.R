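test_that("eval_model uses the (x - start) origin and half-open pieces", {
  m <- ppc_model(rbind(piece(0, 10, 3), piece(10, 5, c(1, 0.5))))
  expect_equal(eval_model(m, 7), 3)
  expect_equal(eval_model(m, 12), 2.0)
  expect_error(eval_model(m, 15), "outside")
})

test_that("poly_area matches closed-form antiderivatives", {
  expect_equal(poly_area(5, start = 0, 0, 10), 50)
  expect_equal(poly_area(c(0, 1), start = 0, 0, 2), 2)
  expect_equal(poly_area(c(1, 1, 1), start = 0, 0, 1), 1 + 1 / 2 + 1 / 3)
})

test_that("fit_poly reproduces representable data exactly", {
  s <- rle_signal(c(4, 6), c(5, 5))
  expect_equal(fit_poly(s, 0, 10, 1), c(5, 0), tolerance = 1e-12)
  s2 <- rle_signal(c(2, 2), c(1, 3))
  expect_equal(fit_poly(s2, 0, 4, 0), 2, tolerance = 1e-12)
})

test_that("fit_poly matches the quadrature oracle on random windows", {
  set.seed(101)
  for (i in 1:40) {
    s <- random_signal(sample(3:20, 1))
    L <- signal_length(s)
    a <- sample.int(L - 2, 1) - 1
    b <- a + sample.int(L - a - 1, 1) + 1
    for (ord in 0:2) {
      got <- fit_poly(s, a, b, ord)
      want <- oracle_fit(s, a, b, ord)
      expect_equal(got, want, tolerance = 1e-8)
    }
  }
})

test_that("constrained fits satisfy constraints and match the oracle", {
  s <- rle_signal(c(5, 5), c(5, 5))
  expect_equal(fit_poly_constrained(s, 0, 10, 1, at = 0, value = 5), c(5, 0),
               tolerance = 1e-12)

  z <- rle_signal(10, 0)
  cst <- fit_poly_constrained(z, 0, 10, 1, at = 0, value = 1)
  expect_equal(cst[1], 1, tolerance = 1e-12)   # constraint honoured exactly
  expect_equal(cst, oracle_fit(z, 0, 10, 1, at = 0, value = 1),
               tolerance = 1e-8)

  # two constraints on a line determine it regardless of the data
  s2 <- random_signal(6, seed = 8)
  cst2 <- fit_poly_constrained(s2, 0, signal_length(s2), 2,
                               at = c(0, 4), value = c(1, 9))
  expect_equal(cst2[1] + 0 * cst2[2], 1, tolerance = 1e-10)
  expect_equal(sum(cst2 * c(1, 4, 16)), 9, tolerance = 1e-10)

  set.seed(55)
  for (i in 1:25) {
    s <- random_signal(sample(3:15, 1))
    L <- signal_length(s)
    ord <- sample(1:2, 1)
    at <- runif(1, 0, L)
    v <- runif(1, -2, 12)
    expect_equal(fit_poly_constrained(s, 0, L, ord, at, v),
                 oracle_fit(s, 0, L, ord, at = at, value = v),
                 tolerance = 1e-8)
  }
})

test_that("zero constraints reduce to the unconstrained fit", {
  s <- random_signal(10, seed = 3)
  L <- signal_length(s)
  expect_identical(fit_poly_constrained(s, 0, L, 2, numeric(0), numeric(0)),
                   fit_poly(s, 0, L, 2))
  expect_error(fit_poly_constrained(s, 0, L, 1, at = c(1, 2), value = c(1, 2)),
               "constraints")
})

test_that("fit coefficients transform correctly under window translation", {
  set.seed(77)
  s <- random_signal(12)
  L <- signal_length(s)
  sh <- rle_signal(s$lengths, s$values, origin = s$origin + 1000)
  for (ord in 0:2) {
    c1 <- fit_poly(s, 0, L, ord)
    c2 <- fit_poly(sh, 1000, 1000 + L, ord)
    expect_equal(c1, c2, tolerance = 1e-9)  # same coefficients, shifted origin
  }
})

test_that("the fit minimizes the integral squared error", {
  set.seed(31)
  s <- random_signal(10)
  L <- signal_length(s)
  for (ord in 0:2) {
    cf <- fit_poly(s, 0, L, ord)
    mfit <- ppc_model(piece(0, L, cf))
    e_fit <- local_error(mfit, s)
    for (i in 1:50) {
      alt <- cf + rnorm(ord + 1, sd = 10^runif(1, -4, 0))
      e_alt <- local_error(ppc_model(piece(0, L, alt)), s)
      expect_gte(e_alt, e_fit - 1e-9)
    }
    # higher order never fits worse than the order-0 mean
    e0 <- local_error(ppc_model(piece(0, L, fit_poly(s, 0, L, 0))), s)
    expect_lte(e_fit, e0 + 1e-9)
  }
})

test_that("local_error is exact against a Riemann-sum oracle", {
  m <- ppc_model(piece(0, 4, 1))
  z <- rle_signal(4, 0)
  expect_equal(local_error(m, z), 4)
  expect_equal(local_error(rle_to_model(z), z), 0)

  set.seed(13)
  s <- random_signal(10)
  L <- signal_length(s)
  mm <- ppc_model(rbind(piece(0, floor(L / 3), c(2, 0.1)),
                        piece(floor(L / 3), L - floor(L / 3),
                              c(4, -0.05, 0.001))))
  expect_equal(local_error(mm, s), riemann_error(mm, s, 0, L),
               tolerance = 1e-5)
})

test_that("area_pairs clips windows and is consistent with poly_area", {
  s <- rle_signal(10, 2)
  m <- ppc_model(piece(0, 10, 2))
  ap <- area_pairs(s, m)
  expect_equal(ap$A, 20)
  expect_equal(ap$P, 20)

  mline <- ppc_model(piece(0, 10, c(0, 0.4)))
  expect_equal(area_pairs(s, mline)$P, 20)

  s3 <- rle_signal(c(4, 4, 4), c(1, 2, 3))
  ap3 <- area_pairs(s3, rle_to_model(s3), a = 0, b = 10)  # clips the last run
  expect_equal(nrow(ap3), 3)
  expect_equal(ap3$A, c(4, 8, 6))
  expect_equal(sum(ap3$P),
               sum(vapply(1:3, function(i)
                 poly_area(s3$values[i], 0, max(0, 4 * (i - 1)),
                           min(10, 4 * i)) , numeric(1))))
})
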