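test_that("zero-error merges are accepted, incompatible ones rejected", {
  # two equal runs merge under any criterion at any positive alpha
  s <- rle_signal(c(5, 5), c(2, 2))
  for (mth in c("relative", "poisson")) {
    f <- ppc_smooth(s, mth, alpha = 0.01, order = 0, seed = 1)
    expect_equal(nrow(f$model), 1)
    expect_equal(f$model$c0, 2)
  }
  # a 0 -> 10 step at alpha = 0.01 stays split (merged mean misses by 50%)
  st <- rle_signal(c(5, 5), c(0, 10))
  f <- ppc_smooth(st, "relative", alpha = 0.01, order = 0, seed = 1)
  expect_equal(nrow(f$model), 2)
  expect_equal(f$model$c0, c(0, 10))
})

test_that("strict limit: alpha = 0 returns the input runs bit-exactly", {
  set.seed(2)
  for (i in 1:5) {
    s <- random_signal(30)
    for (ord in 0:1) {
      f <- ppc_smooth(s, "relative", alpha = 0, order = ord, seed = i)
      expect_equal(nrow(f$model), n_runs(s))
      expect_identical(f$model$c0, s$values)
      expect_identical(f$model$length, s$lengths)
      expect_true(all(f$model$order == 0))
    }
  }
})

test_that("loose limit: huge alpha collapses any signal to one piece", {
  set.seed(3)
  for (i in 1:5) {
    s <- random_signal(50)
    f <- ppc_smooth(s, "relative", alpha = 1e9, order = sample(0:1, 1),
                    seed = i)
    expect_equal(nrow(f$model), 1)
    expect_equal(f$model$length, signal_length(s))
  }
})

test_that("models tile the extent and never exceed the input run count", {
  set.seed(4)
  for (mth in c("relative", "poisson", "ttest")) {
    s <- random_signal(80)
    f <- ppc_smooth(s, mth, alpha = 0.5, order = 0, seed = 7)
    m <- f$model
    expect_equal(m$start[1], s$origin)
    expect_equal(sum(m$length), signal_length(s))
    expect_true(all(m$start[-1] == cumsum(m$length)[-nrow(m)]))
    expect_lte(nrow(m), n_runs(s))
    expect_equal(nrow(m), n_runs(s) - f$knots_removed)
  }
})

test_that("noise-free steps are recovered exactly at their boundaries", {
  set.seed(6)
  lens <- sample(1:5, 500, TRUE)
  vals <- rep(1:10, each = 50)
  s <- rle_signal(lens, vals)
  true_bp <- cumsum(lens)[seq(50, 450, by = 50)]
  for (seed in c(1, 99)) {
    f <- ppc_smooth(s, "relative", alpha = 0.01, order = 0, seed = seed)
    expect_equal(nrow(f$model), 10)
    expect_equal(f$model$start[-1], as.numeric(true_bp))
    expect_equal(f$model$c0, as.numeric(1:10))
  }
})

test_that("a knot one run off a noise-free step moves onto the step", {
  # levels 0 and 10 with an interior boundary; alpha small enough that the
  # two-level structure cannot merge, so the only way to zero error is a
  # knot exactly at the step
  s <- rle_signal(c(3, 3, 3, 3), c(0, 0, 10, 10))
  f <- ppc_smooth(s, "relative", alpha = 0.05, order = 0, seed = 5)
  expect_equal(nrow(f$model), 2)
  expect_equal(f$model$start[2], 6)
  expect_equal(local_error(f$model, s), 0)
})

test_that("continuity adjustment joins pieces at a kink without error loss", {
  # a piecewise-linear ramp with a slope change: removal cannot satisfy a
  # tight relative bound, but two constrained pieces sharing the knot value
  # can; the joint knot value must match an independent 1-d minimization
  x <- 0:19
  vals <- ifelse(x < 10, x + 0.5, 10.5 + 3 * (x - 10))
  s <- rle_signal(rep(1, 20), vals)
  f <- ppc_smooth(s, "relative", alpha = 0.05, order = 1, seed = 2)
  m <- f$model
  expect_gt(nrow(m), 1)  # not collapsed
  if (any(m$continuous_left)) {
    k <- which(m$continuous_left)[1]
    xk <- m$start[k]
    left_end <- eval_model(m, xk - 1e-9)
    right_start <- eval_model(m, xk)
    expect_equal(left_end, right_start, tolerance = 1e-6)
    # independent oracle: optimal common value at the knot minimizes the
    # sum of the two constrained quadrature fits' errors
    a <- m$start[k - 1]; b <- m$start[k] + m$length[k]
    errfun <- function(v) {
      cl <- oracle_fit(s, a, xk, 1, at = xk, value = v)
      cr <- oracle_fit(s, xk, b, 1, at = xk, value = v)
      mm <- ppc_model(rbind(piece(a, xk - a, cl), piece(xk, b - xk, cr)))
      local_error(mm, s, a, b)
    }
    vstar <- stats::optimize(errfun, c(min(vals) - 5, max(vals) + 5),
                             tol = 1e-10)$minimum
    expect_equal(right_start, vstar, tolerance = 1e-4)
  }
})

test_that("smoothing is deterministic given the seed", {
  s <- simulate_read_coverage(20000, 75, n_reads = 600, seed = 40)
  f1 <- ppc_smooth(s, "poisson", alpha = 2, order = 1, seed = 12)
  f2 <- ppc_smooth(s, "poisson", alpha = 2, order = 1, seed = 12)
  expect_identical(f1$model, f2$model)
  expect_identical(f1$passes_used, f2$passes_used)
  # and does not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(ppc_smooth(s, "poisson", alpha = 2, seed = 5))
  expect_identical(runif(1), a)
})

test_that("repeated smoothing is reproducible and uses consecutive seeds", {
  s <- random_signal(60, seed = 14)
  r1 <- ppc_smooth_multi(s, k = 3, seed = 5, method = "relative", alpha = 0.3)
  r2 <- ppc_smooth_multi(s, k = 3, seed = 5, method = "relative", alpha = 0.3)
  expect_identical(lapply(r1, `[[`, "model"), lapply(r2, `[[`, "model"))
  expect_equal(vapply(r1, `[[`, integer(1), "seed"), 5:7)
  single <- ppc_smooth(s, "relative", alpha = 0.3, seed = 5)
  expect_identical(r1[[1]]$model, single$model)
})

test_that("method preconditions are enforced", {
  s <- rle_signal(c(2, 2), c(-1, 1))
  expect_error(ppc_smooth(s, "poisson", alpha = 1), "non-negative")
  expect_error(ppc_smooth(rle_signal(4, 1), "ttest", alpha = 0.05, order = 1),
               "order 0")
})

test_that("fitted values and residuals decompose the signal per run", {
  s <- random_signal(40, seed = 17)
  f <- ppc_smooth(s, "relative", alpha = 0.4, order = 1, seed = 2)
  expect_equal(fitted(f) + residuals(f), s$values, tolerance = 1e-9)
  expect_equal(predict(f, s$origin), eval_model(f$model, s$origin))
  cf <- coef(f)
  expect_equal(dim(cf), c(nrow(f$model), 3))
})
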