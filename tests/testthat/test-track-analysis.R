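test_that("icr counts serialized fields", {
  s <- random_signal(100, seed = 1)
  expect_equal(icr(s, rle_to_model(s)), 1.0)

  one <- ppc_model(piece(0, signal_length(s), mean(s$values)))
  expect_equal(icr(s, one), 100)

  m10 <- ppc_model(do.call(rbind, lapply(0:9, function(i)
    piece(i * 10, 10, c(1, 0)))))
  s100 <- rle_signal(rep(1, 100), rnorm(100))
  expect_equal(icr(s100, m10), 200 / 30)
})

test_that("mse is the length-normalized integral squared error", {
  s <- rle_signal(c(5, 5), c(0, 2))
  expect_equal(mse(rle_to_model(s), s), 0)
  expect_equal(mse(ppc_model(piece(0, 10, 1)), s), 1.0)  # the variance

  r <- random_signal(12, seed = 9)
  m <- ppc_model(piece(0, signal_length(r),
                       fit_poly(r, 0, signal_length(r), 2)))
  expect_equal(mse(m, r),
               riemann_error(m, r, 0, signal_length(r)) / signal_length(r),
               tolerance = 1e-5)
})

test_that("fixed windows average by integral mean and conserve area", {
  s <- random_signal(30, seed = 4)
  expect_equal(fixed_window_average(s, 1), compact(s))

  L <- signal_length(s)
  w_all <- fixed_window_average(s, L)
  expect_equal(n_runs(w_all), 1)
  expect_equal(w_all$values, sum(s$lengths * s$values) / L)

  for (w in c(3, 7, 16)) {
    fw <- fixed_window_average(s, w)
    expect_equal(sum(fw$lengths * fw$values), sum(s$lengths * s$values),
                 tolerance = 1e-9)
    expect_equal(signal_length(fw), L)
  }
})

test_that("composite median takes position-wise medians of models", {
  m1 <- ppc_model(piece(0, 10, 1))
  m2 <- ppc_model(piece(0, 10, 2))
  m3 <- ppc_model(rbind(piece(0, 5, 3), piece(5, 5, 0)))
  cm <- composite_median(list(m1, m2, m3))
  expect_equal(eval_model(cm, c(2, 7)), c(2, 1))

  same <- composite_median(list(m3, m3, m3))
  expect_equal(same$start, m3$start)
  expect_equal(same$c0, m3$c0)
  expect_error(composite_median(list(m1, ppc_model(piece(0, 8, 1)))),
               "extent")
})

test_that("median-of-5 composites reduce aCGH probe-wise error on average", {
  sse_single <- sse_comp <- numeric(10)
  for (seed in 1:10) {
    sim <- simulate_acgh(600, 4, min_amplitude = 1, seed = seed)
    lev <- acgh_levels(sim$truth)
    fits <- ppc_smooth_multi(sim$signal, k = 5, seed = seed * 10,
                             method = "ttest", alpha = 0.01, order = 0,
                             keep_signal = FALSE)
    sse_single[seed] <- mean(vapply(fits, function(f)
      probewise_sse(f$model, lev), numeric(1)))
    sse_comp[seed] <- probewise_sse(composite_median(fits), lev)
  }
  expect_lte(mean(sse_comp), mean(sse_single))
})

test_that("probewise_sse matches a per-probe loop", {
  m <- ppc_model(piece(0, 50, 0))
  truth <- rep(0, 50); truth[21:30] <- 1.5
  expect_equal(probewise_sse(m, truth), 10 * 1.5^2)

  sim <- simulate_acgh(200, 2, seed = 3)
  f <- ppc_smooth(sim$signal, "ttest", alpha = 0.01, order = 0, seed = 1)
  lev <- acgh_levels(sim$truth)
  loop <- sum(vapply(1:200, function(i)
    (eval_model(f$model, i - 0.5) - lev[i])^2, numeric(1)))
  expect_equal(probewise_sse(f$model, lev), loop)
})

test_that("majority-overlap labels follow the strict half-width rule", {
  m <- ppc_model(rbind(piece(0, 10, 1), piece(10, 10, 1), piece(20, 10, 1)))
  reg <- data.frame(start = 5, width = 10)  # second window: exactly half
  lab <- label_windows(m, reg)
  expect_identical(lab, c(FALSE, FALSE, FALSE))
  reg2 <- data.frame(start = 4, width = 12)
  expect_identical(label_windows(m, reg2), c(TRUE, TRUE, FALSE))

  # brute-force cross-check on random tilings
  set.seed(8)
  for (i in 1:10) {
    lens <- sample(1:9, 30, TRUE)
    mm <- rle_to_model(rle_signal(lens, runif(30)))
    reg <- data.frame(start = c(10, 60), width = c(15, 9))
    base_ab <- logical(sum(lens))
    for (j in seq_len(nrow(reg)))
      base_ab[(reg$start[j] + 1):(reg$start[j] + reg$width[j])] <- TRUE
    want <- vapply(seq_len(nrow(mm)), function(k) {
      idx <- (mm$start[k] + 1):(mm$start[k] + mm$length[k])
      sum(base_ab[idx]) > mm$length[k] / 2
    }, logical(1))
    expect_identical(label_windows(mm, reg), want)
  }
})

test_that("classification counts sum to the analyzed length", {
  m <- ppc_model(rbind(piece(0, 60, 1), piece(60, 40, 1)))
  reg <- data.frame(start = 50, width = 10)
  lab <- c(FALSE, TRUE)
  cnt <- classification_rates(m, lab, reg)
  expect_equal(sum(cnt), 100)
  expect_equal(unname(cnt["fn"]), 10)  # the aberrant bases sit in piece 1
  expect_equal(unname(cnt["fp"]), 40)

  one <- ppc_model(piece(0, 100, 1))
  cnt1 <- classification_rates(one, TRUE, reg)
  expect_equal(unname(cnt1[c("tp", "fp", "fn")]), c(10, 90, 0))
})

test_that("discontinuities are read off the piece polynomials", {
  cont <- ppc_model(rbind(piece(0, 10, c(0, 1)), piece(10, 10, c(10, -1))))
  expect_length(detect_discontinuities(cont), 0)

  stp <- ppc_model(rbind(piece(0, 100, 0), piece(100, 50, 10)))
  expect_equal(detect_discontinuities(stp), 100)
  expect_length(detect_discontinuities(stp, tolerance_jump = 11), 0)
})

test_that("boundary slopes are inward-oriented and steep_filter works", {
  # exon [100, 300); left boundary piece rises, right boundary piece rises
  # toward the end (inward-down from the right side)
  m <- ppc_model(rbind(piece(0, 100, 0),
                       piece(100, 30, c(10, 1)),
                       piece(130, 140, 40),
                       piece(270, 30, c(40, 1)),
                       piece(300, 100, 0)))
  ex <- data.frame(start = 100, width = 200)
  rec <- boundary_slopes(m, ex)
  expect_equal(rec$direction, c("inward-up", "inward-down"))
  expect_equal(rec$length, c(30, 30))
  expect_equal(rec$slope, c(1, -1))

  st <- steep_filter(rec)
  expect_equal(nrow(st), 2)   # |slope| 1 > 0.7, length 30 > 25
  expect_equal(nrow(steep_filter(rec, min_length = 30)), 0)

  flat <- boundary_slopes(ppc_model(piece(0, 400, 5)), ex)
  expect_true(all(flat$direction == "flat"))
})

test_that("binomial sign test is exact and symmetric", {
  expect_equal(binomial_sign_test(5, 5), 1)
  expect_equal(binomial_sign_test(10, 0), 2 * 0.5^10)
  expect_equal(binomial_sign_test(3, 8), binomial_sign_test(8, 3))
  expect_lt(binomial_sign_test(7086, 5871), 1e-6)
})

test_that("cg_mi approaches its independence and determinism limits", {
  n <- 6000
  m <- ppc_model(do.call(rbind, lapply(0:(n - 1), function(i)
    piece(i * 10, 10, 0))))
  set.seed(12)
  # coverage independent of sequence
  sq <- simulate_genome_seq(n * 10, cg_rate = 0.5, seed = 1)
  cov_ind <- rle_signal(rep(10, n), runif(n), origin = 0)
  expect_lt(cg_mi(m, sq, cov_ind), 0.05)

  # coverage a deterministic function of CG fraction
  raw <- charToRaw(sq)
  cg <- raw == charToRaw("C") | raw == charToRaw("G")
  frac <- vapply(seq_len(n), function(i) mean(cg[(i * 10 - 9):(i * 10)]),
                 numeric(1))
  cov_det <- rle_signal(rep(10, n), frac * 100 + 1)
  expect_gt(cg_mi(m, sq, cov_det), 0.8 * log(16))
  expect_equal(cg_mi(m, sq, cov_det, unit = "bits") * log(2),
               cg_mi(m, sq, cov_det))

  expect_warning(cg_mi(ppc_model(rbind(piece(0, 50, 1), piece(50, 50, 2),
                                       piece(100, 60, 1))),
                       simulate_genome_seq(160, seed = 2),
                       rle_signal(160, 3), bins = 16),
                 "reduced")
})
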