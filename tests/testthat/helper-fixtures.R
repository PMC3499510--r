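# fixtures and independent oracles used across the suite

# random RLE signal with strictly positive, pairwise-distinct values
random_signal <- function(n_runs, max_len = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rle_signal(sample.int(max_len, n_runs, replace = TRUE),
             runif(n_runs, 0.5, 10))
}

# ---------------------------------------------------------------------------
# quadrature oracle for integral least-squares fits: normal equations are
# assembled with stats::integrate (adaptive quadrature), independently of the
# package's closed-form moment accumulation, and solved with base solve().
oracle_fit <- function(signal, a, b, order, at = numeric(0),
                       value = numeric(0)) {
  b_run <- signal$origin + cumsum(c(0, signal$lengths))
  f <- function(x) {
    i <- findInterval(x, b_run, rightmost.closed = FALSE)
    i <- pmin(pmax(i, 1), length(signal$values))
    signal$values[i]
  }
  p <- order + 1
  G <- matrix(0, p, p)
  m <- numeric(p)
  for (j in seq_len(p)) {
    for (k in seq_len(p)) {
      G[j, k] <- stats::integrate(function(x) (x - a)^(j + k - 2), a, b,
                                  rel.tol = 1e-12)$value
    }
    # integrate run by run so the staircase discontinuities are respected
    m[j] <- sum(vapply(seq_along(signal$values), function(r) {
      u <- max(b_run[r], a); w <- min(b_run[r + 1], b)
      if (w <= u) return(0)
      signal$values[r] *
        stats::integrate(function(x) (x - a)^(j - 1), u, w,
                         rel.tol = 1e-12)$value
    }, numeric(1)))
  }
  ncon <- length(at)
  if (ncon == 0) return(solve(G, m))
  B <- t(vapply(at, function(x) (x - a)^(0:order), numeric(p)))
  K <- rbind(cbind(G, t(B)), cbind(B, matrix(0, ncon, ncon)))
  solve(K, c(m, value))[seq_len(p)]
}

# Riemann-sum oracle for the integral squared error of a model
riemann_error <- function(model, signal, a, b, n = 1e5) {
  # snap the grid to the (integer) run boundaries so that midpoint cells
  # never straddle a staircase jump
  n <- (b - a) * ceiling(n / (b - a))
  xs <- seq(a, b, length.out = n + 1)
  mid <- (xs[-1] + xs[-(n + 1)]) / 2
  h <- (b - a) / n
  b_run <- signal$origin + cumsum(c(0, signal$lengths))
  i <- findInterval(mid, b_run, rightmost.closed = FALSE)
  f <- signal$values[pmin(pmax(i, 1), length(signal$values))]
  sum((eval_model(model, mid) - f)^2) * h
}

# model pieces as a data frame for hand-built models
piece <- function(start, length, coef, chrom = "chr1", cont = FALSE) {
  ord <- length(coef) - 1
  data.frame(chrom = chrom, start = start, length = length, order = ord,
             c0 = coef[1], c1 = if (ord >= 1) coef[2] else NA_real_,
             c2 = if (ord >= 2) coef[3] else NA_real_,
             continuous_left = cont)
}
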