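#' Fit a piecewise polynomial curve by bottom-up knot adjustment
#'
#' `ppc_smooth()` converts a run-length-encoded track into a piecewise
#' polynomial curve (PPC) model.  Every run start of the input is initially
#' a knot and every run an order-0 piece.  The algorithm then visits the
#' interior knots in a uniformly random order and attempts, in this order
#' and stopping at the first success per knot:
#'
#' 1. **removal** — replace the two adjacent pieces by a single integral
#'    least-squares polynomial ([fit_poly()]);
#' 2. **continuity adjustment** — refit both pieces with a shared free
#'    value at the knot ([fit_poly_constrained()]), removing the
#'    discontinuity (orders >= 1 only);
#' 3. **relocation** — move the knot to the original run boundary inside
#'    the two adjacent pieces that minimizes the combined local error,
#'    provided the error strictly decreases.
#'
#' Each operation is carried out only if the configured acceptance
#' criterion passes on the affected region (see [check_relative()],
#' [check_poisson()], [check_ttest()]); continuity adjustment additionally
#' requires the combined [local_error()] not to increase.  Subsequent
#' passes revisit only knots modified in the previous pass or adjacent to
#' one, and the procedure ends when no active knots remain (or at
#' `pass_cap`, flagged in the result).  The randomized visiting order is
#' the only stochastic element, so results are reproducible from `seed`;
#' repeated runs with different seeds can produce slightly different,
#' equally acceptable models.
#'
#' Two limits bracket the behaviour: `alpha = 0` returns the input runs
#' unchanged, and a very loose `alpha` (relative method) collapses the
#' signal into a single polynomial piece.
#'
#' @param signal an [rle_signal()] (one chromosome).
#' @param method acceptance criterion: `"poisson"` (default; counts-like
#'   data, requires non-negative values), `"relative"`, or `"ttest"`
#'   (order 0 only; array-CGH-style data).
#' @param alpha non-negative criterion parameter: area-deviation threshold
#'   (relative), dispersion multiplier (poisson), or p-value cutoff
#'   (ttest).
#' @param order maximal polynomial order of the pieces, 0, 1 or 2.
#' @param seed integer seed for the randomized visiting order.
#' @param pass_cap maximal number of passes; default
#'   `100 + 20 * log2(n_runs)`, a safety net not expected to bind.
#' @param keep_signal store the input signal in the fit (needed by
#'   `residuals()`, `plot()` and `summary()` diagnostics).
#'
#' @return An object of class `"ppc"`: a list with elements `model` (a
#'   [ppc_model()]), `passes_used`, `knots_removed`, `capped`, `seed`,
#'   `method`, `alpha`, `order` and (optionally) `signal`, supporting
#'   `print()`, `summary()`, `coef()`, `predict()`, `fitted()`,
#'   `residuals()` and `plot()`.
#' @examples
#' set.seed(1)
#' s <- simulate_read_coverage(10000, read_len = 75, n_reads = 400, seed = 7)
#' fit <- ppc_smooth(s, method = "poisson", alpha = 2, order = 0, seed = 1)
#' fit
#' icr(s, fit)
#' @export
ppc_smooth <- function(signal, method = c("poisson", "relative", "ttest"),
                       alpha = 1, order = 0, seed = 1L, pass_cap = NULL,
                       keep_signal = TRUE) {
  validate_rle_signal(signal)
  method <- match.arg(method)
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 0,
            order %in% 0:2)
  if (method == "ttest" && order != 0)
    stop("the ttest criterion is defined for order 0 (segmentation) only")
  if (method == "poisson" && any(signal$values < 0))
    stop("the poisson criterion needs non-negative values; ",
         "use method 'relative' or 'ttest'")
  n0 <- n_runs(signal)
  if (is.null(pass_cap)) pass_cap <- ceiling(100 + 20 * log2(max(n0, 2)))
  mcode <- match(method, c("relative", "poisson", "ttest")) - 1L

  seed <- as.integer(seed)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  raw <- cpp_smooth(run_boundaries(signal), signal$values, mcode,
                    alpha, as.integer(order), as.integer(pass_cap))

  cf <- raw$coef
  cf[raw$order < 2, 3] <- NA
  cf[raw$order < 1, 2] <- NA
  model <- ppc_model(data.frame(chrom = signal$chrom, start = raw$start,
                                length = raw$length, order = raw$order,
                                c0 = cf[, 1], c1 = cf[, 2], c2 = cf[, 3],
                                continuous_left = raw$continuous))
  if (raw$capped)
    warning("pass cap (", pass_cap, ") reached before convergence; ",
            "the model is valid but may admit further operations")
  structure(list(model = model, passes_used = raw$passes_used,
                 knots_removed = raw$knots_removed, capped = raw$capped,
                 seed = seed, method = method, alpha = alpha, order = order,
                 n_runs_in = n0,
                 signal = if (keep_signal) signal else NULL,
                 call = match.call()),
            class = "ppc")
}

#' Repeated stochastic smoothing
#'
#' Runs [ppc_smooth()] `k` times with seeds `seed, seed + 1, ...`; the
#' ensemble of models measures the uncertainty of the stochastic knot
#' search and feeds [composite_median()].
#'
#' @inheritParams ppc_smooth
#' @param k number of independent runs.
#' @param ... passed on to [ppc_smooth()].
#' @return A list of `k` `"ppc"` fits.
#' @export
ppc_smooth_multi <- function(signal, k, seed = 1L, ...) {
  stopifnot(k >= 1)
  lapply(seq_len(k) - 1L, function(i) ppc_smooth(signal, seed = seed + i, ...))
}

#' @export
print.ppc <- function(x, ...) {
  cat(sprintf("Piecewise polynomial curve fit (method %s, alpha %g, order %d, seed %d)\n",
              x$method, x$alpha, x$order, x$seed))
  cat(sprintf("  %d input runs -> %d pieces in %d passes (%d knots removed%s)\n",
              x$n_runs_in, nrow(x$model), x$passes_used, x$knots_removed,
              if (x$capped) "; pass cap reached" else ""))
  invisible(x)
}

#' @method summary ppc
#' @export
summary.ppc <- function(object, ...) {
  m <- object$model
  out <- list(fit = object,
              seg_len = summary(m$length),
              orders = table(m$order),
              continuous = sum(m$continuous_left))
  if (!is.null(object$signal)) {
    out$icr <- icr(object$signal, m)
    out$mse <- mse(m, object$signal)
  }
  class(out) <- "summary.ppc"
  out
}

#' @export
print.summary.ppc <- function(x, ...) {
  print(x$fit)
  cat("  piece lengths: ")
  print(x$seg_len)
  cat(sprintf("  continuous joins: %d\n", x$continuous))
  if (!is.null(x$icr))
    cat(sprintf("  ICR %.3f, MSE %.5g\n", x$icr, x$mse))
  invisible(x)
}

#' @method coef ppc
#' @export
coef.ppc <- function(object, ...) {
  m <- object$model
  cf <- as.matrix(m[c("c0", "c1", "c2")])
  rownames(cf) <- sprintf("%.0f", m$start)
  cf
}

#' @export
predict.ppc <- function(object, x, ...) eval_model(object$model, x)

#' @export
fitted.ppc <- function(object, ...) {
  if (is.null(object$signal)) stop("fit was built with keep_signal = FALSE")
  ap <- area_pairs(object$signal, object$model)
  ap$P / object$signal$lengths[ap$run]
}

#' @method residuals ppc
#' @export
residuals.ppc <- function(object, ...) {
  if (is.null(object$signal)) stop("fit was built with keep_signal = FALSE")
  ap <- area_pairs(object$signal, object$model)
  object$signal$values[ap$run] - ap$P / object$signal$lengths[ap$run]
}

#' @method plot ppc
#' @export
plot.ppc <- function(x, n_points = 2000, ...) {
  if (is.null(x$signal)) stop("fit was built with keep_signal = FALSE")
  s <- x$signal
  b <- run_boundaries(s)
  plot(NA, xlim = range(b), ylim = range(s$values),
       xlab = sprintf("%s position", s$chrom), ylab = "signal", ...)
  segments(b[-length(b)], s$values, b[-1], s$values, col = grey(0.7))
  ext <- model_extent(x$model)
  xs <- seq(ext[1], ext[2] - 1e-9, length.out = n_points)
  lines(xs, eval_model(x$model, xs), col = "blue", lwd = 1.5)
  invisible(x)
}
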