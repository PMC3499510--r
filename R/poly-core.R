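#' Functional least-squares polynomial fits to run-length-encoded data
#'
#' `fit_poly()` returns the coefficients of the polynomial of the requested
#' order that minimizes the exact integral of the squared difference between
#' the polynomial and the staircase signal over the window `[a, b)`:
#' `int_a^b (poly(x) - f(x))^2 dx`.  The normal equations are assembled from
#' closed-form interval moments accumulated run by run (each run contributes
#' analytically; nothing is ever expanded per base), which keeps the cost
#' proportional to the number of runs in the window.  Coefficients are
#' reported with the window start as polynomial origin, i.e. the fit is
#' `c0 + c1*(x - a) + c2*(x - a)^2`, so they stay well-conditioned on
#' genome-scale coordinates.
#'
#' `fit_poly_constrained()` performs the same minimization subject to exact
#' interpolation constraints `poly(x_k) == v_k` (at most `order` of them),
#' solved by Lagrange elimination; with zero constraints it is identical to
#' `fit_poly()`.
#'
#' Degenerate windows fall back to the largest order whose normal equations
#' are numerically non-singular rather than failing, so genome-scale passes
#' never abort on pathological windows.
#'
#' @param signal an [rle_signal()].
#' @param a,b window, `origin <= a < b <= origin + length`, `b - a >= 1`.
#' @param order polynomial order, 0, 1 or 2.
#' @param at,value equal-length vectors of constraint coordinates (within
#'   `[a, b]`) and values.
#' @return Numeric coefficient vector of length `order + 1` (or shorter
#'   after a degeneracy fallback), origin at `a`.
#' @export
fit_poly <- function(signal, a, b, order) {
  check_window(signal, a, b)
  stopifnot(order %in% 0:2)
  cpp_fit_poly(run_boundaries(signal), signal$values, a, b, as.integer(order),
               numeric(0), numeric(0))
}

#' @rdname fit_poly
#' @export
fit_poly_constrained <- function(signal, a, b, order, at, value) {
  check_window(signal, a, b)
  stopifnot(order %in% 0:2, length(at) == length(value))
  if (length(at) > order)
    stop("more constraints than free degrees of freedom at this order")
  if (length(at) && (any(at < a) || any(at > b)))
    stop("constraint coordinates must lie in [a, b]")
  cpp_fit_poly(run_boundaries(signal), signal$values, a, b, as.integer(order),
               as.numeric(at), as.numeric(value))
}

check_window <- function(signal, a, b) {
  stopifnot(inherits(signal, "rle_signal"))
  lo <- signal$origin
  hi <- signal$origin + signal_length(signal)
  if (a < lo || b > hi || b - a < 1)
    stop(sprintf("window [%g, %g) outside signal extent [%g, %g) or too short",
                 a, b, lo, hi))
}

#' Exact integral of a polynomial piece
#'
#' Antiderivative value of `sum_j c_j (x - start)^j` over `[a, b)`, which
#' must lie within the piece.
#'
#' @param coef coefficient vector `(c0, ..., cp)`.
#' @param start origin of the piece.
#' @param a,b integration window.
#' @return The exact integral as a number.
#' @export
poly_area <- function(coef, start, a, b) {
  if (b < a) stop("empty window")
  j <- seq_along(coef)
  sum(coef / j * ((b - start)^j - (a - start)^j))
}

#' Local error between a model and a signal
#'
#' The exact `int_a^b (model(x) - f(x))^2 dx`, accumulated analytically over
#' the intersection partition of model pieces and signal runs.  Zero if and
#' only if the model equals the staircase almost everywhere on the window.
#'
#' @param model a [ppc_model()] (or fitted `"ppc"`, or an [rle_signal()]
#'   taken as its identity model).
#' @param signal an [rle_signal()].
#' @param a,b window; defaults to the whole signal extent.
#' @return Non-negative number.
#' @export
local_error <- function(model, signal, a = NULL, b = NULL) {
  m <- as_ppc_model(model)
  if (is.null(a)) a <- signal$origin
  if (is.null(b)) b <- signal$origin + signal_length(signal)
  check_window(signal, a, b)
  cpp_local_error(m$start, m$length, m$order, model_coef_matrix(m),
                  run_boundaries(signal), signal$values, a, b)
}

#' Run-wise areas under the signal and under a candidate model
#'
#' For every original run overlapping `[a, b)` (windows clipped to the
#' evaluation range) returns the area `A` under the staircase and the exact
#' integral `P` of the candidate model over the same window.  These pairs
#' are what the acceptance criteria of [ppc_smooth()] compare.
#'
#' @inheritParams local_error
#' @return A data frame with columns `run` (1-based run index), `A`, `P`.
#' @export
area_pairs <- function(signal, model, a = NULL, b = NULL) {
  m <- as_ppc_model(model)
  if (is.null(a)) a <- signal$origin
  if (is.null(b)) b <- signal$origin + signal_length(signal)
  check_window(signal, a, b)
  as.data.frame(cpp_area_pairs(m$start, m$length, m$order,
                               model_coef_matrix(m),
                               run_boundaries(signal), signal$values, a, b))
}
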