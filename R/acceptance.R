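#' Acceptance criteria gating knot operations
#'
#' Every knot operation of [ppc_smooth()] is accepted or rejected by one of
#' three user-selectable criteria, all evaluated on the original runs
#' spanned by the operation's affected region only:
#'
#' * **relative** — accepts iff `|A_i - P_i| <= alpha * max(|A_i|, 1e-12)`
#'   for *all* run-wise area pairs, i.e. the model may displace at most a
#'   fraction `alpha` of each run's area (the `1e-12` floor guards
#'   zero-area runs).
#' * **poisson** — accepts iff `|A_i - P_i| <= alpha * sqrt(max(A_i, 1))`
#'   for all pairs: deviations are bounded in units of the Poisson standard
#'   deviation of the run's count-like area, with `alpha` modulating under-
#'   or over-dispersion.  Requires non-negative areas.
#' * **ttest** — a Welch two-sample t test between the runs on the two
#'   sides of the knot, each run expanded to per-unit observations (value
#'   repeated length times, computed in closed form from run weights).
#'   The merge is allowed iff `p > alpha`, or when either side has fewer
#'   than two observations.  Zero-variance sides are handled
#'   deterministically: equal means accept (p = 1), unequal constant means
#'   reject (p = 0).
#'
#' @param pairs a data frame with columns `A` and `P` as returned by
#'   [area_pairs()].
#' @param alpha positive criterion parameter (threshold, dispersion
#'   multiplier, or p-value cutoff; `alpha = 0` rejects every non-exact
#'   change).
#' @return `TRUE` if the change is acceptable.
#' @export
check_relative <- function(pairs, alpha) {
  stopifnot(alpha >= 0)
  all(abs(pairs$A - pairs$P) <= alpha * pmax(abs(pairs$A), 1e-12))
}

#' @rdname check_relative
#' @export
check_poisson <- function(pairs, alpha) {
  stopifnot(alpha >= 0)
  if (any(pairs$A < 0))
    stop("the poisson criterion needs non-negative (counts-like) areas; ",
         "use method 'relative' or 'ttest' for signed signals")
  all(abs(pairs$A - pairs$P) <= alpha * sqrt(pmax(pairs$A, 1)))
}

#' @rdname check_relative
#' @param left,right the two sides of the knot, as [rle_signal()] objects
#'   or lists with `lengths` and `values`.
#' @export
check_ttest <- function(left, right, alpha) {
  stopifnot(alpha >= 0)
  p <- cpp_welch_p(as.numeric(left$lengths), as.numeric(left$values),
                   as.numeric(right$lengths), as.numeric(right$values))
  p > alpha   # p == 2 encodes "too few observations": always allowed
}

#' @rdname check_relative
#' @export
welch_p_value <- function(left, right) {
  p <- cpp_welch_p(as.numeric(left$lengths), as.numeric(left$values),
                   as.numeric(right$lengths), as.numeric(right$values))
  if (p > 1) NA_real_ else p
}
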