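#' Run-length-encoded genomic signal
#'
#' An `rle_signal` represents a one-dimensional genomic track as ordered runs
#' of `(length, value)` pairs tiling the half-open interval
#' `[origin, origin + sum(lengths))` on one chromosome, using 0-based
#' coordinates.  This piecewise-constant form is the native input of
#' [ppc_smooth()]: the start of every run is a candidate knot.
#'
#' @param lengths integer vector of run lengths (each >= 1), in nucleotides
#'   or probes.
#' @param values numeric vector of run values, same length as `lengths`;
#'   all values must be finite.
#' @param chrom sequence name.
#' @param origin 0-based start coordinate of the first run.
#'
#' @return An object of class `"rle_signal"` with fields `chrom`, `origin`,
#'   `lengths`, `values`.
#' @examples
#' s <- rle_signal(c(5, 3), c(1.5, 2))
#' signal_length(s)   # 8
#' @export
rle_signal <- function(lengths, values, chrom = "chr1", origin = 0) {
  lengths <- as.numeric(lengths)
  values <- as.numeric(values)
  s <- structure(list(chrom = as.character(chrom)[1], origin = as.numeric(origin)[1],
                      lengths = lengths, values = values),
                 class = "rle_signal")
  validate_rle_signal(s)
  s
}

validate_rle_signal <- function(s) {
  if (length(s$lengths) != length(s$values) || length(s$values) < 1)
    stop("an rle_signal needs matching non-empty 'lengths' and 'values'")
  if (any(!is.finite(s$lengths)) || any(s$lengths < 1) ||
      any(s$lengths != round(s$lengths)))
    stop("run lengths must be positive integers")
  if (any(!is.finite(s$values)))
    stop("run values must all be finite")
  if (!is.finite(s$origin)) stop("origin must be finite")
  invisible(s)
}

#' @rdname rle_signal
#' @param s an `rle_signal`.
#' @export
signal_length <- function(s) sum(s$lengths)

#' @rdname rle_signal
#' @export
n_runs <- function(s) length(s$lengths)

# absolute run boundaries: n + 1 values, run i covers [b[i], b[i+1])
run_boundaries <- function(s) s$origin + cumsum(c(0, s$lengths))

#' Merge adjacent equal-valued runs
#'
#' Canonicalizes a run-length encoding by fusing consecutive runs that carry
#' the same value.  Idempotent; preserves total length and total area
#' exactly.
#'
#' @param s an [rle_signal()].
#' @return A compacted `rle_signal` over the same extent.
#' @export
compact <- function(s) {
  stopifnot(inherits(s, "rle_signal"))
  n <- length(s$values)
  if (n == 1L) return(s)
  keep <- c(TRUE, s$values[-1] != s$values[-n])
  grp <- cumsum(keep)
  rle_signal(as.vector(tapply(s$lengths, grp, sum)),
             s$values[keep], s$chrom, s$origin)
}

#' @export
print.rle_signal <- function(x, ...) {
  L <- signal_length(x)
  cat(sprintf("rle_signal: %s:[%g, %g)  %d runs, length %g, mean run %.2f\n",
              x$chrom, x$origin, x$origin + L, n_runs(x), L, L / n_runs(x)))
  cat(sprintf("  values: min %.4g, mean %.4g, max %.4g\n",
              min(x$values), sum(x$values * x$lengths) / L, max(x$values)))
  invisible(x)
}

#' @method as.data.frame rle_signal
#' @export
as.data.frame.rle_signal <- function(x, ...) {
  b <- run_boundaries(x)
  data.frame(chrom = x$chrom, start = b[-length(b)], end = b[-1],
             length = x$lengths, value = x$values)
}

# staircase value at integer positions (vectorized); used by analyses
signal_value_at <- function(s, x) {
  b <- run_boundaries(s)
  i <- findInterval(x, b, rightmost.closed = FALSE)
  if (any(i < 1 | i > n_runs(s)))
    stop("position outside the signal extent")
  s$values[i]
}
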