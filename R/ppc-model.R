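#' Piecewise polynomial model table
#'
#' A `ppc_model` is an ordered, gap-free tiling of an interval by polynomial
#' pieces.  Each row holds one piece: its `start` (0-based), `length`,
#' polynomial `order` (0, 1 or 2), coefficients `c0`, `c1`, `c2` (unused
#' ones are `NA`) and `continuous_left`, which records whether the piece was
#' made continuous with its left neighbour by a knot adjustment.  The piece
#' evaluates to `c0 + c1*(x - start) + c2*(x - start)^2` on
#' `[start, start + length)`.
#'
#' @param df a data frame with columns `chrom`, `start`, `length`, `order`,
#'   `c0`, `c1`, `c2`, `continuous_left`.
#' @return An object of classes `"ppc_model"` and `"data.frame"`.
#' @seealso [ppc_smooth()], [read_ppc()], [write_ppc()]
#' @export
ppc_model <- function(df) {
  need <- c("chrom", "start", "length", "order", "c0", "c1", "c2",
            "continuous_left")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing ppc_model columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$order <- as.integer(df$order)
  m <- structure(df, class = c("ppc_model", "data.frame"))
  validate_ppc_model(m)
  m
}

validate_ppc_model <- function(m) {
  if (nrow(m) < 1) stop("empty model")
  if (any(m$length < 1)) stop("piece lengths must be >= 1")
  if (!all(m$order %in% 0:2)) stop("order must be 0, 1 or 2")
  if (nrow(m) > 1) {
    if (is.unsorted(m$start, strictly = TRUE)) stop("pieces must be sorted by start")
    gap <- m$start[-1] - (m$start[-nrow(m)] + m$length[-nrow(m)])
    if (any(gap != 0)) stop("pieces must tile the extent without gaps or overlaps")
  }
  cf <- as.matrix(m[c("c0", "c1", "c2")])
  for (p in 0:2) {
    r <- m$order == p
    if (any(r & !is.finite(cf[, 1]))) stop("c0 must be finite")
    if (p >= 1 && any(r & !is.finite(cf[, 2]))) stop("c1 missing for order >= 1")
    if (p >= 2 && any(r & !is.finite(cf[, 3]))) stop("c2 missing for order 2")
    if (any(r & !is.na(cf[, p + 1 + seq_len(2 - p)])))
      stop("coefficients beyond the order must be NA")
  }
  invisible(m)
}

# internal: coefficient matrix with NAs as 0, for the compiled evaluators
model_coef_matrix <- function(m) {
  cf <- as.matrix(m[c("c0", "c1", "c2")])
  cf[is.na(cf)] <- 0
  unname(cf)
}

model_extent <- function(m) c(m$start[1], m$start[nrow(m)] + m$length[nrow(m)])

#' Evaluate a piecewise polynomial model
#'
#' Returns the model value at each coordinate: the unique piece containing
#' `x` is evaluated with the `(x - start)` origin convention.  Coordinates
#' at or past the model end are an error (half-open pieces).
#'
#' @param model a [ppc_model()] (or a fitted `"ppc"` object).
#' @param x numeric vector of 0-based coordinates.
#' @return Numeric vector of model values.
#' @export
eval_model <- function(model, x) {
  m <- as_ppc_model(model)
  cpp_eval_model(m$start, m$length, m$order, model_coef_matrix(m),
                 as.numeric(x))
}

#' @rdname eval_model
#' @export
as_ppc_model <- function(model) {
  if (inherits(model, "ppc")) return(model$model)
  if (inherits(model, "ppc_model")) return(model)
  if (inherits(model, "rle_signal")) return(rle_to_model(model))
  stop("cannot interpret object of class ", paste(class(model), collapse = "/"),
       " as a ppc_model")
}

#' Order-0 model from a run-length-encoded signal
#'
#' Encodes each run of `s` as one constant piece, i.e. the identity PPC
#' model of the signal.
#'
#' @param s an [rle_signal()].
#' @return A [ppc_model()].
#' @export
rle_to_model <- function(s) {
  b <- run_boundaries(s)
  ppc_model(data.frame(chrom = s$chrom, start = b[-length(b)],
                       length = s$lengths, order = 0L,
                       c0 = s$values, c1 = NA_real_, c2 = NA_real_,
                       continuous_left = FALSE))
}

#' @export
print.ppc_model <- function(x, ...) {
  ext <- model_extent(x)
  cat(sprintf("ppc_model: %s:[%g, %g)  %d pieces (orders: %s)\n",
              x$chrom[1], ext[1], ext[2], nrow(x),
              paste(names(table(x$order)), table(x$order),
                    sep = "x", collapse = ", ")))
  NextMethod()
}
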