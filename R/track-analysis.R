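#' Inverse compression ratio of a PPC model
#'
#' The cost of the run-length encoding divided by the cost of the PPC, on
#' the canonical field-count serialization: an RLE run costs 2 fields
#' (length, value), a PPC piece costs `1 + (order + 1)` fields (length plus
#' its coefficients).  The identity model has ICR exactly 1; values above 1
#' mean the model is the more compact representation.  ICR >= 1 is not
#' guaranteed: weakly structured (e.g. low-coverage) signals may not
#' compress.
#'
#' @param signal the original [rle_signal()].
#' @param model the [ppc_model()] (or `"ppc"` fit) derived from it.
#' @return A single number.
#' @export
icr <- function(signal, model) {
  m <- as_ppc_model(model)
  (2 * n_runs(signal)) / sum(2 + m$order)
}

#' Mean square error between a model and a track
#'
#' The whole-extent [local_error()] divided by the signal length, i.e. the
#' mean of the squared model-minus-staircase difference over the track.
#'
#' @inheritParams icr
#' @return A single non-negative number.
#' @export
mse <- function(model, signal) {
  local_error(model, signal) / signal_length(signal)
}

# exact staircase integral over each [a_i, b_i), vectorized
signal_area <- function(signal, a, b) {
  bnd <- run_boundaries(signal)
  ca <- cumsum(c(0, signal$values * signal$lengths))
  val_at <- function(x) {
    i <- findInterval(x, bnd, rightmost.closed = FALSE)
    i <- pmin(pmax(i, 1), n_runs(signal))
    ca[i] + signal$values[i] * (x - bnd[i])
  }
  val_at(b) - val_at(a)
}

#' Average a track in non-overlapping fixed-width windows
#'
#' Divides the signal into consecutive windows of width `w` (the last one
#' truncated) and replaces each window by its integral mean, the standard
#' fixed-window alternative to dynamic segmentation.  Total area is
#' preserved exactly.
#'
#' @param signal an [rle_signal()].
#' @param w window width (>= 1).
#' @return An [rle_signal()] of window means (compacted).
#' @export
fixed_window_average <- function(signal, w) {
  stopifnot(w >= 1)
  m <- fixed_window_model(signal, w)
  compact(rle_signal(m$length, m$c0, chrom = signal$chrom,
                     origin = signal$origin))
}

#' @rdname fixed_window_average
#' @return `fixed_window_model()` returns the same windowing as an order-0
#'   [ppc_model()] with one piece per window (not compacted), which is the
#'   honest serialization cost of the fixed-window representation.
#' @export
fixed_window_model <- function(signal, w) {
  L <- signal_length(signal)
  lo <- signal$origin
  edges <- unique(c(seq(lo, lo + L, by = w), lo + L))
  starts <- edges[-length(edges)]
  lens <- diff(edges)
  means <- signal_area(signal, starts, starts + lens) / lens
  ppc_model(data.frame(chrom = signal$chrom, start = starts, length = lens,
                       order = 0L, c0 = means, c1 = NA_real_, c2 = NA_real_,
                       continuous_left = FALSE))
}

#' Median composite of repeated stochastic segmentations
#'
#' Combines `k` PPC models of the same extent into one order-0 model: at
#' every position the composite value is the median of the k model values
#' (models are evaluated on the partition induced by the union of all their
#' breakpoints, at interval midpoints), and the result is compacted.
#' Averaging several stochastic runs this way reduces the error of
#' individual segmentations.
#'
#' @param models a list of [ppc_model()] objects or `"ppc"` fits (identical
#'   extents; an odd count avoids interpolated medians).
#' @return An order-0 [ppc_model()].
#' @export
composite_median <- function(models) {
  ms <- lapply(models, as_ppc_model)
  exts <- lapply(ms, model_extent)
  if (length(unique(vapply(exts, paste, character(1), collapse = ","))) != 1)
    stop("models must share one extent")
  ext <- exts[[1]]
  cuts <- sort(unique(c(ext, unlist(lapply(ms, function(m) m$start)))))
  starts <- cuts[-length(cuts)]
  lens <- diff(cuts)
  mids <- starts + lens / 2
  vals <- apply(vapply(ms, function(m) eval_model(m, mids),
                       numeric(length(mids))), 1, median)
  grp <- cumsum(c(TRUE, vals[-1] != vals[-length(vals)]))
  agg_len <- as.vector(tapply(lens, grp, sum))
  k <- length(agg_len)
  ppc_model(data.frame(chrom = ms[[1]]$chrom[1],
                       start = ext[1] + cumsum(c(0, agg_len))[seq_len(k)],
                       length = agg_len, order = 0L,
                       c0 = vals[!duplicated(grp)],
                       c1 = NA_real_, c2 = NA_real_, continuous_left = FALSE))
}

#' Probe-wise sum of squared distances to the true signal
#'
#' Evaluates the model at each probe centre and accumulates the squared
#' distance to the noise-free truth level, the segmentation-quality measure
#' used to compare array segmentations.
#'
#' @param model a [ppc_model()] or `"ppc"` fit over `n` unit-length probes.
#' @param truth_levels numeric vector of true per-probe levels.
#' @return A single non-negative number.
#' @export
probewise_sse <- function(model, truth_levels) {
  m <- as_ppc_model(model)
  ext <- model_extent(m)
  n <- length(truth_levels)
  stopifnot(ext[2] - ext[1] == n)
  v <- eval_model(m, ext[1] + seq_len(n) - 0.5)
  sum((v - truth_levels)^2)
}

#' Majority-overlap labelling of segments against truth regions
#'
#' Labels each segment (or fixed window) as copy-number aberrant iff
#' strictly more than half of its width overlaps an aberrant truth region.
#' The rule is blind to how the segments were produced, so the labels are
#' the best possible classification achievable by a perfect caller given
#' the segmentation.
#'
#' @param model a [ppc_model()] or `"ppc"` fit tiling the extent.
#' @param regions data frame of aberrant truth regions with columns
#'   `start`, `width` (e.g. [aberrant_regions()]).
#' @return Logical vector, one label per segment.
#' @export
label_windows <- function(model, regions) {
  m <- as_ppc_model(model)
  ov <- overlap_lengths(m$start, m$length, regions)
  ov > m$length / 2
}

overlap_lengths <- function(starts, lens, regions) {
  ov <- numeric(length(starts))
  for (i in seq_len(nrow(regions))) {
    a <- regions$start[i]; b <- a + regions$width[i]
    ov <- ov + pmax(0, pmin(starts + lens, b) - pmax(starts, a))
  }
  ov
}

#' Base-level confusion counts of a labelled segmentation
#'
#' Treats each segment's label as the call for all of its bases and counts
#' true/false positive/negative bases against the aberrant truth regions.
#' The four counts always sum to the analyzed length.
#'
#' @inheritParams label_windows
#' @param labels logical labels from [label_windows()].
#' @return Named numeric vector `tp`, `fp`, `tn`, `fn` (class
#'   `"classification_counts"`).
#' @export
classification_rates <- function(model, labels, regions) {
  m <- as_ppc_model(model)
  stopifnot(length(labels) == nrow(m))
  ov <- overlap_lengths(m$start, m$length, regions)
  tp <- sum(ov[labels])
  fp <- sum(m$length[labels]) - tp
  fn <- sum(ov[!labels])
  tn <- sum(m$length[!labels]) - fn
  structure(c(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "classification_counts")
}

#' Positions of model discontinuities
#'
#' Interior piece boundaries where the left piece's end value and the right
#' piece's start value differ by more than `tolerance_jump`, computed from
#' the piece polynomials' one-sided limits.
#'
#' @param model a [ppc_model()] or `"ppc"` fit.
#' @param tolerance_jump minimal jump magnitude to report.
#' @return Numeric vector of boundary coordinates.
#' @export
detect_discontinuities <- function(model, tolerance_jump = 0) {
  m <- as_ppc_model(model)
  if (nrow(m) < 2) return(numeric(0))
  cf <- model_coef_matrix(m)
  i <- seq_len(nrow(m) - 1)
  left_end <- cf[i, 1] + cf[i, 2] * m$length[i] + cf[i, 3] * m$length[i]^2
  right_start <- cf[i + 1, 1]
  m$start[i + 1][abs(left_end - right_start) > tolerance_jump]
}

#' Slopes of the innermost segments at exon boundaries
#'
#' For each exon side, reports the model piece containing the first base
#' inside the exon, with its slope oriented in the inward direction (so a
#' coverage ramp rising into the exon is "up" on either side).  Pieces with
#' |slope| < 1e-9 are "flat".  `steep_filter()` keeps the records the
#' slope-bias analysis calls steep and long: inward |slope| > 0.7 signal
#' units/nt and piece length > 25 nt.
#'
#' @param model an order-0/1 [ppc_model()] or `"ppc"` fit of the coverage.
#' @param exons data frame of non-overlapping exons with columns `start`,
#'   `width`.
#' @return A data frame with columns `exon`, `side` (`"left"`/`"right"`),
#'   `direction` (`"inward-up"`, `"inward-down"`, `"flat"`), `length`,
#'   `slope` (inward-signed) and `magnitude`.
#' @export
boundary_slopes <- function(model, exons) {
  m <- as_ppc_model(model)
  piece_at <- function(x) findInterval(x, m$start)
  cf <- model_coef_matrix(m)
  rec <- function(exon, side, x, orient) {
    i <- piece_at(x)
    slope <- orient * cf[i, 2]
    data.frame(exon = exon, side = side,
               direction = if (abs(slope) < 1e-9) "flat" else
                 if (slope > 0) "inward-up" else "inward-down",
               length = m$length[i], slope = slope, magnitude = abs(slope))
  }
  out <- lapply(seq_len(nrow(exons)), function(e) rbind(
    rec(e, "left", exons$start[e], +1),
    rec(e, "right", exons$start[e] + exons$width[e] - 1, -1)))
  do.call(rbind, out)
}

#' @rdname boundary_slopes
#' @param records a data frame from `boundary_slopes()`.
#' @param min_slope,min_length steepness and length cutoffs.
#' @export
steep_filter <- function(records, min_slope = 0.7, min_length = 25) {
  records[records$magnitude > min_slope & records$length > min_length, ,
          drop = FALSE]
}

#' Exact two-sided binomial sign test
#'
#' Tests whether upward- and downward-sloping segment counts are consistent
#' with equal probability 1/2; symmetric in its arguments.
#'
#' @param n_up,n_down non-negative counts, `n_up + n_down >= 1`.
#' @return The exact two-sided p-value.
#' @export
binomial_sign_test <- function(n_up, n_down) {
  stopifnot(n_up + n_down >= 1)
  stats::binom.test(n_up, n_up + n_down, p = 0.5)$p.value
}

#' Mutual information between CG content and coverage across segments
#'
#' For each segment of the model (or fixed windowing) computes the CG
#' fraction of the underlying sequence and the mean coverage, discretizes
#' both by equal-frequency binning into `bins` bins, and returns the
#' plug-in mutual information of the binned pair.  Higher MI means the
#' segmentation resolves the CG-coverage dependence better; independent
#' pairs give MI near 0 and a deterministic dependence approaches
#' `log(bins)`.
#'
#' @param model a [ppc_model()], `"ppc"` fit, or [fixed_window_model()]
#'   over `[0, nchar(sequence))`.
#' @param sequence a single character string of bases (e.g. from
#'   [simulate_genome_seq()]).
#' @param coverage the coverage [rle_signal()].
#' @param bins number of equal-frequency bins (default 16); reduced with a
#'   warning when there are fewer segments than bins.
#' @param unit `"nats"` (natural log, default) or `"bits"`.
#' @return A single non-negative number.
#' @export
cg_mi <- function(model, sequence, coverage, bins = 16, unit = c("nats", "bits")) {
  unit <- match.arg(unit)
  m <- as_ppc_model(model)
  raw <- charToRaw(sequence)
  cg <- cumsum(raw == charToRaw("C") | raw == charToRaw("G") |
                 raw == charToRaw("c") | raw == charToRaw("g"))
  cg <- c(0, cg)
  st <- m$start; en <- m$start + m$length
  stopifnot(st[1] >= 0, max(en) <= length(raw))
  cg_frac <- (cg[en + 1] - cg[st + 1]) / m$length
  cov_mean <- signal_area(coverage, st, en) / m$length
  n <- length(cg_frac)
  if (n < bins) {
    while (n < bins && bins > 2) bins <- max(2, floor(bins / 2))
    warning("fewer segments than bins; reduced to ", bins, " bins")
  }
  eq_bin <- function(x) ceiling(rank(x, ties.method = "first") * bins / length(x))
  tab <- table(eq_bin(cg_frac), eq_bin(cov_mean))
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
  if (unit == "bits") mi / log(2) else mi
}
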