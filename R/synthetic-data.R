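#' Simulate coverage from uniform random read placement
#'
#' Places `n_reads` single-end reads of length `read_len` uniformly at
#' random on a chromosome of length `chrom_len` (read starts uniform on
#' `[0, chrom_len - read_len]`, so every read fits) and returns the
#' per-base read-overlap count, run-length encoded.  Total area is exactly
#' `n_reads * read_len`.
#'
#' @param chrom_len chromosome length in nt.
#' @param read_len read length in nt (default 75).
#' @param n_reads number of reads; alternatively give `rate` in reads per
#'   nucleotide and `n_reads = round(rate * chrom_len)` is used.
#' @param rate reads-per-nucleotide placement rate (ignored when `n_reads`
#'   is given).
#' @param seed integer seed.
#' @param chrom sequence name.
#' @return An [rle_signal()] of coverage counts.
#' @export
simulate_read_coverage <- function(chrom_len, read_len = 75, n_reads = NULL,
                                   rate = NULL, seed = 1L, chrom = "chr1") {
  stopifnot(read_len <= chrom_len)
  if (is.null(n_reads)) {
    if (is.null(rate)) stop("give n_reads or rate")
    n_reads <- round(rate * chrom_len)
  }
  with_seed(seed, {
    if (n_reads == 0)
      return(rle_signal(chrom_len, 0, chrom = chrom))
    starts <- sample.int(chrom_len - read_len + 1, n_reads, replace = TRUE) - 1L
    coverage_from_starts(starts, read_len, chrom_len, chrom)
  })
}

# per-base coverage from read start positions (0-based), reads clipped at L
coverage_from_starts <- function(starts, read_len, L, chrom) {
  up <- tabulate(starts + 1L, nbins = L)
  dn <- tabulate(pmin(starts + read_len, L) + 1L, nbins = L)
  cov <- cumsum(up - dn)
  r <- rle(cov)
  rle_signal(r$lengths, r$values, chrom = chrom)
}

# evaluate an expression with a temporary RNG state
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Simulate array-CGH probe signals with planted copy-number events
#'
#' Probe values are drawn from a standard normal (zero mean, unit standard
#' deviation); each of `n_events` events adds a constant amplitude, itself
#' drawn from N(0, 1), over a window of probes whose length is uniform in
#' `event_len_range`.  Events may overlap; the true signal level at a probe
#' is the sum of the amplitudes of events covering it.  All run lengths are
#' 1 (one run per probe).
#'
#' @param n_probes number of probes.
#' @param n_events number of planted events (1-10 in the simulated study
#'   design; 0 gives pure noise).
#' @param event_len_range integer range `(lo, hi)` of event lengths in
#'   probes.  The default (20, 150) is a reconstruction: the published
#'   range is typographically lost in the source.
#' @param min_amplitude optional lower bound on `|amplitude|`; amplitudes
#'   are redrawn until they clear it (0 disables).
#' @param seed integer seed.
#' @param chrom sequence name.
#' @return A list with `signal` (an [rle_signal()]) and `truth` (class
#'   `"acgh_truth"`: data frame of `start`, `length`, `amplitude` with
#'   attribute `n_probes`).
#' @export
simulate_acgh <- function(n_probes, n_events, event_len_range = c(20, 150),
                          min_amplitude = 0, seed = 1L, chrom = "chr1") {
  stopifnot(n_events >= 0, n_events <= 10,
            event_len_range[1] >= 1, event_len_range[2] <= n_probes)
  with_seed(seed, {
    y <- rnorm(n_probes)
    ev <- data.frame(start = integer(0), length = integer(0),
                     amplitude = numeric(0))
    for (i in seq_len(n_events)) {
      len <- sample(event_len_range[1]:event_len_range[2], 1)
      st <- sample.int(n_probes - len + 1, 1) - 1L
      a <- rnorm(1)
      while (abs(a) < min_amplitude) a <- rnorm(1)
      y[(st + 1):(st + len)] <- y[(st + 1):(st + len)] + a
      ev <- rbind(ev, data.frame(start = st, length = len, amplitude = a))
    }
    truth <- structure(ev, class = c("acgh_truth", "data.frame"),
                       n_probes = n_probes)
    list(signal = rle_signal(rep(1, n_probes), y, chrom = chrom),
         truth = truth)
  })
}

#' True probe levels and breakpoints of an aCGH truth
#'
#' `acgh_levels()` returns the noise-free level at every probe (sum of the
#' amplitudes of covering events); `truth_breakpoints()` the 0-based probe
#' boundaries where that level changes.
#'
#' @param truth an `"acgh_truth"` object from [simulate_acgh()].
#' @return Numeric vector of levels / integer vector of breakpoint
#'   positions.
#' @export
acgh_levels <- function(truth) {
  n <- attr(truth, "n_probes")
  lev <- numeric(n)
  for (i in seq_len(nrow(truth)))
    lev[(truth$start[i] + 1):(truth$start[i] + truth$length[i])] <-
      lev[(truth$start[i] + 1):(truth$start[i] + truth$length[i])] +
      truth$amplitude[i]
  lev
}

#' @rdname acgh_levels
#' @export
truth_breakpoints <- function(truth) {
  lev <- acgh_levels(truth)
  which(lev[-1] != lev[-length(lev)])
}

#' Copy-number genome truth
#'
#' Describes a chromosome of length `chrom_len` with a diploid baseline
#' (copy state 2) and regions of altered copy state in 0 (homozygous
#' deletion), 1, 3 or 4 (duplication of one or both copies).
#'
#' @param chrom_len chromosome length in nt.
#' @param regions data frame with columns `start`, `width`, `state`.
#' @param chrom sequence name.
#' @return An object of class `"cn_truth"`.
#' @export
cn_truth <- function(chrom_len, regions, chrom = "chr1") {
  stopifnot(all(regions$state %in% 0:4), all(regions$start >= 0),
            all(regions$start + regions$width <= chrom_len))
  structure(list(chrom = chrom, chrom_len = chrom_len,
                 regions = as.data.frame(regions)),
            class = "cn_truth")
}

#' @rdname cn_truth
#' @param width aberrant region width in nt (around 2 kb in the simulated
#'   study design).
#' @param seed integer seed.
#' @export
random_cn_truth <- function(chrom_len, width = 2000, seed = 1L,
                            chrom = "chr1") {
  with_seed(seed, {
    st <- sample.int(chrom_len - width + 1, 1) - 1L
    state <- sample(c(0L, 1L, 3L, 4L), 1)
    cn_truth(chrom_len, data.frame(start = st, width = width, state = state),
             chrom = chrom)
  })
}

# per-region tiling of [0, chrom_len) with copy states (baseline 2)
cn_state_tiling <- function(truth) {
  reg <- truth$regions[order(truth$regions$start), , drop = FALSE]
  st <- 0; out <- NULL
  for (i in seq_len(nrow(reg))) {
    if (reg$start[i] > st)
      out <- rbind(out, data.frame(start = st, width = reg$start[i] - st,
                                   state = 2L))
    out <- rbind(out, reg[i, c("start", "width", "state")])
    st <- reg$start[i] + reg$width[i]
  }
  if (st < truth$chrom_len)
    out <- rbind(out, data.frame(start = st, width = truth$chrom_len - st,
                                 state = 2L))
  out
}

#' @rdname cn_truth
#' @param truth a `"cn_truth"` object.
#' @export
aberrant_regions <- function(truth) {
  reg <- truth$regions
  reg[reg$state != 2L, c("start", "width"), drop = FALSE]
}

#' Simulate read-depth coverage over a genome with copy-number changes
#'
#' Reads are placed uniformly on the aberrant genome described by `truth`
#' and projected to reference coordinates: the local read-start rate is
#' proportional to the copy state, so expected coverage is
#' `depth * state / 2` per region (deleted regions receive no reads,
#' duplications proportionally more), with edge effects of order
#' `read_len` at region boundaries.
#'
#' @param truth a [cn_truth()].
#' @param read_len read length in nt (75 in the simulated study design).
#' @param depth target diploid coverage depth (30 in the study design).
#' @param seed integer seed.
#' @return An [rle_signal()] of coverage counts over the reference.
#' @export
simulate_cn_coverage <- function(truth, read_len = 75, depth = 30,
                                 seed = 1L) {
  stopifnot(inherits(truth, "cn_truth"))
  tiles <- cn_state_tiling(truth)
  L <- truth$chrom_len
  w <- tiles$width * tiles$state
  n_reads <- round(depth / 2 * sum(w) / read_len)
  with_seed(seed, {
    if (n_reads == 0) return(rle_signal(L, 0, chrom = truth$chrom))
    reg <- sample.int(nrow(tiles), n_reads, replace = TRUE, prob = w)
    starts <- tiles$start[reg] + floor(runif(n_reads) * tiles$width[reg])
    coverage_from_starts(as.integer(starts), read_len, L, truth$chrom)
  })
}

#' Exon structure for RNA-seq coverage simulation
#'
#' Non-overlapping exons with a per-exon expression plateau, optional
#' linear ramps inside each boundary (a ramp of length `len` and slope
#' `slope` replaces the plateau on the innermost `len` bases, reaching the
#' plateau at its inner end), and a low intronic background.  The
#' discontinuity magnitude at an annotated boundary is the difference
#' between the exonic value at the boundary and the background.
#'
#' @param exons data frame with columns `start`, `width`, `level` and
#'   optionally `lramp_len`, `lramp_slope`, `rramp_len`, `rramp_slope`
#'   (0 when absent).
#' @param total_len total simulated region length in nt.
#' @param background intronic/intergenic expected coverage.
#' @param chrom sequence name.
#' @return An object of class `"exon_truth"`.
#' @export
exon_truth <- function(exons, total_len, background = 0.1, chrom = "chr1") {
  exons <- as.data.frame(exons)
  for (col in c("lramp_len", "lramp_slope", "rramp_len", "rramp_slope"))
    if (is.null(exons[[col]])) exons[[col]] <- 0
  o <- order(exons$start)
  exons <- exons[o, , drop = FALSE]
  ends <- exons$start + exons$width
  if (nrow(exons) > 1 && any(exons$start[-1] < ends[-nrow(exons)]))
    stop("exons must be non-overlapping")
  stopifnot(all(ends <= total_len), all(exons$start >= 0), background >= 0)
  structure(list(exons = exons, total_len = total_len,
                 background = background, chrom = chrom),
            class = "exon_truth")
}

# noise-free expected coverage, per base
exon_lambda <- function(truth) {
  lam <- rep(truth$background, truth$total_len)
  ex <- truth$exons
  for (i in seq_len(nrow(ex))) {
    idx <- (ex$start[i] + 1):(ex$start[i] + ex$width[i])
    lam[idx] <- ex$level[i]
    if (ex$lramp_len[i] > 0) {
      k <- seq_len(min(ex$lramp_len[i], ex$width[i]))
      # rises (slope > 0) toward the plateau, reached at the ramp's inner end
      lam[ex$start[i] + k] <- ex$level[i] - ex$lramp_slope[i] * (ex$lramp_len[i] - k + 1)
    }
    if (ex$rramp_len[i] > 0) {
      k <- seq_len(min(ex$rramp_len[i], ex$width[i]))
      lam[ex$start[i] + ex$width[i] - k + 1] <-
        ex$level[i] - ex$rramp_slope[i] * (ex$rramp_len[i] - k + 1)
    }
  }
  pmax(lam, 0)
}

#' Simulate RNA-seq exon coverage
#'
#' Per-base Poisson noise around the expected coverage profile of an
#' [exon_truth()]: expression plateaus on exons, configurable linear ramps
#' inside boundaries, near-zero intronic background, and a discontinuity of
#' the constructed magnitude exactly at each annotated boundary.
#'
#' @param truth an [exon_truth()].
#' @param seed integer seed.
#' @return An [rle_signal()] of coverage counts.
#' @export
simulate_rnaseq_exons <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "exon_truth"))
  lam <- exon_lambda(truth)
  with_seed(seed, {
    y <- rpois(length(lam), lam)
    r <- rle(y)
    rle_signal(r$lengths, as.numeric(r$values), chrom = truth$chrom)
  })
}

#' Random nucleotide sequence with optional CG-rate modulation
#'
#' Generates an i.i.d. random A/C/G/T sequence; when `cg_rate` is a
#' function of position (0-based), the local probability of drawing C or G
#' follows it, which plants a position-dependent CG content for
#' [cg_mi()]-style analyses.
#'
#' @param length sequence length in nt.
#' @param cg_rate scalar CG probability in (0, 1), or a function of the
#'   0-based position vector returning per-base CG probabilities.
#' @param seed integer seed.
#' @return A single character string of bases.
#' @export
simulate_genome_seq <- function(length, cg_rate = 0.5, seed = 1L) {
  with_seed(seed, {
    p <- if (is.function(cg_rate)) cg_rate(seq_len(length) - 1) else
      rep(cg_rate, length)
    stopifnot(all(p >= 0 & p <= 1))
    is_cg <- runif(length) < p
    half <- runif(length) < 0.5
    bases <- ifelse(is_cg, ifelse(half, "C", "G"), ifelse(half, "A", "T"))
    paste(bases, collapse = "")
  })
}
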