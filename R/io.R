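#' Read genomic tracks into run-length-encoded signals
#'
#' `read_bedgraph()` and `read_wiggle()` parse the two standard text
#' carriers of run-length-encoded tracks (via \pkg{rtracklayer}) and return
#' one [rle_signal()] per chromosome.  Internal coordinates are 0-based and
#' half-open; wiggle input (1-based, with `span` honoured) is shifted on
#' ingress.  Gaps between reported intervals are filled with zero-valued
#' runs (no reported interval means zero coverage), adjacent equal-valued
#' runs are merged, and overlapping intervals are an error.
#'
#' @param path path to a bedGraph / wiggle (fixedStep or variableStep) file.
#' @return A single `rle_signal` when the file covers one chromosome,
#'   otherwise a named list of signals, one per chromosome.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  granges_to_signals(gr)
}

#' @rdname read_bedgraph
#' @export
read_wiggle <- function(path) {
  gr <- rtracklayer::import(path, format = "wig")
  granges_to_signals(gr)
}

granges_to_signals <- function(gr) {
  if (length(gr) == 0) stop("no runs")
  score <- S4Vectors::mcols(gr)$score
  if (is.null(score)) stop("track has no score column")
  if (any(!is.finite(score))) stop("non-finite signal value in track")
  out <- list()
  for (ch in as.character(unique(GenomicRanges::seqnames(gr)))) {
    g <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
    o <- order(GenomicRanges::start(g))
    st <- GenomicRanges::start(g)[o] - 1   # to 0-based
    en <- GenomicRanges::end(g)[o]         # 1-based closed end == 0-based open end
    v <- S4Vectors::mcols(g)$score[o]
    if (any(st[-1] < en[-length(en)]))
      stop("overlapping intervals on ", ch)
    gap <- c(0, st[-1] - en[-length(en)])
    lengths <- numeric(0); values <- numeric(0)
    for (i in seq_along(st)) {
      if (gap[i] > 0) { lengths <- c(lengths, gap[i]); values <- c(values, 0) }
      lengths <- c(lengths, en[i] - st[i]); values <- c(values, v[i])
    }
    out[[ch]] <- compact(rle_signal(lengths, values, chrom = ch, origin = st[1]))
  }
  if (length(out) == 1L) out[[1]] else out
}

#' Write a run-length-encoded signal as bedGraph
#'
#' One interval per run (0-based, half-open).  `read_bedgraph()` of the
#' result reproduces `compact(s)`.
#'
#' @param s an [rle_signal()].
#' @param path output file path.
#' @param comments optional character vector written as `##` header lines.
#' @export
write_bedgraph <- function(s, path, comments = character()) {
  stopifnot(inherits(s, "rle_signal"))
  b <- run_boundaries(s)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("## ", comments), con)
  writeLines(sprintf("%s\t%.0f\t%.0f\t%s", s$chrom, b[-length(b)], b[-1],
                     format_num(s$values)), con)
  invisible(path)
}

# 17 significant digits: doubles survive the text round trip exactly
format_num <- function(x) sprintf("%.17g", x)

#' Plain two-column RLE files
#'
#' A headerless `length<TAB>value` table (lines starting with `#` are
#' skipped), the simplest on-disk form of a run-length-encoded signal.
#'
#' @param path file path.
#' @param chrom,origin sequence name and 0-based start assigned to the
#'   signal on read.
#' @return `read_rle()` returns an [rle_signal()].
#' @export
read_rle <- function(path, chrom = "chr1", origin = 0) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("length", "value"),
                          colClasses = "numeric")
  if (nrow(df) == 0) stop("no runs")
  rle_signal(df$length, df$value, chrom = chrom, origin = origin)
}

#' @rdname read_rle
#' @param s an [rle_signal()].
#' @param comments optional `##` header lines.
#' @export
write_rle <- function(s, path, comments = character()) {
  stopifnot(inherits(s, "rle_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("## ", comments), con)
  writeLines(sprintf("%.0f\t%s", s$lengths, format_num(s$values)), con)
  invisible(path)
}

#' Read and write piecewise polynomial model tables
#'
#' The on-disk PPC format is a TSV with one piece per row:
#' `chrom start length order c0 [c1 [c2]] continuous_left`, with a `#`
#' header line, optional `##` comment lines, floats carrying 10
#' significant digits, and one coefficient column per polynomial order.
#' `read_ppc(write_ppc(m))` reproduces `m` bit-exactly at that precision.
#'
#' @param model a [ppc_model()] or fitted `"ppc"` object.
#' @param path file path.
#' @param comments optional character vector written as `##` lines.
#' @return `read_ppc()` returns a [ppc_model()].
#' @export
write_ppc <- function(model, path, comments = character()) {
  m <- as_ppc_model(model)
  maxord <- max(m$order)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("## ", comments), con)
  writeLines(paste(c("#chrom", "start", "length", "order",
                     paste0("c", 0:maxord), "continuous_left"),
                   collapse = "\t"), con)
  cf <- as.matrix(m[c("c0", "c1", "c2")])
  rows <- vapply(seq_len(nrow(m)), function(i) {
    coefs <- sprintf("%.10g", cf[i, seq_len(m$order[i] + 1)])
    paste(c(m$chrom[i], sprintf("%.0f", m$start[i]),
            sprintf("%.0f", m$length[i]), m$order[i], coefs,
            as.integer(m$continuous_left[i])), collapse = "\t")
  }, character(1))
  writeLines(rows, con)
  invisible(path)
}

#' @rdname write_ppc
#' @export
read_ppc <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) stop("no pieces in ", path)
  rows <- strsplit(lines, "\t", fixed = TRUE)
  parse_row <- function(f, ln) {
    if (length(f) < 6) stop("malformed PPC row at line ", ln)
    ord <- as.integer(f[4])
    if (is.na(ord) || ord < 0 || ord > 2 || length(f) != 5 + ord + 1)
      stop("bad order/field count in PPC row at line ", ln)
    coefs <- as.numeric(f[5:(5 + ord)])
    c(f[1], f[2], f[3], f[4], coefs[1],
      if (ord >= 1) coefs[2] else NA, if (ord >= 2) coefs[3] else NA,
      f[length(f)])
  }
  parsed <- t(vapply(seq_along(rows), function(i) parse_row(rows[[i]], i),
                     character(8)))
  ppc_model(data.frame(chrom = parsed[, 1],
                       start = as.numeric(parsed[, 2]),
                       length = as.numeric(parsed[, 3]),
                       order = as.integer(parsed[, 4]),
                       c0 = as.numeric(parsed[, 5]),
                       c1 = as.numeric(parsed[, 6]),
                       c2 = as.numeric(parsed[, 7]),
                       continuous_left = as.logical(as.integer(parsed[, 8]))))
}
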