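#' Binned signal track
#'
#' A sparse fixed-bin-width signal container: per chromosome a numeric vector
#' indexed from bin 0 (element 1). Bins never written read back as 0
#' (missing-as-zero contract). Units are tags per 10 million unless rescaled.
#'
#' @param bin_width bin width in bp
#' @param values named list of numeric vectors, one per chromosome; element
#'   `i` is the value of bin `i - 1` (bp `[(i-1)*bin_width, i*bin_width)`)
#' @return an object of class `signal_track`
#' @export
signal_track <- function(bin_width, values = list()) {
  if (bin_width <= 0 || bin_width != round(bin_width))
    stop("bin_width must be a positive integer")
  stopifnot(is.list(values))
  if (length(values) && is.null(names(values)))
    stop("values must be a named list (chromosome -> vector)")
  structure(list(bin_width = as.integer(bin_width), values = values),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: bin_width=%d bp, %d chromosome(s), %d bins\n",
              x$bin_width, length(x$values), sum(lengths(x$values))))
  invisible(x)
}

#' Query bin values (missing bins are 0)
#' @param track a signal_track
#' @param chrom chromosome name
#' @param bins 0-based bin indices
#' @return numeric vector
#' @export
track_values <- function(track, chrom, bins) {
  v <- track$values[[chrom]]
  out <- numeric(length(bins))
  if (!is.null(v)) {
    in_range <- bins >= 0 & bins < length(v)
    out[in_range] <- v[bins[in_range] + 1]
  }
  out
}

#' Read a bedGraph into a signal track
#'
#' Records must align to the stated bin grid: start and end multiples of
#' `bin_width` (a record may span several whole bins). A final short record is
#' accepted only if it ends exactly at the chromosome length given in
#' `chrom_sizes`.
#'
#' @param path bedGraph path
#' @param bin_width grid width in bp
#' @param chrom_sizes optional named length vector (enables short final bins)
#' @return a [signal_track()]
#' @export
read_bedgraph <- function(path, bin_width, chrom_sizes = NULL) {
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- nzchar(lines) & !grepl("^(track|browser|#)", lines)
  lines <- lines[keep]; lineno <- lineno[keep]
  vals <- list()
  if (length(lines)) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 4))
      stop(sprintf("parse error at line %d: fewer than 4 fields",
                   lineno[which(lengths(fields) < 4)[1]]))
    chrom <- vapply(fields, `[`, character(1), 1)
    start <- as.numeric(vapply(fields, `[`, character(1), 2))
    end <- as.numeric(vapply(fields, `[`, character(1), 3))
    value <- as.numeric(vapply(fields, `[`, character(1), 4))
    if (anyNA(start) || anyNA(end) || anyNA(value))
      stop("parse error: non-numeric coordinates or value")
    end_ok <- end %% bin_width == 0
    if (!is.null(chrom_sizes))
      end_ok <- end_ok | (end == chrom_sizes[chrom] & !is.na(chrom_sizes[chrom]))
    bad <- which(start %% bin_width != 0 | !end_ok | end <= start)
    if (length(bad))
      stop(sprintf("record not aligned to %d bp grid at line %d: %s:%g-%g",
                   bin_width, lineno[bad[1]], chrom[bad[1]], start[bad[1]], end[bad[1]]))
    for (cn in unique(chrom)) {
      i <- chrom == cn
      b0 <- start[i] %/% bin_width
      b1 <- (end[i] - 1) %/% bin_width          # inclusive final bin
      v <- numeric(max(b1) + 1)
      for (j in seq_along(b0)) v[(b0[j]:b1[j]) + 1] <- value[i][j]
      vals[[cn]] <- v
    }
  }
  signal_track(bin_width, vals)
}

#' Write a signal track as bedGraph
#'
#' Runs of equal-valued adjacent bins are collapsed; zero bins are omitted.
#'
#' @param track a signal_track
#' @param path output path
#' @param chrom_sizes optional sizes to truncate the final bin
#' @export
write_bedgraph <- function(track, path, chrom_sizes = NULL) {
  bw <- track$bin_width
  rows <- list()
  for (cn in names(track$values)) {
    v <- track$values[[cn]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    s <- starts[keep] * bw
    e <- ends[keep] * bw
    if (!is.null(chrom_sizes) && !is.na(chrom_sizes[cn]))
      e <- pmin(e, chrom_sizes[cn])
    rows[[cn]] <- data.frame(chrom = cn, start = s, end = e,
                             value = r$values[keep])
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(),
               end = numeric(), value = numeric())
  utils::write.table(format(df, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Sum of track signal over intervals, pro-rating partial bins
#'
#' @param track a signal_track
#' @param gr GRanges of intervals
#' @return numeric vector of per-interval sums (partial bin values weighted by
#'   the fraction of the bin covered)
#' @export
track_interval_sums <- function(track, gr) {
  bw <- track$bin_width
  chr <- as.character(seqnames(gr))
  s <- start0(gr); e <- end0(gr)
  vapply(seq_along(gr), function(i) {
    b0 <- s[i] %/% bw; b1 <- (e[i] - 1) %/% bw
    bins <- b0:b1
    v <- track_values(track, chr[i], bins)
    lo <- pmax(bins * bw, s[i]); hi <- pmin((bins + 1) * bw, e[i])
    sum(v * (hi - lo) / bw)
  }, numeric(1))
}

#' Mean track signal over an arbitrary (possibly fractional-bp) window
#' @param track a signal_track
#' @param chrom chromosome
#' @param from,to window bounds (0-based half-open; `from < to`); positions
#'   outside recorded bins contribute 0
#' @return mean signal per bp over the window
#' @export
track_region_mean <- function(track, chrom, from, to) {
  if (to <= from) stop("empty window")
  bw <- track$bin_width
  b0 <- floor(from / bw); b1 <- ceiling(to / bw) - 1
  bins <- b0:b1
  v <- track_values(track, chrom, bins)
  lo <- pmax(bins * bw, from); hi <- pmin((bins + 1) * bw, to)
  sum(v * (hi - lo)) / (to - from)
}

#' Multiply every bin of a track by a positive factor
#' @param track a signal_track
#' @param factor positive scalar (e.g. a ChIP-rx factor)
#' @return rescaled signal_track on the same bin grid
#' @export
scale_track <- function(track, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0)
    stop("scale factor must be a positive scalar")
  track$values <- lapply(track$values, function(v) v * factor)
  track
}
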