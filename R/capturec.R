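#' Capture-C experiment design for one probe
#'
#' @param probe_id label
#' @param probe GRanges(1): probe hybridization site
#' @param domain GRanges(1): interaction-domain bounds (probe must lie inside)
#' @param exclusion_radius bp around the probe removed from testing
#'   (default 10000, the proximity-ligation artifact zone)
#' @param n_replicates replicates per condition (>= 2 for testing)
#' @return object of class `capture_design`
#' @export
capture_design <- function(probe_id, probe, domain,
                           exclusion_radius = 10000, n_replicates = 3) {
  stopifnot(length(probe) == 1, length(domain) == 1)
  if (exclusion_radius < 0) stop("exclusion_radius must be >= 0")
  if (as.character(seqnames(probe)) != as.character(seqnames(domain)) ||
      start0(probe) < start0(domain) || end0(probe) > end0(domain))
    stop("probe must lie inside the interaction domain")
  structure(list(probe_id = probe_id, probe = probe, domain = domain,
                 exclusion_radius = exclusion_radius,
                 n_replicates = as.integer(n_replicates)),
            class = "capture_design")
}

#' Per-DpnII-fragment count matrix
#'
#' @param fragments sorted, disjoint GRanges of cis restriction fragments
#' @param counts non-negative integer matrix, fragments x samples; column
#'   names `<condition>_<rep>` with condition in {control, dot1li}
#' @param cis_totals named per-sample totals of cis-reported reads (>= column
#'   sums)
#' @return object of class `fragment_counts`
#' @export
fragment_counts <- function(fragments, counts, cis_totals) {
  counts <- as.matrix(counts)
  if (length(fragments) != nrow(counts))
    stop("counts must have one row per fragment")
  if (any(counts < 0)) stop("negative counts")
  if (is.null(colnames(counts))) stop("counts need '<condition>_<rep>' column names")
  parsed <- parse_sample_names(colnames(counts))
  if (!setequal(names(cis_totals), colnames(counts)))
    stop("cis_totals must be named by sample")
  cis_totals <- cis_totals[colnames(counts)]
  low <- cis_totals < colSums(counts)
  if (any(low))
    stop("cis_totals below per-fragment sums for: ",
         paste(colnames(counts)[low], collapse = ", "))
  if (is.unsorted(order(as.character(seqnames(fragments)),
                        BiocGenerics::start(fragments))) ||
      any(GenomicRanges::countOverlaps(fragments, fragments,
                                       ignore.strand = TRUE) > 1))
    stop("fragments must be sorted and non-overlapping")
  structure(list(fragments = fragments, counts = counts,
                 samples = parsed, cis_totals = cis_totals,
                 normalized = FALSE),
            class = "fragment_counts")
}

parse_sample_names <- function(nms) {
  m <- regmatches(nms, regexec("^(control|dot1li)_([0-9]+)$", nms))
  bad <- lengths(m) != 3
  if (any(bad))
    stop("sample names must be '<condition>_<rep>' with condition control/dot1li: ",
         paste(nms[bad], collapse = ", "))
  data.frame(sample = nms,
             condition = vapply(m, `[`, character(1), 2),
             replicate = as.integer(vapply(m, `[`, character(1), 3)),
             stringsAsFactors = FALSE)
}

#' @export
print.fragment_counts <- function(x, ...) {
  cat(sprintf("fragment_counts: %d fragments x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Normalize fragment counts to reads per 100k cis-reported reads
#'
#' Each count in sample s becomes `count * 1e5 / cis_totals[s]`.
#'
#' @param fcm a [fragment_counts()] object
#' @return normalized fragment_counts (flagged `normalized = TRUE`)
#' @export
normalize_counts <- function(fcm) {
  zero <- fcm$cis_totals <= 0
  if (any(zero))
    stop("zero cis_total for replicate(s): ",
         paste(names(fcm$cis_totals)[zero], collapse = ", "))
  fcm$counts <- sweep(fcm$counts, 2, 1e5 / fcm$cis_totals, `*`)
  fcm$normalized <- TRUE
  fcm
}

#' Filter interaction peaks per the published rules
#'
#' Retained iff on the probe chromosome (cis), fully inside the interaction
#' domain, and with edge-to-edge distance from the probe hybridization site
#' strictly greater than the exclusion radius (overlap counts as distance 0).
#'
#' @param peaks GRanges of candidate interaction peaks
#' @param design a [capture_design()]
#' @return retained peaks
#' @export
filter_peaks <- function(peaks, design) {
  if (!length(peaks)) return(peaks)
  cis <- as.character(seqnames(peaks)) == as.character(seqnames(design$probe))
  inside <- cis &
    start0(peaks) >= start0(design$domain) &
    end0(peaks) <= end0(design$domain)
  d <- rep(Inf, length(peaks))
  d[cis] <- GenomicRanges::distance(peaks[cis], design$probe,
                                    ignore.strand = TRUE)
  d[is.na(d)] <- Inf
  peaks[inside & d > design$exclusion_radius]
}

#' Test one interaction peak for differential contact
#'
#' Pairs every fragment overlapping the peak (>= 1 bp) with itself across
#' conditions, replicate i of control against replicate i of dot1li, pooling
#' fragments and replicates into one paired signed-rank test.
#'
#' @param peak GRanges(1), already past [filter_peaks()]
#' @param fcm normalized [fragment_counts()]
#' @param exact_limit passed to [paired_signed_rank()]
#' @return list(peak, n_fragments, n_pairs, mean_control, mean_dot1li,
#'   mean_delta, statistic, p_raw)
#' @export
test_peak <- function(peak, fcm, exact_limit = 25) {
  idx <- which(IRanges::overlapsAny(fcm$fragments, peak, ignore.strand = TRUE))
  test_peak_idx(peak, idx, fcm, exact_limit)
}

# worker shared with run_capture_diff, which batches the overlap lookup
test_peak_idx <- function(peak, idx, fcm, exact_limit = 25) {
  if (!fcm$normalized)
    warning("testing raw counts; call normalize_counts() first")
  if (!length(idx)) stop("peak overlaps no fragment")
  ctrl_s <- fcm$samples[fcm$samples$condition == "control", ]
  trt_s <- fcm$samples[fcm$samples$condition == "dot1li", ]
  if (nrow(ctrl_s) != nrow(trt_s))
    stop("unequal replicate counts across conditions; pairing undefined")
  ctrl_s <- ctrl_s[order(ctrl_s$replicate), ]
  trt_s <- trt_s[order(trt_s$replicate), ]
  ctrl <- as.vector(fcm$counts[idx, ctrl_s$sample, drop = FALSE])
  trt <- as.vector(fcm$counts[idx, trt_s$sample, drop = FALSE])
  tst <- paired_signed_rank(ctrl, trt, exact_limit = exact_limit)
  list(peak = peak,
       n_fragments = length(idx),
       n_pairs = length(ctrl),
       mean_control = mean(ctrl),
       mean_dot1li = mean(trt),
       mean_delta = mean(trt - ctrl),
       statistic = tst$statistic,
       p_raw = tst$p.value)
}

#' Smoothed differential Capture-C track
#'
#' Per fragment, the mean over replicates of (dot1li - control) normalized
#' counts, smoothed by a centred sliding mean of `window_fragments` fragments
#' (odd; truncated at the ends).
#'
#' @param fcm normalized [fragment_counts()]
#' @param window_fragments odd window size in fragments (default 5; 1 = raw)
#' @return GRanges of fragments with a `score` column (the smoothed signed
#'   difference), writable as bedGraph via [write_bed()]-style columns
#' @export
differential_track <- function(fcm, window_fragments = 5) {
  if (window_fragments %% 2 == 0 || window_fragments < 1)
    stop("window_fragments must be odd and >= 1")
  ctrl_s <- fcm$samples[fcm$samples$condition == "control", ]
  trt_s <- fcm$samples[fcm$samples$condition == "dot1li", ]
  if (nrow(ctrl_s) != nrow(trt_s))
    stop("unequal replicate counts across conditions")
  delta <- rowMeans(fcm$counts[, trt_s$sample, drop = FALSE]) -
    rowMeans(fcm$counts[, ctrl_s$sample, drop = FALSE])
  half <- (window_fragments - 1) / 2
  n <- length(delta)
  sm <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(delta[lo:hi])
  }, numeric(1))
  out <- fcm$fragments
  mcols(out)$score <- sm
  out
}

#' Write a per-fragment signed track as bedGraph
#' @param gr GRanges with a `score` column (e.g. from [differential_track()])
#' @param path output path
#' @export
write_fragment_bedgraph <- function(gr, path) {
  df <- data.frame(as.character(seqnames(gr)), start0(gr), end0(gr),
                   mcols(gr)$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Differential Capture-C analysis for one probe
#'
#' Normalizes, filters the candidate peaks, tests each retained peak with the
#' paired signed-rank test, Holm-adjusts within the probe's retained-peak
#' family, attaches the enhancer class by >= 1 bp overlap (KEE precedence)
#' when calls are provided, and emits the smoothed differential track.
#'
#' @param design a [capture_design()]
#' @param fcm a raw [fragment_counts()] (normalized internally)
#' @param peaks candidate interaction peak GRanges
#' @param enhancers optional enhancer-call GRanges with `klass`
#' @param window_fragments smoothing window for the differential track
#' @param exact_limit passed to the signed-rank test
#' @return list(results = data.frame (one row per retained peak),
#'   track = GRanges with score, design = design)
#' @export
run_capture_diff <- function(design, fcm, peaks, enhancers = NULL,
                             window_fragments = 5, exact_limit = 25) {
  fcm <- if (fcm$normalized) fcm else normalize_counts(fcm)
  kept <- filter_peaks(peaks, design)
  track <- differential_track(fcm, window_fragments)
  if (!length(kept)) {
    res <- data.frame(probe_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      enhancer_class = character(), n_fragments = integer(),
                      n_pairs = integer(), mean_control = numeric(),
                      mean_dot1li = numeric(), mean_delta = numeric(),
                      p_raw = numeric(), p_holm = numeric())
    return(list(results = res, track = track, design = design))
  }
  ov <- GenomicRanges::findOverlaps(kept, fcm$fragments, ignore.strand = TRUE)
  idx_by_peak <- split(subjectHits(ov), factor(queryHits(ov),
                                               levels = seq_along(kept)))
  tests <- lapply(seq_along(kept), function(i)
    test_peak_idx(kept[i], idx_by_peak[[i]], fcm, exact_limit = exact_limit))
  klass <- rep("unassigned", length(kept))
  if (!is.null(enhancers) && length(enhancers)) {
    kl <- mcols(enhancers)$klass
    hit_kee <- IRanges::overlapsAny(kept, enhancers[kl == "KEE"],
                                    ignore.strand = TRUE)
    hit_non <- IRanges::overlapsAny(kept, enhancers[kl == "nonKEE"],
                                    ignore.strand = TRUE)
    klass[hit_non] <- "nonKEE"
    klass[hit_kee] <- "KEE"     # KEE precedence
  }
  p_raw <- vapply(tests, `[[`, numeric(1), "p_raw")
  res <- data.frame(
    probe_id = design$probe_id,
    chrom = as.character(seqnames(kept)),
    start = start0(kept), end = end0(kept),
    enhancer_class = klass,
    n_fragments = vapply(tests, `[[`, integer(1), "n_fragments"),
    n_pairs = vapply(tests, `[[`, integer(1), "n_pairs"),
    mean_control = vapply(tests, `[[`, numeric(1), "mean_control"),
    mean_dot1li = vapply(tests, `[[`, numeric(1), "mean_dot1li"),
    mean_delta = vapply(tests, `[[`, numeric(1), "mean_delta"),
    p_raw = p_raw,
    p_holm = holm_adjust(p_raw),
    stringsAsFactors = FALSE)
  list(results = res, track = track, design = design)
}

#' Read a fragment count matrix from TSV
#'
#' Columns: chrom, start, end, then one column per sample named
#' `<condition>_<rep>`. Cis totals are read from a companion two-column TSV
#' (sample, cis_total); if absent they default to the column sums.
#'
#' @param path counts TSV
#' @param cis_totals_path optional totals TSV
#' @return a [fragment_counts()]
#' @export
read_fragment_counts <- function(path, cis_totals_path = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("chrom", "start", "end") %in% names(tab)))
    stop("counts table must start with chrom, start, end")
  frags <- granges0(tab$chrom, tab$start, tab$end)
  cnt <- as.matrix(tab[, setdiff(names(tab), c("chrom", "start", "end")),
                       drop = FALSE])
  if (is.null(cis_totals_path)) {
    totals <- colSums(cnt)
  } else {
    tt <- utils::read.table(cis_totals_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    totals <- stats::setNames(tt$cis_total, tt$sample)
  }
  fragment_counts(frags, cnt, totals)
}

#' Write a fragment count matrix (inverse of [read_fragment_counts()])
#' @param fcm a [fragment_counts()]
#' @param path counts TSV path
#' @param cis_totals_path optional totals TSV path
#' @export
write_fragment_counts <- function(fcm, path, cis_totals_path = NULL) {
  df <- data.frame(chrom = as.character(seqnames(fcm$fragments)),
                   start = start0(fcm$fragments), end = end0(fcm$fragments),
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(fcm$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cis_totals_path))
    utils::write.table(data.frame(sample = names(fcm$cis_totals),
                                  cis_total = as.numeric(fcm$cis_totals)),
                       cis_totals_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read a capture design table
#'
#' TSV with header: probe_id, chrom, start, end, domain_start, domain_end
#' (0-based half-open), optional exclusion_radius and n_replicates columns.
#'
#' @param path design TSV
#' @return list of [capture_design()] objects, one per row
#' @export
read_capture_design <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "start", "end", "domain_start", "domain_end")
  if (!all(need %in% names(tab)))
    stop("design table must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    capture_design(
      probe_id = tab$probe_id[i],
      probe = granges0(tab$chrom[i], tab$start[i], tab$end[i]),
      domain = granges0(tab$chrom[i], tab$domain_start[i], tab$domain_end[i]),
      exclusion_radius = if ("exclusion_radius" %in% names(tab))
        tab$exclusion_radius[i] else 10000,
      n_replicates = if ("n_replicates" %in% names(tab))
        tab$n_replicates[i] else 3)
  })
}

#' Write a capture design table
#' @param designs list of [capture_design()] objects
#' @param path output TSV
#' @export
write_capture_design <- function(designs, path) {
  df <- do.call(rbind, lapply(designs, function(d) data.frame(
    probe_id = d$probe_id,
    chrom = as.character(seqnames(d$probe)),
    start = start0(d$probe), end = end0(d$probe),
    domain_start = start0(d$domain), domain_end = end0(d$domain),
    exclusion_radius = d$exclusion_radius,
    n_replicates = d$n_replicates)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
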