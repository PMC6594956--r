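#' @importFrom GenomicRanges GRanges reduce distanceToNearest countOverlaps
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqnames seqlengths seqlevels
NULL

# All coordinates exposed by this package are 0-based half-open (BED
# convention). GRanges objects are 1-based closed internally; the two helper
# converters below are the only place the shift happens.

#' Build a GRanges from 0-based half-open coordinates
#'
#' @param chrom character vector of chromosome names
#' @param start,end 0-based half-open coordinates (start < end)
#' @param ... metadata columns
#' @param strand strand vector ("+", "-", "." or "*"); "." maps to "*"
#' @return a GRanges
#' @export
granges0 <- function(chrom, start, end, ..., strand = NULL) {
  if (any(start < 0)) stop("negative start coordinate")
  if (any(end <= start)) stop("interval with end <= start")
  s <- if (is.null(strand)) rep("*", length(chrom))
       else rep_len(ifelse(strand == ".", "*", strand), length(chrom))
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end), strand = s, ...)
}

#' 0-based starts / exclusive ends of a GRanges
#' @param gr a GRanges
#' @return integer vector
#' @export
start0 <- function(gr) BiocGenerics::start(gr) - 1L

#' @rdname start0
#' @export
end0 <- function(gr) BiocGenerics::end(gr)

#' Read a two-column chrom.sizes file
#'
#' @param path file with lines `<name>\t<length>`
#' @return named integer vector of chromosome lengths
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("name", "length"),
                           colClasses = c("character", "numeric"))
  chrom_sizes(tab$name, tab$length)
}

#' Construct a validated chrom-sizes vector
#' @param name chromosome names (unique)
#' @param length chromosome lengths in bp (> 0)
#' @return named integer-valued numeric vector
#' @export
chrom_sizes <- function(name, length) {
  if (anyDuplicated(name)) stop("duplicate chromosome names")
  if (any(length <= 0) || any(length != round(length)))
    stop("chromosome lengths must be positive integers")
  stats::setNames(as.numeric(length), name)
}

#' Write chrom sizes
#' @param sizes named vector as returned by [chrom_sizes()]
#' @param path output path
#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(data.frame(names(sizes), as.integer(sizes)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

validate_against_sizes <- function(gr, sizes, what = "interval") {
  chr <- as.character(seqnames(gr))
  unknown <- setdiff(unique(chr), names(sizes))
  if (length(unknown))
    stop("chromosome(s) not in chrom sizes: ", paste(unknown, collapse = ", "))
  bad <- which(end0(gr) > sizes[chr])
  if (length(bad))
    stop(sprintf("%s %d exceeds chromosome length (%s:%d-%d)",
                 what, bad[1], chr[bad[1]], start0(gr)[bad[1]], end0(gr)[bad[1]]))
  invisible(gr)
}

#' Read a BED3/BED6/narrowPeak file
#'
#' Columns beyond the sixth (e.g. narrowPeak signal/p/q/summit) are dropped.
#' Missing name/score/strand fill as ".", 0 and "*". Track/browser/comment
#' lines are skipped. Intervals are returned sorted by (chrom, start).
#'
#' @param path BED path
#' @param chrom_sizes optional named length vector; intervals are validated
#'   against it
#' @return GRanges with `name` and `score` metadata columns
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- nzchar(lines) & !grepl("^(track|browser|#)", lines)
  lines <- lines[keep]; lineno <- lineno[keep]
  if (!length(lines)) {
    return(GenomicRanges::GRanges(name = character(), score = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop(sprintf("parse error at line %d: fewer than 3 fields", lineno[which(nf < 3)[1]]))
  col <- function(i, default) vapply(fields, function(f)
    if (length(f) >= i) f[i] else default, character(1))
  chrom <- col(1, NA_character_)
  start <- suppressWarnings(as.numeric(col(2, NA_character_)))
  end <- suppressWarnings(as.numeric(col(3, NA_character_)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad))
    stop(sprintf("parse error at line %d: non-integer coordinates", lineno[bad[1]]))
  bad <- which(start < 0 | end <= start)
  if (length(bad))
    stop(sprintf("parse error at line %d: invalid interval (start >= end or start < 0)",
                 lineno[bad[1]]))
  name <- col(4, ".")
  score <- suppressWarnings(as.numeric(col(5, "0")))
  score[is.na(score)] <- 0
  strand <- col(6, ".")
  bad <- which(!strand %in% c("+", "-", "."))
  if (length(bad))
    stop(sprintf("parse error at line %d: invalid strand '%s'", lineno[bad[1]], strand[bad[1]]))
  gr <- granges0(chrom, start, end, name = name, score = score, strand = strand)
  if (!is.null(chrom_sizes)) validate_against_sizes(gr, chrom_sizes)
  sort_granges(gr)
}

#' Write intervals as BED6
#'
#' Round-trips with [read_bed()] on the six retained columns. Intervals are
#' written sorted by (chrom, start).
#'
#' @param gr GRanges; optional `name`/`score` metadata columns are used
#' @param path output path
#' @export
write_bed <- function(gr, path) {
  if (!methods::is(gr, "GRanges")) stop("write_bed expects a GRanges")
  gr <- sort_granges(gr)
  n <- length(gr)
  nm <- if (!is.null(mcols(gr)$name)) as.character(mcols(gr)$name) else rep(".", n)
  sc <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else rep(0, n)
  st <- as.character(BiocGenerics::strand(gr))
  st[st == "*"] <- "."
  df <- data.frame(as.character(seqnames(gr)), start0(gr), end0(gr), nm, sc, st)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Sort a GRanges by (chrom, start, end) with stable chromosome name order
#' @param gr GRanges
#' @return sorted GRanges
#' @export
sort_granges <- function(gr) {
  o <- order(as.character(seqnames(gr)), BiocGenerics::start(gr), BiocGenerics::end(gr))
  gr[o]
}

#' Merge intervals closer than a maximum gap
#'
#' Two intervals end up in the same merged interval iff they are linked by a
#' chain of gaps each strictly smaller than `max_gap` (gap = next start minus
#' previous end, half-open coordinates). Overlapping and bookended intervals
#' always merge for `max_gap` >= 1.
#'
#' @param gr GRanges
#' @param max_gap non-negative gap threshold in bp (strict `<`)
#' @return merged, sorted, strand-free GRanges without metadata
#' @export
merge_intervals <- function(gr, max_gap = 0) {
  if (max_gap < 0) stop("max_gap must be >= 0")
  # reduce() keeps ranges separated by >= min.gapwidth apart, i.e. merges
  # exactly the strict-< gap rule when min.gapwidth = max_gap
  GenomicRanges::reduce(sort_granges(gr), min.gapwidth = max_gap,
                        ignore.strand = TRUE)
}

#' Pairwise any-overlap under half-open semantics
#'
#' @param a,b GRanges
#' @return logical vector along `a`: does each interval share >= 1 bp with
#'   any interval of `b`
#' @export
interval_overlaps <- function(a, b) {
  IRanges::overlapsAny(a, b, ignore.strand = TRUE)
}

#' Nearest feature with deterministic tie-breaking
#'
#' Distance is the bp gap between closest edges (0 when overlapping). Ties are
#' broken by smaller target start, then lexicographic target id. The signed
#' distance is negative when the target lies 5' of the query (target end <=
#' query start) and positive when 3'.
#'
#' @param query GRanges
#' @param targets GRanges; ids taken from `mcols(targets)$gene_id`, then
#'   `$name`, then index
#' @param reference distance reference on the target: whole `body` or `tss`
#'   (requires `mcols(targets)$tss`, 0-based position)
#' @return data.frame with `target_idx`, `target_id`, `distance`,
#'   `signed_distance` per query
#' @export
nearest_feature <- function(query, targets, reference = c("body", "tss")) {
  reference <- match.arg(reference)
  if (!length(targets)) stop("empty target set")
  ids <- mcols(targets)$gene_id
  if (is.null(ids)) ids <- mcols(targets)$name
  if (is.null(ids)) ids <- as.character(seq_along(targets))
  ids <- as.character(ids)
  ref <- targets
  if (reference == "tss") {
    tss <- mcols(targets)$tss
    if (is.null(tss)) stop("tss reference requires a 'tss' metadata column")
    ref <- granges0(as.character(seqnames(targets)), tss, tss + 1)
  }
  qchr <- as.character(seqnames(query))
  tchr <- as.character(seqnames(ref))
  missing_chr <- setdiff(unique(qchr), unique(tchr))
  if (length(missing_chr))
    stop("no targets on chromosome(s): ", paste(missing_chr, collapse = ", "))
  idx <- integer(length(query)); dist <- numeric(length(query))
  tstart <- BiocGenerics::start(targets)
  # exhaustive per-chromosome scan so that ties across directions are seen
  for (cn in unique(qchr)) {
    ti <- which(tchr == cn)
    for (i in which(qchr == cn)) {
      d <- GenomicRanges::distance(query[i], ref[ti], ignore.strand = TRUE)
      best <- min(d)
      cand <- ti[which(d == best)]
      o <- order(tstart[cand], ids[cand])
      idx[i] <- cand[o[1]]; dist[i] <- best
    }
  }
  tgt <- targets[idx]
  sgn <- rep(0, length(query))
  before <- end0(tgt) <= start0(query)   # target 5' of query
  after <- start0(tgt) >= end0(query)    # target 3' of query
  sgn[before] <- -1; sgn[after] <- 1
  data.frame(target_idx = idx, target_id = ids[idx],
             distance = dist, signed_distance = sgn * dist,
             stringsAsFactors = FALSE)
}

#' Read a gene model table
#'
#' Tab-separated with header: gene_id, gene_name, chrom, start, end, strand
#' (0-based half-open). The TSS is derived from the strand: start for `+`,
#' end - 1 for `-`.
#'
#' @param path TSV path
#' @param chrom_sizes optional validation vector
#' @return GRanges with gene_id, gene_name and tss metadata columns
#' @export
read_gene_table <- function(path, chrom_sizes = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "gene_name", "chrom", "start", "end", "strand")
  if (!all(need %in% names(tab)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$gene_id)) stop("duplicate gene_id in gene table")
  gr <- granges0(tab$chrom, tab$start, tab$end, strand = tab$strand,
                 gene_id = tab$gene_id, gene_name = tab$gene_name)
  mcols(gr)$tss <- ifelse(tab$strand == "-", tab$end - 1, tab$start)
  if (!is.null(chrom_sizes)) validate_against_sizes(gr, chrom_sizes, "gene")
  sort_granges(gr)
}

#' Write a gene model table (inverse of [read_gene_table()])
#' @param genes GRanges with gene_id/gene_name metadata
#' @param path output path
#' @export
write_gene_table <- function(genes, path) {
  df <- data.frame(gene_id = mcols(genes)$gene_id,
                   gene_name = mcols(genes)$gene_name,
                   chrom = as.character(seqnames(genes)),
                   start = start0(genes), end = end0(genes),
                   strand = as.character(BiocGenerics::strand(genes)))
  df$strand[df$strand == "*"] <- "+"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
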