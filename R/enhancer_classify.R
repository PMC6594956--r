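#' Tile the genome into fixed-width buckets
#'
#' @param chrom_sizes named vector from [chrom_sizes()]
#' @param width bucket width in bp (default 200)
#' @return GRanges of buckets; per chromosome `ceiling(len/width)` buckets,
#'   all `width` bp except possibly the last
#' @export
bucketize <- function(chrom_sizes, width = 200) {
  if (width <= 0) stop("bucket width must be > 0")
  rows <- lapply(names(chrom_sizes), function(cn) {
    len <- chrom_sizes[[cn]]
    s <- seq(0, len - 1, by = width)
    data.frame(chrom = cn, start = s, end = pmin(s + width, len))
  })
  df <- do.call(rbind, rows)
  granges0(df$chrom, df$start, df$end)
}

#' Classify buckets by histone-mark peak presence
#'
#' A bucket is a KEE bucket if it overlaps (>= 1 bp) at least one peak of each
#' of H3K4me1, H3K27ac and H3K79me2/3; a non-KEE bucket if it overlaps H3K4me1
#' and H3K27ac but no H3K79 peak; otherwise `none`. The H3K79 slot takes
#' either the me2 or the me3 peak set.
#'
#' @param buckets GRanges from [bucketize()]
#' @param h3k4me1,h3k27ac,h3k79 peak GRanges
#' @return `buckets` with a `state` metadata column in {KEE, nonKEE, none}
#' @export
classify_buckets <- function(buckets, h3k4me1, h3k27ac, h3k79) {
  for (nm in c("h3k4me1", "h3k27ac", "h3k79")) {
    p <- get(nm)
    if (is.null(p) || !methods::is(p, "GRanges"))
      stop("missing or invalid peak set: ", nm)
  }
  a <- IRanges::overlapsAny(buckets, h3k4me1, ignore.strand = TRUE)
  b <- IRanges::overlapsAny(buckets, h3k27ac, ignore.strand = TRUE)
  k <- IRanges::overlapsAny(buckets, h3k79, ignore.strand = TRUE)
  state <- rep("none", length(buckets))
  state[a & b & !k] <- "nonKEE"
  state[a & b & k] <- "KEE"
  mcols(buckets)$state <- state
  buckets
}

#' Merge classified buckets into enhancer calls
#'
#' Enhancer buckets (state != none) less than `max_gap` bp apart (strict `<`)
#' are merged; a merged enhancer is a KEE iff it contains at least one KEE
#' bucket.
#'
#' @param classified GRanges with a `state` column from [classify_buckets()]
#' @param max_gap merge gap in bp (default 1000, the "< 1 kb" rule)
#' @return GRanges of enhancers with metadata `klass` ("KEE"/"nonKEE"),
#'   `n_kee_buckets`, `n_nonkee_buckets`
#' @export
call_enhancers <- function(classified, max_gap = 1000) {
  st <- mcols(classified)$state
  if (is.null(st)) stop("buckets are not classified (no 'state' column)")
  enh_buckets <- classified[st != "none"]
  merged <- merge_intervals(enh_buckets, max_gap = max_gap)
  kee_b <- classified[st == "KEE"]
  non_b <- classified[st == "nonKEE"]
  n_kee <- GenomicRanges::countOverlaps(merged, kee_b, ignore.strand = TRUE)
  n_non <- GenomicRanges::countOverlaps(merged, non_b, ignore.strand = TRUE)
  mcols(merged)$klass <- ifelse(n_kee >= 1, "KEE", "nonKEE")
  mcols(merged)$n_kee_buckets <- n_kee
  mcols(merged)$n_nonkee_buckets <- n_non
  mcols(merged)$name <- mcols(merged)$klass
  mcols(merged)$score <- n_kee
  merged
}

#' Annotate enhancers as intragenic or intergenic
#'
#' Intragenic iff the enhancer shares >= 1 bp with any gene body.
#'
#' @param enhancers GRanges of enhancer calls
#' @param genes gene GRanges
#' @return `enhancers` with a `location` metadata column
#' @export
annotate_location <- function(enhancers, genes) {
  hit <- IRanges::overlapsAny(enhancers, genes, ignore.strand = TRUE)
  mcols(enhancers)$location <- ifelse(hit, "intragenic", "intergenic")
  enhancers
}

#' Assign each enhancer to its nearest gene
#'
#' Distance to the gene body by default (an intragenic enhancer is assigned
#' its host gene, distance 0); `reference = "tss"` measures to the TSS
#' instead. Ties break on smaller gene start, then gene_id.
#'
#' @param enhancers GRanges of enhancer calls
#' @param genes gene GRanges with `gene_id` (and `tss` for tss mode)
#' @param reference "body" or "tss"
#' @return `enhancers` with `gene_id` and `gene_distance` metadata
#' @export
assign_genes <- function(enhancers, genes, reference = c("body", "tss")) {
  reference <- match.arg(reference)
  echr <- unique(as.character(seqnames(enhancers)))
  gchr <- unique(as.character(seqnames(genes)))
  orphan <- setdiff(echr, gchr)
  if (length(orphan))
    stop("chromosome(s) bear enhancers but no genes: ",
         paste(orphan, collapse = ", "))
  nf <- nearest_feature(enhancers, genes, reference = reference)
  mcols(enhancers)$gene_id <- nf$target_id
  mcols(enhancers)$gene_distance <- nf$distance
  enhancers
}

#' Label genes by their assigned enhancers
#'
#' A gene is a KEE gene if at least one KEE is assigned to it (regardless of
#' any non-KEE assignments); a non-KEE gene if it has only non-KEEs; `none`
#' otherwise.
#'
#' @param enhancers GRanges with `klass` and `gene_id` (from [assign_genes()])
#' @param genes gene GRanges with `gene_id`
#' @param h3k79_peaks optional H3K79 peak GRanges; adds the per-gene
#'   `h3k79_marked` flag (gene body overlaps >= 1 peak)
#' @return data.frame: gene_id, label in {KEE_gene, nonKEE_gene, none},
#'   n_kee, n_nonkee, h3k79_marked
#' @export
label_genes <- function(enhancers, genes, h3k79_peaks = NULL) {
  gid <- as.character(mcols(genes)$gene_id)
  kl <- mcols(enhancers)$klass
  eg <- mcols(enhancers)$gene_id
  if (is.null(kl) || is.null(eg))
    stop("enhancers must carry 'klass' and 'gene_id' (run assign_genes first)")
  n_kee <- table(factor(eg[kl == "KEE"], levels = gid))
  n_non <- table(factor(eg[kl == "nonKEE"], levels = gid))
  label <- ifelse(n_kee >= 1, "KEE_gene",
                  ifelse(n_non >= 1, "nonKEE_gene", "none"))
  out <- data.frame(gene_id = gid, label = as.character(label),
                    n_kee = as.integer(n_kee), n_nonkee = as.integer(n_non),
                    stringsAsFactors = FALSE)
  if (!is.null(h3k79_peaks))
    out$h3k79_marked <- mark_h3k79_genes(genes, h3k79_peaks)
  out
}

#' Flag genes whose body overlaps an H3K79me2/3 peak
#' @param genes gene GRanges
#' @param h3k79_peaks peak GRanges
#' @return logical vector along `genes`
#' @export
mark_h3k79_genes <- function(genes, h3k79_peaks) {
  if (is.null(h3k79_peaks)) stop("h3k79 peak set is required")
  IRanges::overlapsAny(genes, h3k79_peaks, ignore.strand = TRUE)
}

#' Summarise enhancer calls by class
#'
#' @param enhancers GRanges with `klass` (and optionally `location`)
#' @return data.frame per class: n, proportion, median_length_bp and (when
#'   location is annotated) intragenic_fraction
#' @export
kee_fraction_summary <- function(enhancers) {
  if (!length(enhancers)) stop("no enhancer calls")
  kl <- mcols(enhancers)$klass
  len <- BiocGenerics::width(enhancers)
  classes <- c("KEE", "nonKEE")
  n <- vapply(classes, function(k) sum(kl == k), numeric(1))
  out <- data.frame(klass = classes, n = as.integer(n),
                    proportion = n / length(enhancers),
                    median_length_bp = vapply(classes, function(k)
                      if (any(kl == k)) stats::median(len[kl == k]) else NA_real_,
                      numeric(1)))
  loc <- mcols(enhancers)$location
  if (!is.null(loc))
    out$intragenic_fraction <- vapply(classes, function(k)
      if (any(kl == k)) mean(loc[kl == k] == "intragenic") else NA_real_,
      numeric(1))
  rownames(out) <- NULL
  out
}

#' Run the full enhancer classification
#'
#' Bucketize, classify by mark presence, merge (< 1 kb), annotate genomic
#' location, assign nearest genes and label genes.
#'
#' @param chrom_sizes named length vector
#' @param h3k4me1,h3k27ac,h3k79 peak GRanges (the H3K79 slot takes me2 or me3)
#' @param genes gene GRanges
#' @param bucket_width bucket width in bp
#' @param merge_gap merge gap in bp (strict `<`)
#' @param exclude optional GRanges (e.g. a blacklist or H3K4me3 promoter
#'   peaks); enhancers overlapping it are dropped before gene assignment
#' @return list(enhancers = GRanges, gene_labels = data.frame,
#'   summary = data.frame)
#' @export
classify_enhancers <- function(chrom_sizes, h3k4me1, h3k27ac, h3k79, genes,
                               bucket_width = 200, merge_gap = 1000,
                               exclude = NULL) {
  buckets <- bucketize(chrom_sizes, bucket_width)
  cls <- classify_buckets(buckets, h3k4me1, h3k27ac, h3k79)
  enh <- call_enhancers(cls, max_gap = merge_gap)
  if (!is.null(exclude))
    enh <- enh[!IRanges::overlapsAny(enh, exclude, ignore.strand = TRUE)]
  enh <- annotate_location(enh, genes)
  enh <- assign_genes(enh, genes)
  labels <- label_genes(enh, genes, h3k79_peaks = h3k79)
  list(enhancers = enh, gene_labels = labels,
       summary = kee_fraction_summary(enh))
}
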