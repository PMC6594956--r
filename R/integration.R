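#' Correlate two signal tracks over a set of intervals
#'
#' Per interval, the signal is the sum of overlapped bin values with partial
#' bins pro-rated by overlap fraction; Pearson correlation is computed on the
#' transformed per-interval pairs.
#'
#' @param track_a,track_b [signal_track()]s on the same bin grid
#' @param intervals GRanges (>= 3)
#' @param transform "log2p1" (log2(x + 1), default) or "raw"
#' @return list(values = data.frame(a, b), r = Pearson correlation)
#' @export
correlate_signal <- function(track_a, track_b, intervals,
                             transform = c("log2p1", "raw")) {
  transform <- match.arg(transform)
  if (track_a$bin_width != track_b$bin_width)
    stop("tracks must share a bin grid")
  if (length(intervals) < 3) stop("need at least 3 intervals")
  a <- track_interval_sums(track_a, intervals)
  b <- track_interval_sums(track_b, intervals)
  if (transform == "log2p1") {
    a <- log2(a + 1); b <- log2(b + 1)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in interval signal; correlation undefined")
  list(values = data.frame(a = a, b = b), r = stats::cor(a, b))
}

#' Derive DE status from log2FC and FDR
#'
#' down iff FDR < `alpha` and log2FC < 0; up iff FDR < `alpha` and
#' log2FC > 0; otherwise insensitive.
#'
#' @param log2fc,fdr numeric vectors
#' @param alpha FDR threshold (default 0.05)
#' @return character vector in {up, down, insensitive}
#' @export
de_status <- function(log2fc, fdr, alpha = 0.05) {
  ifelse(fdr < alpha & log2fc < 0, "down",
         ifelse(fdr < alpha & log2fc > 0, "up", "insensitive"))
}

#' Read a differential-expression table (gene_id, log2fc, fdr)
#' @param path TSV with header
#' @return data.frame with a recomputed `status` column
#' @export
read_de_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("gene_id", "log2fc", "fdr") %in% names(tab)))
    stop("DE table must have columns gene_id, log2fc, fdr")
  tab$status <- de_status(tab$log2fc, tab$fdr)
  tab
}

#' Compare expression between KEE genes and non-KEE genes
#'
#' Two-sided Wilcoxon rank-sum test on a per-gene expression value, KEE_gene
#' vs nonKEE_gene, optionally restricted to H3K79me2/3-marked genes.
#'
#' @param gene_labels data.frame from [label_genes()] (needs `h3k79_marked`
#'   when restricting)
#' @param expression data.frame(gene_id, value)
#' @param restrict_to_h3k79_marked drop genes without gene-body H3K79 marking
#' @return list(groups = named list of values, medians, iqrs, p.value)
#' @export
compare_expression <- function(gene_labels, expression,
                               restrict_to_h3k79_marked = TRUE) {
  m <- merge(gene_labels, expression, by = "gene_id")
  if (restrict_to_h3k79_marked) {
    if (is.null(m$h3k79_marked))
      stop("gene_labels lack the h3k79_marked flag")
    m <- m[m$h3k79_marked, ]
  }
  kee <- m$value[m$label == "KEE_gene"]
  non <- m$value[m$label == "nonKEE_gene"]
  if (!length(kee) || !length(non))
    stop("one of the comparison groups is empty")
  tst <- rank_sum_test(kee, non)
  list(groups = list(KEE_gene = kee, nonKEE_gene = non),
       medians = c(KEE_gene = stats::median(kee),
                   nonKEE_gene = stats::median(non)),
       iqrs = c(KEE_gene = stats::IQR(kee), nonKEE_gene = stats::IQR(non)),
       p.value = tst$p.value)
}

#' Cross-tabulate DE status by enhancer class of the gene
#'
#' @param gene_labels data.frame from [label_genes()]
#' @param de data.frame(gene_id, log2fc, fdr); status is recomputed
#' @param restrict_to_h3k79_marked drop genes without gene-body H3K79 marking
#' @return list(table = class x status counts, proportions, mean_log2fc per
#'   class, collapsed = 2x2 down vs not-down, fisher = [fisher_exact()] on the
#'   collapsed table)
#' @export
de_by_class <- function(gene_labels, de, restrict_to_h3k79_marked = TRUE) {
  if (anyDuplicated(gene_labels$gene_id) || anyDuplicated(de$gene_id))
    stop("duplicate gene_id")
  m <- merge(gene_labels, de, by = "gene_id")
  if (restrict_to_h3k79_marked) {
    if (is.null(m$h3k79_marked))
      stop("gene_labels lack the h3k79_marked flag")
    m <- m[m$h3k79_marked, ]
  }
  m <- m[m$label %in% c("KEE_gene", "nonKEE_gene"), ]
  if (!nrow(m)) stop("no labelled genes after restriction")
  m$status <- de_status(m$log2fc, m$fdr)
  tab <- table(class = factor(m$label, c("KEE_gene", "nonKEE_gene")),
               status = factor(m$status, c("down", "up", "insensitive")))
  props <- prop.table(tab, margin = 1)
  mean_fc <- tapply(m$log2fc, factor(m$label, c("KEE_gene", "nonKEE_gene")),
                    mean)
  collapsed <- cbind(down = tab[, "down"], not_down = rowSums(tab) - tab[, "down"])
  list(table = tab, proportions = props, mean_log2fc = mean_fc,
       collapsed = collapsed, fisher = fisher_exact(collapsed))
}

#' ATAC accessibility change by enhancer class and transcription
#'
#' Every ATAC peak is assigned to exactly one class bucket: KEE if it overlaps
#' any KEE enhancer, else nonKEE if it overlaps any non-KEE, else neither
#' (KEE precedence). For decreased peaks lying in enhancers, peaks map to the
#' containing enhancer's assigned gene (nearest gene as fallback when `genes`
#' is supplied) and are cross-tabulated against that gene's DE status.
#'
#' @param atac GRanges with a `direction` metadata column in
#'   {increased, decreased, unchanged}
#' @param enhancers enhancer-call GRanges with `klass` and `gene_id`
#' @param de data.frame(gene_id, log2fc, fdr)
#' @param genes optional gene GRanges for the nearest-gene fallback
#' @return list(direction_by_class, decreased_by_gene_status, proportions of
#'   down-gene association per class, fisher on the collapsed 2x2)
#' @export
atac_cross_tab <- function(atac, enhancers, de, genes = NULL) {
  kl <- mcols(enhancers)$klass
  kee_hit <- IRanges::overlapsAny(atac, enhancers[kl == "KEE"],
                                  ignore.strand = TRUE)
  non_hit <- IRanges::overlapsAny(atac, enhancers[kl == "nonKEE"],
                                  ignore.strand = TRUE)
  klass <- ifelse(kee_hit, "KEE", ifelse(non_hit, "nonKEE", "neither"))
  dir <- factor(mcols(atac)$direction,
                c("increased", "decreased", "unchanged"))
  t1 <- table(direction = dir, class = factor(klass, c("KEE", "nonKEE", "neither")))

  de$status <- de_status(de$log2fc, de$fdr)
  dec <- which(dir == "decreased" & klass != "neither")
  gene_of_peak <- function(i) {
    cand <- enhancers[kl == klass[i]]
    ov <- which(IRanges::overlapsAny(cand, atac[i], ignore.strand = TRUE))
    if (length(ov)) return(as.character(mcols(cand)$gene_id[ov[1]]))
    if (is.null(genes)) return(NA_character_)
    nearest_feature(atac[i], genes)$target_id
  }
  gid <- vapply(dec, gene_of_peak, character(1))
  status <- de$status[match(gid, de$gene_id)]
  t2 <- table(class = factor(klass[dec], c("KEE", "nonKEE")),
              status = factor(status, c("down", "up", "insensitive")))
  collapsed <- cbind(down = t2[, "down"], not_down = rowSums(t2) - t2[, "down"])
  rs <- rowSums(t2)
  props <- ifelse(rs > 0, t2[, "down"] / rs, NA_real_)
  list(direction_by_class = t1,
       decreased_by_gene_status = t2,
       down_proportion = stats::setNames(as.numeric(props), c("KEE", "nonKEE")),
       fisher = fisher_exact(collapsed))
}

#' Read a differential-ATAC table
#'
#' TSV with header: chrom, start, end, direction, fdr.
#'
#' @param path TSV path
#' @return GRanges with direction and fdr metadata
#' @export
read_atac_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "direction", "fdr")
  if (!all(need %in% names(tab)))
    stop("ATAC table must have columns: ", paste(need, collapse = ", "))
  granges0(tab$chrom, tab$start, tab$end,
           direction = tab$direction, fdr = tab$fdr)
}

#' Scaled-body metaprofile of a signal track over an interval set
#'
#' Each interval's body is rescaled to `n_body_bins` equal sub-windows (mean
#' signal per bp in each), flanks are `n_flank_bins` fixed-width windows of
#' `flank_bp / n_flank_bins` bp each side; the profile is the unweighted mean
#' across intervals. Intervals shorter than one track bin are skipped with a
#' warning.
#'
#' @param track a [signal_track()]
#' @param intervals GRanges
#' @param flank_bp flank width each side (default 2000)
#' @param n_body_bins body bins (default 50)
#' @param n_flank_bins flank bins per side (default 10)
#' @return list(profile = numeric vector of length
#'   `n_body_bins + 2 n_flank_bins`, n_used, n_skipped)
#' @export
metaprofile <- function(track, intervals, flank_bp = 2000,
                        n_body_bins = 50, n_flank_bins = 10) {
  if (!length(intervals)) stop("no intervals")
  if (n_body_bins < 1 || n_flank_bins < 0) stop("bins must be >= 1")
  short <- BiocGenerics::width(intervals) < track$bin_width
  if (any(short))
    warning(sum(short), " interval(s) shorter than one track bin skipped")
  intervals <- intervals[!short]
  if (!length(intervals)) stop("all intervals skipped")
  chr <- as.character(seqnames(intervals))
  s <- start0(intervals); e <- end0(intervals)
  fw <- if (n_flank_bins > 0) flank_bp / n_flank_bins else 0
  prof <- vapply(seq_along(intervals), function(i) {
    body_edges <- seq(s[i], e[i], length.out = n_body_bins + 1)
    body <- vapply(seq_len(n_body_bins), function(k)
      track_region_mean(track, chr[i], body_edges[k], body_edges[k + 1]),
      numeric(1))
    if (n_flank_bins == 0) return(body)
    up_edges <- seq(s[i] - flank_bp, s[i], length.out = n_flank_bins + 1)
    dn_edges <- seq(e[i], e[i] + flank_bp, length.out = n_flank_bins + 1)
    up <- vapply(seq_len(n_flank_bins), function(k)
      track_region_mean(track, chr[i], up_edges[k], up_edges[k + 1]),
      numeric(1))
    dn <- vapply(seq_len(n_flank_bins), function(k)
      track_region_mean(track, chr[i], dn_edges[k], dn_edges[k + 1]),
      numeric(1))
    c(up, body, dn)
  }, numeric(n_body_bins + 2 * n_flank_bins))
  list(profile = rowMeans(as.matrix(prof)),
       n_used = length(intervals), n_skipped = sum(short))
}
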