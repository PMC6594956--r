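#' Synthetic-data generator configuration
#'
#' Defaults define the study conditions the generator emulates: tens of
#' enhancers on a small two-chromosome genome, a 0.95 latent correlation
#' between the paired H3K79me2/me3 marks, a 33%/20% KEE/non-KEE downregulation
#' gap, a 0.4 multiplicative attenuation of KEE-promoter contacts under DOT1L
#' inhibition, and near-complete (x0.1) global loss of target-genome H3K79
#' ChIP material against the spike-in.
#'
#' @param seed integer seed; every generator op derives its own substream
#' @param n_chroms,chrom_length_bp genome shape
#' @param n_genes genes to place (non-overlapping)
#' @param n_kee,n_nonkee true enhancers per class
#' @param frac_intragenic fraction of enhancers placed inside gene bodies
#' @param me2_me3_agreement probability an H3K79me2 enhancer peak is also
#'   present in the H3K79me3 set
#' @param track_bg_rate,track_peak_rate per-200bp-bin Poisson rates
#' @param latent_mark_correlation latent log-scale correlation between paired
#'   mark tracks at enhancers
#' @param track_latent_sd log-scale sd of the shared latent factor
#' @param capture,de,atac,spikein named lists overriding the nested defaults
#'   (see source for fields)
#' @return a validated `sim_config` list
#' @export
sim_config <- function(seed = 7,
                       n_chroms = 2, chrom_length_bp = 1200000,
                       n_genes = 100,
                       n_kee = 30, n_nonkee = 30,
                       frac_intragenic = 0.5,
                       me2_me3_agreement = 0.95,
                       track_bg_rate = 0.5, track_peak_rate = 400,
                       latent_mark_correlation = 0.95,
                       track_latent_sd = 1.0,
                       capture = list(), de = list(), atac = list(),
                       spikein = list()) {
  capture <- utils::modifyList(list(
    n_probes = 2, mean_fragment_bp = 400,
    decay_exponent = 1, decay_scale_kb = 1, baseline = 100,
    peak_boost = 4, dot1li_effect = 0.4, nb_dispersion = 0.1,
    n_replicates = 3, library_size_range = c(0.8, 1.25),
    domain_halfwidth_bp = 250000, exclusion_radius = 10000), capture)
  de <- utils::modifyList(list(
    p_down_kee = 0.33, p_down_nonkee = 0.20, p_up = 0.15,
    log2fc_mean = 1, log2fc_sd = 0.5), de)
  atac <- utils::modifyList(list(
    p_decreased_kee = 0.6, p_decreased_nonkee = 0.15,
    p_down_given_decreased_kee = 0.73,
    p_down_given_decreased_nonkee = 0.21), atac)
  spikein <- utils::modifyList(list(
    true_global_loss = 0.1, depth = 1e7,
    ip_target_share = 0.8, target_input = 9e6, spike_input = 1e6), spikein)
  cfg <- list(seed = as.integer(seed), n_chroms = n_chroms,
              chrom_length_bp = chrom_length_bp, n_genes = n_genes,
              n_kee = n_kee, n_nonkee = n_nonkee,
              frac_intragenic = frac_intragenic,
              me2_me3_agreement = me2_me3_agreement,
              track_bg_rate = track_bg_rate,
              track_peak_rate = track_peak_rate,
              latent_mark_correlation = latent_mark_correlation,
              track_latent_sd = track_latent_sd,
              capture = capture, de = de, atac = atac, spikein = spikein)
  probs <- c(cfg$frac_intragenic, cfg$me2_me3_agreement,
             de$p_down_kee, de$p_down_nonkee, de$p_up,
             atac$p_decreased_kee, atac$p_decreased_nonkee,
             atac$p_down_given_decreased_kee, atac$p_down_given_decreased_nonkee)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (capture$dot1li_effect <= 0 || capture$dot1li_effect > 1)
    stop("dot1li_effect must lie in (0, 1]")
  if (spikein$true_global_loss <= 0 || spikein$true_global_loss > 1)
    stop("true_global_loss must lie in (0, 1]")
  if (capture$decay_exponent <= 0 || track_bg_rate < 0 || track_peak_rate < 0)
    stop("rates must be positive")
  cfg
}

# named substream: deterministic sub-seed per generator op
sub_seed <- function(seed, k) (as.numeric(seed) * 1009 + k) %% 2147483647

#' Simulate the genome and non-overlapping gene models
#'
#' @param config a [sim_config()]
#' @return list(chrom_sizes, genes = GRanges with gene_id/gene_name/tss)
#' @export
simulate_genome_and_genes <- function(config) {
  set.seed(sub_seed(config$seed, 1))
  sizes <- chrom_sizes(paste0("chr", seq_len(config$n_chroms)),
                       rep(config$chrom_length_bp, config$n_chroms))
  rows <- list()
  placed <- 0
  for (cn in names(sizes)) {
    pos <- 5000
    len <- sizes[[cn]]
    while (placed < config$n_genes) {
      gl <- round(stats::runif(1, 4000, 10000))
      if (pos + gl > len - 5000) break
      placed <- placed + 1
      rows[[placed]] <- data.frame(chrom = cn, start = pos, end = pos + gl)
      pos <- pos + gl + round(stats::runif(1, 6000, 10000))
    }
  }
  if (placed < config$n_genes)
    stop(sprintf("cannot place %d non-overlapping genes in %d x %g bp",
                 config$n_genes, config$n_chroms, config$chrom_length_bp))
  if (!placed) {
    genes <- granges0(character(), numeric(), numeric(),
                      gene_id = character(), gene_name = character())
    mcols(genes)$tss <- numeric()
    return(list(chrom_sizes = sizes, genes = genes))
  }
  df <- do.call(rbind, rows)
  strand <- sample(c("+", "-"), nrow(df), replace = TRUE)
  genes <- granges0(df$chrom, df$start, df$end, strand = strand,
                    gene_id = sprintf("g%04d", seq_len(nrow(df))),
                    gene_name = sprintf("GENE%04d", seq_len(nrow(df))))
  mcols(genes)$tss <- ifelse(strand == "-", df$end - 1, df$start)
  list(chrom_sizes = sizes, genes = sort_granges(genes))
}

#' Simulate true enhancers and the histone-mark peak sets
#'
#' Every true KEE emits coincident H3K4me1, H3K27ac and H3K79me2 peaks exactly
#' at its interval; the H3K79me3 copy of each enhancer peak is retained with
#' probability `me2_me3_agreement`. True non-KEEs emit only H3K4me1 + H3K27ac.
#' A random subset of genes hosting no non-KEE additionally carries an H3K79
#' gene-body block (so gene-body marking is decoupled from enhancer marking).
#' Placement keeps >= 2 kb clearance between distinct enhancers and between
#' non-KEEs and any H3K79 feature, so bucket-level classification of the
#' emitted peaks recovers the truth exactly.
#'
#' @param config a [sim_config()]
#' @param genome output of [simulate_genome_and_genes()]
#' @return list(peaks = list of 4 GRanges, truth = enhancer GRanges with
#'   klass/location, gene_blocks = GRanges, me3_dropped = logical per KEE)
#' @export
simulate_enhancers_and_peaks <- function(config, genome) {
  set.seed(sub_seed(config$seed, 2))
  genes <- genome$genes
  n <- config$n_kee + config$n_nonkee
  klass <- c(rep("KEE", config$n_kee), rep("nonKEE", config$n_nonkee))
  med <- ifelse(klass == "KEE", 1000, 800)
  elen <- round(pmin(pmax(stats::rlnorm(n, log(med), 0.35), 300), 2500))

  n_intra <- round(config$frac_intragenic * n)
  intra <- rep(FALSE, n)
  if (n_intra > 0) intra[sample.int(n, n_intra)] <- TRUE

  gw <- BiocGenerics::width(genes)
  host_pool <- which(gw >= max(elen) + 1200)
  if (sum(intra) > length(host_pool))
    stop("not enough genes to host intragenic enhancers")
  hosts <- sample(host_pool, sum(intra))

  # intergenic gaps between consecutive genes on a chromosome
  gchr <- as.character(seqnames(genes))
  gaps <- do.call(rbind, lapply(unique(gchr), function(cn) {
    g <- genes[gchr == cn]
    if (length(g) < 2) return(NULL)
    data.frame(chrom = cn,
               start = end0(g)[-length(g)], end = start0(g)[-1])
  }))
  gaps <- gaps[gaps$end - gaps$start >= max(elen) + 4000, ]
  if (sum(!intra) > nrow(gaps))
    stop("not enough intergenic gaps for enhancers")
  slots <- sample(nrow(gaps), sum(!intra))

  chrom <- character(n); s <- numeric(n)
  ii <- 1; jj <- 1
  for (k in seq_len(n)) {
    if (intra[k]) {
      g <- genes[hosts[ii]]; ii <- ii + 1
      chrom[k] <- as.character(seqnames(g))
      s[k] <- round(stats::runif(1, start0(g) + 600,
                                 end0(g) - 600 - elen[k]))
    } else {
      gp <- gaps[slots[jj], ]; jj <- jj + 1
      chrom[k] <- gp$chrom
      s[k] <- round(stats::runif(1, gp$start + 2000,
                                 gp$end - 2000 - elen[k]))
    }
  }
  truth <- granges0(chrom, s, s + elen, klass = klass,
                    location = ifelse(intra, "intragenic", "intergenic"),
                    name = sprintf("enh%03d", seq_len(n)))
  truth <- sort_granges(truth)

  kl <- mcols(truth)$klass
  kee <- truth[kl == "KEE"]
  me3_keep <- stats::runif(length(kee)) < config$me2_me3_agreement

  # H3K79 gene-body blocks over genes hosting no non-KEE
  nonkee_hosts <- unique(queryHits(GenomicRanges::findOverlaps(
    genes, truth[kl == "nonKEE"], ignore.strand = TRUE)))
  eligible <- setdiff(seq_along(genes), nonkee_hosts)
  blocks <- genes[sample(eligible, max(1, round(0.3 * length(eligible))))]
  blocks <- granges0(as.character(seqnames(blocks)), start0(blocks),
                     end0(blocks), name = mcols(blocks)$gene_id)

  strip <- function(gr) {
    out <- granges0(as.character(seqnames(gr)), start0(gr), end0(gr),
                    name = if (!is.null(mcols(gr)$name)) mcols(gr)$name
                           else rep(".", length(gr)))
    sort_granges(out)
  }
  peaks <- list(
    H3K4me1 = strip(truth),
    H3K27ac = strip(truth),
    H3K79me2 = strip(suppressWarnings(c(kee, blocks))),
    H3K79me3 = strip(suppressWarnings(c(kee[me3_keep], blocks))))
  list(peaks = peaks, truth = truth, gene_blocks = blocks,
       me3_dropped = !me3_keep)
}

#' Simulate a correlated pair of binned signal tracks
#'
#' Background Poisson everywhere; bins inside `intervals` add Poisson signal
#' whose rate carries a shared per-interval log-normal latent factor with
#' log-scale correlation `rho` between the two tracks. When `dot1li_effect`
#' < 1, the second track's rate is multiplied by it at intervals flagged in
#' `kee` (the DOT1L-inhibited variant).
#'
#' @param chrom_sizes named length vector
#' @param intervals GRanges of signal regions
#' @param bg_rate,peak_rate per-bin Poisson rates
#' @param rho latent correlation in \[0, 1\]
#' @param latent_sd log-scale sd of the latent factor
#' @param bin_width bp per bin
#' @param dot1li_effect multiplicative attenuation applied to track b
#' @param kee logical per interval (which intervals are attenuated)
#' @param seed integer seed
#' @return list(a = signal_track, b = signal_track)
#' @export
simulate_track_pair <- function(chrom_sizes, intervals, bg_rate, peak_rate,
                                rho, latent_sd = 1, bin_width = 200,
                                dot1li_effect = 1, kee = NULL, seed = 1) {
  set.seed(seed)
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  mk_bg <- function() lapply(chrom_sizes, function(len)
    stats::rpois(ceiling(len / bin_width), bg_rate) * 1.0)
  va <- mk_bg(); vb <- mk_bg()
  if (length(intervals) && peak_rate > 0) {
    z1 <- stats::rnorm(length(intervals))
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(length(intervals))
    la <- exp(latent_sd * z1 - latent_sd^2 / 2)
    lb <- exp(latent_sd * z2 - latent_sd^2 / 2)
    eff <- if (is.null(kee)) rep(1, length(intervals))
           else ifelse(kee, dot1li_effect, 1)
    chr <- as.character(seqnames(intervals))
    s <- start0(intervals); e <- end0(intervals)
    for (i in seq_along(intervals)) {
      bins <- (s[i] %/% bin_width):((e[i] - 1) %/% bin_width) + 1
      va[[chr[i]]][bins] <- va[[chr[i]]][bins] +
        stats::rpois(length(bins), peak_rate * la[i])
      vb[[chr[i]]][bins] <- vb[[chr[i]]][bins] +
        stats::rpois(length(bins), peak_rate * lb[i] * eff[i])
    }
  }
  list(a = signal_track(bin_width, va), b = signal_track(bin_width, vb))
}

# expected normalized contact count at distance d (bp) from the probe:
# power-law decay on the kb scale
contact_decay_mu <- function(d_bp, baseline, decay_scale_kb, decay_exponent) {
  baseline * (abs(d_bp) / 1000 + decay_scale_kb)^(-decay_exponent)
}

#' Simulate a Capture-C experiment around one probe
#'
#' Lays consecutive DpnII-like fragments (lengths 50 bp + Exponential) across
#' the probe's interaction domain, gives each fragment a power-law
#' distance-decay expected count, boosts fragments under enhancer peaks by
#' `peak_boost`, attenuates KEE fragments by `dot1li_effect` in the dot1li
#' condition only, and draws negative-binomial counts with per-replicate
#' library factors.
#'
#' @param config a [sim_config()]
#' @param genome output of [simulate_genome_and_genes()]
#' @param truth enhancer truth GRanges (from [simulate_enhancers_and_peaks()])
#' @param probe_gene_id gene at whose TSS the probe sits; default = the gene
#'   with most enhancers within the domain halfwidth
#' @param probe_index substream index (distinguishes multiple probes)
#' @return list(design, fcm = raw [fragment_counts()], peaks = true peak
#'   GRanges with klass and true_effect, probe_gene_id)
#' @export
simulate_capturec <- function(config, genome, truth, probe_gene_id = NULL,
                              probe_index = 1) {
  set.seed(sub_seed(config$seed, 100 + probe_index))
  cp <- config$capture
  genes <- genome$genes
  if (is.null(probe_gene_id)) {
    tss <- mcols(genes)$tss
    n_near <- vapply(seq_along(genes), function(i) {
      win <- granges0(as.character(seqnames(genes))[i],
                      max(0, tss[i] - cp$domain_halfwidth_bp),
                      tss[i] + cp$domain_halfwidth_bp)
      sum(IRanges::overlapsAny(truth, win, ignore.strand = TRUE))
    }, numeric(1))
    probe_gene_id <- mcols(genes)$gene_id[order(-n_near)][probe_index]
  }
  g <- genes[mcols(genes)$gene_id == probe_gene_id]
  if (!length(g)) stop("unknown probe gene: ", probe_gene_id)
  cn <- as.character(seqnames(g))
  tss <- mcols(g)$tss
  probe <- granges0(cn, max(0, tss - 60), tss + 60)
  dom_s <- max(0, tss - cp$domain_halfwidth_bp)
  dom_e <- min(genome$chrom_sizes[[cn]], tss + cp$domain_halfwidth_bp)
  if (dom_e - dom_s < 4 * cp$exclusion_radius)
    stop("interaction domain too small for the probe exclusion zone")
  domain <- granges0(cn, dom_s, dom_e)
  design <- capture_design(probe_gene_id, probe, domain,
                           exclusion_radius = cp$exclusion_radius,
                           n_replicates = cp$n_replicates)

  # fragment map
  lens <- numeric(0); pos <- dom_s
  while (pos < dom_e) {
    l <- 50 + round(stats::rexp(1, 1 / max(1, cp$mean_fragment_bp - 50)))
    l <- min(l, dom_e - pos)
    lens <- c(lens, l); pos <- pos + l
  }
  starts <- dom_s + cumsum(c(0, lens[-length(lens)]))
  frags <- granges0(cn, starts, starts + lens)

  probe_mid <- (start0(probe) + end0(probe)) / 2
  mids <- (start0(frags) + end0(frags)) / 2
  mu <- contact_decay_mu(mids - probe_mid, cp$baseline,
                         cp$decay_scale_kb, cp$decay_exponent)
  kl <- mcols(truth)$klass
  in_enh <- IRanges::overlapsAny(frags, truth, ignore.strand = TRUE)
  in_kee <- IRanges::overlapsAny(frags, truth[kl == "KEE"],
                                 ignore.strand = TRUE)
  mu[in_enh] <- mu[in_enh] * cp$peak_boost
  mu_trt <- mu
  mu_trt[in_kee] <- mu_trt[in_kee] * cp$dot1li_effect

  samples <- c(paste0("control_", seq_len(cp$n_replicates)),
               paste0("dot1li_", seq_len(cp$n_replicates)))
  s_r <- stats::runif(length(samples), cp$library_size_range[1],
                      cp$library_size_range[2])
  counts <- sapply(seq_along(samples), function(j) {
    m <- if (grepl("^dot1li", samples[j])) mu_trt else mu
    stats::rnbinom(length(m), mu = m * s_r[j], size = 1 / cp$nb_dispersion)
  })
  colnames(counts) <- samples
  totals <- round(colSums(counts) * 1.25) + 1
  fcm <- fragment_counts(frags, counts, stats::setNames(totals, samples))

  in_dom <- IRanges::overlapsAny(truth, domain, ignore.strand = TRUE) &
    as.character(seqnames(truth)) == cn
  peaks <- truth[in_dom]
  mcols(peaks)$true_effect <- ifelse(mcols(peaks)$klass == "KEE",
                                     cp$dot1li_effect, 1)
  list(design = design, fcm = fcm, peaks = peaks,
       probe_gene_id = probe_gene_id)
}

#' Simulate a set of interaction peaks for calibration and recovery studies
#'
#' A compact construction on one synthetic chromosome: each peak is a run of
#' `n_fragments` consecutive fragments with a per-peak probe distance drawn
#' uniformly on `distance_range_kb`, expected counts from the power-law decay
#' times `peak_boost`, negative-binomial noise, per-replicate library factors
#' removed by cis-total normalization. KEE peaks are attenuated by `effect`
#' in the dot1li condition only; `effect = 1` is the null configuration.
#'
#' @param n_kee,n_nonkee peaks per class
#' @param effect dot1li multiplicative effect at KEE peaks (1 = null)
#' @param n_fragments fragments per peak
#' @param n_replicates replicates per condition
#' @param nb_dispersion negative-binomial dispersion (var = mu + disp mu^2)
#' @param baseline,decay_scale_kb,decay_exponent,peak_boost decay-curve
#'   parameters as in [sim_config()]
#' @param library_size_range per-replicate library factor range
#' @param distance_range_kb per-peak probe distance range
#' @param fragment_bp fragment width
#' @param seed integer seed
#' @return list(design, fcm, peaks = GRanges with klass and true_effect)
#' @export
simulate_peak_set <- function(n_kee, n_nonkee, effect,
                              n_fragments = 10, n_replicates = 3,
                              nb_dispersion = 0.1, baseline = 100,
                              decay_scale_kb = 1, decay_exponent = 1,
                              peak_boost = 4,
                              library_size_range = c(0.8, 1.25),
                              distance_range_kb = c(20, 200),
                              fragment_bp = 400, seed = 1) {
  set.seed(seed)
  n_peaks <- n_kee + n_nonkee
  klass <- sample(c(rep("KEE", n_kee), rep("nonKEE", n_nonkee)))
  cn <- "chrSim"
  probe <- granges0(cn, 0, 120)
  peak_gap <- 2000
  peak_span <- n_fragments * fragment_bp
  peak_starts <- 20000 + (seq_len(n_peaks) - 1) * (peak_span + peak_gap)
  frag_starts <- as.vector(vapply(peak_starts, function(s)
    s + (seq_len(n_fragments) - 1) * fragment_bp, numeric(n_fragments)))
  frags <- granges0(cn, frag_starts, frag_starts + fragment_bp)
  peaks <- granges0(cn, peak_starts, peak_starts + peak_span,
                    klass = klass,
                    true_effect = ifelse(klass == "KEE", effect, 1))
  d_kb <- stats::runif(n_peaks, distance_range_kb[1], distance_range_kb[2])
  mu_peak <- baseline * (d_kb + decay_scale_kb)^(-decay_exponent) * peak_boost
  mu <- rep(mu_peak, each = n_fragments)
  mu_trt <- rep(mu_peak * ifelse(klass == "KEE", effect, 1),
                each = n_fragments)
  samples <- c(paste0("control_", seq_len(n_replicates)),
               paste0("dot1li_", seq_len(n_replicates)))
  s_r <- stats::runif(length(samples), library_size_range[1],
                      library_size_range[2])
  counts <- sapply(seq_along(samples), function(j) {
    m <- if (grepl("^dot1li", samples[j])) mu_trt else mu
    stats::rnbinom(length(m), mu = m * s_r[j], size = 1 / nb_dispersion)
  })
  colnames(counts) <- samples
  totals <- pmax(round(1e5 * s_r), colSums(counts))
  design <- capture_design("sim_probe", probe,
                           granges0(cn, 0, max(end0(frags))),
                           n_replicates = n_replicates)
  fcm <- fragment_counts(frags, counts, stats::setNames(totals, samples))
  list(design = design, fcm = fcm, peaks = peaks)
}

#' Simulate a differential-expression table from gene labels
#'
#' Genes go down with probability `p_down_kee` or `p_down_nonkee` by label
#' (unlabelled genes use the non-KEE rate), up with `p_up`; log2 fold changes
#' are drawn with magnitude |N(log2fc_mean, log2fc_sd)| (floored at 0.01) and
#' the sign of the status, near zero for insensitive genes; FDR is < 0.05 iff
#' the gene changed, consistent with the status rule.
#'
#' @param gene_labels data.frame with gene_id and label columns
#' @param config a [sim_config()] (uses `config$de`)
#' @param seed optional seed override (default derives from config)
#' @return data.frame(gene_id, log2fc, fdr, status, true_status)
#' @export
simulate_de_table <- function(gene_labels, config, seed = NULL) {
  set.seed(if (is.null(seed)) sub_seed(config$seed, 3) else seed)
  de <- config$de
  n <- nrow(gene_labels)
  p_down <- ifelse(gene_labels$label == "KEE_gene", de$p_down_kee,
                   de$p_down_nonkee)
  u <- stats::runif(n)
  status <- ifelse(u < p_down, "down",
                   ifelse(u < p_down + de$p_up, "up", "insensitive"))
  mag <- pmax(abs(stats::rnorm(n, de$log2fc_mean, de$log2fc_sd)), 0.01)
  log2fc <- ifelse(status == "down", -mag,
                   ifelse(status == "up", mag, stats::rnorm(n, 0, 0.05)))
  fdr <- ifelse(status == "insensitive", stats::runif(n, 0.05, 1),
                stats::runif(n, 0, 0.0499))
  data.frame(gene_id = gene_labels$gene_id, log2fc = log2fc, fdr = fdr,
             status = de_status(log2fc, fdr), true_status = status,
             stringsAsFactors = FALSE)
}

#' Simulate a differential-ATAC table over enhancer calls
#'
#' One ATAC peak per enhancer (its central 60%); direction decreased with
#' probability `p_decreased_kee` / `p_decreased_nonkee` by class, otherwise
#' increased (0.2 of the remainder) or unchanged; FDR consistent with the
#' direction.
#'
#' @param enhancers enhancer GRanges with `klass`
#' @param config a [sim_config()] (uses `config$atac`)
#' @param seed optional seed override
#' @return GRanges with direction and fdr metadata
#' @export
simulate_atac <- function(enhancers, config, seed = NULL) {
  set.seed(if (is.null(seed)) sub_seed(config$seed, 4) else seed)
  at <- config$atac
  kl <- mcols(enhancers)$klass
  n <- length(enhancers)
  w <- BiocGenerics::width(enhancers)
  s <- round(start0(enhancers) + 0.2 * w)
  e <- pmax(s + 1, round(end0(enhancers) - 0.2 * w))
  p_dec <- ifelse(kl == "KEE", at$p_decreased_kee, at$p_decreased_nonkee)
  u <- stats::runif(n)
  direction <- ifelse(u < p_dec, "decreased",
                      ifelse(u < p_dec + 0.2 * (1 - p_dec),
                             "increased", "unchanged"))
  fdr <- ifelse(direction == "unchanged", stats::runif(n, 0.05, 1),
                stats::runif(n, 0, 0.0499))
  granges0(as.character(seqnames(enhancers)), s, e,
           direction = direction, fdr = fdr)
}

#' Construct a coupled enhancer/ATAC/DE experiment
#'
#' Builds `n_kee` + `n_nonkee` enhancers, each with its own gene and a
#' decreased ATAC peak inside it, and assigns the gene's DE status down with
#' the class-conditional probability (the cross-tab recovery construction).
#'
#' @param n_kee,n_nonkee enhancers per class
#' @param p_down_kee,p_down_nonkee P(gene down | decreased ATAC peak, class)
#' @param seed integer seed
#' @return list(enhancers, atac, de)
#' @export
simulate_atac_experiment <- function(n_kee, n_nonkee,
                                     p_down_kee = 0.73,
                                     p_down_nonkee = 0.21, seed = 1) {
  set.seed(seed)
  n <- n_kee + n_nonkee
  klass <- c(rep("KEE", n_kee), rep("nonKEE", n_nonkee))
  s <- (seq_len(n) - 1) * 5000 + 1000
  gid <- sprintf("g%04d", seq_len(n))
  enh <- granges0("chr1", s, s + 1000, klass = klass, gene_id = gid)
  atac <- granges0("chr1", s + 200, s + 800,
                   direction = "decreased",
                   fdr = stats::runif(n, 0, 0.0499))
  p <- ifelse(klass == "KEE", p_down_kee, p_down_nonkee)
  u <- stats::runif(n)
  status <- ifelse(u < p, "down",
                   ifelse(u < p + 0.1, "up", "insensitive"))
  mag <- pmax(abs(stats::rnorm(n, 1, 0.5)), 0.01)
  log2fc <- ifelse(status == "down", -mag,
                   ifelse(status == "up", mag, stats::rnorm(n, 0, 0.05)))
  fdr <- ifelse(status == "insensitive", stats::runif(n, 0.05, 1),
                stats::runif(n, 0, 0.0499))
  de <- data.frame(gene_id = gid, log2fc = log2fc, fdr = fdr,
                   stringsAsFactors = FALSE)
  list(enhancers = enh, atac = atac, de = de)
}

#' Simulate spike-in read-count tables for control and dot1li
#'
#' The IP library is a fixed sequencing depth split between target and spike
#' material; under dot1li the target material is scaled by `true_global_loss`
#' while spike material is held constant, so the ratio of the two rx factors
#' recovers the loss.
#'
#' @param config a [sim_config()] (uses `config$spikein`)
#' @param deterministic skip Poisson count noise (exact ratio)
#' @param seed optional seed override
#' @return data.frame, one row per condition, with an `rx_factor` column
#' @export
simulate_spikein <- function(config, deterministic = FALSE, seed = NULL) {
  set.seed(if (is.null(seed)) sub_seed(config$seed, 5) else seed)
  sp <- config$spikein
  g <- sp$true_global_loss
  if (g <= 0) stop("true_global_loss must be > 0")
  tgt <- sp$ip_target_share
  spk <- 1 - sp$ip_target_share
  draw <- function(x) if (deterministic) round(x) else stats::rpois(1, x)
  row <- function(cond, loss) {
    mass <- tgt * loss + spk
    data.frame(sample = cond,
               n_target_ip = draw(sp$depth * tgt * loss / mass),
               n_spike_ip = draw(sp$depth * spk / mass),
               n_target_input = draw(sp$target_input),
               n_spike_input = draw(sp$spike_input))
  }
  out <- rbind(row("control", 1), row("dot1li", g))
  out$rx_factor <- mapply(compute_rx_factor, out$n_target_ip, out$n_spike_ip,
                          out$n_target_input, out$n_spike_input)
  out
}

#' Score KEE/non-KEE call recovery against the ground truth
#'
#' A call is a true positive of its class when it overlaps exactly one true
#' enhancer of the same class.
#'
#' @param calls enhancer-call GRanges with `klass`
#' @param truth true enhancer GRanges with `klass`
#' @return list(precision, recall per class, n_calls, n_true, exact =
#'   calls and truth agree one-to-one with matching classes)
#' @export
kee_recovery <- function(calls, truth) {
  hits <- GenomicRanges::findOverlaps(calls, truth, ignore.strand = TRUE)
  call_kl <- mcols(calls)$klass
  true_kl <- mcols(truth)$klass
  n_hit <- GenomicRanges::countOverlaps(calls, truth, ignore.strand = TRUE)
  match_class <- rep(FALSE, length(calls))
  one <- which(n_hit == 1)
  qh <- queryHits(hits); sh <- subjectHits(hits)
  m <- match(one, qh)
  match_class[one] <- call_kl[one] == true_kl[sh[m]]
  per_class <- function(k) {
    called <- call_kl == k
    covered <- IRanges::overlapsAny(truth[true_kl == k], calls[called & match_class],
                                    ignore.strand = TRUE)
    c(precision = if (any(called)) mean(match_class[called]) else NA_real_,
      recall = mean(covered))
  }
  list(KEE = per_class("KEE"), nonKEE = per_class("nonKEE"),
       n_calls = length(calls), n_true = length(truth),
       exact = length(calls) == length(truth) && all(n_hit == 1) &&
         all(match_class))
}
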