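#' Write every simulated pipeline input to a directory
#'
#' Generates the genome, gene models, four histone-mark peak BEDs (with known
#' KEE ground truth), the paired H3K79me2/me3 and H3K27ac control/dot1li
#' tracks, spike-in read counts, the Capture-C experiment (design, fragment
#' counts, cis totals, true peak list) and a ground-truth manifest JSON.
#'
#' @param outdir output directory (created)
#' @param config a [sim_config()]
#' @return (invisibly) list(genome, sim, cap, spike)
#' @export
write_sim_inputs <- function(outdir, config = sim_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outdir, f)

  genome <- simulate_genome_and_genes(config)
  write_chrom_sizes(genome$chrom_sizes, pth("chrom.sizes"))
  write_gene_table(genome$genes, pth("genes.tsv"))

  sim <- simulate_enhancers_and_peaks(config, genome)
  for (mark in names(sim$peaks))
    write_bed(sim$peaks[[mark]], pth(sprintf("peaks_%s.bed", mark)))

  kl_true <- mcols(sim$truth)$klass
  mark_regions <- suppressWarnings(c(sim$truth[kl_true == "KEE"],
                                     sim$gene_blocks))
  tr79 <- simulate_track_pair(genome$chrom_sizes, mark_regions,
                              config$track_bg_rate, config$track_peak_rate,
                              rho = config$latent_mark_correlation,
                              latent_sd = config$track_latent_sd,
                              seed = sub_seed(config$seed, 10))
  write_bedgraph(tr79$a, pth("h3k79me2.bedgraph"), genome$chrom_sizes)
  write_bedgraph(tr79$b, pth("h3k79me3.bedgraph"), genome$chrom_sizes)

  tr27 <- simulate_track_pair(genome$chrom_sizes, sim$truth,
                              config$track_bg_rate, config$track_peak_rate,
                              rho = 1,
                              latent_sd = config$track_latent_sd,
                              dot1li_effect = config$capture$dot1li_effect,
                              kee = kl_true == "KEE",
                              seed = sub_seed(config$seed, 11))
  write_bedgraph(tr27$a, pth("h3k27ac_control.bedgraph"), genome$chrom_sizes)
  write_bedgraph(tr27$b, pth("h3k27ac_dot1li.bedgraph"), genome$chrom_sizes)

  spike <- simulate_spikein(config)
  utils::write.table(spike[, 1:5], pth("spikein.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cap <- simulate_capturec(config, genome, sim$truth)
  write_capture_design(list(cap$design), pth("capture_design.tsv"))
  write_fragment_counts(cap$fcm, pth("capture_counts.tsv"),
                        pth("capture_cis_totals.tsv"))
  write_bed(cap$peaks, pth("capture_peaks.bed"))

  manifest <- list(
    config = config,
    enhancers = data.frame(chrom = as.character(seqnames(sim$truth)),
                           start = start0(sim$truth), end = end0(sim$truth),
                           klass = kl_true,
                           location = mcols(sim$truth)$location),
    capture_probe_gene = cap$probe_gene_id)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(genome = genome, sim = sim, cap = cap, spike = spike))
}

#' Run the full synthetic workflow end to end
#'
#' simulate -> classify -> spike-in normalize -> Capture-C differential ->
#' integration statistics, writing every declared file under `outdir`:
#' simulated inputs (chrom.sizes, genes.tsv, four peak BEDs, paired mark
#' bedGraphs, spikein.tsv, capture counts/design/peaks, de.tsv, atac.tsv,
#' manifest.json) and analysis outputs (enhancers.bed, gene_labels.tsv,
#' classify_summary.json, rx-scaled bedGraph, capture_results.tsv,
#' capture_differential.bedgraph, integration_summary.json).
#'
#' Classification runs on the files read back from disk, so the whole I/O
#' surface is exercised.
#'
#' @param outdir output directory (created)
#' @param config a [sim_config()]
#' @return (invisibly) list with the intermediate objects and file paths
#' @export
run_kee_pipeline <- function(outdir, config = sim_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outdir, f)

  sim_objs <- write_sim_inputs(outdir, config)
  genome <- sim_objs$genome
  sim <- sim_objs$sim

  ## -- classify (from the files on disk) ------------------------------------
  sizes <- read_chrom_sizes(pth("chrom.sizes"))
  genes <- read_gene_table(pth("genes.tsv"), sizes)
  pk <- lapply(c(H3K4me1 = "peaks_H3K4me1.bed", H3K27ac = "peaks_H3K27ac.bed",
                 H3K79me2 = "peaks_H3K79me2.bed",
                 H3K79me3 = "peaks_H3K79me3.bed"),
               function(f) read_bed(pth(f), sizes))
  cls <- classify_enhancers(sizes, pk$H3K4me1, pk$H3K27ac, pk$H3K79me2, genes)
  write_bed(cls$enhancers, pth("enhancers.bed"))
  utils::write.table(cls$gene_labels, pth("gene_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  recov <- kee_recovery(cls$enhancers, sim$truth)
  jsonlite::write_json(list(summary = cls$summary, recovery = recov),
                       pth("classify_summary.json"), auto_unbox = TRUE,
                       digits = NA)

  ## -- spike-in normalization ------------------------------------------------
  rx <- read_spikein_counts(pth("spikein.tsv"))
  track_me3 <- read_bedgraph(pth("h3k79me3.bedgraph"), 200, sizes)
  f_dot1li <- rx$rx_factor[rx$sample == "dot1li"]
  write_bedgraph(scale_track(track_me3, f_dot1li),
                 pth("h3k79me3_dot1li_rx.bedgraph"), sizes)

  ## -- Capture-C differential -------------------------------------------------
  designs <- read_capture_design(pth("capture_design.tsv"))
  fcm <- read_fragment_counts(pth("capture_counts.tsv"),
                              pth("capture_cis_totals.tsv"))
  cap_peaks <- read_bed(pth("capture_peaks.bed"), sizes)
  diff <- run_capture_diff(designs[[1]], fcm, cap_peaks,
                           enhancers = cls$enhancers)
  utils::write.table(diff$results, pth("capture_results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_fragment_bedgraph(diff$track, pth("capture_differential.bedgraph"))

  ## -- integration -------------------------------------------------------------
  de <- simulate_de_table(cls$gene_labels, config)
  utils::write.table(de[, c("gene_id", "log2fc", "fdr")], pth("de.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  atac <- simulate_atac(cls$enhancers, config)
  utils::write.table(
    data.frame(chrom = as.character(seqnames(atac)), start = start0(atac),
               end = end0(atac), direction = mcols(atac)$direction,
               fdr = mcols(atac)$fdr),
    pth("atac.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  kl <- mcols(cls$enhancers)$klass
  me2 <- read_bedgraph(pth("h3k79me2.bedgraph"), 200, sizes)
  me3 <- read_bedgraph(pth("h3k79me3.bedgraph"), 200, sizes)
  corr <- correlate_signal(me2, me3, cls$enhancers[kl == "KEE"])
  # desk-scale genomes carry too few H3K79-marked non-KEE genes for the
  # restricted contrast; the pipeline summary uses all labelled genes
  dbc <- de_by_class(cls$gene_labels, read_de_table(pth("de.tsv")),
                     restrict_to_h3k79_marked = FALSE)
  act <- atac_cross_tab(read_atac_table(pth("atac.tsv")), cls$enhancers,
                        read_de_table(pth("de.tsv")), genes = genes)
  ctrl27 <- read_bedgraph(pth("h3k27ac_control.bedgraph"), 200, sizes)
  meta_kee <- metaprofile(ctrl27, cls$enhancers[kl == "KEE"])
  meta_non <- metaprofile(ctrl27, cls$enhancers[kl == "nonKEE"])
  integ <- list(
    mark_correlation = corr$r,
    de_proportions = as.data.frame.matrix(dbc$proportions),
    de_fisher_p = dbc$fisher$p.value,
    atac_down_proportion = as.list(act$down_proportion),
    atac_fisher_p = act$fisher$p.value,
    metaprofile_kee = meta_kee$profile,
    metaprofile_nonkee = meta_non$profile)
  jsonlite::write_json(integ, pth("integration_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(outdir = outdir, config = config, genome = genome,
                 sim = sim, classification = cls, recovery = recov,
                 spikein = rx, capture = diff, de = de,
                 integration = integ))
}
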