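#!/usr/bin/env Rscript
# Step 4: differential Capture-C enhancer-promoter interaction testing.
#
# Per-DpnII-fragment counts are normalized to reads per 100k cis-reported
# reads; candidate peaks outside the interaction domain, on trans chromosomes
# or within 10 kb of the probe are removed; each retained peak is tested with
# a paired signed-rank over fragments x replicates (control vs DOT1Li) and
# Holm-adjusted within the probe's peak family.

suppressPackageStartupMessages(library(keescan))

if (!file.exists("results/sim/capture_counts.tsv"))
  stop("run analysis/01_simulate.R first")
if (!file.exists("results/enhancers.bed"))
  stop("run analysis/02_classify_enhancers.R first")

sizes <- read_chrom_sizes("results/sim/chrom.sizes")
design <- read_capture_design("results/sim/capture_design.tsv")[[1]]
fcm <- read_fragment_counts("results/sim/capture_counts.tsv",
                            "results/sim/capture_cis_totals.tsv")
peaks <- read_bed("results/sim/capture_peaks.bed", sizes)
enhancers <- read_bed("results/enhancers.bed", sizes)
S4Vectors::mcols(enhancers)$klass <- S4Vectors::mcols(enhancers)$name

diff <- run_capture_diff(design, fcm, peaks, enhancers = enhancers)
write.table(diff$results, "results/capture_results.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_fragment_bedgraph(diff$track, "results/capture_differential.bedgraph")

res <- diff$results
sig <- res$p_holm < 0.05
message(sprintf("probe %s: %d peaks tested, %d significant after Holm",
                design$probe_id, nrow(res), sum(sig)))
print(table(class = res$enhancer_class, significant = sig))
message(sprintf("mean interaction change at KEE peaks: %.1f; non-KEE: %.1f",
                mean(res$mean_delta[res$enhancer_class == "KEE"]),
                mean(res$mean_delta[res$enhancer_class == "nonKEE"])))
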