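#!/usr/bin/env Rscript
# Step 1: generate the synthetic study inputs under results/sim/.
#
# Emulates the sequencing-derived inputs of the enhancer study: histone-mark
# peak calls with known KEE (H3K79me2/3-marked enhancer) ground truth, paired
# H3K79me2/me3 signal tracks, H3K27ac control/DOT1Li tracks, spike-in read
# counts with a true 10x global loss, and a Capture-C experiment in which
# KEE-promoter contacts are attenuated 0.4x under DOT1Li.

suppressPackageStartupMessages(library(keescan))

cfg <- sim_config(seed = 7)
objs <- write_sim_inputs("results/sim", cfg)

truth <- objs$sim$truth
message(sprintf("genome: %d chromosomes x %g bp, %d genes",
                cfg$n_chroms, cfg$chrom_length_bp, length(objs$genome$genes)))
message(sprintf("true enhancers: %d KEE + %d non-KEE (%d intragenic)",
                cfg$n_kee, cfg$n_nonkee,
                sum(S4Vectors::mcols(truth)$location == "intragenic")))
message(sprintf("capture probe at gene %s; %d fragments in the domain",
                objs$cap$probe_gene_id, length(objs$cap$fcm$fragments)))
message("inputs written to results/sim/ (ground truth in manifest.json)")
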