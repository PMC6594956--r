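#!/usr/bin/env Rscript
# Step 5: integration statistics linking enhancer class to transcription and
# chromatin accessibility.
#
# (a) H3K79me2 vs H3K79me3 signal correlation at KEE calls; (b) the DE-status
# x enhancer-class contingency with Fisher's exact test; (c) decreased-ATAC x
# class x gene-status cross-tabulation; (d) H3K27ac metaprofiles over KEEs vs
# non-KEEs. The DE and ATAC tables are generated here from the classified
# gene labels (they are inputs consumed, not computed, by the real analysis).

suppressPackageStartupMessages(library(keescan))

if (!file.exists("results/gene_labels.tsv"))
  stop("run analysis/02_classify_enhancers.R first")
cfg <- sim_config(seed = 7)
sizes <- read_chrom_sizes("results/sim/chrom.sizes")
genes <- read_gene_table("results/sim/genes.tsv", sizes)
enhancers <- read_bed("results/enhancers.bed", sizes)
S4Vectors::mcols(enhancers)$klass <- S4Vectors::mcols(enhancers)$name
enhancers <- assign_genes(enhancers, genes)
labels <- read.table("results/gene_labels.tsv", header = TRUE, sep = "\t")

# (a) mark-mark correlation at KEEs
me2 <- read_bedgraph("results/sim/h3k79me2.bedgraph", 200, sizes)
me3 <- read_bedgraph("results/sim/h3k79me3.bedgraph", 200, sizes)
kee <- enhancers[S4Vectors::mcols(enhancers)$klass == "KEE"]
corr <- correlate_signal(me2, me3, kee)
message(sprintf("H3K79me2 vs me3 correlation at %d KEEs: R = %.3f",
                length(kee), corr$r))
write.table(data.frame(log2_me2 = corr$values$a, log2_me3 = corr$values$b),
            "results/mark_correlation_points.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# (b) differential expression by enhancer class
de <- simulate_de_table(labels, cfg)
write.table(de[, c("gene_id", "log2fc", "fdr")], "results/de.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
dbc <- de_by_class(labels, read_de_table("results/de.tsv"),
                   restrict_to_h3k79_marked = FALSE)
print(dbc$table)
message(sprintf("downregulated: %.0f%% of KEE genes vs %.0f%% of non-KEE genes (Fisher p = %.3g)",
                100 * dbc$proportions["KEE_gene", "down"],
                100 * dbc$proportions["nonKEE_gene", "down"],
                dbc$fisher$p.value))
write.table(as.data.frame(dbc$table), "results/de_by_class.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# (c) decreased ATAC peaks vs transcription, by enhancer class
atac_gr <- simulate_atac(enhancers, cfg)
write.table(data.frame(chrom = as.character(GenomeInfoDb::seqnames(atac_gr)),
                       start = start0(atac_gr), end = end0(atac_gr),
                       direction = S4Vectors::mcols(atac_gr)$direction,
                       fdr = S4Vectors::mcols(atac_gr)$fdr),
            "results/atac.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
act <- atac_cross_tab(read_atac_table("results/atac.tsv"), enhancers,
                      read_de_table("results/de.tsv"), genes = genes)
print(act$decreased_by_gene_status)
message(sprintf("decreased ATAC peaks over down genes: %.0f%% in KEEs vs %.0f%% in non-KEEs",
                100 * act$down_proportion["KEE"],
                100 * act$down_proportion["nonKEE"]))

# (d) H3K27ac metaprofiles
ctrl <- read_bedgraph("results/sim/h3k27ac_control.bedgraph", 200, sizes)
non <- enhancers[S4Vectors::mcols(enhancers)$klass == "nonKEE"]
mk <- metaprofile(ctrl, kee)
mn <- metaprofile(ctrl, non)
write.table(data.frame(bin = seq_along(mk$profile), kee = mk$profile,
                       nonkee = mn$profile),
            "results/h3k27ac_metaprofile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("integration tables written under results/")
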