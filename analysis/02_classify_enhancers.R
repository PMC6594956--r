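#!/usr/bin/env Rscript
# Step 2: classify enhancers into KEEs and non-KEEs from the peak calls.
#
# 200 bp genome buckets are classified by mark presence (KEE = H3K4me1 +
# H3K27ac + H3K79me2; non-KEE = H3K4me1 + H3K27ac without H3K79me2), runs
# < 1 kb apart are merged, merged calls are labelled KEE if any KEE bucket is
# present, annotated intragenic/intergenic, and assigned to their nearest
# gene; genes inherit KEE labels with KEE precedence.

suppressPackageStartupMessages(library(keescan))

if (!file.exists("results/sim/chrom.sizes"))
  stop("run analysis/01_simulate.R first")
sizes <- read_chrom_sizes("results/sim/chrom.sizes")
genes <- read_gene_table("results/sim/genes.tsv", sizes)
pk <- lapply(c(H3K4me1 = "H3K4me1", H3K27ac = "H3K27ac",
               H3K79me2 = "H3K79me2"),
             function(m) read_bed(sprintf("results/sim/peaks_%s.bed", m), sizes))

cls <- classify_enhancers(sizes, pk$H3K4me1, pk$H3K27ac, pk$H3K79me2, genes)
write_bed(cls$enhancers, "results/enhancers.bed")
write.table(cls$gene_labels, "results/gene_labels.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cls$summary, "results/enhancer_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

print(cls$summary)

# score calls against the generator's ground truth
man <- jsonlite::read_json("results/sim/manifest.json", simplifyVector = TRUE)
truth <- granges0(man$enhancers$chrom, man$enhancers$start, man$enhancers$end,
                  klass = man$enhancers$klass)
rec <- kee_recovery(cls$enhancers, truth)
message(sprintf("recovery vs manifest: KEE precision %.2f recall %.2f (exact: %s)",
                rec$KEE["precision"], rec$KEE["recall"], rec$exact))
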