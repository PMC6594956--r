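test_that("bucketize tiles each chromosome with a short final bucket", {
  b <- bucketize(chrom_sizes(c("chr1", "chr2"), c(500, 400)), 200)
  b1 <- b[as.character(seqnames(b)) == "chr1"]
  expect_equal(start0(b1), c(0, 200, 400))
  expect_equal(end0(b1), c(200, 400, 500))
  expect_equal(sum(as.character(seqnames(b)) == "chr2"), 2)
  expect_error(bucketize(chrom_sizes("chr1", 500), 0), "> 0")
})

test_that("bucket states follow the three-mark presence rule", {
  buckets <- bucketize(chrom_sizes("chr1", 1000), 200)
  k4 <- granges0("chr1", c(0, 400), c(400, 600))
  k27 <- granges0("chr1", 0, 600)
  k79 <- granges0("chr1", c(0, 600), c(200, 800))
  st <- S4Vectors::mcols(classify_buckets(buckets, k4, k27, k79))$state
  # bucket0: all three -> KEE; 1-2: k4+k27 only -> nonKEE;
  # bucket3: k79 only -> none; bucket4: nothing
  expect_equal(st, c("KEE", "nonKEE", "nonKEE", "none", "none"))
  expect_error(classify_buckets(buckets, k4, k27, NULL), "h3k79")
})

test_that("call_enhancers merges runs and labels by KEE-bucket presence", {
  # single KEE bucket -> one KEE enhancer at the bucket
  one <- call_enhancers(bucket_fixture(c("none", "none", "none", "none", "none",
                                         "KEE", "none")))
  expect_equal(c(start0(one), end0(one)), c(1000, 1200))
  expect_equal(S4Vectors::mcols(one)$klass, "KEE")

  # KEE run [0,600) and nonKEE run [1400,1600): gap 800 -> one KEE enhancer
  st <- rep("none", 8)
  st[1:3] <- "KEE"; st[8] <- "nonKEE"
  merged <- call_enhancers(bucket_fixture(st))
  expect_equal(length(merged), 1)
  expect_equal(c(start0(merged), end0(merged)), c(0, 1600))
  expect_equal(S4Vectors::mcols(merged)$klass, "KEE")
  expect_equal(S4Vectors::mcols(merged)$n_kee_buckets, 3)
  expect_equal(S4Vectors::mcols(merged)$n_nonkee_buckets, 1)

  # two nonKEE runs, gap 1200 -> two nonKEE enhancers
  st2 <- rep("none", 10)
  st2[1:2] <- "nonKEE"; st2[9:10] <- "nonKEE"
  two <- call_enhancers(bucket_fixture(st2))
  expect_equal(length(two), 2)
  expect_equal(unique(S4Vectors::mcols(two)$klass), "nonKEE")
})

test_that("location, gene assignment and gene labels follow the rules", {
  genes <- granges0("chr1", c(1000, 20000, 40000), c(6000, 30000, 45000),
                    strand = c("+", "-", "+"),
                    gene_id = c("gA", "gB", "gC"),
                    gene_name = c("A", "B", "C"))
  S4Vectors::mcols(genes)$tss <- c(1000, 29999, 40000)
  enh <- granges0("chr1", c(2000, 9999, 31000, 46000), c(2600, 10500, 31400, 46600),
                  klass = c("KEE", "nonKEE", "nonKEE", "KEE"))
  enh <- annotate_location(enh, genes)
  expect_equal(S4Vectors::mcols(enh)$location,
               c("intragenic", "intergenic", "intergenic", "intergenic"))
  enh <- assign_genes(enh, genes)
  # intragenic -> host gene at distance 0; exhaustive-by-hand distances:
  # enh2 mid-gap: 3999 to gA end vs 9500 to gB start -> gA
  # enh3: 1000 past gB end, 8600 before gC -> gB; enh4 -> gC (1000 past end)
  expect_equal(S4Vectors::mcols(enh)$gene_id, c("gA", "gA", "gB", "gC"))
  expect_equal(S4Vectors::mcols(enh)$gene_distance, c(0, 3999, 1000, 1000))

  labels <- label_genes(enh, genes, h3k79_peaks = granges0("chr1", 2000, 2600))
  expect_equal(labels$label, c("KEE_gene", "nonKEE_gene", "KEE_gene"))
  expect_equal(labels$h3k79_marked, c(TRUE, FALSE, FALSE))

  # a gene with both KEE and non-KEE assignments is a KEE gene
  mixed <- granges0("chr1", c(2000, 3000, 3500), c(2200, 3200, 3700),
                    klass = c("KEE", "nonKEE", "nonKEE"))
  mixed <- assign_genes(mixed, genes)
  expect_equal(label_genes(mixed, genes)$label[1], "KEE_gene")

  expect_error(assign_genes(granges0("chr9", 0, 100, klass = "KEE"), genes),
               "chr9")
})

test_that("gene-body H3K79 marking is body-only with >=1 bp overlap", {
  genes <- granges0("chr1", c(1000, 5000), c(2000, 6000),
                    gene_id = c("gA", "gB"), gene_name = c("A", "B"))
  peaks <- granges0("chr1", c(1500, 4000), c(1600, 5000))
  # second peak ends exactly at gB start (half-open: no overlap)
  expect_equal(mark_h3k79_genes(genes, peaks), c(TRUE, FALSE))
  expect_equal(mark_h3k79_genes(genes, granges0("chr1", 4000, 5001)),
               c(FALSE, TRUE))
})

test_that("kee_fraction_summary computes counts, medians and fractions", {
  enh <- granges0("chr1",
                  c(0, 2000, 5000, 10000, 20000),
                  c(400, 3000, 6600, 10800, 20800),
                  klass = c("KEE", "KEE", "KEE", "nonKEE", "nonKEE"),
                  location = c("intragenic", "intragenic", "intragenic",
                               "intergenic", "intragenic"))
  s <- kee_fraction_summary(enh)
  expect_equal(s$median_length_bp[s$klass == "KEE"], 1000)
  expect_equal(s$proportion, c(0.6, 0.4))
  expect_equal(s$intragenic_fraction, c(1, 0.5))
  expect_error(kee_fraction_summary(enh[0]), "no enhancer")
})

test_that("classification is invariant to peak order and H3K79 set identity", {
  cfg <- sim_config(seed = 19)
  genome <- simulate_genome_and_genes(cfg)
  sim <- simulate_enhancers_and_peaks(cfg, genome)
  pk <- sim$peaks
  base <- classify_enhancers(genome$chrom_sizes, pk$H3K4me1, pk$H3K27ac,
                             pk$H3K79me2, genome$genes)
  # shuffled peak input order
  shuffle <- function(gr) gr[sample(length(gr))]
  set.seed(5)
  perm <- classify_enhancers(genome$chrom_sizes, shuffle(pk$H3K4me1),
                             shuffle(pk$H3K27ac), shuffle(pk$H3K79me2),
                             genome$genes)
  expect_identical(as.data.frame(base$enhancers), as.data.frame(perm$enhancers))
  # an H3K79 set identical to me2 gives identical calls
  copy <- granges0(as.character(seqnames(pk$H3K79me2)), start0(pk$H3K79me2),
                   end0(pk$H3K79me2))
  same <- classify_enhancers(genome$chrom_sizes, pk$H3K4me1, pk$H3K27ac,
                             copy, genome$genes)
  expect_identical(as.data.frame(base$enhancers), as.data.frame(same$enhancers))
})

test_that("me2 and me3 classifications agree at high peak concordance", {
  cfg <- sim_config(seed = 7)
  genome <- simulate_genome_and_genes(cfg)
  sim <- simulate_enhancers_and_peaks(cfg, genome)
  me2 <- classify_enhancers(genome$chrom_sizes, sim$peaks$H3K4me1,
                            sim$peaks$H3K27ac, sim$peaks$H3K79me2,
                            genome$genes)$enhancers
  me3 <- classify_enhancers(genome$chrom_sizes, sim$peaks$H3K4me1,
                            sim$peaks$H3K27ac, sim$peaks$H3K79me3,
                            genome$genes)$enhancers
  kee2 <- me2[S4Vectors::mcols(me2)$klass == "KEE"]
  kee3 <- me3[S4Vectors::mcols(me3)$klass == "KEE"]
  inter <- sum(interval_overlaps(kee2, kee3))
  union <- length(kee2) + length(kee3) - inter
  expect_gte(inter / union, 0.9)
})

test_that("KEE/non-KEE invariants hold when rescanning calls against inputs", {
  cfg <- sim_config(seed = 23)
  genome <- simulate_genome_and_genes(cfg)
  sim <- simulate_enhancers_and_peaks(cfg, genome)
  buckets <- bucketize(genome$chrom_sizes)
  cls <- classify_buckets(buckets, sim$peaks$H3K4me1, sim$peaks$H3K27ac,
                          sim$peaks$H3K79me2)
  enh <- call_enhancers(cls)
  st <- S4Vectors::mcols(cls)$state
  kl <- S4Vectors::mcols(enh)$klass
  # every KEE call contains >= 1 triple-marked bucket
  expect_true(all(GenomicRanges::countOverlaps(
    enh[kl == "KEE"], cls[st == "KEE"]) >= 1))
  # no non-KEE call contains a bucket overlapped by an H3K79 peak
  h79_buckets <- cls[IRanges::overlapsAny(cls, sim$peaks$H3K79me2) &
                       st != "none"]
  expect_equal(sum(GenomicRanges::countOverlaps(
    enh[kl == "nonKEE"], h79_buckets)), 0)
})
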