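test_that("correlate_signal handles identity, negation and errors", {
  tr <- signal_track(200, list(chr1 = c(1, 5, 2, 8, 3, 9, 4, 0)))
  iv <- granges0("chr1", c(0, 400, 1000), c(400, 1000, 1600))
  expect_equal(correlate_signal(tr, tr, iv)$r, 1)
  neg <- signal_track(200, list(chr1 = -tr$values$chr1))
  expect_equal(correlate_signal(tr, neg, iv, transform = "raw")$r, -1)
  expect_error(correlate_signal(tr, tr, iv[1:2]), "at least 3")
  flat <- signal_track(200, list(chr1 = rep(2, 8)))
  iv_eq <- granges0("chr1", c(0, 400, 800), c(400, 800, 1200))
  expect_error(correlate_signal(flat, tr, iv_eq), "zero variance")
  expect_error(correlate_signal(tr, signal_track(100), iv), "bin grid")
})

test_that("rank-sum test matches enumeration and wilcox.test", {
  # groups of sizes 3 and 4: enumeration over all 35 assignments
  x <- c(1.2, 3.4, 2.2); y <- c(0.1, 4.4, 5.5, 6.6)
  expect_equal(rank_sum_test(x, y)$p.value, oracle_rank_sum_p(x, y))
  expect_equal(rank_sum_test(x, y)$p.value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value)
  set.seed(3)
  for (rep in 1:10) {
    a <- sample(1:8, 6, replace = TRUE)   # ties likely
    b <- sample(1:8, 6, replace = TRUE)
    expect_equal(rank_sum_test(a, b)$p.value, oracle_rank_sum_p(a, b))
  }
  big <- rank_sum_test(rnorm(300), rnorm(300) + 1)
  expect_equal(big$method, "normal")
  expect_lt(big$p.value, 1e-10)
})

test_that("compare_expression detects a constant shift and respects groups", {
  labels <- data.frame(gene_id = sprintf("g%02d", 1:40),
                       label = rep(c("KEE_gene", "nonKEE_gene"), each = 20),
                       h3k79_marked = TRUE)
  expr <- data.frame(gene_id = labels$gene_id,
                     value = c(seq(1, 20) + 10, seq(1, 20)))
  r <- compare_expression(labels, expr)
  expect_equal(unname(r$medians["KEE_gene"] - r$medians["nonKEE_gene"]), 10)
  expect_lt(r$p.value, 0.01)
  # restriction empties a group -> error
  labels$h3k79_marked <- labels$label == "KEE_gene"
  expect_error(compare_expression(labels, expr), "empty")
})

test_that("de_status implements the FDR/sign rule", {
  expect_equal(de_status(c(-2, 1.5, -0.5, 2), c(0.01, 0.001, 0.2, 0.06)),
               c("down", "up", "insensitive", "insensitive"))
})

test_that("de_by_class cross-tabulates and is order-invariant", {
  labels <- data.frame(gene_id = sprintf("g%02d", 1:14),
                       label = c(rep("KEE_gene", 10), rep("nonKEE_gene", 4)),
                       h3k79_marked = TRUE)
  de <- data.frame(gene_id = labels$gene_id,
                   log2fc = c(rep(-1, 4), rep(0.01, 6), rep(-1, 1), rep(0.01, 3)),
                   fdr = c(rep(0.01, 4), rep(0.5, 6), rep(0.01, 1), rep(0.5, 3)))
  r <- de_by_class(labels, de)
  expect_equal(unname(r$proportions["KEE_gene", "down"]), 0.4)
  expect_equal(unname(r$table["nonKEE_gene", "down"]), 1)
  expect_equal(sum(r$proportions["KEE_gene", ]), 1)
  # shuffling both tables leaves every statistic unchanged
  set.seed(9)
  r2 <- de_by_class(labels[sample(14), ], de[sample(14), ])
  expect_equal(r2$table, r$table)
  expect_equal(r2$fisher$p.value, r$fisher$p.value)
  expect_error(de_by_class(rbind(labels, labels[1, ]), de), "duplicate")
  # no downregulated genes -> zero column, Fisher p = 1
  de0 <- transform(de, log2fc = abs(log2fc))
  r0 <- de_by_class(labels, de0)
  expect_equal(unname(r0$collapsed[, "down"]), c(0, 0))
  expect_equal(r0$fisher$p.value, 1)
})

test_that("fisher_exact matches stats and closed forms", {
  sym <- fisher_exact(matrix(c(5, 5, 5, 5), 2, 2))
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p.value, 1)
  r <- fisher_exact(matrix(c(8, 1, 2, 5), 2, 2))  # [[8,2],[1,5]]
  expect_equal(r$odds_ratio, 20)
  expect_equal(r$p.value, oracle_fisher_p(matrix(c(8, 1, 2, 5), 2, 2)))
  expect_equal(r$p.value, 0.035, tolerance = 0.01)
  # [[0,n],[n,0]] -> OR 0, p = 2 / C(2n, n)
  for (n in c(3, 5, 7)) {
    ex <- fisher_exact(matrix(c(0, n, n, 0), 2, 2))
    expect_equal(ex$odds_ratio, 0)
    expect_true(ex$or_degenerate)
    expect_equal(ex$p.value, min(1, 2 / choose(2 * n, n)))
  }
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2, 2)), "non-negative")
})

test_that("atac_cross_tab applies KEE precedence and recovers proportions", {
  # peak overlapping both classes counts as KEE
  enh <- granges0("chr1", c(1000, 1800), c(1600, 2400),
                  klass = c("KEE", "nonKEE"), gene_id = c("gA", "gB"))
  atac <- granges0("chr1", 1500, 1900, direction = "decreased", fdr = 0.01)
  de <- data.frame(gene_id = c("gA", "gB"), log2fc = c(-2, -2),
                   fdr = c(0.01, 0.01))
  r <- atac_cross_tab(atac, enh, de)
  expect_equal(unname(r$direction_by_class["decreased", "KEE"]), 1)
  expect_equal(unname(r$decreased_by_gene_status["KEE", "down"]), 1)
  # all decreased peaks at KEEs of down genes -> proportion 1
  expect_equal(unname(r$down_proportion["KEE"]), 1)
  # conditional-coupling recovery at the generator's target proportions
  ex <- simulate_atac_experiment(200, 200, p_down_kee = 0.7,
                                 p_down_nonkee = 0.2, seed = 31)
  rx <- atac_cross_tab(ex$atac, ex$enhancers, ex$de)
  expect_equal(unname(rx$down_proportion["KEE"]), 0.7, tolerance = 0.07)
  expect_equal(unname(rx$down_proportion["nonKEE"]), 0.2, tolerance = 0.35)
  expect_lt(rx$fisher$p.value, 1e-6)
})

test_that("metaprofile scales bodies, averages flanks and skips short input", {
  # constant track -> flat profile at the constant
  flat <- signal_track(200, list(chr1 = rep(3, 100)))
  iv <- granges0("chr1", c(4000, 9000), c(5000, 11000))
  mp <- metaprofile(flat, iv, flank_bp = 1000, n_body_bins = 10,
                    n_flank_bins = 5)
  expect_equal(length(mp$profile), 20)
  expect_true(all(abs(mp$profile - 3) < 1e-12))
  # one interval spanning exactly one bin of value v -> body all v
  tr <- signal_track(200, list(chr1 = c(0, 0, 7, 0)))
  one <- metaprofile(tr, granges0("chr1", 400, 600), flank_bp = 0,
                     n_body_bins = 4, n_flank_bins = 0)
  expect_equal(one$profile, rep(7, 4))
  # two intervals with constant values 2 and 4 -> mean profile 3
  tr2 <- signal_track(200, list(chr1 = c(2, 2, 2, 4, 4, 4)))
  two <- metaprofile(tr2, granges0("chr1", c(0, 600), c(600, 1200)),
                     flank_bp = 0, n_body_bins = 3, n_flank_bins = 0)
  expect_equal(two$profile, rep(3, 3))
  # intervals shorter than one track bin are skipped with a warning
  expect_warning(
    short <- metaprofile(tr2, granges0("chr1", c(0, 100), c(600, 150)),
                         flank_bp = 0, n_body_bins = 3, n_flank_bins = 0),
    "skipped")
  expect_equal(short$n_skipped, 1)
  expect_equal(short$n_used, 1)
})

test_that("metaprofiles separate KEE from non-KEE on enriched synthetic tracks", {
  cfg <- sim_config(seed = 7)
  genome <- simulate_genome_and_genes(cfg)
  sim <- simulate_enhancers_and_peaks(cfg, genome)
  kl <- S4Vectors::mcols(sim$truth)$klass
  # signal only at KEEs
  tp <- simulate_track_pair(genome$chrom_sizes, sim$truth[kl == "KEE"],
                            bg_rate = 0.5, peak_rate = 50, rho = 1, seed = 2)
  mk <- metaprofile(tp$a, sim$truth[kl == "KEE"], n_body_bins = 20,
                    n_flank_bins = 5)
  mn <- metaprofile(tp$a, sim$truth[kl == "nonKEE"], n_body_bins = 20,
                    n_flank_bins = 5)
  body <- 6:25
  expect_true(all(mk$profile[body] > mn$profile[body]))
})

test_that("ATAC and DE tables round-trip through their readers", {
  f <- withr::local_tempfile()
  utils::write.table(data.frame(chrom = "chr1", start = 100, end = 300,
                                direction = "decreased", fdr = 0.001),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  at <- read_atac_table(f)
  expect_equal(S4Vectors::mcols(at)$direction, "decreased")
  utils::write.table(data.frame(gene_id = "g1", log2fc = -2, fdr = 0.01),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  de <- read_de_table(f)
  expect_equal(de$status, "down")
})
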