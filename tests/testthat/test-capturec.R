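make_fcm <- function(counts, frag_bp = 400, chrom = "chr1", offset = 20000,
                     totals = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  frags <- granges0(chrom, offset + (seq_len(n) - 1) * frag_bp,
                    offset + seq_len(n) * frag_bp)
  if (is.null(totals)) totals <- colSums(counts)
  fragment_counts(frags, counts, stats::setNames(totals, colnames(counts)))
}

test_that("normalize_counts rescales to reads per 100k cis reads", {
  cnt <- cbind(control_1 = c(10, 0, 30), dot1li_1 = c(4, 4, 4))
  fcm <- make_fcm(cnt, totals = c(50000, 100000))
  nn <- normalize_counts(fcm)
  expect_equal(unname(nn$counts[, "control_1"]), c(20, 0, 60))
  expect_equal(unname(nn$counts[, "dot1li_1"]), c(4, 4, 4))  # identity at 1e5
  bad <- fcm; bad$cis_totals["dot1li_1"] <- 0
  expect_error(normalize_counts(bad), "dot1li_1")
})

test_that("fragment count validation catches malformed inputs", {
  frags <- granges0("chr1", c(0, 400), c(400, 800))
  cnt <- cbind(control_1 = c(1, 2), dot1li_1 = c(3, 4))
  expect_error(fragment_counts(frags, cnt, c(control_1 = 2, dot1li_1 = 7)),
               "cis_totals below")
  colnames(cnt) <- c("ctl_1", "dot1li_1")
  expect_error(fragment_counts(frags, cnt, c(ctl_1 = 5, dot1li_1 = 7)),
               "condition")
})

test_that("peak filtering applies domain, cis and exclusion-zone rules", {
  design <- capture_design("p1", granges0("chr1", 100000, 100120),
                           granges0("chr1", 0, 300000))
  peaks <- granges0(c("chr2", "chr1", "chr1", "chr1", "chr1"),
                    c(150000, 104000, 150000, 290000, 250000),
                    c(151000, 105120, 151000, 301000, 251000))
  kept <- filter_peaks(peaks, design)
  # trans chromosome, 3880 bp edge gap (<= 10 kb) and domain-overhang removed
  expect_equal(start0(kept), c(150000, 250000))
  # edge distance exactly 10 kb is still removed (strict >)
  at10k <- granges0("chr1", 110121, 111000)
  expect_equal(length(filter_peaks(at10k, design)), 1)
  expect_equal(length(filter_peaks(granges0("chr1", 110120, 111000), design)), 0)
  expect_error(capture_design("p", granges0("chr1", 0, 100),
                              granges0("chr1", 50, 500)), "inside")
})

test_that("signed-rank conventions: zeros dropped, midranks, exact p", {
  expect_equal(paired_signed_rank(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  r1 <- paired_signed_rank(rep(0, 5), c(1, 2, 3, 4, 5))
  expect_equal(r1$statistic, 15)
  expect_equal(r1$p.value, 0.0625)
  r2 <- paired_signed_rank(rep(0, 5), c(5, -1, 2, 3, 4))
  expect_equal(r2$statistic, 14)
  expect_equal(r2$p.value, 0.125)
  # zero differences reduce n
  r3 <- paired_signed_rank(c(1, 5, 5), c(2, 5, 5))
  expect_equal(r3$n_used, 1)
  expect_equal(r3$p.value, 1)  # single pair: both tails = 1/2
  expect_error(paired_signed_rank(numeric(0), numeric(0)), "empty")
})

test_that("exact signed-rank p matches enumeration for random ties/zeros", {
  set.seed(11)
  for (n in 3:10) {
    for (rep in 1:5) {
      d <- sample(c(-3, -2, -1, 0, 1, 2, 3), n, replace = TRUE)
      expect_equal(paired_signed_rank(rep(0, n), d)$p.value,
                   oracle_signed_rank_p(d), info = paste("n =", n))
    }
  }
})

test_that("signed-rank agrees with wilcox.test on tie-free data", {
  set.seed(13)
  for (rep in 1:10) {
    x <- rnorm(12); y <- rnorm(12)
    ours <- paired_signed_rank(x, y)
    ref <- stats::wilcox.test(y, x, paired = TRUE, exact = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p.value, ref$p.value)
  }
})

test_that("normal-approximation branch is close to the exact p", {
  set.seed(17)
  d <- rnorm(30) + 0.4
  approx <- paired_signed_rank(rep(0, 30), d, exact_limit = 25)
  exact <- paired_signed_rank(rep(0, 30), d, exact_limit = 30)
  expect_equal(approx$method, "normal")
  expect_equal(exact$method, "exact")
  expect_equal(approx$p.value, exact$p.value, tolerance = 0.05)
})

test_that("holm adjustment matches the step-down trace and its properties", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  p <- c(0.001, 0.2, 0.04, 0.04, 0.9)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  # permutation equivariance
  perm <- sample(length(p))
  expect_equal(holm_adjust(p[perm]), adj[perm])
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("test_peak pools fragments x replicates with index pairing", {
  cnt <- cbind(control_1 = c(10, 20, 30, 40), control_2 = c(12, 22, 32, 42),
               control_3 = c(9, 19, 29, 39),
               dot1li_1 = c(10, 20, 30, 40), dot1li_2 = c(12, 22, 32, 42),
               dot1li_3 = c(9, 19, 29, 39))
  fcm <- normalize_counts(make_fcm(cnt, totals = rep(1e5, 6)))
  peak <- granges0("chr1", 20000, 21600)
  r <- test_peak(peak, fcm)
  expect_equal(r$n_fragments, 4)
  expect_equal(r$n_pairs, 12)
  expect_equal(r$mean_delta, 0)
  expect_equal(r$p_raw, 1)
  # all dot1li halved -> minimal W, negative delta
  cnt2 <- cnt
  cnt2[, 4:6] <- cnt2[, 1:3] / 2
  fcm2 <- normalize_counts(make_fcm(cnt2, totals = rep(1e5, 6)))
  r2 <- test_peak(peak, fcm2)
  expect_equal(r2$statistic, 0)
  expect_lt(r2$mean_delta, 0)
  expect_lt(r2$p_raw, 0.001)
  expect_error(test_peak(granges0("chr1", 0, 100), fcm), "no fragment")
  # unequal replicate structure
  cnt3 <- cnt[, c(1, 2, 3, 4)]
  fcm3 <- normalize_counts(make_fcm(cnt3, totals = rep(1e5, 4)))
  expect_error(test_peak(peak, fcm3), "unequal replicate")
})

test_that("differential track smooths per-fragment condition differences", {
  cnt <- cbind(control_1 = c(1, 2, 3, 4, 5), dot1li_1 = c(2, 2, 9, 4, 5))
  fcm <- normalize_counts(make_fcm(cnt, totals = c(1e5, 1e5)))
  raw <- differential_track(fcm, 1)
  expect_equal(S4Vectors::mcols(raw)$score, c(1, 0, 6, 0, 0))
  sm <- differential_track(fcm, 3)
  expect_equal(S4Vectors::mcols(sm)$score,
               c(1 / 2, 7 / 3, 2, 2, 0))
  expect_error(differential_track(fcm, 2), "odd")
  # identical conditions -> all-zero track
  same <- normalize_counts(make_fcm(cbind(control_1 = 1:5, dot1li_1 = 1:5),
                                    totals = c(1e5, 1e5)))
  expect_true(all(S4Vectors::mcols(differential_track(same))$score == 0))
  # window 1 conserves the summed library difference over the region
  expect_equal(sum(S4Vectors::mcols(raw)$score),
               sum(fcm$counts[, 2]) - sum(fcm$counts[, 1]))
})

test_that("run_capture_diff filters, tests, adjusts per family and classifies", {
  sim <- simulate_peak_set(3, 3, effect = 0.2, n_fragments = 8, seed = 41)
  out <- run_capture_diff(sim$design, sim$fcm, sim$peaks,
                          enhancers = sim$peaks)
  expect_equal(nrow(out$results), 6)
  expect_true(all(out$results$p_holm >= out$results$p_raw))
  expect_equal(out$results$p_holm, holm_adjust(out$results$p_raw))
  expect_setequal(unique(out$results$enhancer_class), c("KEE", "nonKEE"))
  # single retained peak: p_holm equals p_raw
  one <- run_capture_diff(sim$design, sim$fcm, sim$peaks[1])
  expect_equal(one$results$p_holm, one$results$p_raw)
  expect_equal(one$results$enhancer_class, "unassigned")
  # zero retained peaks -> empty result
  none <- run_capture_diff(sim$design, sim$fcm,
                           granges0("chr9", 1000, 2000))
  expect_equal(nrow(none$results), 0)
})

test_that("fragment counts and design tables round-trip through TSV", {
  sim <- simulate_peak_set(2, 2, effect = 0.5, seed = 43)
  cf <- withr::local_tempfile(); tf <- withr::local_tempfile()
  df <- withr::local_tempfile()
  write_fragment_counts(sim$fcm, cf, tf)
  back <- read_fragment_counts(cf, tf)
  expect_equal(back$counts, sim$fcm$counts)
  expect_equal(back$cis_totals, sim$fcm$cis_totals)
  expect_equal(start0(back$fragments), start0(sim$fcm$fragments))
  write_capture_design(list(sim$design), df)
  d2 <- read_capture_design(df)[[1]]
  expect_equal(d2$probe_id, sim$design$probe_id)
  expect_equal(start0(d2$domain), start0(sim$design$domain))
  expect_equal(d2$exclusion_radius, sim$design$exclusion_radius)
})

test_that("family-wise error with Holm stays controlled under the null", {
  sim <- simulate_peak_set(5000, 5000, effect = 1, n_fragments = 8, seed = 47)
  p_raw <- run_capture_diff(sim$design, sim$fcm, sim$peaks)$results$p_raw
  fam <- rep(seq_len(200), each = 50)
  fwer <- mean(vapply(split(p_raw, fam), function(p)
    any(holm_adjust(p) < 0.05), logical(1)))
  expect_lte(fwer, 0.10)
})
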