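suppressPackageStartupMessages(library(GenomicRanges))

# Independent brute-force oracles, deliberately naive.

# distribution of the signed-rank W over all 2^n sign assignments for the
# non-zero magnitudes of d (midranks on |d|)
oracle_signed_rank_dist <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(0)
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  as.vector(signs %*% r)
}

oracle_signed_rank_p <- function(d, dist = NULL) {
  dd <- d[d != 0]
  if (!length(dd)) return(1)
  if (is.null(dist)) dist <- oracle_signed_rank_dist(dd)
  r <- rank(abs(dd))
  W <- sum(r[dd > 0])
  min(1, 2 * min(mean(dist <= W + 1e-9), mean(dist >= W - 1e-9)))
}

# all-assignments enumeration p for the rank-sum test
oracle_rank_sum_p <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  idx <- utils::combn(length(r), n1)
  sums <- colSums(matrix(r[idx], nrow = n1))
  W <- sum(r[seq_len(n1)])
  min(1, 2 * min(mean(sums <= W + 1e-9), mean(sums >= W - 1e-9)))
}

# hypergeometric enumeration two-sided p for a 2x2 table (fixed margins;
# same relative tolerance fisher.test uses when collecting tables no more
# probable than the observed one)
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  N <- a + b + c_ + d
  if (N == 0) return(1)
  r1 <- a + b; c1 <- a + c_
  lo <- max(0, r1 + c1 - N); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, N - c1, r1)
  obs <- stats::dhyper(a, c1, N - c1, r1)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# quadratic all-pairs overlap scan on 0-based half-open intervals
oracle_overlaps_any <- function(a_df, b_df) {
  vapply(seq_len(nrow(a_df)), function(i) {
    any(b_df$chrom == a_df$chrom[i] &
          b_df$start < a_df$end[i] &
          a_df$start[i] < b_df$end)
  }, logical(1))
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000) {
  s <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = s, end = s + sample.int(500, n, replace = TRUE))
}

df_to_granges <- function(df) granges0(df$chrom, df$start, df$end)

# classified bucket fixture: states laid onto a 200 bp grid of one chromosome
bucket_fixture <- function(states, width = 200, chrom = "chr1") {
  n <- length(states)
  b <- granges0(chrom, (seq_len(n) - 1) * width, seq_len(n) * width)
  S4Vectors::mcols(b)$state <- states
  b
}
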