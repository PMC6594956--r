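#' Paired Wilcoxon signed-rank test with exact enumeration p-value
#'
#' Conventions: differences `treated - control`; zero differences dropped
#' (reduced-sample convention); midranks on tied |d|; W = sum of positive
#' ranks. For n (non-zero pairs) up to `exact_limit` the two-sided p-value is
#' exact over all 2^n sign assignments (computed by a convolution over the
#' doubled midranks, which is identical to full enumeration); beyond that, a
#' normal approximation with tie-corrected variance `sum(rank^2)/4` and a 0.5
#' continuity correction is used. All-zero differences give W = 0, p = 1.
#'
#' @param control,treated paired numeric vectors (replicate i of control pairs
#'   with replicate i of treated)
#' @param exact_limit largest n for the exact p-value (default 25)
#' @return list(statistic = W, p.value, n_used = non-zero pairs,
#'   method = "exact" or "normal")
#' @export
paired_signed_rank <- function(control, treated, exact_limit = 25) {
  if (length(control) != length(treated))
    stop("control and treated must have equal length")
  if (!length(control)) stop("empty input")
  d <- treated - control
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = 0, p.value = 1, n_used = 0L, method = "exact"))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    p <- signed_rank_exact_p(r, W)
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = W, p.value = p, n_used = as.integer(n), method = method)
}

# Exact two-sided p for the signed-rank statistic given midranks r.
# Distribution of W over all 2^n equiprobable sign assignments via generating
# function on doubled ranks (integers); p = min(1, 2 * min tail), the tails
# including the observed value. Equals naive enumeration exactly.
signed_rank_exact_p <- function(r, W) {
  w2 <- as.integer(round(2 * r))
  total <- sum(w2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (w in w2) {
    g <- f
    g[(w + 1):(total + 1)] <- g[(w + 1):(total + 1)] + f[1:(total + 1 - w)]
    f <- g / 2
  }
  W2 <- round(2 * W)
  lower <- sum(f[seq_len(W2 + 1)])
  upper <- sum(f[(W2 + 1):(total + 1)])
  min(1, 2 * min(lower, upper))
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact two-sided p by enumeration of all assignments of the pooled values to
#' the smaller group when `choose(n, n_min)` is at most `max_exact_tables`
#' (ties handled exactly through midranks); otherwise a normal approximation
#' with tie-corrected variance and 0.5 continuity correction. Two-sided p is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param x,y numeric vectors (two groups)
#' @param max_exact_tables enumeration budget (default 2e5 assignments)
#' @return list(statistic = rank sum of `x`, p.value, method)
#' @export
rank_sum_test <- function(x, y, max_exact_tables = 2e5) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  m <- min(n1, n2)
  if (choose(n, m) <= max_exact_tables) {
    sums <- utils::combn(r, m, sum)
    obs <- if (n1 <= n2) W else sum(r) - W
    eps <- 1e-9
    lower <- mean(sums <= obs + eps)
    upper <- mean(sums >= obs - eps)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n1 * (n + 1) / 2
    tie <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = W, p.value = p, method = method)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Wraps `stats::p.adjust(method = "holm")` after validating the input range:
#' sorted ascending, `adj_(i) = max_{j<=i} min(1, (m-j+1) p_(j))`, mapped back
#' to input order.
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @return adjusted p-values in the input order
#' @export
holm_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Fisher's exact test on a 2x2 table with the sample odds ratio
#'
#' p-value from `stats::fisher.test` (sum of hypergeometric probabilities of
#' tables, at fixed margins, no more probable than the observed one). The
#' odds ratio reported is the sample OR `(a d)/(b c)`; degenerate tables give
#' `Inf` (bc = 0 < ad) or `0` (ad = 0 < bc), flagged via `or_degenerate`.
#'
#' @param tab 2x2 matrix of non-negative integer counts
#' @return list(odds_ratio, p.value, or_degenerate)
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("fisher_exact expects a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("cells must be non-negative integers")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  degenerate <- (a * d == 0) || (b * c_ == 0)
  or <- if (a * d == 0 && b * c_ == 0) NA_real_
        else if (b * c_ == 0) Inf
        else (a * d) / (b * c_)
  p <- if (sum(tab) == 0) 1 else stats::fisher.test(tab)$p.value
  list(odds_ratio = or, p.value = p, or_degenerate = degenerate)
}
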