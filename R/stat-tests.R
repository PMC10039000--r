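#' @title Test-result container
#' @description Internal constructor for the lightweight result object shared
#'   by the rank-sum and exact count tests.
#' @param method Test method label.
#' @param statistic Test statistic.
#' @param p_value Two-sided P-value.
#' @param n1,n2 Group sizes (or margins).
#' @param alpha Significance level carried along for reporting (default 0.05).
#' @return List of class `p53cc_test`.
#' @keywords internal
new_test_result <- function(method, statistic, p_value, n1, n2, alpha = 0.05) {
  stopifnot(is.finite(p_value), p_value >= 0)
  structure(list(method = method, statistic = statistic,
                 p_value = min(1, p_value), n1 = n1, n2 = n2, alpha = alpha),
            class = "p53cc_test")
}

#' @export
print.p53cc_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, P = %.4g (n1 = %d, n2 = %d)\n",
              x$method, x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

# exact null distribution of the (mid-)rank sum of an m-subset of scaled
# integer ranks, by the shift/convolution algorithm; returns probabilities
# over sums 0..sum(scaled)
.ranksum_distribution <- function(scaled, m) {
  S <- sum(scaled)
  f <- matrix(0, nrow = m + 1, ncol = S + 1)
  f[1, 1] <- 1
  for (v in scaled) {
    kmax <- m
    for (k in kmax:1) {
      f[k + 1, (v + 1):(S + 1)] <- f[k + 1, (v + 1):(S + 1)] + f[k, 1:(S + 1 - v)]
    }
  }
  f[m + 1, ] / choose(length(scaled), m)
}

#' Wilcoxon rank-sum test (exact or normal approximation)
#'
#' Two-sided two-sample rank-sum test using mid-ranks for ties. The exact
#' mode enumerates the full permutation null distribution of the rank sum of
#' the smaller group with a shift (dynamic-programming) algorithm, which
#' remains exact in the presence of ties, and reports
#' `p = min(1, 2 * min(P(W <= w), P(W >= w)))`. The normal mode uses
#' `z = (W - m(N+1)/2) / sqrt(m n (N+1) / 12)` with no continuity correction
#' and no tie correction, `p = 2 * (1 - Phi(|z|))`.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param mode `"exact"` or `"normal"`.
#' @param alpha Significance level carried in the result (default 0.05).
#' @return A `p53cc_test`; `statistic` is the rank sum of `x`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("exact", "normal"), alpha = 0.05) {
  mode <- match.arg(mode)
  if (length(x) < 1 || length(y) < 1) stop("both groups must be non-empty")
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))          # mid-ranks for ties
  Wx <- sum(r[seq_len(n1)])

  if (mode == "normal") {
    z <- (Wx - n1 * (N + 1) / 2) / sqrt(n1 * n2 * (N + 1) / 12)
    p <- 2 * pnorm(-abs(z))
    return(new_test_result("wilcoxon_normal", Wx, p, n1, n2, alpha))
  }

  # work with the smaller group's rank sum; doubled ranks are integers
  scaled <- as.integer(round(2 * r))
  if (n1 <= n2) {
    m <- n1; w <- as.integer(round(2 * Wx))
  } else {
    m <- n2; w <- as.integer(round(2 * sum(r[(n1 + 1):N])))
  }
  pm <- .ranksum_distribution(scaled, m)
  lo <- sum(pm[seq_len(w + 1)])          # P(W <= w)
  hi <- sum(pm[(w + 1):length(pm)])      # P(W >= w)
  p <- min(1, 2 * min(lo, hi))
  new_test_result("wilcoxon_exact", Wx, p, n1, n2, alpha)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided P-value by probability ordering: the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed the observed one (up to a `1 + 1e-7` relative tolerance,
#' the convention of `stats::fisher.test`, which performs the enumeration).
#' A table with a zero margin carries no information; it returns P = 1 with
#' a warning.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param alpha Significance level carried in the result.
#' @return A `p53cc_test`; `statistic` is the conditional odds-ratio
#'   estimate.
#' @export
fisher_2x2 <- function(tab, alpha = 0.05) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0),
            all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin: Fisher test is degenerate, P = 1")
    return(new_test_result("fisher_2x2", NA_real_, 1,
                           sum(tab[1, ]), sum(tab[2, ]), alpha))
  }
  ft <- stats::fisher.test(tab)
  new_test_result("fisher_2x2", unname(ft$estimate), ft$p.value,
                  sum(tab[1, ]), sum(tab[2, ]), alpha)
}

#' Fisher-Freeman-Halton exact test on an r x c table
#'
#' Generalizes the probability-ordering two-sided Fisher test to r x c
#' tables: the P-value sums the multivariate hypergeometric probabilities of
#' every margin-matched table no more probable than the observed one
#' (`stats::fisher.test` performs the margin-constrained enumeration). A
#' coarse bound on the number of margin-matched tables guards against
#' infeasible enumerations.
#'
#' @param tab r x c matrix of non-negative integer counts.
#' @param alpha Significance level carried in the result.
#' @param max_tables Enumeration guard (default 1e7 candidate tables).
#' @return A `p53cc_test` (statistic is `NA`; the test is defined by its
#'   P-value).
#' @export
fisher_rxc <- function(tab, alpha = 0.05, max_tables = 1e7) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), all(tab == round(tab)))
  r <- nrow(tab); cc <- ncol(tab)
  if (r == 1 || cc == 1) {
    return(new_test_result("fisher_rxc", NA_real_, 1,
                           sum(tab), sum(tab), alpha))
  }
  if (all(dim(tab) == c(2, 2))) {
    res <- fisher_2x2(tab, alpha)
    res$method <- "fisher_rxc"
    return(res)
  }
  # upper bound: each of the first r-1 rows distributes its total over c
  # cells in at most choose(total + c - 1, c - 1) ways
  bound <- prod(choose(rowSums(tab)[-r] + cc - 1, cc - 1))
  if (!is.finite(bound) || bound > max_tables) {
    stop("margin-constrained enumeration too large (bound ",
         format(bound, digits = 3),
         " tables); consider a Monte-Carlo approximation")
  }
  ft <- stats::fisher.test(tab, workspace = 2e7)
  new_test_result("fisher_rxc", NA_real_, ft$p.value,
                  sum(tab[1, ]), sum(tab), alpha)
}
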