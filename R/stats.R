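# Nonparametric group comparisons and the effect sizes used when reporting
# pipeline outputs across neurons, regions or transmitter systems.

#' Mann-Whitney comparison with rank-biserial effect size
#'
#' Two-sided Mann-Whitney rank-sum test (exact where
#' \code{stats::wilcox.test} permits, normal approximation otherwise) with
#' the rank-biserial correlation \code{r = 1 - 2U/(n1*n2)}, where U is the
#' statistic for group \code{a} (the number of (a, b) pairs with a > b).
#' Sign convention: r is +1 when every value of \code{a} lies below every
#' value of \code{b} and -1 in the reverse ordering. A bootstrap percentile
#' CI on r is attached.
#'
#' @param a,b numeric samples (each of length >= 2).
#' @param nBoot bootstrap replicates for the CI.
#' @param seed RNG seed for the bootstrap.
#' @return list (group comparison): \code{test}, \code{statistic} (U),
#'   \code{p}, \code{effect} (r), \code{ci}, \code{n}.
#' @export
mannWhitneyEffect <- function(a, b, nBoot = 2000L, seed = 1L) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  n1 <- length(a); n2 <- length(b)
  rbr <- function(x, y) {
    u <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    1 - 2 * u / (length(x) * length(y))
  }
  if (length(unique(c(a, b))) == 1L) {
    return(list(test = "Mann-Whitney", statistic = n1 * n2 / 2, p = 1,
                effect = 0, ci = c(0, 0), n = c(n1, n2)))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL,
                                            correct = TRUE))
  r <- rbr(a, b)
  set.seed(seed)
  bs <- replicate(nBoot, rbr(sample(a, n1, TRUE), sample(b, n2, TRUE)))
  list(test = "Mann-Whitney", statistic = unname(wt$statistic),
       p = wt$p.value, effect = r,
       ci = unname(stats::quantile(bs, c(0.025, 0.975))), n = c(n1, n2))
}

#' Kruskal-Wallis comparison with epsilon-squared effect sizes
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p value (k - 1 df), and
#' two effect-size variants: the form \code{(H - k + 1) / (n - k)}
#' (\code{effect}, labeled publication-compatible because it reproduces published
#' epsilon-squared values computed this way) and the textbook
#' \code{epsilon^2 = H / ((n^2 - 1)/(n + 1)) = H / (n - 1)}
#' (\code{effectClassic}).
#'
#' @param groups list of numeric vectors (>= 3 groups, each >= 2 values).
#' @param nBoot bootstrap replicates for the CI on \code{effect}; 0
#'   disables.
#' @param seed RNG seed for the bootstrap.
#' @return list (group comparison): \code{test}, \code{statistic} (H),
#'   \code{df}, \code{p}, \code{effect}, \code{effectClassic}, \code{ci},
#'   \code{n}.
#' @export
kruskalEffect <- function(groups, nBoot = 2000L, seed = 1L) {
  if (length(groups) < 3L) stop("need at least 3 groups")
  stopifnot(all(vapply(groups, length, integer(1)) >= 2L))
  k <- length(groups)
  n <- sum(lengths(groups))
  vals <- unlist(groups)
  labs <- factor(rep(seq_len(k), lengths(groups)))
  kt <- stats::kruskal.test(vals, labs)
  H <- unname(kt$statistic)
  eff <- (H - k + 1) / (n - k)
  effClassic <- H / (n - 1)
  ci <- c(NA_real_, NA_real_)
  if (nBoot > 0) {
    set.seed(seed)
    bs <- replicate(nBoot, {
      g2 <- lapply(groups, function(g) sample(g, length(g), TRUE))
      v2 <- unlist(g2)
      H2 <- unname(stats::kruskal.test(v2, labs)$statistic)
      (H2 - k + 1) / (n - k)
    })
    ci <- unname(stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE))
  }
  list(test = "Kruskal-Wallis", statistic = H, df = unname(kt$parameter),
       p = kt$p.value, effect = eff, effectClassic = effClassic, ci = ci,
       n = lengths(groups))
}

#' Recompute the publication-compatible epsilon-squared from printed summaries
#'
#' Inverts a reported Kruskal-Wallis p value (chi-square, k - 1 df) to H
#' and applies \code{(H - k + 1) / (n - k)}; lets an epsilon-squared be
#' reproduced exactly from a figure legend's n, k and p alone.
#'
#' @param n total sample size.
#' @param k number of groups.
#' @param p reported p value.
#' @return epsilon-squared (numeric).
#' @examples
#' epsilonSquaredFromP(n = 83, k = 4, p = 0.27)  # about 0.0117
#' @export
epsilonSquaredFromP <- function(n, k, p) {
  stopifnot(n > k, k >= 2, p > 0, p < 1)
  H <- stats::qchisq(1 - p, df = k - 1)
  (H - k + 1) / (n - k)
}
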