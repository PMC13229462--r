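# Brute-force oracles, written along different routes than the
# implementations they cross-check.

auc_pair_count <- function(scores, labels) {
  x <- scores[labels]; y <- scores[!labels]
  total <- 0
  for (xi in x) for (yj in y)
    total <- total + (xi > yj) + 0.5 * (xi == yj)
  total / (length(x) * length(y))
}

ece_by_hand <- function(conf, correct, n_bins = 10) {
  n <- length(conf)
  total <- 0
  for (b in seq_len(n_bins)) {
    lo <- (b - 1) / n_bins; hi <- b / n_bins
    in_b <- if (b == n_bins) conf >= lo & conf <= hi else conf >= lo & conf < hi
    if (any(in_b))
      total <- total + sum(in_b) / n * abs(mean(conf[in_b]) - mean(correct[in_b]))
  }
  total
}

cochran_q_by_hand <- function(x) {
  # column-deviation form of the statistic rather than the totals form
  m <- ncol(x); Tj <- colSums(x); Ti <- rowSums(x); T_ <- sum(x)
  num <- m * (m - 1) * sum((Tj - T_ / m)^2)
  den <- m * T_ - sum(Ti^2)
  num / den
}

fleiss_by_hand <- function(tab) {
  # pairwise-agreement counting instead of the squared-count identity
  n <- sum(tab[1, ]); N <- nrow(tab)
  pairs_agree <- vapply(seq_len(N), function(i)
    sum(choose(tab[i, ], 2)) / choose(n, 2), numeric(1))
  Pbar <- mean(pairs_agree)
  pj <- colSums(tab) / (N * n)
  Pe <- sum(pj^2)
  (Pbar - Pe) / (1 - Pe)
}

fisher_two_sided <- function(tab) {
  # hypergeometric enumeration, minimum-likelihood summation
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  dens <- stats::dhyper(support, r1, n - r1, c1)
  obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(dens[dens <= obs * (1 + 1e-7)])
}
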