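# Independent brute-force oracles used to verify the package's statistics.
# These deliberately avoid stats::phyper / stats::pbinom / stats::p.adjust
# and the package's own code paths.

## P(X >= k), X ~ Binomial(n, p), by direct summation of the mass function
## written out with choose().
binomTailOracle <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j),
             numeric(1)))
}

## P(X >= k) for the hypergeometric by exhaustive enumeration of all
## C(N, n) draws from a population of N items whose first K are successes.
hyperEnumOracle <- function(N, K, n, k) {
  if (k <= 0) return(1)
  if (n == 0) return(if (k > 0) 0 else 1)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

## Hypergeometric upper tail by direct summation of choose() products
## (a second independent route, usable when enumeration is too big).
hyperSumOracle <- function(N, K, n, k) {
  if (k <= 0) return(1)
  js <- k:min(K, n)
  js <- js[js >= max(0, n - (N - K))]
  if (length(js) == 0) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

## Benjamini-Hochberg step-up by its textbook definition.
bhOracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) {
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

## KLD in bits by an explicit double loop over positions and residues.
kldOracle <- function(pmat, qmat) {
  total <- 0
  for (j in seq_len(ncol(pmat))) {
    for (a in seq_len(nrow(pmat))) {
      if (pmat[a, j] > 0) {
        total <- total + pmat[a, j] * log2(pmat[a, j] / qmat[a, j])
      }
    }
  }
  total
}
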