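# Independent brute-force oracles. These deliberately avoid the package's
# computational shortcuts: pi by explicit pair enumeration, Fisher's exact p
# by explicit hypergeometric summation.

oracle_pi <- function(mat) {
  n <- nrow(mat)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(mat[i, ] != mat[j, ])
  tot / choose(n, 2)
}

oracle_theta_w <- function(S, n) {
  a1 <- 0
  for (i in seq_len(n - 1)) a1 <- a1 + 1 / i
  S / a1
}

oracle_tajd <- function(mat) {
  n <- nrow(mat)
  cs <- colSums(mat)
  S <- sum(cs > 0 & cs < n)
  if (S == 0) return(NaN)
  pi <- oracle_pi(mat)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# one-sided (enrichment in cell [1,1]) Fisher p for table rows (low, high) x
# cols (category, reference), by direct hypergeometric mass summation
oracle_fisher_greater <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  xs <- max(0, k - n2):min(m, k)
  pr <- exp(lchoose(m, xs) + lchoose(n2, k - xs) - lchoose(m + n2, k))
  sum(pr[xs >= a])
}

random_hap_matrix <- function(n, S) {
  matrix(rbinom(n * S, 1, runif(1, 0.1, 0.9)), n, S)
}

binom_ci <- function(x, n, conf = 0.99) {
  as.numeric(stats::binom.test(x, n, conf.level = conf)$conf.int)
}
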