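# Independent brute-force oracles for the robust estimators. These follow
# the definitions directly with plain R enumeration (sort-based order
# statistics), independent of the package's C++ kernels.

oracle_sn_factor <- function(n) {
  if (n <= 9) c(NA, 0.743, 1.851, 0.954, 1.351, 0.993, 1.198, 1.005, 1.131)[n]
  else if (n %% 2 == 1) n / (n - 0.9)
  else 1
}

oracle_sn <- function(x) {
  n <- length(x)
  himeds <- vapply(seq_len(n), function(i) {
    d <- sort(abs(x[i] - x[-i]))
    d[(n - 1) %/% 2 + 1]          # high median of n - 1 values
  }, numeric(1))
  lomed <- sort(himeds)[(n + 1) %/% 2]  # low median of n values
  1.1926 * oracle_sn_factor(n) * lomed
}

oracle_mad <- function(x) 1.4826 * median(abs(x - median(x)))

oracle_sn_correlation <- function(x, y) {
  u <- (x - median(x)) / (sqrt(2) * oracle_mad(x)) +
    (y - median(y)) / (sqrt(2) * oracle_mad(y))
  v <- (x - median(x)) / (sqrt(2) * oracle_mad(x)) -
    (y - median(y)) / (sqrt(2) * oracle_mad(y))
  (oracle_sn(u)^2 - oracle_sn(v)^2) / (oracle_sn(u)^2 + oracle_sn(v)^2)
}

oracle_theil_sen <- function(x, y) {
  slopes <- c()
  for (i in seq_along(x)) {
    for (j in seq_along(x)) {
      if (j > i && x[j] != x[i]) {
        slopes <- c(slopes, (y[j] - y[i]) / (x[j] - x[i]))
      }
    }
  }
  slope <- median(slopes)
  list(slope = slope, intercept = median(y - slope * x))
}

oracle_hodges_lehmann <- function(x) {
  w <- c()
  for (i in seq_along(x)) {
    for (j in i:length(x)) w <- c(w, (x[i] + x[j]) / 2)
  }
  median(w)
}

oracle_ned <- function(x, y, s) {
  total <- 0
  for (i in seq_along(x)) total <- total + (x[i] - y[i])^2 / s[i]^2
  sqrt(total)
}

# Step-up BH by hand: adj p_(i) = min over k >= i of p_(k) * n / k.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
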