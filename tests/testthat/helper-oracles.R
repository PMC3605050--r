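# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Upper-tail probability of the chi-square distribution with 6 d.f. via the
# closed-form series for even degrees of freedom:
# P(X > x) = exp(-x/2) * (1 + x/2 + (x/2)^2 / 2)
chisq6_upper_tail <- function(x) {
  h <- x / 2
  exp(-h) * (1 + h + h^2 / 2)
}

# Weir & Cockerham (1984) theta for two groups of diploids, computed
# spreadsheet-style: every intermediate written out, no shared helpers.
# n = c(n1, n2) diploid counts, p = allele frequencies, h = observed
# heterozygote proportions.
wc_theta_oracle <- function(n, p, h) {
  r <- 2
  n1 <- n[1]; n2 <- n[2]
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p[1] + n2 * p[2]) / (n1 + n2)
  s2 <- (n1 * (p[1] - pbar)^2 + n2 * (p[2] - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h[1] + n2 * h[2]) / (n1 + n2)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# Brute-force binomial log-likelihood: term-by-term summation using the
# factorial form of the binomial coefficient, independent of dbinom.
brute_force_loglik <- function(data, freqs, eps = 1e-9) {
  total <- 0
  for (i in seq_len(nrow(data))) {
    n <- data$n[i]; k <- data$k[i]
    p <- min(max(freqs[i], eps), 1 - eps)
    lchoose_nk <- lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)
    total <- total + lchoose_nk + k * log(p) + (n - k) * log(1 - p)
  }
  total
}

# Exhaustive grid search over (center, width) for the two-parameter sigmoid
# model with p fixed at 0 and 1. Vectorized over the grid; independent of
# the package's optimizer and of scaled_cline().
grid_search_sigmoid <- function(data, center_grid, width_grid) {
  grid <- expand.grid(center = center_grid, width = width_grid)
  ll <- rep(0, nrow(grid))
  for (i in seq_len(nrow(data))) {
    p <- 1 / (1 + exp(-4 * (data$distance[i] - grid$center) / grid$width))
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    ll <- ll + dbinom(data$k[i], data$n[i], p, log = TRUE)
  }
  best <- which.max(ll)
  list(logLik = ll[best], center = grid$center[best], width = grid$width[best])
}

# A small deterministic toy dataset (steep ascending cline, 6 populations).
toy_cline_data <- function() {
  tibble::tibble(
    population = paste0("P", 1:6),
    distance = c(0, 4, 8, 12, 16, 20),
    n = c(40L, 40L, 40L, 40L, 40L, 40L),
    k = c(1L, 4L, 15L, 28L, 37L, 39L))
}
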