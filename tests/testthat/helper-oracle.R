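## independent brute-force oracles used by the tests

## Predictive joint over (p(1|1), p(2|2)) after observing `stim`, for the
## coupled change-point filter: direct summation over all 2^(T-1)
## change-point configurations. Each configuration partitions observations
## 2..T into constant-theta segments; non-final segments are marginalized
## over the flat grid prior, the final segment carries theta. The result is
## mixed once more with the prior (the one-step-ahead convention).
oracle_coupled_joint <- function(stim, pc, G) {
  g <- (seq_len(G) - 0.5) / G
  T <- length(stim)
  lik <- function(t, th11, th22) {
    if (stim[t - 1] == 1) {
      if (stim[t] == 1) th11 else 1 - th11
    } else {
      if (stim[t] == 2) th22 else 1 - th22
    }
  }
  W <- matrix(0, G, G)
  configs <- as.matrix(expand.grid(rep(list(0:1), T - 1)))
  for (k in seq_len(nrow(configs))) {
    cvec <- configs[k, ]
    pr_c <- prod(ifelse(cvec == 1, pc, 1 - pc))
    seg_start <- sort(unique(c(2, which(cvec == 1) + 1)))
    seg_end <- c(seg_start[-1] - 1, T)
    contrib <- matrix(1, G, G)
    for (s in seq_along(seg_start)) {
      Lseg <- matrix(1, G, G)
      for (t in seg_start[s]:seg_end[s]) {
        Lt <- outer(g, g, function(a, b) {
          mapply(function(x, y) lik(t, x, y), a, b)
        })
        Lseg <- Lseg * Lt
      }
      if (s < length(seg_start)) {
        contrib <- contrib * mean(Lseg)
      } else {
        contrib <- contrib * Lseg / (G * G)
      }
    }
    W <- W + pr_c * contrib
  }
  W <- W / sum(W)
  (1 - pc) * W + pc / (G * G)
}

## marginal moments of an oracle joint (rows: p(1|1), cols: p(2|2))
oracle_moments <- function(W) {
  G <- nrow(W)
  g <- (seq_len(G) - 0.5) / G
  r <- rowSums(W)
  cl <- colSums(W)
  list(mean11 = sum(r * g), var11 = sum(r * g^2) - sum(r * g)^2,
       mean22 = sum(cl * g), var22 = sum(cl * g^2) - sum(cl * g)^2)
}

## closed-form Beta moments
beta_mean <- function(a, b) a / (a + b)
beta_var <- function(a, b) a * b / ((a + b)^2 * (a + b + 1))

## mean of the geometric distribution truncated (by resampling) at kmax
truncated_geom_moments <- function(mean_period, kmax) {
  q <- 1 / mean_period
  k <- seq_len(kmax)
  pmf <- q * (1 - q)^(k - 1)
  pmf <- pmf / sum(pmf)
  mu <- sum(k * pmf)
  list(mean = mu, var = sum(k^2 * pmf) - mu^2)
}
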