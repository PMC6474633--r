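## Flat (leaky-count Beta) observer engine.
##
## Counts follow the recursion n_t = e_t + exp(-1/omega) * n_{t-1}, so the
## k-th past observation carries weight exp(-k/omega); stats::filter computes
## the whole block in one pass. Estimates and confidence are the mean and
## log-precision of the Beta posterior implied by counts + pseudo-counts.

run_flat_block <- function(observer, stim) {
  if (observer$statistic == "frequency") {
    run_flat_block_freq(observer, stim)
  } else {
    run_flat_block_trans(observer, stim)
  }
}

leaky_count <- function(events, decay) {
  as.numeric(stats::filter(events, decay, method = "recursive"))
}

run_flat_block_trans <- function(observer, stim) {
  T <- length(stim)
  d <- if (is.infinite(observer$omega)) 1 else exp(-1 / observer$omega)
  pr <- observer$prior_counts  # n11, n21, n22, n12
  prev <- c(NA_integer_, stim[-T])
  e11 <- as.numeric(prev == 1L & stim == 1L); e11[1] <- 0
  e21 <- as.numeric(prev == 1L & stim == 2L); e21[1] <- 0
  e22 <- as.numeric(prev == 2L & stim == 2L); e22[1] <- 0
  e12 <- as.numeric(prev == 2L & stim == 1L); e12[1] <- 0
  a11 <- leaky_count(e11, d) + pr[1]
  b11 <- leaky_count(e21, d) + pr[2]
  a22 <- leaky_count(e22, d) + pr[3]
  b22 <- leaky_count(e12, d) + pr[4]
  s11 <- beta_summary(a11, b11)
  s22 <- beta_summary(a22, b22)
  p1 <- ifelse(stim == 1L, s11$mean, 1 - s22$mean)
  conf <- ifelse(stim == 1L, s11$log_precision, s22$log_precision)
  data.frame(stim = stim, p1 = p1, conf = conf,
             mean11 = s11$mean, var11 = s11$var, conf11 = s11$log_precision,
             mean22 = s22$mean, var22 = s22$var, conf22 = s22$log_precision)
}

run_flat_block_freq <- function(observer, stim) {
  d <- if (is.infinite(observer$omega)) 1 else exp(-1 / observer$omega)
  pr <- observer$prior_counts
  a <- leaky_count(as.numeric(stim == 1L), d) + pr[1]
  b <- leaky_count(as.numeric(stim == 2L), d) + pr[2]
  s <- beta_summary(a, b)
  data.frame(stim = stim, p1 = s$mean, conf = s$log_precision,
             mean1 = s$mean, var1 = s$var)
}
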