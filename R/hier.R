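## Hierarchical observer engine: forward filtering of the change-point HMM
## over a discretized probability grid.
##
## Per observation, the filtered joint weight over the statistic theta is
## multiplied by the Bernoulli likelihood of the new observation, normalized,
## and then passed through the change-point mixture
##   q(theta) = (1 - pc) * posterior(theta) + pc * prior(theta),
## which is the one-step-ahead posterior p(theta_{t+1} | y_{1:t}). All trace
## quantities (predictive probability, posterior moments, confidence) are
## moments of q on the grid. The first observation of a block carries a
## constant likelihood of 1/2 (no conditioning context), leaving the prior
## untouched. Coupled transition filtering uses a 2-D joint over
## (p(1|1), p(2|2)); uncoupled and frequency variants use 1-D filters.

run_hier_block <- function(observer, stim) {
  switch(paste(observer$statistic,
               if (observer$statistic == "transitions") observer$coupling else ""),
         "transitions coupled" = run_hier_coupled(observer, stim),
         "transitions uncoupled" = run_hier_uncoupled(observer, stim),
         "frequency " = run_hier_freq(observer, stim))
}

grid_moments <- function(w, g) {
  m <- sum(w * g)
  v <- sum(w * g * g) - m * m
  c(mean = m, var = max(v, 0))
}

run_hier_coupled <- function(observer, stim) {
  G <- observer$grid_n
  g <- prob_grid(G)
  pc <- observer$pc
  T <- length(stim)
  ## likelihood lookup: rows index p(1|1), columns p(2|2)
  L <- list(`11` = matrix(g, G, G), `12` = matrix(1 - g, G, G),
            `22` = matrix(g, G, G, byrow = TRUE),
            `21` = matrix(1 - g, G, G, byrow = TRUE))
  W <- matrix(1 / (G * G), G, G)
  mean11 <- var11 <- mean22 <- var22 <- numeric(T)
  for (t in seq_len(T)) {
    if (t > 1L) {
      W <- W * L[[paste0(stim[t - 1L], stim[t])]]
      s <- sum(W)
      if (s <= 0) stop_cfg("numerical underflow in forward filtering")
      W <- W / s
    }
    if (pc > 0) W <- (1 - pc) * W + pc / (G * G)
    m1 <- grid_moments(rowSums(W), g)
    m2 <- grid_moments(colSums(W), g)
    mean11[t] <- m1[1]; var11[t] <- m1[2]
    mean22[t] <- m2[1]; var22[t] <- m2[2]
  }
  finish_hier_trace(stim, mean11, var11, mean22, var22)
}

run_hier_uncoupled <- function(observer, stim) {
  G <- observer$grid_n
  g <- prob_grid(G)
  pc <- observer$pc
  T <- length(stim)
  w1 <- rep(1 / G, G)  # over p(1|1)
  w2 <- rep(1 / G, G)  # over p(2|2)
  mean11 <- var11 <- mean22 <- var22 <- numeric(T)
  for (t in seq_len(T)) {
    if (t > 1L) {
      if (stim[t - 1L] == 1L) {
        w1 <- w1 * (if (stim[t] == 1L) g else 1 - g)
        s <- sum(w1)
        if (s <= 0) stop_cfg("numerical underflow in forward filtering")
        w1 <- w1 / s
      } else {
        w2 <- w2 * (if (stim[t] == 2L) g else 1 - g)
        s <- sum(w2)
        if (s <= 0) stop_cfg("numerical underflow in forward filtering")
        w2 <- w2 / s
      }
    }
    if (pc > 0) {
      w1 <- (1 - pc) * w1 + pc / G
      w2 <- (1 - pc) * w2 + pc / G
    }
    m1 <- grid_moments(w1, g)
    m2 <- grid_moments(w2, g)
    mean11[t] <- m1[1]; var11[t] <- m1[2]
    mean22[t] <- m2[1]; var22[t] <- m2[2]
  }
  finish_hier_trace(stim, mean11, var11, mean22, var22)
}

finish_hier_trace <- function(stim, mean11, var11, mean22, var22) {
  p1 <- ifelse(stim == 1L, mean11, 1 - mean22)
  conf <- ifelse(stim == 1L, -log(var11), -log(var22))
  data.frame(stim = stim, p1 = p1, conf = conf,
             mean11 = mean11, var11 = var11, conf11 = -log(var11),
             mean22 = mean22, var22 = var22, conf22 = -log(var22))
}

run_hier_freq <- function(observer, stim) {
  G <- observer$grid_n
  g <- prob_grid(G)
  pc <- observer$pc
  T <- length(stim)
  w <- rep(1 / G, G)
  mean1 <- var1 <- numeric(T)
  for (t in seq_len(T)) {
    w <- w * (if (stim[t] == 1L) g else 1 - g)
    s <- sum(w)
    if (s <= 0) stop_cfg("numerical underflow in forward filtering")
    w <- w / s
    if (pc > 0) w <- (1 - pc) * w + pc / G
    m <- grid_moments(w, g)
    mean1[t] <- m[1]; var1[t] <- m[2]
  }
  data.frame(stim = stim, p1 = mean1, conf = -log(var1),
             mean1 = mean1, var1 = var1)
}
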