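#' @keywords internal
"_PACKAGE"

## odds ratio p/(1-p)
odds <- function(p) p / (1 - p)

## fold change in odds ratio between two probabilities (symmetric, >= 1)
odds_fold <- function(p, q) {
  op <- odds(p); oq <- odds(q)
  pmax(op / oq, oq / op)
}

clip01 <- function(x) pmin(1, pmax(0, x))

## Beta moments from pseudo-count pair (a successes, b failures).
## a + b == 0 gives the degenerate flat start: mean 1/2, variance undefined.
beta_summary <- function(a, b) {
  s <- a + b
  mean <- ifelse(s > 0, a / s, 0.5)
  var <- ifelse(a > 0 & b > 0, a * b / (s^2 * (s + 1)), NA_real_)
  list(a = a, b = b, mean = mean, var = var, log_precision = -log(var))
}

## midpoints of a uniform partition of (0,1)
prob_grid <- function(n) (seq_len(n) - 0.5) / n

stop_cfg <- function(...) stop(..., call. = FALSE)
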