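#' Ideal observer constructors
#'
#' Both observers estimate, trial by trial, either the two repetition
#' (transition) probabilities \eqn{p(1|1)} and \eqn{p(2|2)} of a binary
#' sequence, or the frequency of stimulus 1 (\code{statistic =
#' "frequency"}), and report a predictive probability for the next stimulus
#' together with a confidence defined as the log-precision (negative log
#' variance) of the posterior over the relevant statistic.
#'
#' \code{hier_observer()} is the hierarchical Bayes-optimal observer: it
#' assumes the tracked statistic can change at any observation with fixed
#' probability \code{pc} and filters the resulting change-point hidden
#' Markov model forward over a discretized probability grid (midpoints of a
#' uniform partition of (0,1), \code{grid_n} points per dimension, flat
#' prior). \code{coupling = "coupled"} means both transition probabilities
#' share change points (the joint posterior is two-dimensional);
#' \code{"uncoupled"} runs two independent one-dimensional filters. All
#' reported quantities come from the one-step-ahead posterior
#' \eqn{p(\theta_{t+1} | y_{1:t})}, i.e. after the change-point mixture has
#' been applied, which is the distribution the predictive probability of the
#' next stimulus integrates over.
#'
#' \code{flat_observer()} is the non-hierarchical observer: it keeps leaky
#' event counts in which the k-th past observation has weight
#' \eqn{e^{-k/\omega}}, adds Beta pseudo-counts \code{prior_counts}, and
#' reads its estimate and confidence off the implied Beta posterior. With
#' \code{omega = Inf} counts are not leaky and the observer performs exact
#' conjugate updating. With prior counts \code{c(0, 0)} the posterior mean is
#' asymptotically a delta rule with learning rate \eqn{1 - e^{-1/\omega}};
#' before both counts of the relevant transition are populated the estimate
#' is reported as 0.5 and the confidence as \code{NA} (undefined).
#'
#' @param pc Per-trial change-point probability.
#' @param grid_n Grid points per dimension (at least 5).
#' @param coupling \code{"coupled"} or \code{"uncoupled"} change points
#'   (transitions statistic only).
#' @param statistic \code{"transitions"} or \code{"frequency"}.
#' @param omega Leak time constant, in trials; \code{Inf} for perfect
#'   integration.
#' @param prior_counts Beta pseudo-counts: length 2 \code{c(a, b)} applied to
#'   both transitions, or length 4 in the order \code{n11, n21, n22, n12}.
#' @return An object of class \code{c("hier_observer", "observer")} or
#'   \code{c("flat_observer", "observer")}.
#' @name observers
NULL

#' @rdname observers
#' @export
hier_observer <- function(pc = 1 / 75, grid_n = 50L,
                          coupling = c("coupled", "uncoupled"),
                          statistic = c("transitions", "frequency")) {
  coupling <- match.arg(coupling)
  statistic <- match.arg(statistic)
  if (pc < 0 || pc > 1) stop_cfg("pc must be in [0, 1]")
  if (grid_n < 5) stop_cfg("grid_n must be >= 5")
  structure(list(pc = pc, grid_n = as.integer(grid_n), coupling = coupling,
                 statistic = statistic),
            class = c("hier_observer", "observer"))
}

#' @rdname observers
#' @export
flat_observer <- function(omega = 20, prior_counts = c(1, 1),
                          statistic = c("transitions", "frequency")) {
  statistic <- match.arg(statistic)
  if (!(omega > 0)) stop_cfg("omega must be positive (possibly Inf)")
  if (length(prior_counts) == 2L) prior_counts <- rep(prior_counts, 2L)
  if (length(prior_counts) != 4L || any(prior_counts < 0))
    stop_cfg("prior_counts must be 2 or 4 nonnegative pseudo-counts")
  structure(list(omega = omega, prior_counts = prior_counts,
                 statistic = statistic),
            class = c("flat_observer", "observer"))
}

#' @export
print.observer <- function(x, ...) {
  if (inherits(x, "hier_observer")) {
    cat(sprintf("Hierarchical observer: pc = %g, grid_n = %d, %s, %s\n",
                x$pc, x$grid_n, x$coupling, x$statistic))
  } else {
    cat(sprintf("Flat observer: omega = %g, prior counts [%s], %s\n",
                x$omega, paste(x$prior_counts, collapse = " "), x$statistic))
  }
  invisible(x)
}

#' Run an observer over a stimulus sequence
#'
#' Produces the per-trial trace of the observer: the predictive probability
#' that the next stimulus is a 1 (\code{p1}), the confidence (log-precision
#' of the posterior over the transition probability conditioned on the
#' current stimulus, or over the frequency), and the posterior mean, variance
#' and log-precision of each tracked statistic. The observer is reset to its
#' prior at every block boundary.
#'
#' @param observer An observer from \code{\link{hier_observer}} or
#'   \code{\link{flat_observer}}.
#' @param seq A \code{"stim_seq"} data frame, or any data frame with columns
#'   \code{stim} (1/2) and optionally \code{block}.
#' @return An \code{"observer_trace"} data frame with columns \code{trial},
#'   \code{block}, \code{stim}, \code{p1}, \code{conf} and, for the
#'   transitions statistic, \code{mean11}, \code{var11}, \code{conf11},
#'   \code{mean22}, \code{var22}, \code{conf22}; for the frequency statistic,
#'   \code{mean1}, \code{var1}.
#' @export
run_observer <- function(observer, seq) {
  UseMethod("run_observer")
}

#' @export
run_observer.hier_observer <- function(observer, seq) {
  run_by_block(observer, seq, run_hier_block)
}

#' @export
run_observer.flat_observer <- function(observer, seq) {
  run_by_block(observer, seq, run_flat_block)
}

run_by_block <- function(observer, seq, engine) {
  stim <- seq$stim
  block <- if ("block" %in% names(seq)) seq$block else rep(1L, length(stim))
  parts <- lapply(split(seq_along(stim), block), function(idx) {
    tr <- engine(observer, stim[idx])
    tr$trial <- idx
    tr$block <- block[idx]
    tr
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  front <- c("trial", "block", "stim")
  out <- out[order(out$trial), c(front, setdiff(names(out), front))]
  class(out) <- c("observer_trace", "data.frame")
  attr(out, "observer") <- observer
  out
}

#' @export
print.observer_trace <- function(x, ...) {
  obs <- attr(x, "observer")
  cat("Observer trace,", nrow(x), "trials\n")
  if (!is.null(obs)) print(obs)
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more trials\n")
  invisible(x)
}

#' @export
plot.observer_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$trial, x$p1, type = "l", xlab = "trial",
       ylab = "p(next = 1)", ylim = c(0, 1), ...)
  graphics::abline(h = 0.5, lty = 3)
  plot(x$trial, x$conf, type = "l", xlab = "trial",
       ylab = "confidence (log-precision)", ...)
  invisible(x)
}

#' Apparent learning rate of a trace
#'
#' The ratio between the update of the reported estimate and the prediction
#' error that produced it: \eqn{(\theta_{t+1} - \theta_t) / (y_{t+1} -
#' \theta_t)}, where \eqn{\theta_t} is the observer's estimate (here, the
#' predictive probability of stimulus 1) and \eqn{y_{t+1}} the next outcome
#' coded 1/0. Trials with \eqn{|y_{t+1} - \theta_t|} below \code{tol} are
#' masked as \code{NA}. Intended for frequency-statistic traces, where a
#' single estimate is updated by every observation.
#'
#' @param trace An \code{"observer_trace"}.
#' @param seq The sequence the trace was computed on (defaults to the
#'   \code{stim} column of the trace).
#' @param tol Prediction-error masking tolerance.
#' @return Numeric vector of length \code{nrow(trace) - 1}; element t is the
#'   apparent rate of the update caused by observation t + 1.
#' @export
apparent_learning_rate <- function(trace, seq = NULL, tol = 1e-6) {
  stim <- if (is.null(seq)) trace$stim else seq$stim
  y <- as.numeric(stim == 1L)
  est <- trace$p1
  T <- length(est)
  pe <- y[-1] - est[-T]
  lr <- (est[-1] - est[-T]) / pe
  lr[abs(pe) < tol] <- NA_real_
  lr
}
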