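#' Default parameter grids for grid-search fitting
#'
#' Log-spaced grids: 61 points over \eqn{10^{-4}}–0.5 for the hierarchical
#' change probability \code{pc}, and 61 points over 1–1000 trials for the
#' flat leak constant \code{omega}.
#'
#' @param model \code{"hierarchical"} or \code{"flat"}.
#' @param n Number of grid points.
#' @return Ascending numeric vector.
#' @export
default_param_grid <- function(model = c("hierarchical", "flat"), n = 61L) {
  model <- match.arg(model)
  if (model == "hierarchical") {
    10^seq(log10(1e-4), log10(0.5), length.out = n)
  } else {
    10^seq(0, 3, length.out = n)
  }
}

build_observer <- function(model, param, ...) {
  if (model == "hierarchical") hier_observer(pc = param, ...)
  else flat_observer(omega = param, ...)
}

## model predictive probability assigned to each realized observation;
## element t is p(y_t | y_{1:t-1}); NA on the first trial of each block
## (the transitions likelihood there is the constant 1/2)
predictive_of_observed <- function(trace) {
  p_prev <- c(NA_real_, trace$p1[-nrow(trace)])
  p <- ifelse(trace$stim == 1L, p_prev, 1 - p_prev)
  first <- !duplicated(trace$block)
  p[first] <- NA_real_
  p
}

## generative probability of each realized observation
generative_of_observed <- function(seq, statistic) {
  if (statistic == "frequency") {
    p <- ifelse(seq$stim == 1L, seq$p1_gen, 1 - seq$p1_gen)
  } else {
    prev <- c(NA_integer_, seq$stim[-nrow(seq)])
    rep_prob <- ifelse(prev == 1L, seq$p11, seq$p22)
    repeated <- seq$stim == prev
    p <- ifelse(repeated, rep_prob, 1 - rep_prob)
  }
  first <- if ("block" %in% names(seq)) !duplicated(seq$block) else
    c(TRUE, rep(FALSE, nrow(seq) - 1L))
  p[first] <- NA_real_
  p
}

new_fit <- function(model, param_grid, objective, target_kind, fixed) {
  stopifnot(length(param_grid) >= 1L, all(is.finite(objective)))
  best <- param_grid[which.min(objective)]  # ties break toward smaller values
  structure(list(model = model,
                 param_name = if (model == "hierarchical") "pc" else "omega",
                 param_grid = param_grid, objective = objective,
                 best = best, target_kind = target_kind, fixed = fixed),
            class = "observer_fit")
}

#' Fit an observer's free parameter by grid search
#'
#' Each observer has a single free parameter (\code{pc} for the hierarchical
#' model, \code{omega} for the flat model). \code{fit_to_generative}
#' minimizes the sum of squared errors, over all trials of all sequences,
#' between the model's predictive probability of each realized observation
#' and its true generative probability. \code{fit_to_subject_prob} replaces
#' the generative values with a subject's probability reports, using
#' question trials only. \code{fit_to_subject_conf} computes, per grid
#' point, the residual sum of squares of a linear regression (with
#' intercept) of the subject's confidence reports on the model's confidence
#' at question trials — subject sliders and model log-precision live on
#' different scales, so only the affine-invariant residual is meaningful.
#' Ties are broken toward the smaller parameter value.
#'
#' @param model \code{"hierarchical"} or \code{"flat"}.
#' @param sequences A \code{"stim_seq"} data frame or a list of them.
#' @param subject A subject record (see \code{\link{generate_subject}}).
#' @param design The \code{"experiment_design"} the subject responded to.
#' @param param_grid Ascending grid of candidate parameter values.
#' @param ... Passed to the observer constructor (e.g. \code{grid_n},
#'   \code{coupling}, \code{statistic}, \code{prior_counts}).
#' @return An object of class \code{"observer_fit"} with the searched grid,
#'   the SSE objective per grid point and the argmin; supports
#'   \code{print}, \code{summary}, \code{coef}, \code{plot} and
#'   \code{predict}.
#' @seealso \code{\link{compare_models_mse}}
#' @export
fit_to_generative <- function(model = c("hierarchical", "flat"), sequences,
                              param_grid = default_param_grid(model), ...) {
  model <- match.arg(model)
  if (length(param_grid) == 0L) stop_cfg("empty parameter grid")
  if (is.data.frame(sequences)) sequences <- list(sequences)
  sse <- vapply(param_grid, function(par) {
    obs <- build_observer(model, par, ...)
    sum(vapply(sequences, function(sq) {
      tr <- run_observer(obs, sq)
      p_model <- predictive_of_observed(tr)
      p_gen <- generative_of_observed(sq, obs$statistic)
      sum((p_model - p_gen)^2, na.rm = TRUE)
    }, numeric(1)))
  }, numeric(1))
  new_fit(model, param_grid, sse, "generative", list(...))
}

#' @rdname fit_to_generative
#' @export
fit_to_subject_prob <- function(model = c("hierarchical", "flat"), subject,
                                design,
                                param_grid = default_param_grid(model), ...) {
  model <- match.arg(model)
  if (length(param_grid) == 0L) stop_cfg("empty parameter grid")
  q <- design$questions$trial
  rep_p <- subject$p_report[q]
  keep <- !is.na(rep_p)
  if (!any(keep)) stop_cfg("subject has no probability reports at question trials")
  sse <- vapply(param_grid, function(par) {
    obs <- build_observer(model, par, ...)
    tr <- run_observer(obs, design$sequence)
    sum((tr$p1[q][keep] - rep_p[keep])^2)
  }, numeric(1))
  new_fit(model, param_grid, sse, "subject_prob", list(...))
}

#' @rdname fit_to_generative
#' @export
fit_to_subject_conf <- function(model = c("hierarchical", "flat"), subject,
                                design,
                                param_grid = default_param_grid(model), ...) {
  model <- match.arg(model)
  if (length(param_grid) == 0L) stop_cfg("empty parameter grid")
  q <- design$questions$trial
  rep_c <- subject$conf_report[q]
  keep <- !is.na(rep_c)
  if (sum(keep) < 3L) stop_cfg("need at least 3 confidence reports at question trials")
  sse <- vapply(param_grid, function(par) {
    obs <- build_observer(model, par, ...)
    tr <- run_observer(obs, design$sequence)
    mc <- tr$conf[q][keep]
    ok <- is.finite(mc)
    if (stats::sd(mc[ok]) == 0) {
      sum((rep_c[keep][ok] - mean(rep_c[keep][ok]))^2)
    } else {
      sum(stats::resid(stats::lm(rep_c[keep][ok] ~ mc[ok]))^2)
    }
  }, numeric(1))
  new_fit(model, param_grid, sse, "subject_conf", list(...))
}

#' @export
print.observer_fit <- function(x, ...) {
  cat(sprintf("Grid-search fit (%s model, target: %s)\n", x$model,
              x$target_kind))
  cat(sprintf("  %s = %g (grid of %d points, SSE = %g)\n", x$param_name,
              x$best, length(x$param_grid), min(x$objective)))
  invisible(x)
}

#' @export
summary.observer_fit <- function(object, ...) {
  i <- which.min(object$objective)
  step <- if (length(object$param_grid) > 1)
    exp(mean(abs(diff(log(object$param_grid))))) else NA_real_
  cat(sprintf("Grid-search fit of the %s model (%s target)\n", object$model,
              object$target_kind))
  cat(sprintf("  best %s = %g at grid point %d/%d (log-spacing factor %.3g)\n",
              object$param_name, object$best, i, length(object$param_grid),
              step))
  cat(sprintf("  SSE at optimum %g; grid range [%g, %g]\n",
              min(object$objective), min(object$param_grid),
              max(object$param_grid)))
  invisible(object)
}

#' @export
coef.observer_fit <- function(object, ...) {
  stats::setNames(object$best, object$param_name)
}

#' @export
plot.observer_fit <- function(x, ...) {
  plot(x$param_grid, x$objective, log = "x", type = "b", pch = 16, cex = 0.6,
       xlab = x$param_name, ylab = "SSE", ...)
  graphics::abline(v = x$best, lty = 2)
  invisible(x)
}

#' @param object An \code{"observer_fit"}.
#' @param newdata A \code{"stim_seq"} to run the fitted observer on.
#' @rdname fit_to_generative
#' @export
predict.observer_fit <- function(object, newdata, ...) {
  obs <- do.call(build_observer,
                 c(list(model = object$model, param = object$best),
                   object$fixed))
  run_observer(obs, newdata)
}

#' Paired model-comparison of mean squared error at question trials
#'
#' Computes MSE(hierarchical) minus MSE(flat) for one subject, on either
#' probability reports (raw squared differences between the subject's report
#' and each model's predictive probability) or confidence reports (mean
#' squared residual of the subject-on-model confidence regression, since the
#' two confidence scales are not directly comparable). Negative values mean
#' the hierarchical model fits this subject better. Group-level inference is
#' left to \code{\link{streak_type_contrast}}-style t-tests over subjects.
#'
#' @param subject A subject record.
#' @param trace_hier,trace_flat Observer traces on the subject's sequence.
#' @param design The subject's \code{"experiment_design"}.
#' @param on \code{"prob"} or \code{"conf"}.
#' @return Numeric scalar: the paired MSE difference.
#' @export
compare_models_mse <- function(subject, trace_hier, trace_flat, design,
                               on = c("prob", "conf")) {
  on <- match.arg(on)
  if (nrow(trace_hier) != nrow(subject) || nrow(trace_flat) != nrow(subject))
    stop_cfg("traces are not aligned to the subject's trials")
  q <- design$questions$trial
  if (on == "prob") {
    rep_p <- subject$p_report[q]
    keep <- !is.na(rep_p)
    mse <- function(tr) mean((tr$p1[q][keep] - rep_p[keep])^2)
  } else {
    rep_c <- subject$conf_report[q]
    keep <- !is.na(rep_c)
    mse <- function(tr) {
      mc <- tr$conf[q][keep]
      ok <- is.finite(mc)
      mean(stats::resid(stats::lm(rep_c[keep][ok] ~ mc[ok]))^2)
    }
  }
  mse(trace_hier) - mse(trace_flat)
}
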