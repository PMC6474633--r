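#' Generate a frequency-tracking (reward-probability) sequence
#'
#' The classic single-statistic change-point task: binary observations are
#' drawn from a probability that is resampled at change points. Change
#' points either occur at fixed positions (\code{change_points}) or with a
#' per-trial probability \code{change_prob}. Resampled values are uniform on
#' \code{range} and, when \code{min_odds_fold > 1}, rejection-sampled until
#' the odds ratio of the probability changes at least that many fold.
#'
#' @param n Sequence length in trials.
#' @param change_prob Per-trial change probability (ignored when
#'   \code{change_points} is given).
#' @param change_points Optional fixed change-point trial indices (the trial
#'   at which the new value takes effect).
#' @param min_odds_fold Minimum odds-ratio fold change at each change point.
#' @param range Range of the uniform distribution of the probability.
#' @return A data frame with columns \code{trial}, \code{block},
#'   \code{stim} (1/2), \code{p1_gen} (generative probability of stimulus
#'   1), \code{cp}.
#' @export
gen_freq_sequence <- function(n, change_prob = 0.013, change_points = NULL,
                              min_odds_fold = 1, range = c(0.1, 0.9)) {
  cp <- rep(FALSE, n)
  if (is.null(change_points)) {
    cp[-1] <- stats::runif(n - 1) < change_prob
  } else {
    cp[change_points] <- TRUE
    cp[1] <- FALSE
  }
  draw <- function() stats::runif(1, range[1], range[2])
  redraw <- function(prev) {
    repeat {
      cand <- draw()
      if (min_odds_fold <= 1 || odds_fold(cand, prev) >= min_odds_fold)
        return(cand)
    }
  }
  p <- numeric(n)
  p[1] <- draw()
  for (t in 2:n) p[t] <- if (cp[t]) redraw(p[t - 1]) else p[t - 1]
  stim <- ifelse(stats::runif(n) < p, 1L, 2L)
  data.frame(trial = seq_len(n), block = 1L, stim = stim, p1_gen = p, cp = cp)
}

#' Apparent-learning-rate simulation under two volatility conditions
#'
#' Reproduces the fixed-parameter counter-example: sequences of binary
#' outcomes whose generative probability changes at fixed positions, a
#' low-volatility schedule (\code{cp_low}, 7 change points by default) and a
#' high-volatility schedule adding further change points
#' (\code{cp_extra}). Both observers track the outcome frequency (flat
#' prior counts [1 1]); each observer's single parameter is first fitted by
#' grid search to the generative probabilities of both conditions together,
#' then held fixed while the apparent learning rate
#' (\code{\link{apparent_learning_rate}}) is measured on \code{n_reps}
#' fresh sequences per condition.
#'
#' @param n_trials Sequence length.
#' @param cp_low Low-volatility change-point positions.
#' @param cp_extra Additional change points of the high-volatility
#'   condition (the high schedule is their union with \code{cp_low}).
#' @param n_reps Evaluation repetitions per condition.
#' @param n_fit Training sequences per condition for the joint parameter
#'   fit.
#' @param grid_n Hierarchical observer grid size.
#' @param pc_grid,omega_grid Parameter grids for the joint fit.
#' @param range Range of the generative probability.
#' @param seed Optional seed.
#' @return An object of class \code{"lr_sim"}: fitted parameters, mean
#'   learning-rate curves (\code{curves}: condition x model x trial) and
#'   per-rep statistics (\code{rep_stats}: the mean learning rate and the
#'   post-minus-pre change-point contrast per rep, model and condition).
#' @export
run_lr_sim <- function(n_trials = 560L,
                       cp_low = seq(70L, 490L, by = 70L),
                       cp_extra = seq(35L, 525L, by = 70L),
                       n_reps = 200L, n_fit = 20L, grid_n = 50L,
                       pc_grid = default_param_grid("hierarchical", 25L),
                       omega_grid = default_param_grid("flat", 25L),
                       range = c(0.1, 0.9), seed = NULL, window = 6L) {
  if (!is.null(seed)) set.seed(seed)
  cp_high <- sort(union(cp_low, cp_extra))
  gen <- function(cps) gen_freq_sequence(n_trials, change_points = cps,
                                         range = range)
  train <- c(replicate(n_fit, gen(cp_low), simplify = FALSE),
             replicate(n_fit, gen(cp_high), simplify = FALSE))
  fit_h <- fit_to_generative("hierarchical", train, param_grid = pc_grid,
                             grid_n = grid_n, statistic = "frequency")
  fit_f <- fit_to_generative("flat", train, param_grid = omega_grid,
                             prior_counts = c(1, 1), statistic = "frequency")
  obs <- list(hierarchical = hier_observer(pc = fit_h$best, grid_n = grid_n,
                                           statistic = "frequency"),
              flat = flat_observer(omega = fit_f$best, prior_counts = c(1, 1),
                                   statistic = "frequency"))
  conds <- list(low = cp_low, high = cp_high)
  curves <- list()
  rep_stats <- list()
  for (cond in names(conds)) {
    cps <- conds[[cond]]
    post_idx <- outer(cps, seq_len(window), `+`)          # lr index = trial - 1
    pre_idx <- outer(cps, seq_len(window), `-`) - 1L
    lr_mats <- list(hierarchical = matrix(NA_real_, n_reps, n_trials - 1L),
                    flat = matrix(NA_real_, n_reps, n_trials - 1L))
    for (r in seq_len(n_reps)) {
      sq <- gen(cps)
      for (m in names(obs)) {
        lr <- apparent_learning_rate(run_observer(obs[[m]], sq))
        lr_mats[[m]][r, ] <- lr
        rep_stats[[length(rep_stats) + 1L]] <- data.frame(
          rep = r, model = m, condition = cond,
          mean_lr = mean(lr, na.rm = TRUE),
          cp_contrast = mean(lr[post_idx - 1L], na.rm = TRUE) -
            mean(lr[pre_idx], na.rm = TRUE))
      }
    }
    for (m in names(obs)) {
      curves[[paste(cond, m, sep = ".")]] <- colMeans(lr_mats[[m]], na.rm = TRUE)
    }
  }
  structure(list(fit = list(pc = fit_h$best, omega = fit_f$best),
                 curves = curves,
                 rep_stats = do.call(rbind, rep_stats),
                 change_points = conds, window = window),
            class = "lr_sim")
}

#' @export
print.lr_sim <- function(x, ...) {
  cat("Apparent-learning-rate simulation\n")
  cat(sprintf("  fitted parameters: pc = %.4g, omega = %.4g\n",
              x$fit$pc, x$fit$omega))
  agg <- stats::aggregate(cbind(mean_lr, cp_contrast) ~ model + condition,
                          data = x$rep_stats, FUN = mean)
  print(agg, digits = 3)
  invisible(x)
}

#' @export
plot.lr_sim <- function(x, ...) {
  n <- length(x$curves[[1]])
  cols <- c(low.hierarchical = "black", low.flat = "grey50",
            high.hierarchical = "red3", high.flat = "salmon")
  plot(NA, xlim = c(1, n), ylim = range(unlist(x$curves), na.rm = TRUE),
       xlab = "trial", ylab = "apparent learning rate", ...)
  for (nm in names(x$curves)) graphics::lines(seq_len(n), x$curves[[nm]],
                                              col = cols[[nm]])
  graphics::abline(v = x$change_points$low, lty = 1, col = "grey80")
  graphics::abline(v = setdiff(x$change_points$high, x$change_points$low),
                   lty = 2, col = "grey80")
  graphics::legend("topright", legend = names(x$curves), lwd = 1,
                   col = cols[names(x$curves)], bty = "n", cex = 0.8)
  invisible(x)
}

#' Cross-model correlation map over volatility and step size
#'
#' For each cell of a volatility-by-odds-step grid: training sequences are
#' generated, each model's single parameter is fitted by grid search to the
#' generative probabilities, and on freshly generated evaluation sequences
#' the per-trial probability estimates (and confidence levels) of the two
#' fitted models are pooled and correlated (Pearson). The task is the
#' classic frequency-tracking problem; the flat observer uses prior counts
#' [1 1].
#'
#' @param vol_grid Volatilities (per-trial change probabilities).
#' @param step_grid Minimum odds-ratio fold changes at change points.
#' @param n_train,n_eval Training / evaluation sequences per cell.
#' @param seq_len Trials per sequence.
#' @param grid_n Hierarchical observer grid size.
#' @param pc_grid,omega_grid Fitting grids.
#' @param seed Optional seed.
#' @return An object of class \code{"correlation_map"}: matrices \code{est}
#'   and \code{conf} (volatility x step Pearson correlations) plus the
#'   fitted parameters per cell.
#' @export
correlation_map <- function(vol_grid = c(1 / 300, 0.013, 1 / 20),
                            step_grid = c(1, 2, 4),
                            n_train = 10L, n_eval = 25L, seq_len = 400L,
                            grid_n = 50L,
                            pc_grid = default_param_grid("hierarchical", 25L),
                            omega_grid = default_param_grid("flat", 25L),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  est <- conf <- matrix(NA_real_, length(vol_grid), length(step_grid),
                        dimnames = list(volatility = signif(vol_grid, 3),
                                        step = step_grid))
  pc_fit <- omega_fit <- est
  for (i in seq_along(vol_grid)) {
    for (j in seq_along(step_grid)) {
      cell <- correlation_cell(vol_grid[i], step_grid[j], n_train, n_eval,
                               seq_len, grid_n, pc_grid, omega_grid)
      est[i, j] <- cell$rho_est
      conf[i, j] <- cell$rho_conf
      pc_fit[i, j] <- cell$pc
      omega_fit[i, j] <- cell$omega
    }
  }
  structure(list(est = est, conf = conf, pc = pc_fit, omega = omega_fit,
                 n_eval = n_eval, seq_len = seq_len),
            class = "correlation_map")
}

correlation_cell <- function(vol, step, n_train, n_eval, seq_len, grid_n,
                             pc_grid, omega_grid) {
  gen <- function() gen_freq_sequence(seq_len, change_prob = vol,
                                      min_odds_fold = step)
  train <- replicate(n_train, gen(), simplify = FALSE)
  fit_h <- fit_to_generative("hierarchical", train, param_grid = pc_grid,
                             grid_n = grid_n, statistic = "frequency")
  fit_f <- fit_to_generative("flat", train, param_grid = omega_grid,
                             prior_counts = c(1, 1), statistic = "frequency")
  oh <- hier_observer(pc = fit_h$best, grid_n = grid_n,
                      statistic = "frequency")
  of <- flat_observer(omega = fit_f$best, prior_counts = c(1, 1),
                      statistic = "frequency")
  ph <- pf <- ch <- cf <- vector("list", n_eval)
  for (r in seq_len(n_eval)) {
    sq <- gen()
    th <- run_observer(oh, sq)
    tf <- run_observer(of, sq)
    keep <- -1L  # drop trial 1 (both observers sit at their prior)
    ph[[r]] <- th$p1[keep]; pf[[r]] <- tf$p1[keep]
    ch[[r]] <- th$conf[keep]; cf[[r]] <- tf$conf[keep]
  }
  list(rho_est = stats::cor(unlist(ph), unlist(pf)),
       rho_conf = stats::cor(unlist(ch), unlist(cf)),
       pc = fit_h$best, omega = fit_f$best)
}

#' @export
print.correlation_map <- function(x, ...) {
  cat("Cross-model correlation map (", x$n_eval, "evaluation sequences of",
      x$seq_len, "trials per cell)\n")
  cat("Probability estimates (Pearson rho):\n")
  print(round(x$est, 3))
  cat("Confidence (Pearson rho):\n")
  print(round(x$conf, 3))
  invisible(x)
}
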