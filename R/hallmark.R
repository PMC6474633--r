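#' Classify streaks as suspicious or non-suspicious
#'
#' A streak is suspicious when, from the hierarchical coupled observer's
#' viewpoint, the repetitions it contains arouse the suspicion of a change
#' point: operationally, when the mean per-trial change of the observer's
#' confidence about the repeated transition over the streak is negative
#' (confidence in the probability of the observed repetition decreases on
#' average during the streak).
#'
#' @param trace An \code{"observer_trace"} from the coupled hierarchical
#'   observer run on the same sequence (must carry \code{conf11} /
#'   \code{conf22}).
#' @param streaks Output of \code{\link{find_streaks}}.
#' @return \code{streaks} with the \code{label} column filled in.
#' @export
classify_streaks <- function(trace, streaks) {
  if (nrow(streaks) == 0L) return(streaks)
  if (max(streaks$end) > nrow(trace))
    stop_cfg("streak extends beyond the trace")
  obs <- attr(trace, "observer")
  if (!is.null(obs) && inherits(obs, "hier_observer") && obs$pc == 0)
    warning("classification with pc = 0 is degenerate: confidence never resets")
  conf_rep <- ifelse(streaks$symbol == 1L,
                     trace$conf11[streaks$end] - trace$conf11[streaks$start - 1L],
                     trace$conf22[streaks$end] - trace$conf22[streaks$start - 1L])
  streaks$label <- ifelse(conf_rep / streaks$length < 0,
                          "suspicious", "non_suspicious")
  streaks
}

#' Pre/post streak changes in confidence and probability estimates
#'
#' For each selected streak, takes the value reported at the designated pre
#' question (immediately before the streak) and post question (immediately
#' after it), both of which probe the transition of the non-repeated
#' stimulus, and returns post minus pre differences. Works on an observer
#' trace (model-level effects: confidence is the log-precision about the
#' non-repeating transition, the estimate its posterior mean) or a subject
#' record (reported confidence and reported probability). Three differences
#' are returned per streak: \code{d_conf}, the confidence about the probed
#' (non-repeating) transition; \code{d_prob}, the probability assigned to
#' stimulus 1 on the report scale — the scale on which reports are actually
#' given, and on which the sign of any estimate shift alternates with the
#' streak symbol; and \code{d_dist}, the distance of the probed transition
#' estimate from the prior value 0.5, which isolates the subtler reset of
#' the estimate itself. Streaks with a missing report at either question are
#' dropped with a warning.
#'
#' @param x An \code{"observer_trace"} or subject record aligned to
#'   \code{design$sequence}.
#' @param design An \code{"experiment_design"}.
#' @return Data frame with one row per selected streak: \code{streak_id},
#'   \code{label}, \code{symbol}, \code{length}, \code{d_conf},
#'   \code{d_prob}, \code{d_dist}.
#' @export
pre_post_change <- function(x, design) {
  st <- design$streaks[design$streaks$selected, , drop = FALSE]
  if (nrow(st) == 0L) stop_cfg("design has no selected streaks")
  pre <- st$pre_trial
  post <- st$post_trial
  if (inherits(x, "observer_trace")) {
    conf_other <- function(i) ifelse(st$symbol == 1L, x$conf22[i], x$conf11[i])
    est_other <- function(i) ifelse(st$symbol == 1L, x$mean22[i], x$mean11[i])
    d_conf <- conf_other(post) - conf_other(pre)
    d_prob <- x$p1[post] - x$p1[pre]
    d_dist <- abs(est_other(post) - 0.5) - abs(est_other(pre) - 0.5)
  } else {
    ## subject record: reports exist only at question trials; the reported
    ## p(next = 1) with current stimulus 2 is the estimate of p(1|2), so the
    ## non-repeating repetition estimate is its complement (and directly the
    ## report when the streak symbol is 2)
    est_other <- function(i) ifelse(st$symbol == 1L, 1 - x$p_report[i],
                                    x$p_report[i])
    d_conf <- x$conf_report[post] - x$conf_report[pre]
    d_prob <- x$p_report[post] - x$p_report[pre]
    d_dist <- abs(est_other(post) - 0.5) - abs(est_other(pre) - 0.5)
    miss <- is.na(d_conf) | is.na(d_prob)
    if (any(miss)) {
      warning(sum(miss), " streak(s) dropped: missing report at a designated question")
      st <- st[!miss, , drop = FALSE]
      d_conf <- d_conf[!miss]
      d_prob <- d_prob[!miss]
      d_dist <- d_dist[!miss]
    }
  }
  data.frame(streak_id = st$streak_id, label = st$label, symbol = st$symbol,
             length = st$length, d_conf = d_conf, d_prob = d_prob,
             d_dist = d_dist)
}

group_stat <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  m <- mean(x)
  sdx <- stats::sd(x)
  s <- sdx / sqrt(n)
  degenerate <- n < 2 || is.na(sdx) || sdx <= 1e-10 * (abs(m) + 1e-10)
  if (degenerate) {
    t <- if (abs(m) <= 1e-12) 0 else Inf * sign(m)
    p <- NA_real_
  } else {
    tt <- stats::t.test(x)
    t <- unname(tt$statistic)
    p <- tt$p.value
  }
  list(mean = m, sem = s, t = t, df = n - 1L, p = p, n = n)
}

#' Group-level streak-type contrast
#'
#' Per subject, the mean pre/post change after non-suspicious streaks minus
#' the mean change after suspicious streaks (the sign convention that makes
#' the hierarchical generalization effect positive for confidence), followed
#' by a one-sample t-test across subjects. Subjects missing one streak type
#' are dropped with a warning.
#'
#' @param effects A data frame binding \code{\link{pre_post_change}} outputs
#'   with a \code{subject} column, or a list of per-subject effect frames.
#' @param value \code{"d_conf"} or \code{"d_prob"}.
#' @return A list with \code{mean}, \code{sem}, \code{t}, \code{df},
#'   \code{p}, \code{n} and the per-subject differences
#'   (\code{per_subject}).
#' @export
streak_type_contrast <- function(effects, value = c("d_conf", "d_prob", "d_dist")) {
  value <- match.arg(value)
  if (is.data.frame(effects)) {
    effects <- split(effects, effects$subject)
  }
  per <- vapply(effects, function(e) {
    v <- e[[value]]
    has <- c("suspicious", "non_suspicious") %in% e$label[!is.na(v)]
    if (!all(has)) return(NA_real_)
    mean(v[e$label == "non_suspicious"], na.rm = TRUE) -
      mean(v[e$label == "suspicious"], na.rm = TRUE)
  }, numeric(1))
  if (anyNA(per))
    warning(sum(is.na(per)), " subject(s) dropped: missing one streak type")
  out <- group_stat(per)
  out$per_subject <- per
  out
}

#' Subject-versus-model regression at question trials
#'
#' Ordinary least squares with intercept, computed per subject, of a
#' subject-report variable on the corresponding optimal-model variable;
#' slopes are then tested against zero at the group level, and the
#' per-subject Pearson correlations are returned alongside.
#'
#' @param y List (one element per subject) of report vectors.
#' @param x List of matching model-value vectors.
#' @return List with \code{beta} (a group stat over slopes), \code{slopes},
#'   \code{rho} (per-subject Pearson correlations) and \code{rho_mean}.
#' @export
subject_regression <- function(y, x) {
  stopifnot(length(y) == length(x))
  one <- function(yy, xx) {
    keep <- !is.na(yy) & !is.na(xx) & is.finite(xx)
    yy <- yy[keep]; xx <- xx[keep]
    if (length(unique(xx)) < 2L) stop_cfg("constant explanatory variable")
    c(slope = unname(stats::coef(stats::lm(yy ~ xx))[2]),
      rho = stats::cor(yy, xx))
  }
  res <- mapply(one, y, x)
  out <- list(beta = group_stat(res["slope", ]), slopes = res["slope", ],
              rho = res["rho", ], rho_mean = mean(res["rho", ]))
  out
}

#' First-order covariates of a probability report
#'
#' The metrics derived from a subject's own first-order estimates that are
#' regressed out of confidence before asking whether residual confidence
#' still tracks optimal confidence: the distance of the report from 0.5, the
#' Shannon entropy of the reported distribution, and the surprise
#' \eqn{-\log p} assigned by the report to the stimulus that actually
#' followed the question.
#'
#' @param p_report Reported probability that the next stimulus is a 1.
#' @param next_stim The stimulus (1/2) actually observed after the question,
#'   or \code{NA}.
#' @return Data frame with columns \code{dist}, \code{entropy},
#'   \code{surprise}.
#' @export
first_order_covariates <- function(p_report, next_stim) {
  p <- clip01(p_report)
  eps <- 1e-12
  ent <- -(p * log(p + eps) + (1 - p) * log(1 - p + eps))
  surprise <- ifelse(next_stim == 1L, -log(p + eps), -log(1 - p + eps))
  data.frame(dist = abs(p - 0.5), entropy = ent, surprise = surprise)
}

zscore <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) return(rep(NA_real_, length(x)))
  (x - mean(x, na.rm = TRUE)) / s
}

#' Residual confidence test
#'
#' Per subject: regress confidence reports on z-scored first-order
#' covariates (dropping collinear/degenerate columns with a warning), then
#' regress the residuals on the z-scored optimal confidence; the slopes are
#' tested against zero at the group level. A positive group slope means
#' confidence reports carry information about optimal confidence over and
#' above anything derivable from the subject's own probability estimates.
#'
#' @param conf List (per subject) of confidence-report vectors.
#' @param opt_conf List of matching optimal (model) confidence vectors.
#' @param covariates List of matching covariate data frames, e.g. from
#'   \code{\link{first_order_covariates}}.
#' @return List with \code{beta} (group stat over residual slopes) and
#'   \code{slopes}.
#' @export
residual_confidence_test <- function(conf, opt_conf, covariates) {
  stopifnot(length(conf) == length(opt_conf),
            length(conf) == length(covariates))
  one <- function(cc, oc, cv) {
    keep <- !is.na(cc) & !is.na(oc) & is.finite(oc) &
      apply(!is.na(cv) & is.finite(as.matrix(cv)), 1, all)
    cc <- cc[keep]; oc <- oc[keep]; cv <- cv[keep, , drop = FALSE]
    z <- as.data.frame(lapply(cv, zscore))
    drop <- vapply(z, function(col) all(is.na(col)), logical(1))
    if (any(drop)) {
      warning("dropping degenerate covariate(s): ",
              paste(names(z)[drop], collapse = ", "))
      z <- z[, !drop, drop = FALSE]
    }
    fit1 <- stats::lm(cc ~ ., data = z)
    r <- stats::resid(fit1)
    unname(stats::coef(stats::lm(r ~ zscore(oc)))[2])
  }
  slopes <- mapply(one, conf, opt_conf, covariates)
  list(beta = group_stat(slopes), slopes = slopes)
}

#' Exclude poorly performing subjects
#'
#' A subject is excluded when the Pearson correlation between their
#' probability reports and the optimal (hierarchical) probability estimates
#' at question trials falls below 0.18 (strict inequality: a correlation of
#' exactly 0.18 is included).
#'
#' @param reports List (per subject) of probability-report vectors at
#'   question trials.
#' @param optimal List of matching optimal probability estimates.
#' @param threshold Exclusion threshold on Pearson's rho.
#' @return List with \code{included} (indices), \code{excluded},
#'   \code{rho}.
#' @export
exclusion_filter <- function(reports, optimal, threshold = 0.18) {
  rho <- mapply(function(y, x) {
    keep <- !is.na(y) & !is.na(x)
    stats::cor(y[keep], x[keep])
  }, reports, optimal)
  list(included = which(rho >= threshold), excluded = which(rho < threshold),
       rho = rho)
}
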