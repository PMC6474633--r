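#' Generative configuration for the change-point transition-probability task
#'
#' Describes the generative process of the behavioral task: binary stimuli
#' (coded 1 and 2) drawn from two hidden repetition probabilities
#' \eqn{p(1|1)} and \eqn{p(2|2)} that are piecewise constant between abrupt
#' change points. Stable periods are geometric with mean \code{mean_period}
#' trials, truncated (by resampling) at \code{max_period}. At every change
#' point the affected probabilities are redrawn uniformly on
#' \code{[prob_low, prob_high]} under the constraint that the odds ratio
#' \eqn{p/(1-p)} of at least one affected probability changes by a factor of
#' \code{min_odds_fold} or more. When \code{coupled} is \code{TRUE} (the main
#' task) both probabilities share the same change points; when \code{FALSE}
#' (the control task) each has its own independent change points and only the
#' affected probability is redrawn.
#'
#' @param change_prob Per-trial change probability (the task's volatility).
#' @param mean_period Expected stable-period length in trials.
#' @param max_period Truncation bound on stable-period length, in trials.
#' @param prob_low,prob_high Range of the uniform distribution of repetition
#'   probabilities.
#' @param min_odds_fold Minimum fold change of the odds ratio at a change
#'   point, for at least one affected probability.
#' @param coupled Logical; shared (\code{TRUE}) or independent (\code{FALSE})
#'   change points for the two probabilities.
#' @param block_length Trials per block.
#' @param n_blocks Number of blocks per experiment.
#' @param question_rate Mean number of trials between questions.
#' @param n_questions_total Total number of question trials per experiment.
#' @param n_streak_questions Number of streak-targeted (pre/post) questions.
#' @return An object of class \code{"gen_config"} (a named list).
#' @export
gen_config <- function(change_prob = 1 / 75, mean_period = 75, max_period = 300,
                       prob_low = 0.1, prob_high = 0.9, min_odds_fold = 4,
                       coupled = TRUE, block_length = 380, n_blocks = 4,
                       question_rate = 15, n_questions_total = 100,
                       n_streak_questions = 32) {
  if (!(prob_low > 0 && prob_low < prob_high && prob_high < 1))
    stop_cfg("need 0 < prob_low < prob_high < 1")
  if (min_odds_fold < 1) stop_cfg("min_odds_fold must be >= 1")
  if (mean_period <= 0) stop_cfg("mean_period must be positive")
  if (max_period < 1) stop_cfg("max_period must be >= 1")
  cfg <- list(
    change_prob = change_prob, mean_period = mean_period,
    max_period = max_period, prob_low = prob_low, prob_high = prob_high,
    min_odds_fold = min_odds_fold, coupled = coupled,
    block_length = as.integer(block_length), n_blocks = as.integer(n_blocks),
    question_rate = question_rate,
    n_questions_total = as.integer(n_questions_total),
    n_streak_questions = as.integer(n_streak_questions)
  )
  structure(cfg, class = "gen_config")
}

#' Read a generative configuration from a YAML file
#'
#' The file holds flat key-value pairs mirroring the arguments of
#' \code{\link{gen_config}}; absent keys take their defaults.
#'
#' @param path Path to a YAML file.
#' @return A \code{"gen_config"} object.
#' @export
read_gen_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(gen_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop_cfg("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(gen_config, vals)
}

#' @export
print.gen_config <- function(x, ...) {
  cat("Generative task configuration\n")
  cat(sprintf("  volatility 1/%g (periods truncated at %d), probabilities U(%g, %g)\n",
              x$mean_period, x$max_period, x$prob_low, x$prob_high))
  cat(sprintf("  odds-fold step >= %g, change points %s\n", x$min_odds_fold,
              if (x$coupled) "coupled" else "uncoupled"))
  cat(sprintf("  %d blocks x %d trials, %d questions (%d streak-targeted)\n",
              x$n_blocks, x$block_length, x$n_questions_total,
              x$n_streak_questions))
  invisible(x)
}

#' Sample stable-period lengths
#'
#' Draws period lengths from a geometric distribution on \{1, 2, ...\} with
#' mean \code{cfg$mean_period}, resampling any draw exceeding
#' \code{cfg$max_period} (so the distribution stays geometric below the
#' bound), until the periods cover \code{total_length} trials; the last
#' period is truncated to fit exactly.
#'
#' @param cfg A \code{\link{gen_config}}.
#' @param total_length Number of trials to cover.
#' @return Integer vector of period lengths summing to \code{total_length}.
#' @export
sample_stable_periods <- function(cfg, total_length) {
  if (cfg$mean_period <= 0) stop_cfg("mean_period must be positive")
  stopifnot(total_length > 0)
  q <- 1 / cfg$mean_period
  acc <- list()
  tot <- 0
  while (tot < total_length) {
    m <- max(16L, ceiling((total_length - tot) / cfg$mean_period * 1.5))
    draw <- stats::rgeom(m, q) + 1L
    bad <- draw > cfg$max_period
    while (any(bad)) {  # truncation by resampling keeps the law geometric below the bound
      draw[bad] <- stats::rgeom(sum(bad), q) + 1L
      bad <- draw > cfg$max_period
    }
    acc[[length(acc) + 1L]] <- draw
    tot <- tot + sum(draw)
  }
  periods <- unlist(acc)
  cum <- cumsum(periods)
  k <- which(cum >= total_length)[1]
  periods <- periods[seq_len(k)]
  periods[k] <- periods[k] - (cum[k] - as.integer(total_length))
  periods
}

#' Sample a pair of repetition probabilities
#'
#' First-period draws (\code{prev = NULL}) are unconstrained uniform on
#' \code{[prob_low, prob_high]}. Later draws are rejection-sampled until the
#' odds ratio of at least one redrawn probability changes at least
#' \code{min_odds_fold}-fold relative to \code{prev}. \code{which = "both"}
#' redraws both probabilities (coupled change points); \code{which = 1} or
#' \code{2} redraws only that probability (uncoupled change points), with the
#' fold constraint applied to it.
#'
#' @param cfg A \code{\link{gen_config}}.
#' @param prev Previous pair \code{c(p11, p22)}, or \code{NULL}.
#' @param which \code{"both"}, \code{1} or \code{2}.
#' @param max_tries Rejection-sampling bound.
#' @return Named numeric vector \code{c(p11 = , p22 = )}.
#' @export
sample_transition_probs <- function(cfg, prev = NULL, which = "both",
                                    max_tries = 10000L) {
  draw1 <- function() stats::runif(1, cfg$prob_low, cfg$prob_high)
  if (is.null(prev)) {
    return(c(p11 = draw1(), p22 = draw1()))
  }
  prev <- unname(prev)
  if (identical(which, "both")) {
    for (i in seq_len(max_tries)) {
      cand <- c(draw1(), draw1())
      if (any(odds_fold(cand, prev) >= cfg$min_odds_fold))
        return(c(p11 = cand[1], p22 = cand[2]))
    }
  } else {
    j <- as.integer(which)
    stopifnot(j %in% c(1L, 2L))
    for (i in seq_len(max_tries)) {
      cand <- prev
      cand[j] <- draw1()
      if (odds_fold(cand[j], prev[j]) >= cfg$min_odds_fold)
        return(c(p11 = cand[1], p22 = cand[2]))
    }
  }
  stop_cfg("odds-fold constraint not satisfiable within ", max_tries,
           " rejections (min_odds_fold = ", cfg$min_odds_fold, ")")
}

## piecewise-constant trajectory for one probability; returns per-trial value
## and change flags given period lengths and a chain sampler
theta_chain <- function(cfg, periods, which) {
  k <- length(periods)
  vals <- matrix(NA_real_, nrow = k, ncol = 2)
  vals[1, ] <- sample_transition_probs(cfg)
  if (k > 1) {
    for (i in 2:k) {
      vals[i, ] <- sample_transition_probs(cfg, prev = vals[i - 1, ], which = which)
    }
  }
  vals
}

#' Generate one block of stimuli
#'
#' Draws the hidden probability trajectories and then the stimulus sequence:
#' the first stimulus is 1 or 2 with probability one half, every subsequent
#' stimulus repeats the previous one with the current repetition probability
#' of that stimulus.
#'
#' @param cfg A \code{\link{gen_config}}.
#' @return A \code{"stim_seq"} data frame with columns \code{trial},
#'   \code{block}, \code{stim}, \code{p11}, \code{p22}, \code{cp1},
#'   \code{cp2} (per-probability change-point flags; identical columns iff
#'   coupled).
#' @export
generate_block <- function(cfg) {
  L <- cfg$block_length
  if (cfg$coupled) {
    periods <- sample_stable_periods(cfg, L)
    vals <- theta_chain(cfg, periods, which = "both")
    p11 <- rep(vals[, 1], periods)
    p22 <- rep(vals[, 2], periods)
    cp <- rep(FALSE, L)
    if (length(periods) > 1) cp[cumsum(periods)[-length(periods)] + 1L] <- TRUE
    cp1 <- cp2 <- cp
  } else {
    traj <- function(j) {
      periods <- sample_stable_periods(cfg, L)
      k <- length(periods)
      v <- numeric(k)
      v[1] <- unname(sample_transition_probs(cfg))[j]
      if (k > 1) {
        for (i in 2:k) {
          pr <- c(v[i - 1], v[i - 1])
          v[i] <- unname(sample_transition_probs(cfg, prev = pr, which = j))[j]
        }
      }
      cp <- rep(FALSE, L)
      if (k > 1) cp[cumsum(periods)[-k] + 1L] <- TRUE
      list(p = rep(v, periods), cp = cp)
    }
    t1 <- traj(1L); t2 <- traj(2L)
    p11 <- t1$p; p22 <- t2$p; cp1 <- t1$cp; cp2 <- t2$cp
  }
  stim <- integer(L)
  stim[1] <- sample(1:2, 1)
  if (L > 1) {
    u <- stats::runif(L)
    for (t in 2:L) {
      p_rep <- if (stim[t - 1] == 1L) p11[t] else p22[t]
      stim[t] <- if (u[t] < p_rep) stim[t - 1] else 3L - stim[t - 1]
    }
  }
  out <- data.frame(trial = seq_len(L), block = 1L, stim = stim,
                    p11 = p11, p22 = p22, cp1 = cp1, cp2 = cp2)
  class(out) <- c("stim_seq", "data.frame")
  attr(out, "config") <- cfg
  out
}

#' Generate a multi-block stimulus sequence
#'
#' Concatenates \code{cfg$n_blocks} independently generated blocks. Observers
#' reset at block boundaries; blocks are concatenated only for selection and
#' bookkeeping.
#'
#' @param cfg A \code{\link{gen_config}}.
#' @param seed Optional integer seed, stored as an attribute.
#' @return A \code{"stim_seq"} data frame (see \code{\link{generate_block}});
#'   \code{trial} is the global 1-based index.
#' @export
generate_sequence <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  blocks <- lapply(seq_len(cfg$n_blocks), function(b) {
    blk <- generate_block(cfg)
    blk$block <- as.integer(b)
    blk
  })
  out <- do.call(rbind, blocks)
  out$trial <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("stim_seq", "data.frame")
  attr(out, "config") <- cfg
  attr(out, "seed") <- seed
  out
}

#' Find streaks of repeated stimuli
#'
#' A streak is a maximal run of identical stimuli of length at least
#' \code{min_length} whose first repeated stimulus occurs after the 15th
#' stimulus of its block. Runs are never merged across block boundaries.
#'
#' @param seq A \code{"stim_seq"} data frame.
#' @param min_length Minimum run length (default 7).
#' @param min_start Earliest admissible block-local start index (default 16,
#'   i.e. after the 15th stimulus).
#' @return Data frame with one row per streak: \code{streak_id},
#'   \code{block}, \code{start}, \code{end} (global trial indices,
#'   inclusive), \code{symbol}, \code{length}, \code{terminated} (run ends
#'   before the block does), and \code{label} (\code{"unclassified"}).
#' @export
find_streaks <- function(seq, min_length = 7L, min_start = 16L) {
  out <- lapply(split(seq, seq$block), function(blk) {
    r <- rle(blk$stim)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$lengths >= min_length & starts >= min_start
    data.frame(block = rep(blk$block[1], sum(keep)),
               start = blk$trial[starts[keep]],
               end = blk$trial[ends[keep]],
               symbol = r$values[keep],
               length = r$lengths[keep],
               terminated = ends[keep] < nrow(blk))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (nrow(out)) out <- out[order(out$start), , drop = FALSE]
  out$streak_id <- seq_len(nrow(out))
  out$label <- rep("unclassified", nrow(out))
  out[, c("streak_id", "block", "start", "end", "symbol", "length",
          "terminated", "label")]
}

## choose n_each streaks per label minimizing the mean-duration mismatch;
## randomized subset search (small sets, deterministic under the caller's RNG)
select_matched_streaks <- function(streaks, n_each = 8L, n_search = 300L) {
  susp <- streaks[streaks$label == "suspicious", , drop = FALSE]
  nons <- streaks[streaks$label == "non_suspicious", , drop = FALSE]
  if (nrow(susp) < n_each || nrow(nons) < n_each) return(NULL)
  best <- NULL
  best_gap <- Inf
  for (i in seq_len(n_search)) {
    is_ <- if (nrow(susp) == n_each) seq_len(n_each) else sample(nrow(susp), n_each)
    in_ <- if (nrow(nons) == n_each) seq_len(n_each) else sample(nrow(nons), n_each)
    gap <- abs(mean(susp$length[is_]) - mean(nons$length[in_]))
    if (gap < best_gap) {
      best_gap <- gap
      best <- c(susp$streak_id[is_], nons$streak_id[in_])
    }
    if (nrow(susp) == n_each && nrow(nons) == n_each) break
  }
  list(ids = best, gap = best_gap)
}

#' Place question trials
#'
#' Streak-targeted questions go immediately before each selected streak (on
#' the last trial preceding the first repetition, where the just-observed
#' stimulus is the non-repeating one) and immediately after it (on the
#' terminating, non-repeated stimulus), so that both probe the non-repeating
#' transition. The remaining questions are placed quasi-periodically: ideal
#' slots with a mean gap of \code{cfg$question_rate} trials receive a uniform
#' jitter of up to 5 trials and are nudged locally so that no random question
#' is adjacent to (or collides with) any other question.
#'
#' @param seq A \code{"stim_seq"} data frame.
#' @param selected Data frame of selected streaks (rows of
#'   \code{\link{find_streaks}} output).
#' @param cfg A \code{\link{gen_config}}.
#' @param max_tries Attempts at a collision-free jittered placement.
#' @return Data frame with columns \code{trial}, \code{type} (\code{random},
#'   \code{pre} or \code{post}) and \code{streak_id} (\code{NA} for random).
#' @export
place_questions <- function(seq, selected, cfg, max_tries = 50L) {
  n_total <- cfg$n_questions_total
  pre <- selected$start - 1L
  post <- selected$end + 1L
  fixed <- data.frame(trial = c(pre, post),
                      type = rep(c("pre", "post"), each = nrow(selected)),
                      streak_id = rep(selected$streak_id, 2L))
  if (anyDuplicated(fixed$trial))
    stop_cfg("selected streaks imply colliding pre/post questions")
  n_rand <- n_total - nrow(fixed)
  N <- nrow(seq)
  ideal <- round(seq(cfg$question_rate, N - 1, length.out = n_total))
  ## drop the ideal slots nearest to each fixed question
  for (ft in fixed$trial) {
    ideal <- ideal[-which.min(abs(ideal - ft))]
  }
  stopifnot(length(ideal) == n_rand)
  jitter_max <- 5L
  for (try in seq_len(max_tries)) {
    cand <- ideal + sample(-jitter_max:jitter_max, n_rand, replace = TRUE)
    cand <- pmin(pmax(cand, 2L), N - 1L)
    taken <- fixed$trial
    ok <- TRUE
    pos <- integer(n_rand)
    for (i in seq_len(n_rand)) {
      placed <- FALSE
      for (off in c(0L, 1L, -1L, 2L, -2L, 3L, -3L, 4L, -4L, 5L, -5L, 6L, -6L, 7L, -7L)) {
        p <- cand[i] + off
        if (p < 2L || p > N - 1L) next
        if (all(abs(p - taken) >= 2L) && (i == 1L || all(abs(p - pos[seq_len(i - 1L)]) >= 2L))) {
          pos[i] <- p
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) {
      out <- rbind(fixed,
                   data.frame(trial = pos, type = "random",
                              streak_id = NA_integer_))
      out <- out[order(out$trial), ]
      rownames(out) <- NULL
      stopifnot(nrow(out) == n_total)
      return(out)
    }
  }
  stop_cfg("could not place ", n_rand, " random questions without collisions")
}

#' Assemble an experiment design by rejection sampling
#'
#' Repeatedly generates candidate multi-block sequences, classifies their
#' streaks with a coupled hierarchical observer
#' (\code{\link{classify_streaks}}), and accepts the first sequence that (i)
#' contains at least \code{n_select} suspicious and \code{n_select}
#' non-suspicious terminated streaks (with at least one of each label in
#' every block), (ii) admits a selection of \code{n_select} streaks per label
#' whose mean durations differ by at most \code{duration_tol} trials, and
#' (iii) whose selected suspicious streaks show a mean model-confidence drop
#' (pre minus post, about the non-repeating transition) of at least
#' \code{min_conf_drop} log-precision units. Questions are then placed with
#' \code{\link{place_questions}}.
#'
#' @param cfg A \code{\link{gen_config}}.
#' @param observer Classification observer; defaults to the coupled
#'   hierarchical observer at the generative volatility.
#' @param seed Integer seed; stored in the design so that regeneration is
#'   bit-exact.
#' @param min_conf_drop Selection threshold on the mean suspicious-streak
#'   confidence drop (log-precision units).
#' @param duration_tol Tolerance on the difference of mean streak durations
#'   between labels (trials).
#' @param max_tries Candidate sequences to try before giving up.
#' @return An object of class \code{"experiment_design"}: a list with
#'   elements \code{sequence}, \code{questions}, \code{streaks} (all streaks,
#'   labelled, with a \code{selected} flag and pre/post trial indices),
#'   \code{trace} (the classification observer's trace) and \code{meta}.
#' @export
assemble_experiment <- function(cfg = gen_config(), observer = NULL,
                                seed = NULL, min_conf_drop = 0.5,
                                duration_tol = 2, max_tries = 500L) {
  if (is.null(observer))
    observer <- hier_observer(pc = cfg$change_prob, coupling = "coupled")
  if (!is.null(seed)) set.seed(seed)
  n_each <- cfg$n_streak_questions %/% 4L  # selected streaks per label
  diag <- c(too_few = 0L, block_cover = 0L, duration = 0L, conf_drop = 0L,
            questions = 0L)
  for (try in seq_len(max_tries)) {
    sq <- generate_sequence(cfg)
    tr <- run_observer(observer, sq)
    st <- find_streaks(sq)
    ## streaks must end strictly inside their block so the post question can
    ## probe the terminating stimulus and still be followed by a stimulus
    block_end <- cumsum(rep(cfg$block_length, cfg$n_blocks))
    eligible <- st$terminated & !((st$end + 1L) %in% block_end)
    st <- classify_streaks(tr, st)
    stsel <- st[eligible, , drop = FALSE]
    n_susp <- sum(stsel$label == "suspicious")
    n_non <- sum(stsel$label == "non_suspicious")
    if (n_susp < n_each || n_non < n_each) { diag["too_few"] <- diag["too_few"] + 1L; next }
    cover <- vapply(seq_len(cfg$n_blocks), function(b) {
      all(c("suspicious", "non_suspicious") %in% stsel$label[stsel$block == b])
    }, logical(1))
    if (!all(cover)) { diag["block_cover"] <- diag["block_cover"] + 1L; next }
    sel <- select_matched_streaks(stsel, n_each = n_each)
    if (is.null(sel) || sel$gap > duration_tol) { diag["duration"] <- diag["duration"] + 1L; next }
    chosen <- st[st$streak_id %in% sel$ids, , drop = FALSE]
    ## mean pre->post confidence drop about the non-repeating transition,
    ## suspicious selected streaks, classification observer
    csusp <- chosen[chosen$label == "suspicious", , drop = FALSE]
    conf_other <- ifelse(csusp$symbol == 1L,
                         tr$conf22[csusp$end + 1L] - tr$conf22[csusp$start - 1L],
                         tr$conf11[csusp$end + 1L] - tr$conf11[csusp$start - 1L])
    if (mean(-conf_other) < min_conf_drop) { diag["conf_drop"] <- diag["conf_drop"] + 1L; next }
    q <- tryCatch(place_questions(sq, chosen, cfg),
                  error = function(e) NULL)
    if (is.null(q)) { diag["questions"] <- diag["questions"] + 1L; next }
    st$selected <- st$streak_id %in% sel$ids
    st$pre_trial <- ifelse(st$selected, st$start - 1L, NA_integer_)
    st$post_trial <- ifelse(st$selected, st$end + 1L, NA_integer_)
    design <- list(sequence = sq, questions = q, streaks = st, trace = tr,
                   meta = list(seed = seed, config = cfg, tries = try,
                               observer = observer,
                               min_conf_drop = min_conf_drop,
                               duration_tol = duration_tol))
    class(design) <- "experiment_design"
    return(design)
  }
  stop_cfg("no acceptable sequence in ", max_tries, " candidates; rejections: ",
           paste(names(diag), diag, sep = "=", collapse = ", "))
}

#' @export
print.experiment_design <- function(x, ...) {
  cfg <- x$meta$config
  cat("Experiment design:", cfg$n_blocks, "blocks x", cfg$block_length,
      "trials,", if (cfg$coupled) "coupled" else "uncoupled", "change points\n")
  cat(sprintf("  %d questions (%d random, %d pre/post on %d selected streaks)\n",
              nrow(x$questions), sum(x$questions$type == "random"),
              sum(x$questions$type != "random"), sum(x$streaks$selected)))
  tab <- table(x$streaks$label[x$streaks$selected])
  cat("  selected streaks:", paste(names(tab), tab, sep = "=", collapse = ", "),
      sprintf("(accepted after %d candidate sequences)\n", x$meta$tries))
  invisible(x)
}

#' Export a design as a trial matrix plus JSON sidecar
#'
#' Writes the per-trial nine-column layout (reports and reaction times all
#' \code{NA}, since no subject has responded yet) and a JSON sidecar holding
#' the seed, change points, question table and streak labels.
#'
#' @param design An \code{"experiment_design"}.
#' @param path Output CSV path; the sidecar is written next to it with
#'   extension \code{.json}.
#' @return \code{path}, invisibly.
#' @export
write_design <- function(design, path) {
  sq <- design$sequence
  rec <- empty_subject_record(design)
  utils::write.csv(rec, path, row.names = FALSE)
  side <- list(
    seed = design$meta$seed,
    config = unclass(design$meta$config),
    change_points = list(cp1 = sq$trial[sq$cp1], cp2 = sq$trial[sq$cp2]),
    questions = design$questions,
    streaks = design$streaks[, c("streak_id", "block", "start", "end",
                                 "symbol", "length", "label", "selected")]
  )
  jsonlite::write_json(side, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
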