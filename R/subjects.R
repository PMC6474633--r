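#' Report noise model for synthetic subjects
#'
#' Synthetic subjects map an observer trace into slider reports. Probability
#' reports shrink the model's predictive probability toward 0.5 with slope
#' \code{prob_slope} and add Gaussian noise \code{prob_sd} (clipped to
#' [0, 1]). Confidence reports map the model's log-precision affinely
#' (\code{conf_intercept + conf_slope * conf}) with Gaussian noise
#' \code{conf_sd}, clipped to the [0, 1] slider. The probability defaults
#' are calibrated to land synthetic cohorts near the fit quality observed in
#' humans on this task (group regression slope about 0.66, correlation about
#' 0.56); the confidence slope mirrors the subject-versus-model confidence
#' regression slope of about 0.10, and \code{conf_sd} = 0.15 is a plausible
#' slider report noise.
#'
#' @param prob_slope Shrinkage slope of probability reports toward 0.5.
#' @param prob_sd Probability report noise (probability scale).
#' @param conf_slope,conf_intercept Affine map from log-precision to the
#'   confidence slider.
#' @param conf_sd Confidence slider noise.
#' @return An object of class \code{"noise_model"}.
#' @export
noise_model <- function(prob_slope = 0.66, prob_sd = 0.18,
                        conf_slope = 0.10, conf_intercept = 0.1,
                        conf_sd = 0.15) {
  if (prob_sd < 0 || conf_sd < 0) stop_cfg("noise sds must be >= 0")
  structure(list(prob_slope = prob_slope, prob_sd = prob_sd,
                 conf_slope = conf_slope, conf_intercept = conf_intercept,
                 conf_sd = conf_sd),
            class = "noise_model")
}

subject_columns <- c("modality", "block", "stim", "gen_p12", "gen_p21",
                     "p_report", "conf_report", "rt_prob", "rt_conf")

empty_subject_record <- function(design) {
  sq <- design$sequence
  rec <- data.frame(
    modality = sq$block %% 2L,          # alternating modalities, 1 = visual
    block = sq$block,
    stim = sq$stim,
    gen_p12 = 1 - sq$p22,               # p(1 | previous 2)
    gen_p21 = 1 - sq$p11,               # p(2 | previous 1)
    p_report = NA_real_,
    conf_report = NA_real_,
    rt_prob = NA_real_,
    rt_conf = NA_real_
  )
  class(rec) <- c("subject_record", "data.frame")
  rec
}

#' Generate a synthetic subject from an observer trace
#'
#' Produces a per-trial record in the nine-column trial-matrix layout
#' (modality, block, stimulus, the two generative transition probabilities,
#' probability report, confidence report, two reaction times). Reports are
#' present exactly at the design's question trials and are noisy, bounded
#' mappings of the trace's predictive probability and log-precision
#' confidence (see \code{\link{noise_model}}); reaction times are left
#' missing.
#'
#' @param trace An \code{"observer_trace"} computed on
#'   \code{design$sequence}.
#' @param design An \code{"experiment_design"}.
#' @param noise A \code{\link{noise_model}}.
#' @return A \code{"subject_record"} data frame, one row per trial.
#' @export
generate_subject <- function(trace, design, noise = noise_model()) {
  if (nrow(trace) != nrow(design$sequence))
    stop_cfg("trace is not aligned to the design's sequence")
  rec <- empty_subject_record(design)
  q <- design$questions$trial
  nq <- length(q)
  p <- 0.5 + noise$prob_slope * (trace$p1[q] - 0.5) +
    stats::rnorm(nq, 0, noise$prob_sd)
  cf <- noise$conf_intercept + noise$conf_slope * trace$conf[q] +
    stats::rnorm(nq, 0, noise$conf_sd)
  rec$p_report[q] <- clip01(p)
  rec$conf_report[q] <- clip01(cf)
  rec
}

#' Generate a synthetic cohort
#'
#' One subject per design: the source observer is run on each design's
#' sequence and its trace is turned into noisy reports. The hierarchical
#' source uses the coupled filter on coupled designs and the uncoupled
#' filter on uncoupled designs (each the correct observer for its task).
#'
#' @param designs List of \code{"experiment_design"} objects (recycled to
#'   \code{n}).
#' @param n Cohort size.
#' @param source \code{"hierarchical"} or \code{"flat"}: the observer whose
#'   trace generates the reports.
#' @param noise A \code{\link{noise_model}}.
#' @param pc,omega,grid_n Source observer parameters.
#' @param traces Optional list of precomputed source traces (one per
#'   design), e.g. to amortize observer runs over repeated cohort draws.
#' @param seed Optional seed.
#' @return An object of class \code{"cohort"}: list with \code{subjects},
#'   \code{design_id}, \code{designs}, \code{traces} (source traces),
#'   \code{source}, \code{noise}.
#' @export
generate_cohort <- function(designs, n = 23L,
                            source = c("hierarchical", "flat"),
                            noise = noise_model(), pc = 1 / 75, omega = 20,
                            grid_n = 50L, traces = NULL, seed = NULL) {
  source <- match.arg(source)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(designs, "experiment_design")) designs <- list(designs)
  design_id <- rep_len(seq_along(designs), n)
  traces_by_design <- if (!is.null(traces)) {
    stopifnot(length(traces) == length(designs))
    traces
  } else lapply(designs, function(d) {
    if (source == "hierarchical") {
      coupling <- if (d$meta$config$coupled) "coupled" else "uncoupled"
      run_observer(hier_observer(pc = pc, grid_n = grid_n,
                                 coupling = coupling), d$sequence)
    } else {
      run_observer(flat_observer(omega = omega), d$sequence)
    }
  })
  subjects <- lapply(design_id, function(i) {
    generate_subject(traces_by_design[[i]], designs[[i]], noise)
  })
  structure(list(subjects = subjects, design_id = design_id,
                 designs = designs, traces = traces_by_design,
                 source = source, noise = noise),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects from the %s observer on %d design(s)\n",
              length(x$subjects), x$source, length(x$designs)))
  invisible(x)
}

#' Streak-type contrast for a whole cohort
#'
#' Runs \code{\link{pre_post_change}} for every subject (or for the source
#' model traces, \code{level = "model"}) and returns the group contrast of
#' \code{\link{streak_type_contrast}}.
#'
#' @param cohort A \code{"cohort"}.
#' @param value \code{"d_conf"} or \code{"d_prob"}.
#' @param level \code{"subject"} (reports) or \code{"model"} (source
#'   traces).
#' @return A group-stat list (see \code{\link{streak_type_contrast}}).
#' @export
cohort_streak_contrast <- function(cohort, value = c("d_conf", "d_prob", "d_dist"),
                                   level = c("subject", "model")) {
  value <- match.arg(value)
  level <- match.arg(level)
  effects <- lapply(seq_along(cohort$subjects), function(i) {
    d <- cohort$designs[[cohort$design_id[i]]]
    if (level == "subject") pre_post_change(cohort$subjects[[i]], d)
    else pre_post_change(cohort$traces[[cohort$design_id[i]]], d)
  })
  streak_type_contrast(effects, value = value)
}

#' Write and read cohorts in the deposited trial-matrix layout
#'
#' The on-disk layout mirrors the deposited dataset: three cohort
#' containers — \code{main_included}, \code{main_excluded}, \code{control} —
#' each holding one file per subject whose rows are trials and whose nine
#' columns are documented in \code{\link{generate_subject}}. Files are plain
#' CSV (one per subject, \code{subject_NN.csv}) with \code{NA} as the
#' missing-value sentinel. \code{read_dataset} validates the column count
#' and the binary stimulus coding, and returns the three cohorts as lists
#' of \code{"subject_record"} data frames.
#'
#' @param cohorts Named list with elements \code{main_included},
#'   \code{main_excluded}, \code{control}, each a list of subject records
#'   (possibly empty).
#' @param path Directory to write to / read from.
#' @return \code{write_dataset}: \code{path}, invisibly;
#'   \code{read_dataset}: named list of three cohorts.
#' @export
write_dataset <- function(cohorts, path) {
  stopifnot(all(c("main_included", "main_excluded", "control") %in%
                  names(cohorts)))
  for (cname in c("main_included", "main_excluded", "control")) {
    dir.create(file.path(path, cname), recursive = TRUE, showWarnings = FALSE)
    subs <- cohorts[[cname]]
    for (i in seq_along(subs)) {
      stopifnot(identical(names(subs[[i]]), subject_columns))
      utils::write.csv(subs[[i]],
                       file.path(path, cname, sprintf("subject_%02d.csv", i)),
                       row.names = FALSE)
    }
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  out <- lapply(c(main_included = "main_included",
                  main_excluded = "main_excluded",
                  control = "control"), function(cname) {
    dir <- file.path(path, cname)
    files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
    lapply(files, function(f) {
      rec <- utils::read.csv(f)
      if (!identical(names(rec), subject_columns))
        stop_cfg("file ", basename(f), ": expected columns ",
                 paste(subject_columns, collapse = ", "), "; got ",
                 paste(names(rec), collapse = ", "))
      if (!all(rec$stim %in% c(1L, 2L)))
        stop_cfg("file ", basename(f), ": column 'stim' must be coded 1/2")
      ## all-missing report columns parse as logical; restore numeric types
      for (col in subject_columns[4:9]) rec[[col]] <- as.numeric(rec[[col]])
      for (col in subject_columns[1:3]) rec[[col]] <- as.integer(rec[[col]])
      class(rec) <- c("subject_record", "data.frame")
      rec
    })
  })
  out
}
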