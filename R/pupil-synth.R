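#' Specification of the synthetic pupil generator
#'
#' Parameters of the generative model for synthetic eye-tracker traces:
#' per-trial traces span a fixation phase (3.5 s), a response-terminated
#' stimulus phase (duration drawn uniform on `stimulus_range`) and an
#' outcome phase (2.5 s). The trace is a tonic baseline (per drug state,
#' with an optional slow random-walk drift across trials), plus a biphasic
#' outcome-locked response -- a Gaussian-bump dilation followed by a
#' Gaussian-bump constriction -- plus white noise and inserted blinks
#' (runs of missing samples with lognormal duration, median 150 ms, a
#' small fraction forced beyond 500 ms so the discard rule is exercised).
#'
#' @param sampling_rate Samples per second (default 500).
#' @param tonic_baseline Named vector of baseline diameters per drug state
#'   in arbitrary eye-tracker units (default
#'   `c(placebo = 3000, atomoxetine = 3300)`).
#' @param phasic_amplitude,phasic_latency,phasic_width Dilation bump:
#'   amplitude (units), peak latency and SD width (s) after outcome onset.
#' @param constriction_amplitude,constriction_latency,constriction_width
#'   Constriction bump (subtracted), same conventions.
#' @param blink_rate Expected blinks per second (default 0.1).
#' @param long_blink_prob Fraction of blinks forced longer than 500 ms
#'   (default 0.05).
#' @param noise_sd White-noise SD (units; default 20).
#' @param baseline_drift_sd Per-trial SD of the tonic random-walk drift
#'   (default 8; set 0 for exactly reproducible baselines).
#' @param fixation_s,outcome_s Phase durations (defaults 3.5 and 2.5 s).
#' @param stimulus_range Range of the stimulus-phase duration (default
#'   `c(0.5, 2.5)` s).
#' @return An object of class `pupil_spec`.
#' @export
synthetic_pupil_spec <- function(sampling_rate = 500,
                                 tonic_baseline = c(placebo = 3000,
                                                    atomoxetine = 3300),
                                 phasic_amplitude = 120,
                                 phasic_latency = 0.30,
                                 phasic_width = 0.10,
                                 constriction_amplitude = 80,
                                 constriction_latency = 0.65,
                                 constriction_width = 0.15,
                                 blink_rate = 0.1,
                                 long_blink_prob = 0.05,
                                 noise_sd = 20,
                                 baseline_drift_sd = 8,
                                 fixation_s = 3.5,
                                 outcome_s = 2.5,
                                 stimulus_range = c(0.5, 2.5)) {
  if (sampling_rate <= 0) stop("sampling_rate must be > 0", call. = FALSE)
  if (phasic_latency < 0 || phasic_latency > 1 ||
      constriction_latency < 0 || constriction_latency > 1) {
    stop("phasic latencies must lie within the 1000 ms outcome window",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "pupil_spec")
}

#' Generate synthetic pupil traces for a session
#'
#' Builds one trace per trial of the schedule under the generative model
#' described in [synthetic_pupil_spec()]. Missing samples (blinks) are
#' encoded as `NA` diameters.
#'
#' @param spec A `pupil_spec`.
#' @param schedule A `task_schedule`; one trace is generated per row.
#' @param participant_id,drug_state Identity columns stamped on the
#'   output; `drug_state` selects the tonic baseline.
#' @param seed Optional integer seed.
#' @return A `pupil_traces` data frame: `participant_id`, `drug_state`,
#'   `condition`, `trial` (0-based session-global), `phase`
#'   (fixation/stimulus/outcome), `time_s` (within trial), `diameter`.
#' @examples
#' spec <- synthetic_pupil_spec(sampling_rate = 50, noise_sd = 0,
#'                              blink_rate = 0, baseline_drift_sd = 0)
#' sched <- generate_task_schedule(trials_per_condition = 2,
#'                                 block_size = 4, seed = 1)
#' tr <- generate_pupil_dataset(spec, sched, seed = 1)
#' @export
generate_pupil_dataset <- function(spec, schedule,
                                   participant_id = "sim",
                                   drug_state = "placebo",
                                   seed = NULL) {
  stopifnot(inherits(spec, "pupil_spec"), inherits(schedule, "task_schedule"))
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / spec$sampling_rate
  if (dt > min(spec$fixation_s, spec$outcome_s, spec$stimulus_range[1])) {
    stop("sampling interval longer than the shortest phase", call. = FALSE)
  }
  tonic <- if (length(spec$tonic_baseline) > 1L) {
    if (!drug_state %in% names(spec$tonic_baseline)) {
      stop("no tonic baseline for drug state ", drug_state, call. = FALSE)
    }
    spec$tonic_baseline[[drug_state]]
  } else {
    as.numeric(spec$tonic_baseline)
  }
  n_trials <- nrow(schedule)
  drift <- if (spec$baseline_drift_sd > 0) {
    cumsum(rnorm(n_trials, 0, spec$baseline_drift_sd))
  } else {
    rep(0, n_trials)
  }

  out <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    stim_s <- runif(1, spec$stimulus_range[1], spec$stimulus_range[2])
    durs <- c(fixation = spec$fixation_s, stimulus = stim_s,
              outcome = spec$outcome_s)
    n_per <- round(durs / dt)
    phase <- rep(names(n_per), n_per)
    tt <- (seq_len(sum(n_per)) - 1L) * dt
    out_onset <- (n_per[["fixation"]] + n_per[["stimulus"]]) * dt
    rel <- tt - out_onset
    y <- rep(tonic + drift[i], length(tt))
    resp <- spec$phasic_amplitude *
      exp(-(rel - spec$phasic_latency)^2 / (2 * spec$phasic_width^2)) -
      spec$constriction_amplitude *
      exp(-(rel - spec$constriction_latency)^2 /
            (2 * spec$constriction_width^2))
    y <- y + ifelse(rel >= 0, resp, 0)
    if (spec$noise_sd > 0) y <- y + rnorm(length(y), 0, spec$noise_sd)
    # blinks: Poisson count over the trial, lognormal durations
    n_blink <- stats::rpois(1, spec$blink_rate * max(tt))
    if (n_blink > 0) {
      for (b in seq_len(n_blink)) {
        dur <- rlnorm(1, log(0.150), 0.4)
        if (runif(1) < spec$long_blink_prob) dur <- runif(1, 0.55, 0.80)
        start <- runif(1, 0, max(tt) - dur)
        y[tt >= start & tt < start + dur] <- NA_real_
      }
    }
    out[[i]] <- data.frame(
      participant_id = participant_id, drug_state = drug_state,
      condition = schedule$condition[i], trial = i - 1L,
      phase = phase, time_s = tt, diameter = y,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "sampling_rate") <- spec$sampling_rate
  class(res) <- c("pupil_traces", "data.frame")
  res
}

#' Read / write pupil trace tables
#'
#' Delimited-text interchange for pupil recordings: columns
#' `participant_id, drug_state, condition, trial, phase, time_s, diameter`;
#' missing samples are encoded as an empty diameter field.
#'
#' @param traces A `pupil_traces` data frame.
#' @param path File path.
#' @param sampling_rate Sampling rate recorded on read (Hz); inferred from
#'   the time grid when `NULL`.
#' @return `read_pupil_traces` returns a `pupil_traces` data frame;
#'   `write_pupil_traces` returns `path` invisibly.
#' @export
write_pupil_traces <- function(traces, path) {
  df <- as.data.frame(traces)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_pupil_traces
#' @export
read_pupil_traces <- function(path, sampling_rate = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (is.null(sampling_rate)) {
    tt <- df$time_s[df$trial == df$trial[1] &
                      df$participant_id == df$participant_id[1]]
    sampling_rate <- round(1 / median(diff(sort(unique(tt)))))
  }
  attr(df, "sampling_rate") <- sampling_rate
  class(df) <- c("pupil_traces", "data.frame")
  df
}
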