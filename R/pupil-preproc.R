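#' Interpolate blinks in a single pupil trace
#'
#' Replaces each run of missing samples shorter than 500 ms with linear
#' interpolation anchored on the medians of 100 ms windows before and
#' after the run (anchor points at the window centres); non-missing
#' samples are never altered. Any missing run of 500 ms or longer flags
#' the trial for discarding and its samples are left untouched. A run at
#' the trace boundary with no anchor on one side is filled one-sidedly
#' (constant at the available anchor) and logged.
#'
#' @param trace Data frame for one trial with columns `time_s` and
#'   `diameter` (`NA` = missing sample).
#' @param sampling_rate Samples per second; inferred from the time grid
#'   when `NULL`.
#' @return The trace with interpolated `diameter`, plus attributes
#'   `discard` (logical: a run >= 500 ms was present), `one_sided`
#'   (number of one-sided boundary fills).
#' @examples
#' tr <- data.frame(time_s = (0:99) / 100, diameter = 5)
#' tr$diameter[40:60] <- NA
#' out <- interpolate_blinks(tr)
#' attr(out, "discard")
#' @export
interpolate_blinks <- function(trace, sampling_rate = NULL) {
  y <- trace$diameter
  tt <- trace$time_s
  if (is.null(sampling_rate)) sampling_rate <- 1 / median(diff(tt))
  dt <- 1 / sampling_rate
  anchor_n <- max(1L, round(0.1 / dt))

  miss <- is.na(y)
  discard <- FALSE
  one_sided <- 0L
  if (any(miss)) {
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      dur <- (i1 - i0 + 1L) * dt
      if (dur >= 0.5) {
        discard <- TRUE
        next
      }
      pre_idx <- seq.int(max(1L, i0 - anchor_n), i0 - 1L)
      post_idx <- seq.int(i1 + 1L, min(length(y), i1 + anchor_n))
      pre_idx <- pre_idx[pre_idx >= 1L & !is.na(y[pre_idx])]
      post_idx <- post_idx[post_idx <= length(y) & !is.na(y[post_idx])]
      has_pre <- i0 > 1L && length(pre_idx) > 0L
      has_post <- i1 < length(y) && length(post_idx) > 0L
      gap <- i0:i1
      if (has_pre && has_post) {
        x0 <- mean(tt[pre_idx]); v0 <- median(y[pre_idx])
        x1 <- mean(tt[post_idx]); v1 <- median(y[post_idx])
        y[gap] <- v0 + (v1 - v0) * (tt[gap] - x0) / (x1 - x0)
      } else if (has_pre || has_post) {
        v <- if (has_pre) median(y[pre_idx]) else median(y[post_idx])
        y[gap] <- v
        one_sided <- one_sided + 1L
      } else {
        discard <- TRUE  # nothing to anchor on
      }
    }
  }
  trace$diameter <- y
  attr(trace, "discard") <- discard
  attr(trace, "one_sided") <- one_sided
  trace
}

# Second-order low-pass Butterworth coefficients via bilinear transform.
.butter2_lowpass <- function(cutoff, sampling_rate) {
  if (cutoff <= 0 || cutoff >= sampling_rate / 2) {
    stop("cutoff must lie in (0, Nyquist)", call. = FALSE)
  }
  K <- tan(pi * cutoff / sampling_rate)
  norm <- 1 / (1 + sqrt(2) * K + K^2)
  b <- c(K^2, 2 * K^2, K^2) * norm
  a <- c(1, 2 * (K^2 - 1) * norm, (1 - sqrt(2) * K + K^2) * norm)
  list(b = b, a = a)
}

# IIR filter (direct form II transposed) with steady-state initial
# conditions scaled to the first sample, so a constant signal passes
# through unchanged and edge transients vanish.
.iir_filter <- function(b, a, x) {
  n <- length(x)
  y <- numeric(n)
  g <- sum(b) / sum(a)                 # DC gain (1 for Butterworth)
  z1 <- (g - b[1]) * x[1]
  z2 <- (g - b[1] - b[2] + a[2] * g) * x[1]
  for (i in seq_len(n)) {
    y[i] <- b[1] * x[i] + z1
    z1 <- b[2] * x[i] - a[2] * y[i] + z2
    z2 <- b[3] * x[i] - a[3] * y[i]
  }
  y
}

# Zero-phase pass: forward and backward over an odd-reflection padded
# signal (scipy-style), padding three settling lengths of the filter.
.filtfilt2 <- function(b, a, x) {
  n <- length(x)
  np <- min(n - 1L, 27L)
  pre <- 2 * x[1] - x[seq(np + 1L, 2L, by = -1L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - np, by = -1L)]
  ext <- c(pre, x, post)
  y <- .iir_filter(b, a, ext)
  y <- rev(.iir_filter(b, a, rev(y)))
  y[(np + 1L):(np + n)]
}

#' Zero-phase second-order Butterworth low-pass filter
#'
#' Forward-backward application of a second-order low-pass Butterworth
#' filter (so the effective magnitude response is squared and the phase is
#' zero), with odd-reflection edge padding.
#'
#' @param x Numeric vector (no missing values).
#' @param cutoff Cutoff frequency (Hz).
#' @param sampling_rate Sampling rate (Hz).
#' @return Filtered vector of the same length.
#' @export
butterworth_lowpass <- function(x, cutoff, sampling_rate) {
  if (anyNA(x)) stop("filter input must not contain missing values",
                     call. = FALSE)
  co <- .butter2_lowpass(cutoff, sampling_rate)
  .filtfilt2(co$b, co$a, x)
}

#' Preprocess one recording session into an outcome-phase trial matrix
#'
#' Runs the standard pupil preprocessing chain for one participant and
#' session, in order: (1) blink interpolation per trial ([interpolate_blinks()];
#' trials with any missing run >= 500 ms are discarded); (2) zero-phase
#' second-order Butterworth low-pass filtering per trial; (3) per-trial
#' baseline = median of the final 500 ms of fixation; (4) removal of
#' trials whose baseline lies outside mean +/- 2 SD within the session
#' (SD computed once, before removal; a zero-SD session excludes
#' nothing); (5) subtraction of each retained trial's baseline median
#' from all its samples. Rows are aligned to outcome onset and cropped to
#' the first 1000 ms of the outcome phase.
#'
#' @param traces A `pupil_traces` data frame for one participant x
#'   session (both task conditions allowed).
#' @param filter_config List with `cutoff` (Hz; default 4 -- the
#'   literature-typical choice, as the source pipeline leaves it
#'   unstated) and `order` (fixed at 2).
#' @param outcome_window_s Length of the analysed outcome window
#'   (default 1 s).
#' @return An object of class `pupil_trial_matrix`: list with `outcome`
#'   (matrix, retained trials x time, baseline-corrected), `time_ms`
#'   (within-outcome time of each column), `info` (data frame per retained
#'   row: participant, drug state, condition, trial, baseline),
#'   `baselines` (per input trial), `excluded` (data frame `trial`,
#'   `reason` in long-blink | baseline-outlier), `sampling_rate`.
#' @export
preprocess_session <- function(traces, filter_config = list(cutoff = 4),
                               outcome_window_s = 1.0) {
  df <- as.data.frame(traces)
  fs <- attr(traces, "sampling_rate")
  if (is.null(fs)) {
    tt <- df$time_s[df$trial == df$trial[1]]
    fs <- round(1 / median(diff(tt)))
  }
  cutoff <- filter_config$cutoff %||% 4
  key <- unique(df[c("participant_id", "drug_state")])
  if (nrow(key) != 1L) {
    stop("preprocess_session expects one participant x session",
         call. = FALSE)
  }
  dt <- 1 / fs
  n_base <- round(0.5 / dt)
  n_out <- round(outcome_window_s / dt)

  trials <- sort(unique(df$trial))
  excluded <- list()
  kept <- list()
  baselines <- rep(NA_real_, length(trials))
  names(baselines) <- trials

  for (i in seq_along(trials)) {
    tr <- df[df$trial == trials[i], , drop = FALSE]
    tr <- tr[order(tr$time_s), , drop = FALSE]
    if (sum(tr$phase == "fixation") < n_base) {
      stop("fixation phase shorter than 500 ms", call. = FALSE)
    }
    tr <- interpolate_blinks(tr, sampling_rate = fs)
    if (attr(tr, "discard")) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(trial = trials[i], reason = "long-blink")
      next
    }
    tr$diameter <- butterworth_lowpass(tr$diameter, cutoff, fs)
    fix <- which(tr$phase == "fixation")
    base_idx <- utils::tail(fix, n_base)
    baselines[i] <- median(tr$diameter[base_idx])
    kept[[length(kept) + 1L]] <- tr
  }

  kept_trials <- vapply(kept, function(tr) tr$trial[1], numeric(1))
  base_kept <- baselines[as.character(kept_trials)]
  mu <- mean(base_kept); s <- sd(base_kept)
  if (length(base_kept) > 1L && is.finite(s) && s > 0) {
    out_flag <- abs(base_kept - mu) > 2 * s
  } else {
    out_flag <- rep(FALSE, length(base_kept))
  }

  rows <- list(); info <- list()
  for (i in seq_along(kept)) {
    if (out_flag[i]) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(trial = kept_trials[i], reason = "baseline-outlier")
      next
    }
    tr <- kept[[i]]
    y <- tr$diameter - base_kept[i]
    out_idx <- which(tr$phase == "outcome")[seq_len(n_out)]
    if (anyNA(out_idx)) {
      stop("outcome phase shorter than the analysis window", call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- y[out_idx]
    info[[length(info) + 1L]] <- data.frame(
      participant_id = tr$participant_id[1],
      drug_state = tr$drug_state[1],
      condition = tr$condition[1],
      trial = tr$trial[1],
      baseline = base_kept[i],
      stringsAsFactors = FALSE)
  }

  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(trial = integer(0), reason = character(0))
  structure(list(
    outcome = if (length(rows)) do.call(rbind, rows) else
      matrix(NA_real_, 0, n_out),
    time_ms = (seq_len(n_out) - 1L) * dt * 1000,
    info = if (length(info)) do.call(rbind, info) else NULL,
    baselines = baselines,
    excluded = excluded,
    sampling_rate = fs), class = "pupil_trial_matrix")
}

#' First-order temporal derivative
#'
#' The signed difference between each timepoint and the previous one
#' (per-sample difference, not divided by the sampling interval; the
#' interval is carried in metadata by callers that need it).
#'
#' @param x Numeric vector (length >= 2), uniformly sampled.
#' @param dt Sampling interval, retained as an attribute only.
#' @return Vector of length `length(x) - 1`, element k = `x[k+1] - x[k]`.
#' @examples
#' temporal_derivative(c(1, 3, 2))  # 2, -1
#' @export
temporal_derivative <- function(x, dt = NULL) {
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  out <- diff(x)
  if (!is.null(dt)) attr(out, "dt") <- dt
  out
}

#' Z-score trial rows within participant x session groups
#'
#' Standardises all values of each group (subtract the group mean, divide
#' by the group SD over all retained samples, denominator n - 1), so each
#' group has mean 0 and SD 1 afterwards.
#'
#' @param m Numeric matrix (trials x time).
#' @param groups Factor or character vector, one entry per row, naming
#'   each row's participant x session group.
#' @return The matrix with each group's block standardised.
#' @export
zscore_within <- function(m, groups) {
  stopifnot(is.matrix(m), length(groups) == nrow(m))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    v <- m[idx, , drop = FALSE]
    if (length(v) < 2L) stop("group ", g, " has fewer than 2 values",
                             call. = FALSE)
    s <- sd(as.numeric(v))
    if (!is.finite(s) || s == 0) {
      stop("zero within-group variance in group ", g, call. = FALSE)
    }
    m[idx, ] <- (v - mean(v)) / s
  }
  m
}
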