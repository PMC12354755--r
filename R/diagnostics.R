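#' Split potential scale reduction statistic (split-Rhat)
#'
#' Computes the split-chain potential scale reduction statistic for each
#' parameter: every chain is split in half, and the ratio of pooled to
#' within-chain variance is formed across the resulting half-chains. A
#' value near 1 indicates the chains sample the same distribution; the
#' conventional convergence criterion is Rhat < 1.1 for all parameters.
#' Zero-variance (constant) parameters yield `NaN`, flagged in the
#' `"constant"` attribute rather than raising an error.
#'
#' @param x A `ql_posterior` object, or a numeric matrix of one
#'   parameter's draws with one column per chain.
#' @param ... Unused.
#' @return For a matrix, a single value. For a `ql_posterior`, a named
#'   vector (one entry per parameter) with attribute `"constant"` naming
#'   zero-variance parameters.
#' @export
rhat <- function(x, ...) UseMethod("rhat")

#' @rdname rhat
#' @export
rhat.matrix <- function(x, ...) {
  m <- ncol(x)
  if (m < 2L) stop("rhat needs at least 2 chains", call. = FALSE)
  n <- nrow(x)
  if (n < 4L) stop("rhat needs at least 4 draws per chain", call. = FALSE)
  half <- n %/% 2L
  split <- cbind(x[seq_len(half), , drop = FALSE],
                 x[(n - half + 1L):n, , drop = FALSE])
  .rhat_core(split)
}

.rhat_core <- function(split) {
  n <- nrow(split)
  w <- mean(apply(split, 2, var))
  if (!is.finite(w) || w == 0) return(NaN)
  b <- n * var(colMeans(split))
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' @rdname rhat
#' @export
rhat.ql_posterior <- function(x, ...) {
  chains <- sort(unique(x$chain))
  if (length(chains) < 2L) stop("rhat needs at least 2 chains",
                                call. = FALSE)
  out <- vapply(colnames(x$draws), function(p) {
    rhat.matrix(vapply(chains, function(cc) x$draws[x$chain == cc, p],
                       numeric(sum(x$chain == chains[1]))))
  }, numeric(1))
  attr(out, "constant") <- names(out)[is.nan(out)]
  out
}

#' Convergence report
#'
#' @param samples A `ql_posterior`.
#' @param threshold Flagging threshold on split-Rhat (default 1.1).
#' @return A list: `rhat` (named vector), `max_rhat`, `flagged` (names of
#'   parameters at or above the threshold), `converged`.
#' @export
convergence_report <- function(samples, threshold = 1.1) {
  r <- rhat(samples)
  flagged <- names(r)[!is.nan(r) & r >= threshold]
  list(rhat = r, max_rhat = max(r, na.rm = TRUE), flagged = flagged,
       converged = length(flagged) == 0L)
}

#' Graphical posterior predictive check of learning curves
#'
#' For `n_rep` posterior draws, simulates complete datasets for every
#' participant and drug state on their task schedules, bins trials, and
#' compares the observed per-bin hit-rate curve with the central 89%
#' interval of the replicated curves.
#'
#' @param samples A `ql_posterior`.
#' @param data The fitted `choice_data`; must carry a logical `hit` column
#'   (chose the advantageous option), as produced by [simulate_agent()].
#' @param n_rep Number of replicated datasets (>= 1).
#' @param seed Integer seed.
#' @param schedules Optional nested list `schedules[[pid]][[drug_state]]`
#'   of the schedules actually used (as returned by
#'   [generate_cohort_behaviour()]). When omitted, fresh default schedules
#'   of the observed trial counts are drawn per replicate.
#' @param bin_width Trials per bin for the learning curve (default 8).
#' @return A list: `bins` (data frame with observed and replicated
#'   per-bin hit rates: `observed`, `lo`, `hi`, `rep_mean`), `coverage`
#'   (fraction of bins whose observed value falls inside the central 89%
#'   replicated interval), `n_rep`.
#' @export
posterior_predictive_check <- function(samples, data, n_rep = 200L,
                                       seed = 1L, schedules = NULL,
                                       bin_width = 8L) {
  stopifnot(inherits(samples, "ql_posterior"))
  n_rep <- as.integer(n_rep)
  if (n_rep < 1L) stop("n_rep must be >= 1", call. = FALSE)
  data <- as.data.frame(data)
  if (!"hit" %in% names(data)) {
    stop("data must carry a `hit` column for the predictive check",
         call. = FALSE)
  }
  cond <- samples$metadata$condition
  data <- data[data$condition == cond, , drop = FALSE]
  ids <- samples$metadata$participants
  states <- if (samples$metadata$model == "crossover") {
    c("placebo", "atomoxetine")
  } else {
    unique(data$drug_state)
  }
  set.seed(seed)
  draw_idx <- sample.int(nrow(samples$draws), n_rep,
                         replace = n_rep > nrow(samples$draws))
  nat <- list()
  for (st in states) {
    nat[[st]] <- list(
      alpha = participant_natural_draws(samples, "alpha", if (st == "none")
        "placebo" else st),
      beta = participant_natural_draws(samples, "beta", if (st == "none")
        "placebo" else st))
  }

  n_trials <- max(data$trial) + 1L
  bins <- (seq_len(n_trials) - 1L) %/% bin_width
  u_bins <- sort(unique(bins))

  bin_curve <- function(df) {
    b <- df$trial %/% bin_width
    vapply(u_bins, function(k) mean(df$hit[b == k]), numeric(1))
  }
  observed <- bin_curve(data)

  bin_of_trial <- (seq_len(n_trials) - 1L) %/% bin_width
  bin_ind <- outer(u_bins, bin_of_trial, function(a, b)
    as.numeric(a == b))  # bins x trials indicator
  rep_curves <- matrix(NA_real_, n_rep, length(u_bins))
  for (r in seq_len(n_rep)) {
    i <- draw_idx[r]
    hit_sum <- numeric(length(u_bins))
    hit_n <- numeric(length(u_bins))
    for (pid in ids) {
      for (st in states) {
        sched <- if (!is.null(schedules)) {
          schedules[[pid]][[if (st == "none") 1L else st]]
        } else {
          generate_task_schedule(trials_per_condition = n_trials)
        }
        sched <- sched[sched$condition == cond, , drop = FALSE]
        sim <- cpp_simulate_choices(sched$correct_option,
                                    sched$outcome_correct,
                                    sched$outcome_incorrect,
                                    nat[[st]]$alpha[i, pid],
                                    nat[[st]]$beta[i, pid])
        h <- as.numeric(sim$hit)
        hit_sum <- hit_sum + as.numeric(bin_ind[, seq_along(h)] %*% h)
        hit_n <- hit_n + rowSums(bin_ind[, seq_along(h), drop = FALSE])
      }
    }
    rep_curves[r, ] <- hit_sum / hit_n
  }

  lo <- apply(rep_curves, 2, stats::quantile, probs = 0.055, names = FALSE)
  hi <- apply(rep_curves, 2, stats::quantile, probs = 0.945, names = FALSE)
  inside <- observed >= lo & observed <= hi
  list(bins = data.frame(bin = u_bins, observed = observed, lo = lo,
                         hi = hi, rep_mean = colMeans(rep_curves)),
       coverage = mean(inside), n_rep = n_rep)
}
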