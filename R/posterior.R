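#' Probability of direction
#'
#' The proportion of a posterior sample that is strictly positive or
#' strictly negative, whichever is greater, expressed in percent. Zeros
#' count towards neither side (so they reduce both proportions).
#'
#' @param x Numeric vector of posterior samples (non-empty).
#' @return A percentage in \[50, 100\] (below 50 is impossible for a
#'   zero-free sample; ties with many zeros can fall below 50 and are
#'   returned as computed).
#' @examples
#' probability_of_direction(c(1, 2, -1, 3))  # 75
#' @export
probability_of_direction <- function(x) {
  if (length(x) == 0L) stop("empty sample vector", call. = FALSE)
  if (!all(is.finite(x))) stop("samples must be finite", call. = FALSE)
  100 * max(sum(x > 0), sum(x < 0)) / length(x)
}

#' Highest density interval
#'
#' The narrowest contiguous interval containing a given posterior mass,
#' computed from sorted samples (unimodality assumed). When several
#' windows tie on width, the one with the smallest lower bound is
#' returned.
#'
#' @param x Numeric vector of posterior samples.
#' @param mass Probability mass in (0, 1); default 0.89.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' hdi(rnorm(1e4), mass = 0.89)
#' @export
hdi <- function(x, mass = 0.89) {
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass >= 1) {
    stop("mass must lie in (0, 1)", call. = FALSE)
  }
  n <- length(x)
  if (n < ceiling(1 / (1 - mass))) {
    stop("too few samples for the requested mass", call. = FALSE)
  }
  xs <- sort(x)
  k <- ceiling(mass * n)
  n_win <- n - k + 1L
  widths <- xs[k:n] - xs[seq_len(n_win)]
  i <- which.min(widths)  # first minimum = smallest lower bound
  c(lower = xs[i], upper = xs[i + k - 1L])
}

#' Fraction of the posterior inside the region of practical equivalence
#'
#' The ROPE is `0 +/- 0.1 * SD`, where SD is a point estimate (posterior
#' median) of the group-level standard deviation of the parameter under
#' consideration; 0.1 standardised units is half of the conventional
#' "small" effect. Decisions: `< 2.5%` inside favours rejecting the null
#' ("reject-null"), `> 97.5%` favours accepting it ("accept-null"),
#' otherwise "undecided".
#'
#' @param x Numeric vector of posterior samples of the contrast.
#' @param group_sd_point_estimate Positive scalar SD point estimate.
#' @return A list: `rope` (interval), `pct_inside` (percent of the whole
#'   posterior inside the ROPE), `decision`.
#' @examples
#' rope_fraction(rnorm(1000, 2, 0.1), 1)
#' @export
rope_fraction <- function(x, group_sd_point_estimate) {
  if (!is.numeric(group_sd_point_estimate) ||
      length(group_sd_point_estimate) != 1L ||
      !is.finite(group_sd_point_estimate) ||
      group_sd_point_estimate <= 0) {
    stop("group_sd_point_estimate must be a positive scalar", call. = FALSE)
  }
  if (length(x) == 0L) stop("empty sample vector", call. = FALSE)
  half <- 0.1 * group_sd_point_estimate
  pct <- 100 * sum(x >= -half & x <= half) / length(x)
  decision <- if (pct < 2.5) "reject-null" else if (pct > 97.5)
    "accept-null" else "undecided"
  list(rope = c(lower = -half, upper = half), pct_inside = pct,
       decision = decision)
}

#' Drug contrast of group-level natural-scale means
#'
#' Per-draw difference (atomoxetine minus placebo) of a group-level
#' natural-scale mean, computed draw-wise on the MCMC samples (never on
#' summaries).
#'
#' @param samples A crossover `ql_posterior`.
#' @param parameter `"alpha"` or `"beta"`.
#' @return An object of class `contrast_posterior`: numeric vector of
#'   per-draw differences with a `label` attribute.
#' @export
drug_contrast <- function(samples, parameter = c("alpha", "beta")) {
  parameter <- match.arg(parameter)
  if (samples$metadata$model != "crossover") {
    stop("drug_contrast requires a crossover fit", call. = FALSE)
  }
  v <- group_natural_draws(samples, parameter, "atomoxetine") -
    group_natural_draws(samples, parameter, "placebo")
  structure(v, label = paste0("delta_", parameter, "_",
                              samples$metadata$condition),
            class = c("contrast_posterior", "numeric"))
}

#' Summarise a posterior contrast
#'
#' Median, 89% HDI, probability of direction and ROPE fraction for a
#' contrast vector, in the house style of the group-level analyses.
#'
#' @param x Numeric vector of per-draw contrast values.
#' @param group_sd Positive SD point estimate defining the ROPE.
#' @param mass HDI mass (default 0.89).
#' @return A list with `median`, `hdi`, `p_dir`, `rope_pct`, `decision`.
#' @export
summarize_contrast <- function(x, group_sd, mass = 0.89) {
  rp <- rope_fraction(as.numeric(x), group_sd)
  list(median = median(x), hdi = hdi(as.numeric(x), mass),
       p_dir = probability_of_direction(as.numeric(x)),
       rope_pct = rp$pct_inside, decision = rp$decision)
}

#' Posterior median of a group-level natural-scale SD
#'
#' Point estimate of the between-participant SD of a natural-scale
#' parameter, used to set the ROPE for drug contrasts: per draw, the SD
#' across participants of the natural-scale parameter values (placebo
#' state), summarised by the posterior median.
#'
#' @param samples A `ql_posterior`.
#' @param parameter `"alpha"` or `"beta"`.
#' @param drug_state Drug state over which to take the spread.
#' @return A positive scalar.
#' @export
group_sd_point_estimate <- function(samples,
                                    parameter = c("alpha", "beta"),
                                    drug_state = "placebo") {
  m <- participant_natural_draws(samples, match.arg(parameter), drug_state)
  median(apply(m, 1, sd))
}
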