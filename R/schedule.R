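#' Generate a probabilistic reward task schedule
#'
#' Builds the trial list for a session of the two-condition probabilistic
#' learning task: by default 48 gain and 48 loss trials, interleaved in
#' randomised blocks of 12 (6 gain + 6 loss per block). Each condition has
#' one stimulus pair; option 1 ("option_A") is the advantageous option.
#' Per trial, the payoff the agent would receive from each option is drawn
#' independently: the advantageous option yields the better outcome with
#' probability `contingency` (default 0.75), the other option with
#' probability `1 - contingency`. Gain outcomes are +0.5/0 pounds; loss
#' outcomes are 0/-0.5.
#'
#' @param trials_per_condition Trials per condition (default 48).
#' @param block_size Block length for condition interleaving (default 12;
#'   must be even and divide `2 * trials_per_condition`).
#' @param contingency Probability that the advantageous option carries the
#'   better outcome on a trial (default 0.75).
#' @param exact_counts If `TRUE`, realise the contingency with exact counts
#'   per condition instead of i.i.d. draws (default `FALSE`).
#' @param seed Optional integer seed; when supplied the schedule is
#'   reproducible.
#' @return A `task_schedule` data frame with columns `condition`,
#'   `trial` (0-based within condition), `correct_option` (always 1),
#'   `outcome_correct`, `outcome_incorrect` and attribute `block_size`.
#' @examples
#' sched <- generate_task_schedule(seed = 1)
#' table(sched$condition)
#' @export
generate_task_schedule <- function(trials_per_condition = 48L,
                                   block_size = 12L,
                                   contingency = 0.75,
                                   exact_counts = FALSE,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trials_per_condition <- as.integer(trials_per_condition)
  block_size <- as.integer(block_size)
  if (trials_per_condition < 1L) stop("need at least one trial per condition")
  if (block_size < 2L || block_size %% 2L != 0L) {
    stop("block_size must be an even integer >= 2", call. = FALSE)
  }
  total <- 2L * trials_per_condition
  if (total %% block_size != 0L) {
    stop("trials per condition not divisible into blocks of block_size",
         call. = FALSE)
  }
  if (contingency < 0 || contingency > 1) {
    stop("contingency must lie in [0, 1]", call. = FALSE)
  }

  half <- block_size %/% 2L
  n_blocks <- total %/% block_size
  cond <- unlist(lapply(seq_len(n_blocks), function(b) {
    sample(rep(c("gain", "loss"), each = half))
  }))

  draw_good <- function(n) {
    if (exact_counts) {
      k <- round(contingency * n)
      sample(c(rep(TRUE, k), rep(FALSE, n - k)))
    } else {
      stats::runif(n) < contingency
    }
  }

  sched <- data.frame(condition = cond,
                      trial = NA_integer_,
                      correct_option = 1L,
                      outcome_correct = NA_real_,
                      outcome_incorrect = NA_real_,
                      stringsAsFactors = FALSE)
  for (cc in c("gain", "loss")) {
    idx <- which(cond == cc)
    n <- length(idx)
    good_c <- draw_good(n)           # advantageous option gets better payoff
    good_i <- !draw_good(n)          # other option: better payoff w.p. 1 - p
    if (cc == "gain") {
      better <- 0.5; worse <- 0
    } else {
      better <- 0; worse <- -0.5
    }
    sched$trial[idx] <- seq_len(n) - 1L
    sched$outcome_correct[idx] <- ifelse(good_c, better, worse)
    sched$outcome_incorrect[idx] <- ifelse(good_i, better, worse)
  }
  attr(sched, "block_size") <- block_size
  attr(sched, "contingency") <- contingency
  class(sched) <- c("task_schedule", "data.frame")
  sched
}
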