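#' Agent parameters for the two-parameter Q-learning model
#'
#' Bundles a learning rate `alpha` and an inverse temperature `beta` with
#' hard bound checks. `alpha` weights the prediction error in the
#' delta-rule update; `beta` scales expected-value differences in the
#' softmax choice rule. Bounds (`alpha` in \[0, 1\], `beta` in \[0, 10\])
#' match the fitted model's support.
#'
#' @param alpha Learning rate, in \[0, 1\].
#' @param beta Inverse temperature, in \[0, 10\].
#' @return An object of class `agent_parameters` (a named list).
#' @examples
#' agent_parameters(0.3, 5)
#' @export
agent_parameters <- function(alpha, beta) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("`alpha` must be a single finite value in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta < 0 || beta > 10) {
    stop("`beta` must be a single finite value in [0, 10]", call. = FALSE)
  }
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "agent_parameters")
}

#' @export
print.agent_parameters <- function(x, ...) {
  cat(sprintf("Q-learning agent: alpha = %.4g, beta = %.4g\n",
              x$alpha, x$beta))
  invisible(x)
}

#' Rescorla-Wagner delta-rule update
#'
#' Updates the expected value (Q-value) of the chosen stimulus-action pair
#' towards the observed outcome by a fraction `alpha` of the prediction
#' error: `q + alpha * (r - q)`. With `alpha = 0` the value never moves;
#' with `alpha = 1` it jumps to the last outcome.
#'
#' @param q Current Q-value (finite numeric).
#' @param alpha Learning rate in \[0, 1\].
#' @param r Observed outcome (finite numeric, same units as `q`).
#' @return The updated Q-value. Vectorised over `q` and `r`.
#' @examples
#' rescorla_wagner_update(0, 0.5, 1)   # 0.5
#' rescorla_wagner_update(0.2, 0, 1)   # 0.2 -- no learning
#' @export
rescorla_wagner_update <- function(q, alpha, r) {
  if (!all(is.finite(q)) || !all(is.finite(r)) || !all(is.finite(alpha))) {
    stop("inputs to rescorla_wagner_update must be finite", call. = FALSE)
  }
  if (any(alpha < 0 | alpha > 1)) {
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  }
  q + alpha * (r - q)
}

#' Softmax probability of the chosen action
#'
#' Probability of choosing an action with value `q_chosen` over the
#' alternative with value `q_alternative` under the two-option softmax
#' rule with inverse temperature `beta`. Computed via the logistic of
#' `beta * (q_chosen - q_alternative)`, which is the max-subtracted
#' (numerically stable) form of the two-option softmax.
#'
#' @param q_chosen,q_alternative Finite Q-values.
#' @param beta Inverse temperature in \[0, 10\].
#' @return Probability in (0, 1). Vectorised.
#' @examples
#' softmax_probability(0.5, 0, 10)  # 1 / (1 + exp(-5))
#' @export
softmax_probability <- function(q_chosen, q_alternative, beta) {
  if (!all(is.finite(q_chosen)) || !all(is.finite(q_alternative))) {
    stop("Q-values must be finite", call. = FALSE)
  }
  if (any(!is.finite(beta) | beta < 0 | beta > 10)) {
    stop("`beta` must lie in [0, 10]", call. = FALSE)
  }
  stats::plogis(beta * (q_chosen - q_alternative))
}

# Validate/normalise a choice dataset data frame (class choice_data).
as_choice_data <- function(df) {
  needed <- c("participant_id", "drug_state", "condition", "trial",
              "action", "outcome")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("choice data missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"rt" %in% names(df)) df$rt <- NA_real_
  df$drug_state <- as.character(df$drug_state)
  df$condition <- as.character(df$condition)
  if (!all(df$drug_state %in% c("placebo", "atomoxetine", "none"))) {
    stop("drug_state must be placebo, atomoxetine or none", call. = FALSE)
  }
  if (!all(df$condition %in% c("gain", "loss"))) {
    stop("condition must be gain or loss", call. = FALSE)
  }
  bad_gain <- df$condition == "gain" & !df$outcome %in% c(0.5, 0)
  bad_loss <- df$condition == "loss" & !df$outcome %in% c(-0.5, 0)
  if (any(bad_gain) || any(bad_loss)) {
    stop("outcomes must be {+0.5, 0} on gain and {0, -0.5} on loss trials",
         call. = FALSE)
  }
  key <- interaction(df$participant_id, df$drug_state, df$condition,
                     drop = TRUE)
  if (any(tapply(df$trial, key, function(tr) anyDuplicated(tr) > 0L))) {
    stop("duplicated trial indices within participant/drug/condition",
         call. = FALSE)
  }
  class(df) <- c("choice_data", "data.frame")
  df
}

#' Simulate a Q-learning agent on a task schedule
#'
#' Runs one agent forward through a schedule: on each trial the choice is
#' sampled from the softmax probabilities, the scheduled payoff for the
#' picked option is delivered, and the chosen option's Q-value is updated
#' by the delta rule. Each task condition (gain/loss) has its own pair of
#' Q-values, initialised at 0 so the first choice is uniform.
#'
#' @param params An [agent_parameters] object, or a list with per-condition
#'   elements `gain` and `loss` (each an [agent_parameters]) when the
#'   schedule mixes conditions.
#' @param schedule A `task_schedule` from [generate_task_schedule()].
#' @param participant_id,drug_state Identity columns stamped on the output.
#' @return A `choice_data` data frame with one row per scheduled trial:
#'   `participant_id`, `drug_state`, `condition`, `trial` (0-based within
#'   condition), `action` ("option_A"/"option_B"), `outcome`, `rt` (NA),
#'   `hit` (chose the advantageous option).
#' @examples
#' sched <- generate_task_schedule(seed = 1)
#' set.seed(2)
#' dat <- simulate_agent(agent_parameters(0.3, 5), sched)
#' mean(dat$hit)
#' @export
simulate_agent <- function(params, schedule, participant_id = "sim",
                           drug_state = "none") {
  stopifnot(inherits(schedule, "task_schedule"))
  if (nrow(schedule) == 0L) stop("empty schedule", call. = FALSE)
  if (inherits(params, "agent_parameters")) {
    params <- list(gain = params, loss = params)
  }
  out <- vector("list", 2L)
  names(out) <- c("gain", "loss")
  for (cond in c("gain", "loss")) {
    sub <- schedule[schedule$condition == cond, , drop = FALSE]
    if (nrow(sub) == 0L) next
    p <- params[[cond]]
    stopifnot(inherits(p, "agent_parameters"))
    sim <- cpp_simulate_choices(sub$correct_option, sub$outcome_correct,
                                sub$outcome_incorrect, p$alpha, p$beta)
    out[[cond]] <- data.frame(
      participant_id = participant_id,
      drug_state = drug_state,
      condition = cond,
      trial = seq_len(nrow(sub)) - 1L,
      action = ifelse(sim$action == 1L, "option_A", "option_B"),
      outcome = sim$outcome,
      rt = NA_real_,
      hit = sim$hit,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  as_choice_data(res)
}

# Chosen-option index (1/2) from the action labels.
.chosen_index <- function(action) {
  ifelse(action == "option_A", 1L, 2L)
}

#' Choice log-likelihood of one trial sequence
#'
#' Sum over trials of the log softmax probability of the observed choice,
#' with Q-values evolved along the observed choice/outcome sequence by the
#' delta rule (Q0 = 0). The data must be a single participant x condition x
#' drug-state sequence.
#'
#' @param data A `choice_data` data frame (one sequence).
#' @param params An [agent_parameters] object.
#' @return The log-likelihood in nats (finite, non-positive).
#' @examples
#' sched <- generate_task_schedule(seed = 1)
#' set.seed(1)
#' dat <- simulate_agent(agent_parameters(0.3, 5), sched)
#' gain <- dat[dat$condition == "gain", ]
#' choice_log_likelihood(gain, agent_parameters(0.3, 5))
#' @export
choice_log_likelihood <- function(data, params) {
  stopifnot(inherits(params, "agent_parameters"))
  data <- as_choice_data(as.data.frame(data))
  key <- unique(data[c("participant_id", "drug_state", "condition")])
  if (nrow(key) != 1L) {
    stop("data must be one participant x drug-state x condition sequence",
         call. = FALSE)
  }
  if (is.unsorted(data$trial, strictly = TRUE)) {
    stop("trial indices must be strictly increasing", call. = FALSE)
  }
  cpp_choice_loglik(.chosen_index(data$action), data$outcome,
                    params$alpha, params$beta)
}

#' Read / write choice datasets
#'
#' Delimited-text interchange for trial tables: one trial per row, columns
#' `participant_id, drug_state, condition, trial, action, outcome, rt`,
#' header required, UTF-8.
#'
#' @param path File path.
#' @param data A `choice_data` data frame.
#' @return `read_choice_data` returns a validated `choice_data` data frame;
#'   `write_choice_data` returns `path` invisibly.
#' @export
read_choice_data <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_choice_data(df)
}

#' @rdname read_choice_data
#' @export
write_choice_data <- function(data, path) {
  data <- as_choice_data(as.data.frame(data))
  cols <- c("participant_id", "drug_state", "condition", "trial",
            "action", "outcome", "rt")
  utils::write.csv(data[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
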