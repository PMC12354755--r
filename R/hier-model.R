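#' Probit-scale to natural-scale parameter transform
#'
#' Maps non-centred hierarchical quantities to natural-scale agent
#' parameters. The probit-scale participant value is
#' `mu + sigma * nu` (plus the drug offset `delta` under atomoxetine), and
#' the natural scale is reached through the standard normal CDF:
#' `alpha = pnorm(alpha_prime)`, `beta = 10 * pnorm(beta_prime)`.
#'
#' @param draw A named list with `mu_alpha`, `sigma_alpha`, `nu_alpha`,
#'   `mu_beta`, `sigma_beta`, `nu_beta` and, for crossover draws,
#'   `delta_alpha` and `delta_beta` (participant-level offsets, already
#'   composed as `mu_delta + sigma_delta * nu_delta`).
#' @param drug_state `"placebo"` (offsets ignored) or `"atomoxetine"`
#'   (offsets added on the probit scale before the transform).
#' @return An [agent_parameters] object.
#' @examples
#' transform_to_natural(list(mu_alpha = 0, sigma_alpha = 1, nu_alpha = 0,
#'                           mu_beta = 0, sigma_beta = 1, nu_beta = 0))
#' @export
transform_to_natural <- function(draw,
                                 drug_state = c("placebo", "atomoxetine")) {
  drug_state <- match.arg(drug_state)
  a_pr <- draw$mu_alpha + draw$sigma_alpha * draw$nu_alpha
  b_pr <- draw$mu_beta + draw$sigma_beta * draw$nu_beta
  if (drug_state == "atomoxetine") {
    a_pr <- a_pr + (draw$delta_alpha %||% 0)
    b_pr <- b_pr + (draw$delta_beta %||% 0)
  }
  agent_parameters(pnorm(a_pr), 10 * pnorm(b_pr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a hierarchical Q-learning model specification
#'
#' Prepares the joint log-density (priors plus choice log-likelihoods) for
#' one task condition. Priors: standard normal on all group means `mu` and
#' participant deviations `nu`; half-normal(0, 1) on all group SDs `sigma`
#' (sampled on the log scale with the Jacobian included). The `crossover`
#' design adds group-level location/scale pairs and participant deviations
#' for the drug offsets `delta_alpha`, `delta_beta`; the `single_session`
#' design has none.
#'
#' @param data A `choice_data` data frame.
#' @param condition `"gain"` or `"loss"`; the model is fit per condition.
#' @param design `"crossover"` (both drug states per participant) or
#'   `"single_session"`.
#' @return An object of class `ql_model` with the parameter layout, data
#'   arrays and a `log_post(theta)` function returning `list(lp, grad)`.
#' @examples
#' coh <- generate_cohort_behaviour(cohort_ground_truth(), 4, seed = 1)
#' m <- build_model(coh$data, "gain", "crossover")
#' m$n_par
#' @export
build_model <- function(data, condition = c("gain", "loss"),
                        design = c("crossover", "single_session")) {
  condition <- match.arg(condition)
  design <- match.arg(design)
  crossover <- design == "crossover"
  data <- as_choice_data(as.data.frame(data))
  data <- data[data$condition == condition, , drop = FALSE]
  if (nrow(data) == 0L) stop("no trials for condition ", condition,
                             call. = FALSE)
  participants <- sort(unique(data$participant_id))
  n_sub <- length(participants)

  seq_pid <- integer(0); seq_sess <- integer(0)
  seq_start <- integer(0); seq_len <- integer(0)
  chosen <- integer(0); outcome <- numeric(0)
  for (j in seq_along(participants)) {
    sub <- data[data$participant_id == participants[j], , drop = FALSE]
    states <- unique(sub$drug_state)
    if (crossover &&
        !all(c("placebo", "atomoxetine") %in% states)) {
      stop("participant ", participants[j],
           " lacks a drug state required by the crossover design",
           call. = FALSE)
    }
    if (!crossover && length(states) != 1L) {
      stop("single_session design expects one session per participant",
           call. = FALSE)
    }
    for (st in states) {
      ss <- sub[sub$drug_state == st, , drop = FALSE]
      ss <- ss[order(ss$trial), , drop = FALSE]
      if (anyDuplicated(ss$trial)) {
        stop("duplicated trial indices for ", participants[j], call. = FALSE)
      }
      seq_pid <- c(seq_pid, j - 1L)
      seq_sess <- c(seq_sess, if (st == "atomoxetine") 1L else 0L)
      seq_start <- c(seq_start, length(chosen))
      seq_len <- c(seq_len, nrow(ss))
      chosen <- c(chosen, .chosen_index(ss$action))
      outcome <- c(outcome, ss$outcome)
    }
  }

  if (crossover) {
    theta_names <- c("mu_alpha", "mu_beta", "mu_delta_alpha",
                     "mu_delta_beta", "log_sigma_alpha", "log_sigma_beta",
                     "log_sigma_delta_alpha", "log_sigma_delta_beta",
                     paste0("nu_alpha[", participants, "]"),
                     paste0("nu_beta[", participants, "]"),
                     paste0("nu_delta_alpha[", participants, "]"),
                     paste0("nu_delta_beta[", participants, "]"))
  } else {
    theta_names <- c("mu_alpha", "mu_beta", "log_sigma_alpha",
                     "log_sigma_beta",
                     paste0("nu_alpha[", participants, "]"),
                     paste0("nu_beta[", participants, "]"))
  }

  model <- list(condition = condition, design = design,
                crossover = crossover,
                participants = participants, n_sub = n_sub,
                n_par = length(theta_names), theta_names = theta_names,
                arrays = list(seq_pid = seq_pid, seq_sess = seq_sess,
                              seq_start = seq_start, seq_len = seq_len,
                              chosen = chosen, outcome = outcome))
  model$log_post <- function(theta) {
    cpp_hier_lpgrad(theta, n_sub, crossover,
                    model$arrays$seq_pid, model$arrays$seq_sess,
                    model$arrays$seq_start, model$arrays$seq_len,
                    model$arrays$chosen, model$arrays$outcome)
  }
  class(model) <- "ql_model"
  model
}

#' @export
print.ql_model <- function(x, ...) {
  cat(sprintf("Hierarchical Q-learning model (%s, %s): %d participants, %d parameters\n",
              x$condition, x$design, x$n_sub, x$n_par))
  invisible(x)
}
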