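#' Hierarchical ground truth for a simulated crossover cohort
#'
#' Group-level hyperparameters of the generative model on the probit
#' (unconstrained) scale. Per participant and condition, deviations `nu`
#' are drawn standard normal and natural-scale parameters are obtained by
#' the probit transform: `alpha = pnorm(mu_alpha + sigma_alpha * nu)`,
#' `beta = 10 * pnorm(mu_beta + sigma_beta * nu)`; under atomoxetine a
#' participant-specific offset `Delta = mu_delta + sigma_delta * nu_delta`
#' is added before the transform.
#'
#' Defaults mirror a moderately exploratory placebo cohort (mean alpha
#' around 0.1, mean beta around 2.7) with a positive drug effect on beta
#' of roughly +3 natural units at the group level and no drug effect on
#' alpha.
#'
#' @param mu_alpha,mu_beta Group means (probit scale).
#' @param sigma_alpha,sigma_beta Group SDs (probit scale, >= 0).
#' @param mu_delta_alpha,mu_delta_beta Drug-offset means (probit scale).
#' @param sigma_delta_alpha,sigma_delta_beta Drug-offset SDs (>= 0).
#' @return An object of class `cohort_ground_truth`.
#' @export
cohort_ground_truth <- function(mu_alpha = qnorm(0.10),
                                mu_beta = qnorm(0.27),
                                sigma_alpha = 0.4,
                                sigma_beta = 0.4,
                                mu_delta_alpha = 0,
                                mu_delta_beta = 0.79,
                                sigma_delta_alpha = 0.2,
                                sigma_delta_beta = 0.3) {
  vals <- list(mu_alpha = mu_alpha, mu_beta = mu_beta,
               sigma_alpha = sigma_alpha, sigma_beta = sigma_beta,
               mu_delta_alpha = mu_delta_alpha,
               mu_delta_beta = mu_delta_beta,
               sigma_delta_alpha = sigma_delta_alpha,
               sigma_delta_beta = sigma_delta_beta)
  if (!all(vapply(vals, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v), logical(1)))) {
    stop("all hyperparameters must be single finite numbers", call. = FALSE)
  }
  if (sigma_alpha < 0 || sigma_beta < 0 || sigma_delta_alpha < 0 ||
      sigma_delta_beta < 0) {
    stop("group SDs must be non-negative", call. = FALSE)
  }
  structure(vals, class = "cohort_ground_truth")
}

#' Simulate a crossover cohort with known ground truth
#'
#' Draws `n_participants` Q-learning agents from the hierarchical
#' generative model and simulates a placebo and an atomoxetine session for
#' each, on independent task schedules. Per participant and condition,
#' probit-scale deviations are drawn standard normal; atomoxetine
#' parameters add the participant's drug offset on the probit scale before
#' transforming to natural scale. The exact parameter values used are
#' returned alongside the behaviour.
#'
#' @param truth A [cohort_ground_truth] object. Used for both task
#'   conditions (deviations are drawn independently per condition).
#' @param n_participants Number of participants (>= 1).
#' @param schedule_config Named list passed to [generate_task_schedule()]
#'   (e.g. `list(trials_per_condition = 48)`).
#' @param seed Optional integer seed for full reproducibility.
#' @return A list with elements:
#'   \describe{
#'     \item{data}{`choice_data` data frame of all trials, participants
#'       `P01`, `P02`, ... and both drug states.}
#'     \item{truth}{the input hyperparameters.}
#'     \item{participants}{data frame of per-participant natural-scale
#'       `alpha`/`beta` per condition and drug state, plus the latent
#'       deviations.}
#'     \item{schedules}{nested list `schedules[[pid]][[drug_state]]` of the
#'       task schedules used.}
#'   }
#' @examples
#' coh <- generate_cohort_behaviour(cohort_ground_truth(), 3, seed = 1)
#' head(coh$participants)
#' @export
generate_cohort_behaviour <- function(truth = cohort_ground_truth(),
                                      n_participants,
                                      schedule_config = list(),
                                      seed = NULL) {
  stopifnot(inherits(truth, "cohort_ground_truth"))
  n_participants <- as.integer(n_participants)
  if (n_participants < 1L) stop("n_participants must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  ids <- sprintf("P%02d", seq_len(n_participants))
  data_rows <- list()
  part_rows <- list()
  schedules <- list()

  for (j in seq_len(n_participants)) {
    pid <- ids[j]
    schedules[[pid]] <- list()
    # independent deviations per condition (models are fit per condition)
    pars <- list()
    for (cond in c("gain", "loss")) {
      nu <- stats::rnorm(4L) # alpha, beta, delta_alpha, delta_beta
      a_pr <- truth$mu_alpha + truth$sigma_alpha * nu[1]
      b_pr <- truth$mu_beta + truth$sigma_beta * nu[2]
      d_a <- truth$mu_delta_alpha + truth$sigma_delta_alpha * nu[3]
      d_b <- truth$mu_delta_beta + truth$sigma_delta_beta * nu[4]
      pars[[cond]] <- list(
        placebo = agent_parameters(pnorm(a_pr), 10 * pnorm(b_pr)),
        atomoxetine = agent_parameters(pnorm(a_pr + d_a),
                                       10 * pnorm(b_pr + d_b)))
      part_rows[[length(part_rows) + 1L]] <- data.frame(
        participant_id = pid, condition = cond,
        alpha_placebo = pars[[cond]]$placebo$alpha,
        beta_placebo = pars[[cond]]$placebo$beta,
        alpha_atomoxetine = pars[[cond]]$atomoxetine$alpha,
        beta_atomoxetine = pars[[cond]]$atomoxetine$beta,
        nu_alpha = nu[1], nu_beta = nu[2],
        nu_delta_alpha = nu[3], nu_delta_beta = nu[4],
        stringsAsFactors = FALSE)
    }
    for (drug in c("placebo", "atomoxetine")) {
      sched <- do.call(generate_task_schedule, schedule_config)
      schedules[[pid]][[drug]] <- sched
      sim <- simulate_agent(list(gain = pars$gain[[drug]],
                                 loss = pars$loss[[drug]]),
                            sched, participant_id = pid, drug_state = drug)
      data_rows[[length(data_rows) + 1L]] <- sim
    }
  }

  data <- do.call(rbind, data_rows)
  rownames(data) <- NULL
  list(data = as_choice_data(data),
       truth = truth,
       participants = do.call(rbind, part_rows),
       schedules = schedules)
}
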