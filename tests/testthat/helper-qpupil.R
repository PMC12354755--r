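# Shared fixtures, built in code. The small crossover fit is computed once
# per test run and reused by several files.

.qp_cache <- new.env(parent = emptyenv())

shared_cohort <- function() {
  if (is.null(.qp_cache$coh)) {
    .qp_cache$coh <- generate_cohort_behaviour(cohort_ground_truth(), 20,
                                               seed = 42)
  }
  .qp_cache$coh
}

# Reduced-sampling gain-condition crossover fit of the shared cohort.
shared_fit <- function() {
  if (is.null(.qp_cache$fit)) {
    m <- build_model(shared_cohort()$data, "gain", "crossover")
    .qp_cache$fit <- sample_posterior(m, chains = 4, iter = 2000,
                                      warmup = 1000, seed = 7)
  }
  .qp_cache$fit
}

# Hand-built crossover posterior object with fully controlled draws, for
# exercising draw-wise operations without MCMC.
fake_posterior <- function(draws_list, ids, condition = "gain") {
  n <- length(draws_list[[1]])
  draws <- do.call(cbind, draws_list)
  colnames(draws) <- names(draws_list)
  structure(list(draws = draws,
                 chain = rep(1:2, length.out = n),
                 metadata = list(n_chains = 2, n_iterations = n,
                                 n_warmup = 0, seed = 0,
                                 model = "crossover",
                                 condition = condition,
                                 participants = ids,
                                 n_sub = length(ids))),
            class = "ql_posterior")
}

# Columns required for a crossover posterior over `ids`, all constant.
fake_crossover_cols <- function(ids, n = 50,
                                mu_alpha = 0, mu_beta = 0,
                                mu_delta_alpha = 0, mu_delta_beta = 0,
                                sigma = 0.5, nu = NULL) {
  cols <- list(mu_alpha = rep(mu_alpha, n), mu_beta = rep(mu_beta, n),
               mu_delta_alpha = rep(mu_delta_alpha, n),
               mu_delta_beta = rep(mu_delta_beta, n),
               log_sigma_alpha = rep(log(sigma), n),
               log_sigma_beta = rep(log(sigma), n),
               log_sigma_delta_alpha = rep(log(sigma), n),
               log_sigma_delta_beta = rep(log(sigma), n))
  for (p in c("nu_alpha", "nu_beta", "nu_delta_alpha", "nu_delta_beta")) {
    for (j in seq_along(ids)) {
      v <- if (is.null(nu)) rep(0, n) else rep(nu[[p]][j], n)
      cols[[paste0(p, "[", ids[j], "]")]] <- v
    }
  }
  cols
}

# Constant-diameter pupil traces for hand-built preprocessing fixtures:
# one participant/session, `baselines` gives the flat diameter per trial.
flat_pupil_traces <- function(baselines, fs = 50, fixation_s = 1,
                              stimulus_s = 1, outcome_s = 1.5,
                              participant_id = "P01",
                              drug_state = "placebo") {
  dt <- 1 / fs
  n_fix <- round(fixation_s * fs); n_stim <- round(stimulus_s * fs)
  n_out <- round(outcome_s * fs)
  phase <- rep(c("fixation", "stimulus", "outcome"),
               c(n_fix, n_stim, n_out))
  tt <- (seq_along(phase) - 1) * dt
  out <- do.call(rbind, lapply(seq_along(baselines), function(i) {
    data.frame(participant_id = participant_id, drug_state = drug_state,
               condition = "gain", trial = i - 1L, phase = phase,
               time_s = tt, diameter = baselines[i],
               stringsAsFactors = FALSE)
  }))
  attr(out, "sampling_rate") <- fs
  class(out) <- c("pupil_traces", "data.frame")
  out
}
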